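#' Position-by-position nucleotide composition around poly(A) sites
#'
#' For each site, extracts the genomic sequence from `-upstream` to
#' `+downstream` around the cleavage coordinate on the site's sense strand
#' (reverse-complemented for minus-strand sites; position 0 is the cleavage
#' site, negative positions are transcribed upstream) and tallies per-position
#' base fractions. A genuine poly(A) site shows the canonical tripartite
#' signal: a U-rich far-upstream element, an A-rich element near -20, and a
#' U-rich region embedding the YA cleavage dinucleotide; randomly placed
#' sites give a flat profile near 0.25. T is reported as U (transcript-space
#' convention).
#'
#' Sites whose window would cross a chromosome edge are dropped and counted
#' in the `n_dropped` attribute.
#'
#' @param sites Tibble with `chrom`, `strand` and a position column (`summit`
#'   or `pos`).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param window Integer `c(upstream, downstream)` in nt.
#' @param stratum Label stored with the profile.
#' @return A `pa_profile` tibble: `stratum`, `position` (-upstream..downstream),
#'   `base` (A/C/G/U), `frac`, `n_sites`; attributes `n_dropped`, `window`.
#' @export
composition_profile <- function(sites, genome, window = c(300L, 100L),
                                stratum = "all") {
  if (nrow(sites) == 0) stop("empty site list", call. = FALSE)
  pos <- if ("summit" %in% names(sites)) sites[["summit"]] else
    sites[["pos"]]
  if (is.null(pos)) stop("sites must have a 'summit' or 'pos' column",
                         call. = FALSE)
  up <- as.integer(window[1])
  down <- as.integer(window[2])
  len <- .chrom_lengths(genome)[sites$chrom]
  s <- if_else(sites$strand == "+", pos - up, pos - down)
  e <- if_else(sites$strand == "+", pos + down, pos + up)
  ok <- s >= 1L & e <= len
  n_drop <- sum(!ok)
  if (!any(ok)) stop("all sites dropped: windows exceed chromosome bounds",
                     call. = FALSE)
  seqs <- .extract_sense(genome, sites$chrom[ok], s[ok], e[ok],
                         sites$strand[ok])
  ss <- Biostrings::DNAStringSet(seqs)
  cm <- Biostrings::consensusMatrix(ss, as.prob = TRUE,
                                    baseOnly = TRUE)[c("A", "C", "G", "T"), ,
                                                     drop = FALSE]
  rownames(cm) <- c("A", "C", "G", "U")
  out <- tibble(
    stratum = stratum,
    position = rep(seq(-up, down), each = 4),
    base = rep(c("A", "C", "G", "U"), up + down + 1L),
    frac = as.vector(cm),
    n_sites = length(ss)
  )
  attr(out, "n_dropped") <- n_drop
  attr(out, "window") <- c(up, down)
  class(out) <- c("pa_profile", class(out))
  out
}

#' Stratified nucleotide profiles
#'
#' One profile per non-empty stratum: sense region classes (`3UTR`,
#' `intron`, `CDS`, `intergenic`), the antisense attribution classes
#' (`antisense-overlap` = cases 1-2, `antisense-nearby` = case 3,
#' `antisense-orphan` = case 4), each crossed with the support classes
#' `all`, `single-PAT` (`tag_count == 1`) and `multi-PAT`.
#'
#' @param pacs PAC tibble.
#' @param assignments Assignment tibble from [assign_pacs()].
#' @param genome Named [Biostrings::DNAStringSet].
#' @param params [pa_params()] (supplies the profile window).
#' @return A `pa_profile` tibble with columns `stratum`, `support`,
#'   `position`, `base`, `frac`, `n_sites`; empty strata are omitted.
#' @export
stratified_profiles <- function(pacs, assignments, genome,
                                params = pa_params("mtr")) {
  a <- left_join(assignments,
                 select(pacs, "pac_id", "start", "end"), by = "pac_id")
  strata <- list(
    `3UTR` = filter(a, .data$orientation == "sense", .data$region == "3UTR"),
    intron = filter(a, .data$orientation == "sense",
                    .data$region == "intron"),
    CDS = filter(a, .data$orientation == "sense", .data$region == "CDS"),
    intergenic = filter(a, .data$orientation == "sense",
                        .data$region == "intergenic",
                        is.na(.data$antisense_gene_id)),
    `antisense-overlap` = filter(a, .data$antisense_case %in% c(1L, 2L)),
    `antisense-nearby` = filter(a, !is.na(.data$antisense_case),
                                .data$antisense_case == 3L),
    `antisense-orphan` = filter(a, !is.na(.data$antisense_case),
                                .data$antisense_case == 4L)
  )
  out <- list()
  for (nm in names(strata)) {
    st <- strata[[nm]]
    subsets <- list(all = st,
                    `single-PAT` = filter(st, .data$tag_count == 1L),
                    `multi-PAT` = filter(st, .data$tag_count > 1L))
    for (sp in names(subsets)) {
      sub <- subsets[[sp]]
      if (nrow(sub) == 0) {
        message("stratum ", nm, " / ", sp, ": no sites, omitted")
        next
      }
      pr <- tryCatch(
        composition_profile(sub, genome, window = params$profile_window,
                            stratum = nm),
        error = function(e) NULL
      )
      if (is.null(pr)) {
        message("stratum ", nm, " / ", sp, ": all windows clipped, omitted")
        next
      }
      pr$support <- sp
      out[[paste(nm, sp)]] <- pr
    }
  }
  res <- list_rbind(out) |>
    select("stratum", "support", "position", "base", "frac", "n_sites")
  class(res) <- c("pa_profile", class(res))
  res
}

#' Write profiles as per-stratum TSV
#'
#' Wide per-position layout: `position`, `fracA`, `fracC`, `fracG`, `fracU`,
#' `n_sites` (plus `stratum`/`support` keys when present).
#'
#' @param profile A `pa_profile` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  keys <- intersect(c("stratum", "support", "position", "n_sites"),
                    names(profile))
  wide <- profile |>
    as_tibble() |>
    mutate(base = paste0("frac", .data$base)) |>
    tidyr::pivot_wider(id_cols = dplyr::all_of(keys),
                       names_from = "base", values_from = "frac")
  readr::write_tsv(wide, path)
  invisible(path)
}
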