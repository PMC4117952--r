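#' Assign PACs to genes, regions and antisense cases
#'
#' Resolves every PAC at its summit coordinate. On the PAC's own strand:
#' if a same-strand gene covers the summit the PAC gets that gene's local
#' segment label (the 3' extension is labelled `3UTR`); otherwise a covering
#' same-strand promoter window gives `promoter`; otherwise `intergenic`.
#' When several same-strand features cover the summit, gene body beats
#' extension beats promoter; remaining ties go to the gene with the nearest
#' 3' end, then to the lexicographically smallest `gene_id`.
#'
#' Independently, a PAC whose summit lies inside the annotated body of a
#' gene on the opposite strand is antisense to that gene and receives a
#' read-through attribution case: summit inside a same-strand gene's
#' annotated-or-extended 3'-UTR (case 1), inside any other part of a
#' same-strand gene body (case 2), not covered but within
#' `params$nearby_antisense_distance` nt downstream of a same-strand gene's
#' annotated 3' end - the convergent configuration (case 3), otherwise an
#' orphan (case 4).
#'
#' A PAC can be antisense to one gene while lying sense inside another
#' (overlapping convergent genes); such PACs keep both attributions and are
#' tabulated in both the sense and the antisense tables. `orientation` is
#' `antisense` only when there is an antisense host and no sense gene
#' coverage.
#'
#' @param pacs PAC tibble from [cluster_tags()].
#' @param index `pa_index` from [build_index()].
#' @param params [pa_params()].
#' @return Assignment tibble: `pac_id`, `chrom`, `strand`, `summit`,
#'   `tag_count`, `gene_id`, `region`, `orientation`, `antisense_gene_id`,
#'   `antisense_case`.
#' @export
assign_pacs <- function(pacs, index, params = pa_params("mtr")) {
  if (nrow(pacs) == 0) {
    return(tibble(pac_id = character(), chrom = character(),
                  strand = character(), summit = integer(),
                  tag_count = integer(), gene_id = character(),
                  region = character(), orientation = character(),
                  antisense_gene_id = character(),
                  antisense_case = integer()))
  }
  genes <- index$genes
  gene3p <- setNames(if_else(genes$strand == "+", genes$end, genes$start),
                     genes$gene_id)
  hits <- query_index(index, pacs$chrom, pacs$summit, strand = NULL)
  hits <- hits |>
    mutate(pac_strand = pacs$strand[.data$query],
           summit = pacs$summit[.data$query],
           same = .data$strand == .data$pac_strand,
           dist3p = abs(.data$summit - unname(gene3p[.data$gene_id])))

  sense_best <- hits |>
    filter(.data$same) |>
    group_by(.data$query) |>
    arrange(.data$priority, .data$dist3p, .data$gene_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  anti_best <- hits |>
    filter(!.data$same, .data$kind == "body") |>
    group_by(.data$query) |>
    arrange(.data$dist3p, .data$gene_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup()

  out <- pacs |>
    mutate(query = row_number()) |>
    left_join(select(sense_best, "query", s_gene = "gene_id",
                     s_label = "label", s_kind = "kind"),
              by = "query") |>
    left_join(select(anti_best, "query", a_gene = "gene_id"), by = "query") |>
    mutate(
      region = case_when(
        is.na(.data$s_kind) ~ "intergenic",
        .data$s_kind == "prom" ~ "promoter",
        TRUE ~ .data$s_label
      ),
      gene_id = if_else(!is.na(.data$s_kind) & .data$s_kind != "prom",
                        .data$s_gene, NA_character_),
      antisense_gene_id = .data$a_gene
    )

  # attribute antisense PACs not explained by sense coverage: case 3 or 4
  out$antisense_case <- NA_integer_
  has_host <- !is.na(out$antisense_gene_id)
  covered <- has_host & !is.na(out$gene_id)
  out$antisense_case[covered] <-
    if_else(out$region[covered] == "3UTR", 1L, 2L)
  todo <- which(has_host & is.na(out$gene_id))
  for (i in todo) {
    cand <- genes[genes$chrom == out$chrom[i] &
                    genes$strand == out$strand[i], ]
    d <- if (out$strand[i] == "+") out$summit[i] - cand$end
         else cand$start - out$summit[i]
    out$antisense_case[i] <-
      if (any(d > 0 & d <= params$nearby_antisense_distance)) 3L else 4L
  }
  out |>
    mutate(orientation = if_else(has_host & is.na(.data$gene_id),
                                 "antisense", "sense")) |>
    select("pac_id", "chrom", "strand", "summit", "tag_count", "gene_id",
           "region", "orientation", "antisense_gene_id", "antisense_case")
}

#' Sense-side assignment only
#'
#' Convenience wrapper around [assign_pacs()] returning the sense columns.
#'
#' @inheritParams assign_pacs
#' @return Tibble `pac_id`, `gene_id`, `region`, `orientation`.
#' @export
assign_sense <- function(pacs, index, params = pa_params("mtr")) {
  assign_pacs(pacs, index, params) |>
    select("pac_id", "gene_id", "region", "orientation")
}

#' Classify antisense PACs into cases 1-4
#'
#' @inheritParams assign_pacs
#' @return Assignment rows for antisense PACs (those whose summit lies in an
#'   opposite-strand gene body). Errors if none of the supplied PACs is
#'   antisense to any gene.
#' @export
classify_antisense <- function(pacs, index, params = pa_params("mtr")) {
  out <- assign_pacs(pacs, index, params) |>
    filter(!is.na(.data$antisense_gene_id))
  if (nrow(out) == 0) {
    stop("none of the supplied PACs is antisense to a gene", call. = FALSE)
  }
  out
}

#' Genomic distribution of sense PACs (region tabulation)
#'
#' Tabulates PAC and tag counts per region over the sense table: all PACs
#' except those whose only attribution is antisense. Percentages recompute
#' from the integer counts and sum to 100.
#'
#' @param assignments Assignment tibble from [assign_pacs()].
#' @return Tibble `region`, `n_pacs`, `pct_pacs`, `n_tags`, `pct_tags`.
#' @export
tabulate_regions <- function(assignments) {
  sense <- filter(assignments, .data$orientation == "sense")
  lv <- c("3UTR", "5UTR", "AMB", "CDS", "intergenic", "promoter", "intron")
  sense |>
    mutate(region = factor(.data$region, levels = lv)) |>
    group_by(.data$region, .drop = FALSE) |>
    summarise(n_pacs = n(), n_tags = sum(.data$tag_count), .groups = "drop") |>
    mutate(region = as.character(.data$region),
           pct_pacs = if (sum(.data$n_pacs) > 0)
             100 * .data$n_pacs / sum(.data$n_pacs) else 0,
           pct_tags = if (sum(.data$n_tags) > 0)
             100 * .data$n_tags / sum(.data$n_tags) else 0) |>
    select("region", "n_pacs", "pct_pacs", "n_tags", "pct_tags")
}

#' Antisense case tabulation
#'
#' @param assignments Assignment tibble from [assign_pacs()].
#' @return Tibble `antisense_case` (1-4), `n_pacs`, `pct_pacs`, `n_tags`,
#'   `n_gene_pairs` (distinct host/explaining-gene pairs, cases 1-2 only).
#' @export
tabulate_antisense <- function(assignments) {
  anti <- filter(assignments, !is.na(.data$antisense_gene_id))
  pairs <- anti |>
    filter(.data$antisense_case %in% c(1L, 2L)) |>
    distinct(.data$antisense_case, .data$antisense_gene_id, .data$gene_id) |>
    count(.data$antisense_case, name = "n_gene_pairs")
  anti |>
    mutate(antisense_case = factor(.data$antisense_case, levels = 1:4)) |>
    group_by(.data$antisense_case, .drop = FALSE) |>
    summarise(n_pacs = n(), n_tags = sum(.data$tag_count), .groups = "drop") |>
    mutate(antisense_case = as.integer(as.character(.data$antisense_case)),
           pct_pacs = if (sum(.data$n_pacs) > 0)
             100 * .data$n_pacs / sum(.data$n_pacs) else 0) |>
    left_join(pairs, by = "antisense_case") |>
    mutate(n_gene_pairs = if_else(is.na(.data$n_gene_pairs) &
                                    .data$antisense_case <= 2L,
                                  0L, .data$n_gene_pairs)) |>
    select("antisense_case", "n_pacs", "pct_pacs", "n_tags", "n_gene_pairs")
}

#' Distances of intergenic PACs from neighboring (extended) genes
#'
#' For every purely intergenic PAC (no sense gene, no promoter, no antisense
#' host), the distance from the summit to the nearest boundary of an
#' extended gene (gene body plus 3' extension, either strand), where a PAC
#' immediately adjacent to a gene end has distance 1. Also reports the
#' fraction farther than `far_threshold` and the fraction within
#' `oriented_window` nt downstream of an adjacent, properly oriented
#' (same-strand, pointing at the PAC) annotated gene end.
#'
#' @param assignments Assignment tibble from [assign_pacs()].
#' @param models Extended `pa_models`.
#' @param far_threshold Distance (nt) for the "far from any gene" fraction.
#' @param oriented_window Distance (nt) for the properly-oriented fraction.
#' @return A list of class `pa_intergenic`: `distances` tibble (`pac_id`,
#'   `distance`, `oriented_distance`), `frac_far`, `frac_within_oriented`,
#'   `curve` (sorted distance vs cumulative fraction).
#' @export
intergenic_distances <- function(assignments, models, far_threshold = 1000L,
                                 oriented_window = 400L) {
  g <- models$genes
  inter <- assignments |>
    filter(.data$region == "intergenic", is.na(.data$antisense_gene_id))
  if (nrow(inter) == 0) {
    return(structure(list(
      distances = tibble(pac_id = character(), distance = integer(),
                         oriented_distance = integer()),
      frac_far = NA_real_, frac_within_oriented = NA_real_,
      curve = tibble(distance = integer(), cum_frac = numeric())
    ), class = "pa_intergenic"))
  }
  lo <- pmin(g$start, g$ext_start)
  hi <- pmax(g$end, g$ext_end)
  dist_one <- function(chrom, p) {
    on <- which(g$chrom == chrom)
    if (length(on) == 0) return(NA_integer_)
    d <- pmax(lo[on] - p, p - hi[on], 0L)
    as.integer(min(d))
  }
  orient_one <- function(chrom, strand, p) {
    on <- which(g$chrom == chrom & g$strand == strand)
    if (length(on) == 0) return(NA_integer_)
    d <- if (strand == "+") p - g$end[on] else g$start[on] - p
    d <- d[d > 0]
    if (length(d) == 0) NA_integer_ else as.integer(min(d))
  }
  dist <- mapply(dist_one, inter$chrom, inter$summit)
  odist <- mapply(orient_one, inter$chrom, inter$strand, inter$summit)
  distances <- tibble(pac_id = inter$pac_id, distance = as.integer(dist),
                      oriented_distance = as.integer(odist))
  dd <- sort(distances$distance[!is.na(distances$distance)])
  structure(list(
    distances = distances,
    frac_far = mean(dd > far_threshold),
    frac_within_oriented = mean(!is.na(distances$oriented_distance) &
                                  distances$oriented_distance <=
                                    oriented_window),
    curve = tibble(distance = dd,
                   cum_frac = seq_along(dd) / length(dd))
  ), class = "pa_intergenic")
}

#' @export
print.pa_intergenic <- function(x, ...) {
  cat("<pa_intergenic> ", nrow(x$distances), " intergenic PACs; ",
      round(100 * x$frac_far), "% farther than threshold; ",
      round(100 * x$frac_within_oriented),
      "% within the oriented window\n", sep = "")
  invisible(x)
}
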