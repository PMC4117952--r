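#' @importFrom rlang %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange bind_rows case_when count distinct filter group_by
#'   left_join mutate n pull rename row_number select slice summarise ungroup
#'   if_else anti_join semi_join first last desc
#' @importFrom purrr map map2 pmap map_int map_dbl map_chr map_lgl list_rbind
#' @importFrom stats rnorm rpois runif wilcox.test cor cor.test pchisq median
#'   setNames quantile sd
#' @importFrom utils head tail
NULL

# strand-aware shift: downstream means 3' of the tag/site on its own strand
.downstream_window <- function(pos, strand, width) {
  start <- ifelse(strand == "+", pos + 1L, pos - width)
  end <- ifelse(strand == "+", pos + width, pos - 1L)
  list(start = as.integer(start), end = as.integer(end))
}

# extract sense-strand sequence for 1-based inclusive windows, clipped to the
# chromosome; returns NA for empty windows
.extract_sense <- function(genome, chrom, start, end, strand) {
  stopifnot(all(chrom %in% names(genome)))
  len <- Biostrings::width(genome)[match(chrom, names(genome))]
  s <- pmax(start, 1L)
  e <- pmin(end, len)
  out <- rep(NA_character_, length(chrom))
  ok <- s <= e
  if (any(ok)) {
    v <- Biostrings::DNAStringSet(
      mapply(function(ch, a, b) Biostrings::subseq(genome[[ch]], a, b),
             chrom[ok], s[ok], e[ok], SIMPLIFY = FALSE)
    )
    neg <- strand[ok] == "-"
    if (any(neg)) v[neg] <- Biostrings::reverseComplement(v[neg])
    out[ok] <- as.character(v)
  }
  out
}

.chrom_lengths <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}

# TRUE if x contains a run of >= n consecutive A
.has_a_run <- function(x, n) {
  pat <- strrep("A", n)
  !is.na(x) & grepl(pat, x, fixed = TRUE)
}

.assert_tags <- function(tags) {
  need <- c("tag_id", "chrom", "strand", "pos", "count", "mate_status")
  miss <- setdiff(need, names(tags))
  if (length(miss) > 0) {
    stop("tag table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(tags)
}
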