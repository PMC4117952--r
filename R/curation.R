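#' Classify raw reads as poly(T) tags
#'
#' In the PAT-seq protocol the oligo-dT primed read starts with the
#' reverse-complemented poly(A) tail, so a genuine poly(A) tag begins with a
#' run of T. A read is a poly(T) tag iff it starts with at least `min_t_run`
#' consecutive T; the leading run is trimmed from the remainder.
#'
#' @param sequences Character vector of uppercase reads (`A`,`C`,`G`,`T`,`N`).
#' @param min_t_run Minimum leading-T run length (default 8).
#' @return A tibble with `sequence`, `verdict` (`polyT`/`not_polyT`),
#'   `t_run` (observed leading run length) and `remainder` (read with the
#'   full leading T-run removed; `NA` for non-poly(T) reads).
#' @examples
#' classify_raw_tag(c("TTTTTTTTACGT", "TTTTTTTACGT"))
#' @export
classify_raw_tag <- function(sequences, min_t_run = 8L) {
  if (length(sequences) == 0 || any(!nzchar(sequences)) || any(is.na(sequences))) {
    stop("sequences must be non-empty strings", call. = FALSE)
  }
  m <- regmatches(sequences, regexpr("^T*", sequences))
  t_run <- nchar(m)
  polyt <- t_run >= min_t_run
  tibble(
    sequence = sequences,
    verdict = if_else(polyt, "polyT", "not_polyT"),
    t_run = as.integer(t_run),
    remainder = if_else(polyt, substring(sequences, t_run + 1L), NA_character_)
  )
}

#' Keep only tags whose 5' mates mapped uniquely
#'
#' @param tags Tag tibble with a `mate_status` column
#'   (`paired_unique` / `unpaired` / `mate_multimapped`).
#' @return The subset with `mate_status == "paired_unique"`; the numbers
#'   removed per reason are attached as attribute `"removed"`.
#' @export
filter_pairing <- function(tags) {
  .assert_tags(tags)
  removed <- tags |>
    filter(.data$mate_status != "paired_unique") |>
    count(.data$mate_status, name = "n_tags")
  out <- filter(tags, .data$mate_status == "paired_unique")
  attr(out, "removed") <- removed
  out
}

#' Remove internal-priming artifacts against the genome
#'
#' A tag is discarded iff the `internal_priming_window` genomic nt
#' immediately downstream of its cleavage position, read on the tag's sense
#' strand (reverse-complemented for minus-strand tags), contain a run of at
#' least `internal_priming_a_run` consecutive A. Such tags arise from
#' oligo-dT priming at genome-encoded A-tracts rather than at a genuine
#' poly(A) tail. Windows running past a chromosome end are clipped and the
#' rule applied to the remaining bases.
#'
#' @param tags Tag tibble.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param params [pa_params()].
#' @return A list with tibbles `kept` and `discarded` (both carry the
#'   inspected `downstream_seq` for audit).
#' @export
filter_internal_priming <- function(tags, genome, params = pa_params("mtr")) {
  .assert_tags(tags)
  if (nrow(tags) == 0) {
    return(list(kept = tags, discarded = tags))
  }
  if (!all(tags$chrom %in% names(genome))) {
    stop("genome does not cover all tag chromosomes", call. = FALSE)
  }
  w <- .downstream_window(tags$pos, tags$strand, params$internal_priming_window)
  ds <- .extract_sense(genome, tags$chrom, w$start, w$end, tags$strand)
  bad <- .has_a_run(ds, params$internal_priming_a_run)
  tags$downstream_seq <- ds
  list(kept = tags[!bad, , drop = FALSE], discarded = tags[bad, , drop = FALSE])
}

#' Aggregate tags sharing a cleavage position
#'
#' Tags with identical (`chrom`, `strand`, `pos`) collapse into one record
#' with summed `count`; clustering semantics depend on distinct positions,
#' not read multiplicity.
#'
#' @param tags Tag tibble.
#' @return Aggregated tag tibble (one row per distinct position), carrying
#'   `n_tags` (records merged).
#' @export
aggregate_tags <- function(tags) {
  .assert_tags(tags)
  if (nrow(tags) == 0) {
    return(mutate(select(tags, "chrom", "strand", "pos", "tag_id", "count",
                         "mate_status"),
                  n_tags = integer(0)))
  }
  tags |>
    group_by(.data$chrom, .data$strand, .data$pos) |>
    summarise(tag_id = min(.data$tag_id), count = sum(.data$count),
              mate_status = min(.data$mate_status), n_tags = n(),
              .groups = "drop") |>
    arrange(.data$chrom, .data$strand, .data$pos)
}

#' Run the full tag-curation cascade
#'
#' Applies, in order: mate-pairing concordance, internal-priming removal
#' against the genome, and per-position aggregation. A processing-stage
#' report (raw tags, mate-paired tags, tags after internal-priming
#' exclusion) is attached as attribute `"report"` and retrievable with
#' [curation_report()]. The filters commute with input order; the output is
#' sorted by position.
#'
#' @param tags Raw mapped tag tibble.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param params [pa_params()].
#' @return Curated, aggregated tag tibble.
#' @export
curate_tags <- function(tags, genome, params = pa_params("mtr")) {
  .assert_tags(tags)
  n_raw <- sum(tags$count)
  paired <- filter_pairing(tags)
  n_paired <- sum(paired$count)
  ip <- filter_internal_priming(paired, genome, params)
  n_clean <- sum(ip$kept$count)
  out <- aggregate_tags(ip$kept)
  attr(out, "report") <- tibble(
    stage = c("mapped tags", "mate-paired tags",
              "internal-priming excluded tags"),
    n_tags = c(n_raw, n_paired, n_clean)
  )
  attr(out, "discarded_internal_priming") <- ip$discarded
  out
}

#' Retrieve the curation cascade report
#'
#' @param curated Output of [curate_tags()].
#' @return Tibble with `stage` and `n_tags`, monotonically non-increasing.
#' @export
curation_report <- function(curated) {
  attr(curated, "report")
}
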