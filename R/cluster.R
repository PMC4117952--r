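#' Chain curated tags into poly(A)-site clusters (PACs)
#'
#' Single-linkage chaining per chromosome and strand: adjacent distinct
#' cleavage positions separated by fewer than `params$cluster_gap` nt (24 by
#' default) join the same PAC, absorbing the nucleotide-scale
#' microheterogeneity around a biological poly(A) site. Opposite strands
#' never merge. The summit is the position with the maximal tag count; ties
#' break toward the 3'-most position on the PAC's strand.
#'
#' @param tags Curated tag tibble (deduplicated per position, e.g. from
#'   [curate_tags()] or [aggregate_tags()]; un-aggregated input is
#'   aggregated on the fly).
#' @param params [pa_params()].
#' @return A PAC tibble: `pac_id`, `chrom`, `strand`, `start`, `end`,
#'   `summit`, `tag_count`, `n_positions`.
#' @examples
#' tags <- tibble::tibble(
#'   tag_id = c("a", "b"), chrom = "chr1", strand = "+",
#'   pos = c(100L, 123L), count = 1L, mate_status = "paired_unique"
#' )
#' cluster_tags(tags)$n_positions # 2: separated by 23 < 24, one PAC
#' @export
cluster_tags <- function(tags, params = pa_params("mtr")) {
  .assert_tags(tags)
  if (nrow(tags) == 0) {
    return(tibble(pac_id = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  summit = integer(), tag_count = integer(),
                  n_positions = integer()))
  }
  if (anyDuplicated(tags[c("chrom", "strand", "pos")]) > 0) {
    tags <- aggregate_tags(tags)
  }
  gap <- params$cluster_gap
  tags <- arrange(tags, .data$chrom, .data$strand, .data$pos)
  tags |>
    group_by(.data$chrom, .data$strand) |>
    mutate(.cl = cumsum(c(TRUE, diff(.data$pos) >= gap))) |>
    group_by(.data$chrom, .data$strand, .data$.cl) |>
    summarise(
      start = min(.data$pos),
      end = max(.data$pos),
      summit = {
        cand <- .data$pos[.data$count == max(.data$count)]
        if (first(.data$strand) == "+") max(cand) else min(cand)
      },
      tag_count = sum(.data$count),
      n_positions = n(),
      .groups = "drop"
    ) |>
    arrange(.data$chrom, .data$start) |>
    mutate(pac_id = sprintf("PAC%05d", row_number())) |>
    select("pac_id", "chrom", "strand", "start", "end", "summit",
           "tag_count", "n_positions")
}

#' Per-gene PAC counts and the alternative-polyadenylation summary
#'
#' Counts PACs per gene over gene-assigned PACs (sense assignments with a
#' host gene), builds the marginal table over 1/2/3/4/>=5 PACs per gene, and
#' reports the fraction of genes with more than one PAC (the headline APA
#' statistic).
#'
#' @param assignments Assignment tibble from [assign_pacs()] (or any tibble
#'   with `pac_id` and `gene_id` for gene-assigned sense PACs).
#' @return A list of class `pa_gene_pacs`: `per_gene` (gene_id, n_pacs),
#'   `marginal` (pac_class, n_genes, pct_genes), `frac_multi`.
#' @export
pacs_per_gene <- function(assignments) {
  gene_pacs <- assignments |>
    filter(!is.na(.data$gene_id), .data$orientation == "sense") |>
    distinct(.data$pac_id, .data$gene_id)
  per_gene <- gene_pacs |>
    count(.data$gene_id, name = "n_pacs")
  marginal <- marginal_pac_table(per_gene$n_pacs)
  structure(list(per_gene = per_gene, marginal = marginal,
                 frac_multi = frac_multi_pac(marginal)),
            class = "pa_gene_pacs")
}

#' Marginal table of genes by PAC count
#'
#' @param n_pacs Integer vector of per-gene PAC counts.
#' @return Tibble with `pac_class` (`1`,`2`,`3`,`4`,`>=5`), `n_genes`,
#'   `pct_genes`.
#' @export
marginal_pac_table <- function(n_pacs) {
  cls <- factor(if_else(n_pacs >= 5, ">=5", as.character(n_pacs)),
                levels = c("1", "2", "3", "4", ">=5"))
  tb <- tibble(pac_class = levels(cls),
               n_genes = as.integer(table(cls)))
  mutate(tb, pct_genes = if (sum(tb$n_genes) > 0)
    100 * tb$n_genes / sum(tb$n_genes) else 0)
}

#' Fraction of genes with more than one PAC
#'
#' @param marginal Either a marginal table from [marginal_pac_table()] (whose
#'   first class is single-PAC genes) or a named/ordered numeric vector of
#'   gene counts for 1,2,3,4,>=5 PACs.
#' @return Proportion in `[0, 1]` (0 when there are no genes).
#' @examples
#' frac_multi_pac(c(5126, 3386, 2282, 1446, 1963)) # ~0.639 -> 64%
#' @export
frac_multi_pac <- function(marginal) {
  n <- if (is.data.frame(marginal)) marginal$n_genes else as.numeric(marginal)
  if (sum(n) == 0) return(0)
  sum(n[-1]) / sum(n)
}

#' @export
print.pa_gene_pacs <- function(x, ...) {
  cat("<pa_gene_pacs> ", nrow(x$per_gene), " genes; ",
      round(100 * x$frac_multi), "% with >1 PAC\n", sep = "")
  print(x$marginal)
  invisible(x)
}

#' Partition PACs by single- vs multi-tag support
#'
#' A large share of PACs is typically supported by a single poly(A) tag;
#' comparing their nucleotide profiles against multi-tag PACs is the
#' standard authenticity check for that class.
#'
#' @param pacs PAC tibble.
#' @return List with tibbles `single` (`tag_count == 1`) and `multi`.
#' @export
single_tag_pac_partition <- function(pacs) {
  list(single = filter(pacs, .data$tag_count == 1L),
       multi = filter(pacs, .data$tag_count > 1L))
}
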