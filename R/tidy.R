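#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a feature-conservation test result
#'
#' @param x A `pa_conservation` object.
#' @param ... Unused.
#' @return One-row tibble with the observed and expected shared counts, the
#'   hypergeometric expectation, the chi-square statistic and p-value.
#' @export
tidy.pa_conservation <- function(x, ...) {
  tibble(
    feature = x$feature,
    observed_shared = x$observed_shared,
    sample_size = x$sample_size,
    pool_size = x$pool_size,
    expected_mean = x$expected_mean,
    hyper_expected = x$hyper_expected,
    statistic = x$chi2_stat,
    p.value = x$p_value
  )
}

#' @rdname tidy.pa_conservation
#' @export
glance.pa_conservation <- function(x, ...) {
  tibble(n_trials = x$n_trials, seed = x$seed,
         untestable = isTRUE(x$untestable),
         statistic = x$chi2_stat, p.value = x$p_value)
}

#' Tidy a 3'-UTR length comparison
#'
#' @param x A `pa_utr_comparison` object.
#' @param ... Unused.
#' @return Long tibble of the per-species Wilcoxon results and the two
#'   Pearson correlations (ortholog pairs and the random-pairing control).
#' @export
tidy.pa_utr_comparison <- function(x, ...) {
  bind_rows(
    x$species |>
      mutate(term = paste0("wilcoxon_", .data$species),
             estimate = .data$median_orth - .data$median_nonorth,
             p.value = .data$wilcoxon_p) |>
      select("term", "estimate", "p.value"),
    x$correlation |>
      mutate(term = paste0("pearson_", .data$set), estimate = .data$r,
             p.value = .data$p) |>
      select("term", "estimate", "p.value")
  )
}

#' @rdname tidy.pa_utr_comparison
#' @export
glance.pa_utr_comparison <- function(x, ...) {
  tibble(
    n_pairs = x$correlation$n[x$correlation$set == "ortholog"],
    r_ortholog = x$correlation$r[x$correlation$set == "ortholog"],
    r_random = x$correlation$r[x$correlation$set == "random"],
    seed = x$seed
  )
}

#' Tidy an EST validation report
#'
#' @param x A `pa_est_validation` object.
#' @param ... Unused.
#' @export
tidy.pa_est_validation <- function(x, ...) {
  tibble(n_total = x$n_total, n_validated = x$n_validated,
         pct_validated = x$pct_validated, window = x$window)
}

#' Tidy per-gene PAC counts
#'
#' @param x A `pa_gene_pacs` object.
#' @param ... Unused.
#' @return The marginal table (genes by PAC-count class).
#' @export
tidy.pa_gene_pacs <- function(x, ...) x$marginal

#' @rdname tidy.pa_gene_pacs
#' @export
glance.pa_gene_pacs <- function(x, ...) {
  tibble(n_genes = nrow(x$per_gene), frac_multi = x$frac_multi)
}
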