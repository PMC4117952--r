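#' Per-gene 3'-UTR length implied by poly(A) sites
#'
#' For every gene with at least one 3'-UTR-assigned sense PAC, the distance
#' (nt) from the annotated CDS 3' end to a representative poly(A)
#' coordinate. Three representatives are offered: the tag-count-weighted
#' mean summit distance (default), the most distal summit, or the median
#' summit distance. Genes lacking a CDS 3'-end annotation are skipped and
#' counted in the `n_skipped` attribute.
#'
#' @param pacs PAC tibble.
#' @param assignments Assignment tibble from [assign_pacs()].
#' @param models Extended `pa_models`.
#' @param mode One of `"tag_weighted_mean"`, `"distal_summit"`,
#'   `"median_summit"`.
#' @return Tibble `gene_id`, `utr_length`, `n_pacs`, with attribute
#'   `n_skipped`.
#' @export
utr_lengths_per_gene <- function(pacs, assignments, models,
                                 mode = c("tag_weighted_mean",
                                          "distal_summit", "median_summit")) {
  mode <- match.arg(mode)
  g <- select(models$genes, "gene_id", "strand", "cds_end3p")
  d <- assignments |>
    filter(.data$orientation == "sense", .data$region == "3UTR",
           !is.na(.data$gene_id)) |>
    left_join(g, by = "gene_id", suffix = c("", ".gene")) |>
    mutate(len = if_else(.data$strand == "+",
                         .data$summit - .data$cds_end3p,
                         .data$cds_end3p - .data$summit))
  n_skipped <- d |> filter(is.na(.data$cds_end3p)) |>
    distinct(.data$gene_id) |> nrow()
  out <- d |>
    filter(!is.na(.data$cds_end3p)) |>
    group_by(.data$gene_id) |>
    summarise(
      utr_length = switch(mode,
        tag_weighted_mean = sum(.data$len * .data$tag_count) /
          sum(.data$tag_count),
        distal_summit = max(.data$len),
        median_summit = median(.data$len)
      ),
      n_pacs = n(), .groups = "drop"
    )
  attr(out, "n_skipped") <- n_skipped
  attr(out, "mode") <- mode
  out
}

#' Compare 3'-UTR lengths within and between two species
#'
#' Splits each species' per-gene 3'-UTR lengths into orthologous (the gene
#' appears in the ortholog table) and non-orthologous sets and tests them
#' with a Wilcoxon rank-sum test; computes the Pearson correlation of
#' lengths over ortholog pairs where both genes have a length; and, as the
#' null control, the Pearson correlation over `n_random_pairs` randomly
#' matched gene pairs.
#'
#' @param lengths_a,lengths_b Tibbles `gene_id`, `utr_length` for species A
#'   and B (see [utr_lengths_per_gene()]).
#' @param orthologs Tibble with `gene_a`, `gene_b`.
#' @param n_random_pairs Size of the randomly assembled pair control.
#' @param seed Integer seed for the random pairing.
#' @return A `pa_utr_comparison`: list with `species` (per-species medians
#'   and Wilcoxon p), `correlation` (set = ortholog/random, n, r, p),
#'   `pairs` (the joined ortholog length pairs).
#' @export
compare_utr_lengths <- function(lengths_a, lengths_b, orthologs,
                                n_random_pairs = 2000L, seed = 1L) {
  species_stats <- function(lengths, orth_ids, label) {
    is_orth <- lengths$gene_id %in% orth_ids
    x <- lengths$utr_length[is_orth]
    y <- lengths$utr_length[!is_orth]
    p <- if (length(x) > 0 && length(y) > 0) {
      wilcox.test(x, y)$p.value
    } else NA_real_
    tibble(species = label, n_orth = length(x), n_nonorth = length(y),
           median_orth = median(x), median_nonorth = median(y),
           wilcoxon_p = p)
  }
  species <- bind_rows(
    species_stats(lengths_a, orthologs$gene_a, "A"),
    species_stats(lengths_b, orthologs$gene_b, "B")
  )
  pairs <- orthologs |>
    left_join(rename(lengths_a, len_a = "utr_length"),
              by = c(gene_a = "gene_id")) |>
    left_join(rename(lengths_b, len_b = "utr_length"),
              by = c(gene_b = "gene_id")) |>
    filter(!is.na(.data$len_a), !is.na(.data$len_b))
  corr <- if (nrow(pairs) >= 3) {
    ct <- cor.test(pairs$len_a, pairs$len_b)
    tibble(set = "ortholog", n = nrow(pairs),
           r = unname(ct$estimate), p = ct$p.value)
  } else {
    tibble(set = "ortholog", n = nrow(pairs), r = NA_real_, p = NA_real_)
  }
  set.seed(seed)
  ra <- sample(lengths_a$utr_length, n_random_pairs, replace = TRUE)
  rb <- sample(lengths_b$utr_length, n_random_pairs, replace = TRUE)
  rand <- if (n_random_pairs >= 3) {
    ct <- cor.test(ra, rb)
    tibble(set = "random", n = n_random_pairs, r = unname(ct$estimate),
           p = ct$p.value)
  } else {
    tibble(set = "random", n = n_random_pairs, r = NA_real_, p = NA_real_)
  }
  structure(list(species = species, correlation = bind_rows(corr, rand),
                 pairs = pairs, seed = seed),
            class = "pa_utr_comparison")
}

#' @export
print.pa_utr_comparison <- function(x, ...) {
  cat("<pa_utr_comparison>\n")
  print(x$species)
  print(x$correlation)
  invisible(x)
}

#' Randomization test for cross-species feature conservation
#'
#' Given the species-B genes carrying a feature (e.g. an intronic PAC), the
#' ortholog table, the species-A genes carrying the feature, and the pool of
#' species-A orthologs eligible for sampling: counts how many species-B
#' feature genes have an ortholog in the pool (`sample_size`) and how many
#' of those orthologs carry the feature in species A (`observed_shared`),
#' then draws `params$n_random_trials` random samples of `sample_size` genes
#' from the pool (without replacement) to estimate the expected count under
#' random assortment. Significance is a two-cell chi-square goodness of fit
#' of `{observed, sample_size - observed}` against the randomization
#' expectation; the hypergeometric closed-form expectation
#' `sample_size * |feature_A in pool| / |pool|` is reported alongside (the
#' randomization mean converges to it).
#'
#' Gene-level counting: a gene "possesses" the feature if at least one of
#' its PACs does; many-to-many ortholog tables are deduplicated to unique
#' species-B genes, counting a shared feature if any ortholog partner
#' carries it.
#'
#' @param feature_b Character vector of species-B genes with the feature.
#' @param orthologs Tibble `gene_a`, `gene_b`.
#' @param feature_a Character vector of species-A genes with the feature.
#' @param pool_a Character vector: the species-A sampling pool.
#' @param params [pa_params()] (supplies `n_random_trials`).
#' @param seed Integer seed for the randomization.
#' @param feature Label stored in the result.
#' @return A `pa_conservation` object.
#' @export
feature_conservation_test <- function(feature_b, orthologs, feature_a,
                                      pool_a, params = pa_params("mtr"),
                                      seed = 1L, feature = "feature") {
  pool_a <- unique(pool_a)
  if (length(pool_a) == 0) stop("empty species-A pool", call. = FALSE)
  feature_a <- unique(feature_a)
  fb_set <- unique(feature_b)
  fa_set <- feature_a
  pool_set <- pool_a
  partners <- orthologs |>
    filter(.data$gene_b %in% !!fb_set, .data$gene_a %in% !!pool_set) |>
    group_by(.data$gene_b) |>
    summarise(shared = any(.data$gene_a %in% !!fa_set), .groups = "drop")
  sample_size <- nrow(partners)
  observed <- sum(partners$shared)
  k_pool <- sum(pool_a %in% feature_a)
  n_pool <- length(pool_a)
  hyper_expected <- sample_size * k_pool / n_pool
  if (sample_size == 0) {
    return(structure(list(
      feature = feature, observed_shared = 0L, sample_size = 0L,
      pool_size = n_pool, expected_mean = NA_real_,
      hyper_expected = 0, chi2_stat = NA_real_, p_value = NA_real_,
      n_trials = params$n_random_trials, trial_counts = integer(0),
      seed = seed, untestable = TRUE
    ), class = "pa_conservation"))
  }
  set.seed(seed)
  in_feat <- pool_a %in% feature_a
  trials <- vapply(seq_len(params$n_random_trials), function(i) {
    sum(in_feat[sample.int(n_pool, sample_size)])
  }, numeric(1))
  expected_mean <- mean(trials)
  e <- min(max(expected_mean, 1e-9), sample_size - 1e-9)
  chi2 <- if (abs(observed - expected_mean) < 1e-12) 0 else {
    (observed - e)^2 / e + (observed - e)^2 / (sample_size - e)
  }
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  structure(list(
    feature = feature, observed_shared = as.integer(observed),
    sample_size = as.integer(sample_size), pool_size = as.integer(n_pool),
    expected_mean = expected_mean, hyper_expected = hyper_expected,
    chi2_stat = chi2, p_value = p, n_trials = params$n_random_trials,
    trial_counts = as.integer(trials), seed = seed, untestable = FALSE
  ), class = "pa_conservation")
}

#' @export
print.pa_conservation <- function(x, ...) {
  cat("<pa_conservation> feature:", x$feature, "\n")
  if (isTRUE(x$untestable)) {
    cat("  untestable: no feature genes with orthologs in the pool\n")
    return(invisible(x))
  }
  cat("  observed shared: ", x$observed_shared, " of ", x$sample_size,
      " (pool ", x$pool_size, ")\n", sep = "")
  cat("  randomization mean (", x$n_trials, " trials): ",
      signif(x$expected_mean, 4), "; hypergeometric: ",
      signif(x$hyper_expected, 4), "\n", sep = "")
  cat("  chi-square = ", signif(x$chi2_stat, 4), ", p = ",
      format(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Positional statistics of PAC-containing introns and coding exons
#'
#' For every PAC-containing intron (and coding exon): the relative position
#' of the feature within its gene (feature index / feature count, in the
#' 5' to 3' direction; 1.0 for a single-feature gene) and the relative
#' position of the PAC within the feature (strand-aware offset / length;
#' values above 0.5 mean the PAC sits nearer the feature's 3' end). Length
#' distributions of PAC-containing features are paired with equally sized
#' random draws from all features of the same class.
#'
#' @param pacs PAC tibble.
#' @param assignments Assignment tibble.
#' @param models Extended `pa_models`.
#' @param seed Seed for the random length-control draw.
#' @return A `pa_positional` list: `positions` (per PAC-feature record),
#'   `length_controls` (feature_class, set = with_pac/random, length),
#'   `medians`.
#' @export
intron_exon_positional_stats <- function(pacs, assignments, models,
                                         seed = 1L) {
  seg <- models$segments |>
    filter(.data$label %in% c("intron", "CDS")) |>
    group_by(.data$gene_id, .data$label) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(
      n_features = n(),
      feature_idx = if_else(rep(first(.data$strand) == "+", n()),
                            row_number(), n() - row_number() + 1L),
      feature_len = .data$end - .data$start + 1L
    ) |>
    ungroup()
  hits <- assignments |>
    filter(.data$orientation == "sense", .data$region %in% c("intron", "CDS"),
           !is.na(.data$gene_id)) |>
    left_join(seg, by = c("gene_id", region = "label"),
              relationship = "many-to-many", suffix = c("", ".seg")) |>
    filter(.data$summit >= .data$start, .data$summit <= .data$end) |>
    mutate(
      offset = if_else(.data$strand == "+",
                       .data$summit - .data$start,
                       .data$end - .data$summit),
      rel_feature_pos = .data$feature_idx / .data$n_features,
      rel_within_pos = .data$offset / .data$feature_len
    ) |>
    select(feature_class = "region", "pac_id", "gene_id", "feature_idx",
           "n_features", "rel_feature_pos", "rel_within_pos", "feature_len")
  set.seed(seed)
  controls <- list()
  for (cls in c("intron", "CDS")) {
    with_pac <- hits |> filter(.data$feature_class == cls)
    all_len <- seg$feature_len[seg$label == cls]
    if (nrow(with_pac) == 0 || length(all_len) == 0) next
    draw <- sample(all_len, nrow(with_pac),
                   replace = nrow(with_pac) > length(all_len))
    controls[[cls]] <- bind_rows(
      tibble(feature_class = cls, set = "with_pac",
             length = with_pac$feature_len),
      tibble(feature_class = cls, set = "random", length = draw)
    )
  }
  length_controls <- list_rbind(controls)
  medians <- if (nrow(length_controls) > 0) {
    length_controls |>
      group_by(.data$feature_class, .data$set) |>
      summarise(median_length = median(.data$length), .groups = "drop")
  } else {
    tibble(feature_class = character(), set = character(),
           median_length = numeric())
  }
  structure(list(positions = hits, length_controls = length_controls,
                 medians = medians, seed = seed),
            class = "pa_positional")
}

#' Validate PACs against EST-derived poly(A) sites
#'
#' An EST-derived site is validated iff some PAC summit on the same strand
#' and chromosome lies within `params$est_match_window` nt (inclusive at the
#' window boundary).
#'
#' @param est_sites Tibble `est_id`, `chrom`, `strand`, `pos`.
#' @param pacs PAC tibble.
#' @param params [pa_params()].
#' @return A `pa_est_validation` list: `per_site` (est_id, nearest_dist,
#'   validated), `n_total`, `n_validated`, `pct_validated`.
#' @export
est_validation <- function(est_sites, pacs, params = pa_params("mtr")) {
  if (nrow(est_sites) == 0) stop("empty EST site set", call. = FALSE)
  nearest <- function(chrom, strand, p) {
    s <- pacs$summit[pacs$chrom == chrom & pacs$strand == strand]
    if (length(s) == 0) NA_integer_ else as.integer(min(abs(s - p)))
  }
  d <- mapply(nearest, est_sites$chrom, est_sites$strand, est_sites$pos,
              USE.NAMES = FALSE)
  per_site <- tibble(
    est_id = est_sites$est_id, nearest_dist = as.integer(d),
    validated = !is.na(d) & d <= params$est_match_window
  )
  structure(list(
    per_site = per_site,
    n_total = nrow(per_site),
    n_validated = sum(per_site$validated),
    pct_validated = 100 * sum(per_site$validated) / nrow(per_site),
    window = params$est_match_window
  ), class = "pa_est_validation")
}

#' @export
print.pa_est_validation <- function(x, ...) {
  cat("<pa_est_validation> ", x$n_validated, " of ", x$n_total,
      " EST sites (", round(x$pct_validated), "%) within ", x$window,
      " nt of a PAC summit\n", sep = "")
  invisible(x)
}
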