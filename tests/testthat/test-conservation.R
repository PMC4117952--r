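h_utr_setup <- function() {
  # one plus-strand gene with CDS ending at 2000, annotated 3'UTR to 2200
  ft <- h_tx_features("gA", "chr1", "+", exons = list(c(1001, 2200)),
                      cds = list(c(1001, 2000)), utr3 = c(2001, 2200))
  h_models(ft, c(chr1 = 50000L))
}

test_that("3'-UTR length is the distance from the CDS 3' end to the representative site", {
  models <- h_utr_setup()
  index <- build_index(models)
  one <- assign_pacs(tibble::tibble(
    pac_id = "P1", chrom = "chr1", strand = "+", start = 2180L, end = 2180L,
    summit = 2180L, tag_count = 3L, n_positions = 1L), index)
  l <- utr_lengths_per_gene(cluster_tags(h_tags(2180L)), one, models)
  expect_equal(l$utr_length, 180)

  # two PACs at 100 nt (9 tags) and 200 nt (1 tag): weighted mean 110,
  # distal 200, median 150
  pacs <- tibble::tibble(
    pac_id = c("P1", "P2"), chrom = "chr1", strand = "+",
    start = c(2100L, 2200L), end = c(2100L, 2200L),
    summit = c(2100L, 2200L), tag_count = c(9L, 1L), n_positions = 1L
  )
  a <- assign_pacs(pacs, index)
  expect_equal(utr_lengths_per_gene(pacs, a, models)$utr_length, 110)
  expect_equal(utr_lengths_per_gene(pacs, a, models,
                                    mode = "distal_summit")$utr_length, 200)
  expect_equal(utr_lengths_per_gene(pacs, a, models,
                                    mode = "median_summit")$utr_length, 150)
})

test_that("distal mode is never below the tag-weighted mean", {
  models <- h_utr_setup()
  index <- build_index(models)
  set.seed(12)
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    summits <- sort(sample(2010:2195, k))
    pacs <- tibble::tibble(
      pac_id = sprintf("P%d", seq_len(k)), chrom = "chr1", strand = "+",
      start = summits, end = summits, summit = summits,
      tag_count = sample(1:20, k, replace = TRUE), n_positions = 1L
    )
    a <- assign_pacs(pacs, index)
    lw <- utr_lengths_per_gene(pacs, a, models)$utr_length
    ld <- utr_lengths_per_gene(pacs, a, models,
                               mode = "distal_summit")$utr_length
    expect_gte(ld, lw)
  }
})

test_that("identity ortholog mapping gives Pearson r = 1 and random pairing r near 0", {
  set.seed(5)
  lens <- tibble::tibble(gene_id = sprintf("g%03d", 1:200),
                         utr_length = rnorm(200, 180, 50))
  orth <- tibble::tibble(gene_a = lens$gene_id, gene_b = lens$gene_id)
  cmp <- compare_utr_lengths(lens, lens, orth, n_random_pairs = 2000,
                             seed = 2)
  r <- cmp$correlation
  expect_equal(r$r[r$set == "ortholog"], 1, tolerance = 1e-12)
  expect_lt(abs(r$r[r$set == "random"]), 0.08)
  # fewer than 3 complete pairs -> correlation reported missing
  tiny <- compare_utr_lengths(lens[1:2, ], lens[1:2, ], orth[1:2, ],
                              n_random_pairs = 10, seed = 1)
  expect_true(is.na(tiny$correlation$r[tiny$correlation$set == "ortholog"]))
})

test_that("the Wilcoxon split matches the exact textbook rank-sum p-value", {
  # orthologous lengths {1,2,3} vs non-orthologous {4,5,6}: the rank sum is
  # extreme, exact two-sided p = 2/choose(6,3) = 0.1
  la <- tibble::tibble(gene_id = c("o1", "o2", "o3", "n1", "n2", "n3"),
                       utr_length = c(1, 2, 3, 4, 5, 6))
  orth <- tibble::tibble(gene_a = c("o1", "o2", "o3"),
                         gene_b = c("x1", "x2", "x3"))
  lb <- tibble::tibble(gene_id = c("x1", "x2", "x3"),
                       utr_length = c(10, 20, 30))
  cmp <- compare_utr_lengths(la, lb, orth, n_random_pairs = 3, seed = 1)
  expect_equal(cmp$species$wilcoxon_p[cmp$species$species == "A"], 0.1)
})

test_that("a planted correlation of 0.3 is recovered from paired lengths", {
  pairs <- simulate_utr_lengths(8876, r = 0.3, seed = 9)
  la <- tibble::tibble(gene_id = pairs$gene_a, utr_length = pairs$len_a)
  lb <- tibble::tibble(gene_id = pairs$gene_b, utr_length = pairs$len_b)
  orth <- dplyr::select(pairs, gene_a, gene_b)
  cmp <- compare_utr_lengths(la, lb, orth, n_random_pairs = 2000, seed = 10)
  r <- cmp$correlation$r[cmp$correlation$set == "ortholog"]
  expect_lt(abs(r - 0.3), 0.05)
})

test_that("conservation test is exact when the feature saturates the pool", {
  orth <- simulate_orthologs(300, rate_a = 1, rate_b = 1, joint_rate = 1,
                             seed = 3)
  res <- feature_conservation_test(
    feature_b = orth$gene_b[orth$feature_b], orthologs = orth,
    feature_a = orth$gene_a[orth$feature_a], pool_a = orth$gene_a,
    params = pa_params("mtr", n_random_trials = 50L), seed = 4
  )
  expect_equal(res$observed_shared, 300L)
  expect_equal(res$expected_mean, 300)
  expect_equal(res$chi2_stat, 0)
  expect_equal(res$hyper_expected, 300)
})

test_that("randomization mean agrees with the hypergeometric closed form", {
  orth <- simulate_orthologs(800, rate_a = 0.3, rate_b = 0.4, seed = 6)
  params <- pa_params("mtr", n_random_trials = 1000L)
  res <- feature_conservation_test(
    feature_b = orth$gene_b[orth$feature_b], orthologs = orth,
    feature_a = orth$gene_a[orth$feature_a], pool_a = orth$gene_a,
    params = params, seed = 7
  )
  s <- res$sample_size
  p <- res$hyper_expected / s
  mc_se <- sqrt(s * p * (1 - p)) / sqrt(params$n_random_trials)
  expect_lt(abs(res$expected_mean - res$hyper_expected), 3 * mc_se + 1e-9)
  # determinism under a fixed seed
  res2 <- feature_conservation_test(
    feature_b = orth$gene_b[orth$feature_b], orthologs = orth,
    feature_a = orth$gene_a[orth$feature_a], pool_a = orth$gene_a,
    params = params, seed = 7
  )
  expect_identical(tidy(res), tidy(res2))
})

test_that("an empty overlap between feature genes and the pool is untestable", {
  orth <- simulate_orthologs(50, rate_a = 0.5, rate_b = 0.5, seed = 8)
  res <- feature_conservation_test(
    feature_b = character(0), orthologs = orth,
    feature_a = orth$gene_a[orth$feature_a], pool_a = orth$gene_a,
    params = pa_params("mtr", n_random_trials = 10L), seed = 1
  )
  expect_true(res$untestable)
  expect_true(is.na(res$p_value))
})

test_that("PAC positions within introns and exons use strand-aware 5'->3' indexing", {
  # plus strand: 4 introns, PAC in the third
  ft <- h_tx_features(
    "gA", "chr1", "+",
    exons = list(c(1001, 1200), c(1401, 1600), c(1801, 2000),
                 c(2201, 2400), c(2601, 2800)),
    cds = list(c(1001, 1200), c(1401, 1600), c(1801, 2000),
               c(2201, 2400), c(2601, 2800))
  )
  models <- h_models(ft, c(chr1 = 50000L))
  index <- build_index(models)
  # third intron is 2001-2200 (200 nt); offset 150 -> position 2151
  pacs <- tibble::tibble(pac_id = "P1", chrom = "chr1", strand = "+",
                         start = 2151L, end = 2151L, summit = 2151L,
                         tag_count = 1L, n_positions = 1L)
  a <- assign_pacs(pacs, index)
  st <- intron_exon_positional_stats(pacs, a, models, seed = 1)
  hit <- st$positions[st$positions$feature_class == "intron", ]
  expect_equal(hit$feature_idx, 3L)
  expect_equal(hit$n_features, 4L)
  expect_equal(hit$rel_feature_pos, 0.75)
  expect_equal(hit$rel_within_pos, 150 / 200)

  # minus strand: genomically-first intron is the last in transcript order
  ftm <- h_tx_features(
    "gB", "chr2", "-",
    exons = list(c(1001, 1200), c(1401, 1600), c(1801, 2000)),
    cds = list(c(1001, 1200), c(1401, 1600), c(1801, 2000))
  )
  mm <- h_models(ftm, c(chr2 = 50000L))
  pm <- tibble::tibble(pac_id = "P1", chrom = "chr2", strand = "-",
                       start = 1251L, end = 1251L, summit = 1251L,
                       tag_count = 1L, n_positions = 1L)
  am <- assign_pacs(pm, build_index(mm))
  stm <- intron_exon_positional_stats(pm, am, mm, seed = 1)
  hm <- stm$positions[stm$positions$feature_class == "intron", ]
  expect_equal(hm$feature_idx, 2L)  # 5'->3' on minus strand
  # intron 1201-1400 (200 nt), minus-strand offset = 1400 - 1251 = 149
  expect_equal(hm$rel_within_pos, 149 / 200)
})

test_that("the random length control equals a direct seeded resampling oracle", {
  sim <- simulate_genome(sim_config(n_genes = 14, n_chromosomes = 1,
                                    chrom_length = 70000, seed = 71))
  tags <- simulate_tags(sim)
  run <- run_pipeline(sim$genome, sim$features, tags, seed = 71)
  st <- intron_exon_positional_stats(run$pacs, run$assignments, run$models,
                                     seed = 123)
  seg <- run$models$segments
  set.seed(123)
  for (cls in c("intron", "CDS")) {
    with_pac <- st$length_controls |>
      dplyr::filter(feature_class == cls, set == "with_pac")
    if (nrow(with_pac) == 0) next
    all_len <- seg[seg$label == cls, ]
    all_len <- all_len$end - all_len$start + 1L
    want <- sample(all_len, nrow(with_pac),
                   replace = nrow(with_pac) > length(all_len))
    got <- st$length_controls |>
      dplyr::filter(feature_class == cls, set == "random")
    expect_equal(got$length, want)
  }
})

test_that("EST validation window is inclusive at the boundary", {
  pacs <- cluster_tags(h_tags(1000L))
  est <- tibble::tibble(est_id = c("e1", "e2"), chrom = "chr1",
                        strand = "+", pos = c(1050L, 1051L))
  res <- est_validation(est, pacs)
  expect_equal(res$per_site$validated, c(TRUE, FALSE))
  expect_equal(res$n_validated, 1L)
  expect_equal(res$pct_validated, 50)
  # strand-aware: a minus-strand EST cannot validate against a plus PAC
  est2 <- tibble::tibble(est_id = "e3", chrom = "chr1", strand = "-",
                         pos = 1000L)
  expect_equal(est_validation(est2, pacs)$n_validated, 0L)
  expect_error(est_validation(est[0, ], pacs), "empty")
})
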