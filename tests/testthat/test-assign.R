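h_pac <- function(summit, strand = "+", chrom = "chr1", tag_count = 1L) {
  n <- max(length(summit), length(strand))
  tibble::tibble(
    pac_id = sprintf("P%03d", seq_len(n)), chrom = chrom,
    strand = rep_len(strand, n), start = as.integer(summit),
    end = as.integer(summit), summit = as.integer(summit),
    tag_count = rep_len(as.integer(tag_count), n),
    n_positions = 1L
  )
}

test_that("a summit in the 400-nt extension of a UTR-less gene is sense 3UTR", {
  ft <- h_tx_features("gA", "chr1", "+", exons = list(c(1001, 2000)),
                      cds = list(c(1001, 2000)))
  index <- build_index(h_models(ft, c(chr1 = 50000L)))
  # summit 150 nt past the stop codon
  a <- assign_pacs(h_pac(2150L), index)
  expect_equal(a$gene_id, "gA")
  expect_equal(a$region, "3UTR")
  expect_equal(a$orientation, "sense")
})

test_that("promoter window is honored and positions beyond it are intergenic", {
  ft <- h_tx_features("gA", "chr1", "+", exons = list(c(5001, 6000)),
                      cds = list(c(5001, 6000)))
  index <- build_index(h_models(ft, c(chr1 = 50000L)))
  # 2500 nt upstream of the 5' end: beyond the 2000-nt promoter
  far <- assign_pacs(h_pac(2500L), index)
  expect_equal(far$region, "intergenic")
  expect_true(is.na(far$gene_id))
  near <- assign_pacs(h_pac(3500L), index)
  expect_equal(near$region, "promoter")
  expect_true(is.na(near$gene_id))
})

test_that("gene body beats extension beats promoter when features overlap", {
  # gLeft(+) extension runs into gRight(+) promoter region upstream of gRight
  ft <- dplyr::bind_rows(
    h_tx_features("gLeft", "chr1", "+", exons = list(c(1001, 2000)),
                  cds = list(c(1001, 2000))),
    h_tx_features("gRight", "chr1", "+", exons = list(c(4001, 5000)),
                  cds = list(c(4001, 5000)))
  )
  index <- build_index(h_models(ft, c(chr1 = 50000L)))
  # 2100 is inside gLeft's extension AND gRight's promoter -> extension wins
  a <- assign_pacs(h_pac(2100L), index)
  expect_equal(a$gene_id, "gLeft")
  expect_equal(a$region, "3UTR")
  # inside gRight's body AND nothing else -> body label
  b <- assign_pacs(h_pac(4500L), index)
  expect_equal(b$gene_id, "gRight")
  expect_equal(b$region, "CDS")
})

test_that("antisense PAC in a convergent neighbor's extended 3'UTR is case 1", {
  # gA(+) 1001-3000 with annotated 3'UTR; gB(-) body starts at 3000+g+1
  g <- 50L
  ft <- dplyr::bind_rows(
    h_tx_features("gA", "chr1", "+", exons = list(c(1001, 3000)),
                  cds = list(c(1001, 2800)), utr3 = c(2801, 3000)),
    h_tx_features("gB", "chr1", "-", exons = list(c(3001 + g, 4500 + g)),
                  cds = list(c(3001 + g, 4500 + g)))
  )
  index <- build_index(h_models(ft, c(chr1 = 50000L)))
  # minus-strand PAC at 2900 inside gA's body: antisense to gA;
  # gB's 400-nt extension [2651, 3050] covers 2900 -> case 1
  a <- assign_pacs(h_pac(2900L, strand = "-"), index)
  expect_equal(a$antisense_gene_id, "gA")
  expect_equal(a$antisense_case, 1L)
  expect_equal(a$gene_id, "gB") # dual tabulation: sense in gB's extension
  expect_equal(a$region, "3UTR")
  expect_equal(a$orientation, "sense")
})

test_that("antisense PAC inside an overlapping neighbor's CDS is case 2", {
  ft <- dplyr::bind_rows(
    h_tx_features("gA", "chr1", "+", exons = list(c(1001, 3000)),
                  cds = list(c(1001, 3000))),
    h_tx_features("gB", "chr1", "-", exons = list(c(2500, 4000)),
                  cds = list(c(2500, 4000)))
  )
  index <- build_index(h_models(ft, c(chr1 = 50000L)))
  a <- assign_pacs(h_pac(2700L, strand = "-"), index)
  expect_equal(a$antisense_gene_id, "gA")
  expect_equal(a$gene_id, "gB")
  expect_equal(a$antisense_case, 2L)
})

test_that("an isolated antisense PAC with no convergent candidate is case 4", {
  ft <- h_tx_features("gA", "chr1", "+", exons = list(c(10001, 13000)),
                      cds = list(c(10001, 13000)))
  index <- build_index(h_models(ft, c(chr1 = 50000L)))
  a <- assign_pacs(h_pac(11500L, strand = "-"), index)
  expect_equal(a$antisense_gene_id, "gA")
  expect_equal(a$antisense_case, 4L)
  expect_equal(a$orientation, "antisense")
  expect_true(is.na(a$gene_id))
  expect_error(classify_antisense(h_pac(500L), index), "antisense")
})

test_that("antisense case labels switch at the extension and nearby-distance boundaries", {
  # gA(+) with annotated 3'UTR ending at 3000; PAC on '-' at 2900 inside gA.
  # gB(-) body [3001+g, 4500+g], annotated 3'UTR so its extension is 200 nt:
  # covers 2900 iff g <= 99; gB's annotated 3' end is 3001+g, distance to the
  # summit is g+101 -> case 3 iff g+101 <= 500 (g <= 399); case 4 beyond.
  params <- pa_params("mtr")
  for (g in seq(0L, 1000L, by = 100L)) {
    ft <- dplyr::bind_rows(
      h_tx_features("gA", "chr1", "+", exons = list(c(1001, 3000)),
                    cds = list(c(1001, 2800)), utr3 = c(2801, 3000)),
      h_tx_features("gB", "chr1", "-",
                    exons = list(c(3001 + g, 4500 + g)),
                    cds = list(c(3201 + g, 4500 + g)),
                    utr3 = c(3001 + g, 3200 + g))
    )
    index <- build_index(h_models(ft, c(chr1 = 50000L), params))
    a <- assign_pacs(h_pac(2900L, strand = "-"), index, params)
    expected_case <- if (g <= 99) 1L else if (g + 101 <= 500) 3L else 4L
    expect_equal(a$antisense_case, expected_case,
                 label = sprintf("case at gap %d", g))
  }
})

test_that("assignments are total, disjoint by construction, and percentages sum to 100", {
  sim <- simulate_genome(sim_config(n_genes = 16, n_chromosomes = 1,
                                    chrom_length = 80000, seed = 51))
  tags <- simulate_tags(sim)
  run <- run_pipeline(sim$genome, sim$features, tags, seed = 51)
  a <- run$assignments
  expect_equal(nrow(a), nrow(run$pacs))
  expect_equal(sort(a$pac_id), sort(run$pacs$pac_id))
  expect_equal(sum(run$region_table$pct_pacs), 100,
               tolerance = 1e-9)
  anti <- run$antisense_table
  if (sum(anti$n_pacs) > 0) {
    expect_equal(sum(anti$pct_pacs), 100, tolerance = 1e-9)
  }
  # antisense_case implies an antisense host
  expect_true(all(is.na(a$antisense_case) | !is.na(a$antisense_gene_id)))
  # intergenic implies no sense gene
  expect_true(all(a$region != "intergenic" | is.na(a$gene_id)))
})

test_that("intergenic distances match a brute-force nearest-boundary search", {
  sim <- simulate_genome(sim_config(n_genes = 8, n_chromosomes = 1,
                                    chrom_length = 80000, seed = 52))
  models <- h_models(sim$features, c(chr1 = 80000L))
  index <- build_index(models)
  set.seed(52)
  pacs <- h_pac(sample.int(80000L, 300), strand = sample(c("+", "-"), 300,
                                                         replace = TRUE))
  a <- assign_pacs(pacs, index)
  res <- intergenic_distances(a, models)
  g <- models$genes
  lo <- pmin(g$start, g$ext_start)
  hi <- pmax(g$end, g$ext_end)
  inter <- a[a$region == "intergenic" & is.na(a$antisense_gene_id), ]
  expect_equal(nrow(res$distances), nrow(inter))
  for (i in seq_len(nrow(inter))) {
    p <- inter$summit[i]
    want <- min(vapply(seq_len(nrow(g)), function(j) {
      if (p < lo[j]) lo[j] - p else if (p > hi[j]) p - hi[j] else 0L
    }, numeric(1)))
    expect_equal(res$distances$distance[res$distances$pac_id ==
                                          inter$pac_id[i]], want)
  }
  # binning convention: 999 nt counts as within 1000
  expect_equal(res$frac_far,
               mean(res$distances$distance > 1000))
})

test_that("no intergenic PACs yields an empty distance report", {
  ft <- h_tx_features("gA", "chr1", "+", exons = list(c(1001, 2000)),
                      cds = list(c(1001, 2000)))
  models <- h_models(ft, c(chr1 = 50000L))
  a <- assign_pacs(h_pac(1500L), build_index(models))
  res <- intergenic_distances(a, models)
  expect_equal(nrow(res$distances), 0L)
  expect_true(is.na(res$frac_far))
})
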