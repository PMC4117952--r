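test_that("a single two-exon transcript yields 5UTR/CDS/intron/CDS/3UTR with no AMB", {
  ft <- h_tx_features(
    "gA", "chr1", "+",
    exons = list(c(101, 300), c(401, 600)),
    cds = list(c(151, 300), c(401, 550)),
    utr5 = c(101, 150), utr3 = c(551, 600)
  )
  m <- build_gene_models(ft, c(chr1 = 10000L))
  seg <- m$segments
  expect_equal(seg$label, c("5UTR", "CDS", "intron", "CDS", "3UTR"))
  expect_equal(seg$start, c(101L, 151L, 301L, 401L, 551L))
  expect_equal(seg$end, c(150L, 300L, 400L, 550L, 600L))
  expect_false(any(seg$label == "AMB"))
  expect_true(m$genes$had_utr3)
  expect_equal(m$genes$cds_end3p, 550L)

  # two identical transcripts: merged model equals the single-transcript one
  ft2 <- dplyr::bind_rows(
    ft,
    h_tx_features("gA", "chr1", "+",
                  exons = list(c(101, 300), c(401, 600)),
                  cds = list(c(151, 300), c(401, 550)),
                  utr5 = c(101, 150), utr3 = c(551, 600),
                  tx_id = "gA.t2", with_gene_row = FALSE)
  )
  m2 <- build_gene_models(ft2, c(chr1 = 10000L))
  expect_equal(m2$segments, m$segments)
})

test_that("conflicting per-position labels between isoforms become AMB", {
  # t1: CDS across 201-400; t2: CDS 201-300, intron 301-400, CDS 401-500
  ft <- dplyr::bind_rows(
    h_tx_features("gB", "chr1", "+",
                  exons = list(c(201, 500)), cds = list(c(201, 500))),
    h_tx_features("gB", "chr1", "+",
                  exons = list(c(201, 300), c(401, 500)),
                  cds = list(c(201, 300), c(401, 500)),
                  tx_id = "gB.t2", with_gene_row = FALSE)
  )
  m <- build_gene_models(ft, c(chr1 = 10000L))
  amb <- m$segments[m$segments$label == "AMB", ]
  expect_equal(nrow(amb), 1L)
  expect_equal(c(amb$start, amb$end), c(301L, 400L))
  # flanks agree between isoforms and stay CDS
  expect_equal(m$segments$label[m$segments$start == 201], "CDS")
  expect_equal(m$segments$label[m$segments$start == 401], "CDS")
})

test_that("transcripts on mixed strands are rejected naming the gene", {
  ft <- dplyr::bind_rows(
    h_tx_features("gBad", "chr1", "+", exons = list(c(1, 100)),
                  cds = list(c(1, 100))),
    h_tx_features("gBad", "chr1", "-", exons = list(c(200, 300)),
                  cds = list(c(200, 300)), tx_id = "gBad.t2",
                  with_gene_row = FALSE)
  )
  expect_error(build_gene_models(ft, c(chr1 = 10000L)), "gBad")
})

test_that("3' extension lengths follow the annotated-3'UTR rule per species", {
  # plus-strand gene ending at 10000 WITH annotated 3'UTR: +200 nt
  with_utr <- h_tx_features("gC", "chr1", "+",
                            exons = list(c(9001, 10000)),
                            cds = list(c(9001, 9800)),
                            utr3 = c(9801, 10000))
  m <- h_models(with_utr, c(chr1 = 50000L), pa_params("mtr"))
  expect_equal(c(m$genes$ext_start, m$genes$ext_end), c(10001L, 10200L))
  expect_equal(m$genes$ext_len, 200L)

  # minus-strand gene starting at 501 WITHOUT annotated 3'UTR: 400 nt leftward
  no_utr <- h_tx_features("gD", "chr1", "-",
                          exons = list(c(501, 1500)), cds = list(c(501, 1500)))
  m2 <- h_models(no_utr, c(chr1 = 50000L), pa_params("mtr"))
  expect_equal(c(m2$genes$ext_start, m2$genes$ext_end), c(101L, 500L))
  expect_equal(m2$genes$ext_len, 400L)

  # Arabidopsis-like parameters: 338 nt for a UTR-less gene
  m3 <- h_models(no_utr, c(chr1 = 50000L), pa_params("ath"))
  expect_equal(m3$genes$ext_len, 338L)

  # clipping at the chromosome start
  near_edge <- h_tx_features("gE", "chr1", "-",
                             exons = list(c(301, 900)), cds = list(c(301, 900)))
  m4 <- h_models(near_edge, c(chr1 = 50000L), pa_params("mtr"))
  expect_equal(m4$genes$ext_start, 1L)
  expect_equal(m4$genes$ext_len, 300L)
})

test_that("extensions truncate at a downstream same-strand gene body but not at opposite-strand genes", {
  up <- h_tx_features("gUp", "chr1", "+", exons = list(c(1001, 2000)),
                      cds = list(c(1001, 2000)))
  down_same <- h_tx_features("gDown", "chr1", "+", exons = list(c(2151, 3000)),
                             cds = list(c(2151, 3000)))
  m <- h_models(dplyr::bind_rows(up, down_same), c(chr1 = 50000L))
  gu <- m$genes[m$genes$gene_id == "gUp", ]
  expect_equal(gu$ext_len, 150L) # truncated from 400 at gDown's body

  down_opp <- h_tx_features("gOpp", "chr1", "-", exons = list(c(2151, 3000)),
                            cds = list(c(2151, 3000)))
  m2 <- h_models(dplyr::bind_rows(up, down_opp), c(chr1 = 50000L))
  gu2 <- m2$genes[m2$genes$gene_id == "gUp", ]
  expect_equal(gu2$ext_len, 400L) # convergent overlap allowed
})

test_that("promoter is exactly promoter_extent upstream, clipped at edges", {
  ft <- h_tx_features("gF", "chr1", "+", exons = list(c(5001, 6000)),
                      cds = list(c(5101, 6000)), utr5 = c(5001, 5100))
  m <- h_models(ft, c(chr1 = 50000L))
  expect_equal(c(m$genes$prom_start, m$genes$prom_end), c(3001L, 5000L))
  expect_equal(m$genes$prom_end - m$genes$prom_start + 1L, 2000L)

  # clipped at chromosome start; anchor falls back to gene start without 5'UTR
  ft2 <- h_tx_features("gG", "chr1", "+", exons = list(c(501, 1500)),
                       cds = list(c(501, 1500)))
  m2 <- h_models(ft2, c(chr1 = 50000L))
  expect_equal(c(m2$genes$prom_start, m2$genes$prom_end), c(1L, 500L))
})

test_that("index point queries match a linear-scan oracle on 1000 fuzzed points", {
  set.seed(42)
  sim <- simulate_genome(sim_config(n_genes = 20, n_chromosomes = 1,
                                    chrom_length = 90000, seed = 5))
  models <- h_models(sim$features, c(chr1 = 90000L))
  index <- build_index(models)
  pos <- sample.int(90000L, 1000, replace = TRUE)
  strand <- sample(c("+", "-"), 1000, replace = TRUE)
  params <- pa_params("mtr")
  pacs <- tibble::tibble(
    pac_id = sprintf("P%04d", seq_len(1000)), chrom = "chr1",
    strand = strand, start = pos, end = pos, summit = pos,
    tag_count = 1L, n_positions = 1L
  )
  got <- assign_pacs(pacs, index, params)
  for (i in seq_len(1000)) {
    want <- h_assign_oracle("chr1", pos[i], strand[i], models, params)
    expect_identical(got$region[i], want$region)
    expect_identical(got$gene_id[i], want$gene)
  }
})

test_that("a query position covered by two opposite-strand genes returns both", {
  ft <- dplyr::bind_rows(
    h_tx_features("gP", "chr1", "+", exons = list(c(1001, 2000)),
                  cds = list(c(1001, 2000))),
    h_tx_features("gM", "chr1", "-", exons = list(c(1500, 2500)),
                  cds = list(c(1500, 2500)))
  )
  index <- build_index(h_models(ft, c(chr1 = 10000L)))
  hits <- query_index(index, "chr1", 1700L, strand = NULL) |>
    dplyr::filter(kind == "body")
  expect_setequal(hits$gene_id, c("gP", "gM"))
  expect_warning(query_index(index, "chrX", 100L), "unknown chromosome")
})

test_that("annotation GFF3 round-trips through disk byte-compatibly at the model level", {
  sim <- simulate_genome(sim_config(n_genes = 10, n_chromosomes = 1,
                                    chrom_length = 50000, seed = 11))
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_annotation_gff3(sim$features, gff)
  reread <- read_annotation(gff)
  m1 <- build_gene_models(sim$features, c(chr1 = 50000L))
  m2 <- build_gene_models(reread, c(chr1 = 50000L))
  expect_equal(m2$segments, m1$segments)
  expect_equal(m2$genes, m1$genes)
  # the generator's own segment tiling is reproduced exactly
  gen <- sim$truth$segments |>
    dplyr::arrange(chrom, start) |>
    dplyr::select(gene_id, chrom, strand, start, end, label)
  got <- m2$segments |>
    dplyr::arrange(chrom, start) |>
    dplyr::select(gene_id, chrom, strand, start, end, label)
  expect_equal(got, gen)
})

test_that("merged-model GFF3 export preserves coordinates and labels", {
  sim <- simulate_genome(sim_config(n_genes = 8, n_chromosomes = 1,
                                    chrom_length = 40000, seed = 12))
  models <- h_models(sim$features, c(chr1 = 40000L))
  out <- withr::local_tempfile(fileext = ".gff3")
  write_models_gff3(models, out)
  back <- read_models_gff3(out, c(chr1 = 40000L))
  expect_equal(
    dplyr::arrange(back$segments, chrom, start, gene_id),
    dplyr::arrange(models$segments, chrom, start, gene_id)
  )
  g1 <- dplyr::select(dplyr::arrange(back$genes, gene_id),
                      gene_id, start, end, ext_start, ext_end, ext_len)
  g2 <- dplyr::select(dplyr::arrange(models$genes, gene_id),
                      gene_id, start, end, ext_start, ext_end, ext_len)
  expect_equal(g1, g2)
})

test_that("extension never alters gene-body segments", {
  sim <- simulate_genome(sim_config(n_genes = 10, n_chromosomes = 1,
                                    chrom_length = 50000, seed = 13))
  m0 <- build_gene_models(sim$features, c(chr1 = 50000L))
  m1 <- extend_models(m0, pa_params("mtr"))
  expect_equal(m1$segments, m0$segments)
})
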