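#' Run the poly(A)-site pipeline end to end
#'
#' Executes curation (mate pairing, internal-priming removal, aggregation),
#' PAC clustering, merged/extended gene-model construction, region and
#' antisense assignment, region/antisense/per-gene tabulations, intergenic
#' distances and stratified nucleotide profiles; optionally EST validation
#' (when `est_sites` is given) and the ortholog feature-conservation tests
#' (when `orthologs` with `feature_a`/`feature_b` flags is given). When
#' `outdir` is set, report TSVs, PAC GFF3/BED and a JSON run manifest
#' (parameters, seed, per-stage counts) are written; rerunning with the same
#' inputs and seed writes byte-identical outputs.
#'
#' @param genome Named [Biostrings::DNAStringSet] (or FASTA path).
#' @param annotation Feature tibble (see [read_annotation()]) or GFF3 path.
#' @param tags Tag tibble (see [simulate_tags()], [read_tags_bed()]) or BED
#'   path.
#' @param est_sites Optional EST site tibble.
#' @param orthologs Optional ortholog tibble with feature flags.
#' @param params [pa_params()].
#' @param outdir Optional output directory.
#' @param seed Seed for the randomized stages (conservation trials).
#' @return A `pa_run` list with every intermediate and report.
#' @export
run_pipeline <- function(genome, annotation, tags, est_sites = NULL,
                         orthologs = NULL, params = pa_params("mtr"),
                         outdir = NULL, seed = 1L) {
  if (is.character(genome)) genome <- read_genome_fasta(genome)
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  if (is.character(tags)) tags <- read_tags_bed(tags)
  .assert_tags(tags)

  curated <- curate_tags(tags, genome, params)
  pacs <- cluster_tags(curated, params)
  models <- build_gene_models(annotation, .chrom_lengths(genome)) |>
    extend_models(params)
  index <- build_index(models)
  assignments <- assign_pacs(pacs, index, params)
  region_table <- tabulate_regions(assignments)
  antisense_table <- tabulate_antisense(assignments)
  gene_pacs <- pacs_per_gene(assignments)
  intergenic <- intergenic_distances(assignments, models)
  profiles <- if (nrow(pacs) > 0) {
    suppressMessages(stratified_profiles(pacs, assignments, genome, params))
  } else NULL
  est <- if (!is.null(est_sites) && nrow(est_sites) > 0 && nrow(pacs) > 0) {
    est_validation(est_sites, pacs, params)
  } else NULL
  conservation <- NULL
  if (!is.null(orthologs) && all(c("feature_a", "feature_b") %in%
                                 names(orthologs))) {
    conservation <- feature_conservation_test(
      feature_b = orthologs$gene_b[orthologs$feature_b],
      orthologs = orthologs,
      feature_a = orthologs$gene_a[orthologs$feature_a],
      pool_a = orthologs$gene_a,
      params = params, seed = seed, feature = "ortholog_feature"
    )
  }

  manifest <- list(
    seed = seed,
    params = unclass(params),
    stages = list(
      raw_tags = sum(tags$count),
      curated_tags = sum(curated$count),
      distinct_positions = nrow(curated),
      pacs = nrow(pacs),
      genes = nrow(models$genes),
      assigned_sense_gene_pacs = sum(!is.na(assignments$gene_id)),
      antisense_pacs = sum(!is.na(assignments$antisense_gene_id)),
      intergenic_pacs = nrow(intergenic$distances),
      est_sites = if (is.null(est)) 0L else est$n_total
    )
  )
  run <- structure(list(
    params = params, curated = curated, curation_report =
      curation_report(curated), pacs = pacs, models = models,
    assignments = assignments, region_table = region_table,
    antisense_table = antisense_table, gene_pacs = gene_pacs,
    intergenic = intergenic, profiles = profiles, est = est,
    conservation = conservation, manifest = manifest
  ), class = "pa_run")

  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    readr::write_tsv(run$curation_report,
                     file.path(outdir, "curation_cascade.tsv"))
    readr::write_tsv(region_table, file.path(outdir, "region_table.tsv"))
    readr::write_tsv(antisense_table,
                     file.path(outdir, "antisense_table.tsv"))
    readr::write_tsv(gene_pacs$marginal,
                     file.path(outdir, "genes_by_pac_count.tsv"))
    readr::write_tsv(assignments, file.path(outdir, "assignments.tsv"))
    if (nrow(pacs) > 0) {
      write_pacs(pacs, file.path(outdir, "pacs.gff3"))
      write_pacs(pacs, file.path(outdir, "pacs.bed"))
      write_models_gff3(models, file.path(outdir, "models_extended.gff3"))
    }
    if (!is.null(profiles)) {
      write_profile_tsv(profiles, file.path(outdir, "profiles.tsv"))
    }
    if (!is.null(est)) {
      readr::write_tsv(est$per_site, file.path(outdir, "est_validation.tsv"))
    }
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run
}

#' @export
print.pa_run <- function(x, ...) {
  st <- x$manifest$stages
  cat("<pa_run>\n")
  cat("  tags: ", st$raw_tags, " raw -> ", st$curated_tags, " curated (",
      st$distinct_positions, " distinct positions)\n", sep = "")
  cat("  PACs: ", st$pacs, " (", st$assigned_sense_gene_pacs,
      " in genes, ", st$antisense_pacs, " antisense, ",
      st$intergenic_pacs, " intergenic)\n", sep = "")
  cat("  genes with >=1 PAC: ", nrow(x$gene_pacs$per_gene), "; ",
      round(100 * x$gene_pacs$frac_multi), "% with >1 PAC\n", sep = "")
  invisible(x)
}
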