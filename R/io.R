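#' Write simulated (or real) genome sequences as FASTA
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA path.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write an annotation feature table as GFF3
#'
#' @param features Feature tibble as produced by [simulate_genome()] /
#'   [read_annotation()] (`chrom`, `start`, `end`, `strand`, `type`, `id`,
#'   `tx_id`, `gene_id`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(features, path) {
  if (nrow(features) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  parent <- dplyr::case_when(
    features$type == "gene" ~ NA_character_,
    features$type == "mRNA" ~ features$gene_id,
    TRUE ~ features$tx_id
  )
  gr <- GenomicRanges::GRanges(features$chrom,
                               IRanges::IRanges(features$start, features$end),
                               strand = features$strand)
  gr$type <- features$type
  gr$ID <- features$id
  gr$Parent <- IRanges::CharacterList(
    lapply(parent, function(p) if (is.na(p)) character(0) else p)
  )
  gr$phase <- ifelse(features$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write tag records as 6-column BED
#'
#' One single-base interval per tag: the cleavage coordinate (1-based `pos`)
#' becomes the BED interval `[pos - 1, pos)`. The name field carries the tag
#' id and the score field the tag count.
#'
#' @param tags Tag tibble (see [simulate_tags()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tags_bed <- function(tags, path) {
  .assert_tags(tags)
  gr <- GenomicRanges::GRanges(tags$chrom,
                               IRanges::IRanges(tags$pos, tags$pos),
                               strand = tags$strand)
  gr$name <- tags$tag_id
  gr$score <- tags$count
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read 6-column BED tag records
#'
#' @param path BED path.
#' @param mate_status Mate flag to assign to all records (plain BED carries
#'   no mate information).
#' @return A tag tibble.
#' @export
read_tags_bed <- function(path, mate_status = "paired_unique") {
  gr <- rtracklayer::import(path, format = "bed")
  tibble(
    tag_id = if (!is.null(gr$name)) as.character(gr$name)
             else sprintf("t%06d", seq_along(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    pos = GenomicRanges::end(gr),
    count = if (!is.null(gr$score)) as.integer(gr$score) else 1L,
    mate_status = mate_status
  )
}

#' Write / read a two-column ortholog pair table (TSV)
#'
#' @param orthologs Tibble with `gene_a`, `gene_b` (feature flag columns, if
#'   present, are written too).
#' @param path TSV path.
#' @return `path` (write) or a tibble (read).
#' @export
write_orthologs_tsv <- function(orthologs, path) {
  readr::write_tsv(orthologs, path)
  invisible(path)
}

#' @rdname write_orthologs_tsv
#' @export
read_orthologs_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write the full simulation bundle to a directory
#'
#' Emits `genome.fa`, `annotation.gff3`, `tags.bed` (when tags are given)
#' and a JSON ground-truth sidecar `truth.json`.
#'
#' @param sim A `pa_sim`.
#' @param dir Output directory (created if missing).
#' @param tags Optional tag tibble from [simulate_tags()].
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir, tags = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_genome_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_annotation_gff3(sim$features, file.path(dir, "annotation.gff3"))
  if (!is.null(tags)) write_tags_bed(tags, file.path(dir, "tags.bed"))
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write PACs as GFF3 and/or BED
#'
#' The GFF3 uses feature type `PAC` with attributes `tag_count`, `summit`
#' and `n_positions`; the BED uses the PAC span with the summit recorded in
#' the name field.
#'
#' @param pacs PAC tibble from [cluster_tags()].
#' @param path Output path; format chosen by extension (`.gff3`/`.gff` or
#'   `.bed`).
#' @return `path`, invisibly.
#' @export
write_pacs <- function(pacs, path) {
  gr <- GenomicRanges::GRanges(pacs$chrom,
                               IRanges::IRanges(pacs$start, pacs$end),
                               strand = pacs$strand)
  if (grepl("\\.bed$", path)) {
    gr$name <- sprintf("%s|summit=%d", pacs$pac_id, pacs$summit)
    gr$score <- pacs$tag_count
    rtracklayer::export(gr, path, format = "bed")
  } else {
    gr$type <- "PAC"
    gr$ID <- pacs$pac_id
    gr$tag_count <- pacs$tag_count
    gr$summit <- pacs$summit
    gr$n_positions <- pacs$n_positions
    rtracklayer::export(gr, path, format = "gff3")
  }
  invisible(path)
}
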