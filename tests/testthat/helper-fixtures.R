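# In-code fixtures: tiny genomes, hand-built annotations and tag tables.

h_genome <- function(...) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(seqs)
  g
}

h_random_genome <- function(len, chroms = "chr1", seed = 1) {
  set.seed(seed)
  g <- Biostrings::DNAStringSet(vapply(chroms, function(ch) {
    paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1)))
  names(g) <- chroms
  g
}

# feature rows for one transcript; exons/cds/utr5/utr3 are lists of
# c(start, end) pairs (1-based inclusive)
h_tx_features <- function(gene_id, chrom, strand, exons, cds,
                          utr5 = NULL, utr3 = NULL,
                          tx_id = paste0(gene_id, ".t1"),
                          with_gene_row = TRUE) {
  block <- function(type, blocks) {
    if (is.null(blocks)) return(NULL)
    if (!is.list(blocks)) blocks <- list(blocks)
    tibble::tibble(
      chrom = chrom, start = vapply(blocks, `[`, numeric(1), 1),
      end = vapply(blocks, `[`, numeric(1), 2), strand = strand,
      type = type, id = NA_character_, tx_id = tx_id, gene_id = gene_id
    )
  }
  rows <- dplyr::bind_rows(
    block("exon", exons), block("CDS", cds),
    block("five_prime_UTR", utr5), block("three_prime_UTR", utr3)
  )
  span <- c(min(rows$start), max(rows$end))
  hdr <- dplyr::bind_rows(
    if (with_gene_row)
      tibble::tibble(chrom = chrom, start = span[1], end = span[2],
                     strand = strand, type = "gene", id = gene_id,
                     tx_id = NA_character_, gene_id = gene_id),
    tibble::tibble(chrom = chrom, start = span[1], end = span[2],
                   strand = strand, type = "mRNA", id = tx_id,
                   tx_id = tx_id, gene_id = gene_id)
  )
  dplyr::bind_rows(hdr, rows) |>
    dplyr::mutate(start = as.integer(start), end = as.integer(end))
}

h_tags <- function(pos, strand = "+", chrom = "chr1", count = 1L,
                   mate_status = "paired_unique") {
  n <- max(length(pos), length(strand), length(count))
  tibble::tibble(
    tag_id = sprintf("t%04d", seq_len(n)),
    chrom = chrom,
    strand = rep_len(strand, n),
    pos = as.integer(rep_len(pos, n)),
    count = as.integer(rep_len(count, n)),
    mate_status = rep_len(mate_status, n)
  )
}

# models for a set of feature tables over one genome
h_models <- function(features, chrom_lengths, params = pa_params("mtr")) {
  build_gene_models(features, chrom_lengths) |> extend_models(params)
}

# brute-force transitive closure of the "< gap" relation over positions;
# returns cluster id per position (independent of the chaining code path)
h_closure_clusters <- function(pos, gap = 24L) {
  n <- length(pos)
  adj <- abs(outer(pos, pos, "-")) < gap
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier) > 0) {
      nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & is.na(comp))
      comp[nxt] <- cur
      frontier <- nxt
    }
  }
  comp
}

# linear-scan assignment oracle mirroring the documented precedence rules
h_assign_oracle <- function(chrom, pos, strand, models, params) {
  g <- models$genes
  seg <- models$segments
  best <- list(priority = Inf, dist = Inf, gene = NA_character_,
               label = NA_character_, kind = NA_character_)
  consider <- function(priority, dist, gene, label, kind) {
    if (priority < best$priority ||
        (priority == best$priority && dist < best$dist) ||
        (priority == best$priority && dist == best$dist &&
         !is.na(best$gene) && gene < best$gene)) {
      best <<- list(priority = priority, dist = dist, gene = gene,
                    label = label, kind = kind)
    }
  }
  for (i in seq_len(nrow(g))) {
    if (g$chrom[i] != chrom || g$strand[i] != strand) next
    g3p <- if (g$strand[i] == "+") g$end[i] else g$start[i]
    d <- abs(pos - g3p)
    if (pos >= g$start[i] && pos <= g$end[i]) {
      s <- seg[seg$gene_id == g$gene_id[i] & seg$start <= pos &
                 seg$end >= pos, ]
      consider(1, d, g$gene_id[i], s$label[1], "body")
    } else if (g$ext_len[i] > 0 && pos >= g$ext_start[i] &&
               pos <= g$ext_end[i]) {
      consider(2, d, g$gene_id[i], "3UTR", "ext")
    } else if (pos >= g$prom_start[i] && pos <= g$prom_end[i]) {
      consider(3, d, g$gene_id[i], "promoter", "prom")
    }
  }
  if (is.infinite(best$priority)) {
    list(gene = NA_character_, region = "intergenic")
  } else if (best$kind == "prom") {
    list(gene = NA_character_, region = "promoter")
  } else {
    list(gene = best$gene, region = best$label)
  }
}
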