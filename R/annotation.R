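#' Read a GFF3 gene annotation into a feature table
#'
#' Parses `gene`, `mRNA`, `exon`, `CDS`, `five_prime_UTR` and
#' `three_prime_UTR` features and resolves each child feature to its
#' transcript and gene. Coordinates are 1-based inclusive, as in GFF3.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`, `type`,
#'   `id`, `tx_id`, `gene_id`.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- c("gene", "mRNA", "transcript", "exon", "CDS",
            "five_prime_UTR", "three_prime_UTR")
  gr <- gr[as.character(gr$type) %in% keep]
  first_parent <- function(p) {
    vapply(as.list(p), function(x) if (length(x) > 0) x[[1]] else NA_character_,
           character(1))
  }
  ft <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    parent = if (!is.null(gr$Parent)) first_parent(gr$Parent) else NA_character_
  )
  ft$type[ft$type == "transcript"] <- "mRNA"
  tx <- ft[ft$type == "mRNA", ]
  tx_gene <- setNames(tx$parent, tx$id)
  ft <- ft |>
    mutate(
      tx_id = case_when(
        type == "mRNA" ~ id,
        type == "gene" ~ NA_character_,
        TRUE ~ parent
      ),
      gene_id = case_when(
        type == "gene" ~ id,
        type == "mRNA" ~ parent,
        # children may hang off an mRNA or directly off a gene
        TRUE ~ if_else(parent %in% names(tx_gene),
                       unname(tx_gene[parent]), parent)
      )
    ) |>
    select("chrom", "start", "end", "strand", "type", "id", "tx_id", "gene_id")
  # children attached straight to a gene: synthesize one transcript per gene
  direct <- ft$type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR") &
    !(ft$tx_id %in% tx$id)
  ft$tx_id[direct] <- paste0(ft$gene_id[direct], ".t1")
  ft
}

# label the bases of ONE transcript: 5UTR / CDS / intron / 3UTR
# returns tibble(start, end, label); 1-based inclusive
.tx_segments <- function(tx) {
  strand <- tx$strand[1]
  ir <- function(d) IRanges::reduce(IRanges::IRanges(d$start, d$end))
  exons <- tx[tx$type == "exon", ]
  cds <- tx[tx$type == "CDS", ]
  if (nrow(exons) == 0) exons <- cds
  if (nrow(exons) == 0) return(tibble(start = integer(), end = integer(),
                                      label = character()))
  ex <- ir(exons)
  span <- IRanges::IRanges(min(IRanges::start(ex)), max(IRanges::end(ex)))
  introns <- IRanges::setdiff(span, ex)
  if (nrow(cds) == 0) {
    # protein-coding prediction fallback: exon bases count as CDS
    cd <- ex
    utr <- IRanges::IRanges()
  } else {
    cd <- ir(cds)
    utr <- IRanges::setdiff(ex, cd)
  }
  out <- list(
    tibble(start = IRanges::start(cd), end = IRanges::end(cd), label = "CDS"),
    tibble(start = IRanges::start(introns), end = IRanges::end(introns),
           label = "intron")
  )
  if (length(utr) > 0) {
    cds_lo <- min(IRanges::start(cd))
    cds_hi <- max(IRanges::end(cd))
    us <- IRanges::start(utr)
    lab <- if_else(us < cds_lo,
                   if (strand == "+") "5UTR" else "3UTR",
                   if (strand == "+") "3UTR" else "5UTR")
    out <- c(out, list(tibble(start = us, end = IRanges::end(utr), label = lab)))
  }
  bind_rows(out) |> arrange(.data$start)
}

#' Merge the transcripts of one gene into a unique gene model
#'
#' Positions annotated identically in every transcript that covers them keep
#' that label; positions whose label differs between transcripts (for
#' example CDS in one isoform, intron in another) become `AMB`. Gaps inside
#' the merged span covered by no transcript are labelled `intron`.
#'
#' @param tx_segments A tibble with columns `tx_id`, `start`, `end`, `label`
#'   (labels among `5UTR`, `CDS`, `intron`, `3UTR`), all on one strand of one
#'   chromosome.
#' @return A tibble of maximal non-overlapping segments (`start`, `end`,
#'   `label`) tiling the merged gene span.
#' @export
merge_gene <- function(tx_segments) {
  if (nrow(tx_segments) == 0) {
    return(tibble(start = integer(), end = integer(), label = character()))
  }
  ir <- IRanges::IRanges(tx_segments$start, tx_segments$end)
  span <- IRanges::IRanges(min(tx_segments$start), max(tx_segments$end))
  d <- IRanges::disjoin(ir)
  ov <- IRanges::findOverlaps(d, ir)
  labs <- split(tx_segments$label[S4Vectors::subjectHits(ov)],
                S4Vectors::queryHits(ov))
  dl <- vapply(labs, function(u) {
    u <- unique(u)
    if (length(u) == 1L) u else "AMB"
  }, character(1))
  seg <- tibble(start = IRanges::start(d), end = IRanges::end(d), label = dl)
  gaps <- IRanges::setdiff(span, d)
  if (length(gaps) > 0) {
    seg <- bind_rows(seg, tibble(start = IRanges::start(gaps),
                                 end = IRanges::end(gaps), label = "intron"))
  }
  seg <- arrange(seg, .data$start)
  # coalesce adjacent segments with the same label
  brk <- cumsum(c(TRUE, seg$label[-1] != seg$label[-nrow(seg)] |
                    seg$start[-1] != seg$end[-nrow(seg)] + 1L))
  seg |>
    mutate(.grp = brk) |>
    group_by(.data$.grp) |>
    summarise(start = min(.data$start), end = max(.data$end),
              label = first(.data$label), .groups = "drop") |>
    select("start", "end", "label")
}

#' Build merged gene models from an annotation feature table
#'
#' Applies [merge_gene()] to every gene, records whether the gene has any
#' annotated 3'-UTR bases, and locates the 3'-most CDS coordinate (used for
#' 3'-UTR length measurements) and the 5'-most transcribed coordinate (the
#' promoter anchor).
#'
#' @param features Feature table from [read_annotation()] or
#'   [simulate_genome()].
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return A `pa_models` object: a list with tibbles `genes` and `segments`
#'   plus the chromosome lengths. Extensions and promoters are filled in by
#'   [extend_models()].
#' @export
build_gene_models <- function(features, chrom_lengths) {
  parts <- features |>
    filter(.data$type %in% c("exon", "CDS", "five_prime_UTR",
                             "three_prime_UTR"))
  if (nrow(parts) == 0) {
    return(structure(list(genes = tibble(), segments = tibble(),
                          chrom_lengths = chrom_lengths),
                     class = "pa_models"))
  }
  by_gene <- split(parts, parts$gene_id)
  one <- function(g) {
    if (length(unique(g$strand)) != 1) {
      stop("gene ", g$gene_id[1], " has transcripts on mixed strands",
           call. = FALSE)
    }
    segs <- split(g, g$tx_id) |>
      map(.tx_segments) |>
      (\(l) bind_rows(l, .id = "tx_id"))()
    merged <- merge_gene(segs)
    strand <- g$strand[1]
    cds <- g[g$type == "CDS", ]
    cds_end3p <- if (nrow(cds) == 0) NA_integer_ else {
      if (strand == "+") max(cds$end) else as.integer(min(cds$start))
    }
    tss <- if (strand == "+") min(merged$start) else max(merged$end)
    list(
      gene = tibble(
        gene_id = g$gene_id[1], chrom = g$chrom[1], strand = strand,
        start = min(merged$start), end = max(merged$end),
        had_utr3 = any(merged$label == "3UTR"),
        cds_end3p = cds_end3p, tss_anchor = as.integer(tss),
        n_tx = length(unique(g$tx_id))
      ),
      segments = mutate(merged, gene_id = g$gene_id[1], chrom = g$chrom[1],
                        strand = strand)
    )
  }
  res <- map(by_gene, one)
  structure(
    list(
      genes = list_rbind(map(res, "gene")) |> arrange(.data$chrom, .data$start),
      segments = list_rbind(map(res, "segments")) |>
        select("gene_id", "chrom", "strand", "start", "end", "label") |>
        arrange(.data$chrom, .data$start),
      chrom_lengths = chrom_lengths
    ),
    class = "pa_models"
  )
}

#' Extend gene models at their 3' ends and attach promoter windows
#'
#' Genes with an annotated 3'-UTR are extended by `params$ext_with_utr` nt
#' downstream of the gene body; genes without one by
#' `params$ext_without_utr` nt. Extensions are clipped at chromosome edges
#' and truncated where they would run into the body of the nearest
#' downstream gene on the same strand (overlap with opposite-strand genes is
#' allowed: that is what produces convergent antisense overlap). The promoter
#' is the `params$promoter_extent` nt upstream of the 5'-most transcribed
#' coordinate, clipped at the chromosome edge.
#'
#' @param models A `pa_models` object from [build_gene_models()].
#' @param params A [pa_params()] object.
#' @return The models with `ext_start`, `ext_end`, `ext_len`, `prom_start`,
#'   `prom_end` columns filled in `genes`. Empty extensions (fully truncated)
#'   have `ext_len = 0`.
#' @export
extend_models <- function(models, params = pa_params("mtr")) {
  g <- models$genes
  if (nrow(g) == 0) {
    models$genes <- g
    return(models)
  }
  len <- models$chrom_lengths[g$chrom]
  want <- if_else(g$had_utr3, params$ext_with_utr, params$ext_without_utr)
  ext_start <- if_else(g$strand == "+", g$end + 1L, pmax(1L, g$start - want))
  ext_end <- if_else(g$strand == "+", pmin(as.integer(len), g$end + want),
                     g$start - 1L)
  # truncate at the nearest same-strand downstream gene body
  for (i in seq_len(nrow(g))) {
    same <- g$chrom == g$chrom[i] & g$strand == g$strand[i] &
      g$gene_id != g$gene_id[i]
    if (g$strand[i] == "+") {
      ds <- g$start[same & g$start > g$end[i]]
      if (length(ds) > 0) ext_end[i] <- min(ext_end[i], min(ds) - 1L)
    } else {
      ds <- g$end[same & g$end < g$start[i]]
      if (length(ds) > 0) ext_start[i] <- max(ext_start[i], max(ds) + 1L)
    }
  }
  prom_start <- if_else(g$strand == "+",
                        pmax(1L, g$tss_anchor - params$promoter_extent),
                        g$tss_anchor + 1L)
  prom_end <- if_else(g$strand == "+", g$tss_anchor - 1L,
                      pmin(as.integer(len), g$tss_anchor + params$promoter_extent))
  models$genes <- g |>
    mutate(
      ext_start = as.integer(ext_start), ext_end = as.integer(ext_end),
      ext_len = pmax(0L, .data$ext_end - .data$ext_start + 1L),
      prom_start = as.integer(prom_start), prom_end = as.integer(prom_end)
    )
  models$params <- params
  models
}

#' @export
print.pa_models <- function(x, ...) {
  cat("<pa_models> ", nrow(x$genes), " genes, ", nrow(x$segments),
      " segments on ", length(x$chrom_lengths), " chromosome(s)\n", sep = "")
  if (!is.null(x$genes$ext_len)) {
    cat("  3' extensions attached (median ", median(x$genes$ext_len),
        " nt)\n", sep = "")
  }
  invisible(x)
}

#' Build a strand-aware interval index over gene models
#'
#' Indexes gene-body segments, 3' extensions (labelled `3UTR`) and promoter
#' windows as a `GRanges` for sublinear point queries.
#'
#' @param models Extended `pa_models` (see [extend_models()]).
#' @return A `pa_index` object wrapping a `GRanges` with metadata columns
#'   `gene_id`, `label`, `kind` (`body`/`ext`/`prom`) and `priority`.
#' @export
build_index <- function(models) {
  g <- models$genes
  if (is.null(g$ext_start)) {
    stop("models must be extended with extend_models() before indexing",
         call. = FALSE)
  }
  rows <- bind_rows(
    models$segments |>
      mutate(kind = "body", priority = 1L),
    g |>
      filter(.data$ext_len > 0) |>
      mutate(start = .data$ext_start, end = .data$ext_end, label = "3UTR",
             kind = "ext", priority = 2L) |>
      select("gene_id", "chrom", "strand", "start", "end", "label",
             "kind", "priority"),
    g |>
      filter(.data$prom_end >= .data$prom_start) |>
      mutate(start = .data$prom_start, end = .data$prom_end,
             label = "promoter", kind = "prom", priority = 3L) |>
      select("gene_id", "chrom", "strand", "start", "end", "label",
             "kind", "priority")
  )
  gr <- GenomicRanges::GRanges(
    seqnames = rows$chrom,
    ranges = IRanges::IRanges(rows$start, rows$end),
    strand = rows$strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = rows$gene_id, label = rows$label, kind = rows$kind,
    priority = rows$priority
  )
  structure(list(gr = gr, genes = g, chrom_lengths = models$chrom_lengths,
                 warned_chroms = new.env(parent = emptyenv())),
             class = "pa_index")
}

#' Point query against the gene-model index
#'
#' @param index A `pa_index` from [build_index()].
#' @param chrom,pos,strand Vectors describing query points. `strand = NULL`
#'   returns hits on both strands.
#' @return A tibble with one row per (query, hit): `query`, `gene_id`,
#'   `label`, `kind`, `priority`, `strand`.
#' @export
query_index <- function(index, chrom, pos, strand = NULL) {
  known <- chrom %in% names(index$chrom_lengths) |
    chrom %in% unique(as.character(GenomicRanges::seqnames(index$gr)))
  unknown <- unique(chrom[!known])
  for (u in unknown) {
    if (!exists(u, envir = index$warned_chroms)) {
      warning("unknown chromosome in query: ", u, call. = FALSE)
      assign(u, TRUE, envir = index$warned_chroms)
    }
  }
  q <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(pos, pos),
    strand = strand %||% "*"
  )
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(q, index$gr, ignore.strand = is.null(strand))
  )
  hit <- S4Vectors::subjectHits(ov)
  m <- S4Vectors::mcols(index$gr)
  tibble(
    query = S4Vectors::queryHits(ov),
    gene_id = m$gene_id[hit],
    label = m$label[hit],
    kind = m$kind[hit],
    priority = m$priority[hit],
    strand = as.character(GenomicRanges::strand(index$gr))[hit]
  )
}

#' Write merged and extended gene models as GFF3
#'
#' Emits one `gene` feature per model plus segment features using the types
#' `five_prime_UTR`, `CDS`, `intron`, `three_prime_UTR` and the custom type
#' `AMB`, and (when present) a custom `three_prime_UTR_extension` feature
#' whose attributes record the extension length.
#'
#' @param models A `pa_models` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_models_gff3 <- function(models, path) {
  lab2type <- c(`5UTR` = "five_prime_UTR", CDS = "CDS", intron = "intron",
                `3UTR` = "three_prime_UTR", AMB = "AMB")
  g <- models$genes
  seg <- models$segments
  rows <- bind_rows(
    tibble(chrom = g$chrom, start = g$start, end = g$end, strand = g$strand,
           type = "gene", ID = g$gene_id, Parent = NA_character_,
           ext_len = if (is.null(g$ext_len)) NA_integer_ else g$ext_len),
    tibble(chrom = seg$chrom, start = seg$start, end = seg$end,
           strand = seg$strand, type = unname(lab2type[seg$label]),
           ID = NA_character_, Parent = seg$gene_id, ext_len = NA_integer_)
  )
  if (!is.null(g$ext_len) && any(g$ext_len > 0)) {
    ge <- g[g$ext_len > 0, ]
    rows <- bind_rows(rows, tibble(
      chrom = ge$chrom, start = ge$ext_start, end = ge$ext_end,
      strand = ge$strand, type = "three_prime_UTR_extension",
      ID = NA_character_, Parent = ge$gene_id, ext_len = ge$ext_len
    ))
  }
  rows <- arrange(rows, .data$chrom, .data$start, .data$type != "gene")
  gr <- GenomicRanges::GRanges(rows$chrom, IRanges::IRanges(rows$start, rows$end),
                               strand = rows$strand)
  gr$type <- rows$type
  gr$ID <- rows$ID
  gr$Parent <- IRanges::CharacterList(
    lapply(rows$Parent, function(p) if (is.na(p)) character(0) else p)
  )
  gr$ext_len <- rows$ext_len
  gr$phase <- ifelse(rows$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models written by [write_models_gff3()]
#'
#' @param path Path to the GFF3 file.
#' @param chrom_lengths Named chromosome lengths.
#' @return A `pa_models` object (without re-derived extensions; the stored
#'   extension features are attached as `genes$ext_start/ext_end/ext_len`).
#' @export
read_models_gff3 <- function(path, chrom_lengths) {
  gr <- rtracklayer::import(path, format = "gff3")
  type2lab <- c(five_prime_UTR = "5UTR", CDS = "CDS", intron = "intron",
                three_prime_UTR = "3UTR", AMB = "AMB")
  ty <- as.character(gr$type)
  parent <- if (is.null(gr$Parent)) {
    rep(NA_character_, length(gr))
  } else {
    vapply(as.list(gr$Parent),
           function(x) if (length(x) > 0) x[[1]] else NA_character_,
           character(1))
  }
  tb <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)), type = ty,
    id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    parent = parent
  )
  seg <- tb |>
    filter(.data$type %in% names(type2lab)) |>
    mutate(gene_id = .data$parent, label = unname(type2lab[.data$type])) |>
    select("gene_id", "chrom", "strand", "start", "end", "label") |>
    arrange(.data$chrom, .data$start)
  genes <- tb |>
    filter(.data$type == "gene") |>
    mutate(gene_id = .data$id) |>
    select("gene_id", "chrom", "strand", "start", "end")
  ext <- tb |>
    filter(.data$type == "three_prime_UTR_extension") |>
    select(gene_id = "parent", ext_start = "start", ext_end = "end")
  genes <- genes |>
    left_join(ext, by = "gene_id") |>
    mutate(ext_len = if_else(is.na(.data$ext_start), 0L,
                             .data$ext_end - .data$ext_start + 1L)) |>
    left_join(
      seg |>
        group_by(.data$gene_id) |>
        summarise(had_utr3 = any(.data$label == "3UTR"), .groups = "drop"),
      by = "gene_id"
    )
  structure(list(genes = genes, segments = seg, chrom_lengths = chrom_lengths),
            class = "pa_models")
}
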