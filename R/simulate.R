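#' Configuration for the synthetic PAT-seq simulator
#'
#' Defines the study conditions the generator emulates: gene-dense
#' chromosomes with uniform base composition, convergently transcribed gene
#' pairs, planted poly(A) sites with cluster microheterogeneity, genomic
#' oligo-A tracts with internal-priming artifact tags placed immediately
#' upstream, and a mix of genes with and without annotated 3'-UTRs (to
#' exercise the 200 vs 400 nt extension rule).
#'
#' The default per-gene site-count distribution follows the reported
#' gene-level APA spectrum (36/24/16/10/14 percent of genes with
#' 1/2/3/4/5 sites, i.e. 64 percent of genes with more than one site), and
#' the default region mix mirrors the reported genomic distribution of
#' sense PACs (3'-UTR dominated, with minorities in introns and CDS) plus an
#' antisense component.
#'
#' @param n_chromosomes,chrom_length Number and length (nt) of chromosomes.
#' @param n_genes Total genes across all chromosomes.
#' @param fraction_convergent_pairs Probability that a placement unit is a
#'   convergent (head-to-head 3' ends) gene pair rather than a single gene.
#' @param mean_exons_per_gene Mean number of coding exons per gene (min 1).
#' @param sites_per_gene_probs Probabilities for a gene carrying 1..5
#'   planted poly(A) sites.
#' @param region_mix Named proportions over `3UTR`, `intron`, `CDS`,
#'   `antisense`; must sum to 1.
#' @param microheterogeneity_sd SD (nt) of the discrete truncated-normal
#'   cleavage jitter; truncated at +/- 11 nt so the tags of one site always
#'   stay pairwise within the 24 nt clustering gap.
#' @param internal_priming_rate Proportion of emitted tags that are
#'   internal-priming artifacts anchored at planted A-tracts.
#' @param a_tract_density Planted A(>=6) tracts per kb of genome.
#' @param tags_per_site Mean tag count per planted site (Poisson, min 1).
#' @param unpaired_rate Proportion of genuine tags whose 5' mate failed
#'   (split between `unpaired` and `mate_multimapped`).
#' @param utr3_rate Fraction of genes given an annotated 3'-UTR.
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2L,
                       chrom_length = 100000L,
                       n_genes = 40L,
                       fraction_convergent_pairs = 0.3,
                       mean_exons_per_gene = 3,
                       sites_per_gene_probs = c(`1` = 0.36, `2` = 0.24,
                                                `3` = 0.16, `4` = 0.10,
                                                `5` = 0.14),
                       region_mix = c(`3UTR` = 0.71, intron = 0.07,
                                      CDS = 0.12, antisense = 0.10),
                       microheterogeneity_sd = 3,
                       internal_priming_rate = 0.05,
                       a_tract_density = 0.5,
                       tags_per_site = 10,
                       unpaired_rate = 0.10,
                       utr3_rate = 0.6,
                       seed = 1L) {
  props <- c(fraction_convergent_pairs, internal_priming_rate, unpaired_rate,
             utr3_rate, sites_per_gene_probs, region_mix)
  if (any(props < 0 | props > 1)) {
    stop("all proportions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(region_mix) - 1) > 1e-8) {
    stop("region_mix must sum to 1", call. = FALSE)
  }
  if (!setequal(names(region_mix), c("3UTR", "intron", "CDS", "antisense"))) {
    stop("region_mix must be named 3UTR, intron, CDS, antisense", call. = FALSE)
  }
  if (abs(sum(sites_per_gene_probs) - 1) > 1e-8) {
    stop("sites_per_gene_probs must sum to 1", call. = FALSE)
  }
  if (microheterogeneity_sd < 0 || a_tract_density < 0 || tags_per_site <= 0) {
    stop("microheterogeneity_sd and a_tract_density must be >= 0 and ",
         "tags_per_site > 0", call. = FALSE)
  }
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_genes = as.integer(n_genes),
    fraction_convergent_pairs = fraction_convergent_pairs,
    mean_exons_per_gene = mean_exons_per_gene,
    sites_per_gene_probs = sites_per_gene_probs,
    region_mix = region_mix,
    microheterogeneity_sd = microheterogeneity_sd,
    internal_priming_rate = internal_priming_rate,
    a_tract_density = a_tract_density,
    tags_per_site = tags_per_site,
    unpaired_rate = unpaired_rate,
    utr3_rate = utr3_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# one gene structure in local coordinates (lengths only)
.random_gene_shape <- function(config) {
  n_ex <- 1L + rpois(1, max(0, config$mean_exons_per_gene - 1))
  list(
    utr5 = if (runif(1) < 0.7) sample(80:150, 1) else 0L,
    exons = sample(150:300, n_ex, replace = TRUE),
    introns = if (n_ex > 1) sample(120:250, n_ex - 1, replace = TRUE)
              else integer(0),
    utr3 = if (runif(1) < config$utr3_rate) sample(120:250, 1) else 0L
  )
}

# instantiate one gene at genomic position x; returns feature rows and a
# per-gene record with its segment tiling
.place_gene <- function(gene_id, chrom, strand, x, shape) {
  # blocks listed 5' -> 3' in transcript orientation
  labs <- c(if (shape$utr5 > 0) "5UTR",
            as.vector(rbind(rep("CDS", length(shape$exons)),
                            c(rep("intron", length(shape$introns)), NA)))[
                              seq_len(length(shape$exons) +
                                        length(shape$introns))],
            if (shape$utr3 > 0) "3UTR")
  lens <- c(if (shape$utr5 > 0) shape$utr5,
            as.vector(rbind(shape$exons, c(shape$introns, NA)))[
              seq_len(length(shape$exons) + length(shape$introns))],
            if (shape$utr3 > 0) shape$utr3)
  lens <- as.integer(lens)
  if (strand == "-") {
    labs <- rev(labs)
    lens <- rev(lens)
  }
  ends <- x - 1L + cumsum(lens)
  starts <- ends - lens + 1L
  seg <- tibble(gene_id = gene_id, chrom = chrom, strand = strand,
                start = starts, end = ends, label = labs)
  gene_start <- min(starts)
  gene_end <- max(ends)
  tx_id <- paste0(gene_id, ".t1")
  # exon features include flanking UTR bases
  cds <- seg[seg$label == "CDS", ]
  utr5 <- seg[seg$label == "5UTR", ]
  utr3 <- seg[seg$label == "3UTR", ]
  ex <- cds
  # stitch terminal UTRs onto the first/last coding exon
  for (u in list(utr5, utr3)) {
    if (nrow(u) == 1) {
      if ((u$end + 1L) %in% ex$start) {
        i <- which(ex$start == u$end + 1L)
        ex$start[i] <- u$start
      } else if ((u$start - 1L) %in% ex$end) {
        i <- which(ex$end == u$start - 1L)
        ex$end[i] <- u$end
      }
    }
  }
  feat <- bind_rows(
    tibble(chrom = chrom, start = gene_start, end = gene_end, strand = strand,
           type = "gene", id = gene_id, tx_id = NA_character_,
           gene_id = gene_id),
    tibble(chrom = chrom, start = gene_start, end = gene_end, strand = strand,
           type = "mRNA", id = tx_id, tx_id = tx_id, gene_id = gene_id),
    tibble(chrom = chrom, start = ex$start, end = ex$end, strand = strand,
           type = "exon", id = NA_character_, tx_id = tx_id, gene_id = gene_id),
    tibble(chrom = chrom, start = cds$start, end = cds$end, strand = strand,
           type = "CDS", id = NA_character_, tx_id = tx_id, gene_id = gene_id),
    if (nrow(utr5) > 0)
      tibble(chrom = chrom, start = utr5$start, end = utr5$end,
             strand = strand, type = "five_prime_UTR", id = NA_character_,
             tx_id = tx_id, gene_id = gene_id),
    if (nrow(utr3) > 0)
      tibble(chrom = chrom, start = utr3$start, end = utr3$end,
             strand = strand, type = "three_prime_UTR", id = NA_character_,
             tx_id = tx_id, gene_id = gene_id)
  )
  list(features = feat, segments = seg,
       gene = tibble(gene_id = gene_id, chrom = chrom, strand = strand,
                     start = gene_start, end = gene_end,
                     had_utr3 = nrow(utr3) > 0, length = gene_end - gene_start + 1L))
}

# replicate the antisense case definition on the generator's own records
.truth_antisense_case <- function(pos, strand, chrom, genes, segments,
                                  ext_with = 200L, ext_without = 400L,
                                  near = 500L) {
  cand <- genes[genes$chrom == chrom & genes$strand == strand, ]
  if (nrow(cand) == 0) return(4L)
  cover <- cand[cand$start <= pos & cand$end >= pos, ]
  if (nrow(cover) > 0) {
    seg <- segments[segments$gene_id == cover$gene_id[1] &
                      segments$start <= pos & segments$end >= pos, ]
    return(if (nrow(seg) > 0 && seg$label[1] == "3UTR") 1L else 2L)
  }
  for (i in seq_len(nrow(cand))) {
    L <- if (cand$had_utr3[i]) ext_with else ext_without
    same <- genes[genes$chrom == chrom & genes$strand == cand$strand[i] &
                    genes$gene_id != cand$gene_id[i], ]
    if (cand$strand[i] == "+") {
      hi <- cand$end[i] + L
      ds <- same$start[same$start > cand$end[i]]
      if (length(ds) > 0) hi <- min(hi, min(ds) - 1L)
      if (pos > cand$end[i] && pos <= hi) return(1L)
    } else {
      lo <- cand$start[i] - L
      ds <- same$end[same$end < cand$start[i]]
      if (length(ds) > 0) lo <- max(lo, max(ds) + 1L)
      if (pos < cand$start[i] && pos >= lo) return(1L)
    }
  }
  d <- if_else(cand$strand == "+", pos - cand$end, cand$start - pos)
  if (any(d > 0 & d <= near)) 3L else 4L
}

#' Simulate a genome, annotation and planted poly(A)-site ground truth
#'
#' Generates uniform-composition chromosome sequences, lays out genes (singly
#' or as convergent pairs), plants poly(A) sites per gene according to the
#' configured region mix, plants genomic A-tracts (the internal-priming
#' decoys), and scrubs any accidental A-run from the 10 nt downstream of each
#' genuine planted site so that the internal-priming filter has an exact
#' ground truth.
#'
#' Antisense ground-truth case labels (1-4) are computed from the generator's
#' own layout using the Medicago-like extension rules (200/400 nt) and a
#' 500 nt "nearby" distance.
#'
#' @param config A [sim_config()].
#' @return A `pa_sim` object: list with `genome` (a
#'   [Biostrings::DNAStringSet]), `features` (GFF3-shaped tibble), and
#'   `truth` (list with `sites`, `a_tracts`, `genes`, `segments`, `config`).
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  seqs <- lapply(chroms, function(ch) {
    sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE)
  })
  names(seqs) <- chroms
  empty_sites <- tibble(site_id = character(), chrom = character(),
                        strand = character(), pos = integer(),
                        gene_id = character(), region = character(),
                        antisense_case = integer())
  empty_tracts <- tibble(chrom = character(), start = integer(),
                         end = integer())
  genes_tbl <- tibble(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), had_utr3 = logical(),
                      length = integer())
  features <- tibble(chrom = character(), start = integer(), end = integer(),
                     strand = character(), type = character(),
                     id = character(), tx_id = character(),
                     gene_id = character())
  segments <- tibble(gene_id = character(), chrom = character(),
                     strand = character(), start = integer(), end = integer(),
                     label = character())

  if (config$n_genes > 0) {
    per_chrom <- table(factor(rep(chroms, length.out = config$n_genes),
                              levels = chroms))
    gid <- 0L
    placed <- list()
    for (ch in chroms) {
      x <- 2100L
      left <- as.integer(per_chrom[[ch]])
      while (left > 0) {
        pair <- left >= 2 && runif(1) < config$fraction_convergent_pairs
        if (pair) {
          sa <- .random_gene_shape(config)
          sb <- .random_gene_shape(config)
          la <- sum(sa$utr5, sa$exons, sa$introns, sa$utr3)
          gap <- sample(c(30L, 80L, 150L, 250L, 350L, 450L, 600L, 900L), 1)
          lb <- sum(sb$utr5, sb$exons, sb$introns, sb$utr3)
          if (x + la + gap + lb > config$chrom_length - 600L) break
          gid <- gid + 1L
          placed[[length(placed) + 1L]] <-
            .place_gene(sprintf("g%03d", gid), ch, "+", x, sa)
          gid <- gid + 1L
          placed[[length(placed) + 1L]] <-
            .place_gene(sprintf("g%03d", gid), ch, "-", x + la + gap, sb)
          x <- x + la + gap + lb + sample(1800:3500, 1)
          left <- left - 2L
        } else {
          s <- .random_gene_shape(config)
          l <- sum(s$utr5, s$exons, s$introns, s$utr3)
          if (x + l > config$chrom_length - 600L) break
          gid <- gid + 1L
          placed[[length(placed) + 1L]] <-
            .place_gene(sprintf("g%03d", gid), ch, sample(c("+", "-"), 1), x, s)
          x <- x + l + sample(1800:3500, 1)
          left <- left - 1L
        }
      }
      if (left > 0) {
        warning("chromosome ", ch, " too short for ", left,
                " remaining gene(s); they were dropped", call. = FALSE)
      }
    }
    if (length(placed) > 0) {
      features <- list_rbind(map(placed, "features"))
      segments <- list_rbind(map(placed, "segments"))
      genes_tbl <- list_rbind(map(placed, "gene"))
    }
  }

  # ---- plant poly(A) sites ----
  sites <- empty_sites
  if (nrow(genes_tbl) > 0) {
    occupied <- list() # per chrom+strand sorted positions, for min spacing
    key <- function(ch, s) paste0(ch, s)
    far_enough <- function(ch, s, p, min_d = 50L) {
      o <- occupied[[key(ch, s)]]
      is.null(o) || all(abs(o - p) >= min_d)
    }
    add_occ <- function(ch, s, p) {
      occupied[[key(ch, s)]] <<- c(occupied[[key(ch, s)]], p)
    }
    site_rows <- list()
    sid <- 0L
    n_site_choices <- as.integer(names(config$sites_per_gene_probs))
    for (i in seq_len(nrow(genes_tbl))) {
      gene <- genes_tbl[i, ]
      gseg <- segments[segments$gene_id == gene$gene_id, ]
      n_sites <- sample(n_site_choices, 1, prob = config$sites_per_gene_probs)
      for (k in seq_len(n_sites)) {
        region <- sample(names(config$region_mix), 1,
                         prob = config$region_mix)
        if (region == "intron" && !any(gseg$label == "intron")) region <- "3UTR"
        strand <- if (region == "antisense") {
          if (gene$strand == "+") "-" else "+"
        } else gene$strand
        pos <- NA_integer_
        for (try in 1:25) {
          p <- switch(
            region,
            `3UTR` = {
              u <- gseg[gseg$label == "3UTR", ]
              if (nrow(u) > 0) {
                sample(seq(u$start[1] + 5L, u$end[1] - 5L), 1)
              } else {
                # plant in the (truncated) downstream extension window
                same <- genes_tbl[genes_tbl$chrom == gene$chrom &
                                    genes_tbl$strand == gene$strand &
                                    genes_tbl$gene_id != gene$gene_id, ]
                if (gene$strand == "+") {
                  hi <- min(gene$end + 400L, config$chrom_length - 30L)
                  ds <- same$start[same$start > gene$end]
                  if (length(ds) > 0) hi <- min(hi, min(ds) - 1L)
                  if (hi - gene$end < 40L) NA_integer_
                  else sample(seq(gene$end + 20L, hi - 10L), 1)
                } else {
                  lo <- max(gene$start - 400L, 30L)
                  ds <- same$end[same$end < gene$start]
                  if (length(ds) > 0) lo <- max(lo, max(ds) + 1L)
                  if (gene$start - lo < 40L) NA_integer_
                  else sample(seq(lo + 10L, gene$start - 20L), 1)
                }
              }
            },
            intron = {
              it <- gseg[gseg$label == "intron", ]
              j <- sample(nrow(it), 1)
              sample(seq(it$start[j] + 15L, it$end[j] - 15L), 1)
            },
            CDS = {
              cd <- gseg[gseg$label == "CDS", ]
              j <- sample(nrow(cd), 1)
              sample(seq(cd$start[j] + 15L, cd$end[j] - 15L), 1)
            },
            antisense = sample(seq(gene$start + 15L, gene$end - 15L), 1)
          )
          if (!is.na(p) && far_enough(gene$chrom, strand, p)) {
            pos <- p
            break
          }
        }
        if (is.na(pos)) next
        add_occ(gene$chrom, strand, pos)
        sid <- sid + 1L
        site_rows[[sid]] <- tibble(
          site_id = sprintf("s%04d", sid), chrom = gene$chrom,
          strand = strand, pos = as.integer(pos), gene_id = gene$gene_id,
          region = region, antisense_case = NA_integer_
        )
      }
    }
    if (sid > 0) sites <- list_rbind(site_rows)
    if (nrow(sites) > 0) {
      as_i <- which(sites$region == "antisense")
      for (j in as_i) {
        sites$antisense_case[j] <- .truth_antisense_case(
          sites$pos[j], sites$strand[j], sites$chrom[j], genes_tbl, segments
        )
      }
    }
  }

  # ---- scrub accidental priming-like runs downstream of genuine sites ----
  if (nrow(sites) > 0) {
    for (j in seq_len(nrow(sites))) {
      ch <- sites$chrom[j]
      p <- sites$pos[j]
      if (sites$strand[j] == "+") {
        w <- seq(max(1L, p - 10L), min(config$chrom_length, p + 21L))
        bad <- "A"; sub <- "C"
      } else {
        w <- seq(max(1L, p - 21L), min(config$chrom_length, p + 10L))
        bad <- "T"; sub <- "G"
      }
      r <- rle(seqs[[ch]][w] == bad)
      if (any(r$values & r$lengths >= 6)) {
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (ri in which(r$values & r$lengths >= 6)) {
          mid <- w[starts[ri] + (r$lengths[ri] %/% 2L)]
          seqs[[ch]][mid] <- sub
        }
      }
    }
  }

  # ---- plant A-tracts (internal-priming decoys) ----
  a_tracts <- empty_tracts
  if (config$a_tract_density > 0) {
    rows <- list()
    for (ch in chroms) {
      n_tr <- round(config$a_tract_density * config$chrom_length / 1000)
      site_pos <- sites$pos[sites$chrom == ch]
      placed_tr <- integer(0)
      for (k in seq_len(n_tr)) {
        for (try in 1:50) {
          len <- sample(6:9, 1)
          t0 <- sample(seq(30L, config$chrom_length - 30L - len), 1)
          if (length(site_pos) > 0 &&
              min(abs(site_pos - t0), abs(site_pos - (t0 + len - 1L))) < 60L) {
            next
          }
          if (length(placed_tr) > 0 && min(abs(placed_tr - t0)) < 60L) next
          seqs[[ch]][t0:(t0 + len - 1L)] <- "A"
          placed_tr <- c(placed_tr, t0)
          rows[[length(rows) + 1L]] <- tibble(chrom = ch, start = t0,
                                              end = t0 + len - 1L)
          break
        }
      }
    }
    if (length(rows) > 0) a_tracts <- list_rbind(rows)
  }

  genome <- Biostrings::DNAStringSet(vapply(seqs, paste0, character(1),
                                            collapse = ""))
  names(genome) <- chroms
  structure(list(
    genome = genome,
    features = features,
    truth = list(sites = sites, a_tracts = a_tracts, genes = genes_tbl,
                 segments = segments, config = config)
  ), class = "pa_sim")
}

#' @export
print.pa_sim <- function(x, ...) {
  cat("<pa_sim> ", length(x$genome), " chromosome(s), ",
      nrow(x$truth$genes), " genes, ", nrow(x$truth$sites),
      " planted sites, ", nrow(x$truth$a_tracts), " A-tracts\n", sep = "")
  invisible(x)
}

# discrete truncated-normal jitter, truncated at +/- 11 nt
.jitter <- function(n, sd, trunc = 11L) {
  if (sd == 0 || n == 0) return(integer(n))
  out <- as.integer(round(rnorm(n, 0, sd)))
  bad <- abs(out) > trunc
  while (any(bad)) {
    out[bad] <- as.integer(round(rnorm(sum(bad), 0, sd)))
    bad <- abs(out) > trunc
  }
  out
}

#' Simulate mapped poly(A)-tag records from planted sites
#'
#' Every planted site emits a Poisson number of tags (minimum one) whose
#' cleavage coordinates are jittered by a discrete truncated normal
#' (truncation +/- 11 nt keeps all tags of one site pairwise closer than the
#' 24 nt clustering gap). Internal-priming artifact tags are placed
#' immediately upstream of planted A-tracts so that their downstream decamer
#' contains the A-run. Each tag carries a mate-status flag; the first tag of
#' every site is always mate-paired so that no planted site is lost to the
#' pairing filter.
#'
#' @param sim A `pa_sim` from [simulate_genome()].
#' @param config The simulation configuration (defaults to the one stored in
#'   `sim`). Tag generation draws its RNG stream from `seed + 1`.
#' @return A tibble of tag records: `tag_id`, `chrom`, `strand`, `pos`
#'   (cleavage coordinate = last transcribed nt, 1-based), `count`,
#'   `mate_status`, plus ground-truth columns `site_id` and `is_artifact`.
#' @export
simulate_tags <- function(sim, config = sim$truth$config) {
  stopifnot(inherits(sim, "pa_sim"))
  set.seed(config$seed + 1L)
  sites <- sim$truth$sites
  chrom_len <- .chrom_lengths(sim$genome)
  rows <- list()
  n_skipped <- 0L
  if (nrow(sites) > 0) {
    for (i in seq_len(nrow(sites))) {
      n <- max(1L, rpois(1, config$tags_per_site))
      pos <- sites$pos[i] + .jitter(n, config$microheterogeneity_sd)
      ok <- pos >= 1L & pos <= chrom_len[[sites$chrom[i]]]
      n_skipped <- n_skipped + sum(!ok)
      pos <- pos[ok]
      if (length(pos) == 0) next
      u <- config$unpaired_rate
      mate <- c("paired_unique",
                sample(c("paired_unique", "unpaired", "mate_multimapped"),
                       length(pos) - 1L, replace = TRUE,
                       prob = c(1 - u, 0.7 * u, 0.3 * u)))
      rows[[length(rows) + 1L]] <- tibble(
        chrom = sites$chrom[i], strand = sites$strand[i],
        pos = as.integer(pos), count = 1L, mate_status = mate,
        site_id = sites$site_id[i], is_artifact = FALSE
      )
    }
  }
  real <- if (length(rows) > 0) list_rbind(rows) else
    tibble(chrom = character(), strand = character(), pos = integer(),
           count = integer(), mate_status = character(),
           site_id = character(), is_artifact = logical())
  n_real <- nrow(real)
  art <- NULL
  tracts <- sim$truth$a_tracts
  if (config$internal_priming_rate > 0 && nrow(tracts) > 0 && n_real > 0) {
    rate <- config$internal_priming_rate
    n_art <- round(rate / (1 - rate) * n_real)
    if (n_art > 0) {
      pick <- sample(nrow(tracts), n_art, replace = TRUE)
      art <- tibble(
        chrom = tracts$chrom[pick], strand = "+",
        pos = tracts$start[pick] - 1L, count = 1L,
        mate_status = "paired_unique", site_id = NA_character_,
        is_artifact = TRUE
      ) |>
        filter(.data$pos >= 1L)
    }
  }
  tags <- bind_rows(real, art)
  if (n_skipped > 0) {
    warning(n_skipped, " tag(s) fell outside chromosome bounds and were ",
            "skipped", call. = FALSE)
  }
  tags |>
    mutate(tag_id = sprintf("t%06d", row_number())) |>
    select("tag_id", "chrom", "strand", "pos", "count", "mate_status",
           "site_id", "is_artifact")
}

#' Simulate EST-derived poly(A) sites near planted sense sites
#'
#' Draws a subset of planted sense sites and reports each once (EST
#' collections define a single site per cDNA) with a small positional offset,
#' emulating poly(A)-tailed EST-to-genome mappings.
#'
#' @param sim A `pa_sim`.
#' @param n Number of EST sites (capped at the number of sense sites).
#' @param max_offset Maximum absolute offset (nt) from the planted site.
#' @param seed Integer seed.
#' @return Tibble `est_id`, `chrom`, `strand`, `pos`, `site_id`.
#' @export
simulate_est_sites <- function(sim, n = 50, max_offset = 10L, seed = 1L) {
  set.seed(seed)
  sense <- sim$truth$sites |> filter(.data$region != "antisense")
  if (nrow(sense) == 0) {
    return(tibble(est_id = character(), chrom = character(),
                  strand = character(), pos = integer(), site_id = character()))
  }
  n <- min(n, nrow(sense))
  pick <- sample(nrow(sense), n)
  sense[pick, ] |>
    mutate(pos = .data$pos + sample(seq(-max_offset, max_offset), n,
                                    replace = TRUE),
           est_id = sprintf("est%04d", row_number())) |>
    select("est_id", "chrom", "strand", "pos", "site_id")
}

#' Simulate an ortholog pair table with planted feature conservation
#'
#' Each pair carries Boolean feature flags for species A (the pool species)
#' and species B with the requested marginal rates and joint rate. Setting
#' `joint_rate = rate_a * rate_b` plants independence (the conservation test
#' should then be non-significant); a larger joint rate plants conservation
#' enrichment.
#'
#' @param n_pairs Number of ortholog pairs (one-to-one).
#' @param rate_a,rate_b Marginal feature rates in species A and B.
#' @param joint_rate P(both orthologs carry the feature); must satisfy
#'   `max(0, rate_a + rate_b - 1) <= joint_rate <= min(rate_a, rate_b)`.
#' @param seed Integer seed.
#' @return Tibble `gene_a`, `gene_b`, `feature_a`, `feature_b`.
#' @export
simulate_orthologs <- function(n_pairs, rate_a, rate_b,
                               joint_rate = rate_a * rate_b, seed = 1L) {
  if (rate_a < 0 || rate_a > 1 || rate_b < 0 || rate_b > 1) {
    stop("marginal rates must lie in [0, 1]", call. = FALSE)
  }
  lo <- max(0, rate_a + rate_b - 1)
  hi <- min(rate_a, rate_b)
  if (joint_rate < lo - 1e-9 || joint_rate > hi + 1e-9) {
    stop("joint_rate ", joint_rate, " incompatible with marginals [",
         signif(lo, 4), ", ", signif(hi, 4), "]", call. = FALSE)
  }
  set.seed(seed)
  if (n_pairs == 0) {
    return(tibble(gene_a = character(), gene_b = character(),
                  feature_a = logical(), feature_b = logical()))
  }
  p <- c(joint_rate, rate_a - joint_rate, rate_b - joint_rate,
         1 - rate_a - rate_b + joint_rate)
  p <- pmax(p, 0)
  cat4 <- sample.int(4, n_pairs, replace = TRUE, prob = p)
  tibble(
    gene_a = sprintf("athG%05d", seq_len(n_pairs)),
    gene_b = sprintf("mtrG%05d", seq_len(n_pairs)),
    feature_a = cat4 %in% c(1L, 2L),
    feature_b = cat4 %in% c(1L, 3L)
  )
}

#' Simulate per-gene 3'-UTR lengths for ortholog pairs with planted
#' correlation
#'
#' Lengths are bivariate normal (rounded, floored at 1 nt) so that the
#' planted Pearson correlation `r` is recovered by [compare_utr_lengths()].
#' Defaults reflect the reported median 3'-UTR lengths (about 180 nt in the
#' query species, 169 nt in the reference species).
#'
#' @param n_pairs Number of ortholog pairs.
#' @param r Planted Pearson correlation between paired lengths.
#' @param mean_a,sd_a,mean_b,sd_b Length distribution parameters (nt).
#' @param seed Integer seed.
#' @return Tibble `gene_a`, `gene_b`, `len_a`, `len_b`.
#' @export
simulate_utr_lengths <- function(n_pairs, r = 0.3, mean_a = 169, sd_a = 50,
                                 mean_b = 180, sd_b = 60, seed = 1L) {
  stopifnot(abs(r) <= 1)
  set.seed(seed)
  z1 <- rnorm(n_pairs)
  z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n_pairs)
  tibble(
    gene_a = sprintf("athG%05d", seq_len(n_pairs)),
    gene_b = sprintf("mtrG%05d", seq_len(n_pairs)),
    len_a = pmax(1, round(mean_a + sd_a * z1)),
    len_b = pmax(1, round(mean_b + sd_b * z2))
  )
}
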