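#' Analysis parameters
#'
#' Bundles every numeric constant used by the pipeline: the PAC clustering
#' gap, the internal-priming filter geometry, the species-specific 3'-UTR
#' extension lengths, the promoter extent, the EST validation window, the
#' number of randomization trials for the conservation tests, the nucleotide
#' profile window and the "nearby convergent gene" distance used for
#' antisense case 3.
#'
#' Two species profiles are provided. `"mtr"` (Medicago-like annotations,
#' where most gene models lack an annotated 3'-UTR) extends annotated 3'-UTRs
#' by 200 nt and UTR-less genes by 400 nt; `"ath"` (Arabidopsis-like) uses
#' 120 and 338 nt. All other defaults are shared: tags separated by fewer
#' than 24 nt chain into one PAC, a tag is an internal-priming artifact when
#' the 10 genomic nt downstream of its cleavage site contain a run of 6 or
#' more A, the promoter is the 2000 nt upstream of the 5'-most transcribed
#' coordinate, an EST-derived site validates a PAC within 50 nt, and
#' randomization tests run 1000 trials.
#'
#' @param species `"mtr"`, `"ath"`, or `"custom"`. `"custom"` requires
#'   `ext_with_utr` and `ext_without_utr` to be supplied.
#' @param cluster_gap Tags on the same strand whose adjacent cleavage
#'   positions differ by less than this many nt are chained into one PAC.
#' @param internal_priming_a_run Minimum length of the downstream genomic
#'   A-run that marks a tag as an internal-priming artifact.
#' @param internal_priming_window Number of genomic nt immediately downstream
#'   of the cleavage position scanned for the A-run.
#' @param ext_with_utr 3' extension (nt) for genes with an annotated 3'-UTR.
#' @param ext_without_utr 3' extension (nt) for genes without one.
#' @param promoter_extent Promoter window length (nt) upstream of the 5'-most
#'   transcribed coordinate.
#' @param est_match_window Maximum distance (nt, inclusive) between an
#'   EST-derived poly(A) site and a PAC summit for validation.
#' @param n_random_trials Number of random draws in the conservation tests.
#' @param profile_window Integer vector `c(upstream, downstream)` for
#'   nucleotide composition profiles around the cleavage site.
#' @param nearby_antisense_distance Maximum distance (nt) from a convergent
#'   gene's annotated 3' end for an uncovered antisense PAC to be attributed
#'   to read-through (case 3).
#' @param min_t_run Minimum leading-T run length for a raw read to be called
#'   a poly(T) tag.
#'
#' @return A list of class `pa_params`.
#' @examples
#' pa_params("mtr")$ext_without_utr # 400
#' pa_params("ath")$ext_with_utr    # 120
#' @export
pa_params <- function(species = c("mtr", "ath", "custom"),
                      cluster_gap = 24L,
                      internal_priming_a_run = 6L,
                      internal_priming_window = 10L,
                      ext_with_utr = NULL,
                      ext_without_utr = NULL,
                      promoter_extent = 2000L,
                      est_match_window = 50L,
                      n_random_trials = 1000L,
                      profile_window = c(300L, 100L),
                      nearby_antisense_distance = 500L,
                      min_t_run = 8L) {
  species <- match.arg(species)
  if (species == "mtr") {
    ext_with_utr <- ext_with_utr %||% 200L
    ext_without_utr <- ext_without_utr %||% 400L
  } else if (species == "ath") {
    ext_with_utr <- ext_with_utr %||% 120L
    ext_without_utr <- ext_without_utr %||% 338L
  } else if (is.null(ext_with_utr) || is.null(ext_without_utr)) {
    stop("species = 'custom' requires ext_with_utr and ext_without_utr",
         call. = FALSE)
  }
  p <- list(
    species = species,
    cluster_gap = as.integer(cluster_gap),
    internal_priming_a_run = as.integer(internal_priming_a_run),
    internal_priming_window = as.integer(internal_priming_window),
    ext_with_utr = as.integer(ext_with_utr),
    ext_without_utr = as.integer(ext_without_utr),
    promoter_extent = as.integer(promoter_extent),
    est_match_window = as.integer(est_match_window),
    n_random_trials = as.integer(n_random_trials),
    profile_window = as.integer(profile_window),
    nearby_antisense_distance = as.integer(nearby_antisense_distance),
    min_t_run = as.integer(min_t_run)
  )
  scalar <- setdiff(names(p), c("species", "profile_window"))
  bad <- scalar[!vapply(p[scalar], function(x) length(x) == 1 && !is.na(x) && x > 0,
                        logical(1))]
  if (length(bad) > 0) {
    stop("parameters must be positive integers: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(p$profile_window) != 2 || any(p$profile_window <= 0)) {
    stop("profile_window must be two positive integers (upstream, downstream)",
         call. = FALSE)
  }
  structure(p, class = "pa_params")
}

#' @export
print.pa_params <- function(x, ...) {
  cat("<pa_params> species profile:", x$species, "\n")
  cat("  cluster gap < ", x$cluster_gap, " nt; internal priming: >=",
      x$internal_priming_a_run, " A within ", x$internal_priming_window,
      " nt downstream\n", sep = "")
  cat("  3' extension: ", x$ext_with_utr, " nt (annotated 3'UTR) / ",
      x$ext_without_utr, " nt (none); promoter ", x$promoter_extent, " nt\n",
      sep = "")
  cat("  EST window ", x$est_match_window, " nt; ", x$n_random_trials,
      " randomization trials; profile -", x$profile_window[1], "/+",
      x$profile_window[2], " nt; antisense 'nearby' <= ",
      x$nearby_antisense_distance, " nt\n", sep = "")
  invisible(x)
}
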