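#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_step
#'   facet_grid facet_wrap labs theme_bw scale_x_continuous geom_vline vars
#' @export
ggplot2::autoplot

#' Plot nucleotide composition profiles
#'
#' One trace per base (A, C, G, U) of the fractional content at each
#' position relative to the cleavage site (position 0); faceted by stratum
#' (and support class when present).
#'
#' @param object A `pa_profile` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pa_profile <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$position, y = .data$frac,
                          colour = .data$base)) +
    geom_line() +
    geom_vline(xintercept = 0, linetype = "dotted") +
    labs(x = "position relative to cleavage site (nt)",
         y = "fraction of sites", colour = "base") +
    theme_bw()
  if ("support" %in% names(object) && "stratum" %in% names(object)) {
    p + facet_grid(rows = vars(.data$support), cols = vars(.data$stratum))
  } else if ("stratum" %in% names(object)) {
    p + facet_wrap(vars(.data$stratum))
  } else {
    p
  }
}

#' Plot the cumulative distance curve of intergenic PACs
#'
#' @param object A `pa_intergenic` object from [intergenic_distances()].
#' @param ... Unused.
#' @return A ggplot object (cumulative fraction of intergenic PACs vs
#'   distance from the nearest extended gene, log-scaled x).
#' @export
autoplot.pa_intergenic <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$distance, y = .data$cum_frac)) +
    geom_step() +
    scale_x_continuous(trans = "log10") +
    labs(x = "distance from nearest extended gene (nt)",
         y = "cumulative fraction of intergenic PACs") +
    theme_bw()
}

#' Plot ortholog 3'-UTR length pairs
#'
#' @param object A `pa_utr_comparison` object.
#' @param ... Unused.
#' @return A ggplot scatter of paired lengths with the Pearson r in the
#'   subtitle.
#' @export
autoplot.pa_utr_comparison <- function(object, ...) {
  r <- object$correlation$r[object$correlation$set == "ortholog"]
  ggplot(object$pairs, aes(x = .data$len_a, y = .data$len_b)) +
    geom_point(alpha = 0.3, size = 0.8) +
    labs(x = "3'-UTR length, species A (nt)",
         y = "3'-UTR length, species B (nt)",
         subtitle = sprintf("Pearson r = %.2f over %d ortholog pairs",
                            r, nrow(object$pairs))) +
    theme_bw()
}
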