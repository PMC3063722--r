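#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_point
#'   geom_abline scale_fill_viridis_c labs theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a binned 2-D response function
#'
#' Spike probability over the reduced input plane; unsampled cells (never
#' visited inputs) are blank, distinct from sampled cells with probability 0.
#'
#' @param object an `mne_brf` from [bin_response_2d()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot mne_brf
#' @export
autoplot.mne_brf <- function(object, ...) {
  ggplot(dplyr::filter(object, !is.na(.data$probability)),
         aes(.data$s1_mid, .data$s2_mid, fill = .data$probability)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(x = "s1", y = "s2", fill = "P(spike)",
         title = "Binned response function") +
    theme_minimal()
}

#' Plot an order scan
#'
#' Percentage of the empirical mutual information captured at each
#' interaction order.
#'
#' @param object an `mne_scan` from [scan_orders()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot mne_scan
#' @export
autoplot.mne_scan <- function(object, ...) {
  ggplot(object, aes(.data$order, .data$percent)) +
    geom_line() +
    geom_point(size = 2) +
    labs(x = "interaction order", y = "% information captured") +
    theme_minimal()
}

#' Scatter of predicted versus observed unconstrained moments
#'
#' Diagnostic for moment prediction beyond the constraint set: points on the
#' identity line mean the model also captures moments it was not fitted to.
#'
#' @param comparison a tibble from [predict_unconstrained_moments()], or a
#'   row-bound combination of several (add a grouping column and facet
#'   yourself for model comparisons).
#' @return a ggplot.
#' @export
plot_moment_comparison <- function(comparison) {
  ggplot(dplyr::filter(comparison, !.data$constrained),
         aes(.data$observed, .data$predicted)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    geom_point() +
    labs(x = "observed moment", y = "model-predicted moment") +
    theme_minimal()
}
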