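#' Plot methods for result objects
#'
#' Each benchmark result type has an `autoplot()` method returning a ggplot.
#'
#' @name plots
NULL

#' Plot a precision/recall-versus-cutoff curve
#'
#' Precision and recall (macro-averaged per drug over drugs with at least
#' one prediction) against the score cutoff.
#'
#' @param object An `eval_curve` from [cutoff_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eval_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("cutoff", "precision", "recall")],
    c("precision", "recall"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$cutoff, y = .data$value,
                               colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "mTC cutoff", y = "mean per-drug value",
                  colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot the flagged-drug fraction versus killing-index threshold
#'
#' @param object A `kappa_curve` from [kappa_fraction_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kappa_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$threshold,
                               y = .data$fraction_flagged)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_drugs), alpha = 0.7) +
    ggplot2::labs(x = expression("killing index threshold" ~ (kappa >= t)),
                  y = "fraction withdrawn / illicit / investigational",
                  size = "drugs") +
    ggplot2::theme_minimal()
}

#' Plot a ranked screen
#'
#' Score against rank, with predicted interactions highlighted when a cutoff
#' was applied.
#'
#' @param object A `drugcast_screen` from [screen_proteome()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.drugcast_screen <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$mtc))
  if ("predicted" %in% names(d)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$predicted))
  } else {
    p <- p + ggplot2::geom_point()
  }
  cutoff <- attr(object, "mtc_cutoff")
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = 2)
  }
  p + ggplot2::labs(x = "rank", y = "mTC") + ggplot2::theme_minimal()
}
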