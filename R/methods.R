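#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang %||% .data
NULL

#' Tidiers for screening results
#'
#' `tidy()` returns the ranked hits as a plain tibble; `glance()` returns a
#' one-row summary (library size, best score, predicted-interaction count).
#'
#' @param x A `drugcast_screen` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.drugcast_screen <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "drugcast_screen")
  tibble::as_tibble(out)
}

#' @rdname tidy.drugcast_screen
#' @export
glance.drugcast_screen <- function(x, ...) {
  tibble::tibble(
    query_id = attr(x, "query_id") %||% NA_character_,
    n_targets = nrow(x),
    top_mtc = max(x$mtc),
    w = attr(x, "w"),
    mtc_cutoff = attr(x, "mtc_cutoff") %||% NA_real_,
    n_predicted = if ("predicted" %in% names(x)) sum(x$predicted)
                  else NA_integer_
  )
}

#' Tidiers for side-effect benchmark results
#'
#' `tidy()` returns the per-drug precision/recall table; `glance()` the
#' macro-averaged summary row (averages over drugs with at least one
#' prediction, with the zero-included averages alongside).
#'
#' @param x A `sidefx_eval` object from [consistency_test()] or
#'   [jackknife_test()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sidefx_eval <- function(x, ...) x$per_drug

#' @rdname tidy.sidefx_eval
#' @export
glance.sidefx_eval <- function(x, ...) x$macro

#' Tidiers for pocket alignments
#'
#' `tidy()` returns the residue correspondence table; `glance()` a one-row
#' summary with the aligned-residue count, RMSD and score.
#'
#' @param x A `pocket_alignment` object from [align_pocket()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pocket_alignment <- function(x, ...) x$correspondence

#' @rdname tidy.pocket_alignment
#' @export
glance.pocket_alignment <- function(x, ...) {
  tibble::tibble(n_aligned = x$n_aligned, rmsd = x$rmsd, score = x$score,
                 converged = x$converged)
}
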