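#' Benchmark metrics for ranked screens and set-valued predictions
#'
#' Per-drug ROC AUC (rank-based), enrichment factors within a top fraction
#' of a ranked library, set precision/recall, precision/recall-versus-cutoff
#' curves, and the observed-precision-by-known-target-count analysis.
#'
#' @name evalx
NULL

#' Precision and recall of a predicted set against a truth set
#'
#' TP is the size of the intersection; precision = TP / |predicted|,
#' recall = TP / |truth|. Quantities that are undefined (no predictions, or
#' empty truth) come back as `NA`, never as 0, so averages can exclude them
#' explicitly.
#'
#' @param predicted,truth Vectors treated as sets (duplicates dropped).
#' @return One-row tibble: `tp`, `n_predicted`, `n_truth`, `precision`,
#'   `recall`.
#' @export
precision_recall <- function(predicted, truth) {
  predicted <- unique(predicted); truth <- unique(truth)
  tp <- length(intersect(predicted, truth))
  tibble::tibble(
    tp = tp,
    n_predicted = length(predicted),
    n_truth = length(truth),
    precision = if (length(predicted)) tp / length(predicted) else NA_real_,
    recall = if (length(truth)) tp / length(truth) else NA_real_
  )
}

#' Number of entries in the top x fraction of a library of size n
#'
#' Ceiling rounding: the top 1% of 3,576 targets is 36 entries.
#'
#' @param x Fraction in (0, 1\].
#' @param n Library size.
#' @return Integer count.
#' @export
top_fraction_size <- function(x, n) {
  stopifnot(x > 0, x <= 1, n >= 1)
  as.integer(ceiling(x * n))
}

#' Enrichment factor within the top x fraction of a ranking
#'
#' \deqn{EF_x = \frac{\#\{\text{true targets in the top } \lceil xN \rceil\} /
#'   |\text{truth}|}{x}.}
#' EF of 1 means random, 1/x means every true target is inside the top
#' fraction (EF of 100 at x = 0.01).
#'
#' @param ranked Tibble with `target_id` ordered best-first (e.g. a
#'   [screen_proteome()] result), or a character vector of target ids in rank
#'   order.
#' @param truth Character vector of true target ids (non-empty).
#' @param x Top fraction in (0, 1\].
#' @return EF value in \[0, 1/x\].
#' @export
enrichment_factor <- function(ranked, truth, x = 0.01) {
  ids <- if (is.data.frame(ranked)) {
    if ("rank" %in% names(ranked)) ranked$target_id[order(ranked$rank)]
    else ranked$target_id
  } else as.character(ranked)
  truth <- unique(truth)
  if (length(truth) == 0L) stop("empty truth set", call. = FALSE)
  n_top <- top_fraction_size(x, length(ids))
  found <- sum(utils::head(ids, n_top) %in% truth)
  (found / length(truth)) / x
}

#' Per-drug ROC AUC of a ranked screen
#'
#' Rank-based (Mann-Whitney) AUC: the fraction of (positive, negative) target
#' pairs in which the positive target scores higher, ties counted one half.
#' Degenerate truth (no positives, or all targets positive) gives `NA`.
#'
#' @param ranked Tibble with `target_id` and `mtc` score columns covering the
#'   whole library.
#' @param truth Character vector of true target ids.
#' @return AUC in \[0, 1\], or `NA` for degenerate truth.
#' @export
auc_per_drug <- function(ranked, truth) {
  scores <- ranked$mtc
  pos <- ranked$target_id %in% truth
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Precision/recall versus score cutoff, averaged per drug
#'
#' At each cutoff, a drug's predictions are its hits with score at or above
#' the cutoff; per-drug precision and recall are macro-averaged over the
#' drugs that still have at least one prediction, and that count is reported.
#' As the cutoff rises past a drug's best score the drug drops out of the
#' average, which is what produces the characteristic high-cutoff drop of the
#' averaged precision.
#'
#' @param hits Tibble with `drug_id`, `target_id`, `mtc` (all drugs' screens
#'   stacked).
#' @param truth Tibble with `drug_id`, `target_id` known interactions.
#' @param cutoffs Ascending numeric vector of score cutoffs in \[0, 1\].
#' @return Tibble of class `eval_curve`: `cutoff`, `precision`, `recall`,
#'   `n_drugs_with_predictions` (`NA` averages when no drug predicts).
#' @export
cutoff_curve <- function(hits, truth, cutoffs = seq(0, 1, by = 0.05)) {
  stopifnot(!is.unsorted(cutoffs))
  truth_sets <- split(truth$target_id, truth$drug_id)
  hit_split <- split(hits[, c("target_id", "mtc")], hits$drug_id)
  drug_ids <- intersect(names(hit_split), names(truth_sets))
  rows <- purrr::map(cutoffs, function(co) {
    pr <- purrr::map(drug_ids, function(d) {
      h <- hit_split[[d]]
      predicted <- h$target_id[h$mtc >= co]
      if (length(predicted) == 0L) return(NULL)
      precision_recall(predicted, truth_sets[[d]])
    })
    pr <- dplyr::bind_rows(pr)
    tibble::tibble(
      cutoff = co,
      precision = if (nrow(pr)) mean(pr$precision) else NA_real_,
      recall = if (nrow(pr)) mean(pr$recall) else NA_real_,
      n_drugs_with_predictions = nrow(pr)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("eval_curve", class(out))
  out
}

#' Observed precision binned by the number of known targets
#'
#' Precision measured against an incomplete truth list ("observed precision")
#' under-estimates true precision; drugs with many known targets suffer less
#' from missing labels. Binning per-drug observed precision by the known
#' target count makes that dependence visible.
#'
#' @param per_drug Tibble with `drug_id` and `precision` (observed, e.g. at a
#'   fixed score cutoff).
#' @param truth Tibble with `drug_id`, `target_id`.
#' @param breaks Bin edges for the known-target count (right-closed), as in
#'   [cut()].
#' @return Tibble: `bin`, `n_drugs`, `mean_precision`; empty bins omitted.
#' @export
observed_precision_by_truth_count <- function(per_drug, truth,
                                              breaks = c(0, 1, 2, 4, 9, Inf)) {
  counts <- truth |>
    dplyr::distinct(.data$drug_id, .data$target_id) |>
    dplyr::count(.data$drug_id, name = "n_known")
  d <- dplyr::inner_join(tibble::as_tibble(per_drug), counts, by = "drug_id")
  d <- d[!is.na(d$precision), , drop = FALSE]
  d$bin <- cut(d$n_known, breaks = breaks)
  d |>
    dplyr::filter(!is.na(.data$bin)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n_drugs = dplyr::n(),
                     mean_precision = mean(.data$precision)) |>
    dplyr::ungroup()
}

#' Average rank of true targets in a set of ranked screens
#'
#' Emitted both ways the averaging can be read: per drug then averaged over
#' drugs, and pooled over all true (drug, target) pairs.
#'
#' @param hits Tibble with `drug_id`, `target_id`, `rank`.
#' @param truth Tibble with `drug_id`, `target_id`.
#' @return One-row tibble: `mean_rank_per_drug`, `mean_rank_pooled`.
#' @export
average_true_rank <- function(hits, truth) {
  joined <- dplyr::inner_join(
    tibble::as_tibble(truth[, c("drug_id", "target_id")]),
    hits[, c("drug_id", "target_id", "rank")],
    by = c("drug_id", "target_id")
  )
  per_drug <- joined |>
    dplyr::group_by(.data$drug_id) |>
    dplyr::summarise(m = mean(.data$rank))
  tibble::tibble(mean_rank_per_drug = mean(per_drug$m),
                 mean_rank_pooled = mean(joined$rank))
}
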