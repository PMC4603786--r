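#' Side-effect inference, prediction and the killing index
#'
#' Protein-target side effects are inferred deterministically from a
#' drug-to-side-effect table: when a target binds k > 1 drugs with
#' side-effect records, the side effects shared by all of them (the
#' intersection) are attributed to the target. A drug's predicted side
#' effects are then the union over its targets' inferred sets. Because every
#' attributed term is carried by every supporting drug, re-predicting a drug
#' from the full table can never produce a false positive.
#'
#' @name sidefx
NULL

#' Normalize side-effect terms
#'
#' Terms are free strings compared case-insensitively after trimming and
#' collapsing internal whitespace; no ontology mapping is attempted.
#'
#' @param x Character vector of terms.
#' @return Normalized character vector.
#' @export
normalize_terms <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

#' The default list of serious side effects
#'
#' Eight terms whose presence in a target's inferred side-effect set makes
#' the target count toward a drug's killing index: death, sudden death,
#' sudden cardiac death, cardiac death, cancer, hemorrhagic strokes, heart
#' failure, congestive heart failure. Extendable by the user.
#'
#' @param extra Additional terms to append.
#' @return Character vector of normalized terms.
#' @export
serious_side_effects <- function(extra = character()) {
  base <- c("death", "sudden death", "sudden cardiac death", "cardiac death",
            "cancer", "hemorrhagic strokes", "heart failure",
            "congestive heart failure")
  unique(normalize_terms(c(base, extra)))
}

check_se_table <- function(drug_se) {
  stopifnot(all(c("drug_id", "term") %in% names(drug_se)))
  drug_se <- tibble::as_tibble(drug_se)
  drug_se$term <- normalize_terms(drug_se$term)
  if (any(!nzchar(drug_se$term))) stop("empty side-effect term", call. = FALSE)
  dplyr::distinct(drug_se)
}

#' Infer protein-target side effects from drug side effects
#'
#' For each target bound by at least two drugs that have side-effect records,
#' the target's side effects are the intersection of those drugs' sets.
#' Targets with fewer than two annotated binders, or whose binders share no
#' term, are omitted. Drugs present in the interaction table but absent from
#' the side-effect table are ignored (they neither support nor veto terms);
#' treating them as empty sets would erase every target they touch.
#'
#' @param interactions Tibble of (drug_id, target_id) interaction pairs.
#' @param drug_se Tibble of (drug_id, term) drug side-effect pairs.
#' @return Tibble of class `drugcast_target_se`: `target_id`, `term`,
#'   `supporting_drug_count` (>= 2, constant within a target).
#' @export
infer_target_side_effects <- function(interactions, drug_se) {
  stopifnot(all(c("drug_id", "target_id") %in% names(interactions)),
            nrow(interactions) > 0)
  drug_se <- check_se_table(drug_se)
  inter <- dplyr::distinct(tibble::as_tibble(
    interactions[, c("drug_id", "target_id")]))
  annotated <- unique(drug_se$drug_id)
  inter <- inter[inter$drug_id %in% annotated, , drop = FALSE]
  se_sets <- split(drug_se$term, drug_se$drug_id)
  per_target <- split(inter$drug_id, inter$target_id)
  rows <- purrr::imap(per_target, function(drugs, t_id) {
    if (length(drugs) < 2L) return(NULL)
    shared <- Reduce(intersect, se_sets[drugs])
    if (length(shared) == 0L) return(NULL)
    tibble::tibble(target_id = t_id, term = sort(shared),
                   supporting_drug_count = length(drugs))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(target_id = character(), term = character(),
                          supporting_drug_count = integer())
  }
  out <- out[order(out$target_id, out$term), ]
  class(out) <- c("drugcast_target_se", class(out))
  out
}

#' Predict drug side effects from inferred target side effects
#'
#' A drug's predicted side effects are the union of the inferred side-effect
#' sets of all its targets. Drugs whose targets carry no inferred terms get
#' an empty prediction (no rows).
#'
#' @param interactions Tibble of (drug_id, target_id) pairs.
#' @param target_se Inferred target side effects from
#'   [infer_target_side_effects()].
#' @param drug_ids Drugs to predict; defaults to every drug in `interactions`.
#' @return Tibble (`drug_id`, `term`), one row per predicted term.
#' @export
predict_drug_side_effects <- function(interactions, target_se,
                                      drug_ids = NULL) {
  inter <- dplyr::distinct(tibble::as_tibble(
    interactions[, c("drug_id", "target_id")]))
  if (is.null(drug_ids)) drug_ids <- sort(unique(inter$drug_id))
  joined <- dplyr::inner_join(
    inter[inter$drug_id %in% drug_ids, , drop = FALSE],
    target_se[, c("target_id", "term")],
    by = "target_id", relationship = "many-to-many"
  )
  out <- dplyr::distinct(joined[, c("drug_id", "term")])
  out[order(out$drug_id, out$term), ]
}

score_predictions <- function(drug_ids, predicted_sets, known_sets) {
  per_drug <- purrr::map(drug_ids, function(d) {
    pred <- predicted_sets[[d]] %||% character()
    known <- known_sets[[d]] %||% character()
    pr <- precision_recall(pred, known)
    tibble::tibble(drug_id = d, n_known = length(known),
                   n_predicted = length(pred), tp = pr$tp,
                   precision = pr$precision, recall = pr$recall)
  })
  dplyr::bind_rows(per_drug)
}

new_sidefx_eval <- function(per_drug, mode) {
  with_pred <- per_drug[per_drug$n_predicted > 0, , drop = FALSE]
  macro <- tibble::tibble(
    mode = mode,
    precision = mean(with_pred$precision),
    recall = mean(with_pred$recall),
    n_drugs_with_predictions = nrow(with_pred),
    n_drugs = nrow(per_drug),
    precision_incl_zero = mean(dplyr::coalesce(per_drug$precision, 0)),
    recall_incl_zero = mean(dplyr::coalesce(per_drug$recall, 0))
  )
  structure(list(per_drug = per_drug, macro = macro, mode = mode),
            class = "sidefx_eval")
}

#' Consistency test of the side-effect inference rule
#'
#' All drug side-effect records build the target side-effect map; each drug
#' is then re-predicted from it and scored against its own known set. The
#' intersection/union construction makes false positives impossible here:
#' every term attributed to a target is carried by all of its supporting
#' drugs, so every predicted term for a drug is one of its known terms. The
#' test therefore measures how much of the known data the inferred map can
#' reproduce (recall), at precision 1 wherever a prediction exists.
#'
#' @inheritParams infer_target_side_effects
#' @return An object of class `sidefx_eval` with `per_drug` and macro-average
#'   components; see [tidy.sidefx_eval()] and [glance.sidefx_eval()].
#'   Macro averages are over drugs with at least one predicted term; the
#'   all-drug averages (zeros included) are reported alongside.
#' @export
consistency_test <- function(interactions, drug_se) {
  drug_se <- check_se_table(drug_se)
  target_se <- infer_target_side_effects(interactions, drug_se)
  drug_ids <- sort(unique(drug_se$drug_id[
    drug_se$drug_id %in% interactions$drug_id]))
  pred <- predict_drug_side_effects(interactions, target_se,
                                    drug_ids = drug_ids)
  new_sidefx_eval(
    score_predictions(drug_ids,
                      split(pred$term, pred$drug_id),
                      split(drug_se$term, drug_se$drug_id)),
    mode = "consistency"
  )
}

#' Jackknife (leave-one-drug-out) test of side-effect prediction
#'
#' For each drug, the target side-effect map is rebuilt with that drug's
#' side-effect record removed, and the left-out drug is predicted from the
#' rebuilt map. Only the targets the drug binds can change, so the rebuild
#' is done locally per drug. This measures genuine predictive power: terms
#' must be recoverable from co-binders alone.
#'
#' @inheritParams infer_target_side_effects
#' @return A `sidefx_eval` object, as for [consistency_test()].
#' @export
jackknife_test <- function(interactions, drug_se) {
  drug_se <- check_se_table(drug_se)
  inter <- dplyr::distinct(tibble::as_tibble(
    interactions[, c("drug_id", "target_id")]))
  se_sets <- split(drug_se$term, drug_se$drug_id)
  annotated <- names(se_sets)
  inter <- inter[inter$drug_id %in% annotated, , drop = FALSE]
  per_target <- split(inter$drug_id, inter$target_id)
  drug_ids <- sort(intersect(annotated, inter$drug_id))
  if (length(drug_ids) < 2L) stop("jackknife needs >= 2 annotated drugs",
                                  call. = FALSE)
  predicted <- purrr::map(drug_ids, function(d) {
    targets_of_d <- inter$target_id[inter$drug_id == d]
    terms <- purrr::map(targets_of_d, function(t_id) {
      others <- setdiff(per_target[[t_id]], d)
      if (length(others) < 2L) return(character())
      Reduce(intersect, se_sets[others])
    })
    sort(unique(unlist(terms)))
  })
  names(predicted) <- drug_ids
  new_sidefx_eval(score_predictions(drug_ids, predicted, se_sets),
                  mode = "jackknife")
}

#' Killing index of drugs
#'
#' The killing index kappa of a drug is the number of its targets whose
#' inferred side-effect set contains at least one serious term. A target
#' carrying several serious terms still contributes 1: kappa counts targets,
#' not terms, so kappa is bounded by the drug's target count.
#'
#' @inheritParams predict_drug_side_effects
#' @param serious Character vector of serious terms
#'   (default [serious_side_effects()]).
#' @return Tibble (`drug_id`, `kappa`, `n_targets`), one row per drug.
#' @export
killing_index <- function(interactions, target_se, drug_ids = NULL,
                          serious = serious_side_effects()) {
  serious <- normalize_terms(serious)
  inter <- dplyr::distinct(tibble::as_tibble(
    interactions[, c("drug_id", "target_id")]))
  if (is.null(drug_ids)) drug_ids <- sort(unique(inter$drug_id))
  serious_targets <- unique(
    target_se$target_id[target_se$term %in% serious])
  inter <- inter[inter$drug_id %in% drug_ids, , drop = FALSE]
  counts <- inter |>
    dplyr::group_by(.data$drug_id) |>
    dplyr::summarise(
      kappa = sum(.data$target_id %in% serious_targets),
      n_targets = dplyr::n()
    )
  out <- dplyr::left_join(tibble::tibble(drug_id = drug_ids), counts,
                          by = "drug_id")
  out$kappa <- dplyr::coalesce(out$kappa, 0L)
  out$n_targets <- dplyr::coalesce(out$n_targets, 0L)
  out
}

#' Cumulative fraction of flagged drugs versus killing-index threshold
#'
#' For each threshold t from 0 to the maximum kappa, the fraction of flagged
#' drugs (withdrawn, illicit or investigational) among the drugs with
#' kappa >= t. Thresholds whose cohort is empty are omitted. The Pearson
#' correlation between the curve and the threshold is attached, summarising
#' whether a high killing index predicts problematic status.
#'
#' @param drugs Tibble with `drug_id` and logical `flagged`.
#' @param kappas Tibble from [killing_index()] (`drug_id`, `kappa`).
#' @return Tibble of class `kappa_curve` (`threshold`, `n_drugs`,
#'   `fraction_flagged`) with attribute `correlation`.
#' @export
kappa_fraction_curve <- function(drugs, kappas) {
  stopifnot(all(c("drug_id", "flagged") %in% names(drugs)))
  d <- dplyr::inner_join(tibble::as_tibble(drugs),
                         kappas[, c("drug_id", "kappa")], by = "drug_id")
  rows <- purrr::map(0:max(d$kappa, 0), function(t) {
    cohort <- d[d$kappa >= t, , drop = FALSE]
    if (nrow(cohort) == 0L) return(NULL)
    tibble::tibble(threshold = t, n_drugs = nrow(cohort),
                   fraction_flagged = mean(cohort$flagged))
  })
  out <- dplyr::bind_rows(rows)
  corr <- if (nrow(out) >= 3 && stats::sd(out$fraction_flagged) > 0) {
    stats::cor(out$threshold, out$fraction_flagged)
  } else NA_real_
  attr(out, "correlation") <- corr
  class(out) <- c("kappa_curve", class(out))
  out
}

#' Read/write drug side-effect and target side-effect tables
#'
#' Drug side effects are TSV with columns `drug_id`, `term` (SIDER-like);
#' target side effects are TSV with `target_id`, `term`,
#' `supporting_drug_count`.
#'
#' @param path File path.
#' @param target_se Table from [infer_target_side_effects()].
#' @return Tibbles; writers return `path` invisibly.
#' @export
read_side_effects <- function(path) {
  check_se_table(readr::read_tsv(path, show_col_types = FALSE,
                                 progress = FALSE))
}

#' @rdname read_side_effects
#' @export
write_target_side_effects <- function(target_se, path) {
  readr::write_tsv(tibble::as_tibble(target_se), path, progress = FALSE)
  invisible(path)
}

#' @export
print.sidefx_eval <- function(x, ...) {
  cat("Side-effect ", x$mode, " test: ", x$macro$n_drugs_with_predictions,
      "/", x$macro$n_drugs, " drugs with predictions; macro precision ",
      sprintf("%.3f", x$macro$precision), ", recall ",
      sprintf("%.3f", x$macro$recall), "\n", sep = "")
  invisible(x)
}
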