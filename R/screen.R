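#' Virtual target screening by ligand homology
#'
#' A query compound is scored against each protein target through the
#' target's template ligands: small molecules associated with the target
#' because they bind evolutionarily related template proteins. Template
#' ligands arrive through three evidence channels (holo PDB structures,
#' virtual holo templates with DrugBank ligands, virtual holo templates with
#' ChEMBL ligands) and the best channel score is kept.
#'
#' @name screen
NULL

#' Declared template-ligand evidence channels, in tie-break order.
#' @export
LIGAND_CHANNELS <- c("PDB_HOLO", "VIRTUAL_HOLO_DRUGBANK", "VIRTUAL_HOLO_CHEMBL")

#' mTC score of a query against a set of template ligands
#'
#' For template ligands \eqn{L_l} with Tanimoto similarity \eqn{TC(L_l, q)} to
#' the query and true-ligand indicator \eqn{\delta_l} (1 when the ligand is an
#' experimentally confirmed binder of the target itself),
#' \deqn{mTC = \max_l \left[(1 - w)\, TC(L_l, q) + w\, \delta_l\right]}
#' with weight \eqn{w = 0.1} by default, so confirmed binders are up-weighted
#' and an identical true ligand scores exactly 1. An empty ligand set scores 0
#' so every target stays rankable.
#'
#' @param tc Numeric vector of Tanimoto similarities, one per template ligand.
#' @param is_true_ligand Logical vector parallel to `tc`.
#' @param w True-ligand weight in \[0, 1\].
#' @return Score in \[0, 1\].
#' @export
mtc_score <- function(tc, is_true_ligand, w = 0.1) {
  stopifnot(length(w) == 1L, w >= 0, w <= 1)
  if (length(tc) == 0L) return(0)
  stopifnot(length(tc) == length(is_true_ligand))
  max((1 - w) * tc + w * as.numeric(is_true_ligand))
}

#' Exclusion policy for benchmark-mode screening
#'
#' In benchmark mode, template ligands that would leak the answer are removed
#' before scoring: ligands nearly identical to the query (Tanimoto > the
#' ligand TC cutoff, 0.99 by default), ligands inherited from template
#' proteins whose sequence identity to the target under evaluation exceeds
#' the identity cutoff, and any template-ligand record that is the query
#' compound itself annotated on the target. Both comparisons are strict
#' inequalities. In prediction mode (`enabled = FALSE`) ligand sets pass
#' through unchanged.
#'
#' @param enabled Apply exclusions (benchmark mode)?
#' @param seq_identity_cutoff Percent identity above which a source template
#'   protein is considered too close to the target (common choices 95, 30).
#' @param ligand_tc_cutoff Tanimoto similarity above which a template ligand
#'   is considered the same molecule as the query.
#' @return A list of class `exclusion_policy`.
#' @export
exclusion_policy <- function(enabled = FALSE, seq_identity_cutoff = 95,
                             ligand_tc_cutoff = 0.99) {
  stopifnot(seq_identity_cutoff >= 0, seq_identity_cutoff <= 100,
            ligand_tc_cutoff >= 0, ligand_tc_cutoff <= 1)
  structure(list(enabled = isTRUE(enabled),
                 seq_identity_cutoff = seq_identity_cutoff,
                 ligand_tc_cutoff = ligand_tc_cutoff),
            class = "exclusion_policy")
}

#' Global sequence identity between two protein sequences
#'
#' One global (Needleman-Wunsch) alignment with BLOSUM62, affine gaps
#' (open 11, extend 1); identity is the number of identical aligned positions
#' over the length of the shorter sequence, in percent.
#'
#' @param a,b Amino-acid strings (20-letter alphabet, `X` tolerated).
#' @return Percent identity in \[0, 100\].
#' @export
sequence_identity <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
    type = "global"
  )
  100 * Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

# BLOSUM62 matrix, loaded once per session from Biostrings' data sets.
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# Memoized identity lookup over a named sequence vector; unknown ids give NA.
make_identity_lookup <- function(sequences) {
  memo <- new.env(parent = emptyenv())
  function(id_a, id_b) {
    if (is.null(sequences)) return(NA_real_)
    if (!id_a %in% names(sequences) || !id_b %in% names(sequences)) {
      return(NA_real_)
    }
    sa <- sequences[[id_a]]; sb <- sequences[[id_b]]
    if (is.na(sa) || is.na(sb)) return(NA_real_)
    key <- paste(sort(c(id_a, id_b)), collapse = "\r")
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- sequence_identity(sa, sb)
    memo[[key]] <- v
    v
  }
}

#' Apply benchmark-mode exclusions to a template-ligand table
#'
#' @param template_ligands Tibble with columns `target_id`, `compound_id`,
#'   `channel`, `is_true_ligand`, `source_protein_id`, and a `tc` column of
#'   Tanimoto similarities to the query (added by the caller or by
#'   [screen_proteome()]).
#' @param query_id Identifier of the query compound (used to drop the exact
#'   query-target interaction record); may be `NULL`.
#' @param policy An [exclusion_policy()].
#' @param sequences Named character vector of protein sequences covering the
#'   targets and the source template proteins. A ligand whose source protein
#'   has no sequence is retained and a warning is issued (identity unknown).
#' @return The filtered tibble.
#' @export
apply_exclusions <- function(template_ligands, query_id = NULL,
                             policy = exclusion_policy(TRUE),
                             sequences = NULL) {
  if (!isTRUE(policy$enabled)) return(template_ligands)
  tl <- template_ligands
  stopifnot("tc" %in% names(tl))
  keep <- tl$tc <= policy$ligand_tc_cutoff
  if (!is.null(query_id)) keep <- keep & tl$compound_id != query_id
  ident <- make_identity_lookup(sequences)
  pairs <- dplyr::distinct(tl[keep, c("source_protein_id", "target_id")])
  if (nrow(pairs)) {
    pairs$identity <- purrr::map2_dbl(pairs$source_protein_id, pairs$target_id,
                                      ident)
    missing <- unique(pairs$source_protein_id[is.na(pairs$identity)])
    if (length(missing)) {
      warning("no sequence for source protein(s) ",
              paste(utils::head(missing, 5), collapse = ", "),
              if (length(missing) > 5) " ..." else "",
              "; their template ligands are retained", call. = FALSE)
    }
    drop_pairs <- pairs[!is.na(pairs$identity) &
                          pairs$identity > policy$seq_identity_cutoff, ]
    if (nrow(drop_pairs)) {
      bad <- paste(tl$source_protein_id, tl$target_id) %in%
        paste(drop_pairs$source_protein_id, drop_pairs$target_id)
      keep <- keep & !bad
    }
  }
  tl[keep, , drop = FALSE]
}

# Shared scoring core: ligand table must carry a `tc` column.
score_ligand_table <- function(tl, w) {
  if (nrow(tl) == 0L) {
    return(list(mtc = 0, best_channel = NA_character_,
                best_template_ligand = NA_character_))
  }
  contrib <- (1 - w) * tl$tc + w * as.numeric(tl$is_true_ligand)
  ord <- order(-contrib, match(tl$channel, LIGAND_CHANNELS), tl$compound_id)
  best <- ord[1L]
  list(mtc = contrib[best], best_channel = tl$channel[best],
       best_template_ligand = tl$compound_id[best])
}

#' Score one target against a query compound
#'
#' Computes the per-channel mTC on the (optionally exclusion-filtered)
#' template-ligand set of a single target and keeps the best channel.
#'
#' @param template_ligands One target's template-ligand tibble (columns
#'   `compound_id`, `channel`, `is_true_ligand`, `source_protein_id`,
#'   optionally `target_id`).
#' @param query_fp Query fingerprint (0/1 vector).
#' @param fingerprints Tibble with `compound_id` and `fingerprint` list-column
#'   covering the template ligands.
#' @param w True-ligand weight.
#' @param policy [exclusion_policy()]; exclusions apply only when enabled.
#' @inheritParams apply_exclusions
#' @return One-row tibble: `mtc`, `best_channel`, `best_template_ligand`.
#' @export
score_target <- function(template_ligands, query_fp, fingerprints, w = 0.1,
                         policy = exclusion_policy(), query_id = NULL,
                         sequences = NULL) {
  tl <- add_tc_column(template_ligands, query_fp, fingerprints)
  tl <- apply_exclusions(tl, query_id = query_id, policy = policy,
                         sequences = sequences)
  res <- score_ligand_table(tl, w)
  tibble::as_tibble(res)
}

add_tc_column <- function(tl, query_fp, fingerprints) {
  tl <- tibble::as_tibble(tl)
  if (nrow(tl) == 0L) {
    tl$tc <- numeric(0)
    return(tl)
  }
  ids <- unique(tl$compound_id)
  idx <- match(ids, fingerprints$compound_id)
  if (anyNA(idx)) {
    stop("no fingerprint for template ligand(s): ",
         paste(utils::head(ids[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  fpm <- fp_matrix(fingerprints$fingerprint[idx], ids)
  tcs <- tanimoto_many(query_fp, fpm)
  tl$tc <- tcs[match(tl$compound_id, ids)]
  tl
}

#' Screen a query compound against a target library
#'
#' Every target in the library is scored by [mtc_score()] over its
#' channel-partitioned template-ligand set (after benchmark-mode exclusions,
#' when enabled) and the targets are ranked by descending score, ties broken
#' by ascending `target_id` so rankings are reproducible and invariant to the
#' input order. Targets with no (surviving) template ligands score 0 and stay
#' in the ranking.
#'
#' @param template_ligands Template-ligand tibble: `target_id`, `compound_id`,
#'   `channel`, `is_true_ligand`, `source_protein_id`.
#' @param query_fp Query fingerprint (0/1 vector of 1024 bits).
#' @param fingerprints Tibble (`compound_id`, `fingerprint` list-column)
#'   covering all template ligands.
#' @param targets Optional character vector (or tibble with `target_id`) fixing
#'   the library; defaults to the targets present in `template_ligands`.
#'   Targets listed here but absent from the ligand table are ranked with
#'   score 0.
#' @param w True-ligand weight (default 0.1).
#' @param policy [exclusion_policy()].
#' @param query_id Optional query compound identifier (benchmark exclusions).
#' @param sequences Named character vector of protein sequences (benchmark
#'   exclusions).
#' @param mtc_cutoff Optional score cutoff; when given, a `predicted` column
#'   flags hits with `mtc >= mtc_cutoff` (inclusive).
#' @return A tibble of class `drugcast_screen`: `target_id`, `mtc`, `rank`,
#'   `best_channel`, `best_template_ligand` (+ `predicted`), sorted by
#'   descending `mtc`.
#' @export
screen_proteome <- function(template_ligands, query_fp, fingerprints,
                            targets = NULL, w = 0.1,
                            policy = exclusion_policy(), query_id = NULL,
                            sequences = NULL, mtc_cutoff = NULL) {
  tl <- add_tc_column(template_ligands, query_fp, fingerprints)
  tl <- apply_exclusions(tl, query_id = query_id, policy = policy,
                         sequences = sequences)
  if (is.null(targets)) {
    targets <- sort(unique(template_ligands$target_id))
  } else if (is.data.frame(targets)) {
    targets <- targets$target_id
  }
  stopifnot(length(targets) > 0L, !anyDuplicated(targets))
  scored <- purrr::map(targets, function(t_id) {
    score_ligand_table(tl[tl$target_id == t_id, , drop = FALSE], w)
  })
  hits <- tibble::tibble(
    target_id = targets,
    mtc = purrr::map_dbl(scored, "mtc"),
    best_channel = purrr::map_chr(scored, "best_channel"),
    best_template_ligand = purrr::map_chr(scored, "best_template_ligand")
  )
  hits <- hits[order(-hits$mtc, hits$target_id), ]
  hits$rank <- seq_len(nrow(hits))
  hits <- hits[, c("target_id", "mtc", "rank", "best_channel",
                   "best_template_ligand")]
  if (!is.null(mtc_cutoff)) hits$predicted <- hits$mtc >= mtc_cutoff
  attr(hits, "query_id") <- query_id
  attr(hits, "w") <- w
  attr(hits, "policy") <- policy
  attr(hits, "mtc_cutoff") <- mtc_cutoff
  class(hits) <- c("drugcast_screen", class(hits))
  hits
}

#' Audit benchmark-mode exclusion soundness
#'
#' Recomputes, post hoc, that no surviving template ligand violates the
#' exclusion policy for a given (query, target) pair: no survivor has
#' Tanimoto above the ligand cutoff to the query and no survivor's source
#' protein exceeds the identity cutoff to the target (where sequences are
#' known).
#'
#' @inheritParams screen_proteome
#' @return TRUE invisibly, or an error describing the violation.
#' @export
audit_exclusions <- function(template_ligands, query_fp, fingerprints,
                             policy, query_id = NULL, sequences = NULL) {
  tl <- add_tc_column(template_ligands, query_fp, fingerprints)
  surv <- apply_exclusions(tl, query_id = query_id, policy = policy,
                           sequences = sequences)
  if (any(surv$tc > policy$ligand_tc_cutoff)) {
    stop("exclusion audit failed: surviving ligand with TC > cutoff")
  }
  ident <- make_identity_lookup(sequences)
  idents <- purrr::map2_dbl(surv$source_protein_id, surv$target_id, ident)
  if (any(!is.na(idents) & idents > policy$seq_identity_cutoff)) {
    stop("exclusion audit failed: surviving ligand from over-identical source")
  }
  invisible(TRUE)
}

#' @export
print.drugcast_screen <- function(x, ...) {
  q <- attr(x, "query_id")
  cat("Virtual target screen", if (!is.null(q)) paste0(" for ", q), ": ",
      nrow(x), " targets, w = ", attr(x, "w"), sep = "")
  co <- attr(x, "mtc_cutoff")
  if (!is.null(co)) cat(", ", sum(x$predicted), " predicted at mTC >= ", co,
                        sep = "")
  cat("\n")
  NextMethod()
}
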