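#' Table readers, run configuration and the two end-to-end reports
#'
#' The two workflows a user runs: (a) screen a compound against a target
#' library and report ranked hits plus predicted interactions; (b) predict a
#' compound's side effects and killing index from its predicted targets.
#' All interchange formats are headered TSV; identifiers are opaque strings.
#'
#' @name reports
NULL

#' Run configuration with the method's default parameters
#'
#' Defaults are the method's operating point: true-ligand weight w = 0.1,
#' predicted-interaction cutoff mTC = 0.90, benchmark exclusion cutoffs of
#' 95% sequence identity and Tanimoto 0.99, enrichment fractions 1%, 5%,
#' 10%.
#'
#' @param w True-ligand weight.
#' @param mtc_cutoff Score at or above which a hit is a predicted
#'   interaction.
#' @param seq_identity_cutoff Benchmark sequence-identity exclusion (percent;
#'   95 for the standard benchmark, 30 for the remote-homology one).
#' @param ligand_tc_cutoff Benchmark ligand-similarity exclusion.
#' @param ef_fractions Top fractions for enrichment factors.
#' @param serious Serious side-effect terms.
#' @param mode `"predict"` (no exclusions) or `"benchmark"`.
#' @param seed Optional integer recorded in reports.
#' @return List of class `run_config`.
#' @export
run_config <- function(w = 0.1, mtc_cutoff = 0.90, seq_identity_cutoff = 95,
                       ligand_tc_cutoff = 0.99,
                       ef_fractions = c(0.01, 0.05, 0.1),
                       serious = serious_side_effects(),
                       mode = c("predict", "benchmark"), seed = NULL) {
  mode <- match.arg(mode)
  structure(list(w = w, mtc_cutoff = mtc_cutoff,
                 seq_identity_cutoff = seq_identity_cutoff,
                 ligand_tc_cutoff = ligand_tc_cutoff,
                 ef_fractions = ef_fractions, serious = serious,
                 mode = mode, seed = seed),
            class = "run_config")
}

check_cols <- function(tab, cols, what) {
  missing <- setdiff(cols, names(tab))
  if (length(missing)) {
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(tab)
}

#' Read the documented TSV interchange tables
#'
#' `read_template_ligands()`: target_id, compound_id, channel,
#' is_true_ligand, source_protein_id. `read_interactions()`: drug_id,
#' target_id. `read_fasta_sequences()`: FASTA to a named character vector.
#'
#' @param path File path.
#' @return A tibble (or named character vector for FASTA).
#' @export
read_template_ligands <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tab <- check_cols(tab, c("target_id", "compound_id", "channel",
                           "is_true_ligand", "source_protein_id"),
                    "template-ligand table")
  bad <- !tab$channel %in% LIGAND_CHANNELS
  if (any(bad)) {
    stop("template-ligand table line(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "),
         ": unknown channel", call. = FALSE)
  }
  tab$is_true_ligand <- as.logical(tab$is_true_ligand)
  tab
}

#' @rdname read_template_ligands
#' @export
read_interactions <- function(path) {
  check_cols(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
             c("drug_id", "target_id"), "interaction table")
}

#' @rdname read_template_ligands
#' @export
read_fasta_sequences <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
}

#' Write / read a ranked-hits table
#'
#' TSV with drug_id (when known), target_id, rank, mtc, best_channel,
#' best_template_ligand and the predicted flag when a cutoff was applied.
#'
#' @param hits A [screen_proteome()] result.
#' @param path File path.
#' @export
write_hits <- function(hits, path) {
  out <- tibble::as_tibble(hits)
  q <- attr(hits, "query_id")
  if (!is.null(q)) out <- dplyr::bind_cols(tibble::tibble(drug_id = q), out)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_hits
#' @export
read_hits <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

as_library <- function(library) {
  if (is.character(library) && length(library) == 1L) read_fixtures(library)
  else library
}

query_fp_from <- function(library, query) {
  if (is.character(query) && length(query) == 1L) {
    i <- match(query, library$compounds$compound_id)
    if (is.na(i)) stop("query '", query, "' not in the compound table",
                       call. = FALSE)
    library$compounds$fingerprint[[i]]
  } else {
    query
  }
}

#' Screen a compound against a library directory and report
#'
#' Runs the full ranked screen (benchmark exclusions when
#' `config$mode == "benchmark"`, including a post-hoc exclusion audit),
#' flags predicted interactions at the configured mTC cutoff and summarises.
#'
#' @param library A fixture directory path (see [emit_fixtures()]) or an
#'   equivalent list of tables.
#' @param query A compound_id present in the library's compound table, or a
#'   raw fingerprint vector.
#' @param config A [run_config()].
#' @return List: `hits` (ranked tibble), `predicted` (hits at or above the
#'   cutoff), `summary` (one-row tibble).
#' @export
run_screen_report <- function(library, query, config = run_config()) {
  lib <- as_library(library)
  query_fp <- query_fp_from(lib, query)
  query_id <- if (is.character(query)) query else NULL
  policy <- exclusion_policy(config$mode == "benchmark",
                             config$seq_identity_cutoff,
                             config$ligand_tc_cutoff)
  targets <- if (!is.null(lib$targets)) sort(lib$targets$target_id)
             else sort(unique(lib$template_ligands$target_id))
  hits <- screen_proteome(lib$template_ligands, query_fp,
                          fingerprints = lib$compounds, targets = targets,
                          w = config$w, policy = policy,
                          query_id = query_id, sequences = lib$sequences,
                          mtc_cutoff = config$mtc_cutoff)
  if (policy$enabled) {
    audit_exclusions(lib$template_ligands, query_fp, lib$compounds, policy,
                     query_id = query_id, sequences = lib$sequences)
  }
  predicted <- hits[hits$predicted, , drop = FALSE]
  if (nrow(predicted) == 0L && config$mtc_cutoff > 1) {
    warning("mTC cutoff ", config$mtc_cutoff,
            " exceeds the score range; no interaction can be flagged",
            call. = FALSE)
  }
  list(hits = hits, predicted = tibble::as_tibble(predicted),
       summary = glance(hits))
}

#' Side-effect and killing-index report for a compound
#'
#' Screens the compound, takes the targets predicted at the configured mTC
#' cutoff, infers target side effects from the library's interaction and
#' drug side-effect tables, and reports the union of side effects over the
#' predicted targets (with per-term supporting-target counts) plus the
#' killing index and its contributing targets.
#'
#' @inheritParams run_screen_report
#' @param drug_se Drug side-effect table (tibble or TSV path); defaults to
#'   the library's own `drug_se` table.
#' @return List: `side_effects` (tibble `term`, `n_supporting_targets`),
#'   `kappa`, `kappa_targets` (character), `predicted_targets`, `hits`.
#' @export
run_sidefx_report <- function(library, query, config = run_config(),
                              drug_se = NULL) {
  lib <- as_library(library)
  if (is.null(drug_se)) drug_se <- lib$drug_se
  if (is.character(drug_se)) drug_se <- read_side_effects(drug_se)
  scr <- run_screen_report(lib, query, config)
  predicted_targets <- scr$predicted$target_id
  target_se <- infer_target_side_effects(lib$interactions, drug_se)
  se_hit <- target_se[target_se$target_id %in% predicted_targets, ]
  side_effects <- se_hit |>
    dplyr::count(.data$term, name = "n_supporting_targets") |>
    dplyr::arrange(dplyr::desc(.data$n_supporting_targets), .data$term)
  serious <- normalize_terms(config$serious)
  kappa_targets <- sort(unique(
    se_hit$target_id[se_hit$term %in% serious]))
  list(side_effects = side_effects,
       kappa = length(kappa_targets),
       kappa_targets = kappa_targets,
       predicted_targets = predicted_targets,
       hits = scr$hits)
}
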