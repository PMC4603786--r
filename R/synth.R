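#' Synthetic worlds with planted ground truth
#'
#' Generates the full set of inputs the pipeline consumes — compound
#' fingerprints, channel-partitioned template-ligand sets, drug-target
#' interaction truth, drug side-effect tables, protein sequences — from a
#' known generative model, so screening, side-effect inference and the
#' benchmark metrics can all be validated against planted truth without any
#' external data.
#'
#' The generative model: each target carries a latent side-effect set drawn
#' from a term catalog (serious terms injected at a configured rate); drugs
#' bind a long-tailed (log-normal) number of targets; a drug's side-effect
#' set is the union of its targets' latent sets, corrupted by term noise and
#' dropout; each target's template-ligand set holds noisy fingerprint copies
#' (bit flips) of its true binders plus random decoy compounds; target and
#' template-protein sequences descend from a common ancestor with controlled
#' mutation so pairwise identities are predictable. A fraction of true
#' interactions can be hidden from the labeled truth to emulate incomplete
#' interaction databases.
#'
#' @name synth
NULL

#' Parameters of a synthetic world
#'
#' @param n_targets Number of protein targets.
#' @param n_drugs Number of drugs (each gets a random 1024-bit fingerprint).
#' @param n_decoys Number of decoy compounds available as non-true template
#'   ligands.
#' @param decoys_per_target Decoy template ligands attached to each target.
#' @param fp_nbits_on Expected number of set bits in a random fingerprint.
#' @param fp_noise_rate Per-bit flip probability when a true binder's
#'   fingerprint is copied into a template-ligand record (0 = exact copy).
#' @param se_catalog_size Number of distinct ordinary side-effect terms.
#' @param se_per_target Latent side-effect terms per target.
#' @param serious_rate Probability that a target's latent set also contains
#'   one serious term.
#' @param se_noise_rate Expected number of spurious terms added to a drug's
#'   side-effect record, as a fraction of its true set size.
#' @param se_dropout_rate Probability that a true term is dropped from a
#'   drug's record.
#' @param promiscuity_meanlog,promiscuity_sdlog Log-normal parameters of the
#'   targets-per-drug count (long-tailed, echoing the heavy right tail of
#'   real drug promiscuity).
#' @param truth_completeness Fraction of planted true interactions exposed in
#'   the labeled truth table (1 = complete labels).
#' @param flag_base_rate Probability that a drug is flagged
#'   withdrawn/illicit/investigational, independent of its kappa.
#' @param flag_kappa_slope Additional per-serious-target increment of the
#'   flag probability (0 = flags independent of kappa).
#' @param seq_length Length of the ancestral protein sequence.
#' @param source_identity_true Target-to-source-protein sequence identity for
#'   template ligands copied from true binders; the default 0.90 sits between
#'   the two standard benchmark cutoffs, so these ligands survive a 95%
#'   exclusion but not a 30% one.
#' @param source_identity_decoy Identity for decoy-ligand source proteins.
#' @return A named list of class `synth_params`.
#' @export
synth_params <- function(n_targets = 40, n_drugs = 25, n_decoys = 60,
                         decoys_per_target = 4, fp_nbits_on = 120,
                         fp_noise_rate = 0, se_catalog_size = 60,
                         se_per_target = 4, serious_rate = 0.15,
                         se_noise_rate = 0, se_dropout_rate = 0,
                         promiscuity_meanlog = log(3),
                         promiscuity_sdlog = 0.8,
                         truth_completeness = 1, flag_base_rate = 0.25,
                         flag_kappa_slope = 0, seq_length = 120,
                         source_identity_true = 0.90,
                         source_identity_decoy = 0.25) {
  p <- as.list(environment())
  stopifnot(p$n_targets >= 2, p$n_drugs >= 2,
            p$se_per_target <= p$se_catalog_size,
            p$fp_noise_rate >= 0, p$fp_noise_rate <= 1,
            p$truth_completeness > 0, p$truth_completeness <= 1,
            p$source_identity_true > 0, p$source_identity_true <= 1)
  structure(p, class = "synth_params")
}

random_fp <- function(n_on) {
  bits <- integer(FP_NBITS)
  bits[sample.int(FP_NBITS, min(n_on, FP_NBITS))] <- 1L
  bits
}

flip_bits <- function(fp, rate) {
  if (rate <= 0) return(fp)
  flip <- stats::runif(FP_NBITS) < rate
  as.integer(xor(fp == 1L, flip))
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

mutate_sequence <- function(seq_chr, identity) {
  chars <- strsplit(seq_chr, "")[[1]]
  n_mut <- round((1 - identity) * length(chars))
  if (n_mut > 0) {
    pos <- sample.int(length(chars), n_mut)
    for (i in pos) {
      chars[i] <- sample(setdiff(AA20, chars[i]), 1)
    }
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic world
#'
#' All randomness flows from `seed`; identical parameters and seed give an
#' identical world.
#'
#' @param params A [synth_params()] list.
#' @param seed Integer seed.
#' @return An object of class `synth_world`: a list of tibbles `targets`,
#'   `drugs`, `compounds` (with `fingerprint` list-column),
#'   `template_ligands`, `interactions` (labeled truth), `planted_truth`
#'   (complete truth), `drug_se`, `latent_target_se`, plus `sequences`
#'   (named character vector), `params`, and `seed`.
#' @export
make_world <- function(params = synth_params(), seed = 1) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  set.seed(seed)

  target_ids <- sprintf("T%03d", seq_len(p$n_targets))
  drug_ids <- sprintf("D%03d", seq_len(p$n_drugs))
  decoy_ids <- if (p$n_decoys > 0) sprintf("X%03d", seq_len(p$n_decoys))
               else character()
  catalog <- sprintf("se_%03d", seq_len(p$se_catalog_size))
  serious <- serious_side_effects()

  # (i) latent target side-effect sets
  latent <- purrr::map(target_ids, function(t) {
    terms <- sample(catalog, p$se_per_target)
    if (stats::runif(1) < p$serious_rate) terms <- c(terms, sample(serious, 1))
    sort(terms)
  })
  names(latent) <- target_ids
  latent_tbl <- tibble::tibble(
    target_id = rep(target_ids, lengths(latent)),
    term = unlist(latent, use.names = FALSE)
  )

  # (ii) true drug-target interactions (long-tailed promiscuity)
  promiscuity <- pmin(
    pmax(1L, round(stats::rlnorm(p$n_drugs, p$promiscuity_meanlog,
                                 p$promiscuity_sdlog))),
    p$n_targets)
  planted <- purrr::map2(drug_ids, promiscuity, function(d, k) {
    tibble::tibble(drug_id = d, target_id = sort(sample(target_ids, k)))
  }) |> dplyr::bind_rows()

  # (iii) drug side effects: union of latent sets + noise - dropout
  drug_se <- purrr::map(drug_ids, function(d) {
    tgts <- planted$target_id[planted$drug_id == d]
    terms <- sort(unique(unlist(latent[tgts])))
    if (p$se_dropout_rate > 0 && length(terms)) {
      terms <- terms[stats::runif(length(terms)) >= p$se_dropout_rate]
    }
    if (p$se_noise_rate > 0) {
      n_noise <- stats::rpois(1, p$se_noise_rate * max(length(terms), 1))
      terms <- unique(c(terms, sample(catalog, min(n_noise,
                                                   length(catalog)))))
    }
    if (length(terms) == 0L) return(NULL)
    tibble::tibble(drug_id = d, term = sort(terms))
  }) |> dplyr::bind_rows()

  # compounds: drugs and decoys get random fingerprints
  compounds <- tibble::tibble(
    compound_id = c(drug_ids, decoy_ids),
    kind = c(rep("drug", p$n_drugs), rep("decoy", length(decoy_ids))),
    fingerprint = c(
      purrr::map(seq_len(p$n_drugs), function(i) random_fp(p$fp_nbits_on)),
      purrr::map(seq_along(decoy_ids), function(i) random_fp(p$fp_nbits_on))
    )
  )

  # (iv) template ligands: noisy copies of true binders + decoys
  fp_of <- function(id) {
    compounds$fingerprint[[match(id, compounds$compound_id)]]
  }
  lig_counter <- 0L
  tl_rows <- list()
  lig_fps <- list()
  for (t in target_ids) {
    binders <- planted$drug_id[planted$target_id == t]
    for (d in binders) {
      lig_counter <- lig_counter + 1L
      lid <- sprintf("L%05d", lig_counter)
      lig_fps[[lid]] <- flip_bits(fp_of(d), p$fp_noise_rate)
      tl_rows[[length(tl_rows) + 1L]] <- tibble::tibble(
        target_id = t, compound_id = lid,
        channel = sample(LIGAND_CHANNELS, 1),
        is_true_ligand = TRUE,
        source_protein_id = paste0("S_", t, "_true")
      )
    }
    if (p$decoys_per_target > 0 && length(decoy_ids)) {
      dec <- sample(decoy_ids, min(p$decoys_per_target, length(decoy_ids)))
      tl_rows[[length(tl_rows) + 1L]] <- tibble::tibble(
        target_id = t, compound_id = dec,
        channel = sample(LIGAND_CHANNELS, length(dec), replace = TRUE),
        is_true_ligand = FALSE,
        source_protein_id = paste0("S_", t, "_decoy")
      )
    }
  }
  template_ligands <- dplyr::bind_rows(tl_rows)
  compounds <- dplyr::bind_rows(
    compounds,
    tibble::tibble(compound_id = names(lig_fps), kind = "template_ligand",
                   fingerprint = unname(lig_fps))
  )

  # sequences: ancestor-derived, with controlled source-protein identities
  ancestor <- paste(sample(AA20, p$seq_length, replace = TRUE),
                    collapse = "")
  sequences <- character()
  for (t in target_ids) {
    sequences[[t]] <- mutate_sequence(ancestor, 0.55)
    sequences[[paste0("S_", t, "_true")]] <-
      mutate_sequence(sequences[[t]], p$source_identity_true)
    sequences[[paste0("S_", t, "_decoy")]] <-
      mutate_sequence(ancestor, p$source_identity_decoy)
  }

  # (v) labeled truth, possibly incomplete
  interactions <- planted
  if (p$truth_completeness < 1) {
    keep <- stats::runif(nrow(planted)) < p$truth_completeness
    interactions <- planted[keep, , drop = FALSE]
  }

  # drug status flags for the kappa analysis
  n_serious_targets <- purrr::map_int(drug_ids, function(d) {
    tgts <- planted$target_id[planted$drug_id == d]
    sum(purrr::map_lgl(latent[tgts], function(s) any(s %in% serious)))
  })
  flag_p <- pmin(1, p$flag_base_rate + p$flag_kappa_slope * n_serious_targets)
  drugs <- tibble::tibble(
    drug_id = drug_ids,
    promiscuity = as.integer(promiscuity),
    flagged = stats::runif(p$n_drugs) < flag_p
  )

  structure(list(
    targets = tibble::tibble(target_id = target_ids,
                             sequence = unname(sequences[target_ids])),
    drugs = drugs,
    compounds = compounds,
    template_ligands = template_ligands,
    interactions = interactions,
    planted_truth = planted,
    drug_se = drug_se,
    latent_target_se = latent_tbl,
    sequences = sequences,
    params = p,
    seed = seed
  ), class = "synth_world")
}

#' Write a synthetic world to plain-text fixture files
#'
#' Emits the documented interchange formats: `fingerprints.tsv`
#' (compound_id, kind, bits), `targets.tsv`, `template_ligands.tsv`,
#' `interactions.tsv`
#' (labeled truth), `planted_truth.tsv` (complete truth),
#' `side_effects.tsv`, `drugs.tsv` (status flags), `sequences.fasta`, and a
#' key-value `manifest.txt` with the generator parameters and seed.
#'
#' @param world A `synth_world`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
emit_fixtures <- function(world, dir) {
  stopifnot(inherits(world, "synth_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(x) file.path(dir, x)
  write_fingerprints(world$compounds, f("fingerprints.tsv"))
  readr::write_tsv(world$targets["target_id"], f("targets.tsv"),
                   progress = FALSE)
  readr::write_tsv(world$template_ligands, f("template_ligands.tsv"),
                   progress = FALSE)
  readr::write_tsv(world$interactions, f("interactions.tsv"),
                   progress = FALSE)
  readr::write_tsv(world$planted_truth, f("planted_truth.tsv"),
                   progress = FALSE)
  readr::write_tsv(world$drug_se, f("side_effects.tsv"), progress = FALSE)
  readr::write_tsv(world$drugs, f("drugs.tsv"), progress = FALSE)
  seqs <- Biostrings::AAStringSet(world$sequences)
  Biostrings::writeXStringSet(seqs, f("sequences.fasta"))
  manifest <- c(
    sprintf("seed\t%d", world$seed),
    sprintf("%s\t%s", names(world$params),
            vapply(world$params, function(v) format(v, digits = 15),
                   character(1)))
  )
  writeLines(manifest, f("manifest.txt"))
  invisible(dir)
}

#' Reload fixture tables written by [emit_fixtures()]
#'
#' @param dir Fixture directory.
#' @return List with the same table components as a `synth_world`
#'   (`compounds`, `template_ligands`, `interactions`, `planted_truth`,
#'   `drug_se`, `drugs`, `sequences`, `manifest`).
#' @export
read_fixtures <- function(dir) {
  f <- function(x) file.path(dir, x)
  seqs <- Biostrings::readAAStringSet(f("sequences.fasta"))
  manifest_lines <- readLines(f("manifest.txt"))
  kv <- strsplit(manifest_lines, "\t")
  manifest <- stats::setNames(vapply(kv, `[`, character(1), 2),
                              vapply(kv, `[`, character(1), 1))
  list(
    compounds = read_fingerprints(f("fingerprints.tsv")),
    targets = readr::read_tsv(f("targets.tsv"), show_col_types = FALSE,
                              progress = FALSE),
    template_ligands = readr::read_tsv(f("template_ligands.tsv"),
                                       show_col_types = FALSE,
                                       progress = FALSE),
    interactions = readr::read_tsv(f("interactions.tsv"),
                                   show_col_types = FALSE, progress = FALSE),
    planted_truth = readr::read_tsv(f("planted_truth.tsv"),
                                    show_col_types = FALSE,
                                    progress = FALSE),
    drug_se = readr::read_tsv(f("side_effects.tsv"), show_col_types = FALSE,
                              progress = FALSE),
    drugs = readr::read_tsv(f("drugs.tsv"), show_col_types = FALSE,
                            progress = FALSE),
    sequences = stats::setNames(as.character(seqs), names(seqs)),
    manifest = manifest
  )
}

#' @export
print.synth_world <- function(x, ...) {
  cat("Synthetic world (seed ", x$seed, "): ", nrow(x$targets), " targets, ",
      nrow(x$drugs), " drugs, ", nrow(x$template_ligands),
      " template ligands, ", nrow(x$planted_truth),
      " planted interactions\n", sep = "")
  invisible(x)
}
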