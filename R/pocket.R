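#' Binding-pocket extraction and structure-pocket alignment
#'
#' A pocket model of a holo template is the ordered C-alpha trace of the
#' residues near the bound ligand: residues with any heavy atom within 4.5 A
#' of a ligand heavy atom, plus residues whose C-alpha lies within 8 A of a
#' ligand heavy atom. A target structure is aligned onto a pocket by an
#' exhaustive, sequence-order-dependent triplet search: every pair of
#' C-alpha triplets whose three internal distances agree within 1 A seeds a
#' least-squares superposition, the alignment is grown by pairing residues
#' within 1 A, and superposition and growth are iterated to a fixed point;
#' the best-scoring fixed point over all seeds wins.
#'
#' Structures are tibbles with columns `residue_index` (1-based, strictly
#' increasing per chain), `aa` (one-letter code), `atom` (atom name, `"CA"`
#' for the trace), and coordinates `x`, `y`, `z` in Angstroms.
#'
#' @name pocket
NULL

AA_3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

coords_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    m <- x
  } else {
    stopifnot(all(c("x", "y", "z") %in% names(x)))
    m <- cbind(x$x, x$y, x$z)
  }
  storage.mode(m) <- "double"
  if (!all(is.finite(m))) stop("non-finite coordinates", call. = FALSE)
  m
}

#' Extract a ligand-binding pocket from a holo structure
#'
#' @param structure Full-atom structure tibble (`residue_index`, `aa`,
#'   `atom`, `x`, `y`, `z`); must include heavy atoms, not just the trace.
#' @param ligand Ligand heavy-atom coordinates: matrix with 3 columns or
#'   tibble with `x`, `y`, `z`. Must have at least one atom.
#' @param heavy_cutoff Distance (A) from any residue heavy atom to any
#'   ligand heavy atom for rule (i); default 4.5.
#' @param ca_cutoff Distance (A) from the residue C-alpha to any ligand
#'   heavy atom for rule (ii); default 8.
#' @return Pocket model: C-alpha tibble of the selected residues in chain
#'   order, class `pocket_model`. May have zero rows if the ligand is far
#'   from every residue.
#' @export
extract_pocket <- function(structure, ligand, heavy_cutoff = 4.5,
                           ca_cutoff = 8) {
  lig <- coords_matrix(ligand)
  if (nrow(lig) == 0L) stop("ligand has no atoms", call. = FALSE)
  structure <- tibble::as_tibble(structure)
  atoms <- coords_matrix(structure)
  # min distance from each structure atom to the ligand
  d2 <- outer(rowSums(atoms^2), rowSums(lig^2), "+") -
    2 * atoms %*% t(lig)
  mind <- sqrt(pmax(apply(d2, 1, min), 0))
  near_any <- structure$residue_index[mind <= heavy_cutoff]
  is_ca <- structure$atom == "CA"
  near_ca <- structure$residue_index[is_ca & mind <= ca_cutoff]
  keep <- sort(unique(c(near_any, near_ca)))
  pocket <- structure[is_ca & structure$residue_index %in% keep, ]
  pocket <- pocket[order(pocket$residue_index),
                   c("residue_index", "aa", "atom", "x", "y", "z")]
  class(pocket) <- c("pocket_model", class(pocket))
  pocket
}

#' C-alpha trace of a full-atom structure
#'
#' @param structure Structure tibble.
#' @return The `atom == "CA"` rows in chain order.
#' @export
ca_trace <- function(structure) {
  tr <- tibble::as_tibble(structure)
  tr <- tr[tr$atom == "CA", , drop = FALSE]
  tr[order(tr$residue_index), ]
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimizing the RMSD of
#' `moving %*% R + t` to `fixed`. Reflections are excluded by construction.
#'
#' @param moving,fixed Coordinate matrices (n x 3) or tibbles with `x`, `y`,
#'   `z`; equal length, n >= 3 and non-collinear.
#' @return List: `rotation` (3 x 3), `translation` (length 3), `rmsd` (A).
#' @export
kabsch_superpose <- function(moving, fixed) {
  M <- coords_matrix(moving); F <- coords_matrix(fixed)
  if (nrow(M) != nrow(F)) stop("point counts differ", call. = FALSE)
  if (nrow(M) < 3L) stop("need >= 3 points", call. = FALSE)
  cm <- colMeans(M); cf <- colMeans(F)
  Mc <- sweep(M, 2, cm); Fc <- sweep(F, 2, cf)
  sv_m <- svd(Mc)$d; sv_f <- svd(Fc)$d
  if (sv_m[2] < 1e-8 * max(sv_m[1], 1) || sv_f[2] < 1e-8 * max(sv_f[1], 1)) {
    stop("degenerate (collinear) point set", call. = FALSE)
  }
  H <- t(Mc) %*% Fc
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t_vec <- as.numeric(cf - cm %*% R)
  moved <- M %*% R + matrix(t_vec, nrow(M), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - F)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

apply_transform <- function(coords, rotation, translation) {
  coords %*% rotation + matrix(translation, nrow(coords), 3, byrow = TRUE)
}

# Order-preserving pairing of transformed target residues to pocket
# residues: dynamic programming over pairs within `tol`, maximizing the
# number of pairs and, among matchings of equal size, minimizing the total
# distance. Order-preserving on both sides; a chain that folds back cannot
# steal a pocket residue and shift the register, which a one-pass greedy
# sweep is vulnerable to.
order_pairs <- function(tt, pp, tol = 1) {
  n <- nrow(tt); m <- nrow(pp)
  d2 <- outer(rowSums(tt^2), rowSums(pp^2), "+") - 2 * tt %*% t(pp)
  d <- sqrt(pmax(d2, 0))
  allowed <- d <= tol
  if (!any(allowed)) return(cbind(target = integer(0), pocket = integer(0)))
  big <- 2 * tol + 1              # any pair beats any distance penalty
  val <- big - d
  f <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      best <- max(f[i, j + 1], f[i + 1, j])
      if (allowed[i, j]) best <- max(best, f[i, j] + val[i, j])
      f[i + 1, j + 1] <- best
    }
  }
  pairs_t <- integer(0); pairs_p <- integer(0)
  i <- n; j <- m
  while (i > 0 && j > 0) {
    if (allowed[i, j] &&
        abs(f[i + 1, j + 1] - (f[i, j] + val[i, j])) < 1e-9) {
      pairs_t <- c(i, pairs_t); pairs_p <- c(j, pairs_p)
      i <- i - 1; j <- j - 1
    } else if (f[i, j + 1] >= f[i + 1, j]) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  cbind(target = pairs_t, pocket = pairs_p)
}

# Pairwise score of an alignment: distance term + BLOSUM62 sequence term.
alignment_score <- function(dists, aa_t, aa_p, d0 = 3, seq_weight = 0.5) {
  b62 <- blosum62()
  bmax <- max(abs(b62))
  aa_t <- ifelse(aa_t %in% rownames(b62), aa_t, "X")
  aa_p <- ifelse(aa_p %in% rownames(b62), aa_p, "X")
  seqterm <- b62[cbind(aa_t, aa_p)] / bmax
  sum(1 / (1 + (dists / d0)^2) + seq_weight * seqterm)
}

enumerate_triplets <- function(n, max_span = Inf) {
  if (n < 3L) return(matrix(integer(0), 0, 3))
  idx <- utils::combn(n, 3)
  keep <- (idx[3, ] - idx[1, ]) <= max_span
  t(idx[, keep, drop = FALSE])
}

triplet_distances <- function(coords, trip) {
  d <- function(a, b) sqrt(rowSums((coords[a, , drop = FALSE] -
                                      coords[b, , drop = FALSE])^2))
  cbind(d12 = d(trip[, 1], trip[, 2]),
        d13 = d(trip[, 1], trip[, 3]),
        d23 = d(trip[, 2], trip[, 3]))
}

empty_alignment <- function() {
  structure(list(
    correspondence = tibble::tibble(target_residue = integer(),
                                    pocket_residue = integer(),
                                    distance = numeric()),
    rotation = diag(3), translation = c(0, 0, 0),
    rmsd = NA_real_, score = 0, n_aligned = 0L, converged = TRUE
  ), class = "pocket_alignment")
}

#' Align a target C-alpha structure onto a template pocket
#'
#' Heuristic sequence-order-dependent triplet alignment. All target triplets
#' within a sequence span cap are compared with all pocket triplets; a pair
#' whose three internal C-alpha distances each agree within `seed_tol` seeds
#' a superposition. Residues of the superposed target within `pair_tol` of a
#' pocket residue (order-preserving on both sides) form the grown
#' alignment, superposition and growth iterate to a fixed point (or the
#' iteration cap, keeping the best iterate), and the best-scoring fixed
#' point over all seeds is returned. The score sums, over aligned pairs, a
#' distance term 1 / (1 + (d / d0)^2) and a BLOSUM62 sequence-similarity
#' term scaled by `seq_weight`.
#'
#' @param target C-alpha structure tibble (>= 3 residues).
#' @param pocket Pocket model from [extract_pocket()] (>= 3 residues).
#' @param seed_tol Per-distance agreement tolerance for seed triplets (A).
#' @param pair_tol Residue pairing distance in the growth step (A).
#' @param max_span Maximum residue-index span of a target seed triplet;
#'   bounds the otherwise cubic triplet enumeration. `Inf` for exhaustive.
#' @param max_seeds Refine at most this many admissible seeds, taken in
#'   order of triplet-distance agreement (best first, deterministic
#'   tie-break); `Inf` refines them all.
#' @param iter_cap Maximum refinement iterations per seed.
#' @param d0 Distance scale of the score (A).
#' @param seq_weight Weight of the sequence term in the score.
#' @return `pocket_alignment` object: `correspondence` tibble
#'   (`target_residue`, `pocket_residue`, `distance`), `rotation`,
#'   `translation`, `rmsd`, `score`, `n_aligned`, `converged`. No admissible
#'   seed yields an empty alignment with score 0.
#' @export
align_pocket <- function(target, pocket, seed_tol = 1, pair_tol = 1,
                         max_span = 30, max_seeds = 400, iter_cap = 100,
                         d0 = 3, seq_weight = 0.5) {
  target <- ca_trace(target)
  pocket_t <- tibble::as_tibble(pocket)
  stopifnot(nrow(target) >= 3L, nrow(pocket_t) >= 3L)
  Tc <- coords_matrix(target); Pc <- coords_matrix(pocket_t)
  trip_t <- enumerate_triplets(nrow(Tc), max_span)
  trip_p <- enumerate_triplets(nrow(Pc))
  if (nrow(trip_t) == 0L || nrow(trip_p) == 0L) return(empty_alignment())
  dist_t <- triplet_distances(Tc, trip_t)
  dist_p <- triplet_distances(Pc, trip_p)

  # all admissible seed pairs, best distance agreement first
  seeds <- vector("list", nrow(trip_p))
  for (pi in seq_len(nrow(trip_p))) {
    dev1 <- abs(dist_t[, 1] - dist_p[pi, 1])
    dev2 <- abs(dist_t[, 2] - dist_p[pi, 2])
    dev3 <- abs(dist_t[, 3] - dist_p[pi, 3])
    ok <- which(dev1 <= seed_tol & dev2 <= seed_tol & dev3 <= seed_tol)
    if (length(ok)) {
      seeds[[pi]] <- cbind(ti = ok, pi = pi,
                           dev = dev1[ok] + dev2[ok] + dev3[ok])
    }
  }
  seeds <- do.call(rbind, seeds)
  if (is.null(seeds)) return(empty_alignment())
  seeds <- seeds[order(seeds[, "dev"], seeds[, "ti"], seeds[, "pi"]), ,
                 drop = FALSE]
  if (nrow(seeds) > max_seeds) seeds <- seeds[seq_len(max_seeds), ,
                                              drop = FALSE]

  best <- empty_alignment()
  seen <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(seeds))) {
    ti <- seeds[k, "ti"]; pi <- seeds[k, "pi"]
    seed_fit <- tryCatch(
      kabsch_superpose(Tc[trip_t[ti, ], ], Pc[trip_p[pi, ], ]),
      error = function(e) NULL)
    if (is.null(seed_fit)) next
    key <- paste(round(c(seed_fit$rotation, seed_fit$translation), 1),
                 collapse = ",")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    res <- refine_alignment(Tc, Pc, seed_fit, pair_tol, iter_cap,
                            target$aa, pocket_t$aa, d0, seq_weight)
    if (!is.null(res) && res$score > best$score) {
      best <- res
      best$correspondence$target_residue <-
        target$residue_index[best$pair_idx[, "target"]]
      best$correspondence$pocket_residue <-
        pocket_t$residue_index[best$pair_idx[, "pocket"]]
    }
  }
  best$pair_idx <- NULL
  best
}

refine_alignment <- function(Tc, Pc, fit, pair_tol, iter_cap, aa_t, aa_p,
                             d0, seq_weight) {
  best <- NULL
  prev_key <- ""
  converged <- FALSE
  for (it in seq_len(iter_cap)) {
    tt <- apply_transform(Tc, fit$rotation, fit$translation)
    pairs <- order_pairs(tt, Pc, tol = pair_tol)
    if (nrow(pairs) < 3L) break
    key <- paste(pairs[, 1], pairs[, 2], collapse = ";")
    dists <- sqrt(rowSums((tt[pairs[, 1], , drop = FALSE] -
                             Pc[pairs[, 2], , drop = FALSE])^2))
    score <- alignment_score(dists, aa_t[pairs[, 1]], aa_p[pairs[, 2]],
                             d0, seq_weight)
    cand <- structure(list(
      correspondence = tibble::tibble(
        target_residue = pairs[, 1], pocket_residue = pairs[, 2],
        distance = dists),
      rotation = fit$rotation, translation = fit$translation,
      rmsd = sqrt(mean(dists^2)), score = score,
      n_aligned = nrow(pairs), converged = FALSE,
      pair_idx = pairs
    ), class = "pocket_alignment")
    if (is.null(best) || cand$score > best$score) best <- cand
    if (identical(key, prev_key)) { converged <- TRUE; break }
    prev_key <- key
    fit <- tryCatch(
      kabsch_superpose(Tc[pairs[, 1], , drop = FALSE],
                       Pc[pairs[, 2], , drop = FALSE]),
      error = function(e) NULL)
    if (is.null(fit)) break
  }
  if (!is.null(best)) best$converged <- converged
  best
}

#' Best pocket alignment over target segments and candidate pockets
#'
#' Runs [align_pocket()] for every (segment, pocket) pair and keeps the
#' best-scoring one; ties go to the earlier segment, then the earlier
#' pocket, so the choice is deterministic.
#'
#' @param target_segments List of C-alpha structure tibbles.
#' @param pockets List of pocket models.
#' @param ... Passed to [align_pocket()].
#' @return List: `segment` (index), `pocket` (index), `alignment`.
#' @export
best_segment_pocket <- function(target_segments, pockets, ...) {
  stopifnot(length(target_segments) >= 1L, length(pockets) >= 1L)
  best <- NULL
  for (si in seq_along(target_segments)) {
    for (pi in seq_along(pockets)) {
      al <- align_pocket(target_segments[[si]], pockets[[pi]], ...)
      if (is.null(best) || al$score > best$alignment$score) {
        best <- list(segment = si, pocket = pi, alignment = al)
      }
    }
  }
  best
}

#' Read a protein structure (and optionally its ligand) from a PDB file
#'
#' First MODEL only; for duplicated atom positions the highest-occupancy
#' alternate location is kept; waters are excluded. HETATM records of the
#' named residue define the ligand heavy atoms (hydrogens dropped).
#'
#' @param path PDB file path.
#' @param ligand Optional HET residue name (e.g. `"LIG"`).
#' @return List: `structure` (full-atom tibble), `ligand` (coordinate
#'   matrix or NULL).
#' @export
read_structure_pdb <- function(path, ligand = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("reading PDB files requires the bio3d package", call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- tibble::as_tibble(pdb$atom)
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), ]
  # highest-occupancy altLoc per (chain, resno, atom name)
  at$o[is.na(at$o)] <- 1
  at <- at[order(at$chain, at$resno, at$elety, -at$o), ]
  at <- at[!duplicated(at[, c("chain", "resno", "elety")]), ]
  prot <- at[at$type == "ATOM", ]
  prot <- prot[!grepl("^H", prot$elety), ]
  structure_tbl <- tibble::tibble(
    residue_index = prot$resno,
    aa = unname(AA_3TO1[prot$resid]),
    atom = prot$elety,
    x = prot$x, y = prot$y, z = prot$z
  )
  structure_tbl$aa[is.na(structure_tbl$aa)] <- "X"
  structure_tbl <- structure_tbl[order(structure_tbl$residue_index), ]
  lig_m <- NULL
  if (!is.null(ligand)) {
    het <- at[at$type == "HETATM" & at$resid == ligand, ]
    het <- het[!grepl("^H", het$elety), ]
    if (nrow(het) == 0L) stop("no HETATM records for ligand '", ligand, "'",
                              call. = FALSE)
    lig_m <- cbind(het$x, het$y, het$z)
  }
  list(structure = structure_tbl, ligand = lig_m)
}

#' Write an alignment correspondence table
#'
#' TSV with the aligned residue indices and post-superposition distances.
#'
#' @param alignment `pocket_alignment` object.
#' @param path File path.
#' @export
write_alignment <- function(alignment, path) {
  readr::write_tsv(alignment$correspondence, path, progress = FALSE)
  invisible(path)
}

#' @export
print.pocket_alignment <- function(x, ...) {
  cat("Pocket alignment: ", x$n_aligned, " residues aligned, RMSD ",
      if (is.na(x$rmsd)) "NA" else sprintf("%.3f A", x$rmsd),
      ", score ", sprintf("%.3f", x$score),
      if (!x$converged) " (iteration cap hit)", "\n", sep = "")
  invisible(x)
}
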