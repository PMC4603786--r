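# Shared fixture builders: everything is generated in code at test time.

# fingerprint with the given 1-based bit positions set
fp_bits <- function(...) {
  bits <- integer(1024)
  bits[c(...)] <- 1L
  bits
}

random_bits <- function(n_on = 100) {
  bits <- integer(1024)
  bits[sample.int(1024, n_on)] <- 1L
  bits
}

# brute-force Tanimoto oracle: explicit bit loop
tanimoto_oracle <- function(a, b) {
  inter <- 0L; un <- 0L
  for (i in seq_along(a)) {
    ai <- a[i] != 0; bi <- b[i] != 0
    if (ai && bi) inter <- inter + 1L
    if (ai || bi) un <- un + 1L
  }
  if (un == 0L) 0 else inter / un
}

# brute-force pairwise AUC oracle
auc_oracle <- function(scores, positive) {
  pos <- which(positive); neg <- which(!positive)
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (scores[p] > scores[n]) + 0.5 * (scores[p] == scores[n])
  }
  tot / (length(pos) * length(neg))
}

# a fingerprint table tibble from named fingerprints
fp_table <- function(fps) {
  tibble::tibble(compound_id = names(fps), fingerprint = unname(fps))
}

# one-target template-ligand tibble
tl_row <- function(target_id, compound_id, channel = "PDB_HOLO",
                   is_true_ligand = FALSE, source_protein_id = "src") {
  tibble::tibble(target_id = target_id, compound_id = compound_id,
                 channel = channel, is_true_ligand = is_true_ligand,
                 source_protein_id = source_protein_id)
}

# random CA chain with realistic ~3.8 A spacing
make_ca_chain <- function(n, seed = NULL, start_index = 1L) {
  if (!is.null(seed)) set.seed(seed)
  steps <- matrix(stats::rnorm(n * 3), ncol = 3)
  steps <- steps / sqrt(rowSums(steps^2)) * 3.8
  ca <- apply(steps, 2, cumsum)
  tibble::tibble(
    residue_index = seq.int(start_index, length.out = n),
    aa = sample(c("A", "L", "K", "D", "F", "G", "S"), n, replace = TRUE),
    atom = "CA",
    x = ca[, 1], y = ca[, 2], z = ca[, 3]
  )
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

transform_structure <- function(structure, rotation, translation) {
  m <- cbind(structure$x, structure$y, structure$z) %*% rotation +
    matrix(translation, nrow(structure), 3, byrow = TRUE)
  out <- structure
  out$x <- m[, 1]; out$y <- m[, 2]; out$z <- m[, 3]
  out
}

# mutate an amino-acid sequence to an exact number of substitutions
mutate_n <- function(seq_chr, n_mut) {
  chars <- strsplit(seq_chr, "")[[1]]
  pos <- sample(seq_along(chars), n_mut)
  alpha <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
             "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  for (i in pos) chars[i] <- sample(setdiff(alpha, chars[i]), 1)
  paste(chars, collapse = "")
}

random_aa_seq <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               n, replace = TRUE), collapse = "")
}

random_rotation_small <- function(eps) {
  v <- stats::rnorm(3); v <- v / sqrt(sum(v^2)) * eps
  th <- sqrt(sum(v^2)); u <- v / th
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}
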