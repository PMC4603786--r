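#' Molecular fingerprints and Tanimoto similarity
#'
#' Compounds are represented by fixed-length 1024-bit binary fingerprints.
#' The default scheme is the hashed linear-fragment (path-based, Daylight-style)
#' FP2 fingerprint computed by Open Babel; SMILES are canonicalized first so
#' textual variants of the same molecule map to identical bit vectors.
#' All downstream scores depend only on the bit-vector contract, not on the
#' particular hashing scheme.
#'
#' @name fingerprints
NULL

#' Number of bits in a fingerprint
#' @keywords internal
FP_NBITS <- 1024L

#' Compute a 1024-bit fingerprint from a SMILES string
#'
#' Canonicalizes the SMILES via Open Babel, then hashes linear fragments into
#' a 1024-bit vector (FP2). Deterministic: the same molecule, however written,
#' yields the same bits.
#'
#' @param smiles A single SMILES string.
#' @param id Optional identifier used in error messages.
#' @return An integer vector of 0/1 of length 1024 with attribute
#'   `scheme = "openbabel/FP2"`.
#' @examples
#' \dontrun{
#' fp <- compute_fingerprint("CCO")
#' sum(fp)
#' }
#' @export
compute_fingerprint <- function(smiles, id = NULL) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  who <- if (is.null(id)) sprintf("SMILES '%s'", smiles) else
    sprintf("record '%s' (SMILES '%s')", id, smiles)
  can <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "CAN", source = smiles)
  )
  can <- sub("[\t\n ].*$", "", can)
  if (!nzchar(can)) {
    stop("unparsable ", who, call. = FALSE)
  }
  mol <- ChemmineOB::forEachMol("SMILES", can, identity)
  bits <- as.integer(ChemmineOB::fingerprint_OB(mol, "FP2") > 0)
  if (length(bits) != FP_NBITS) {
    stop("fingerprint backend returned ", length(bits), " bits for ", who,
         call. = FALSE)
  }
  structure(bits, scheme = "openbabel/FP2")
}

#' Tanimoto coefficient of two binary fingerprints
#'
#' \eqn{TC(a, b) = |a \wedge b| / |a \vee b|}. Symmetric and bounded in
#' \[0, 1\]. Two all-zero fingerprints have TC 0 by convention so that
#' featureless molecules never break a ranking.
#'
#' @param a,b Integer/logical 0-1 vectors of equal length (1024 bits).
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    stop("fingerprint length mismatch: ", length(a), " vs ", length(b),
         call. = FALSE)
  }
  a <- as.logical(a); b <- as.logical(b)
  un <- sum(a | b)
  if (un == 0L) return(0)
  sum(a & b) / un
}

#' Tanimoto similarity of one query fingerprint against many
#'
#' Vectorized over the rows of a fingerprint matrix; used internally by the
#' screening engine.
#'
#' @param query Single 0/1 fingerprint vector.
#' @param fpmat Matrix with one fingerprint per row (0/1).
#' @return Numeric vector of similarities, one per row.
#' @export
tanimoto_many <- function(query, fpmat) {
  stopifnot(is.matrix(fpmat), ncol(fpmat) == length(query))
  q <- as.numeric(query != 0)
  m <- (fpmat != 0) * 1
  inter <- as.numeric(m %*% q)
  un <- rowSums(m) + sum(q) - inter
  out <- ifelse(un == 0, 0, inter / un)
  as.numeric(out)
}

#' Build a fingerprint table from compound records
#'
#' Takes a data frame with at least `compound_id` and `smiles` columns and
#' returns it with a `fingerprint` list-column added. Rows whose SMILES do not
#' parse raise an error naming the offending record.
#'
#' @param compounds Data frame with `compound_id` and `smiles`.
#' @return A tibble with a `fingerprint` list-column of 0/1 integer vectors.
#' @export
fingerprint_compounds <- function(compounds) {
  stopifnot(all(c("compound_id", "smiles") %in% names(compounds)))
  compounds <- tibble::as_tibble(compounds)
  compounds$fingerprint <- purrr::map2(
    compounds$smiles, compounds$compound_id,
    function(s, id) compute_fingerprint(s, id = id)
  )
  compounds
}

fp_to_string <- function(fp) paste(as.integer(fp != 0), collapse = "")

fp_from_string <- function(s) {
  bits <- as.integer(strsplit(s, "", fixed = TRUE)[[1]])
  if (length(bits) != FP_NBITS || anyNA(bits) || any(bits > 1L)) {
    stop("malformed fingerprint bit string (need ", FP_NBITS, " chars of 0/1)",
         call. = FALSE)
  }
  bits
}

#' Read and write fingerprint tables
#'
#' The on-disk format is TSV with columns `compound_id` and `bits`
#' (a 1024-character 0/1 string); extra columns (e.g. `smiles`, `name`) are
#' carried through.
#'
#' @param compounds Tibble with `compound_id` and `fingerprint` list-column.
#' @param path File path.
#' @return `read_fingerprints()` returns a tibble with a `fingerprint`
#'   list-column; `write_fingerprints()` returns `path` invisibly.
#' @export
write_fingerprints <- function(compounds, path) {
  stopifnot(all(c("compound_id", "fingerprint") %in% names(compounds)))
  out <- compounds
  out$bits <- purrr::map_chr(out$fingerprint, fp_to_string)
  out$fingerprint <- NULL
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("compound_id", "bits") %in% names(tab)))
  tab$fingerprint <- purrr::map(tab$bits, fp_from_string)
  tab$bits <- NULL
  tibble::as_tibble(tab)
}

#' Read a SMILES file
#'
#' One record per line: SMILES, whitespace, identifier (identifier optional;
#' missing identifiers become `cmpd_<line>`). Returns a tibble ready for
#' [fingerprint_compounds()].
#'
#' @param path Path to a SMILES file.
#' @return Tibble with `compound_id` and `smiles`.
#' @export
read_smiles <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  tibble::tibble(
    compound_id = purrr::imap_chr(parts, function(p, i) {
      if (length(p) >= 2) p[[2]] else sprintf("cmpd_%d", i)
    }),
    smiles = purrr::map_chr(parts, 1L)
  )
}

#' Convert between fingerprint list-columns and matrices
#'
#' @param fingerprints List of 0/1 vectors (e.g. a `fingerprint` list-column).
#' @param ids Optional rownames.
#' @return 0/1 integer matrix, one fingerprint per row.
#' @keywords internal
fp_matrix <- function(fingerprints, ids = NULL) {
  m <- do.call(rbind, lapply(fingerprints, function(f) as.integer(f != 0)))
  if (!is.null(ids)) rownames(m) <- ids
  m
}
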