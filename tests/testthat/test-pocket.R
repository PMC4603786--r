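# Pocket extraction, Kabsch superposition, triplet alignment

# full-atom synthetic residue: CA at `ca`, optional side-chain atom at `sc`
residue_atoms <- function(index, ca, sc = NULL, aa = "A") {
  rows <- tibble::tibble(residue_index = index, aa = aa, atom = "CA",
                         x = ca[1], y = ca[2], z = ca[3])
  if (!is.null(sc)) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      residue_index = index, aa = aa, atom = "CB",
      x = sc[1], y = sc[2], z = sc[3]))
  }
  rows
}

test_that("pocket extraction applies both distance rules at their boundaries", {
  lig <- matrix(c(0, 0, 0), 1, 3)
  struct <- dplyr::bind_rows(
    # side-chain atom at 4.4 A, CA at 9 A: in via the heavy-atom rule
    residue_atoms(1, ca = c(9, 0, 0), sc = c(4.4, 0, 0)),
    # CA at 7.9 A, nothing within 4.5: in via the CA rule
    residue_atoms(2, ca = c(0, 7.9, 0), sc = c(0, 6.0, 0)),
    # CA at 8.1 A, nothing within 4.5: out
    residue_atoms(3, ca = c(0, 8.1, 0), sc = c(0, 6.0, 0)),
    # far away entirely
    residue_atoms(4, ca = c(25, 0, 0), sc = c(24, 0, 0))
  )
  pocket <- extract_pocket(struct, lig)
  expect_equal(pocket$residue_index, c(1, 2))
  expect_true(all(pocket$atom == "CA"))

  # ligand > 20 A from everything: empty pocket
  far <- extract_pocket(struct, matrix(c(100, 100, 100), 1, 3))
  expect_equal(nrow(far), 0)

  expect_error(extract_pocket(struct, matrix(numeric(0), 0, 3)), "no atoms")
})

test_that("kabsch recovers rigid transforms and rejects degenerate input", {
  set.seed(4)
  pts <- matrix(rnorm(30), 10, 3)
  same <- kabsch_superpose(pts, pts)
  expect_equal(same$rmsd, 0, tolerance = 1e-12)
  expect_equal(same$rotation, diag(3), tolerance = 1e-9)

  theta <- 37 * pi / 180
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  moved <- pts %*% R + matrix(c(3, -2, 7), 10, 3, byrow = TRUE)
  fit <- kabsch_superpose(pts, moved)
  expect_lt(fit$rmsd, 1e-9)
  # proper rotation, never a reflection
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  expect_error(kabsch_superpose(pts[1:2, ], pts[1:2, ]), ">= 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("kabsch RMSD is minimal against a randomized rigid-transform oracle", {
  set.seed(12)
  a <- matrix(rnorm(24), 8, 3)
  b <- a + matrix(rnorm(24, sd = 0.3), 8, 3)    # perturbed copy
  fit <- kabsch_superpose(a, b)
  rmsd_of <- function(R, t) {
    moved <- a %*% R + matrix(t, nrow(a), 3, byrow = TRUE)
    sqrt(mean(rowSums((moved - b)^2)))
  }
  for (i in 1:300) {
    expect_gte(rmsd_of(random_rotation(), rnorm(3, sd = 2)) + 1e-12,
               fit$rmsd)
  }
  # local perturbations of the optimum do not improve it
  for (i in 1:100) {
    eps <- rnorm(3, sd = 1e-3)
    Rp <- fit$rotation %*% random_rotation_small(1e-3)
    expect_gte(rmsd_of(Rp, fit$translation + eps) + 1e-12, fit$rmsd)
  }
})

test_that("self-alignment of a pocket is the identity correspondence", {
  chain <- make_ca_chain(30, seed = 10)
  pocket <- chain[8:16, ]
  al <- align_pocket(pocket, pocket)
  expect_equal(al$n_aligned, 9L)
  expect_equal(al$correspondence$target_residue,
               al$correspondence$pocket_residue)
  expect_equal(al$rmsd, 0, tolerance = 1e-9)
})

test_that("alignment recovers a rigidly transformed planted pocket exactly", {
  set.seed(23)
  chain <- make_ca_chain(45, seed = 23)
  pocket <- chain[15:24, ]
  rot <- random_rotation(); tr <- rnorm(3, sd = 10)
  target <- transform_structure(chain, rot, tr)
  al <- align_pocket(target, pocket)
  expect_identical(al$correspondence$target_residue, 15:24)
  expect_identical(al$correspondence$pocket_residue, 15:24)
  expect_lt(al$rmsd, 1e-6)
  # stored RMSD is reproducible from the stored transform
  tt <- drugcast:::apply_transform(
    drugcast:::coords_matrix(ca_trace(target)), al$rotation, al$translation)
  pp <- drugcast:::coords_matrix(pocket)
  ti <- match(al$correspondence$target_residue, target$residue_index)
  pi <- match(al$correspondence$pocket_residue, pocket$residue_index)
  rmsd2 <- sqrt(mean(rowSums((tt[ti, ] - pp[pi, ])^2)))
  expect_equal(rmsd2, al$rmsd, tolerance = 1e-6)
})

test_that("alignment score and RMSD are invariant under rigid transforms", {
  set.seed(31)
  chain <- make_ca_chain(35, seed = 31)
  pocket <- chain[5:12, ]
  base <- align_pocket(chain, pocket)
  for (i in 1:5) {
    moved <- transform_structure(chain, random_rotation(), rnorm(3, sd = 8))
    al <- align_pocket(moved, pocket)
    expect_equal(al$score, base$score, tolerance = 1e-6)
    expect_equal(al$rmsd, base$rmsd, tolerance = 1e-6)
    expect_equal(al$n_aligned, base$n_aligned)
  }
})

test_that("no admissible seed yields an empty alignment with score 0", {
  chain <- make_ca_chain(10, seed = 2)
  # scale the pocket so no triplet distances can match within 1 A
  pocket <- chain[1:5, ]
  pocket$x <- pocket$x * 5; pocket$y <- pocket$y * 5
  pocket$z <- pocket$z * 5
  al <- align_pocket(chain, pocket)
  expect_equal(al$n_aligned, 0L)
  expect_equal(al$score, 0)
})

test_that("best_segment_pocket picks the planted pair deterministically", {
  set.seed(44)
  seg_a <- make_ca_chain(25, seed = 101)
  chainb <- make_ca_chain(25, seed = 102)
  pocket <- chainb[5:13, ]
  seg_b <- transform_structure(chainb, random_rotation(), rnorm(3, sd = 5))
  best <- best_segment_pocket(list(seg_a, seg_b),
                              list(make_ca_chain(8, seed = 103), pocket))
  expect_equal(best$segment, 2L)
  expect_equal(best$pocket, 2L)
  expect_lt(best$alignment$rmsd, 1e-6)
  # identical segments: first wins by tie-break
  tie <- best_segment_pocket(list(seg_b, seg_b), list(pocket))
  expect_equal(tie$segment, 1L)
})

test_that("PDB reading feeds pocket extraction", {
  skip_if_not_installed("bio3d")
  # two residues + one ligand heteroatom, written as PDB text
  pdb_lines <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       1.500   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2      20.000   0.000   0.000  1.00  0.00           C",
    "HETATM    4  C1  LIG A  90       3.000   0.000   0.000  1.00  0.00           C",
    "HETATM    5  O   HOH A  91       3.000   1.000   0.000  1.00  0.00           O",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb_lines, path)
  parsed <- read_structure_pdb(path, ligand = "LIG")
  expect_equal(nrow(parsed$ligand), 1)
  expect_setequal(unique(parsed$structure$residue_index), c(1L, 2L))
  expect_false("HOH" %in% parsed$structure$aa)
  pocket <- extract_pocket(parsed$structure, parsed$ligand)
  expect_identical(pocket$residue_index, 1L)
  expect_identical(pocket$aa, "A")
})
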