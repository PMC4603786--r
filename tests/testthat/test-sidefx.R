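# Side-effect inference, benchmarks and the killing index

three_drug_world <- function() {
  list(
    interactions = tibble::tibble(
      drug_id = c("D1", "D2", "D3", "D1"),
      target_id = c("T1", "T1", "T1", "T2")
    ),
    drug_se = tibble::tibble(
      drug_id = c(rep("D1", 3), rep("D2", 2), rep("D3", 2)),
      term = c("a", "b", "c", "b", "c", "b", "d")
    )
  )
}

test_that("target side effects are the intersection over annotated binders", {
  w <- three_drug_world()
  tse <- infer_target_side_effects(w$interactions, w$drug_se)
  # T1: {a,b,c} & {b,c} & {b,d} = {b}
  expect_identical(tse$term[tse$target_id == "T1"], "b")
  expect_identical(unique(tse$supporting_drug_count[tse$target_id == "T1"]),
                   3L)
  # T2 bound by a single drug: omitted
  expect_false("T2" %in% tse$target_id)

  # empty intersection omitted
  tse2 <- infer_target_side_effects(
    tibble::tibble(drug_id = c("D1", "D2"), target_id = "T1"),
    tibble::tibble(drug_id = c("D1", "D2"), term = c("a", "b")))
  expect_equal(nrow(tse2), 0)
})

test_that("drugs without side-effect records are ignored, not empty sets", {
  inter <- tibble::tibble(drug_id = c("D1", "D2", "D9"), target_id = "T1")
  se <- tibble::tibble(drug_id = c("D1", "D1", "D2"),
                       term = c("a", "b", "a"))
  tse <- infer_target_side_effects(inter, se)
  # D9 has no record; intersection over D1, D2 only
  expect_identical(tse$term, "a")
  expect_identical(unique(tse$supporting_drug_count), 2L)
})

test_that("terms are compared case-insensitively after trimming", {
  inter <- tibble::tibble(drug_id = c("D1", "D2"), target_id = "T1")
  se <- tibble::tibble(drug_id = c("D1", "D2"),
                       term = c("  Heart   Failure ", "heart failure"))
  tse <- infer_target_side_effects(inter, se)
  expect_identical(tse$term, "heart failure")
})

test_that("drug prediction is the union over its targets", {
  tse <- infer_target_side_effects(
    tibble::tibble(drug_id = c("D1", "D2", "D1", "D3"),
                   target_id = c("T1", "T1", "T2", "T2")),
    tibble::tibble(drug_id = c("D1", "D1", "D2", "D2", "D3", "D3"),
                   term = c("a", "b", "a", "b", "b", "c")))
  # T1 = {a,b}, T2 = {b}
  pred <- predict_drug_side_effects(
    tibble::tibble(drug_id = "D1", target_id = c("T1", "T2")), tse,
    drug_ids = "D1")
  expect_setequal(pred$term, c("a", "b"))
  # drug with no targets -> empty
  none <- predict_drug_side_effects(
    tibble::tibble(drug_id = "D1", target_id = "T1"), tse, drug_ids = "DX")
  expect_equal(nrow(none), 0)
})

test_that("adding a binder can only shrink a target's inferred set", {
  set.seed(14)
  for (i in 1:20) {
    drugs <- sprintf("D%d", 1:4)
    se <- tibble::tibble(
      drug_id = rep(drugs, each = 5),
      term = as.character(sapply(drugs, function(d) sample(letters[1:8], 5)))
    )
    inter3 <- tibble::tibble(drug_id = drugs[1:3], target_id = "T")
    inter4 <- tibble::tibble(drug_id = drugs, target_id = "T")
    t3 <- infer_target_side_effects(inter3, se)
    t4 <- infer_target_side_effects(inter4, se)
    expect_true(all(t4$term %in% t3$term))
  }
})

test_that("consistency test predicts subsets of the known sets (no false positives)", {
  w <- three_drug_world()
  ct <- consistency_test(w$interactions, w$drug_se)
  per <- tidy(ct)
  expect_true(all(per$tp == per$n_predicted))
  expect_true(all(per$precision[per$n_predicted > 0] == 1))
  # D3's private term d is shared by no co-binder: unrecalled
  expect_lt(per$recall[per$drug_id == "D3"], 1)
  # D1, D2, D3 each recover only "b" of their sets
  expect_equal(per$tp, c(1L, 1L, 1L))

  # two drugs with identical sets on one target: recall 1 for both
  ct2 <- consistency_test(
    tibble::tibble(drug_id = c("A", "B"), target_id = "T"),
    tibble::tibble(drug_id = rep(c("A", "B"), each = 2),
                   term = c("x", "y", "x", "y")))
  expect_true(all(tidy(ct2)$recall == 1))
  expect_equal(glance(ct2)$precision, 1)
})

test_that("jackknife matches a brute-force leave-one-out recomputation", {
  w <- make_world(synth_params(n_targets = 12, n_drugs = 10), seed = 77)
  jt <- jackknife_test(w$interactions, w$drug_se)
  per <- tidy(jt)
  for (d in per$drug_id) {
    reduced_se <- w$drug_se[w$drug_se$drug_id != d, ]
    tse <- tryCatch(infer_target_side_effects(w$interactions, reduced_se),
                    error = function(e) NULL)
    pred <- if (is.null(tse)) character() else {
      p <- predict_drug_side_effects(w$interactions, tse, drug_ids = d)
      p$term
    }
    known <- w$drug_se$term[w$drug_se$drug_id == d]
    oracle <- precision_recall(pred, known)
    row <- per[per$drug_id == d, ]
    expect_equal(row$n_predicted, oracle$n_predicted)
    expect_equal(row$precision, oracle$precision)
    expect_equal(row$recall, oracle$recall)
  }
})

test_that("jackknife handles support collapse and perfect sharing", {
  # every target of D loses its second binder on removal: no prediction
  jt <- jackknife_test(
    tibble::tibble(drug_id = c("A", "B"), target_id = "T"),
    tibble::tibble(drug_id = c("A", "B"), term = c("x", "x")))
  expect_true(all(tidy(jt)$n_predicted == 0))
  # three drugs with identical sets: leave-one-out recovers everything
  jt3 <- jackknife_test(
    tibble::tibble(drug_id = c("A", "B", "C"), target_id = "T"),
    tibble::tibble(drug_id = rep(c("A", "B", "C"), each = 2),
                   term = c("a", "b", "a", "b", "a", "b")))
  expect_true(all(tidy(jt3)$precision == 1))
  expect_true(all(tidy(jt3)$recall == 1))
})

test_that("killing index counts targets, not serious terms", {
  tse <- tibble::tibble(
    target_id = c("T1", "T2", "T2", "T3", "T3"),
    term = c("nausea", "death", "rash", "heart failure", "cancer"),
    supporting_drug_count = 2L
  )
  inter <- tibble::tibble(drug_id = "D", target_id = c("T1", "T2", "T3"))
  ki <- killing_index(inter, tse)
  expect_equal(ki$kappa, 2L)           # T2 and T3; T3 counts once
  expect_lte(ki$kappa, ki$n_targets)
  # drug with no targets
  ki0 <- killing_index(inter, tse, drug_ids = "D_none")
  expect_equal(ki0$kappa, 0L)
})

test_that("kappa equals a brute-force recount on a synthetic world", {
  w <- make_world(synth_params(n_targets = 15, n_drugs = 12), seed = 5)
  tse <- infer_target_side_effects(w$interactions, w$drug_se)
  ki <- killing_index(w$interactions, tse)
  serious <- serious_side_effects()
  tse_sets <- split(tse$term, tse$target_id)
  for (i in seq_len(nrow(ki))) {
    d <- ki$drug_id[i]
    tgts <- unique(w$interactions$target_id[w$interactions$drug_id == d])
    brute <- sum(vapply(tgts, function(t)
      any(tse_sets[[t]] %in% serious), logical(1)))
    expect_identical(ki$kappa[i], as.integer(brute))
  }
})

test_that("kappa-fraction curve behaves under planted flag regimes", {
  # all drugs flagged: constant 1
  drugs <- tibble::tibble(drug_id = c("A", "B", "C"), flagged = TRUE)
  kap <- tibble::tibble(drug_id = c("A", "B", "C"), kappa = c(0L, 1L, 3L))
  cv <- kappa_fraction_curve(drugs, kap)
  expect_true(all(cv$fraction_flagged == 1))

  # flags planted to increase with kappa: positive correlation
  set.seed(33)
  wmono <- make_world(synth_params(n_drugs = 60, n_targets = 30,
                                   serious_rate = 0.4,
                                   flag_base_rate = 0.05,
                                   flag_kappa_slope = 0.25), seed = 8)
  tse <- infer_target_side_effects(wmono$interactions, wmono$drug_se)
  ki <- killing_index(wmono$interactions, tse)
  cvm <- kappa_fraction_curve(wmono$drugs, ki)
  expect_gt(attr(cvm, "correlation"), 0)

  # flags independent of kappa: every point near the base rate
  wflat <- make_world(synth_params(n_drugs = 150, n_targets = 30,
                                   serious_rate = 0.4,
                                   flag_base_rate = 0.3,
                                   flag_kappa_slope = 0), seed = 9)
  tsef <- infer_target_side_effects(wflat$interactions, wflat$drug_se)
  kif <- killing_index(wflat$interactions, tsef)
  cvf <- kappa_fraction_curve(wflat$drugs, kif)
  rate <- mean(wflat$drugs$flagged)
  tol <- 3 * sqrt(rate * (1 - rate) / pmax(cvf$n_drugs, 1))
  expect_true(all(abs(cvf$fraction_flagged - rate) <= tol + 1e-12))
})
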