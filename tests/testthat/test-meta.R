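test_that("study inclusion rules apply the boundary exactly", {
  st <- tibble::tibble(
    study = c("A", "B", "C", "D"),
    category = c("endurance", "endurance", "mixed", "power"),
    n_athletes = c(19, 20, 500, 45)
  )
  out <- filter_studies(st)
  expect_equal(out$retained, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(out$exclusion_reason[1], "n<20")
  expect_equal(out$exclusion_reason[3], "unclassified")
})

test_that("sainte_lague_allocate matches the quotient-table oracle", {
  expect_equal(sainte_lague_allocate(7, c(5, 3, 1)), c(4, 2, 1))
  expect_equal(sainte_lague_allocate(0, c(5, 3, 1)), c(0, 0, 0))
  expect_equal(sainte_lague_allocate(10, 7), 10)
  expect_error(sainte_lague_allocate(3, c(0, 0)), "all-zero")
  set.seed(91)
  for (i in 1:60) {
    nb <- sample(1:6, 1)
    total <- sample(0:50, 1)
    w <- round(runif(nb, 0, 100), 1)
    if (all(w == 0)) w[1] <- 1
    got <- sainte_lague_allocate(total, w)
    expect_equal(got, oracle_sainte_lague(total, w))
    expect_equal(sum(got), total)
    expect_true(all(got >= 0))
  }
})

test_that("split_controls conserves genotype class totals and allele frequency", {
  controls <- c(c_CC = 40, c_CT = 18, c_TT = 2)
  ath <- c(running = 60, cycling = 30, jumping = 10)
  out <- split_controls(controls, ath)
  expect_equal(sum(out$c_CC), 40)
  expect_equal(sum(out$c_CT), 18)
  expect_equal(sum(out$c_TT), 2)
  # equals independent Sainte-Lague runs per class
  expect_equal(out$c_CC, sainte_lague_allocate(40, ath))
  expect_equal(out$c_CT, sainte_lague_allocate(18, ath))
  expect_equal(out$c_TT, sainte_lague_allocate(2, ath))
  # allele frequency preserved within 1/(2 n_alloc)
  pooled_f <- (18 + 2 * 2) / (2 * 60)
  n_alloc <- out$c_CC + out$c_CT + out$c_TT
  f <- (out$c_CT + 2 * out$c_TT) / (2 * n_alloc)
  expect_true(all(abs(f - pooled_f) <= 1 / (2 * n_alloc) + 1e-12))
  # scale invariance of weights
  expect_equal(split_controls(controls, ath * 7)[, -1], out[, -1])
  # single discipline: unchanged
  single <- split_controls(controls, c(all = 50))
  expect_equal(unlist(single[1, -1], use.names = FALSE), c(40, 18, 2))
  expect_error(split_controls(controls, c(a = 0, b = 0)), "zero athletes")
})

test_that("study_odds_ratio matches the hand 2x2 computation and logistic regression", {
  counts <- tibble::tibble(a_CC = 90, a_CT = 8, a_TT = 2,
                           c_CC = 70, c_CT = 25, c_TT = 5)
  est <- study_odds_ratio(counts, model = "carrier")
  expect_equal(est$OR, (10 * 70) / (90 * 30), tolerance = 1e-12)
  expect_equal(est$std.error, sqrt(1 / 10 + 1 / 90 + 1 / 30 + 1 / 70),
               tolerance = 1e-12)
  # numerically identical to single-covariate logistic regression
  df <- data.frame(
    athlete = rep(c(1, 0), c(100, 100)),
    carrier = c(rep(c(1, 0), c(10, 90)), rep(c(1, 0), c(30, 70)))
  )
  fit <- glm(athlete ~ carrier, family = binomial, data = df)
  expect_equal(est$logOR, unname(coef(fit)["carrier"]), tolerance = 1e-6)
  expect_equal(est$std.error,
               unname(sqrt(diag(vcov(fit)))["carrier"]), tolerance = 1e-6)
  # equal proportions: OR = 1
  eq <- study_odds_ratio(tibble::tibble(a_CC = 80, a_CT = 15, a_TT = 5,
                                        c_CC = 160, c_CT = 30, c_TT = 10))
  expect_equal(eq$logOR, 0, tolerance = 1e-12)
  # zero cell: Haldane-Anscombe correction flagged, finite OR
  z <- study_odds_ratio(tibble::tibble(a_CC = 50, a_CT = 0, a_TT = 0,
                                       c_CC = 45, c_CT = 5, c_TT = 0))
  expect_true(z$zero_cell)
  expect_true(is.finite(z$logOR))
  expect_error(study_odds_ratio(tibble::tibble(a_CC = 0, a_CT = 0, a_TT = 0,
                                               c_CC = 10, c_CT = 5, c_TT = 0)),
               "empty margin")
})

test_that("odds-ratio antisymmetry: swapping athletes and controls inverts OR", {
  set.seed(3)
  for (i in 1:10) {
    n <- sample(50:200, 2)
    counts <- tibble::tibble(
      a_CC = sample(10:100, 1), a_CT = sample(1:40, 1), a_TT = sample(1:10, 1),
      c_CC = sample(10:100, 1), c_CT = sample(1:40, 1), c_TT = sample(1:10, 1))
    swapped <- tibble::tibble(a_CC = counts$c_CC, a_CT = counts$c_CT,
                              a_TT = counts$c_TT, c_CC = counts$a_CC,
                              c_CT = counts$a_CT, c_TT = counts$a_TT)
    expect_equal(study_odds_ratio(swapped)$OR, 1 / study_odds_ratio(counts)$OR,
                 tolerance = 1e-12)
  }
})

test_that("pool_fixed_effect matches the hand computation and metafor", {
  est <- tibble::tibble(logOR = c(-0.5, -0.3), std.error = c(0.2, 0.4))
  res <- pool_fixed_effect(est)
  expect_equal(res$pooled$logOR, -0.46, tolerance = 1e-12)
  expect_equal(res$pooled$std.error, 1 / sqrt(25 + 6.25), tolerance = 1e-12)
  # single study passes through
  one <- pool_fixed_effect(est[1, ])
  expect_equal(one$pooled$logOR, -0.5)
  expect_equal(one$pooled$std.error, 0.2)
  # identical studies: Q = 0
  expect_equal(pool_fixed_effect(tibble::tibble(
    logOR = c(-0.4, -0.4), std.error = c(0.3, 0.3)))$pooled$Q, 0)
  expect_error(pool_fixed_effect(tibble::tibble(logOR = 0, std.error = 0)),
               "non-positive")
  skip_if_not_installed("metafor")
  set.seed(14)
  yi <- rnorm(6, -0.5, 0.3)
  sei <- runif(6, 0.1, 0.5)
  ours <- pool_fixed_effect(tibble::tibble(logOR = yi, std.error = sei))
  mf <- metafor::rma(yi = yi, sei = sei, method = "FE")
  expect_equal(ours$pooled$logOR, as.numeric(mf$beta), tolerance = 1e-10)
  expect_equal(ours$pooled$std.error, mf$se, tolerance = 1e-10)
  expect_equal(ours$pooled$Q, mf$QE, tolerance = 1e-10)
})

test_that("pooled estimate is bounded by the study estimates", {
  set.seed(77)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    est <- tibble::tibble(logOR = rnorm(k, 0, 0.6),
                          std.error = runif(k, 0.05, 0.5))
    res <- pool_fixed_effect(est)
    expect_gte(res$pooled$logOR, min(est$logOR) - 1e-12)
    expect_lte(res$pooled$logOR, max(est$logOR) + 1e-12)
    expect_lte(res$pooled$std.error, min(est$std.error))
  }
})

test_that("run_meta splits pooled controls and pools within category", {
  # single study input equals study_odds_ratio of that study
  st1 <- tibble::tibble(study = "A", discipline = "running",
                        category = "endurance", a_CC = 80, a_CT = 15,
                        a_TT = 5, c_CC = 120, c_CT = 25, c_TT = 5)
  res <- run_meta(st1)
  direct <- study_odds_ratio(st1)
  expect_equal(res$endurance$pooled$logOR, direct$logOR, tolerance = 1e-12)
  expect_equal(res$endurance$pooled$std.error, direct$std.error,
               tolerance = 1e-12)
  # a multi-discipline study's pooled controls are apportioned, not reused
  st2 <- tibble::tibble(
    study = "B", discipline = c("running", "sprint"),
    category = c("endurance", "power"),
    a_CC = c(50, 25), a_CT = c(8, 4), a_TT = c(2, 1),
    c_CC = c(100, 100), c_CT = c(20, 20), c_TT = c(5, 5))
  res2 <- run_meta(st2)
  # each category sees its allocated share of the 125 controls
  ath <- c(running = 60, sprint = 30)
  splt <- split_controls(c(c_CC = 100, c_CT = 20, c_TT = 5), ath)
  exp_run <- study_odds_ratio(tibble::tibble(
    a_CC = 50, a_CT = 8, a_TT = 2,
    c_CC = splt$c_CC[1], c_CT = splt$c_CT[1], c_TT = splt$c_TT[1]))
  expect_equal(res2$endurance$pooled$logOR, exp_run$logOR, tolerance = 1e-12)
  # inconsistent pooled controls raise an error
  st3 <- st2
  st3$c_CC[2] <- 99
  expect_error(run_meta(st3), "inconsistent pooled control")
  # missing column named in the error
  expect_error(run_meta(dplyr::select(st1, -"c_TT")), "c_TT")
  # excluded-category warning
  tiny <- tibble::tibble(study = "T", discipline = "x", category = "power",
                         a_CC = 5, a_CT = 3, a_TT = 1, c_CC = 8, c_CT = 4,
                         c_TT = 1)
  expect_warning(run_meta(tiny), "no retained studies")
})
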