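test_that("linear_velocity recovers exact slopes and validates windows", {
  t_s <- seq(0, 300, by = 20)
  trace <- tibble::tibble(time_s = t_s, A340 = 0.05 + 0.01 * t_s / 60)
  out <- linear_velocity(trace, window = c(0, 5))
  expect_equal(out$slope_per_min, 0.01, tolerance = 1e-12)
  expect_equal(out$intercept, 0.05, tolerance = 1e-12)
  # flat trace
  flat <- tibble::tibble(time_s = t_s, A340 = 0.05)
  expect_equal(linear_velocity(flat, c(0, 5))$slope_per_min, 0)
  expect_error(linear_velocity(trace[1:2, ], c(0, 5)), "fewer than 3")
})

test_that("Beer-Lambert conversion and the specific-activity unit chain are exact", {
  expect_equal(absorbance_to_concentration(0), 0)
  expect_equal(absorbance_to_concentration(0.1), 0.1 / 3856.4,
               tolerance = 1e-12)
  # linearity
  expect_equal(absorbance_to_concentration(0.2),
               2 * absorbance_to_concentration(0.1))
  # hand chain: slope 0.06/min, 215 uL, 0.4 ug -> 8.36 umol/min/mg
  assay <- assay_params()
  expect_equal(specific_activity(0.06, assay),
               0.06 / 3856.4 * 215e-6 * 1e6 / 4e-4, tolerance = 1e-12)
  expect_equal(specific_activity(0.06, assay), 8.36, tolerance = 0.001)
  # halving protein mass doubles activity
  half <- assay_params(protein_mg = 2e-4)
  expect_equal(specific_activity(0.06, half), 2 * specific_activity(0.06, assay))
  expect_equal(specific_activity(0, assay), 0)
  expect_error(assay_params(protein_mg = 0))
  expect_error(absorbance_to_concentration(0.1, epsilon340 = -1), "positive")
})

test_that("si_velocity evaluates the substrate-inhibition curve", {
  expect_equal(si_velocity(0, 20, 0.9, 8.7), 0)
  # published parameter values as inputs: v(1 mM) = 24.96 / 1.72521
  expect_equal(si_velocity(1, 24.96, 0.61, 8.68), 24.96 / (0.61 + 1 * (1 + 1 / 8.68)),
               tolerance = 1e-12)
  expect_equal(si_velocity(1, 24.96, 0.61, 8.68), 14.47, tolerance = 0.001)
  # Michaelis-Menten limit: S = Km, Ki -> Inf gives Vmax/2
  expect_equal(si_velocity(0.9, 20, 0.9, 1e12), 10, tolerance = 1e-6)
  # unique interior maximum at S* = sqrt(Km * Ki)
  s_grid <- seq(0.01, 50, by = 0.01)
  v <- si_velocity(s_grid, 20, 0.9, 8.7)
  expect_equal(s_grid[which.max(v)], sqrt(0.9 * 8.7), tolerance = 0.01)
})

test_that("fit_si recovers noiseless parameters and flags degenerate data", {
  S <- c(0.1, 0.25, 0.5, 1, 2, 3, 5)
  pts <- tibble::tibble(substrate_mM = S, v = si_velocity(S, 20, 0.9, 8.7))
  fit <- fit_si(pts)
  expect_equal(unname(fit$coef), c(20, 0.9, 8.7), tolerance = 1e-6)
  expect_lt(fit$ss, 1e-12)
  # Michaelis-Menten data: Ki runs away, warning emitted
  mm <- tibble::tibble(substrate_mM = S, v = 20 * S / (0.9 + S))
  w <- capture_warnings(fit_si(mm))
  expect_true(any(grepl("Ki", w)))
  expect_true(any(grepl("peak", w)))
  expect_error(fit_si(pts[1:3, ]), "4 distinct")
})

test_that("fit_si confidence intervals bracket estimates and AICc is coherent", {
  set.seed(20)
  S <- rep(c(0.1, 0.25, 0.5, 1, 2, 3, 5), each = 4)
  pts <- tibble::tibble(substrate_mM = S,
                        v = si_velocity(S, 20, 0.9, 8.7) + rnorm(length(S), 0, 0.5))
  fit <- fit_si(pts)
  td <- tidy(fit)
  expect_true(all(td$conf.low < td$estimate & td$estimate < td$conf.high))
  g <- glance(fit)
  expect_equal(g$n, 28)
  expect_equal(g$AICc, 28 * log(g$ss / 28) + 6 + 24 / (28 - 4),
               tolerance = 1e-10)
})

test_that("AICc at equal SS is strictly lower for fewer parameters", {
  for (n in c(20, 28, 56)) {
    for (ss in c(0.5, 5)) {
      a3 <- n * log(ss / n) + 2 * 3 + 2 * 3 * 4 / (n - 3 - 1)
      a6 <- n * log(ss / n) + 2 * 6 + 2 * 6 * 7 / (n - 6 - 1)
      expect_lt(a3, a6)
    }
  }
})

test_that("global_fit degenerates correctly at the sharing extremes", {
  S <- c(0.1, 0.25, 0.5, 1, 2, 3, 5)
  set.seed(4)
  v1 <- si_velocity(S, 20, 0.9, 8.7) + rnorm(7, 0, 0.2)
  v2 <- si_velocity(S, 25, 0.6, 8.7) + rnorm(7, 0, 0.2)
  pts <- tibble::tibble(enzyme = rep(c("e1", "e2"), each = 7),
                        substrate_mM = rep(S, 2), v = c(v1, v2))
  # share none: total SS equals the sum of separate fits
  sep <- global_fit(pts, shared = character(0))
  f1 <- fit_si(pts[pts$enzyme == "e1", ])
  f2 <- fit_si(pts[pts$enzyme == "e2", ])
  expect_equal(sep$ss, f1$ss + f2$ss, tolerance = 1e-6)
  expect_equal(sep$k, 6)
  # share all on identical datasets equals a pooled single fit
  dup <- tibble::tibble(enzyme = rep(c("e1", "e2"), each = 7),
                        substrate_mM = rep(S, 2), v = rep(v1, 2))
  all_sh <- global_fit(dup, shared = c("Vmax", "Km", "Ki"))
  pooled <- fit_si(dplyr::select(dup, "substrate_mM", "v"))
  expect_equal(all_sh$ss, pooled$ss, tolerance = 1e-8)
  expect_equal(all_sh$k, 3)
  q <- all_sh$per_enzyme$estimate[all_sh$per_enzyme$enzyme == "e1"]
  expect_equal(q, unname(pooled$coef), tolerance = 1e-5)
})

test_that("select_sharing ranks patterns sensibly at the extremes", {
  S <- c(0.1, 0.25, 0.5, 1, 2, 3, 5)
  # identical noiseless datasets: full sharing wins on parsimony
  v <- si_velocity(S, 20, 0.9, 8.7)
  same <- tibble::tibble(enzyme = rep(c("e1", "e2"), each = 7),
                         substrate_mM = rep(S, 2), v = rep(v, 2))
  sel <- select_sharing(same)
  expect_equal(sel$table$pattern[1], "Vmax+Km+Ki")
  # entirely different parameters, low noise: no sharing wins
  set.seed(6)
  va <- rep(si_velocity(S, 30, 0.4, 20), each = 4) + rnorm(28, 0, 0.1)
  vb <- rep(si_velocity(S, 10, 2.0, 4), each = 4) + rnorm(28, 0, 0.1)
  diff_pts <- tibble::tibble(enzyme = rep(c("e1", "e2"), each = 28),
                             substrate_mM = rep(rep(S, each = 4), 2),
                             v = c(va, vb))
  sel2 <- select_sharing(diff_pts)
  expect_equal(sel2$table$pattern[1], "none")
})

test_that("compare_enzymes detects separated curves and not identical ones", {
  S <- rep(c(0.1, 0.25, 0.5, 1, 2, 3, 5), each = 2)
  set.seed(8)
  v <- si_velocity(S, 20, 0.9, 8.7) + rnorm(length(S), 0, 0.2)
  same <- tibble::tibble(enzyme = rep(c("e1", "e2"), each = length(S)),
                         substrate_mM = rep(S, 2), v = rep(v, 2))
  res_same <- compare_enzymes(same)
  expect_lt(res_same$F, 1e-6)
  expect_gt(res_same$p, 0.99)
  # p decreases monotonically with Vmax separation
  set.seed(12)
  noise <- rnorm(2 * length(S), 0, 0.3)
  ps <- vapply(c(0, 0.1, 0.25, 0.5), function(d) {
    pts <- tibble::tibble(
      enzyme = rep(c("e1", "e2"), each = length(S)),
      substrate_mM = rep(S, 2),
      v = c(si_velocity(S, 20, 0.9, 8.7), si_velocity(S, 20 * (1 + d), 0.9, 8.7)) + noise)
    compare_enzymes(pts)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("two_sample_ttest matches the textbook pooled formula and conventions", {
  out <- two_sample_ttest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(out$t, -1.2247, tolerance = 1e-4)
  expect_equal(out$df, 4)
  expect_equal(out$p, 0.288, tolerance = 0.001)
  # swapping groups flips t, keeps p
  sw <- two_sample_ttest(c(2, 3, 4), c(1, 2, 3))
  expect_equal(sw$t, -out$t)
  expect_equal(sw$p, out$p)
  # identical groups -> p = 1 by convention
  expect_equal(two_sample_ttest(c(1, 1), c(1, 1))$p, 1)
  expect_warning(res <- two_sample_ttest(c(1, 1), c(2, 2)), "zero variance")
  expect_equal(res$p, 0)
  # welch variant delegates to the standard implementation
  a <- c(1.2, 3.1, 2.2, 5.0); b <- c(2.1, 2.0, 8.5)
  expect_equal(two_sample_ttest(a, b, "welch")$p,
               t.test(a, b)$p.value)
})
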