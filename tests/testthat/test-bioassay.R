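test_that("inhibition rate follows the control-normalized difference", {
  expect_equal(inhibition_rate(0.8, 0.8), 0)
  expect_equal(inhibition_rate(0.8, 0.0), 100)
  expect_equal(inhibition_rate(0.8, 0.6), 25)
  # growth promotion yields a negative rate
  expect_lt(inhibition_rate(0.8, 0.9), 0)
  expect_error(inhibition_rate(0, 0.5), class = "netpharm_undefined_ratio_error")
})

test_that("inhibition rate is invariant to absorbance rescaling", {
  withr::with_seed(1, {
    for (i in 1:20) {
      a0 <- runif(1, 0.2, 1.5)
      a <- runif(1, 0, 1.5)
      cc <- runif(1, 0.1, 10)
      expect_equal(inhibition_rate(a0, a), inhibition_rate(cc * a0, cc * a),
                   tolerance = 1e-12)
    }
  })
})

test_that("noiseless simulated plates invert exactly through the rate formula", {
  sim <- simulate_dose_response(noise_sd = 0, seed = 4)
  tab <- inhibition_table(sim$plate)
  truth <- with(sim$truth, bottom + (top - bottom) /
                  (1 + (tab$dose / ic50)^(-sim$truth$hill)))
  expect_equal(tab$response, truth, tolerance = 1e-12)
})

test_that("4PL fitting recovers a noiseless curve to well under 1%", {
  sim <- simulate_dose_response(
    doses = c(0, 1, 2, 4, 8, 16, 32, 64, 128),
    ic50 = 13.61, hill = 1.5, top = 100, bottom = 0, noise_sd = 0, seed = 1)
  fit <- fit_dose_response(sim$plate)
  expect_true(fit$converged)
  expect_lt(abs(fit$ic50 - 13.61) / 13.61, 0.01)
  expect_equal(fit$hill, 1.5, tolerance = 1e-3)
  expect_lte(fit$bottom, fit$top)
  expect_gt(fit$ic50, 0)
})

test_that("fitting inhibition or viability data gives the same IC50", {
  sim <- simulate_dose_response(noise_sd = 2, seed = 8)
  tab <- inhibition_table(sim$plate)
  fit_inh <- fit_dose_response(tab)
  viab <- dplyr::mutate(tab, response = 100 - response)
  fit_via <- fit_dose_response(viab)
  expect_true(fit_inh$converged && fit_via$converged)
  expect_equal(fit_inh$ic50, fit_via$ic50, tolerance = 1e-6)
})

test_that("flat responses are flagged non-identifiable", {
  flat <- data.frame(dose = rep(c(1, 2, 4, 8), each = 3), response = 50)
  fit <- fit_dose_response(flat)
  expect_false(fit$converged)
  expect_error(predict(fit), class = "netpharm_validation_error")
  expect_error(
    fit_dose_response(data.frame(dose = c(1, 1), response = c(10, 20))),
    class = "netpharm_validation_error")
})

test_that("ddCt fold changes follow the closed form", {
  ct <- data.frame(
    gene = rep(c("Bad", "GAPDH"), each = 4),
    group = rep(c("control", "treated"), times = 4),
    replicate = 1,
    ct = c(25, 25, 25, 25, 16, 16, 16, 16))
  expect_equal(fold_change_ddct(ct, "Bad", "treated"), 1.0)
  ct$ct[c(2, 4)] <- 26  # treated gene Ct one cycle later: ddCt = +1
  expect_equal(fold_change_ddct(ct, "Bad", "treated"), 0.5)
  expect_error(fold_change_ddct(ct, "Bax", "treated"),
               class = "netpharm_validation_error")
  expect_error(fold_change_ddct(ct, "Bad", "treated", control_group = "mock"),
               class = "netpharm_validation_error")
})

test_that("ddCt is invariant to a plate-wide Ct shift", {
  sim <- simulate_ct_table(fold_changes = c(Bad = 2.5, `Bcl-xL` = 0.35),
                           noise_sd = 0.2, seed = 6)
  f1 <- fold_change_ddct(sim$ct, "Bad", "treated")
  shifted <- dplyr::mutate(sim$ct, ct = ct + 3)
  expect_equal(fold_change_ddct(shifted, "Bad", "treated"), f1,
               tolerance = 1e-12)
})

test_that("planted fold changes invert exactly at zero noise", {
  folds <- c(Bad = 2.0, Bax = 1.8, `Bcl-2` = 0.6, `Bcl-xL` = 0.35)
  sim <- simulate_ct_table(fold_changes = folds, noise_sd = 0, seed = 2)
  tab <- fold_change_table(sim$ct)
  expect_equal(setNames(tab$fold_change, tab$gene)[names(folds)], folds,
               tolerance = 1e-12)
  one <- simulate_ct_table(fold_changes = c(Bad = 1.0), noise_sd = 0, seed = 3)
  expect_equal(fold_change_ddct(one$ct, "Bad", "treated"), 1.0, tolerance = 1e-12)
})

test_that("noisy Ct tables recover planted log2 fold changes on average", {
  errs <- vapply(1:50, function(s) {
    sim <- simulate_ct_table(fold_changes = c(Bad = 2.0), noise_sd = 0.1, seed = s)
    log2(fold_change_ddct(sim$ct, "Bad", "treated")) - 1
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.1)
})

test_that("quadrant gating counts thresholds as negative and sums to one", {
  ev <- data.frame(channel1 = c(10, 200, 10, 200),
                   channel2 = c(10, 10, 200, 200))
  qs <- classify_quadrants(ev, thresholds = c(100, 100))
  expect_equal(setNames(qs$fraction, qs$quadrant),
               c(Q1 = 0.25, Q2 = 0.25, Q3 = 0.25, Q4 = 0.25))
  # exactly at threshold counts negative
  at <- classify_quadrants(data.frame(channel1 = 100, channel2 = 100),
                           thresholds = c(100, 100))
  expect_equal(at$fraction[at$quadrant == "Q3"], 1)
  low <- classify_quadrants(data.frame(channel1 = c(1, 2), channel2 = c(3, 4)))
  expect_equal(low$fraction[low$quadrant == "Q3"], 1)
  expect_equal(sum(qs$fraction), 1, tolerance = 1e-12)
  expect_error(classify_quadrants(ev[0, ]),
               class = "netpharm_undefined_ratio_error")
})

test_that("quadrant fractions sum to one on random event sets", {
  for (s in 1:20) {
    sim <- simulate_flow_events(n_events = 500, seed = s)
    qs <- classify_quadrants(sim$events)
    expect_equal(sum(qs$fraction), 1, tolerance = 1e-12)
    expect_true(all(qs$fraction >= 0 & qs$fraction <= 1))
  }
})

test_that("apoptotic fraction pools the annexin-positive quadrants", {
  ev <- data.frame(channel1 = c(10, 200, 10, 200),
                   channel2 = c(10, 10, 200, 200))
  qs <- classify_quadrants(ev)
  expect_equal(apoptotic_fraction(qs, "early"), 0.25)
  expect_equal(apoptotic_fraction(qs, "total"), 0.5)
  viable <- classify_quadrants(data.frame(channel1 = c(1, 1), channel2 = c(1, 1)))
  expect_equal(apoptotic_fraction(viable, "total"), 0)
})

test_that("JC-1 depolarized fraction respects the ratio gate", {
  # aggregate >> monomer: polarized
  pol <- data.frame(channel1 = rep(10, 5), channel2 = rep(1000, 5))
  expect_equal(as.numeric(jc1_depolarized_fraction(pol)), 0)
  # purely monomeric signal
  mono <- data.frame(channel1 = rep(1000, 5), channel2 = rep(1, 5))
  expect_equal(as.numeric(jc1_depolarized_fraction(mono)), 1)
  # zero-monomer events are excluded with a logged count
  mix <- data.frame(channel1 = c(0, 1000), channel2 = c(5, 1))
  expect_message(f <- jc1_depolarized_fraction(mix), "zero monomer")
  expect_equal(attr(f, "n_excluded"), 1)
  expect_equal(attr(f, "n_used"), 1)
  all_zero <- data.frame(channel1 = 0, channel2 = 5)
  expect_error(suppressMessages(jc1_depolarized_fraction(all_zero)),
               class = "netpharm_undefined_ratio_error")
})

test_that("dose trend test detects a clean monotone trend", {
  dat <- data.frame(dose = rep(c(1, 2, 4, 8), each = 3),
                    response = rep(c(40, 30, 20, 10), each = 3) + rep(c(-1, 0, 1), 4))
  res <- dose_trend_test(dat, n_perm = 10000, seed = 1)
  expect_lt(res$p_value, 0.05)
  expect_lt(res$statistic, 0)
  const <- data.frame(dose = rep(c(1, 2, 4), each = 2), response = 5)
  expect_equal(dose_trend_test(const, n_perm = 100, seed = 1)$statistic, 0)
  expect_error(dose_trend_test(data.frame(dose = c(1, 1, 2, 2),
                                          response = 1:4)),
               class = "netpharm_validation_error")
  expect_error(dose_trend_test(data.frame(dose = c(1, 2, 3), response = 1:3)),
               class = "netpharm_validation_error")
})

test_that("group comparison reports ANOVA and pairwise Welch t", {
  dat <- withr::with_seed(21, data.frame(
    value = c(rnorm(5, 0), rnorm(5, 3), rnorm(5, 6)),
    group = rep(c("control", "low", "high"), each = 5)))
  res <- compare_groups(dat)
  expect_named(res, c("anova", "pairwise"))
  expect_equal(nrow(res$pairwise), 2)
  expect_true(all(res$pairwise$p_value >= 0 & res$pairwise$p_value <= 1))
  expect_error(compare_groups(dat, control_group = "sham"),
               class = "netpharm_validation_error")
})
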