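test_that("group derivation applies the strict 34-week boundary", {
  md <- data.frame(sample_id = c("a", "b", "c"),
                   ga_weeks = c(33.9, 34.0, 40),
                   pe = c(TRUE, FALSE, TRUE))
  g <- derive_groups(md)
  expect_equal(g$group, c("EP-PE", "NTT-N", "NTT-PE"))

  md$ga_weeks[2] <- NA
  expect_error(derive_groups(md), "row 2")
})

test_that("Mann-Whitney p-values match exhaustive enumeration", {
  # the extreme 3v3 split: exact two-sided p = 2/20
  cmp <- compare_groups(c(1, 2, 3, 4, 5, 6),
                        rep(c("a", "b"), each = 3),
                        pairs = list(c("a", "b")))
  expect_equal(cmp$p_value, 0.1)
  expect_equal(cmp$p_value, oracle_mw_p(c(1, 2, 3), c(4, 5, 6)))

  set.seed(51)
  for (sizes in list(c(3, 4), c(5, 5), c(6, 8))) {
    x <- stats::rnorm(sizes[1])
    y <- stats::rnorm(sizes[2]) + 0.5
    cmp <- compare_groups(c(x, y),
                          rep(c("a", "b"), times = sizes),
                          pairs = list(c("a", "b")))
    expect_equal(cmp$p_value, oracle_mw_p(x, y), tolerance = 1e-12)
  }
})

test_that("BH adjustment follows the step-up definition", {
  cmpd <- stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH")
  expect_equal(cmpd, rep(0.04, 4))
  set.seed(52)
  for (i in 1:10) {
    p <- stats::runif(sample(3:12, 1))
    expect_equal(stats::p.adjust(p, method = "BH"), oracle_bh(p))
  }
  # compare_groups adjusts across the pairs of one call
  vals <- c(stats::rnorm(6), stats::rnorm(6, 2), stats::rnorm(6, 4))
  lab <- rep(c("a", "b", "c"), each = 6)
  cmp <- compare_groups(vals, lab)
  expect_equal(cmp$p_adjusted, oracle_bh(cmp$p_value))
})

test_that("Fisher enrichment reports both odds ratios and the exact p", {
  r <- enrichment_test(matrix(c(2, 1, 1, 2), 2, byrow = TRUE))
  expect_equal(r$sample_or, 4.0)
  expect_equal(r$p_value, oracle_fisher_p(2, 1, 1, 2), tolerance = 1e-9)

  r2 <- enrichment_test(matrix(c(27, 11, 18, 56), 2, byrow = TRUE))
  expect_equal(r2$sample_or, 27 * 56 / (11 * 18))
  expect_equal(r2$p_value, oracle_fisher_p(27, 11, 18, 56),
               tolerance = 1e-9)
  expect_true(r2$or_defined)
  expect_lt(r2$ci_low, r2$odds_ratio)
  expect_gt(r2$ci_high, r2$odds_ratio)

  r3 <- enrichment_test(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))
  expect_false(r3$or_defined)
  expect_equal(r3$p_value, 2 / choose(10, 5), tolerance = 1e-9)

  # flag-vector interface builds the same table
  carriers <- c(rep(TRUE, 3), rep(FALSE, 3))
  outcome <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  r4 <- enrichment_test(carriers, outcome, set_name = "tgfb")
  expect_equal(c(r4$a, r4$b, r4$c, r4$d), c(2, 1, 1, 2))
})

sim_cox_table <- function(seed, n = 500, log_hr = log(1.7),
                          mean_variants = 150) {
  spec <- simulation_spec(n_samples = n, group_scheme = NULL, seed = seed,
                          true_log_hr_instability = log_hr,
                          mean_variants_per_sample = mean_variants,
                          n_background_genes = 40)
  b <- simulate_cohort(spec)
  tr <- b$truth$per_sample
  tab <- b$metadata
  tab$burden <- tr$planted_burden
  tab$hypoxia <- tr$planted_hypoxia
  tab
}

test_that("Cox fit recovers a planted log hazard ratio", {
  tab <- sim_cox_table(seed = 1)
  fit <- fit_cox(tab, c("burden", "hypoxia"), event = "pe", seed = 1,
                 ph_check = FALSE)
  expect_lt(abs(fit$coefficients["burden"] - log(1.7)), 0.15)
  expect_equal(unname(fit$hazard_ratios),
               unname(exp(fit$coefficients)))
  expect_true(all(fit$ci_low < fit$ci_high))
})

test_that("duplicating every sample leaves the estimate unchanged", {
  tab <- sim_cox_table(seed = 9, n = 100)
  f1 <- fit_cox(tab, c("burden", "hypoxia"), event = "pe",
                penalizer_grid = 0, ph_check = FALSE)
  f2 <- fit_cox(rbind(tab, tab), c("burden", "hypoxia"), event = "pe",
                penalizer_grid = 0, ph_check = FALSE)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
})

test_that("degenerate Cox inputs are rejected", {
  tab <- sim_cox_table(seed = 3, n = 50)
  expect_error(fit_cox(tab[1:10, ], "burden", event = "pe"), "20")
  tab$burden[5] <- NA
  expect_error(fit_cox(tab, "burden", event = "pe"), "missing")
  tab2 <- sim_cox_table(seed = 3, n = 50)
  tab2$ga_weeks <- 30
  expect_error(fit_cox(tab2, "burden", event = "pe"), "tied")
})

test_that("features failing the proportional-hazards check are squared", {
  set.seed(10)
  n <- 300
  x <- stats::runif(n, 0, 2)
  # effect strength changes with time (Weibull shape depends on x), a
  # textbook proportional-hazards violation
  t <- pmin(20 + stats::rweibull(n, 0.5 + 1.5 * x, 8), 42)
  tab <- data.frame(ga_weeks = t, pe = TRUE, x = x,
                    z = stats::rnorm(n))
  fit <- fit_cox(tab, c("x", "z"), event = "pe", penalizer_grid = 0,
                 seed = 1)
  expect_true("x" %in% fit$transformed_features)
  expect_true("x_sq" %in% fit$features)
  expect_false(is.null(fit$ph_test))
  expect_false(fit$ph_test$pass[fit$ph_test$feature == "x"])
})

test_that("partial-effect curves order with the coefficient sign", {
  tab <- sim_cox_table(seed = 5, n = 200)
  fit <- fit_cox(tab, c("burden", "hypoxia"), event = "pe",
                 penalizer_grid = 0, ph_check = FALSE)
  cur <- partial_effect_curves(fit, "burden")
  expect_true(all(diff(cur$cuminc_low) >= 0))
  expect_true(all(diff(cur$cuminc_high) >= 0))
  # planted positive effect: high-burden curve dominates
  expect_true(all(cur$cuminc_high >= cur$cuminc_low))

  # zero coefficient: curves coincide
  fit0 <- fit
  fit0$coefficients["burden"] <- 0
  cur0 <- partial_effect_curves(fit0, "burden")
  expect_equal(cur0$cuminc_low, cur0$cuminc_high)

  expect_error(partial_effect_curves(fit, "burden", c(0, 90)),
               "percentiles")
})
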