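test_that("max-|t| adjustment reduces to the raw p-value for a single hypothesis", {
  p <- adjust_maxt(2.1, matrix(1), df = 30)
  expect_equal(p, 2 * stats::pt(2.1, 30, lower.tail = FALSE))
})

test_that("independent hypotheses reproduce the Sidak closed form", {
  t <- c(1.4, 2.6)
  R <- diag(2)
  p_raw <- 2 * stats::pt(abs(t), 500, lower.tail = FALSE)
  sidak <- 1 - (1 - p_raw)^2
  expect_equal(adjust_maxt(t, R, 500, method = "sidak"), sidak)
  p_mc <- adjust_maxt(t, R, 500, mc_draws = 2e5, seed = 42)
  expect_equal(p_mc, sidak, tolerance = 0.02)
})

test_that("Monte-Carlo adjustment matches the equicorrelated quadrature oracle", {
  m <- 5; rho <- 0.5; df <- 100
  R <- matrix(rho, m, m); diag(R) <- 1
  t <- c(0.8, 1.5, 2.2, 2.9, 3.4)
  mc <- adjust_maxt(t, R, df, mc_draws = 1e5, seed = 7)
  for (i in seq_along(t)) {
    oracle <- maxt_equicorr_p(abs(t[i]), m, rho, df)
    se <- sqrt(oracle * (1 - oracle) / 1e5)
    expect_lt(abs(mc[i] - oracle), 3 * se + 1e-6)
  }
})

test_that("adjusted p-values are monotone in |t| and never below raw", {
  m <- 8
  R <- matrix(0.3, m, m); diag(R) <- 1
  t <- seq(-3, 3.5, length.out = m)
  p <- adjust_maxt(t, R, 40, mc_draws = 5e4, seed = 1)
  p_raw <- 2 * stats::pt(abs(t), 40, lower.tail = FALSE)
  expect_true(all(p >= p_raw - 1e-12))
  ord <- order(abs(t))
  expect_true(all(diff(p[ord]) <= 1e-12))
  expect_error(adjust_maxt(c(1, 2), matrix(c(1, 2, 2, 1), 2), 10),
               "positive semi-definite")
})

test_that("grand-mean estimates sum to zero and are null under equal genotype means", {
  d <- generate_trial(trial_design(n_genotypes = 12),
                      list(y = variance_spec(mu = 5, sigma2_block = 0.2,
                                             sigma2_resid = 1)),
                      seed = 8)
  dm <- build_design(d, "y", "fixed_gxe", "iid")
  ft <- reml_fit(dm)
  g <- grand_mean_contrasts(ft, dm, levels(dm$plot$year)[1],
                            mc_draws = 2e4, seed = 2)
  expect_lt(abs(sum(g$estimate)), 1e-10)
  expect_true(all(abs(g$estimate) < 2.5))
  # contrast correlation under balance: equicorrelated at -1/(m-1)
  R <- attr(g, "correlation")
  off <- R[upper.tri(R)]
  expect_equal(unname(off), rep(-1 / 11, length(off)), tolerance = 1e-6)
})

test_that("a strongly shifted accession is flagged while others compensate", {
  shift <- matrix(10, 1, 1, dimnames = list("ACC03", "y"))
  d <- generate_trial(trial_design(n_genotypes = 12),
                      list(y = variance_spec(mu = 5, sigma2_resid = 1)),
                      seed = 9, genotype_shifts = shift)
  dm <- build_design(d, "y", "fixed_gxe", "iid")
  ft <- reml_fit(dm)
  g <- grand_mean_contrasts(ft, dm, levels(dm$plot$year)[1],
                            mc_draws = 2e4, seed = 2)
  expect_lt(g$p_adj[g$hypothesis == "ACC03"], 0.001)
  others <- g$estimate[g$hypothesis != "ACC03"]
  expect_lt(mean(others), 0)  # the shifted accession drags up the grand mean
})

test_that("single-step results agree with multcomp's glht on the same fit", {
  skip_if_not_installed("multcomp")
  d <- simulate_quinoa_trial(seed = 13)
  dm <- build_design(d, "seed_yield", "fixed_gxe", "iid")
  ft <- reml_fit(dm)
  yr <- levels(dm$plot$year)[1]
  g <- grand_mean_contrasts(ft, dm, yr, mc_draws = 1e5, seed = 3)
  acc <- levels(dm$cells$accession)
  K_cell <- t(vapply(acc, function(a) {
    as.numeric(dm$cells$accession == a & dm$cells$year == yr) -
      as.numeric(dm$cells$year == yr) / length(acc)
  }, numeric(nrow(dm$cells))))
  K <- K_cell %*% dm$M
  set.seed(99)
  gh <- summary(multcomp::glht(ft$engine, linfct = K))
  expect_equal(unname(g$estimate), unname(gh$test$coefficients),
               tolerance = 1e-8)
  expect_equal(unname(g$se), unname(gh$test$sigma), tolerance = 1e-8)
  expect_equal(unname(g$p_adj), unname(as.numeric(gh$test$pvalues)),
               tolerance = 0.02)
})

test_that("year contrasts equal cell-mean differences and flip under relabeling", {
  d <- simulate_quinoa_trial(seed = 14)
  dm <- build_design(d, "tkw", "fixed_gxe", "iid")
  ft <- reml_fit(dm)
  yc <- year_contrasts(ft, dm, mc_draws = 2e4, seed = 5)
  cm <- adjusted_cell_means(ft, dm)
  yrs <- levels(dm$cells$year)
  for (a in c("ACC01", "ACC27")) {
    expected <- cm$value[cm$accession == a & cm$year == yrs[2]] -
      cm$value[cm$accession == a & cm$year == yrs[1]]
    expect_equal(yc$estimate[yc$hypothesis == a], expected, tolerance = 1e-8)
  }
  d2 <- d
  d2$year <- factor(as.character(d2$year), levels = rev(levels(d$year)))
  dm2 <- build_design(d2, "tkw", "fixed_gxe", "iid")
  yc2 <- year_contrasts(reml_fit(dm2), dm2, mc_draws = 2e4, seed = 5)
  expect_equal(yc2$estimate, -yc$estimate, tolerance = 1e-6)
  expect_equal(yc2$stable, yc$stable)
})

test_that("correlations hit the exact limits for degenerate trait pairs", {
  acc <- sprintf("A%02d", 1:8)
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  base <- data.frame(accession = acc, year = "2020", block = "1",
                     column = "c1", stringsAsFactors = FALSE)
  d <- rbind(data.frame(base, trait = "t1", value = x),
             data.frame(base, trait = "t2", value = -x),
             data.frame(base, trait = "t3", value = x))
  class(d) <- c("trial_data", "data.frame")
  pc <- pearson_ci(d, year = "2020")
  r12 <- pc[pc$trait1 == "t1" & pc$trait2 == "t2", ]
  expect_equal(r12$r, -1)
  expect_equal(r12$lower, -1)
  expect_equal(r12$upper, -1)
  r13 <- pc[pc$trait1 == "t1" & pc$trait2 == "t3", ]
  expect_equal(r13$r, 1)
  expect_error(pearson_ci(d, year = "1999"), "not present")
})

test_that("Fisher-z intervals achieve nominal coverage for correlated genotype effects", {
  gc <- genetic_correlation(c("a", "b"), matrix(c(1, 0.6, 0.6, 1), 2))
  specs <- list(a = variance_spec(mu = 0, sigma2_g = 1, sigma2_resid = 0.3),
                b = variance_spec(mu = 0, sigma2_g = 1, sigma2_resid = 0.3))
  # true correlation of accession means over 2 years x 3 blocks
  r_true <- 0.6 / (1 + 0.3 / 6)
  n_trial <- 300
  cover <- logical(n_trial)
  for (r in seq_len(n_trial)) {
    d <- generate_trial(trial_design(), specs, gcorr = gc, seed = 7000 + r)
    d$year <- factor("2020")  # pool both years into one accession mean set
    pc <- pearson_ci(d, year = "2020")
    cover[r] <- pc$lower <= r_true && r_true <= pc$upper
  }
  se3 <- 3 * sqrt(0.95 * 0.05 / n_trial)
  expect_gt(mean(cover), 0.95 - se3 - 0.02)
  expect_lt(mean(cover), 1.0)
})
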