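test_that("fixed-model design matrix has the expected dimensions", {
  d <- generate_trial(trial_design(n_genotypes = 2, n_blocks = 1),
                      list(y = variance_spec(mu = 0, sigma2_resid = 1)),
                      seed = 1)
  dm <- build_design(d, "y", "fixed_gxe")
  # intercept + 1 genotype + 1 year + 1 interaction under reference coding
  expect_equal(ncol(dm$X), 4)
  expect_equal(nrow(dm$X), 4)
})

test_that("all-random design exposes the six incidence matrices with correct level counts", {
  d <- simulate_quinoa_trial(seed = 2)
  dm <- build_design(d, "dtf", "all_random")
  expect_named(dm$Z, c("genotype", "year", "gxy", "block", "block_year",
                       "column"))
  expect_equal(vapply(dm$Z, ncol, integer(1)),
               c(genotype = 48L, year = 2L, gxy = 96L, block = 3L,
                 block_year = 6L, column = 24L))
  expect_true(all(vapply(dm$Z, nrow, integer(1)) == 288L))
})

test_that("coefficient names map back to factor levels bijectively", {
  d <- generate_trial(trial_design(n_genotypes = 3),
                      list(y = variance_spec(mu = 0, sigma2_resid = 1)),
                      seed = 1)
  dm <- build_design(d, "y", "fixed_gxe")
  expect_equal(nrow(dm$coef_map), ncol(dm$X))
  expect_false(anyDuplicated(paste(dm$coef_map$factor, dm$coef_map$level)) > 0)
  expect_false(anyNA(dm$coef_map$factor))
})

test_that("single-year data cannot request the G-x-Y fixed model", {
  d <- generate_trial(trial_design(n_years = 1),
                      list(y = variance_spec(mu = 0, sigma2_resid = 1)),
                      seed = 1)
  expect_error(build_design(d, "y", "fixed_gxe"), "single-year")
  expect_error(build_design(d, "nope", "fixed_gxe"), "not present")
})

test_that("pure-residual data pins the genotype component near the zero boundary", {
  d <- generate_trial(trial_design(n_genotypes = 10),
                      list(y = variance_spec(mu = 3, sigma2_resid = 2)),
                      seed = 4)
  d$column <- NULL
  ft <- reml_fit(build_design(d, "y", "all_random"), refine = FALSE)
  expect_lt(ft$vc$components[["genotype"]], 0.4)
  expect_lt(abs(ft$vc$components[["residual"]] - 2) / 2, 0.3)
  expect_true(any(ft$vc$boundary))
})

test_that("REML equals the expected-mean-squares oracle on balanced interior fixtures", {
  n_interior <- 0
  for (seed in 1:10) {
    d <- balanced_fixture(seed)
    plot <- data.frame(accession = d$accession, year = d$year,
                       block = d$block, y = d$value)
    ems <- ems_components(plot)
    if (any(ems <= 0)) next
    n_interior <- n_interior + 1
    ft <- reml_fit(build_design(d, "y", "all_random"))
    reml <- ft$vc$components[names(ems)]
    expect_lt(max(abs(reml - ems) / abs(ems)), 1e-6)
  }
  expect_gte(n_interior, 3)
})

test_that("rescaling the response scales variance components by c^2 and leaves F unchanged", {
  d <- balanced_fixture(1)
  ft1 <- reml_fit(build_design(d, "y", "all_random"), refine = FALSE)
  dmf1 <- build_design(d, "y", "fixed_gxe", "iid")
  ff1 <- reml_fit(dmf1)
  cc <- 3.7
  d2 <- d; d2$value <- d2$value * cc
  ft2 <- reml_fit(build_design(d2, "y", "all_random"), refine = FALSE)
  dmf2 <- build_design(d2, "y", "fixed_gxe", "iid")
  ff2 <- reml_fit(dmf2)
  expect_equal(ft2$vc$components, ft1$vc$components * cc^2, tolerance = 1e-4)
  a1 <- wald_anova(ff1, dmf1); a2 <- wald_anova(ff2, dmf2)
  expect_equal(a2$F, a1$F, tolerance = 1e-8)
})

test_that("GLS cell means equal arithmetic cell means on balanced data", {
  d <- simulate_quinoa_trial(seed = 6)
  dm <- build_design(d, "plant_height", "fixed_gxe", "hetero_corr")
  ft <- reml_fit(dm)
  expect_equal(ft$structure_used, "hetero_corr")
  cm <- adjusted_cell_means(ft, dm)
  raw <- d[d$trait == "plant_height", ]
  arith <- tapply(raw$value, list(raw$accession, raw$year), mean)
  got <- tapply(cm$value, list(cm$accession, cm$year), mean)
  expect_equal(unclass(got), unclass(arith), tolerance = 1e-6)
})

test_that("permuting genotype labels leaves the year F statistic unchanged on balanced data", {
  d <- balanced_fixture(2)
  dm1 <- build_design(d, "y", "fixed_gxe", "iid")
  f1 <- wald_anova(reml_fit(dm1), dm1)
  set.seed(1)
  perm <- sample(levels(d$accession))
  d2 <- d
  d2$accession <- factor(perm[as.integer(d2$accession)], levels = levels(d$accession))
  dm2 <- build_design(d2, "y", "fixed_gxe", "iid")
  f2 <- wald_anova(reml_fit(dm2), dm2)
  expect_equal(f2$F[f2$term == "year"], f1$F[f1$term == "year"],
               tolerance = 1e-8)
})

test_that("genotype F-test p-values are near-uniform under the genotype null", {
  n_trial <- 80
  p <- numeric(n_trial)
  for (r in seq_len(n_trial)) {
    d <- generate_trial(trial_design(n_genotypes = 12),
                        list(y = variance_spec(mu = 0, sigma2_block = 0.3,
                                               sigma2_resid = 1)),
                        seed = 4000 + r)
    dm <- build_design(d, "y", "fixed_gxe", "iid")
    an <- wald_anova(reml_fit(dm), dm)
    p[r] <- an$p[an$term == "accession"]
  }
  frac <- mean(p < 0.05)
  expect_lt(frac, 0.13)  # 3 binomial SEs above the nominal 0.05
  expect_gt(mean(p), 0.35)
})

test_that("strong genotype effects are declared highly significant", {
  d <- generate_trial(trial_design(n_genotypes = 20),
                      list(y = variance_spec(mu = 0, sigma2_g = 10,
                                             sigma2_resid = 0.5)),
                      seed = 5)
  dm <- build_design(d, "y", "fixed_gxe", "iid")
  an <- wald_anova(reml_fit(dm), dm)
  expect_lt(an$p[an$term == "accession"], 1e-3)
})

test_that("pseudo-R2 hits its limits and detects real structure", {
  fake <- structure(list(y = c(1, 2, 3, 4), fitted = c(1, 2, 3, 4)),
                    class = "met_fit")
  expect_equal(pseudo_r2(fake), 1.0)
  fake$fitted <- rep(2.5, 4)
  expect_equal(pseudo_r2(fake), 0.0)
  fake$y <- rep(1, 4)
  expect_error(pseudo_r2(fake), "zero variance")

  d <- generate_trial(trial_design(n_genotypes = 16),
                      list(y = variance_spec(mu = 0, sigma2_g = 8,
                                             sigma2_resid = 1)),
                      seed = 6)
  dm <- build_design(d, "y", "fixed_gxe", "iid")
  r2 <- pseudo_r2(reml_fit(dm))
  set.seed(2)
  d2 <- d
  d2$accession <- factor(sample(as.character(d2$accession)),
                         levels = levels(d2$accession))
  dm2 <- build_design(d2, "y", "fixed_gxe", "iid")
  r2_perm <- pseudo_r2(reml_fit(dm2))
  expect_gt(r2, r2_perm)
})
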