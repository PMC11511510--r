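# Independent oracles used against the package's own implementations.

# Henderson method-3 / expected-mean-squares variance-component estimators
# for a balanced genotype x year x block trial with model
# y = mu + g + a + (ga) + b + (ba) + e, computed from the classical ANOVA
# decomposition -- never via REML.
ems_components <- function(plot) {
  G <- nlevels(plot$accession); Y <- nlevels(plot$year); B <- nlevels(plot$block)
  an <- stats::anova(stats::lm(
    y ~ accession + year + accession:year + block + block:year, data = plot))
  ms <- stats::setNames(an[["Mean Sq"]], rownames(an))
  mse <- ms[["Residuals"]]
  c(genotype   = (ms[["accession"]] - ms[["accession:year"]]) / (Y * B),
    year       = (ms[["year"]] - ms[["accession:year"]] -
                    ms[["year:block"]] + mse) / (G * B),
    gxy        = (ms[["accession:year"]] - mse) / B,
    block      = (ms[["block"]] - ms[["year:block"]]) / (G * Y),
    block_year = (ms[["year:block"]] - mse) / G,
    residual   = mse)
}

# High-resolution numerical-integration oracle for the single-step max-|t|
# adjusted p-value in the equicorrelated case: T_j = (sqrt(rho) Z0 +
# sqrt(1-rho) Z_j) / S with S^2 ~ chi^2_df / df. Integrates over the shared
# factor Z0 and the scale S with adaptive quadrature.
maxt_equicorr_p <- function(t, m, rho, df) {
  inner <- function(s) {
    # P(max_j |T_j| < t | S = s) by integrating out Z0
    f <- function(z) {
      up <- (t * s - sqrt(rho) * z) / sqrt(1 - rho)
      lo <- (-t * s - sqrt(rho) * z) / sqrt(1 - rho)
      (stats::pnorm(up) - stats::pnorm(lo))^m * stats::dnorm(z)
    }
    stats::integrate(f, -9, 9, rel.tol = 1e-10)$value
  }
  dens_s <- function(s) 2 * df * s * stats::dchisq(df * s^2, df)
  g <- function(s) vapply(s, function(si) inner(si) * dens_s(si), numeric(1))
  1 - stats::integrate(g, 1e-6, 6, rel.tol = 1e-9)$value
}

# small balanced fixture with sizeable interior components
balanced_fixture <- function(seed, n_genotypes = 6) {
  d <- generate_trial(
    trial_design(n_genotypes = n_genotypes),
    list(y = variance_spec(mu = 10, sigma2_g = 4, sigma2_year = 2,
                           sigma2_gxy = 1.5, sigma2_block = 1,
                           sigma2_blockxyear = 0.8, sigma2_resid = 1)),
    seed = seed)
  d$column <- NULL  # no column term in the EMS oracle's model
  d
}

# DTF variance components of the reference trial, used as generating values
dtf_components <- function() {
  vc <- quinoa_variance_components()
  as.list(vc[vc$trait == "dtf", c("sigma2_g", "sigma2_gxy", "sigma2_resid")])
}
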