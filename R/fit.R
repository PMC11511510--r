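#' REML fit of a single-trait trial model
#'
#' Maximizes the restricted likelihood of the model described by a
#' [build_design()] object. The all-random model is fitted with
#' \pkg{lme4}; the fixed-G-x-Y model with \pkg{nlme}, using the requested
#' residual structure with automatic fallback (per-year variances with
#' cross-year correlation within genotype-by-block cells, then per-year
#' variances only, then iid) when a structure is not estimable; the
#' structure actually used is recorded. Variance components estimated at
#' (or numerically indistinguishable from) zero are reported with a
#' boundary flag.
#'
#' @param dm A `met_design` from [build_design()].
#' @param start Optional named vector of starting variance components
#'   (currently advisory only).
#' @param tol Convergence tolerance passed to the optimizer.
#' @param max_iter Maximum optimizer iterations.
#' @param refine For the all-random model, polish the REML optimum with
#'   extra derivative-free sweeps (default `TRUE`); turn off in large
#'   simulation loops where speed matters more than the last digits.
#' @return An object of class `met_fit`: list with `vc` (named variance
#'   components, boundary flags, residual parameters, REML log-likelihood),
#'   `beta`, `V` (coefficient covariance), `df_resid`, `fitted` (including
#'   predicted random effects), `residuals`, `structure_used`, `converged`,
#'   and the underlying engine fit.
#' @export
reml_fit <- function(dm, start = NULL, tol = 1e-8, max_iter = 200,
                     refine = TRUE) {
  stopifnot(inherits(dm, "met_design"))
  plot <- dm$plot
  if (nrow(plot) <= ncol(dm$X)) stop("fewer observations than fixed parameters")
  if (dm$model == "all_random") {
    reml_fit_all_random(dm, max_iter, refine)
  } else {
    reml_fit_fixed(dm, tol, max_iter)
  }
}

reml_fit_all_random <- function(dm, max_iter, refine = TRUE) {
  plot <- dm$plot
  terms <- c("(1 | accession)", "(1 | year)", "(1 | gxy)", "(1 | block)",
             "(1 | block_year)",
             if (!is.null(plot$column) && nlevels(plot$column) > 1) "(1 | column)")
  f <- stats::as.formula(paste("y ~ 1 +", paste(terms, collapse = " + ")))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            optCtrl = list(maxfun = max_iter * 100,
                                           xtol_abs = 1e-10,
                                           ftol_abs = 1e-12))
  lmod <- lme4::lFormula(f, data = plot, REML = TRUE, control = ctrl)
  devfun <- do.call(lme4::mkLmerDevfun, lmod)
  opt <- lme4::optimizeLmer(devfun, optimizer = "nloptwrap",
                            control = ctrl$optCtrl)
  par <- opt$par
  if (refine) {
    # polish the optimum: the profiled REML deviance is flat near the
    # maximum, and interior solutions must reproduce the closed-form
    # balanced-data estimators to high accuracy
    lower <- lmod$reTrms$lower
    for (sweep in 1:2) {
      # a simplex restart plus coordinate-wise Brent escapes stagnation
      o <- stats::optim(par, devfun, method = "Nelder-Mead",
                        control = list(reltol = 1e-15, maxit = 2000))
      par <- o$par
      for (j in seq_along(par)) {
        g <- function(x) { q <- par; q[j] <- x; devfun(q) }
        oo <- stats::optimize(g, lower = max(lower[j], par[j] - 0.05),
                              upper = par[j] + 0.05, tol = 1e-12)
        if (oo$objective <= devfun(par)) par[j] <- oo$minimum
      }
    }
    par <- newton_polish(devfun, par, lower)
  }
  fit <- lme4::mkMerMod(environment(devfun),
                        list(par = par, fval = devfun(par), conv = 0,
                             message = NULL),
                        lmod$reTrms, lmod$fr)
  vc_raw <- as.data.frame(lme4::VarCorr(fit))
  comp <- stats::setNames(vc_raw$vcov, vc_raw$grp)
  nm_map <- c(accession = "genotype", year = "year", gxy = "gxy",
              block = "block", block_year = "block_year", column = "column",
              Residual = "residual")
  names(comp) <- nm_map[names(comp)]
  order_nm <- intersect(c("genotype", "year", "gxy", "block", "block_year",
                          "column", "residual"), names(comp))
  comp <- comp[order_nm]
  tot <- sum(comp)
  vc <- structure(list(
    components = comp,
    boundary = comp < 1e-8 * max(tot, 1e-12),
    resid_by_year = NULL, rho = NA_real_,
    logLik = as.numeric(stats::logLik(fit)),
    converged = length(fit@optinfo$conv$lme4) == 0 ||
      is.null(fit@optinfo$conv$lme4$messages)
  ), class = "met_vc")
  beta <- lme4::fixef(fit)
  structure(list(model = "all_random", trait = dm$trait, vc = vc,
                 beta = beta, V = as.matrix(stats::vcov(fit)),
                 df_resid = nrow(plot) - length(beta),
                 y = plot$y, fitted = stats::fitted(fit),
                 residuals = stats::residuals(fit),
                 structure_used = "iid", converged = vc$converged,
                 engine = fit), class = "met_fit")
}

# Finite-difference Newton refinement of the REML deviance optimum. The
# deviance is flat to machine precision over relative shifts of ~1e-6 in a
# small component, so direct search stalls there; curvature-based steps
# with moderate step sizes localize the optimum far more precisely.
# Interior components only: coordinates at the boundary are left alone.
newton_polish <- function(devfun, par, lower, iters = 5L) {
  m <- length(par)
  for (it in seq_len(iters)) {
    free <- which(par - lower > 1e-6)
    if (!length(free)) break
    # shrink the gradient step late so its O(h^2) bias stops limiting the
    # final accuracy; the Hessian tolerates a coarser step
    hg <- if (it <= 3) 1e-4 else 1e-5
    hh <- 1e-3
    g <- numeric(length(free)); H <- matrix(0, length(free), length(free))
    f0 <- devfun(par)
    for (a in seq_along(free)) {
      j <- free[a]
      pp <- par; pp[j] <- par[j] + hg; fp <- devfun(pp)
      pp[j] <- par[j] - hg; fm <- devfun(pp)
      g[a] <- (fp - fm) / (2 * hg)
      pp[j] <- par[j] + hh; fph <- devfun(pp)
      pp[j] <- par[j] - hh; fmh <- devfun(pp)
      H[a, a] <- (fph - 2 * f0 + fmh) / hh^2
      for (b in seq_len(a - 1)) {
        k <- free[b]
        pp <- par; pp[j] <- par[j] + hh; pp[k] <- par[k] + hh; fpp <- devfun(pp)
        pp <- par; pp[j] <- par[j] + hh; pp[k] <- par[k] - hh; fpm <- devfun(pp)
        pp <- par; pp[j] <- par[j] - hh; pp[k] <- par[k] + hh; fmp <- devfun(pp)
        pp <- par; pp[j] <- par[j] - hh; pp[k] <- par[k] - hh; fmm <- devfun(pp)
        H[a, b] <- H[b, a] <- (fpp - fpm - fmp + fmm) / (4 * hh^2)
      }
    }
    step <- tryCatch(solve(H, -g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    if (max(abs(step)) > 0.1) step <- step * 0.1 / max(abs(step))
    cand <- par
    cand[free] <- pmax(par[free] + step, lower[free])
    if (devfun(cand) <= f0 + 1e-8) par <- cand else break
    if (it > 3 && max(abs(step)) < 1e-10) break
  }
  par
}

reml_fit_fixed <- function(dm, tol, max_iter) {
  plot <- dm$plot
  ctrl <- nlme::lmeControl(maxIter = max_iter, msMaxIter = max_iter,
                           niterEM = 50, tolerance = tol, opt = "optim",
                           returnObject = FALSE)
  tried <- list(
    hetero_corr = function() nlme::lme(
      y ~ accession * year, random = ~ 1 | block, data = plot,
      weights = nlme::varIdent(form = ~ 1 | year),
      correlation = nlme::corCompSymm(form = ~ 1 | block / accession),
      method = "REML", control = ctrl),
    hetero = function() nlme::lme(
      y ~ accession * year, random = ~ 1 | block, data = plot,
      weights = nlme::varIdent(form = ~ 1 | year),
      method = "REML", control = ctrl),
    iid = function() nlme::lme(
      y ~ accession * year, random = ~ 1 | block, data = plot,
      method = "REML", control = ctrl)
  )
  order <- switch(dm$residual_structure,
                  hetero_corr = c("hetero_corr", "hetero", "iid"),
                  hetero = c("hetero", "iid"),
                  iid = "iid")
  fit <- NULL; used <- NULL
  for (nm in order) {
    fit <- tryCatch(suppressWarnings(tried[[nm]]()), error = function(e) NULL)
    if (!is.null(fit)) { used <- nm; break }
  }
  if (is.null(fit)) stop("no residual structure could be fitted for trait '",
                         dm$trait, "'")
  beta <- nlme::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  sig <- fit$sigma
  yr_lev <- levels(plot$year)
  if (used %in% c("hetero_corr", "hetero")) {
    w <- stats::coef(fit$modelStruct$varStruct, unconstrained = FALSE,
                     allCoef = TRUE)
    resid_by_year <- (sig * w[yr_lev])^2
  } else {
    resid_by_year <- stats::setNames(rep(sig^2, length(yr_lev)), yr_lev)
  }
  rho <- if (used == "hetero_corr") {
    as.numeric(stats::coef(fit$modelStruct$corStruct, unconstrained = FALSE))
  } else NA_real_
  comp <- c(block = as.numeric(nlme::VarCorr(fit)["(Intercept)", "Variance"]),
            residual = mean(resid_by_year))
  vc <- structure(list(components = comp,
                       boundary = comp < 1e-8 * max(sum(comp), 1e-12),
                       resid_by_year = resid_by_year, rho = rho,
                       logLik = as.numeric(stats::logLik(fit)),
                       converged = TRUE), class = "met_vc")
  structure(list(model = "fixed_gxe", trait = dm$trait, vc = vc,
                 beta = beta, V = V,
                 df_resid = nrow(plot) - length(beta),
                 y = plot$y, fitted = as.numeric(stats::fitted(fit)),
                 residuals = as.numeric(stats::residuals(fit)),
                 structure_used = used, converged = TRUE,
                 engine = fit), class = "met_fit")
}

#' @export
print.met_fit <- function(x, ...) {
  cat("Trial model fit (", x$model, ") for trait '", x$trait, "'\n", sep = "")
  cat("  residual structure:", x$structure_used, "\n")
  cat("  variance components:\n")
  print(round(x$vc$components, 5))
  invisible(x)
}

# Accession-by-year cell means and their covariance from a fixed-G-x-Y fit.
cell_mean_estimates <- function(fit, dm) {
  stopifnot(fit$model == "fixed_gxe", !is.null(dm$M))
  mu <- as.numeric(dm$M %*% fit$beta)
  Vmu <- dm$M %*% fit$V %*% t(dm$M)
  list(cells = dm$cells, mu = mu, V = Vmu)
}

#' Wald ANOVA of the fixed-G-x-Y trial model
#'
#' Coding-invariant Wald F tests of the accession, year and
#' accession-by-year fixed terms, formulated as linear hypotheses on the
#' accession-by-year cell means (equality of marginal accession means,
#' equality of marginal year means, vanishing interaction). Denominator
#' degrees of freedom are the residual df.
#'
#' @param fit A `met_fit` from [reml_fit()] of a `fixed_gxe` design.
#' @param dm The matching `met_design`.
#' @return Data frame with columns `term`, `F`, `df1`, `df2`, `p`.
#' @export
wald_anova <- function(fit, dm) {
  stopifnot(inherits(fit, "met_fit"), fit$model == "fixed_gxe")
  cm <- cell_mean_estimates(fit, dm)
  cells <- cm$cells
  acc <- levels(cells$accession); yr <- levels(cells$year)
  ncell <- nrow(cells)
  ind <- function(a = NULL, y = NULL) {
    sel <- rep(TRUE, ncell)
    if (!is.null(a)) sel <- sel & cells$accession == a
    if (!is.null(y)) sel <- sel & cells$year == y
    as.numeric(sel) / sum(sel)
  }
  rows_g <- t(vapply(acc[-1], function(a) ind(a = a) - ind(a = acc[1]),
                     numeric(ncell)))
  rows_a <- t(vapply(yr[-1], function(y) ind(y = y) - ind(y = yr[1]),
                     numeric(ncell)))
  rows_ga <- do.call(rbind, lapply(acc[-1], function(a) {
    t(vapply(yr[-1], function(y) {
      e <- function(ai, yi) as.numeric(cells$accession == ai & cells$year == yi)
      e(a, y) - e(a, yr[1]) - e(acc[1], y) + e(acc[1], yr[1])
    }, numeric(ncell)))
  }))
  one_term <- function(C, term) {
    est <- C %*% cm$mu
    Vc <- C %*% cm$V %*% t(C)
    q <- nrow(C)
    Fs <- as.numeric(t(est) %*% solve(Vc, est)) / q
    data.frame(term = term, F = Fs, df1 = q, df2 = fit$df_resid,
               p = stats::pf(Fs, q, fit$df_resid, lower.tail = FALSE))
  }
  out <- rbind(one_term(rows_g, "accession"),
               one_term(rows_a, "year"),
               one_term(rows_ga, "accession:year"))
  rownames(out) <- NULL
  out
}

#' Conditional pseudo-R2 of a trial model fit
#'
#' Squared Pearson correlation between the observed values and the fitted
#' values including predicted random effects, a simple conditional
#' goodness-of-fit measure for mixed models.
#'
#' @param fit A `met_fit`.
#' @param dm The matching `met_design` (unused, kept for a uniform
#'   signature).
#' @return Proportion in \[0, 1\].
#' @export
pseudo_r2 <- function(fit, dm = NULL) {
  stopifnot(inherits(fit, "met_fit"))
  if (stats::sd(fit$y) == 0) stop("observed values have zero variance")
  if (stats::sd(fit$fitted) == 0) return(0)
  stats::cor(fit$y, fit$fitted)^2
}
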