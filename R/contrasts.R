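#' Single-step max-|t| adjusted p-values
#'
#' Family-wise adjusted p-values for a family of t statistics with known
#' correlation: \eqn{p_i = P(\max_j |T_j| \ge |t_i|)} under the joint
#' multivariate t distribution with the given correlation and degrees of
#' freedom, estimated by seeded Monte Carlo integration. The adjustment is
#' the single-step counterpart of simultaneous multiple contrast tests.
#' Sidak and Bonferroni are available as conservative fallbacks that do
#' not use the correlation.
#'
#' @param t_stats Numeric vector of t statistics.
#' @param correlation Correlation matrix of the t statistics (positive
#'   semi-definite); ignored for the fallback methods.
#' @param df Degrees of freedom (may be `Inf` for the normal limit).
#' @param mc_draws Monte-Carlo sample size (default 1e5).
#' @param seed Integer seed making the adjustment deterministic.
#' @param method `"maxt"` (default), `"sidak"` or `"bonferroni"`.
#' @return Numeric vector of adjusted p-values (always >= the raw
#'   two-sided t p-values).
#' @export
adjust_maxt <- function(t_stats, correlation = NULL, df, mc_draws = 1e5,
                        seed = 1, method = c("maxt", "sidak", "bonferroni")) {
  method <- match.arg(method)
  m <- length(t_stats)
  stopifnot(df > 0)
  p_raw <- 2 * stats::pt(abs(t_stats), df, lower.tail = FALSE)
  if (m == 1) return(p_raw)
  if (method == "sidak") return(pmin(1, 1 - (1 - p_raw)^m))
  if (method == "bonferroni") return(pmin(1, m * p_raw))
  stopifnot(!is.null(correlation), nrow(correlation) == m)
  L <- tryCatch(chol(correlation + diag(1e-10, m)), error = function(e)
    stop("correlation matrix is not positive semi-definite; ",
         "consider method = 'sidak'"))
  maxT <- with_seed(seed, {
    Z <- matrix(stats::rnorm(mc_draws * m), mc_draws) %*% L
    if (is.finite(df)) Z <- Z / sqrt(stats::rchisq(mc_draws, df) / df)
    mt <- abs(Z[, 1])
    for (j in seq_len(m)[-1]) mt <- pmax(mt, abs(Z[, j]))
    mt
  })
  p_adj <- vapply(abs(t_stats), function(ti) mean(maxT >= ti), numeric(1))
  pmax(p_adj, p_raw)  # the single-step adjusted p can never fall below raw
}

# Shared machinery: simultaneous inference on linear combinations of the
# accession-by-year cell means of a fixed-G-x-Y fit.
cell_contrast_test <- function(fit, dm, K_cell, labels, family,
                               mc_draws, seed, method) {
  cm <- cell_mean_estimates(fit, dm)
  est <- as.numeric(K_cell %*% cm$mu)
  Vk <- K_cell %*% cm$V %*% t(K_cell)
  se <- sqrt(pmax(diag(Vk), 0))
  if (any(se == 0)) stop("degenerate contrast with zero standard error")
  tstat <- est / se
  df <- fit$df_resid
  R <- stats::cov2cor(Vk)
  p_raw <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p_adj <- adjust_maxt(tstat, R, df, mc_draws = mc_draws, seed = seed,
                       method = method)
  out <- data.frame(hypothesis = labels, family = family, estimate = est,
                    se = se, t = tstat, df = df, p_raw = p_raw,
                    p_adj = p_adj, stars = p_stars(p_adj),
                    stringsAsFactors = FALSE)
  class(out) <- c("met_contrasts", "data.frame")
  attr(out, "correlation") <- R
  out
}

#' Grand-mean multiple contrast tests within a year
#'
#' Compares each accession's estimated mean in the given year with the
#' average over all accessions in that year (the grand mean difference,
#' GMD), with single-step max-|t| family-wise adjustment across the
#' accessions. By construction the GMD estimates sum to zero within the
#' year.
#'
#' @param fit A converged `met_fit` of a `fixed_gxe` design.
#' @param dm The matching `met_design`.
#' @param year Year level to test within.
#' @param mc_draws,seed,method Passed to [adjust_maxt()].
#' @return A `met_contrasts` data frame: one row per accession with
#'   `estimate` (GMD, trait units), `se`, `t`, `df`, `p_raw`, `p_adj`,
#'   `stars`.
#' @export
grand_mean_contrasts <- function(fit, dm, year, mc_draws = 1e5, seed = 1,
                                 method = "maxt") {
  stopifnot(inherits(fit, "met_fit"), fit$model == "fixed_gxe")
  cells <- dm$cells
  yr <- as.character(year)
  if (!yr %in% levels(cells$year)) stop("year '", yr, "' not in the fit")
  acc <- levels(cells$accession)
  if (length(acc) < 2) stop("need at least 2 accessions")
  ncell <- nrow(cells)
  K <- t(vapply(acc, function(a) {
    row <- as.numeric(cells$accession == a & cells$year == yr)
    row - as.numeric(cells$year == yr) / length(acc)
  }, numeric(ncell)))
  cell_contrast_test(fit, dm, K, acc, paste0("grand-mean year ", yr),
                     mc_draws, seed, method)
}

#' Year-comparison contrasts per accession
#'
#' Tests, for every accession, the difference between its estimated means
#' in the second and first year, with family-wise max-|t| adjustment
#' across accessions. An accession whose adjusted p-value is >= `alpha`
#' shows no evidence of a year effect and is flagged stable.
#'
#' @param fit A converged `met_fit` of a `fixed_gxe` design with two years.
#' @param dm The matching `met_design`.
#' @param alpha Stability threshold on the adjusted p-value (default 0.05).
#' @param mc_draws,seed,method Passed to [adjust_maxt()].
#' @return A `met_contrasts` data frame with one row per accession and an
#'   additional logical `stable` column.
#' @export
year_contrasts <- function(fit, dm, alpha = 0.05, mc_draws = 1e5, seed = 1,
                           method = "maxt") {
  stopifnot(inherits(fit, "met_fit"), fit$model == "fixed_gxe")
  cells <- dm$cells
  yr <- levels(cells$year)
  if (length(yr) != 2) stop("year contrasts require exactly two years")
  acc <- levels(cells$accession)
  ncell <- nrow(cells)
  K <- t(vapply(acc, function(a) {
    as.numeric(cells$accession == a & cells$year == yr[2]) -
      as.numeric(cells$accession == a & cells$year == yr[1])
  }, numeric(ncell)))
  out <- cell_contrast_test(fit, dm, K, acc,
                            paste0("year ", yr[2], " - ", yr[1]),
                            mc_draws, seed, method)
  out$stable <- out$p_adj >= alpha
  out
}

#' Per-year Pearson correlations between traits with Fisher-z intervals
#'
#' Pearson correlation for every trait pair within one year, computed by
#' default on accession means (each accession contributes one value per
#' trait per year), with 95 percent confidence intervals from the Fisher z
#' transformation.
#'
#' @param data A `trial_data` long-format data frame.
#' @param traits Traits to correlate; default all traits in `data`.
#' @param year Year level to restrict to.
#' @param level `"accession"` (correlate accession means, default) or
#'   `"plot"` (correlate plot-level values).
#' @param conf Confidence level (default 0.95).
#' @return Data frame with one row per unordered trait pair: `trait1`,
#'   `trait2`, `year`, `n`, `r`, `lower`, `upper`.
#' @export
pearson_ci <- function(data, traits = NULL, year,
                       level = c("accession", "plot"), conf = 0.95) {
  level <- match.arg(level)
  stopifnot(all(c("accession", "year", "trait", "value") %in% names(data)))
  d <- data[as.character(data$year) == as.character(year), , drop = FALSE]
  if (!nrow(d)) stop("year '", year, "' not present in data")
  if (is.null(traits)) traits <- as.character(unique(d$trait))
  d <- d[as.character(d$trait) %in% traits, , drop = FALSE]
  if (level == "accession") {
    agg <- stats::aggregate(value ~ accession + trait, data = d, FUN = mean)
  } else {
    d$plot_id <- interaction(d$accession, d$block, drop = TRUE)
    agg <- stats::aggregate(value ~ plot_id + trait, data = d, FUN = mean)
    names(agg)[1] <- "accession"
  }
  wide <- stats::reshape(agg, idvar = "accession", timevar = "trait",
                         direction = "wide")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  colnames(mat) <- sub("^value\\.", "", colnames(mat))
  mat <- mat[, intersect(traits, colnames(mat)), drop = FALSE]
  pairs <- utils::combn(colnames(mat), 2)
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    ok <- stats::complete.cases(mat[, c(a, b)])
    n <- sum(ok)
    if (n < 4) stop("fewer than 4 paired observations for ", a, " vs ", b)
    va <- mat[ok, a]; vb <- mat[ok, b]
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
      stop("zero variance in trait '", if (stats::sd(va) == 0) a else b,
           "' in year ", year)
    }
    r <- stats::cor(va, vb)
    if (abs(r) >= 1) {
      lo <- hi <- r
    } else {
      z <- atanh(r); sz <- 1 / sqrt(n - 3)
      lo <- tanh(z - zq * sz); hi <- tanh(z + zq * sz)
    }
    data.frame(trait1 = a, trait2 = b, year = as.character(year), n = n,
               r = r, lower = lo, upper = hi, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
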