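#' Define a multi-environment trial design
#'
#' Describes the field layout of a randomized complete block trial with
#' column effects: every accession appears once per block, blocks are
#' re-randomized each year, and plots within a block are grouped into
#' columns (accessions expected to mature together share a column).
#'
#' @param n_genotypes Number of accessions (default 48).
#' @param n_years Number of trial years (default 2).
#' @param n_blocks Number of complete blocks per year (default 3).
#' @param n_columns_per_block Number of columns within each block (default 4).
#' @param genotype_labels Optional character vector of unique accession
#'   labels; defaults to `ACC01`, `ACC02`, ...
#' @param year_labels Optional character vector of year labels; defaults to
#'   calendar years starting at 2020.
#' @return An object of class `trial_design`.
#' @examples
#' d <- trial_design(n_genotypes = 8)
#' d$n_plots  # 8 accessions x 2 years x 3 blocks = 48
#' @export
trial_design <- function(n_genotypes = 48, n_years = 2, n_blocks = 3,
                         n_columns_per_block = 4,
                         genotype_labels = NULL, year_labels = NULL) {
  stopifnot(n_genotypes >= 1, n_years >= 1, n_blocks >= 1,
            n_columns_per_block >= 1)
  if (is.null(genotype_labels)) {
    genotype_labels <- sprintf("ACC%02d", seq_len(n_genotypes))
  }
  if (length(genotype_labels) != n_genotypes) {
    stop("need exactly ", n_genotypes, " genotype labels")
  }
  if (anyDuplicated(genotype_labels)) stop("genotype labels must be unique")
  if (is.null(year_labels)) year_labels <- as.character(2019 + seq_len(n_years))
  if (length(year_labels) != n_years || anyDuplicated(year_labels)) {
    stop("need ", n_years, " unique year labels")
  }
  structure(list(
    n_genotypes = n_genotypes, n_years = n_years, n_blocks = n_blocks,
    n_columns_per_block = n_columns_per_block,
    genotype_labels = genotype_labels, year_labels = year_labels,
    n_plots = n_genotypes * n_years * n_blocks
  ), class = "trial_design")
}

#' Variance-component specification for one trait
#'
#' Variances of the random effects of the all-random trial model
#' y = mu + g + a + (ga) + b + (ba) + c + e
#' (genotype, year, genotype-by-year, block, block-by-year, column,
#' residual), in squared trait units. Residuals may be heteroscedastic by
#' year (`year_scale`) and correlated across years within a
#' genotype-by-block cell (`rho`).
#'
#' @param mu Trait mean.
#' @param sigma2_g Genotype variance.
#' @param sigma2_year Year variance.
#' @param sigma2_gxy Genotype-by-year interaction variance.
#' @param sigma2_block Block variance.
#' @param sigma2_blockxyear Block-by-year interaction variance.
#' @param sigma2_column Column variance (columns nested in block-by-year).
#' @param sigma2_resid Residual (plot) variance.
#' @param year_scale Optional per-year multiplicative residual SD scale
#'   factors (length `n_years`); default all 1.
#' @param rho Residual correlation across years within a genotype-by-block
#'   cell, in \[-1, 1\]; default 0.
#' @return An object of class `variance_spec`.
#' @export
variance_spec <- function(mu, sigma2_g = 0, sigma2_year = 0, sigma2_gxy = 0,
                          sigma2_block = 0, sigma2_blockxyear = 0,
                          sigma2_column = 0, sigma2_resid = 0,
                          year_scale = NULL, rho = 0) {
  v <- c(sigma2_g, sigma2_year, sigma2_gxy, sigma2_block,
         sigma2_blockxyear, sigma2_column, sigma2_resid)
  if (any(!is.finite(v)) || any(v < 0)) stop("variances must be finite and >= 0")
  if (!is.finite(rho) || rho < -1 || rho > 1) stop("rho must lie in [-1, 1]")
  if (!is.null(year_scale) && any(year_scale <= 0)) {
    stop("year_scale factors must be positive")
  }
  structure(list(mu = mu, sigma2_g = sigma2_g, sigma2_year = sigma2_year,
                 sigma2_gxy = sigma2_gxy, sigma2_block = sigma2_block,
                 sigma2_blockxyear = sigma2_blockxyear,
                 sigma2_column = sigma2_column, sigma2_resid = sigma2_resid,
                 year_scale = year_scale, rho = rho),
            class = "variance_spec")
}

#' Trait metadata: selection direction, bounds and measurement grid
#'
#' @param name Trait name.
#' @param direction `"higher_is_better"` or `"lower_is_better"`; determines
#'   the sign flip applied when the trait enters the selection index so that
#'   larger index values are always desirable.
#' @param bounds Optional length-2 numeric clamp interval applied after all
#'   random effects are summed (e.g. `c(0, 100)` for percentages, `c(1, 9)`
#'   for ordinal scores).
#' @param rounding Optional rounding grid (e.g. 1 for integer days).
#' @return An object of class `trait_spec`.
#' @export
trait_spec <- function(name,
                       direction = c("higher_is_better", "lower_is_better"),
                       bounds = NULL, rounding = NULL) {
  direction <- match.arg(direction)
  if (!is.null(bounds)) {
    stopifnot(length(bounds) == 2, bounds[1] <= bounds[2])
  }
  if (!is.null(rounding)) stopifnot(rounding > 0)
  structure(list(name = name, direction = direction, bounds = bounds,
                 rounding = rounding), class = "trait_spec")
}

#' Genetic correlation structure among traits
#'
#' Correlation matrix of the genotype effects across traits, used to draw
#' genotype effects jointly so that simulated data reproduce trait
#' correlations at the accession level.
#'
#' @param traits Character vector of trait names.
#' @param mat Symmetric positive semi-definite correlation matrix with unit
#'   diagonal, dimensions `length(traits)` square.
#' @return An object of class `genetic_correlation`.
#' @export
genetic_correlation <- function(traits, mat) {
  mat <- as.matrix(mat)
  m <- length(traits)
  stopifnot(nrow(mat) == m, ncol(mat) == m)
  if (max(abs(mat - t(mat))) > 1e-10) stop("correlation matrix must be symmetric")
  if (max(abs(diag(mat) - 1)) > 1e-10) stop("diagonal must be 1")
  ev <- eigen(mat, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("correlation matrix is not positive semi-definite")
  dimnames(mat) <- list(traits, traits)
  structure(list(traits = traits, mat = mat), class = "genetic_correlation")
}

# Run code with a temporary RNG state seeded at `seed`, restoring the
# caller's stream afterwards. All package randomness funnels through this.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Significance stars at the conventional 0.05 / 0.01 / 0.001 ladder.
p_stars <- function(p, ladder = c(0.05, 0.01, 0.001)) {
  vapply(p, function(pi) {
    if (is.na(pi)) return("")
    strrep("*", sum(pi < ladder))
  }, character(1))
}
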