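#' Entry-mean broad-sense heritability from variance components
#'
#' Computes the heritability of accession means over a trial with J years
#' and K blocks per year,
#' \deqn{h^2 = s_g^2 / (s_g^2 + s_{ga}^2 / J + s_r^2 / (J K)),}
#' where \eqn{s_g^2} is the genotype variance, \eqn{s_{ga}^2} the
#' genotype-by-year interaction variance and \eqn{s_r^2} the residual
#' variance of the all-random trial model. At the default two-year,
#' three-block design the divisors are 2 and 6.
#'
#' @param vc A `met_vc` object from [reml_fit()] of an all-random design,
#'   or a named numeric vector/list containing `genotype` (or `sigma2_g`),
#'   `gxy` (or `sigma2_gxy`) and `residual` (or `sigma2_resid`).
#' @param n_years Number of years J (default 2).
#' @param n_blocks Number of blocks per year K (default 3).
#' @return An object of class `heritability` (also a list): `h2`,
#'   the three input components and the divisors used.
#' @examples
#' estimate_heritability(c(genotype = 11.08, gxy = 5.94, residual = 0.95))$h2
#' @export
estimate_heritability <- function(vc, n_years = 2, n_blocks = 3) {
  stopifnot(n_years >= 1, n_blocks >= 1)
  comp <- if (inherits(vc, "met_vc")) vc$components else unlist(vc)
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(comp)) return(as.numeric(comp[nm]))
    stop("variance component '", ..1, "' not found")
  }
  sg <- pick("genotype", "sigma2_g")
  sga <- pick("gxy", "sigma2_gxy")
  sr <- pick("residual", "sigma2_resid")
  if (any(c(sg, sga, sr) < 0)) stop("variance components must be >= 0")
  denom <- sg + sga / n_years + sr / (n_years * n_blocks)
  if (denom == 0) stop("all variance components are zero; h2 undefined")
  structure(list(h2 = sg / denom, sigma2_g = sg, sigma2_gxy = sga,
                 sigma2_resid = sr, n_years = n_years, n_blocks = n_blocks,
                 divisors = c(n_years, n_years * n_blocks)),
            class = "heritability")
}

#' @export
print.heritability <- function(x, ...) {
  cat(sprintf("h2 = %.4f  (sg2 = %g, sga2/%d = %g, sr2/%d = %g)\n",
              x$h2, x$sigma2_g, x$divisors[1], x$sigma2_gxy / x$divisors[1],
              x$divisors[2], x$sigma2_resid / x$divisors[2]))
  invisible(x)
}
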