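#' Simulate a plot-level multi-environment trial dataset
#'
#' Draws one trait observation per accession x year x block plot from the
#' all-random trial model y = mu + g + a + (ga) + b + (ba) + c + e. All
#' random effects are independent Normal(0, sigma2) draws except the
#' genotype effects, which are drawn jointly across traits from the given
#' genetic correlation structure, and the residuals, which may be
#' heteroscedastic by year and correlated across years within a
#' genotype-by-block cell (the repeated unit of a re-randomized trial).
#' Columns are nested in block-by-year: within each block of each year the
#' accessions are randomly split over `n_columns_per_block` columns.
#' Bounds and rounding grids from `traits` are applied after all effects
#' are summed. The same seed always yields an identical dataset.
#'
#' @param design A [trial_design()].
#' @param specs Named list of [variance_spec()], one per trait to simulate.
#' @param gcorr Optional [genetic_correlation()]; traits not listed in it
#'   get independent genotype effects.
#' @param traits Optional named list of [trait_spec()] supplying clamp
#'   bounds and rounding grids.
#' @param seed Integer seed; required, all randomness derives from it.
#' @param missing_frac Fraction of trait values set missing at random
#'   (default 0), for exercising unbalanced-data paths.
#' @param genotype_shifts Optional numeric matrix (accessions x traits,
#'   dimnames required) added to the genotype effects, e.g. to plant known
#'   superior accessions in a simulation study.
#' @return A long-format data frame of class `trial_data` with columns
#'   `accession`, `year`, `block`, `column`, `trait`, `value` and a
#'   `truth` attribute recording the generating parameters.
#' @examples
#' d <- generate_trial(trial_design(n_genotypes = 4),
#'                     list(y = variance_spec(mu = 10, sigma2_g = 2,
#'                                            sigma2_resid = 1)),
#'                     seed = 1)
#' nrow(d)  # 4 x 2 x 3 plots
#' @export
generate_trial <- function(design, specs, gcorr = NULL, traits = NULL,
                           seed, missing_frac = 0, genotype_shifts = NULL) {
  stopifnot(inherits(design, "trial_design"))
  if (missing(seed)) stop("a seed is required")
  if (design$n_genotypes < 1) stop("need at least one genotype")
  if (!length(specs) || is.null(names(specs)) || anyDuplicated(names(specs))) {
    stop("specs must be a uniquely named list of variance_spec objects")
  }
  lapply(specs, function(s) stopifnot(inherits(s, "variance_spec")))
  trait_names <- names(specs)
  ng <- design$n_genotypes; ny <- design$n_years; nb <- design$n_blocks
  ncol_b <- design$n_columns_per_block

  with_seed(seed, {
    # plot layout: one plot per genotype x year x block; random column
    # assignment within each block-by-year, balanced over columns
    plots <- expand.grid(accession = factor(design$genotype_labels,
                                            levels = design$genotype_labels),
                         year = factor(design$year_labels,
                                       levels = design$year_labels),
                         block = factor(seq_len(nb)),
                         KEEP.OUT.ATTRS = FALSE)
    col_of <- integer(nrow(plots))
    for (y in design$year_labels) for (b in seq_len(nb)) {
      idx <- which(plots$year == y & plots$block == b)
      col_of[idx] <- sample(rep_len(seq_len(ncol_b), length(idx)))
    }
    plots$column <- factor(paste0("y", plots$year, "_b", plots$block,
                                  "_c", col_of))

    # genotype effects, jointly across traits
    G <- matrix(stats::rnorm(ng * length(trait_names)), ng)
    colnames(G) <- trait_names
    if (!is.null(gcorr)) {
      stopifnot(inherits(gcorr, "genetic_correlation"))
      shared <- intersect(trait_names, gcorr$traits)
      if (length(shared) > 1) {
        R <- gcorr$mat[shared, shared]
        L <- tryCatch(chol(R + diag(1e-10, nrow(R))),
                      error = function(e) stop("genetic correlation matrix ",
                                               "is not positive semi-definite"))
        G[, shared] <- G[, shared] %*% L
      }
    }
    for (tn in trait_names) G[, tn] <- G[, tn] * sqrt(specs[[tn]]$sigma2_g)
    if (!is.null(genotype_shifts)) {
      stopifnot(is.matrix(genotype_shifts),
                !is.null(rownames(genotype_shifts)),
                !is.null(colnames(genotype_shifts)))
      for (tn in intersect(colnames(genotype_shifts), trait_names)) {
        i <- match(rownames(genotype_shifts), design$genotype_labels)
        G[i, tn] <- G[i, tn] + genotype_shifts[, tn]
      }
    }

    ia <- as.integer(plots$accession); iy <- as.integer(plots$year)
    ib <- as.integer(plots$block); ic <- as.integer(plots$column)
    cell <- (ia - 1) * nb + ib  # genotype-by-block cell, shared across years

    out <- vector("list", length(trait_names))
    for (k in seq_along(trait_names)) {
      tn <- trait_names[k]; s <- specs[[tn]]
      a  <- stats::rnorm(ny, 0, sqrt(s$sigma2_year))
      ga <- stats::rnorm(ng * ny, 0, sqrt(s$sigma2_gxy))
      b  <- stats::rnorm(nb, 0, sqrt(s$sigma2_block))
      ba <- stats::rnorm(nb * ny, 0, sqrt(s$sigma2_blockxyear))
      cc <- stats::rnorm(nlevels(plots$column), 0, sqrt(s$sigma2_column))
      ysc <- if (is.null(s$year_scale)) rep(1, ny) else rep_len(s$year_scale, ny)
      # residuals: MVN across years within each genotype-by-block cell
      sd_y <- sqrt(s$sigma2_resid) * ysc
      Sig <- tcrossprod(sd_y) * (s$rho + diag(1 - s$rho, ny))
      E <- matrix(stats::rnorm(ng * nb * ny), ng * nb)
      if (s$sigma2_resid > 0) {
        E <- E %*% chol(Sig + diag(1e-12 * max(sd_y^2, 1), ny))
      } else E[] <- 0
      val <- s$mu + G[ia, tn] + a[iy] + ga[(ia - 1) * ny + iy] + b[ib] +
        ba[(ib - 1) * ny + iy] + cc[ic] + E[cbind(cell, iy)]
      tsp <- traits[[tn]]
      if (!is.null(tsp)) {
        if (!is.null(tsp$rounding)) val <- round(val / tsp$rounding) * tsp$rounding
        if (!is.null(tsp$bounds)) val <- pmin(pmax(val, tsp$bounds[1]), tsp$bounds[2])
      }
      out[[k]] <- data.frame(plots, trait = tn, value = val,
                             stringsAsFactors = FALSE)
    }
    dat <- do.call(rbind, out)
    rownames(dat) <- NULL
    dat$trait <- factor(dat$trait, levels = trait_names)
    if (missing_frac > 0) {
      drop <- which(stats::runif(nrow(dat)) < missing_frac)
      dat$value[drop] <- NA_real_
    }
    attr(dat, "truth") <- list(design = unclass(design),
                               specs = lapply(specs, unclass),
                               seed = seed, missing_frac = missing_frac)
    class(dat) <- c("trial_data", "data.frame")
    dat
  })
}

#' Simulate the default 48-accession quinoa trial
#'
#' Convenience wrapper around [generate_trial()] with the package's quinoa
#' defaults: 48 accessions x 2 years x 3 blocks, thirteen traits at the
#' reference trial's variance-component magnitudes, correlated genotype
#' effects, and the default bounds/rounding.
#'
#' @param seed Integer seed.
#' @param design A [trial_design()]; default the 48 x 2 x 3 layout.
#' @param rho Residual cross-year correlation (default 0).
#' @param ... Passed on to [generate_trial()].
#' @return A `trial_data` data frame.
#' @export
simulate_quinoa_trial <- function(seed, design = trial_design(), rho = 0, ...) {
  generate_trial(design, quinoa_variance_specs(rho = rho),
                 gcorr = quinoa_genetic_correlation(),
                 traits = quinoa_trait_specs(), seed = seed, ...)
}

#' Per-trait summary statistics of a trial dataset
#'
#' Minimum, maximum, mean, SD and CV% (100 * SD / mean) per trait over all
#' plots, the usual first-look table of a multi-environment trial report.
#' Traits with no non-missing observations are dropped with a warning.
#'
#' @param data A `trial_data` long-format data frame.
#' @return Data frame with columns `trait`, `n`, `min`, `max`, `mean`,
#'   `sd`, `cv`.
#' @export
summarize_traits <- function(data) {
  stopifnot(all(c("trait", "value") %in% names(data)))
  res <- lapply(split(data$value, data$trait), function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NULL)
    m <- mean(v); s <- stats::sd(v)
    if (length(v) == 1) s <- 0
    data.frame(n = length(v), min = min(v), max = max(v), mean = m, sd = s,
               cv = if (m != 0) 100 * s / abs(m) else NA_real_)
  })
  empty <- names(res)[vapply(res, is.null, logical(1))]
  if (length(empty)) {
    warning("traits with no observations excluded: ",
            paste(empty, collapse = ", "))
    res <- res[!vapply(res, is.null, logical(1))]
  }
  if (!length(res)) stop("no non-missing observations in any trait")
  out <- do.call(rbind, res)
  out <- data.frame(trait = names(res), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}
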