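#' Published trait summaries from the reference quinoa trial
#'
#' Per-trait minimum, maximum, mean, SD and CV% observed in the published
#' two-year field trial of 48 quinoa accessions in northern Germany that
#' this package's simulation defaults emulate. Percent traits are on a
#' 0--100 scale, ordinal scores on their 1--9 / 1--5 scales, saponin as
#' afrosimetric foam-column height in mm.
#'
#' @return Data frame with columns `trait`, `min`, `max`, `mean`, `sd`, `cv`.
#' @export
quinoa_trait_summary <- function() {
  data.frame(
    trait = c("dtf", "emergence", "homogeneity", "panicle_length",
              "plant_height", "panicle_density", "panicle_shape",
              "stem_lodging", "mildew", "saponin", "tkw", "seed_yield"),
    min  = c(63, 19.25, 0, 10, 112.5, 1, 1, 0, 1, 0, 1.48, 0.18),
    max  = c(79, 100, 100, 62.5, 217.5, 7, 5, 100, 5, 21, 4.9, 5.8),
    mean = c(69.77, 48.45, 74.83, 33.37, 160, 4.71, 2.79, 24.29, 3.26,
             10.7, 2.42, 2.61),
    sd   = c(4.2, 15.54, 28.52, 7.9, 20.56, 1.23, 0.62, 26.7, 1.16, 5.82,
             0.35, 1.03),
    cv   = c(4.77, 12.4, 24.2, 5.02, 8.44, 17.05, 7.42, 54.9, 17.84,
             19.81, 10.86, 27.27),
    stringsAsFactors = FALSE
  )
}

#' Published variance components and heritabilities from the reference trial
#'
#' Genotype, year, genotype-by-year and residual variance components of the
#' all-random model, together with the published pseudo-R2 of the
#' fixed-effects model and the published entry-mean heritability, for the
#' twelve phenotyped traits of the reference quinoa trial.
#'
#' @return Data frame with columns `trait`, `sigma2_g`, `sigma2_year`,
#'   `sigma2_gxy`, `sigma2_resid`, `r2`, `h2`.
#' @export
quinoa_variance_components <- function() {
  data.frame(
    trait = c("dtf", "emergence", "homogeneity", "panicle_length",
              "plant_height", "panicle_density", "panicle_shape",
              "stem_lodging", "mildew", "saponin", "tkw", "seed_yield"),
    sigma2_g     = c(11.08, 36.19, 327.45, 2.80, 181.49, 0.64, 0.04,
                     177.18, 0.34, 4.43, 0.06, 0.51),
    sigma2_year  = c(0, 51.95, 0, 33.45, 69.82, 0.41, 0, 56.49, 0, 29.17,
                     0, 0.45),
    sigma2_gxy   = c(5.94, 55.58, 318.10, 11.85, 135.87, 0.27, 0.14,
                     319.73, 0.69, 5.48, 0.01, 0.11),
    sigma2_resid = c(0.95, 119.16, 155.44, 29.63, 56.58, 0.34, 0.21,
                     171.27, 0.31, 9.39, 0.02, 0.20),
    r2 = c(0.95, 0.62, 0.8, 0.31, 0.9, 0.77, 0.54, 0.77, 0.78, 0.86,
           0.99, 0.97),
    h2 = c(0.78, 0.43, 0.64, 0.2, 0.7, 0.77, 0.29, 0.48, 0.46, 0.51,
           0.86, 0.85),
    stringsAsFactors = FALSE
  )
}

#' Published per-year selection-index values from the reference trial
#'
#' Heritability-weighted selection-index values and rankings of the 48
#' accessions in each of the two trial years, as published. Used for
#' internal-consistency checks (the published year-stability table reports
#' the absolute difference of these two columns) since the underlying
#' plot-level data are not deposited.
#'
#' @return Data frame with columns `accession`, `name`, `index_2020`,
#'   `rank_2020`, `index_2021`, `rank_2021`.
#' @export
quinoa_index_reference <- function() {
  x <- data.frame(
    accession = c("QP-002", "QP-003", "QP-004", "QP-005", "QP-006", "QP-019",
      "QP-026", "QP-030", "QP-032", "QP-035", "QP-036", "QP-041", "QP-042",
      "QP-043", "QP-046", "QP-055", "QP-060", "QP-061", "QP-065", "QP-084",
      "QP-086", "QP-089", "QP-096", "QP-097", "QP-099", "QP-103", "QP-105",
      "QP-107", "QP-108", "QP-113", "QP-126", "QP-127", "QP-128", "QP-139",
      "QP-141", "QP-165", "QP-169", "QP-172", "QP-175", "QP-176", "QP-181",
      "QP-220", "QP-225", "QP-231", "QP-232", "QP-233", "QP-343", "QP-346"),
    name = c("Moroccan Yellow", "Bouchane-3", "PI-614889", "ICBA-Q5",
      "PI-614927", "E-DK-4", "Indian Quinoa", "PUC-mix-red", "BBR", "RU-5",
      "Regalona", "Ames-13721", "Ames-13745", "Oro-de-Valle", "Ames-13744",
      "PUC-mix-green", "Ames-13743", "BO-58", "Vikinga", "EMBRAPA-Brazil",
      "Nde-09", "RU-2", "PI-634923", "NSL-86649", "BO-29", "BO-03", "NL-6",
      "BO-32", "BO-31", "Redhead", "BO-30", "Bouchane-4", "PI-614883",
      "NSL-91567", "PI-634921", "BO-51", "D-11889", "PI-634919", "BO-63",
      "BO-42", "BO-11", "PI-634918", "Cherry-Vanilla", "Bouchane-2",
      "Bouchane-1", "ICBA-Q3", "PI-614886", "Titicaca"),
    index_2020 = c(-1.31, 2.38, -0.66, -1.2, -1.76, -2.07, -1.85, -3.15,
      -1.8, -1.03, -1.12, 1.06, -1.71, -2.06, -1.77, -0.66, -0.03, -1.21,
      1.72, 0.88, 1, -1.48, -1.53, -2.52, -0.92, 1.35, 2.49, -5.03, -2.38,
      -1.59, -1.21, 0.66, -2.64, -1.29, 0.34, -3.24, -1.2, -4.04, 2.43,
      -2.22, -0.96, -0.58, -0.99, -0.03, 0.25, -0.62, -2.01, 1.59),
    rank_2020 = c(29, 3, 18, 24, 34, 40, 37, 45, 36, 22, 23, 7, 33, 39, 35,
      17, 13, 27, 4, 9, 8, 30, 31, 43, 19, 6, 1, 48, 42, 32, 26, 10, 44,
      28, 11, 46, 25, 47, 2, 41, 20, 15, 21, 14, 12, 16, 38, 5),
    index_2021 = c(-0.53, 0.71, -0.28, -0.37, 2.93, -1.8, 1.8, -0.3, -0.64,
      0.77, -0.42, -0.25, -0.81, 1.25, 1.05, 0.92, 2.07, 0.25, 2.28, 3.48,
      3.02, 1.97, 0.77, 0.07, 2.29, 2.53, 4.31, -2.81, 1.65, 0.73, 1.25,
      1.52, 0.69, 0.26, 1.76, 0.83, 1.01, -1.18, 3.05, 0.62, 0.69, 0.2,
      -1.36, 1.26, 1.11, 2.1, -0.78, 3.54),
    rank_2021 = c(41, 28, 37, 39, 6, 47, 13, 38, 42, 26, 40, 36, 44, 19,
      21, 23, 11, 33, 9, 3, 5, 12, 25, 35, 8, 7, 1, 48, 15, 27, 18, 16,
      30, 32, 14, 24, 22, 45, 4, 31, 29, 34, 46, 17, 20, 10, 43, 2),
    stringsAsFactors = FALSE
  )
  x
}

#' Default trait metadata for the quinoa trial
#'
#' Selection direction, clamp bounds and measurement grid for the thirteen
#' simulated traits (the twelve phenotyped traits plus days to maturity).
#' Directions encode the breeding goal for temperate regions: early
#' flowering and maturity, short plants, low mildew susceptibility, lodging
#' and saponin; high emergence, homogeneity, panicle density, thousand
#' kernel weight and seed yield; short compact panicles.
#'
#' @return Named list of [trait_spec()] objects.
#' @export
quinoa_trait_specs <- function() {
  sp <- list(
    trait_spec("dtf", "lower_is_better", rounding = 1),
    trait_spec("dtm", "lower_is_better", rounding = 1),
    trait_spec("emergence", "higher_is_better", bounds = c(0, 100)),
    trait_spec("homogeneity", "higher_is_better", bounds = c(0, 100)),
    trait_spec("panicle_length", "lower_is_better", bounds = c(0, Inf)),
    trait_spec("plant_height", "lower_is_better", bounds = c(0, Inf)),
    trait_spec("panicle_density", "higher_is_better", bounds = c(1, 9)),
    trait_spec("panicle_shape", "lower_is_better", bounds = c(1, 5)),
    trait_spec("stem_lodging", "lower_is_better", bounds = c(0, 100)),
    trait_spec("mildew", "lower_is_better", bounds = c(1, 5)),
    trait_spec("saponin", "lower_is_better", bounds = c(0, Inf)),
    trait_spec("tkw", "higher_is_better", bounds = c(0, Inf)),
    trait_spec("seed_yield", "higher_is_better", bounds = c(0, Inf))
  )
  names(sp) <- vapply(sp, `[[`, character(1), "name")
  sp
}

#' Traits entering the default selection index
#'
#' The six agronomically most important traits for adaptation to temperate
#' regions, weighted by their heritabilities in the default index.
#' @return Character vector of trait names.
#' @export
quinoa_index_traits <- function() {
  c("tkw", "seed_yield", "dtf", "plant_height", "mildew", "saponin")
}

#' Default variance specifications for simulating the quinoa trial
#'
#' One [variance_spec()] per trait, with genotype, year, genotype-by-year
#' and residual variances equal to the reference trial's published
#' components ([quinoa_variance_components()]) and trait means equal to the
#' published means ([quinoa_trait_summary()]). Block, block-by-year and
#' column variances default to zero (they are nuisance terms not reported
#' for the reference trial). Days to maturity, absent from the published
#' component table, uses plausible values for early-maturing accessions in
#' northern Germany (mean 130 d, sigma2_g 20, sigma2_gxy 8, sigma2_resid 4).
#'
#' @param rho Residual cross-year correlation within genotype-by-block
#'   cells, shared by all traits (default 0).
#' @return Named list of [variance_spec()] objects.
#' @export
quinoa_variance_specs <- function(rho = 0) {
  vc <- quinoa_variance_components()
  ts <- quinoa_trait_summary()
  sp <- lapply(seq_len(nrow(vc)), function(i) {
    variance_spec(mu = ts$mean[match(vc$trait[i], ts$trait)],
                  sigma2_g = vc$sigma2_g[i], sigma2_year = vc$sigma2_year[i],
                  sigma2_gxy = vc$sigma2_gxy[i],
                  sigma2_resid = vc$sigma2_resid[i], rho = rho)
  })
  names(sp) <- vc$trait
  sp$dtm <- variance_spec(mu = 130, sigma2_g = 20, sigma2_year = 0,
                          sigma2_gxy = 8, sigma2_resid = 4, rho = rho)
  sp[c("dtf", "dtm", setdiff(names(sp), c("dtf", "dtm")))]
}

#' Default genetic correlation structure among the simulated traits
#'
#' Correlations among genotype effects chosen to emulate the published
#' per-year phenotypic correlation pattern of the reference trial: days to
#' flowering, days to maturity and plant height positively intercorrelated;
#' seed yield positively correlated with DTF, DTM, TKW and panicle density;
#' mildew susceptibility and stem lodging negatively correlated with seed
#' yield and with phenological earliness; saponin higher in later, higher
#' yielding accessions.
#'
#' @return A [genetic_correlation()] over the thirteen default traits.
#' @export
quinoa_genetic_correlation <- function() {
  tr <- names(quinoa_variance_specs())
  m <- diag(length(tr))
  dimnames(m) <- list(tr, tr)
  set2 <- function(a, b, v) {
    m[a, b] <<- v
    m[b, a] <<- v
  }
  set2("dtf", "dtm", 0.80)
  set2("dtf", "plant_height", 0.50)
  set2("dtm", "plant_height", 0.50)
  set2("dtf", "seed_yield", 0.40)
  set2("dtm", "seed_yield", 0.40)
  set2("tkw", "seed_yield", 0.40)
  set2("panicle_density", "seed_yield", 0.30)
  set2("mildew", "seed_yield", -0.40)
  set2("stem_lodging", "seed_yield", -0.35)
  set2("mildew", "dtf", -0.40)
  set2("mildew", "dtm", -0.40)
  set2("saponin", "dtf", 0.30)
  set2("saponin", "seed_yield", 0.30)
  ev <- eigen(m, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    # project to the nearest PSD correlation matrix (eigenvalue clipping)
    v <- pmax(ev$values, 1e-8)
    m <- ev$vectors %*% diag(v) %*% t(ev$vectors)
    s <- sqrt(diag(m))
    m <- m / tcrossprod(s)
    dimnames(m) <- list(tr, tr)
  }
  genetic_correlation(tr, m)
}
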