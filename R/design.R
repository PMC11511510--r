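#' Build design matrices for the single-trait trial models
#'
#' Extracts one trait from a long-format trial dataset into plot-level form
#' and constructs the response vector, the fixed-effects matrix and the
#' random-effect incidence matrices of either trial model: the fixed-G-x-Y
#' model (fixed accession, year and accession-by-year, random block) or the
#' all-random model (random accession, year, accession-by-year, block,
#' block-by-year and column). Fixed effects use reference-level (treatment)
#' coding on the first accession and first year; accession levels follow
#' the input label order. All reported downstream quantities (cell means,
#' contrasts, ANOVA F statistics) are coding-invariant.
#'
#' @param data A `trial_data` long-format data frame.
#' @param trait Trait name to model.
#' @param model `"fixed_gxe"` (fixed genotype/year/G-x-Y, random block) or
#'   `"all_random"` (all effects random, used for heritability).
#' @param residual_structure Residual model for `fixed_gxe`:
#'   `"hetero_corr"` (per-year variances plus cross-year correlation within
#'   genotype-by-block cells, the default), `"hetero"`, or `"iid"`.
#' @return An object of class `met_design`: list with the plot-level data,
#'   response `y`, fixed matrix `X`, named list `Z` of incidence matrices,
#'   a coefficient map, and the accession-by-year cell-mean map `M`.
#' @export
build_design <- function(data, trait,
                         model = c("fixed_gxe", "all_random"),
                         residual_structure = c("hetero_corr", "hetero", "iid")) {
  model <- match.arg(model)
  residual_structure <- match.arg(residual_structure)
  stopifnot(all(c("accession", "year", "block", "trait", "value") %in% names(data)))
  if (!trait %in% as.character(unique(data$trait))) {
    stop("trait '", trait, "' not present in data")
  }
  d <- data[data$trait == trait & !is.na(data$value), , drop = FALSE]
  plot <- data.frame(
    accession = droplevels(factor(d$accession)),
    year = droplevels(factor(d$year)),
    block = droplevels(factor(d$block)),
    y = d$value
  )
  if ("column" %in% names(d)) plot$column <- droplevels(factor(d$column))
  if (nlevels(plot$accession) < 2) stop("need at least 2 accessions")
  if (model == "fixed_gxe" && nlevels(plot$year) < 2) {
    stop("fixed_gxe includes an accession-by-year term; ",
         "single-year data cannot identify it")
  }
  plot$gxy <- interaction(plot$accession, plot$year, drop = TRUE, sep = ":")
  plot$block_year <- interaction(plot$block, plot$year, drop = TRUE, sep = ":")
  plot$cell_gb <- interaction(plot$block, plot$accession, drop = TRUE, sep = ":")

  incidence <- function(f) {
    m <- matrix(0, length(f), nlevels(f),
                dimnames = list(NULL, levels(f)))
    m[cbind(seq_along(f), as.integer(f))] <- 1
    m
  }
  if (model == "fixed_gxe") {
    X <- stats::model.matrix(~ accession * year, plot)
    Z <- list(block = incidence(plot$block))
  } else {
    X <- stats::model.matrix(~ 1, plot)
    Z <- list(
      genotype = incidence(plot$accession),
      year = incidence(plot$year),
      gxy = incidence(plot$gxy),
      block = incidence(plot$block),
      block_year = incidence(plot$block_year),
      column = if (!is.null(plot$column)) incidence(plot$column) else NULL
    )
    Z <- Z[!vapply(Z, is.null, logical(1))]
  }

  # bijective map from fixed-coefficient name to (factor, level)
  coef_map <- coef_factor_map(colnames(X), plot)

  cells <- expand.grid(accession = factor(levels(plot$accession),
                                          levels = levels(plot$accession)),
                       year = factor(levels(plot$year),
                                     levels = levels(plot$year)),
                       KEEP.OUT.ATTRS = FALSE)
  M <- if (model == "fixed_gxe") stats::model.matrix(~ accession * year, cells)
       else NULL

  structure(list(plot = plot, trait = trait, model = model,
                 residual_structure = residual_structure,
                 y = plot$y, X = X, Z = Z, coef_map = coef_map,
                 cells = cells, M = M),
            class = "met_design")
}

coef_factor_map <- function(cn, plot) {
  acc <- levels(plot$accession); yr <- levels(plot$year)
  map <- data.frame(coef = cn, factor = NA_character_, level = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(cn)) {
    nm <- cn[i]
    if (nm == "(Intercept)") {
      map$factor[i] <- "intercept"
      map$level[i] <- paste(acc[1], yr[1], sep = ":")
    } else if (grepl(":", nm, fixed = TRUE)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      map$factor[i] <- "accession:year"
      map$level[i] <- paste(sub("^accession", "", parts[1]),
                            sub("^year", "", parts[2]), sep = ":")
    } else if (startsWith(nm, "accession")) {
      map$factor[i] <- "accession"
      map$level[i] <- sub("^accession", "", nm)
    } else if (startsWith(nm, "year")) {
      map$factor[i] <- "year"
      map$level[i] <- sub("^year", "", nm)
    }
  }
  map
}
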