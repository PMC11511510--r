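#' Pipeline configuration
#'
#' Bundles the settings of a full trial analysis: trait metadata, index
#' composition, design constants, contrast settings and output directory.
#'
#' @param traits Named list of [trait_spec()] (default the quinoa set).
#' @param index_traits Traits entering the selection index (default the
#'   six quinoa index traits); must be a subset of `traits`.
#' @param n_years,n_blocks Design constants used in the heritability
#'   divisors (defaults 2 and 3).
#' @param alpha Strictly decreasing significance ladder (default
#'   0.05, 0.01, 0.001); the first entry is the selection / stability
#'   threshold.
#' @param mc_draws Monte-Carlo draws for [adjust_maxt()] (default 1e5).
#' @param seed Integer seed governing all randomness in the run.
#' @param residual_structure Preferred residual structure for the
#'   fixed-G-x-Y model (see [build_design()]).
#' @param k Number of accessions to select (default 10).
#' @param out_dir Output directory for the stage tables and manifest.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(traits = quinoa_trait_specs(),
                            index_traits = quinoa_index_traits(),
                            n_years = 2, n_blocks = 3,
                            alpha = c(0.05, 0.01, 0.001),
                            mc_draws = 1e5, seed = 1,
                            residual_structure = "hetero_corr",
                            k = 10, out_dir = tempfile("metsel_run_")) {
  if (!all(index_traits %in% names(traits))) {
    stop("index_traits must be a subset of the named traits")
  }
  if (any(diff(alpha) >= 0)) stop("alpha ladder must be strictly decreasing")
  structure(list(traits = traits, index_traits = index_traits,
                 n_years = n_years, n_blocks = n_blocks, alpha = alpha,
                 mc_draws = mc_draws, seed = seed,
                 residual_structure = residual_structure, k = k,
                 out_dir = out_dir), class = "pipeline_config")
}

#' Run the full trial-analysis pipeline
#'
#' Executes, in order: (1) fixed-G-x-Y model fits per trait with ANOVA and
#' pseudo-R2; (2) per-year Pearson correlations; (3) all-random model fits
#' and entry-mean heritability per trait; (4) trait standardization and
#' the heritability-weighted selection index with per-year ranking;
#' (5) refit of the plot-level index through the fixed-G-x-Y model and
#' year-stability contrasts; (6) grand-mean-difference tests for the index
#' traits and the index, per year; (7) accession selection. Each stage
#' writes a CSV to `config$out_dir` and a JSON manifest records the
#' configuration, seed and stage outputs; identical config, data and seed
#' give byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param data A `trial_data` long data frame.
#' @return Invisibly, a list with every stage result (`anova`,
#'   `correlations`, `heritability`, `index`, `stability`, `gmd`,
#'   `selection`, `manifest`).
#' @export
run_pipeline <- function(config, data) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  traits <- intersect(names(config$traits), as.character(unique(data$trait)))
  if (!length(traits)) stop("stage single_trait_models: no configured trait ",
                            "present in the data")
  years <- levels(factor(data$year))
  alpha1 <- config$alpha[1]
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  res <- list()
  files <- character()

  # 1: single-trait fixed-G-x-Y fits, ANOVA, pseudo-R2
  fits <- list(); designs <- list()
  anova_tab <- stage("single_trait_models", {
    rows <- lapply(traits, function(tn) {
      dm <- build_design(data, tn, "fixed_gxe", config$residual_structure)
      ft <- reml_fit(dm)
      designs[[tn]] <<- dm; fits[[tn]] <<- ft
      an <- wald_anova(ft, dm)
      data.frame(trait = tn, term = an$term, F = an$F, df1 = an$df1,
                 df2 = an$df2, p = an$p, pseudo_r2 = pseudo_r2(ft),
                 residual_structure = ft$structure_used,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  files["anova"] <- write_stage(anova_tab, config, "01_anova.csv")
  res$anova <- anova_tab

  # 2: per-year Pearson correlations
  res$correlations <- stage("correlations", {
    lapply(stats::setNames(years, years), function(y)
      pearson_ci(data, traits = traits, year = y))
  })
  for (y in years) {
    files[paste0("correlations_", y)] <-
      write_stage(res$correlations[[y]], config,
                  paste0("02_correlations_", y, ".csv"))
  }

  # 3: all-random fits and heritability
  h2_tab <- stage("heritability", {
    rows <- lapply(traits, function(tn) {
      dm2 <- build_design(data, tn, "all_random")
      ft2 <- reml_fit(dm2)
      h <- estimate_heritability(ft2$vc, config$n_years, config$n_blocks)
      data.frame(trait = tn, sigma2_g = h$sigma2_g, sigma2_gxy = h$sigma2_gxy,
                 sigma2_resid = h$sigma2_resid,
                 sigma2_year = unname(ft2$vc$components["year"]),
                 h2 = h$h2, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  files["heritability"] <- write_stage(h2_tab, config, "03_heritability.csv")
  res$heritability <- h2_tab

  # 4: standardization and selection index
  idx <- stage("selection_index", {
    means <- do.call(rbind, lapply(config$index_traits, function(tn) {
      if (!tn %in% traits) stop("index trait '", tn, "' absent from data")
      adjusted_cell_means(fits[[tn]], designs[[tn]])
    }))
    std <- standardize_orient(means, config$traits)
    w <- stats::setNames(h2_tab$h2, h2_tab$trait)[config$index_traits]
    list(means = means, std = std,
         table = selection_index(std, w, config$index_traits))
  })
  res$index <- idx$table
  idx_wide <- stats::reshape(
    data.frame(accession = as.character(idx$table$accession),
               year = as.character(idx$table$year),
               index = round(idx$table$index, 4), rank = idx$table$rank),
    idvar = "accession", timevar = "year", direction = "wide")
  files["index"] <- write_stage(idx_wide, config, "04_selection_index.csv")

  # 5: index as an additional trait -> year-stability contrasts
  stab <- stage("index_stability", {
    w <- stats::setNames(h2_tab$h2, h2_tab$trait)[config$index_traits]
    pli <- plot_level_index(data, idx$means, config$traits, w,
                            config$index_traits)
    dm_i <- build_design(pli, "selection_index", "fixed_gxe",
                         config$residual_structure)
    ft_i <- reml_fit(dm_i)
    yc <- year_contrasts(ft_i, dm_i, alpha = alpha1,
                         mc_draws = config$mc_draws, seed = config$seed)
    list(fit = ft_i, dm = dm_i, yc = yc,
         table = index_stability(idx$table, yc))
  })
  res$stability <- stab$table
  stab_out <- data.frame(accession = stab$table$accession,
                         index_diff = round(abs(stab$table$index_diff), 4),
                         p_adj = round(stab$table$p_adj, 4),
                         stable = stab$table$stable)
  files["stability"] <- write_stage(stab_out, config, "05_stability.csv")

  # 6: grand-mean differences for index traits and the index
  gmd <- stage("grand_mean_differences", {
    gl <- list()
    for (tn in config$index_traits) {
      gl[[tn]] <- lapply(stats::setNames(years, years), function(y)
        grand_mean_contrasts(fits[[tn]], designs[[tn]], y,
                             mc_draws = config$mc_draws, seed = config$seed))
    }
    gl$selection_index <- lapply(stats::setNames(years, years), function(y)
      grand_mean_contrasts(stab$fit, stab$dm, y,
                           mc_draws = config$mc_draws, seed = config$seed))
    gl
  })
  flags <- gmd_flags(gmd, config$traits, alpha = alpha1)
  res$gmd <- flags
  gmd_out <- do.call(rbind, lapply(names(gmd), function(tn) {
    do.call(rbind, lapply(names(gmd[[tn]]), function(y) {
      g <- gmd[[tn]][[y]]
      data.frame(trait = tn, year = y, accession = g$hypothesis,
                 gmd = round(g$estimate, 4), p_adj = round(g$p_adj, 4),
                 stars = g$stars, stringsAsFactors = FALSE)
    }))
  }))
  files["gmd"] <- write_stage(gmd_out, config, "06_gmd.csv")

  # 7: selection
  sel <- stage("selection", {
    select_accessions(flags, stab$table, idx$table, k = config$k)
  })
  res$selection <- sel
  files["selection"] <- write_stage(as.data.frame(sel), config,
                                    "07_selection.csv")

  manifest <- list(
    package = "metsel",
    version = as.character(utils::packageVersion("metsel")),
    seed = config$seed,
    config = list(index_traits = config$index_traits,
                  n_years = config$n_years, n_blocks = config$n_blocks,
                  alpha = config$alpha, mc_draws = config$mc_draws,
                  residual_structure = config$residual_structure,
                  k = config$k),
    stages = list(
      single_trait_models = basename(files[["anova"]]),
      correlations = unname(basename(files[grep("^correlations_",
                                                names(files))])),
      heritability = basename(files[["heritability"]]),
      selection_index = basename(files[["index"]]),
      index_stability = basename(files[["stability"]]),
      grand_mean_differences = basename(files[["gmd"]]),
      selection = basename(files[["selection"]])
    ),
    md5 = as.list(unname(tools::md5sum(files)))
  )
  names(manifest$md5) <- basename(files)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

write_stage <- function(df, config, filename) {
  path <- file.path(config$out_dir, filename)
  utils::write.csv(df, path, row.names = FALSE)
  path
}
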