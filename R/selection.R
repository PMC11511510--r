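#' Accession-by-year adjusted means from a fixed-G-x-Y fit
#'
#' Extracts the model-estimated cell means (equal to arithmetic cell means
#' on balanced data) as a long data frame, the input to trait
#' standardization for the selection index.
#'
#' @param fit A `met_fit` of a `fixed_gxe` design.
#' @param dm The matching `met_design`.
#' @return Data frame with columns `accession`, `year`, `trait`, `value`.
#' @export
adjusted_cell_means <- function(fit, dm) {
  cm <- cell_mean_estimates(fit, dm)
  data.frame(accession = cm$cells$accession, year = cm$cells$year,
             trait = dm$trait, value = cm$mu, stringsAsFactors = FALSE)
}

#' Standardize and orient trait means for index construction
#'
#' Z-scores each trait within each year across accessions (sample SD,
#' n - 1 denominator) and flips the sign for lower-is-better traits, so
#' that larger oriented values are always desirable.
#'
#' @param means Long data frame of adjusted means: `accession`, `year`,
#'   `trait`, `value` (e.g. row-bound [adjusted_cell_means()] output).
#' @param specs Named list of [trait_spec()] giving each trait's direction.
#' @return Data frame of class `standardized_traits` with added columns
#'   `z` and `oriented`.
#' @export
standardize_orient <- function(means, specs) {
  stopifnot(all(c("accession", "year", "trait", "value") %in% names(means)))
  means$trait <- as.character(means$trait)
  for (tn in unique(means$trait)) {
    if (is.null(specs[[tn]])) stop("no trait_spec (direction) for '", tn, "'")
  }
  key <- interaction(means$year, means$trait, drop = TRUE)
  if (min(table(key)) < 2) stop("need at least 2 accessions per year x trait")
  z <- numeric(nrow(means))
  for (k in levels(key)) {
    i <- which(key == k)
    s <- stats::sd(means$value[i])
    if (s == 0) {
      stop("zero standard deviation for trait '", means$trait[i[1]],
           "' in year ", means$year[i[1]])
    }
    z[i] <- (means$value[i] - mean(means$value[i])) / s
  }
  means$z <- z
  sgn <- vapply(means$trait, function(tn)
    if (specs[[tn]]$direction == "lower_is_better") -1 else 1, numeric(1))
  means$oriented <- means$z * sgn
  class(means) <- c("standardized_traits", "data.frame")
  means
}

#' Heritability-weighted selection index
#'
#' For each accession and year, the index
#' \deqn{I = \sum_m h_m^2 \, \tilde y_m,}
#' the sum over the index traits of the oriented standardized trait value
#' weighted by that trait's entry-mean heritability. The same weights are
#' applied in every year. Accessions are ranked per year by descending
#' index; ties are broken by accession label order.
#'
#' @param std A `standardized_traits` data frame from
#'   [standardize_orient()].
#' @param h2 Named numeric vector of heritabilities (weights), or a list
#'   of [estimate_heritability()] results named by trait.
#' @param index_traits Traits to include; default all traits in `h2`.
#' @return Data frame of class `index_table`: `accession`, `year`,
#'   `index`, `rank`, with the weights in the `weights` attribute.
#' @export
selection_index <- function(std, h2, index_traits = NULL) {
  if (is.list(h2) && !is.data.frame(h2)) {
    h2 <- vapply(h2, function(x) if (inherits(x, "heritability")) x$h2
                 else as.numeric(x), numeric(1))
  }
  if (is.null(index_traits)) index_traits <- names(h2)
  miss_w <- setdiff(index_traits, names(h2))
  if (length(miss_w)) stop("no heritability weight for: ",
                           paste(miss_w, collapse = ", "))
  w <- h2[index_traits]
  s <- std[std$trait %in% index_traits, , drop = FALSE]
  keys <- unique(s[, c("accession", "year")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- s$accession == keys$accession[i] & s$year == keys$year[i]
    have <- s$trait[sel]
    miss <- setdiff(index_traits, have)
    if (length(miss)) {
      stop("accession ", keys$accession[i], ", year ", keys$year[i],
           " is missing index trait(s): ", paste(miss, collapse = ", "))
    }
    ori <- stats::setNames(s$oriented[sel], s$trait[sel])[index_traits]
    data.frame(accession = keys$accession[i], year = keys$year[i],
               index = sum(w * ori), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rank <- NA_integer_
  acc_ord <- if (is.factor(out$accession)) as.integer(out$accession)
             else match(out$accession, unique(out$accession))
  for (y in unique(out$year)) {
    i <- which(out$year == y)
    out$rank[i][order(-out$index[i], acc_ord[i])] <- seq_along(i)
  }
  attr(out, "weights") <- w
  class(out) <- c("index_table", "data.frame")
  out
}

#' Plot-level selection-index values
#'
#' Applies the index construction to individual plot observations, using
#' the within-year standardization (mean and SD of the accession-level
#' adjusted means) so that the accession-by-year cell means of the
#' plot-level index reproduce the accession-level index on balanced data.
#' The result is a `trial_data` long dataset with the index as a single
#' additional trait, ready to be refitted through the fixed-G-x-Y model
#' for grand-mean and year-stability testing.
#'
#' @param data A `trial_data` long data frame with the raw plot values.
#' @param means Adjusted accession-by-year means of the index traits (as
#'   fed to [standardize_orient()]).
#' @param specs Named list of [trait_spec()].
#' @param h2 Named heritability weights (see [selection_index()]).
#' @param index_traits Traits entering the index.
#' @return A `trial_data` data frame with `trait == "selection_index"`.
#' @export
plot_level_index <- function(data, means, specs, h2, index_traits) {
  if (is.list(h2) && !is.data.frame(h2)) {
    h2 <- vapply(h2, function(x) if (inherits(x, "heritability")) x$h2
                 else as.numeric(x), numeric(1))
  }
  w <- h2[index_traits]
  # standardization constants per year x trait from the adjusted means
  const <- list()
  for (y in unique(as.character(means$year))) {
    for (tn in index_traits) {
      v <- means$value[as.character(means$year) == y & means$trait == tn]
      if (!length(v)) stop("no adjusted means for trait '", tn,
                           "' in year ", y)
      s <- stats::sd(v)
      if (s == 0) stop("zero SD for trait '", tn, "' in year ", y)
      sgn <- if (specs[[tn]]$direction == "lower_is_better") -1 else 1
      const[[paste(y, tn)]] <- c(mean = mean(v), sd = s, sign = sgn)
    }
  }
  d <- data[as.character(data$trait) %in% index_traits, , drop = FALSE]
  if (any(is.na(d$value))) stop("missing plot values in index traits; ",
                                "no silent imputation is performed")
  key <- paste(as.character(d$year), as.character(d$trait))
  cs <- do.call(rbind, const[key])
  zo <- cs[, "sign"] * (d$value - cs[, "mean"]) / cs[, "sd"]
  d$contrib <- zo * w[as.character(d$trait)]
  agg <- stats::aggregate(contrib ~ accession + year + block + column,
                          data = d, FUN = sum)
  n_tr <- stats::aggregate(contrib ~ accession + year + block + column,
                           data = d, FUN = length)
  if (any(n_tr$contrib != length(index_traits))) {
    stop("some plots lack observations for all index traits")
  }
  out <- data.frame(accession = agg$accession, year = agg$year,
                    block = agg$block, column = agg$column,
                    trait = "selection_index", value = agg$contrib,
                    stringsAsFactors = FALSE)
  class(out) <- c("trial_data", "data.frame")
  out
}

#' Year-stability flags for the selection index
#'
#' Joins the year-contrast test of the plot-level selection index back to
#' the index table: an accession is stable when the family-wise adjusted
#' p-value of its between-year index difference is >= the threshold used
#' in [year_contrasts()].
#'
#' @param index An `index_table` from [selection_index()].
#' @param yc A `met_contrasts` result of [year_contrasts()] applied to the
#'   selection index refitted as a trait.
#' @return Data frame with one row per accession: `accession`,
#'   `index_diff` (estimated year difference), `p_adj`, `stable`.
#' @export
index_stability <- function(index, yc) {
  stopifnot(inherits(yc, "met_contrasts"), "stable" %in% names(yc))
  acc <- unique(as.character(index$accession))
  i <- match(acc, yc$hypothesis)
  if (anyNA(i)) stop("year contrasts missing for: ",
                     paste(acc[is.na(i)], collapse = ", "))
  data.frame(accession = acc, index_diff = yc$estimate[i],
             p_adj = yc$p_adj[i], stable = yc$stable[i],
             stringsAsFactors = FALSE)
}

#' Assemble favorable-GMD flags from per-trait contrast results
#'
#' Converts grand-mean contrast results for several traits and years into
#' per accession x trait x year flags: `favorable` when the GMD is
#' significant in the desired direction, `unfavorable` when significant in
#' the undesired direction.
#'
#' @param gmd_list Nested list: `gmd_list[[trait]][[year]]` is the
#'   [grand_mean_contrasts()] result for that trait and year.
#' @param specs Named list of [trait_spec()] (directions); the trait
#'   `"selection_index"` is treated as higher-is-better.
#' @param alpha Significance threshold on adjusted p-values (default 0.05).
#' @return Data frame: `accession`, `trait`, `year`, `estimate`, `p_adj`,
#'   `favorable`, `unfavorable`.
#' @export
gmd_flags <- function(gmd_list, specs, alpha = 0.05) {
  rows <- list()
  for (tn in names(gmd_list)) {
    sgn <- if (tn == "selection_index") 1
           else if (specs[[tn]]$direction == "lower_is_better") -1 else 1
    for (y in names(gmd_list[[tn]])) {
      g <- gmd_list[[tn]][[y]]
      rows[[paste(tn, y)]] <- data.frame(
        accession = g$hypothesis, trait = tn, year = y,
        estimate = g$estimate, p_adj = g$p_adj,
        favorable = g$p_adj < alpha & sgn * g$estimate > 0,
        unfavorable = g$p_adj < alpha & sgn * g$estimate < 0,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select the best-adapted accessions
#'
#' Scores every accession from its grand-mean-difference record and picks
#' the top `k`. The scoring rule, stated so it can be audited or
#' reweighted: each trait contributes the number of years with a
#' significant favorable GMD, but only if the accession has no significant
#' unfavorable GMD for that trait in the other year (a trait with
#' conflicting significant directions across years contributes the
#' negative of its unfavorable count); accessions are ordered by total
#' score, then by stability of the selection index, then by mean index
#' rank across years, then by label order.
#'
#' @param flags Output of [gmd_flags()] covering the criteria traits
#'   (typically the six index traits plus `"selection_index"`).
#' @param stability Output of [index_stability()].
#' @param index An `index_table` from [selection_index()].
#' @param k Number of accessions to select (default 10).
#' @return Data frame of class `selection_report`, one row per accession
#'   ordered best-first: `accession`, `score`, `n_favorable`,
#'   `n_unfavorable`, `stable`, `mean_rank`, `selected`, `rationale`.
#' @export
select_accessions <- function(flags, stability, index, k = 10) {
  acc <- unique(as.character(index$accession))
  if (k > length(acc)) stop("k = ", k, " exceeds the ", length(acc),
                            " available accessions")
  per_acc <- lapply(acc, function(a) {
    f <- flags[flags$accession == a, , drop = FALSE]
    sc <- 0; fav_tr <- character(); unf_tr <- character()
    for (tn in unique(f$trait)) {
      ft <- f[f$trait == tn, ]
      nf <- sum(ft$favorable); nu <- sum(ft$unfavorable)
      if (nu == 0) {
        sc <- sc + nf
        if (nf > 0) fav_tr <- c(fav_tr, paste0(tn, " (", nf, "y)"))
      } else {
        sc <- sc - nu
        unf_tr <- c(unf_tr, tn)
      }
    }
    st <- stability$stable[match(a, stability$accession)]
    mr <- mean(index$rank[as.character(index$accession) == a])
    rationale <- paste0(
      if (length(fav_tr)) paste("favorable GMD:", paste(fav_tr, collapse = ", "))
      else "no significant favorable GMD",
      if (length(unf_tr)) paste0("; unfavorable/inconsistent: ",
                                 paste(unf_tr, collapse = ", ")) else "",
      "; index stability: ", ifelse(isTRUE(st), "stable", "unstable"),
      "; mean index rank ", round(mr, 1))
    data.frame(accession = a, score = sc,
               n_favorable = sum(f$favorable),
               n_unfavorable = sum(f$unfavorable),
               stable = isTRUE(st), mean_rank = mr, rationale = rationale,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_acc)
  ord <- order(-out$score, -as.integer(out$stable), out$mean_rank,
               match(out$accession, acc))
  out <- out[ord, , drop = FALSE]
  out$selected <- seq_len(nrow(out)) <= k
  rownames(out) <- NULL
  class(out) <- c("selection_report", "data.frame")
  attr(out, "k") <- k
  out
}
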