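make_means <- function(vals, trait = "t", year = "2020") {
  data.frame(accession = sprintf("A%02d", seq_along(vals)), year = year,
             trait = trait, value = vals, stringsAsFactors = FALSE)
}

spec1 <- function(direction = "higher_is_better") {
  stats::setNames(list(trait_spec("t", direction)), "t")
}

test_that("z-scoring uses the n-1 SD and respects orientation", {
  std <- standardize_orient(make_means(c(1, 3)), spec1())
  expect_equal(std$z, c(-1, 1) / sqrt(2))
  expect_equal(std$oriented, std$z)
  std_low <- standardize_orient(make_means(c(1, 3)), spec1("lower_is_better"))
  expect_equal(std_low$oriented, -std_low$z)
  # smallest raw value gets the largest oriented score
  expect_equal(which.max(std_low$oriented), which.min(c(1, 3)))
})

test_that("standardization is location invariant and rejects constant traits", {
  v <- c(2, 5, 9, 4)
  s1 <- standardize_orient(make_means(v), spec1())
  s2 <- standardize_orient(make_means(v + 100), spec1())
  expect_equal(s1$z, s2$z)
  expect_error(standardize_orient(make_means(rep(3, 4)), spec1()),
               "zero standard deviation")
  expect_error(standardize_orient(make_means(v), list()), "no trait_spec")
})

test_that("the index is the heritability-weighted sum of oriented scores", {
  w <- c(tkw = 0.86, seed_yield = 0.85, dtf = 0.78, plant_height = 0.70,
         mildew = 0.46, saponin = 0.51)
  std <- do.call(rbind, lapply(names(w), function(tn) {
    data.frame(accession = c("A", "B"), year = "2020", trait = tn,
               value = 0, z = c(1, -1), oriented = c(1, -1),
               stringsAsFactors = FALSE)
  }))
  class(std) <- c("standardized_traits", "data.frame")
  idx <- selection_index(std, w)
  # accession with every oriented z at +1 scores the sum of the weights
  expect_equal(idx$index[idx$accession == "A"], 4.16)
  expect_equal(idx$index[idx$accession == "B"], -4.16)
  expect_equal(sort(idx$rank), c(1L, 2L))
  # zero oriented scores give a zero index
  std0 <- std; std0$oriented <- 0
  expect_true(all(selection_index(std0, w)$index == 0))
  # missing trait for an accession is an error, not an imputation
  expect_error(selection_index(std[std$trait != "dtf" | std$accession != "A", ], w),
               "missing index trait")
})

test_that("the index is invariant to affine rescaling of a raw trait", {
  vals <- c(10, 14, 11, 19, 16)
  m1 <- rbind(make_means(vals, "a"), make_means(c(3, 7, 5, 2, 8), "b"))
  m2 <- rbind(make_means(vals * 12 - 40, "a"), make_means(c(3, 7, 5, 2, 8), "b"))
  specs <- stats::setNames(list(trait_spec("a"), trait_spec("b")), c("a", "b"))
  w <- c(a = 0.8, b = 0.5)
  i1 <- selection_index(standardize_orient(m1, specs), w)
  i2 <- selection_index(standardize_orient(m2, specs), w)
  expect_equal(i1$index, i2$index)
  # recomputing I from stored oriented scores reproduces the stored index
  s1 <- standardize_orient(m1, specs)
  manual <- tapply(s1$oriented * w[s1$trait], s1$accession, sum)
  expect_equal(as.numeric(manual[as.character(i1$accession)]), i1$index)
})

test_that("ranks are a within-year permutation with ties broken by label order", {
  std <- data.frame(accession = c("A", "B", "C"), year = "2020", trait = "t",
                    value = 0, z = c(1, 1, -2), oriented = c(1, 1, -2),
                    stringsAsFactors = FALSE)
  class(std) <- c("standardized_traits", "data.frame")
  idx <- selection_index(std, c(t = 0.5))
  expect_equal(sort(idx$rank), 1:3)
  expect_equal(idx$rank[idx$accession == "A"], 1L)  # tie with B -> label order
  expect_equal(idx$rank[idx$accession == "B"], 2L)
})

test_that("plot-level index cell means reproduce the accession-level index", {
  d <- simulate_quinoa_trial(seed = 21)
  tr <- quinoa_index_traits()
  fits <- list(); dms <- list()
  means <- do.call(rbind, lapply(tr, function(tn) {
    dm <- build_design(d, tn, "fixed_gxe", "iid")
    ft <- reml_fit(dm)
    dms[[tn]] <<- dm; fits[[tn]] <<- ft
    adjusted_cell_means(ft, dm)
  }))
  specs <- quinoa_trait_specs()
  w <- c(tkw = 0.9, seed_yield = 0.8, dtf = 0.7, plant_height = 0.6,
         mildew = 0.5, saponin = 0.4)
  idx <- selection_index(standardize_orient(means, specs), w, tr)
  pli <- plot_level_index(d, means, specs, w, tr)
  cellm <- tapply(pli$value, list(pli$accession, pli$year), mean)
  for (i in sample(nrow(idx), 10)) {
    expect_equal(cellm[as.character(idx$accession[i]),
                       as.character(idx$year[i])],
                 idx$index[i], tolerance = 1e-8)
  }
})

test_that("index stability flags are invariant to year relabeling and catch planted instability", {
  tr <- quinoa_index_traits()
  specs <- quinoa_variance_specs()[tr]
  d <- generate_trial(trial_design(), specs,
                      gcorr = quinoa_genetic_correlation(),
                      traits = quinoa_trait_specs(), seed = 22)
  # blow up one accession's second-year values on every index trait
  yr2 <- levels(d$year)[2]
  for (tn in tr) {
    sel <- d$accession == "ACC05" & d$year == yr2 & d$trait == tn
    sd_t <- sqrt(specs[[tn]]$sigma2_g)
    dir <- quinoa_trait_specs()[[tn]]$direction
    d$value[sel] <- d$value[sel] + ifelse(dir == "lower_is_better", 8, -8) * sd_t
  }
  run_stability <- function(dat) {
    means <- do.call(rbind, lapply(tr, function(tn) {
      dm <- build_design(dat, tn, "fixed_gxe", "iid")
      adjusted_cell_means(reml_fit(dm), dm)
    }))
    w <- stats::setNames(rep(0.7, length(tr)), tr)
    idx <- selection_index(standardize_orient(means, quinoa_trait_specs()), w, tr)
    pli <- plot_level_index(dat, means, quinoa_trait_specs(), w, tr)
    dmi <- build_design(pli, "selection_index", "fixed_gxe", "iid")
    yc <- year_contrasts(reml_fit(dmi), dmi, mc_draws = 2e4, seed = 4)
    index_stability(idx, yc)
  }
  st <- run_stability(d)
  expect_false(st$stable[st$accession == "ACC05"])
  d_swap <- d
  d_swap$year <- factor(as.character(d_swap$year),
                        levels = rev(levels(d$year)))
  st2 <- run_stability(d_swap)
  expect_equal(st2$stable[match(st$accession, st2$accession)], st$stable)
})

test_that("selection scoring rewards dominance and honours k", {
  acc <- c("A", "B", "C")
  mk_flags <- function() {
    expand.grid(accession = acc, trait = c("t1", "t2"),
                year = c("2020", "2021"), stringsAsFactors = FALSE)
  }
  fl <- mk_flags()
  fl$estimate <- 1; fl$p_adj <- 1
  fl$favorable <- FALSE; fl$unfavorable <- FALSE
  fl$favorable[fl$accession == "A"] <- TRUE           # A favorable everywhere
  fl$p_adj[fl$accession == "A"] <- 0.001
  fl$favorable[fl$accession == "B" & fl$year == "2020"] <- TRUE
  fl$unfavorable[fl$accession == "B" & fl$year == "2021"] <- TRUE  # conflicts
  stab <- data.frame(accession = acc, index_diff = 0, p_adj = 1, stable = TRUE)
  idx <- data.frame(accession = rep(acc, 2), year = rep(c("2020", "2021"), each = 3),
                    index = 0, rank = rep(1:3, 2))
  class(idx) <- c("index_table", "data.frame")
  rep1 <- select_accessions(fl, stab, idx, k = 1)
  expect_equal(rep1$accession[1], "A")
  expect_equal(sum(rep1$selected), 1)
  expect_lt(rep1$score[rep1$accession == "B"], 0)  # conflicting years penalized
  rep_all <- select_accessions(fl, stab, idx, k = 3)
  expect_true(all(rep_all$selected))
  expect_error(select_accessions(fl, stab, idx, k = 4), "exceeds")
})
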