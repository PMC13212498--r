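test_that("fixed seed gives bit-identical cohorts", {
  spec <- cohort_spec(n_genes = 60, n_modules = 3, module_size = 12,
                      n_human_case = 20, n_human_control = 10,
                      tissues = "spleen", seed = 11)
  m1 <- generate_mouse_cohort(spec)
  m2 <- generate_mouse_cohort(spec)
  expect_identical(m1, m2)
  h1 <- generate_human_cohort(spec)
  h2 <- generate_human_cohort(spec)
  expect_identical(h1, h2)
  expect_identical(generate_homolog_map(spec), generate_homolog_map(spec))
})

test_that("mouse cohort matches the study layout", {
  spec <- cohort_spec(n_genes = 60, n_modules = 3, module_size = 12,
                      tissues = "spleen", seed = 2)
  m <- generate_mouse_cohort(spec)
  # 4 models x 4 pseudotimes x (10 cases + 5 controls)
  expect_equal(nrow(m$sheet), 4 * 4 * 15)
  expect_equal(sum(m$sheet$role == "case"), 4 * 4 * 10)
  counts <- m$layers$counts_spleen$values
  expect_true(all(counts >= 0) && all(counts == round(counts)))
  # weeks follow each strain's schedule
  wk <- merge(m$sheet, pseudotime_weeks(),
              by.x = c("group", "pseudotime"), by.y = c("model", "pseudotime"))
  expect_true(all(wk$week.x == wk$week.y))
})

test_that("cell proportions are non-negative and panel sums stay below 100%", {
  spec <- cohort_spec(n_genes = 60, n_modules = 3, module_size = 12,
                      tissues = "spleen", seed = 3)
  for (cohort in list(generate_mouse_cohort(spec),
                      generate_human_cohort(spec))) {
    lay <- cohort$layers$cell_proportions
    expect_true(all(lay$values >= 0))
    for (pn in unique(lay$panel)) {
      sel <- names(lay$panel)[lay$panel == pn]
      expect_true(all(colSums(lay$values[sel, , drop = FALSE]) <= 100))
    }
    expect_identical(lay$unit, "percent")
  }
})

test_that("homolog map covers the requested fraction, one-to-one", {
  spec <- cohort_spec(n_genes = 300, n_modules = 15, module_size = 15)
  map <- generate_homolog_map(spec)
  expect_equal(nrow(map), round(0.69 * 225))
  expect_equal(anyDuplicated(map$mouse), 0)
  expect_equal(anyDuplicated(map$human), 0)
  full <- generate_homolog_map(cohort_spec(homolog_fraction = 1))
  expect_equal(nrow(full), 225)
  none <- generate_homolog_map(cohort_spec(homolog_fraction = 0))
  expect_equal(nrow(none), 0)
})

test_that("human cohort populates all five severity categories and carries covariates", {
  spec <- cohort_spec(n_genes = 60, n_modules = 3, module_size = 12,
                      n_human_case = 40, n_human_control = 20, seed = 4)
  h <- generate_human_cohort(spec)
  cases <- h$sheet[h$sheet$role == "case", ]
  lev <- map_severity(h$sheet)
  expect_setequal(unique(lev$level[h$sheet$role == "case"]), 1:5)
  expect_true(all(is.na(h$sheet$sledai[h$sheet$role == "control"])))
  expect_true(all(c("sex", "age", "batch", "rin") %in% names(h$sheet)))
  expect_true(all(rownames(h$domains) == cases$sample_id))
})

test_that("a null spec emits no interaction features", {
  spec <- cohort_spec(n_genes = 60, n_modules = 3, module_size = 12,
                      tissues = "spleen", interaction_frac = 0, seed = 5)
  m <- generate_mouse_cohort(spec)
  expect_equal(nrow(m$truth$interaction_features), 0)
})

test_that("factor-view scenario emits orthogonal severity shapes with truth", {
  sim <- generate_factor_views(seed = 3)
  expect_named(sim$views, c("group1", "group2"))
  expect_length(sim$views$group1, 3)
  Zt <- do.call(rbind, sim$truth$factor_scores)
  cc <- stats::cor(Zt)
  expect_true(all(abs(cc[upper.tri(cc)]) < 0.15))
  expect_equal(sim$truth$smooth_flags, c(TRUE, TRUE, TRUE, FALSE))
  # smooth scores track severity: R2 of score on level means is high
  for (k in 1:3) {
    z <- sim$truth$factor_scores$group1[, k]
    lv <- sim$axis$level[sim$axis$sample_id %in%
                           rownames(sim$truth$factor_scores$group1)]
    fit <- stats::lm(z ~ factor(lv))
    expect_gt(summary(fit)$r.squared, 0.5)
  }
})
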