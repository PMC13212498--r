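test_that("interaction and reduced fits equal lm() to 1e-10", {
  sheet <- toy_mouse_sheet()
  set.seed(21)
  y <- stats::setNames(rnorm(nrow(sheet)), sheet$sample_id)
  rec <- fit_interaction_model(y, sheet, "MRLlpr")
  df <- data.frame(y = y[sheet$sample_id],
                   x1 = as.numeric(sheet$role == "case"),
                   x2 = sheet$pseudotime)
  ref <- summary(stats::lm(y ~ x1 * x2, data = df))$coefficients
  expect_equal(unlist(rec[c("beta0", "beta1", "beta2", "beta3")]),
               ref[, "Estimate"], tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(rec$p_interaction, ref["x1:x2", "Pr(>|t|)"],
               tolerance = 1e-10)

  red <- fit_reduced_model(y, sheet, "MRLlpr")
  dfc <- df[df$x1 == 1, ]
  refr <- summary(stats::lm(y ~ x2, data = dfc))$coefficients
  expect_equal(red$beta_time_reduced, refr["x2", "Estimate"],
               tolerance = 1e-10)
  expect_equal(red$p_time, refr["x2", "Pr(>|t|)"], tolerance = 1e-10)
})

test_that("swapping case/control labels flips group-coded signs, p unchanged", {
  sheet <- toy_mouse_sheet()
  set.seed(22)
  y <- stats::setNames(rnorm(nrow(sheet)) + 0.3 * sheet$pseudotime *
                         (sheet$role == "case"), sheet$sample_id)
  a <- fit_interaction_model(y, sheet, "MRLlpr")
  swapped <- sheet
  swapped$role <- ifelse(sheet$role == "case", "control", "case")
  b <- fit_interaction_model(y, swapped, "MRLlpr")
  expect_equal(b$beta1, -(a$beta1 + 0), tolerance = 1e-9)
  expect_equal(b$beta3, -a$beta3, tolerance = 1e-9)
  expect_equal(b$p_interaction, a$p_interaction, tolerance = 1e-9)
})

test_that("reduced model handles constant y and is order-invariant", {
  sheet <- toy_mouse_sheet()
  y <- stats::setNames(rep(2.5, nrow(sheet)), sheet$sample_id)
  red <- fit_reduced_model(y, sheet, "MRLlpr")
  expect_equal(red$beta_time_reduced, 0, tolerance = 1e-12)
  expect_true(is.na(red$p_time) || red$p_time > 0.99)

  set.seed(23)
  y2 <- stats::setNames(rnorm(nrow(sheet)), sheet$sample_id)
  perm <- sample(nrow(sheet))
  a <- fit_interaction_model(y2, sheet, "MRLlpr")
  b <- fit_interaction_model(y2[perm], sheet[perm, ], "MRLlpr")
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("an injected unit slope is recovered within 3 SE", {
  sheet <- toy_mouse_sheet()
  set.seed(24)
  mu <- ifelse(sheet$role == "case", sheet$pseudotime, 0)
  y <- stats::setNames(mu + rnorm(nrow(sheet), 0, 0.1), sheet$sample_id)
  rec <- fit_interaction_model(y, sheet, "MRLlpr")
  se <- 0.1 * sqrt(1 / 50 + 1 / 25)  # closed-form OLS SE at this design
  expect_lt(abs(rec$beta3 - 1), 3 * se)
})

test_that("interaction p-values are uniform under the null", {
  sheet <- toy_mouse_sheet()
  set.seed(25)
  Y <- matrix(rnorm(1000 * nrow(sheet)), nrow(sheet), 1000,
              dimnames = list(NULL, sprintf("f%04d", 1:1000)))
  rownames(Y) <- sheet$sample_id
  m <- layer_matrix(t(Y), "cytokines", transform = "log10p1")
  rec <- screen_layers(list(cyt = m), sheet)
  ks <- stats::ks.test(rec$p_interaction, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("selection applies stratified BH and the both-model rule", {
  # textbook BH check on a constructed record set
  m <- 100
  p_int <- c(seq(0.001, 0.01, length.out = 10), runif(90, 0.5, 1))
  rec <- data.frame(feature = sprintf("f%03d", 1:m), layer = "cytokines",
                    tissue = "none", model_group = "MRLlpr",
                    beta3 = 1, p_interaction = p_int, p_time = p_int,
                    untestable = FALSE)
  out <- select_longitudinal(rec, alpha = 0.05)
  expect_equal(out$selected, oracle_bh_reject(p_int, 0.05) &
                 oracle_bh_reject(p_int, 0.05))
  expect_equal(out$fdr_interaction, stats::p.adjust(p_int, "BH"))

  # all p = 1: nothing selected
  rec1 <- rec
  rec1$p_interaction <- rec1$p_time <- 1
  expect_false(any(select_longitudinal(rec1)$selected))

  # significant interaction but weak time trend: not selected
  rec2 <- data.frame(feature = "f1", layer = "cytokines", tissue = "none",
                     model_group = "MRLlpr", beta3 = 1,
                     p_interaction = 0.0001, p_time = 0.2,
                     untestable = FALSE)
  expect_false(select_longitudinal(rec2)$selected)

  # untestable features stay out of the FDR denominator
  rec3 <- rbind(rec,
                data.frame(feature = "untest", layer = "cytokines",
                           tissue = "none", model_group = "MRLlpr",
                           beta3 = NA, p_interaction = NA, p_time = NA,
                           untestable = TRUE))
  out3 <- select_longitudinal(rec3, alpha = 0.05)
  expect_equal(out3$fdr_interaction[1:m], out$fdr_interaction)
  expect_true(is.na(out3$fdr_interaction[m + 1]))
  expect_false(out3$selected[m + 1])
})

test_that("rank-deficient designs are flagged untestable", {
  sheet <- toy_mouse_sheet(timepoints = 1)  # single pseudotime
  set.seed(26)
  y <- stats::setNames(rnorm(nrow(sheet)), sheet$sample_id)
  rec <- fit_interaction_model(y, sheet, "MRLlpr")
  expect_true(rec$untestable)
  expect_true(is.na(rec$p_interaction))
})
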