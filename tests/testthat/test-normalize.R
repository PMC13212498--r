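test_that("low-expression filter applies the >=10 reads in >=5 samples rule exactly", {
  v <- rbind(
    keep_boundary = c(10, 10, 10, 10, 10, 0, 0, 0),  # exactly 10 in exactly 5
    drop_boundary = c(50, 50, 50, 50, 9, 9, 9, 9),   # >=10 in only 4
    keep_rich     = rep(100, 8),
    drop_low      = rep(2, 8))
  colnames(v) <- sprintf("s%d", 1:8)
  m <- layer_matrix(v, "counts")
  f <- filter_low_expression(m)
  expect_identical(rownames(f$values), c("keep_boundary", "keep_rich"))

  zeros <- layer_matrix(matrix(0L, 3, 6, dimnames = list(letters[1:3],
                                                         LETTERS[1:6])),
                        "counts")
  expect_silent(fz <- filter_low_expression(zeros))
  expect_equal(nrow(fz$values), 0)

  neg <- m
  neg$values[1, 1] <- -1
  expect_error(filter_low_expression(neg), "non-negative integers")
})

test_that("size-factor + shifted-log transform matches the spreadsheet oracle", {
  counts <- matrix(c(10, 20, 30, 40,
                     100, 80, 60, 40,
                     5, 0, 5, 10,
                     50, 50, 50, 50,
                     8, 16, 24, 32),
                   5, 4, byrow = TRUE,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  expected <- matrix(c(
    3.885183153382, 7.116447176332, 2.979658883969, 6.126806949394,
    3.587460306301, 4.460270479074, 6.410259394504, 0, 5.742329359261,
    4.154634773827, 4.726468744191, 5.69896007594, 2.391096240179,
    5.441469525672, 4.418100755292, 4.882550466447, 4.882550466447,
    3.022283776478, 5.194663639522, 4.572797863538), 5, 4,
    dimnames = dimnames(counts))
  out <- vst_counts(layer_matrix(counts, "counts"))
  expect_equal(out$values, expected, tolerance = 1e-10)
  expect_identical(out$transform, "vst")
  # and against the cell-by-cell oracle at full precision
  expect_equal(out$values, oracle_vst(counts), tolerance = 1e-12)
})

test_that("vst cancels library-size scaling and handles edge cases", {
  base <- matrix(rpois(40, 60) + 1, 10, 4,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  scaled <- base
  scaled[, 2] <- base[, 1] * 3  # exact scalar multiple of sample 1
  scaled[, 1] <- base[, 1]
  out <- vst_counts(layer_matrix(scaled, "counts"))
  expect_equal(out$values[, 1], out$values[, 2], ignore_attr = TRUE,
               tolerance = 1e-12)

  single <- layer_matrix(matrix(c(0L, 3L, 7L), 3, 1,
                                dimnames = list(letters[1:3], "s1")),
                         "counts")
  expect_equal(vst_counts(single)$values[, 1], log2(c(0, 3, 7) + 1),
               ignore_attr = TRUE)

  withzero <- layer_matrix(cbind(s1 = c(5L, 0L), s2 = c(0L, 0L)) |>
                             `rownames<-`(c("a", "b")), "counts")
  expect_error(vst_counts(withzero), "s2")

  already <- vst_counts(layer_matrix(base, "counts"))
  expect_error(vst_counts(already), "double-transform")
})

test_that("log10p1 is exact, guarded, and rank-preserving", {
  v <- matrix(c(0, 9, 99, 3), 2, 2,
              dimnames = list(c("f1", "f2"), c("s1", "s2")))
  m <- layer_matrix(v, "cytokines")
  out <- log10p1(m)
  expect_equal(out$values, matrix(c(0, 1, 2, log10(4)), 2, 2,
                                  dimnames = dimnames(v)))
  expect_identical(out$transform, "log10p1")
  expect_error(log10p1(out), "already transformed")

  neg <- layer_matrix(matrix(c(1, -2), 2, 1,
                             dimnames = list(c("f1", "f2"), "s1")),
                      "cytokines")
  expect_error(log10p1(neg), "feature 'f2', sample 's1'")

  expect_error(log10p1(layer_matrix(matrix(1, 1, 1,
                                           dimnames = list("g", "s")),
                                    "counts")), "applies to")

  # monotone per sample: within-sample feature ranks preserved
  set.seed(1)
  big <- layer_matrix(matrix(rexp(60), 12, 5,
                             dimnames = list(paste0("f", 1:12),
                                             paste0("s", 1:5))),
                      "cell_proportions")
  tr <- log10p1(big)
  for (j in 1:5) {
    expect_identical(order(big$values[, j]), order(tr$values[, j]))
  }
})
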