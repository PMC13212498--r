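# Time-point cross-sectional analysis and early/late classification -----------

#' Classify dysregulation timing from a 4-bit significance pattern
#'
#' A feature significant (FDR < alpha, direction-concordant) at 3 or 4 time
#' points is an early dysregulation; one significant only at pseudotimes 3
#' and/or 4 is late; anything else is unclassified. The classifier is a pure
#' function of the significance pattern; untested time points count as not
#' significant.
#'
#' @param significant logical vector of length 4 (pseudotimes 1..4); NA is
#'   treated as not significant (untested).
#' @return `"early"`, `"late"`, or `"none"`.
#' @export
classify_timing <- function(significant) {
  stopifnot(length(significant) == 4)
  sig <- which(!is.na(significant) & significant)
  if (length(sig) >= 3) return("early")
  if (length(sig) >= 1 && all(sig %in% c(3, 4))) return("late")
  "none"
}

#' Per-time-point case-control tests with timing classification
#'
#' At each pseudotime, cases are compared with controls by OLS (equivalent to
#' a two-sample t-test); BH adjustment runs within each
#' (layer x tissue x model_group x timepoint) stratum. A time point counts as
#' significant only when its change direction agrees with the longitudinal
#' interaction coefficient, after which features are classified early/late
#' via [classify_timing()].
#'
#' @param layers named list of transformed [layer_matrix()]s.
#' @param sheet mouse sample sheet.
#' @param longitudinal screen records from [select_longitudinal()] (supplies
#'   the `beta3` direction per feature x group).
#' @param model_groups strains to test (default: all mouse groups).
#' @param alpha FDR level.
#' @return data.frame of timing records: per-pseudotime p/fdr/direction,
#'   `n_significant_timepoints`, `class`.
#' @export
crosssectional_tests <- function(layers, sheet, longitudinal,
                                 model_groups = NULL, alpha = 0.05) {
  validate_sample_sheet(sheet)
  model_groups <- model_groups %||%
    unique(sheet$group[sheet$species == "mouse"])
  recs <- list()
  for (nm in names(layers)) {
    m <- layers[[nm]]
    for (g in model_groups) {
      sub <- sheet[sheet$group == g &
                     sheet$sample_id %in% colnames(m$values), , drop = FALSE]
      if (nrow(sub) == 0) next
      for (t in 1:4) {
        st <- sub[sub$pseudotime == t, , drop = FALSE]
        tested <- sum(st$role == "case") >= 2 && sum(st$role == "control") >= 2
        if (!tested) {
          recs[[length(recs) + 1]] <- data.frame(
            feature = rownames(m$values), layer = m$layer, tissue = m$tissue,
            model_group = g, pseudotime = t, estimate = NA_real_,
            p = NA_real_, tested = FALSE, stringsAsFactors = FALSE)
          next
        }
        X <- cbind(intercept = 1, case = as.numeric(st$role == "case"))
        fit <- ols_batch(X, t(m$values[, st$sample_id, drop = FALSE]))
        recs[[length(recs) + 1]] <- data.frame(
          feature = rownames(m$values), layer = m$layer, tissue = m$tissue,
          model_group = g, pseudotime = t,
          estimate = fit$beta[2, ], p = fit$p[2, ], tested = TRUE,
          stringsAsFactors = FALSE)
      }
    }
  }
  tests <- do.call(rbind, recs)
  stratum <- interaction(tests$layer, tests$tissue, tests$model_group,
                         tests$pseudotime, drop = TRUE)
  tests$fdr <- stats::ave(tests$p, stratum, FUN = bh_adjust)
  tests$direction <- ifelse(tests$estimate > 0, "up", "down")

  key <- function(df) paste(df$feature, df$layer, df$tissue, df$model_group)
  beta3 <- longitudinal$beta3[match(key(tests), key(longitudinal))]
  long_dir <- ifelse(beta3 > 0, "up", "down")
  tests$significant <- tests$tested & !is.na(tests$fdr) & tests$fdr < alpha &
    !is.na(long_dir) & tests$direction == long_dir

  # one timing record per feature x layer x tissue x group
  split_key <- key(tests)
  out <- lapply(split(tests, split_key), function(df) {
    df <- df[order(df$pseudotime), ]
    sig <- rep(NA, 4)
    sig[df$pseudotime] <- df$significant
    data.frame(feature = df$feature[1], layer = df$layer[1],
               tissue = df$tissue[1], model_group = df$model_group[1],
               p_t1 = df$p[1], p_t2 = df$p[2], p_t3 = df$p[3], p_t4 = df$p[4],
               fdr_t1 = df$fdr[1], fdr_t2 = df$fdr[2], fdr_t3 = df$fdr[3],
               fdr_t4 = df$fdr[4],
               n_significant_timepoints = sum(sig, na.rm = TRUE),
               class = classify_timing(sig), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
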