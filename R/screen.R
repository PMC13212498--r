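# Longitudinal interaction screen ---------------------------------------------
#
# Two linear models per feature and model group:
#   full:    Y = b0 + b1*X1 + b2*X2 + b3*X1*X2 + e   (X1 case indicator,
#            X2 pseudotime 1..4 numeric; two-sided t-test on b3)
#   reduced: Y = b0 + b1*X2 + e, cases only (t-test on the slope)
# Features are selected when BOTH Benjamini-Hochberg FDRs (computed within
# each layer x tissue x model-group stratum) fall below alpha.

interaction_design <- function(sheet_sub) {
  x1 <- as.numeric(sheet_sub$role == "case")
  x2 <- as.numeric(sheet_sub$pseudotime)
  cbind(intercept = 1, group = x1, pseudotime = x2, interaction = x1 * x2)
}

#' Fit the group-by-pseudotime interaction model for one feature
#'
#' @param y named numeric vector of feature values (names = sample ids).
#' @param sheet sample sheet (mouse rows).
#' @param model_group strain label; its cases and paired controls are used.
#' @return A one-row data.frame with coefficients `beta0..beta3`, the
#'   interaction p-value, and `untestable` flag (rank-deficient design).
#' @export
fit_interaction_model <- function(y, sheet, model_group) {
  sub <- sheet[sheet$group == model_group & sheet$sample_id %in% names(y), ,
               drop = FALSE]
  stop_if(nrow(sub) == 0, "no samples for model group '%s'", model_group)
  stop_if(sum(sub$role == "case") < 2 || sum(sub$role == "control") < 2,
          "need >= 2 case and >= 2 control samples")
  X <- interaction_design(sub)
  fit <- ols_batch(X, matrix(y[sub$sample_id], ncol = 1))
  if (is.null(fit)) {
    return(data.frame(model_group = model_group, beta0 = NA, beta1 = NA,
                      beta2 = NA, beta3 = NA, p_interaction = NA,
                      untestable = TRUE))
  }
  data.frame(model_group = model_group,
             beta0 = fit$beta[1, 1], beta1 = fit$beta[2, 1],
             beta2 = fit$beta[3, 1], beta3 = fit$beta[4, 1],
             p_interaction = fit$p[4, 1], untestable = FALSE)
}

#' Fit the case-only pseudotime model for one feature
#'
#' @inheritParams fit_interaction_model
#' @return A one-row data.frame with `beta_time_reduced`, `p_time`.
#' @export
fit_reduced_model <- function(y, sheet, model_group) {
  sub <- sheet[sheet$group == model_group & sheet$role == "case" &
                 sheet$sample_id %in% names(y), , drop = FALSE]
  stop_if(length(unique(sub$pseudotime)) < 2,
          "case samples must span >= 2 pseudotimes")
  X <- cbind(intercept = 1, pseudotime = as.numeric(sub$pseudotime))
  fit <- ols_batch(X, matrix(y[sub$sample_id], ncol = 1))
  if (is.null(fit)) {
    return(data.frame(beta_time_reduced = NA, p_time = NA, untestable = TRUE))
  }
  data.frame(beta_time_reduced = fit$beta[2, 1], p_time = fit$p[2, 1],
             untestable = FALSE)
}

# Batch screen of one layer for one model group: both models for every
# feature at once (shared design).
screen_layer_group <- function(m, sheet, model_group) {
  sub <- sheet[sheet$group == model_group &
                 sheet$sample_id %in% colnames(m$values), , drop = FALSE]
  if (sum(sub$role == "case") < 2 || sum(sub$role == "control") < 2 ||
      length(unique(sub$pseudotime)) < 2) {
    return(NULL)
  }
  Y <- t(m$values[, sub$sample_id, drop = FALSE])
  full <- ols_batch(interaction_design(sub), Y)
  case <- sub$role == "case"
  Xr <- cbind(intercept = 1, pseudotime = as.numeric(sub$pseudotime[case]))
  red <- ols_batch(Xr, Y[case, , drop = FALSE])
  nfeat <- nrow(m$values)
  rec <- data.frame(feature = rownames(m$values),
                    layer = m$layer, tissue = m$tissue,
                    model_group = model_group,
                    stringsAsFactors = FALSE)
  if (is.null(full)) {
    rec$beta0 <- rec$beta1 <- rec$beta2 <- rec$beta3 <- NA_real_
    rec$p_interaction <- NA_real_
    rec$untestable <- TRUE
  } else {
    rec$beta0 <- full$beta[1, ]
    rec$beta1 <- full$beta[2, ]
    rec$beta2 <- full$beta[3, ]
    rec$beta3 <- full$beta[4, ]
    rec$p_interaction <- full$p[4, ]
    rec$untestable <- FALSE
  }
  if (is.null(red)) {
    rec$beta_time_reduced <- NA_real_
    rec$p_time <- NA_real_
    rec$untestable <- TRUE
  } else {
    rec$beta_time_reduced <- red$beta[2, ]
    rec$p_time <- red$p[2, ]
  }
  rec
}

#' Run the longitudinal screen over layers and model groups
#'
#' @param layers named list of transformed [layer_matrix()]s.
#' @param sheet mouse sample sheet.
#' @param model_groups strains to screen (default: all in the sheet).
#' @return data.frame of screen records (one row per feature x group), with
#'   p-values of both models; pass to [select_longitudinal()].
#' @export
screen_layers <- function(layers, sheet, model_groups = NULL) {
  validate_sample_sheet(sheet)
  model_groups <- model_groups %||%
    unique(sheet$group[sheet$species == "mouse"])
  recs <- list()
  for (nm in names(layers)) {
    for (g in model_groups) {
      r <- screen_layer_group(layers[[nm]], sheet, g)
      if (!is.null(r)) recs[[length(recs) + 1]] <- r
    }
  }
  stop_if(length(recs) == 0, "no testable layer/group combinations")
  do.call(rbind, recs)
}

#' Select features significant in both longitudinal models
#'
#' Benjamini-Hochberg FDR is computed separately within each
#' (layer x tissue x model_group) stratum, for the interaction p-values and
#' for the reduced-model p-values; a feature is selected when both FDRs fall
#' below `alpha`. Untestable features are excluded from the FDR denominator.
#'
#' @param records output of [screen_layers()].
#' @param alpha FDR level (default 0.05).
#' @return `records` with `fdr_interaction`, `fdr_time`, `direction`
#'   (`"up"`/`"down"` from the sign of the interaction coefficient) and
#'   `selected` columns.
#' @export
select_longitudinal <- function(records, alpha = 0.05) {
  if (nrow(records) == 0) {
    warning("empty record set", call. = FALSE)
    records$fdr_interaction <- records$fdr_time <- numeric(0)
    records$direction <- character(0)
    records$selected <- logical(0)
    return(records)
  }
  stratum <- interaction(records$layer, records$tissue, records$model_group,
                         drop = TRUE)
  records$fdr_interaction <- stats::ave(
    records$p_interaction, stratum, FUN = bh_adjust)
  records$fdr_time <- stats::ave(records$p_time, stratum, FUN = bh_adjust)
  records$direction <- ifelse(records$beta3 > 0, "up", "down")
  records$selected <- !is.na(records$fdr_interaction) &
    !is.na(records$fdr_time) &
    records$fdr_interaction < alpha & records$fdr_time < alpha
  records
}
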