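# Factor-model diagnostics ----------------------------------------------------

#' Variance explained per factor, view and group
#'
#' For factor k, view m and group g the fraction of the centered view's sum
#' of squares captured by the factor's rank-1 component:
#' `1 - SS(Y - z_k w_k') / SS(Y)`, truncated at 0. When fitted factors are
#' correlated the naive contributions can overlap; they are then rescaled
#' proportionally so their per-(view, group) sum never exceeds the view's
#' total model R-squared (for orthogonal factors the rescale is a no-op).
#' Zero-variance views are reported as `NA`.
#'
#' @param model a fitted [fit_factor_model()] object.
#' @return A 3-d array `factor x view x group`.
#' @export
variance_explained <- function(model) {
  stopifnot(inherits(model, "factor_model"))
  out <- array(NA_real_, c(model$K, length(model$views),
                           length(model$groups)),
               dimnames = list(paste0("factor", seq_len(model$K)),
                               model$views, model$groups))
  for (g in model$groups) {
    sel <- model$g_index == g
    for (vn in model$views) {
      Yg <- model$centered[[vn]][, sel, drop = FALSE]
      ss <- sum(Yg^2)
      if (ss == 0) next
      ve <- vapply(seq_len(model$K), function(k) {
        comp <- tcrossprod(model$W[[vn]][, k], model$Z[[g]][, k])
        max(0, 1 - sum((Yg - comp)^2) / ss)
      }, numeric(1))
      full <- model$W[[vn]] %*% t(model$Z[[g]])
      total_r2 <- max(0, 1 - sum((Yg - full)^2) / ss)
      if (sum(ve) > total_r2 && sum(ve) > 0) {
        ve <- ve * total_r2 / sum(ve)
      }
      out[, vn, g] <- ve
    }
  }
  out
}

#' Per-factor smoothness over the severity covariate
#'
#' The fitted GP signal fraction of each factor, averaged over groups with
#' weights proportional to group sample size. 0 means the factor's scores
#' are unstructured over severity; 1 means fully severity-smooth.
#'
#' @param model a fitted [fit_factor_model()] object.
#' @return numeric vector in `[0, 1]`, one value per factor.
#' @export
smoothness_score <- function(model) {
  stopifnot(inherits(model, "factor_model"))
  w <- vapply(model$samples, length, integer(1))
  as.vector(crossprod(model$gp_s, w) / sum(w))
}

#' Retain factors by smoothness and explained variance
#'
#' A factor stays active when its smoothness reaches `min_smoothness` and
#' its maximum variance explained over (view, group) reaches `min_var`.
#'
#' @param model a fitted [fit_factor_model()] object.
#' @param min_smoothness,min_var retention thresholds.
#' @return logical vector of active flags, one per factor.
#' @export
retain_factors <- function(model, min_smoothness = 0.5, min_var = 0.01) {
  stopifnot(inherits(model, "factor_model"))
  ve <- model$variance_explained %||% variance_explained(model)
  sm <- model$smoothness %||% smoothness_score(model)
  max_ve <- apply(ve, 1, max, na.rm = TRUE)
  sm >= min_smoothness & max_ve >= min_var
}

#' Severity-trend test of factor scores within a group
#'
#' OLS of each factor's scores on the numeric severity covariate, with a
#' two-sided slope test; groups observed at a single severity level are
#' untestable.
#'
#' @param model a fitted [fit_factor_model()] object.
#' @param group group name.
#' @return data.frame `factor`, `slope`, `p`, `testable`.
#' @export
trend_test <- function(model, group) {
  stopifnot(inherits(model, "factor_model"))
  stop_if(!group %in% model$groups, "unknown group '%s'", group)
  ids <- model$samples[[group]]
  x <- model$axis$covariate[match(ids, model$axis$sample_id)]
  testable <- length(unique(x)) >= 2
  if (!testable) {
    return(data.frame(factor = seq_len(model$K), slope = NA_real_,
                      p = NA_real_, testable = FALSE))
  }
  X <- cbind(intercept = 1, covariate = x)
  fit <- ols_batch(X, model$Z[[group]])
  data.frame(factor = seq_len(model$K), slope = fit$beta[2, ],
             p = fit$p[2, ], testable = TRUE)
}

#' Cross-group trend concordance
#'
#' Runs [trend_test()] in every group and reports, per factor, which groups
#' show a significant severity trend and whether the slope signs agree.
#'
#' @param model a fitted [fit_factor_model()] object.
#' @param alpha significance level for the per-group slope test.
#' @return data.frame `factor`, `n_significant`, `concordant`,
#'   `significant_groups`.
#' @export
trend_concordance <- function(model, alpha = 0.05) {
  tests <- lapply(model$groups, function(g) trend_test(model, g))
  names(tests) <- model$groups
  out <- lapply(seq_len(model$K), function(k) {
    slopes <- vapply(tests, function(tt) tt$slope[k], numeric(1))
    ps <- vapply(tests, function(tt) tt$p[k], numeric(1))
    sig <- !is.na(ps) & ps < alpha
    data.frame(factor = k, n_significant = sum(sig),
               concordant = if (sum(sig) >= 2)
                 length(unique(sign(slopes[sig]))) == 1 else NA,
               significant_groups = paste(model$groups[sig], collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
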