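# Human case-control module preselection --------------------------------------

#' Preselect transcriptional modules by case-control differential analysis
#'
#' Regresses each module score on diagnosis with sex, age, sequencing batch
#' and RNA-integrity number as covariates; modules passing BH FDR < alpha
#' enter the integration. Samples with missing covariates are dropped with a
#' warning; constant covariates are dropped from the design.
#'
#' @param module_scores a `modules` [layer_matrix()] (human samples).
#' @param sheet human sample sheet with `sex`, `age`, `batch`, `rin`.
#' @param alpha FDR level.
#' @return list with `selected` (module ids) and `table` (per-module
#'   estimate, p, fdr).
#' @export
human_preselection <- function(module_scores, sheet, alpha = 0.05) {
  validate_sample_sheet(sheet)
  sub <- sheet[sheet$sample_id %in% colnames(module_scores$values), ,
               drop = FALSE]
  covars <- c("sex", "age", "batch", "rin")
  ok <- stats::complete.cases(sub[, covars])
  if (any(!ok)) {
    warning(sprintf("dropping %d sample(s) with missing covariates",
                    sum(!ok)), call. = FALSE)
    sub <- sub[ok, , drop = FALSE]
  }
  design <- data.frame(diagnosis = as.numeric(sub$role == "case"))
  for (cv in covars) {
    v <- sub[[cv]]
    if (length(unique(v)) < 2) {
      message(sprintf("constant covariate '%s' dropped from design", cv))
      next
    }
    if (is.numeric(v)) {
      design[[cv]] <- v
    } else {
      mm <- stats::model.matrix(~v)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cv, seq_len(ncol(mm)))
      design <- cbind(design, mm)
    }
  }
  X <- cbind(intercept = 1, as.matrix(design))
  Y <- t(module_scores$values[, sub$sample_id, drop = FALSE])
  fit <- ols_batch(X, Y)
  stop_if(is.null(fit), "rank-deficient preselection design")
  tab <- data.frame(module = rownames(module_scores$values),
                    estimate = fit$beta["diagnosis", ],
                    p = fit$p["diagnosis", ],
                    stringsAsFactors = FALSE)
  tab$fdr <- bh_adjust(tab$p)
  list(selected = tab$module[!is.na(tab$fdr) & tab$fdr < alpha], table = tab)
}
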