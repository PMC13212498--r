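# Cross-tissue module-score correlations --------------------------------------

#' Per-module Pearson correlation between two tissues
#'
#' Correlates module scores across matched animals (same sample id) between
#' two tissues for one model group, the summary used to judge whether blood
#' is a workable surrogate for spleen immune monitoring.
#'
#' @param scores_a,scores_b `modules` [layer_matrix()]s from two tissues with
#'   matched sample (animal) ids.
#' @param sheet mouse sample sheet.
#' @param model_group strain whose animals (cases and paired controls) enter
#'   the correlation.
#' @param min_animals modules with fewer matched animals are skipped.
#' @return data.frame `module`, `tissue_a`, `tissue_b`, `model_group`, `n`,
#'   `r`.
#' @export
cross_tissue_correlation <- function(scores_a, scores_b, sheet, model_group,
                                     min_animals = 3) {
  stopifnot(inherits(scores_a, "layer_matrix"),
            inherits(scores_b, "layer_matrix"))
  ids <- sheet$sample_id[sheet$group == model_group]
  matched <- Reduce(intersect, list(ids, colnames(scores_a$values),
                                    colnames(scores_b$values)))
  mods <- intersect(rownames(scores_a$values), rownames(scores_b$values))
  out <- lapply(mods, function(md) {
    a <- scores_a$values[md, matched]
    b <- scores_b$values[md, matched]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < min_animals) {
      warning(sprintf("module %s: <%d matched animals, skipped", md,
                      min_animals), call. = FALSE)
      return(NULL)
    }
    data.frame(module = md, tissue_a = scores_a$tissue,
               tissue_b = scores_b$tissue, model_group = model_group,
               n = sum(ok),
               r = if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
                 NA_real_ else stats::cor(a[ok], b[ok]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(module = character(0))
  res
}
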