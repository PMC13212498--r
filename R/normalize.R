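# Per-layer transformations ---------------------------------------------------

#' Filter lowly expressed genes
#'
#' Retains exactly the genes with at least 10 reads in at least 5 samples
#' (order preserved), the standard expression filter applied before
#' variance-stabilizing transformation.
#'
#' @param m a raw-counts [layer_matrix()].
#' @param min_reads,min_samples filter thresholds.
#' @return The filtered layer.
#' @export
filter_low_expression <- function(m, min_reads = 10, min_samples = 5) {
  stopifnot(inherits(m, "layer_matrix"))
  stop_if(m$layer != "counts" || m$transform != "raw",
          "filter_low_expression expects a raw counts layer")
  v <- m$values
  stop_if(any(v < 0) || any(v != round(v)),
          "counts must be non-negative integers")
  keep <- rowSums(v >= min_reads) >= min_samples
  m$values <- v[keep, , drop = FALSE]
  m
}

# Median-of-ratios size factors: reference is the per-gene geometric mean over
# genes observed in every sample (no zero anywhere).
size_factors <- function(v) {
  if (ncol(v) == 1) return(stats::setNames(1, colnames(v)))
  ref_genes <- rowSums(v == 0) == 0
  stop_if(!any(ref_genes),
          "no gene is non-zero in every sample; cannot compute size factors")
  ref <- apply(v[ref_genes, , drop = FALSE], 1, geometric_mean)
  sf <- apply(v[ref_genes, , drop = FALSE], 2, function(col) {
    stats::median(col / ref)
  })
  sf
}

#' Variance-stabilizing transform for counts
#'
#' Size-factor normalization (median-of-ratios, geometric-mean reference over
#' genes with no zero count) followed by a shifted log:
#' `log2(count / size_factor + 1)`. Monotone per sample. The layer's
#' transform tag is set to `"vst"`; applying it twice raises an error rather
#' than double-transforming.
#'
#' @param m a raw (typically filtered) counts [layer_matrix()].
#' @return The transformed layer.
#' @export
vst_counts <- function(m) {
  stopifnot(inherits(m, "layer_matrix"))
  stop_if(m$layer != "counts", "vst_counts expects a counts layer")
  stop_if(m$transform != "raw",
          "layer is already transformed ('%s'); refusing to double-transform",
          m$transform)
  v <- m$values
  all_zero <- colSums(v) == 0
  stop_if(any(all_zero), "sample(s) with all-zero counts: %s",
          paste(colnames(v)[all_zero], collapse = ", "))
  sf <- size_factors(v)
  m$values <- log2(sweep(v, 2, sf, `/`) + 1)
  m$transform <- "vst"
  m
}

#' Shifted log10 transform
#'
#' Elementwise `log10(x + 1)`, the normalization applied to cell proportions,
#' cytokine and autoantibody concentrations.
#'
#' @param m a [layer_matrix()] with non-negative values (layers
#'   `cell_proportions`, `cytokines` or `autoantibodies`).
#' @return The transformed layer, tagged `"log10p1"`.
#' @export
log10p1 <- function(m) {
  stopifnot(inherits(m, "layer_matrix"))
  stop_if(!m$layer %in% c("cell_proportions", "cytokines", "autoantibodies"),
          "log10p1 applies to cell_proportions, cytokines or autoantibodies")
  stop_if(m$transform != "raw",
          "layer is already transformed ('%s')", m$transform)
  v <- m$values
  if (any(v < 0)) {
    idx <- which(v < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at feature '%s', sample '%s'",
                 rownames(v)[idx[1]], colnames(v)[idx[2]]), call. = FALSE)
  }
  m$values <- log10(v + 1)
  m$transform <- "log10p1"
  m
}
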