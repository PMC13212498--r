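#' Molecular layer matrix
#'
#' A `layer_matrix` bundles one molecular view (features in rows, samples in
#' columns) with its layer label, tissue tag and transform state. The five
#' recognised layers are `counts`, `modules`, `cell_proportions`, `cytokines`
#' and `autoantibodies`; the transform tag tracks which normalization has been
#' applied (`raw` counts, `vst`, `log10p1`, or `none` for scores that need no
#' further transformation).
#'
#' @param values numeric matrix, features x samples, with unique row and
#'   column names.
#' @param layer one of `"counts"`, `"modules"`, `"cell_proportions"`,
#'   `"cytokines"`, `"autoantibodies"`.
#' @param tissue tissue tag, one of `"blood"`, `"spleen"`, `"kidney"`,
#'   `"none"`.
#' @param transform transform state, one of `"raw"`, `"vst"`, `"log10p1"`,
#'   `"none"`.
#' @param unit free-text unit annotation (e.g. `"percent"` for cell
#'   proportions); recorded as metadata only.
#' @return An object of class `layer_matrix`.
#' @export
layer_matrix <- function(values, layer, tissue = "none", transform = "raw",
                         unit = NULL) {
  values <- as.matrix(values)
  layer <- match.arg(layer, c("counts", "modules", "cell_proportions",
                              "cytokines", "autoantibodies"))
  tissue <- match.arg(tissue, c("blood", "spleen", "kidney", "none"))
  transform <- match.arg(transform, c("raw", "vst", "log10p1", "none"))
  stop_if(is.null(rownames(values)) || anyDuplicated(rownames(values)) > 0,
          "layer_matrix requires unique feature (row) names")
  stop_if(is.null(colnames(values)) || anyDuplicated(colnames(values)) > 0,
          "layer_matrix requires unique sample (column) names")
  if (layer == "counts" && transform == "raw") {
    stop_if(any(values < 0) || any(values != round(values)),
            "raw counts must be non-negative integers")
  }
  structure(list(values = values, layer = layer, tissue = tissue,
                 transform = transform, unit = unit),
            class = "layer_matrix")
}

#' @export
print.layer_matrix <- function(x, ...) {
  cat(sprintf("<layer_matrix> %s [%s] %d features x %d samples (transform: %s)\n",
              x$layer, x$tissue, nrow(x$values), ncol(x$values), x$transform))
  invisible(x)
}

#' @export
dim.layer_matrix <- function(x) dim(x$values)

# Subset a layer matrix to a sample set (order preserved as given).
subset_samples <- function(m, sample_ids) {
  missing <- setdiff(sample_ids, colnames(m$values))
  stop_if(length(missing) > 0, "samples absent from %s layer: %s",
          m$layer, paste(utils::head(missing, 5), collapse = ", "))
  m$values <- m$values[, sample_ids, drop = FALSE]
  m
}
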