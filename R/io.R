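# Readers and writers ---------------------------------------------------------
#
# All on-disk formats are plain text: TSV matrices (features in rows, header
# of sample ids), MatrixMarket with .rows/.cols sidecars, GMT gene sets,
# two-column homolog TSVs, and structured JSON for simulation truth and run
# manifests. Writers round-trip values to at least 1e-12.

#' Write / read a layer matrix as TSV
#'
#' The first column (`feature`) holds feature ids; remaining columns are
#' samples. Layer metadata (layer, tissue, transform, unit) is stored in a
#' `# slebridge:` header comment and restored on read.
#'
#' @param m a [layer_matrix()].
#' @param path file path.
#' @return `write_layer_tsv` returns `path` invisibly; `read_layer_tsv`
#'   returns a [layer_matrix()].
#' @export
write_layer_tsv <- function(m, path) {
  stopifnot(inherits(m, "layer_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# slebridge: layer=%s tissue=%s transform=%s unit=%s",
                     m$layer, m$tissue, m$transform, m$unit %||% "NA"), con)
  writeLines(paste(c("feature", colnames(m$values)), collapse = "\t"), con)
  v <- m$values
  lines <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i], format_num(v[i, ])), collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_layer_tsv
#' @export
read_layer_tsv <- function(path) {
  header <- readLines(path, n = 1)
  meta <- list(layer = "counts", tissue = "none", transform = "raw",
               unit = NULL)
  if (startsWith(header, "# slebridge:")) {
    kv <- strsplit(sub("# slebridge: ", "", header), " ")[[1]]
    for (pair in strsplit(kv, "=")) {
      if (pair[2] != "NA") meta[[pair[1]]] <- pair[2]
    }
  }
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  if (meta$layer == "counts" && meta$transform == "raw") v <- round(v)
  layer_matrix(v, meta$layer, tissue = meta$tissue,
               transform = meta$transform, unit = meta$unit)
}

#' Write / read a layer matrix as MatrixMarket
#'
#' Writes `<path>.mtx` plus `<path>.rows` / `<path>.cols` sidecars with the
#' feature and sample ids and a `<path>.meta` sidecar with layer metadata.
#'
#' @inheritParams write_layer_tsv
#' @param path path prefix (without extension).
#' @export
write_layer_mtx <- function(m, path) {
  stopifnot(inherits(m, "layer_matrix"))
  Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE),
                  paste0(path, ".mtx"))
  writeLines(rownames(m$values), paste0(path, ".rows"))
  writeLines(colnames(m$values), paste0(path, ".cols"))
  writeLines(sprintf("layer=%s tissue=%s transform=%s unit=%s",
                     m$layer, m$tissue, m$transform, m$unit %||% "NA"),
             paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_layer_mtx
#' @export
read_layer_mtx <- function(path) {
  v <- as.matrix(Matrix::readMM(paste0(path, ".mtx")))
  rownames(v) <- readLines(paste0(path, ".rows"))
  colnames(v) <- readLines(paste0(path, ".cols"))
  meta <- list(layer = "counts", tissue = "none", transform = "raw",
               unit = NULL)
  kv <- strsplit(readLines(paste0(path, ".meta"))[1], " ")[[1]]
  for (pair in strsplit(kv, "=")) {
    if (pair[2] != "NA") meta[[pair[1]]] <- pair[2]
  }
  layer_matrix(v, meta$layer, tissue = meta$tissue,
               transform = meta$transform, unit = meta$unit)
}

#' Write / read sample sheets
#'
#' @param sheet a validated sample-sheet data.frame.
#' @param path file path.
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
  sheet
}

#' Write / read gene-set modules in GMT format
#'
#' One module per line: id, description, then member genes, tab-separated.
#' Reading goes through `fgsea::gmtPathways()`.
#'
#' @param modules named list of character vectors (module id -> genes).
#' @param path file path.
#' @param descriptions optional named character vector of annotations.
#' @export
write_gmt <- function(modules, path, descriptions = NULL) {
  lines <- vapply(names(modules), function(id) {
    desc <- if (!is.null(descriptions) && id %in% names(descriptions))
      descriptions[[id]] else "na"
    paste(c(id, desc, modules[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write / read a two-column homolog table
#'
#' @param map data.frame with columns `mouse`, `human`.
#' @param path file path.
#' @export
write_homolog_map <- function(map, path) {
  utils::write.table(map[, c("mouse", "human")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_homolog_map
#' @export
read_homolog_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  stop_if(!all(c("mouse", "human") %in% names(map)),
          "homolog table needs 'mouse' and 'human' columns")
  resolve_homolog_map(map)
}

#' Write simulation truth as structured JSON
#'
#' @param truth a `simulation_truth` object.
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", pretty = FALSE, na = "null")
  invisible(path)
}

#' Write a full synthetic cohort to a directory
#'
#' Persists the sample sheet, every layer (TSV), the module set (GMT), the
#' homolog map and the simulation truth (JSON).
#'
#' @param cohort output of [generate_mouse_cohort()] or
#'   [generate_human_cohort()].
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sample_sheet(cohort$sheet, file.path(dir, "samples.tsv"))
  for (nm in names(cohort$layers)) {
    write_layer_tsv(cohort$layers[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  if (!is.null(cohort$modules))
    write_gmt(cohort$modules, file.path(dir, "modules.gmt"))
  if (!is.null(cohort$homologs))
    write_homolog_map(cohort$homologs, file.path(dir, "homologs.tsv"))
  if (!is.null(cohort$domains))
    utils::write.table(cohort$domains, file.path(dir, "domains.tsv"),
                       sep = "\t", quote = FALSE, row.names = TRUE)
  if (!is.null(cohort$truth))
    write_truth_json(cohort$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
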