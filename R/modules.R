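# Homolog-based module projection ---------------------------------------------

#' Resolve a homolog table to unambiguous one-to-one pairs
#'
#' Any mouse or human gene appearing more than once (many-to-many homology)
#' is dropped entirely; only unambiguous 1:1 pairs survive.
#'
#' @param map data.frame with columns `mouse`, `human`.
#' @return data.frame of class `homolog_map`.
#' @export
resolve_homolog_map <- function(map) {
  map <- map[, c("mouse", "human")]
  dup_m <- map$mouse %in% map$mouse[duplicated(map$mouse)]
  dup_h <- map$human %in% map$human[duplicated(map$human)]
  map <- map[!dup_m & !dup_h, , drop = FALSE]
  rownames(map) <- NULL
  class(map) <- c("homolog_map", "data.frame")
  map
}

#' Project human gene modules onto a mouse gene universe
#'
#' Replaces each module's human genes by their one-to-one mouse homologs
#' present in `universe`; modules retaining fewer than `min_genes` homologs
#' are discarded. A per-module coverage report is attached as the
#' `"coverage"` attribute. Idempotent: projecting an already projected module
#' set (with an identity map) leaves it unchanged.
#'
#' @param modules named list of character vectors (module id -> human genes).
#' @param map homolog table (`mouse`, `human` columns); resolved to 1:1 pairs.
#' @param universe character vector of mouse gene ids present in the data.
#' @param min_genes minimum surviving module size (default 10).
#' @return Named list of projected modules with a `coverage` attribute
#'   (data.frame `module`, `n_genes`, `n_mapped`, `kept`).
#' @export
project_modules <- function(modules, map, universe, min_genes = 10) {
  stop_if(length(universe) == 0, "empty mouse gene universe")
  stop_if(any(vapply(modules, anyDuplicated, integer(1)) > 0),
          "modules must not contain duplicate genes")
  stop_if(any(lengths(modules) == 0), "modules must contain at least 1 gene")
  map <- resolve_homolog_map(as.data.frame(map))
  lookup <- stats::setNames(map$mouse, map$human)
  projected <- lapply(modules, function(genes) {
    mouse <- unname(lookup[genes])
    mouse <- mouse[!is.na(mouse)]
    mouse[mouse %in% universe]
  })
  coverage <- data.frame(module = names(modules),
                         n_genes = lengths(modules),
                         n_mapped = lengths(projected),
                         stringsAsFactors = FALSE)
  coverage$kept <- coverage$n_mapped >= min_genes
  out <- projected[coverage$kept]
  attr(out, "coverage") <- coverage
  out
}
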