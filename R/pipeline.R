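# End-to-end pipeline ---------------------------------------------------------
#
# simulate -> normalize -> project/score -> screen -> preselect -> integrate
# -> align. Every stage persists its artifacts under the output directory,
# records their md5 hashes in a manifest, and caches its state keyed by the
# hash of its configuration and upstream state; re-running with unchanged
# upstream hashes skips recompute.

#' Build a pipeline run configuration
#'
#' @param overrides named list (possibly nested) overriding the defaults;
#'   `cohort` entries are passed to [cohort_spec()].
#' @param path optional YAML file with overrides (applied before
#'   `overrides`).
#' @return list of class `run_config`. The config round-trips through YAML
#'   serialization unchanged.
#' @export
run_config <- function(overrides = list(), path = NULL) {
  config <- list(
    outdir = file.path(tempdir(), "slebridge_run"),
    seed = 1L,
    simulate = TRUE,
    cohort = list(),
    alpha = 0.05,
    alpha_preselect = 0.05,
    K_init = 15L,
    min_smoothness = 0.5,
    min_var = 0.01,
    max_iter = 200L,
    target_level = "very_high",
    ks_ceiling = 0.5,
    min_module_genes = 10L,
    resume = TRUE)
  if (!is.null(path)) {
    config <- utils::modifyList(config, yaml::read_yaml(path))
  }
  config <- utils::modifyList(config, overrides)
  for (f in c("alpha", "alpha_preselect", "min_smoothness", "min_var"))
    stop_if(config[[f]] <= 0 || config[[f]] >= 1,
            "config field '%s' must lie in (0, 1)", f)
  stop_if(is.null(config$seed), "a seed is mandatory")
  class(config) <- c("run_config", "list")
  config
}

#' Write a run configuration to YAML
#'
#' @param config a [run_config()].
#' @param path output file.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

# Run one stage with manifest-based caching. `inputs` is the upstream state
# key; the stage is skipped (state loaded from cache) when its key matches
# the manifest and all recorded artifacts still hash identically.
run_stage <- function(name, key, state_env, config, compute) {
  cache_dir <- file.path(config$outdir, "cache")
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  cache_file <- file.path(cache_dir, paste0(name, ".rds"))
  manifest <- state_env$manifest
  prev <- manifest$stages[[name]]
  if (isTRUE(config$resume) && !is.null(prev) && identical(prev$key, key) &&
      file.exists(cache_file) &&
      all(file.exists(names(prev$outputs))) &&
      identical(unname(tools::md5sum(names(prev$outputs))),
                unname(unlist(prev$outputs)))) {
    message(sprintf("[%s] up to date, skipping", name))
    return(readRDS(cache_file))
  }
  message(sprintf("[%s] running", name))
  res <- tryCatch(compute(), error = function(e) {
    failed <- file.path(config$outdir, "failed")
    dir.create(failed, showWarnings = FALSE, recursive = TRUE)
    writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
               file.path(failed, paste0(name, ".txt")))
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
  saveRDS(res$state, cache_file, version = 2)
  outs <- tools::md5sum(res$files)
  state_env$manifest$stages[[name]] <-
    list(key = key, outputs = as.list(outs))
  res$state
}

#' Run the full severity-aligned integration pipeline
#'
#' Executes simulate, normalize, score, screen, preselect, integrate and
#' align in order, persisting every intermediate artifact with a manifest of
#' input hashes and the seed. Identical config + seed yields identical
#' manifest hashes.
#'
#' @param config a [run_config()].
#' @return A run report (list): selected features per layer/model, timing
#'   classes, retained factors with diagnostics, and the alignment table.
#'   Also written as `report.json` in the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stop_if(!isTRUE(config$simulate),
          "external data ingestion requires simulate = TRUE in this release or explicit layer paths; see vignette")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(config$outdir, "manifest.json")
  env <- new.env()
  env$manifest <- if (isTRUE(config$resume) && file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else list(stages = list())
  env$manifest$seed <- config$seed
  spec <- do.call(cohort_spec, utils::modifyList(
    list(seed = config$seed), config$cohort))

  # -- simulate ---------------------------------------------------------------
  sim_key <- hash_object(list("simulate", unclass(spec)))
  sim <- run_stage("simulate", sim_key, env, config, function() {
    mouse <- generate_mouse_cohort(spec)
    human <- generate_human_cohort(spec)
    d1 <- write_cohort(mouse, file.path(config$outdir, "sim", "mouse"))
    d2 <- write_cohort(human, file.path(config$outdir, "sim", "human"))
    list(state = list(mouse = mouse, human = human),
         files = c(list.files(d1, full.names = TRUE),
                   list.files(d2, full.names = TRUE)))
  })

  # -- normalize --------------------------------------------------------------
  norm_key <- hash_object(list("normalize", sim_key))
  norm <- run_stage("normalize", norm_key, env, config, function() {
    ndir <- file.path(config$outdir, "normalized")
    dir.create(ndir, showWarnings = FALSE, recursive = TRUE)
    mouse <- list()
    for (nm in names(sim$mouse$layers)) {
      m <- sim$mouse$layers[[nm]]
      mouse[[nm]] <- if (m$layer == "counts") {
        vst_counts(filter_low_expression(m))
      } else log10p1(m)
      write_layer_tsv(mouse[[nm]], file.path(ndir, paste0("mouse_", nm, ".tsv")))
    }
    human <- list()
    for (nm in names(sim$human$layers)) {
      m <- sim$human$layers[[nm]]
      human[[nm]] <- if (m$transform == "raw") log10p1(m) else m
      write_layer_tsv(human[[nm]], file.path(ndir, paste0("human_", nm, ".tsv")))
    }
    list(state = list(mouse = mouse, human = human),
         files = list.files(ndir, full.names = TRUE))
  })

  # -- project + score --------------------------------------------------------
  score_key <- hash_object(list("score", norm_key, config$min_module_genes))
  scored <- run_stage("score", score_key, env, config, function() {
    sdir <- file.path(config$outdir, "scores")
    dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
    out <- list()
    coverage <- list()
    for (nm in grep("^counts_", names(norm$mouse), value = TRUE)) {
      ts <- sub("^counts_", "", nm)
      proj <- project_modules(sim$mouse$modules, sim$mouse$homologs,
                              universe = rownames(norm$mouse[[nm]]$values),
                              min_genes = config$min_module_genes)
      coverage[[ts]] <- attr(proj, "coverage")
      sc <- score_modules(norm$mouse[[nm]], proj)
      out[[paste0("modules_", ts)]] <- sc
      write_layer_tsv(sc, file.path(sdir, paste0("mouse_modules_", ts, ".tsv")))
    }
    list(state = list(scores = out, coverage = coverage),
         files = list.files(sdir, full.names = TRUE))
  })

  # -- screen -----------------------------------------------------------------
  screen_key <- hash_object(list("screen", score_key, config$alpha))
  scr <- run_stage("screen", screen_key, env, config, function() {
    gdir <- file.path(config$outdir, "screen")
    dir.create(gdir, showWarnings = FALSE, recursive = TRUE)
    layers <- c(scored$scores,
                norm$mouse[c("cell_proportions", "cytokines",
                             "autoantibodies")])
    records <- select_longitudinal(
      screen_layers(layers, sim$mouse$sheet), alpha = config$alpha)
    timing <- crosssectional_tests(layers, sim$mouse$sheet, records,
                                   alpha = config$alpha)
    xcorr <- list()
    tissues <- sub("^modules_", "", grep("^modules_", names(scored$scores),
                                         value = TRUE))
    if (length(tissues) >= 2) {
      pairs <- utils::combn(tissues, 2, simplify = FALSE)
      for (pr in pairs) {
        for (g in unique(sim$mouse$sheet$group)) {
          xcorr[[length(xcorr) + 1]] <- cross_tissue_correlation(
            scored$scores[[paste0("modules_", pr[1])]],
            scored$scores[[paste0("modules_", pr[2])]],
            sim$mouse$sheet, g)
        }
      }
      xcorr <- do.call(rbind, xcorr)
    } else xcorr <- NULL
    utils::write.table(records, file.path(gdir, "screen_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(timing, file.path(gdir, "timing_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(xcorr))
      utils::write.table(xcorr, file.path(gdir, "cross_tissue_correlation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    list(state = list(records = records, timing = timing, xcorr = xcorr),
         files = list.files(gdir, full.names = TRUE))
  })

  # -- human preselection -----------------------------------------------------
  pre_key <- hash_object(list("preselect", norm_key, config$alpha_preselect))
  pre <- run_stage("preselect", pre_key, env, config, function() {
    pdir <- file.path(config$outdir, "preselect")
    dir.create(pdir, showWarnings = FALSE, recursive = TRUE)
    res <- human_preselection(norm$human$modules, sim$human$sheet,
                              alpha = config$alpha_preselect)
    utils::write.table(res$table, file.path(pdir, "preselection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(state = res, files = list.files(pdir, full.names = TRUE))
  })

  # -- integrate --------------------------------------------------------------
  int_key <- hash_object(list("integrate", score_key, pre_key, config$K_init,
                              config$min_smoothness, config$min_var,
                              config$max_iter))
  integ <- run_stage("integrate", int_key, env, config, function() {
    idir <- file.path(config$outdir, "integration")
    dir.create(idir, showWarnings = FALSE, recursive = TRUE)
    msheet <- sim$mouse$sheet
    hsheet <- sim$human$sheet
    mouse_modules <- scored$scores[["modules_spleen"]] %||%
      scored$scores[[1]]
    shared_modules <- intersect(rownames(mouse_modules$values),
                                pre$selected)
    stop_if(length(shared_modules) < 2,
            "fewer than 2 modules shared between species after preselection")
    shared_cyt <- intersect(rownames(norm$mouse$cytokines$values),
                            rownames(norm$human$cytokines$values))
    views <- list()
    for (g in unique(msheet$group)) {
      ids <- msheet$sample_id[msheet$group == g & msheet$role == "case"]
      views[[g]] <- list(
        modules = mouse_modules$values[shared_modules, ids, drop = FALSE],
        cell_proportions =
          norm$mouse$cell_proportions$values[, ids, drop = FALSE],
        cytokines = norm$mouse$cytokines$values[shared_cyt, ids,
                                                drop = FALSE],
        autoantibodies = norm$mouse$autoantibodies$values[, ids,
                                                          drop = FALSE])
    }
    views$human <- list(
      modules = norm$human$modules$values[shared_modules, , drop = FALSE],
      cell_proportions = norm$human$cell_proportions$values,
      cytokines = norm$human$cytokines$values[shared_cyt, , drop = FALSE],
      autoantibodies = norm$human$autoantibodies$values)
    axis <- map_severity(rbind(msheet, hsheet))
    model <- fit_factor_model(views, axis, K_init = config$K_init,
                              max_iter = config$max_iter,
                              min_smoothness = config$min_smoothness,
                              min_var = config$min_var, seed = config$seed)
    write_factor_model(model, idir)
    list(state = list(model = model, axis = axis),
         files = list.files(idir, full.names = TRUE))
  })

  # -- align ------------------------------------------------------------------
  align_key <- hash_object(list("align", int_key, config$target_level,
                                config$ks_ceiling))
  ali <- run_stage("align", align_key, env, config, function() {
    adir <- file.path(config$outdir, "alignment")
    dir.create(adir, showWarnings = FALSE, recursive = TRUE)
    model <- integ$model
    axis <- integ$axis
    active <- which(model$active)
    rows <- list()
    dom_rows <- list()
    for (k in active) {
      hz <- stats::setNames(model$Z$human[, k], model$samples$human)
      ch <- cumulative_curves(hz, axis)
      if (!as.character(5) %in% names(ch$samples)) next
      for (g in setdiff(model$groups, "human")) {
        mz <- stats::setNames(model$Z[[g]][, k], model$samples[[g]])
        cm <- suppressWarnings(cumulative_curves(mz, axis))
        res <- match_timepoints(cm, ch, target_level = config$target_level,
                                ceiling = config$ks_ceiling)
        rows[[length(rows) + 1]] <- data.frame(
          factor = k, model_group = g,
          pseudotime = as.integer(names(res$distance)),
          ks_distance = unname(res$distance),
          best_pseudotime = as.character(res$best_pseudotime),
          stringsAsFactors = FALSE)
      }
      da <- domain_association(hz, sim$human$domains)
      da$factor <- k
      dom_rows[[length(dom_rows) + 1]] <- da
    }
    alignment <- if (length(rows)) do.call(rbind, rows) else NULL
    domains <- if (length(dom_rows)) do.call(rbind, dom_rows) else NULL
    if (!is.null(alignment))
      utils::write.table(alignment, file.path(adir, "alignment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(domains))
      utils::write.table(domains, file.path(adir, "domain_association.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    list(state = list(alignment = alignment, domains = domains),
         files = list.files(adir, full.names = TRUE))
  })

  # -- report -----------------------------------------------------------------
  sel <- scr$records[scr$records$selected, , drop = FALSE]
  report <- list(
    seed = config$seed,
    n_samples = list(mouse = nrow(sim$mouse$sheet),
                     human = nrow(sim$human$sheet)),
    selected_by_layer_group = if (nrow(sel) > 0) {
      stats::aggregate(feature ~ layer + tissue + model_group, data = sel,
                       FUN = length)
    } else NULL,
    timing_classes = table(scr$timing$class),
    n_modules_preselected = length(pre$selected),
    n_factors = integ$model$K,
    n_factors_retained = sum(integ$model$active),
    smoothness = integ$model$smoothness,
    alignment = ali$alignment)
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  jsonlite::write_json(env$manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  report
}

#' Serialize a fitted factor model to text artifacts
#'
#' Writes per-view loading TSVs, a factor-score TSV keyed by sample id, and
#' a JSON with diagnostics and GP hyperparameters.
#'
#' @param model a fitted [fit_factor_model()] object.
#' @param dir output directory.
#' @export
write_factor_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (vn in model$views) {
    w <- model$W[[vn]]
    df <- data.frame(feature = rownames(w), w, check.names = FALSE)
    colnames(df)[-1] <- paste0("factor", seq_len(ncol(w)))
    utils::write.table(df, file.path(dir, paste0("loadings_", vn, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  zz <- do.call(rbind, lapply(model$groups, function(g) {
    data.frame(sample_id = rownames(model$Z[[g]]), group = g,
               model$Z[[g]], check.names = FALSE)
  }))
  colnames(zz)[-(1:2)] <- paste0("factor", seq_len(model$K))
  utils::write.table(zz, file.path(dir, "factor_scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(K = model$K, groups = model$groups, views = model$views,
         smoothness = model$smoothness, active = model$active,
         gp_s = model$gp_s, gp_ell = model$gp_ell, sigma2 = model$sigma2,
         variance_explained = model$variance_explained,
         n_iter = model$n_iter),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE, na = "null")
  invisible(dir)
}
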