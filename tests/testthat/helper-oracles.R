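# Independent oracles used across tests. These re-derive expected values by
# direct enumeration / spreadsheet-style arithmetic, deliberately sharing no
# code with the package implementation.

# Naive single-sample enrichment oracle: full random walk, plain loops.
oracle_module_scores <- function(X, modules, tau = 1,
                                 score_mode = "max_diff") {
  p <- nrow(X)
  n <- ncol(X)
  # kernel CDF statistic, one value at a time
  z <- matrix(NA_real_, p, n)
  for (i in seq_len(p)) {
    h <- stats::sd(X[i, ]) / 4
    for (j in seq_len(n)) {
      if (is.na(h) || h == 0) {
        z[i, j] <- 0.5
      } else {
        acc <- 0
        for (k in seq_len(n)) acc <- acc + stats::pnorm((X[i, j] - X[i, k]) / h)
        z[i, j] <- acc / n
      }
    }
  }
  ids <- rownames(X)
  scores <- matrix(NA_real_, length(modules), n,
                   dimnames = list(names(modules), colnames(X)))
  for (j in seq_len(n)) {
    ord <- order(-z[, j], match(ids, sort(ids)))
    ranked_ids <- ids[ord]
    r <- abs(seq_len(p) - (p + 1) / 2)
    for (s in seq_along(modules)) {
      genes <- modules[[s]]
      k <- length(genes)
      in_set <- ranked_ids %in% genes
      denom_in <- sum(r[in_set]^tau)
      v <- 0
      vmax <- 0
      vmin <- 0
      vabs <- 0
      best_abs <- -1
      for (pos in seq_len(p)) {
        v <- v + if (in_set[pos]) r[pos]^tau / denom_in else -1 / (p - k)
        if (v > vmax) vmax <- v
        if (v < vmin) vmin <- v
        # earliest-position extremum on values rounded to 1e-12 (matches the
        # stated tie rule; plain > keeps the first attainment)
        if (abs(round(v, 12)) > best_abs) {
          best_abs <- abs(round(v, 12))
          vabs <- v
        }
      }
      scores[s, j] <- if (score_mode == "max_diff") vmax + vmin else vabs
    }
  }
  scores
}

# Spreadsheet-style size-factor + shifted-log oracle (median-of-ratios with a
# geometric-mean reference over all-nonzero genes), written cell by cell.
oracle_vst <- function(counts) {
  ref_rows <- which(apply(counts, 1, function(r) all(r > 0)))
  geo <- sapply(ref_rows, function(i) prod(counts[i, ])^(1 / ncol(counts)))
  sf <- sapply(seq_len(ncol(counts)), function(j) {
    stats::median(counts[ref_rows, j] / geo)
  })
  out <- counts
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      out[i, j] <- log(counts[i, j] / sf[j] + 1, base = 2)
    }
  }
  out
}

# Textbook Benjamini-Hochberg: sort, compare p_(i) <= i/m * alpha, reject all
# up to the largest passing index.
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  passing <- which(p[ord] <= seq_len(m) / m * alpha)
  rej <- rep(FALSE, m)
  if (length(passing) > 0) rej[ord[seq_len(max(passing))]] <- TRUE
  rej
}

# Small random expression fixture with row/col names.
random_expr <- function(p, n, seed) {
  set.seed(seed)
  matrix(stats::rnorm(p * n), p, n,
         dimnames = list(sprintf("g%03d", seq_len(p)),
                         sprintf("s%02d", seq_len(n))))
}

# Minimal mouse-style sample sheet for screen unit tests.
toy_mouse_sheet <- function(n_case = 10, n_control = 5, timepoints = 1:4,
                            group = "MRLlpr") {
  rows <- list()
  for (t in timepoints) {
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = sprintf("%s_t%d_ca%02d", group, t, seq_len(n_case)),
      species = "mouse", group = group, role = "case", tissue = "none",
      week = t * 2, pseudotime = t, sledai = NA_real_,
      sex = NA_character_, age = NA_real_, batch = NA_character_,
      rin = NA_real_, stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = sprintf("%s_t%d_co%02d", group, t, seq_len(n_control)),
      species = "mouse", group = group, role = "control", tissue = "none",
      week = t * 2, pseudotime = t, sledai = NA_real_,
      sex = NA_character_, age = NA_real_, batch = NA_character_,
      rin = NA_real_, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Layer stack (module scores per tissue + the three measured layers) from a
# generated mouse cohort, the standard path into the screen.
cohort_layers <- function(cohort, min_module_genes = 10) {
  out <- list()
  for (nm in grep("^counts_", names(cohort$layers), value = TRUE)) {
    ts <- sub("^counts_", "", nm)
    v <- vst_counts(filter_low_expression(cohort$layers[[nm]]))
    proj <- project_modules(cohort$modules, cohort$homologs,
                            universe = rownames(v$values),
                            min_genes = min_module_genes)
    out[[paste0("modules_", ts)]] <- score_modules(v, proj)
  }
  out$cell_proportions <- log10p1(cohort$layers$cell_proportions)
  out$cytokines <- log10p1(cohort$layers$cytokines)
  out$autoantibodies <- log10p1(cohort$layers$autoantibodies)
  out
}

# Truth lookup for screened records: flags rows whose feature carries an
# injected interaction slope.
flag_truth <- function(records, truth) {
  tk <- paste(truth$interaction_features$layer,
              truth$interaction_features$tissue,
              truth$interaction_features$feature)
  paste(records$layer, records$tissue, records$feature) %in% tk
}
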