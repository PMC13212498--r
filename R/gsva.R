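# Sample-wise module scoring (rank random walk) -------------------------------
#
# The scorer summarizes expression into per-sample gene-set scores in three
# steps: (1) per gene, a Gaussian-kernel cumulative density estimate of each
# sample's value against the cross-sample distribution (bandwidth SD/4);
# (2) per sample, genes are ranked by that statistic and given symmetric rank
# scores |rank - (p+1)/2|; (3) a weighted Kolmogorov-Smirnov random walk over
# the ranked list, with inside-set increments proportional to r^tau and
# outside-set decrements 1/(p - k). Scores lie in [-1, 1].

# Per-gene kernel CDF statistic: z[i, j] = mean_k Phi((x[i,j] - x[i,k]) / h_i)
# with h_i = sd(x[i, ]) / 4. Constant genes get 0.5 everywhere (tie).
kernel_cdf_stat <- function(v, block_size = 64L) {
  p <- nrow(v)
  n <- ncol(v)
  z <- matrix(0.5, p, n, dimnames = dimnames(v))
  sds <- apply(v, 1, stats::sd)
  constant <- is.na(sds) | sds == 0
  if (any(constant)) {
    message(sprintf("%d constant gene(s) assigned tie statistic 0.5",
                    sum(constant)))
  }
  todo <- which(!constant)
  for (start in seq(1, length(todo), by = block_size)) {
    idx <- todo[start:min(start + block_size - 1L, length(todo))]
    b <- length(idx)
    h <- sds[idx] / 4
    # diffs[(gene,j), k] = (x[g,j] - x[g,k]) / h_g
    xi <- v[idx, , drop = FALSE]
    diffs <- (xi[, rep(seq_len(n), each = n), drop = FALSE] -
                xi[, rep(seq_len(n), times = n), drop = FALSE]) / h
    ph <- stats::pnorm(diffs)
    dim(ph) <- c(b, n, n)  # gene x k x j
    z[idx, ] <- colMeans(aperm(ph, c(2, 1, 3)))
  }
  z
}

# Ranked gene order per sample: decreasing statistic, ties broken by feature
# id lexicographic order (deterministic).
rank_order <- function(z) {
  ids <- rownames(z)
  tie_rank <- order(ids)  # permutation; use position of id in sorted order
  tie_pos <- match(ids, ids[order(ids)])
  apply(z, 2, function(col) order(-col, tie_pos))
}

# Random walk for one sample and one gene set (set given as logical over the
# ranked list). r = symmetric rank scores aligned with the ranked list.
walk_scores_one <- function(in_set, r, tau, score_mode) {
  p <- length(in_set)
  k <- sum(in_set)
  inc <- numeric(p)
  rw <- r[in_set]^tau
  inc[in_set] <- rw / sum(rw)
  inc[!in_set] <- -1 / (p - k)
  v <- cumsum(inc)
  if (score_mode == "max_diff") {
    max(v, 0) + min(v, 0)
  } else {
    # extremum selection on values rounded to 1e-12 so that exact rational
    # ties between the positive and negative deviation resolve by walk
    # position, not floating-point accumulation order
    v[which.max(abs(round(v, 12)))]
  }
}

#' Score gene modules per sample
#'
#' Computes per-sample enrichment scores for each module via a weighted
#' rank-based random walk over genes ordered by their cross-sample relative
#' expression (Gaussian-kernel CDF statistic, bandwidth SD/4). Under the
#' default `max_diff` mode the score is the sum of the maximal positive and
#' maximal negative walk deviations; `two_sided_max` reports the single
#' largest-magnitude deviation.
#'
#' @param m a transformed [layer_matrix()] (`vst` or `log10p1`; module-score
#'   inputs with transform `none` are also accepted).
#' @param modules named list of gene sets; every gene must be present in the
#'   matrix (run [project_modules()] first for mouse data).
#' @param tau rank-weight exponent (default 1).
#' @param score_mode `"max_diff"` (default) or `"two_sided_max"`.
#' @return A `modules` [layer_matrix()] (modules x samples, transform
#'   `"none"`), inheriting the tissue tag.
#' @export
score_modules <- function(m, modules, tau = 1,
                          score_mode = c("max_diff", "two_sided_max")) {
  stopifnot(inherits(m, "layer_matrix"))
  score_mode <- match.arg(score_mode)
  stop_if(m$transform == "raw",
          "score_modules expects a transformed layer (vst or log10p1)")
  v <- m$values
  stop_if(ncol(v) < 3,
          "need at least 3 samples for cross-sample relative expression")
  missing <- lapply(modules, function(g) setdiff(g, rownames(v)))
  bad <- lengths(missing) > 0
  stop_if(any(bad), "module gene(s) absent from matrix (%s): %s",
          paste(names(modules)[bad][1], collapse = ","),
          paste(utils::head(unlist(missing), 5), collapse = ", "))

  p <- nrow(v)
  n <- ncol(v)
  z <- kernel_cdf_stat(v)
  ord <- rank_order(z)                       # p x n, gene indices per sample
  r_by_rank <- abs(seq_len(p) - (p + 1) / 2) # symmetric rank scores

  set_idx <- lapply(modules, function(g) match(g, rownames(v)))
  scores <- matrix(NA_real_, length(modules), n,
                   dimnames = list(names(modules), colnames(v)))
  member <- logical(p)
  for (j in seq_len(n)) {
    oj <- ord[, j]
    for (s in seq_along(set_idx)) {
      member[] <- FALSE
      member[set_idx[[s]]] <- TRUE
      scores[s, j] <- walk_scores_one(member[oj], r_by_rank, tau, score_mode)
    }
  }
  layer_matrix(scores, "modules", tissue = m$tissue, transform = "none")
}
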