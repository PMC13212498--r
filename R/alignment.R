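# Distribution alignment of mouse time points to human severity --------------

#' Per-severity-level empirical cumulative curves of factor scores
#'
#' Factor scores are z-normalized within species (scale is arbitrary per
#' species in any factor model), then an empirical CDF is built per severity
#' level. Levels with fewer than `min_samples` observations are suppressed
#' with a warning.
#'
#' @param scores named numeric vector of one factor's scores (names =
#'   sample ids); normalization happens internally over all supplied
#'   samples.
#' @param axis a [map_severity()] result covering the samples.
#' @param min_samples minimum observations per level.
#' @return An object of class `ecdf_curves`: list of per-level score vectors
#'   (normalized) plus a tidy `curve` data.frame (`level`, `x`, `F`)
#'   evaluated on the pooled score grid.
#' @export
cumulative_curves <- function(scores, axis, min_samples = 3) {
  stop_if(is.null(names(scores)), "scores must be named by sample id")
  axis <- as.data.frame(axis)
  lev <- axis$level[match(names(scores), axis$sample_id)]
  stop_if(any(is.na(lev)), "severity level missing for some samples")
  z <- as.vector(scale(scores))
  names(z) <- names(scores)
  by_level <- split(z, lev)
  small <- names(by_level)[lengths(by_level) < min_samples]
  if (length(small) > 0) {
    warning(sprintf("suppressing level(s) with < %d samples: %s",
                    min_samples, paste(small, collapse = ", ")),
            call. = FALSE)
    by_level <- by_level[lengths(by_level) >= min_samples]
  }
  grid <- sort(unique(unlist(by_level)))
  curve <- do.call(rbind, lapply(names(by_level), function(lv) {
    data.frame(level = as.integer(lv), x = grid,
               F = stats::ecdf(by_level[[lv]])(grid))
  }))
  structure(list(samples = by_level, curve = curve), class = "ecdf_curves")
}

ks_distance <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(grid) - stats::ecdf(b)(grid)))
}

#' Match mouse pseudotimes to the top human severity stratum
#'
#' Computes the Kolmogorov-Smirnov distance between each mouse pseudotime's
#' normalized factor-score distribution and the human target-level
#' distribution; the best pseudotime attains the minimum (ties go to the
#' earliest time point). When even the minimum distance exceeds `ceiling`
#' the mouse trajectory is flagged as never reaching the human stratum
#' (`best_pseudotime = "none reached"`).
#'
#' @param curves_mouse,curves_human [cumulative_curves()] objects (mouse
#'   levels 2-5 correspond to pseudotimes 1-4).
#' @param target_level human severity label or level matched against
#'   (default `"very_high"` = level 5).
#' @param ceiling distance ceiling for the "none reached" call.
#' @return An object of class `alignment_result`: `distance` (named by
#'   pseudotime), `best_pseudotime` (integer or `"none reached"`),
#'   `min_distance`, `target_level`.
#' @export
match_timepoints <- function(curves_mouse, curves_human,
                             target_level = "very_high", ceiling = 0.5) {
  stopifnot(inherits(curves_mouse, "ecdf_curves"),
            inherits(curves_human, "ecdf_curves"))
  lv <- if (is.character(target_level)) {
    match(target_level, severity_labels)
  } else as.integer(target_level)
  stop_if(is.na(lv) || !as.character(lv) %in% names(curves_human$samples),
          "target level '%s' absent from human curves",
          as.character(target_level))
  target <- curves_human$samples[[as.character(lv)]]
  mouse_levels <- names(curves_mouse$samples)
  mouse_levels <- mouse_levels[mouse_levels != "1"]  # controls anchor
  stop_if(length(mouse_levels) == 0, "no mouse case severity levels")
  d <- vapply(mouse_levels, function(ml) {
    ks_distance(curves_mouse$samples[[ml]], target)
  }, numeric(1))
  pt <- as.integer(mouse_levels) - 1L
  names(d) <- pt
  best_i <- which(d == min(d))[1]  # ties -> earliest pseudotime
  structure(list(
    distance = d,
    best_pseudotime = if (min(d) > ceiling) "none reached" else pt[best_i],
    min_distance = unname(min(d)),
    target_level = severity_labels[lv]), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> target %s | best pseudotime: %s (min KS %.3f)\n",
              x$target_level, as.character(x$best_pseudotime),
              x$min_distance))
  invisible(x)
}

#' Associate human factor scores with clinical domains
#'
#' For each binary clinical-domain indicator, compares factor scores of
#' domain-positive and domain-negative patients: the effect is the log2
#' ratio of the group means after shifting all scores to be strictly
#' positive (shift `1 - min`), and the p-value comes from a rank-based
#' two-group comparison (unpaired rank-sum by default; a paired signed-rank
#' variant is available for matched designs). Domains with fewer than 3
#' positives or 3 negatives are reported untested.
#'
#' @param scores named numeric vector of one factor's human scores.
#' @param domains data.frame of binary indicators, rownames = sample ids.
#' @param test `"ranksum"` (default) or `"signedrank"`.
#' @return data.frame `domain`, `n_pos`, `n_neg`, `log2_fc`, `p`, `tier`
#'   (`**` p<0.01, `*` p<0.05, `.` p<0.1), `tested`.
#' @export
domain_association <- function(scores, domains,
                               test = c("ranksum", "signedrank")) {
  test <- match.arg(test)
  ids <- intersect(names(scores), rownames(domains))
  stop_if(length(ids) == 0, "no overlap between scores and domain table")
  s <- scores[ids]
  shift <- 1 - min(s)
  out <- lapply(names(domains), function(d) {
    pos <- domains[ids, d] == 1
    n_pos <- sum(pos)
    n_neg <- sum(!pos)
    if (n_pos < 3 || n_neg < 3) {
      return(data.frame(domain = d, n_pos = n_pos, n_neg = n_neg,
                        log2_fc = NA_real_, p = NA_real_, tier = "",
                        tested = FALSE, stringsAsFactors = FALSE))
    }
    eff <- log2(mean(s[pos] + shift) / mean(s[!pos] + shift))
    p <- if (test == "ranksum") {
      stats::wilcox.test(s[pos], s[!pos], exact = FALSE)$p.value
    } else {
      npair <- min(n_pos, n_neg)
      stats::wilcox.test(s[pos][seq_len(npair)], s[!pos][seq_len(npair)],
                         paired = TRUE, exact = FALSE)$p.value
    }
    tier <- if (p < 0.01) "**" else if (p < 0.05) "*" else
      if (p < 0.1) "." else ""
    data.frame(domain = d, n_pos = n_pos, n_neg = n_neg, log2_fc = eff,
               p = p, tier = tier, tested = TRUE, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
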