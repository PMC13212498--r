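# Multi-group multi-view factor decomposition with severity smoothness --------
#
# Linear-Gaussian model: for group g and view m,  Y[g,m] ~ Z[g] W[m]'.
# Loadings are shared across groups per view; factor scores are per group,
# with a per-(group, factor) squared-exponential Gaussian-process prior over
# the numeric severity covariate:  z ~ N(0, v * (s*K_l + (1-s)*I)).  The
# signal fraction s in [0,1] is the factor's smoothness in that group.
#
# Inference is deterministic block coordinate descent on a single penalized
# objective (an ELBO surrogate):
#   J = sum_m [ N D_m log sigma2_m + ||Y_m - W_m Z'||^2 / sigma2_m ]
#     + sum_k [ alpha_k sum_m ||W_m[,k]||^2 - D_tot log alpha_k ]      (ARD)
#     + sum_{g,k} [ z' C^{-1} z + log|C| ]                             (GP)
# Every update (ridge W, per-factor GP-posterior z, sigma2, alpha, and the
# grid search over (l, s, v)) minimizes its own block exactly, so J is
# non-increasing across iterations.

se_kernel <- function(x, ell) exp(-0.5 * outer(x, x, `-`)^2 / ell^2)

GP_JITTER <- 1e-6

# Cache of eigendecompositions of the SE kernel per group and lengthscale.
# M(s) = s*K + (1-s)*I + jitter*I shares eigenvectors across s.
kernel_cache <- function(x, ell_grid) {
  lapply(ell_grid, function(ell) {
    e <- eigen(se_kernel(x, ell), symmetric = TRUE)
    list(Q = e$vectors, lambda = pmax(e$values, 0))
  })
}

# Marginal objective z'C^{-1}z + log|C| with C = v * M(ell, s), minimized
# over the (ell, s) grid at fixed prior scale v (v is shared across groups
# per factor and updated in closed form afterwards). Returns the chosen
# hyperparameters and the quadratic form q = z' M^{-1} z.
gp_grid_search <- function(z, cache, ell_grid, s_grid, v) {
  n <- length(z)
  best <- list(obj = Inf)
  for (i in seq_along(ell_grid)) {
    zt2 <- as.vector(crossprod(cache[[i]]$Q, z))^2
    lam <- cache[[i]]$lambda
    for (s in s_grid) {
      mdiag <- s * lam + (1 - s) + GP_JITTER
      q <- sum(zt2 / mdiag)
      obj <- q / v + sum(log(mdiag)) + n * log(v)
      if (obj < best$obj) {
        best <- list(obj = obj, ell = ell_grid[i], s = s, idx = i, q = q)
      }
    }
  }
  best
}

# GP-regularized score update for one (group, factor): minimizes
# b * ||z - h/b||^2-type quadratic + z'C^{-1}z with C = v*M.
gp_posterior_mean <- function(h, b, cache_entry, s, v) {
  cdiag <- v * (s * cache_entry$lambda + (1 - s) + GP_JITTER)
  Qh <- crossprod(cache_entry$Q, h)
  as.vector(cache_entry$Q %*% (Qh / (b + 1 / cdiag)))
}

#' Fit the multi-group multi-view factor model
#'
#' Decomposes several molecular views observed on several sample groups into
#' shared latent factors whose per-group scores carry a Gaussian-process
#' smoothness prior over the disease-severity covariate. Views are centered
#' per feature within group internally (inputs arrive on their normalized
#' scales, not rescaled). Loadings are shared across groups; each view must
#' therefore expose the same feature set in every group.
#'
#' @param views nested named list: group -> view -> numeric matrix
#'   (features x samples, column names = sample ids).
#' @param axis a [map_severity()] result (or data.frame with `sample_id`,
#'   `covariate`) covering every sample.
#' @param K_init number of factors at initialization (default 15); automatic
#'   relevance determination down-weights unneeded ones.
#' @param max_iter,tol convergence controls (relative objective change).
#' @param ell_grid,s_grid grids for the GP lengthscale and signal fraction.
#' @param hyper_every update GP hyperparameters every this many iterations.
#' @param min_smoothness,min_var retention thresholds passed to
#'   [retain_factors()].
#' @param seed integer; used only for an infinitesimal symmetry-breaking
#'   perturbation of the deterministic PCA initialization.
#' @param Z_init optional warm-start score matrix (all samples x up to
#'   `K_init` columns, rows ordered as the concatenated groups); columns
#'   beyond `ncol(Z_init)` are initialized from the PCA solution.
#' @return An object of class `factor_model`: per-view loadings `W`,
#'   per-group scores `Z`, GP hyperparameters, noise variances,
#'   `variance_explained` (factor x view x group array), per-factor
#'   `smoothness` and `active` flags, and the objective trace.
#' @export
fit_factor_model <- function(views, axis, K_init = 15, max_iter = 1000,
                             tol = 1e-6,
                             ell_grid = seq(0.1, 2.0, by = 0.1),
                             s_grid = seq(0, 1, by = 0.1),
                             hyper_every = 1, min_smoothness = 0.5,
                             min_var = 0.01, seed = 1, Z_init = NULL) {
  groups <- names(views)
  stop_if(is.null(groups), "views must be a named list of groups")
  view_names <- names(views[[1]])
  for (g in groups) {
    stop_if(!identical(names(views[[g]]), view_names),
            "all groups must carry the same views, in the same order")
  }
  # common feature space per view, centered within group
  feats <- lapply(view_names, function(vn) {
    Reduce(intersect, lapply(groups, function(g) rownames(views[[g]][[vn]])))
  })
  names(feats) <- view_names
  for (vn in view_names) {
    stop_if(length(feats[[vn]]) < 1, "view '%s' has no shared features", vn)
  }
  Y <- list()     # view -> D_m x N matrix (groups concatenated)
  samples_g <- lapply(views, function(v) colnames(v[[1]]))
  for (g in groups) {
    for (vn in view_names) {
      m <- views[[g]][[vn]][feats[[vn]], samples_g[[g]], drop = FALSE]
      stop_if(any(is.na(m)), "view '%s' group '%s' contains NA", vn, g)
      Y[[vn]] <- cbind(Y[[vn]], m - rowMeans(m))
    }
  }
  N_g <- lengths(samples_g)
  N <- sum(N_g)
  g_index <- rep(groups, N_g)
  D_m <- vapply(Y, nrow, integer(1))
  D_tot <- sum(D_m)

  axis <- as.data.frame(axis)
  xs <- lapply(samples_g, function(ids) {
    xi <- axis$covariate[match(ids, axis$sample_id)]
    stop_if(any(is.na(xi)), "severity covariate missing for some samples")
    xi
  })
  sev_levels <- vapply(xs, function(x) length(unique(x)), integer(1))
  stop_if(any(sev_levels < 2),
          "each group needs >= 2 severity levels (group '%s' has %d)",
          groups[which.min(sev_levels)], min(sev_levels))
  caches <- lapply(xs, kernel_cache, ell_grid = ell_grid)

  # deterministic PCA initialization + seed-keyed infinitesimal perturbation
  X_all <- do.call(rbind, Y)
  K <- min(K_init, N - 1, D_tot)
  sv <- svd(X_all, nu = 0, nv = K)
  Z <- sv$v %*% diag(sv$d[seq_len(K)] / sqrt(D_tot), K)
  if (!is.null(Z_init)) {
    kk <- min(ncol(Z_init), K)
    Z[, seq_len(kk)] <- Z_init[, seq_len(kk)]
  }
  withr_seed(seed, {
    Z <- Z + matrix(stats::rnorm(length(Z), 0, 1e-8), nrow(Z))
  })
  rownames(Z) <- unlist(samples_g, use.names = FALSE)
  W <- lapply(Y, function(y) matrix(0, nrow(y), K,
                                    dimnames = list(rownames(y), NULL)))
  sigma2 <- vapply(Y, function(y) stats::var(as.vector(y)) / 2 + 1e-8,
                   numeric(1))
  alpha <- rep(1, K)
  v_k <- pmax(apply(Z, 2, stats::var), 1e-6)  # prior scale, shared per factor
  hyper <- array(list(), c(length(groups), K))
  for (gi in seq_along(groups)) {
    for (k in seq_len(K)) {
      hyper[[gi, k]] <- list(ell = ell_grid[5], s = 0.5, idx = 5L)
    }
  }

  objective <- function() {
    J <- 0
    for (vn in view_names) {
      ss <- sum((Y[[vn]] - W[[vn]] %*% t(Z))^2)
      J <- J + N * D_m[[vn]] * log(sigma2[[vn]]) + ss / sigma2[[vn]]
    }
    for (k in seq_len(K)) {
      J <- J + alpha[k] * sum(vapply(W, function(w) sum(w[, k]^2),
                                     numeric(1))) - D_tot * log(alpha[k])
      for (gi in seq_along(groups)) {
        hp <- hyper[[gi, k]]
        ce <- caches[[gi]][[hp$idx]]
        zk <- Z[g_index == groups[gi], k]
        mdiag <- hp$s * ce$lambda + (1 - hp$s) + GP_JITTER
        zt <- as.vector(crossprod(ce$Q, zk))
        J <- J + sum(zt^2 / (v_k[k] * mdiag)) + sum(log(v_k[k] * mdiag))
      }
    }
    J
  }

  trace <- numeric(0)
  J_prev <- Inf
  for (it in seq_len(max_iter)) {
    # (a) ridge/ARD loading update per view
    ZtZ <- crossprod(Z)
    for (vn in view_names) {
      A <- ZtZ + sigma2[[vn]] * diag(alpha, K)
      W[[vn]] <- t(solve(A, t(Y[[vn]] %*% Z)))
      rownames(W[[vn]]) <- rownames(Y[[vn]])
    }
    # (b) per-group, per-factor GP-regularized score update
    wsq <- vapply(seq_len(K), function(k) {
      sum(vapply(W, function(w) sum(w[, k]^2), numeric(1)))
    }, numeric(1))
    for (gi in seq_along(groups)) {
      sel <- g_index == groups[gi]
      for (k in seq_len(K)) {
        b <- sum(vapply(view_names, function(vn) {
          sum(W[[vn]][, k]^2) / sigma2[[vn]]
        }, numeric(1)))
        h <- rep(0, sum(sel))
        for (vn in view_names) {
          Rk <- crossprod(Y[[vn]][, sel, drop = FALSE], W[[vn]][, k]) -
            Z[sel, , drop = FALSE] %*% crossprod(W[[vn]], W[[vn]][, k]) +
            Z[sel, k] * sum(W[[vn]][, k]^2)
          h <- h + as.vector(Rk) / sigma2[[vn]]
        }
        hp <- hyper[[gi, k]]
        Z[sel, k] <- gp_posterior_mean(h, b, caches[[gi]][[hp$idx]],
                                       hp$s, v_k[k])
      }
    }
    # (c) noise variances
    for (vn in view_names) {
      sigma2[[vn]] <- max(sum((Y[[vn]] - W[[vn]] %*% t(Z))^2) /
                            (N * D_m[[vn]]), 1e-10)
    }
    # ARD precisions
    alpha <- pmin(pmax(D_tot / (vapply(seq_len(K), function(k) {
      sum(vapply(W, function(w) sum(w[, k]^2), numeric(1)))
    }, numeric(1)) + 1e-12), 1e-6), 1e9)
    # (d) GP hyperparameters by marginal-likelihood grid search
    if (it %% hyper_every == 0) {
      for (k in seq_len(K)) {
        q_tot <- 0
        for (gi in seq_along(groups)) {
          sel <- g_index == groups[gi]
          gs <- gp_grid_search(Z[sel, k], caches[[gi]], ell_grid, s_grid,
                               v_k[k])
          hyper[[gi, k]] <- list(ell = gs$ell, s = gs$s, idx = gs$idx)
          q_tot <- q_tot + gs$q
        }
        v_k[k] <- max(q_tot / N, 1e-10)  # closed-form scale update
      }
    }
    J <- objective()
    trace <- c(trace, J)
    if (is.finite(J_prev) && abs(J_prev - J) < tol * abs(J_prev)) break
    J_prev <- J
  }

  # fixed sign convention: the largest-|loading| entry of each factor is
  # positive
  for (k in seq_len(K)) {
    wk <- unlist(lapply(W, function(w) w[, k]), use.names = FALSE)
    if (wk[which.max(abs(wk))] < 0) {
      for (vn in view_names) W[[vn]][, k] <- -W[[vn]][, k]
      Z[, k] <- -Z[, k]
    }
  }

  Z_g <- lapply(groups, function(g) Z[g_index == g, , drop = FALSE])
  names(Z_g) <- groups
  smooth_s <- matrix(NA_real_, length(groups), K,
                     dimnames = list(groups, NULL))
  ell_mat <- smooth_s
  for (gi in seq_along(groups)) {
    for (k in seq_len(K)) {
      smooth_s[gi, k] <- hyper[[gi, k]]$s
      ell_mat[gi, k] <- hyper[[gi, k]]$ell
    }
  }

  model <- structure(list(
    K = K, groups = groups, views = view_names, features = feats,
    W = W, Z = Z_g, sigma2 = sigma2, alpha = alpha,
    gp_s = smooth_s, gp_ell = ell_mat, gp_v = v_k,
    axis = axis, n_iter = length(trace), objective_trace = trace,
    centered = Y, g_index = g_index, samples = samples_g
  ), class = "factor_model")
  model$variance_explained <- variance_explained(model)
  model$smoothness <- smoothness_score(model)
  model$active <- retain_factors(model, min_smoothness = min_smoothness,
                                 min_var = min_var)
  model
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model> %d factors (%d active) | views: %s | groups: %s | %d iterations\n",
              x$K, sum(x$active), paste(x$views, collapse = ", "),
              paste(x$groups, collapse = ", "), x$n_iter))
  invisible(x)
}
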