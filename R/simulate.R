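# Synthetic cohorts -----------------------------------------------------------
#
# The generator emulates the statistical structure the downstream analysis
# assumes: negative-binomial counts around lognormal gene means, logistic-
# normal cell proportions, lognormal serum analytes, latent severity-linked
# factors shared across layers (and species), and case-only group-by-
# pseudotime interaction slopes. Ground truth is always emitted alongside the
# data so every stage can be recovery-tested.

# Deterministic feature universe (no RNG): module genes are human ids
# HGENE0001.., partitioned sequentially into modules; mouse ids MGENE0001..
# pair with the human gene of the same index when the homolog map covers them.
feature_universe <- function(spec) {
  n_mod_genes <- spec$n_modules * spec$module_size
  stop_if(n_mod_genes > spec$n_genes,
          "n_modules * module_size exceeds n_genes (%d > %d)",
          n_mod_genes, spec$n_genes)
  human_genes <- sprintf("HGENE%04d", seq_len(n_mod_genes))
  mouse_genes <- sprintf("MGENE%04d", seq_len(spec$n_genes))
  module_ids <- sprintf("MOD%02d", seq_len(spec$n_modules))
  modules <- split(human_genes,
                   rep(seq_len(spec$n_modules), each = spec$module_size))
  names(modules) <- module_ids
  list(human_genes = human_genes,
       mouse_genes = mouse_genes,
       modules = modules,
       module_of_gene = stats::setNames(
         rep(module_ids, each = spec$module_size), human_genes),
       cell_types = sprintf("CT_%02d", seq_len(spec$n_cell_types)),
       cytokines = sprintf("CYT_%02d", seq_len(spec$n_cytokines)),
       autoantibodies = sprintf("AAB_%02d", seq_len(spec$n_autoantibodies)))
}

#' Generate a mouse-to-human homolog map
#'
#' Draws a one-to-one pairing covering `homolog_fraction` of the module gene
#' universe; the remaining genes stay unpaired. Deterministic for a fixed
#' spec seed.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame of class `homolog_map` with columns `mouse`, `human`.
#' @export
generate_homolog_map <- function(spec) {
  uni <- feature_universe(spec)
  n <- length(uni$human_genes)
  n_pair <- round(spec$homolog_fraction * n)
  withr_seed(child_seed(spec$seed, 2), {
    idx <- sort(sample.int(n, n_pair))
  })
  map <- data.frame(mouse = uni$mouse_genes[idx],
                    human = uni$human_genes[idx],
                    stringsAsFactors = FALSE)
  class(map) <- c("homolog_map", "data.frame")
  map
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Severity-response shapes of the smooth latent factors. The three shapes
# (shared linear, group-antisymmetric linear, centered quadratic) are mutually
# orthogonal over a symmetric covariate grid and carry distinct variance
# scales, which makes the factor decomposition identifiable.
smooth_shape_values <- function(x, k, group_sign = 1) {
  switch(k,
         `1` = 2.6 * (x - 0.5),
         `2` = group_sign * 1.7 * (x - 0.5),
         `3` = 3.2 * ((x - 0.5)^2 - 0.125),
         stop("at most 3 smooth factor shapes are defined"))
}

SCORE_NOISE <- 0.15    # per-sample noise on smooth factor scores
NONSMOOTH_SD <- 0.8    # SD of exchangeable (non-smooth) factor scores

# Per-factor score variance within one group arm under the null law, pooling
# time points: smooth factors contribute their severity-shape variance over
# the group's covariate grid plus per-sample noise; non-smooth factors their
# i.i.d. variance.
factor_score_variances <- function(x_grid, n_factors, n_smooth) {
  vapply(seq_len(n_factors), function(k) {
    if (k <= n_smooth) {
      v <- smooth_shape_values(x_grid, k, group_sign = 1)
      mean((v - mean(v))^2) + SCORE_NOISE^2
    } else NONSMOOTH_SD^2
  }, numeric(1))
}

# Per-feature within-group SD implied by the generative law (residual noise
# plus factor-score variation within a strain arm, pooled over time points).
# Injected interaction slopes are expressed in these units.
within_group_sd <- function(W, factor_vars, factor_strength, noise) {
  sqrt(noise^2 + factor_strength^2 * as.vector(W^2 %*% factor_vars))
}

# Latent factor scores for one group of samples. Smooth factors follow their
# severity shape plus small sample noise; non-smooth factors are i.i.d.
# Inactive (group_activity = FALSE) factors stay at zero.
draw_factor_scores <- function(x, spec_like, group_sign, activity,
                               score_noise = SCORE_NOISE,
                               nonsmooth_sd = NONSMOOTH_SD) {
  n <- length(x)
  K <- spec_like$n_factors
  Z <- matrix(0, n, K)
  for (k in seq_len(K)) {
    if (!activity[k]) next
    if (k <= spec_like$n_smooth_factors) {
      Z[, k] <- smooth_shape_values(x, k, group_sign) +
        stats::rnorm(n, 0, score_noise)
    } else {
      Z[, k] <- stats::rnorm(n, 0, nonsmooth_sd)
    }
  }
  Z
}

# Factor activity pattern per group: all factors active in the mouse strains;
# the third smooth factor is mouse-specific (inactive in humans), mirroring
# the presence of model-specific severity programs.
group_activity_matrix <- function(spec, groups) {
  act <- matrix(TRUE, spec$n_factors, length(groups),
                dimnames = list(NULL, groups))
  if ("human" %in% groups && spec$n_smooth_factors >= 3) {
    act[3, "human"] <- FALSE
  }
  act
}

#' Generate a synthetic mouse cohort
#'
#' Produces the full mouse arm: a sample sheet (one row per animal), raw
#' count matrices per tissue, spleen cell proportions (percent), serum
#' cytokines and autoantibodies, plus the simulation-truth ground truth
#' (latent factor scores, loadings, interaction features).
#'
#' Case animals carry the strain label of their model with `role = "case"`;
#' their genetic controls carry the same `group` label with
#' `role = "control"`, so case/control pairing is implicit in the sheet.
#' Features flagged as interaction features follow mean trajectories
#' `mu0 + beta3 * t` (transformed scale) in cases while controls stay flat;
#' `beta3` is `interaction_effect` within-group noise SDs per pseudotime step.
#'
#' @param spec a [cohort_spec()].
#' @return list with elements `sheet`, `layers` (named [layer_matrix()]s),
#'   `truth`, and `homologs`.
#' @export
generate_mouse_cohort <- function(spec) {
  spec <- validate_cohort_spec(spec)
  uni <- feature_universe(spec)
  homologs <- generate_homolog_map(spec)
  models <- mouse_model_names(spec$n_models)
  weeks <- pseudotime_weeks()

  rows <- list()
  for (m in models) {
    for (t in spec$timepoints) {
      wk <- weeks$week[weeks$model == m & weeks$pseudotime == t]
      for (role in c("case", "control")) {
        n <- if (role == "case") spec$n_case_per_timepoint else
          spec$n_control_per_timepoint
        ids <- sprintf("%s_t%d_%s%02d", m, t, substr(role, 1, 2), seq_len(n))
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = ids, species = "mouse", group = m, role = role,
          tissue = "none", week = wk, pseudotime = t,
          sledai = NA_real_, sex = NA_character_, age = NA_real_,
          batch = NA_character_, rin = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  sheet <- do.call(rbind, rows)
  validate_sample_sheet(sheet)
  n_samp <- nrow(sheet)
  is_case <- sheet$role == "case"
  pt <- sheet$pseudotime
  # Latent factors track the sampling schedule for cases AND controls alike:
  # with no interaction features, case and control trajectories follow the
  # same law (global interaction null). Case-specific divergence enters only
  # through the injected interaction slopes.
  x <- pt / 4

  out <- withr_seed(child_seed(spec$seed, 10), {
    act <- group_activity_matrix(spec, c(models, "human"))

    # latent factor scores, drawn per strain (group signs alternate)
    Z <- matrix(0, n_samp, spec$n_factors)
    for (gi in seq_along(models)) {
      sel <- sheet$group == models[gi]
      gsign <- if (gi %% 2 == 1) 1 else -1
      Z[sel, ] <- draw_factor_scores(x[sel], spec, gsign, act[, models[gi]])
    }

    # interaction features per layer
    n_int_mod <- round(spec$interaction_frac * spec$n_modules)
    int_modules <- sort(sample.int(spec$n_modules, n_int_mod))
    int_sign_mod <- sample(c(-1, 1), n_int_mod, replace = TRUE)
    pick <- function(nfeat, names) {
      k <- round(spec$interaction_frac * nfeat)
      idx <- sort(sample.int(nfeat, k))
      data.frame(feature = names[idx],
                 sign = sample(c(-1, 1), k, replace = TRUE),
                 stringsAsFactors = FALSE)
    }
    int_ct <- pick(spec$n_cell_types, uni$cell_types)
    int_cyt <- pick(spec$n_cytokines, uni$cytokines)
    int_aab <- pick(spec$n_autoantibodies, uni$autoantibodies)

    # module-level loadings shared across tissues; genes inherit their
    # module's loading with jitter so module scores show the factor signal
    W_mod <- matrix(stats::rnorm(spec$n_modules * spec$n_factors) *
                      stats::rbinom(spec$n_modules * spec$n_factors, 1, 0.5),
                    spec$n_modules, spec$n_factors,
                    dimnames = list(names(uni$modules), NULL))

    gene_module_idx <- match(uni$module_of_gene[uni$human_genes],
                             names(uni$modules))
    # mouse gene i pairs with human gene i; module membership via index
    mouse_mod_idx <- rep(NA_integer_, spec$n_genes)
    mouse_mod_idx[seq_along(gene_module_idx)] <- gene_module_idx

    gene_sign <- rep(0, spec$n_genes)
    for (j in seq_along(int_modules)) {
      g <- which(mouse_mod_idx == int_modules[j])
      gene_sign[g] <- int_sign_mod[j]
    }
    factor_vars <- factor_score_variances(spec$timepoints / 4,
                                          spec$n_factors,
                                          spec$n_smooth_factors)

    mu0 <- pmin(pmax(stats::rnorm(spec$n_genes, 5, 1.5), 1), 12)
    disp <- 0.05 + 2 / (2^mu0)
    tissue_scale <- c(blood = 0.8, spleen = 1, kidney = 0.6)

    layers <- list()
    loadings <- list()
    for (ts in spec$tissues) {
      W_gene <- matrix(stats::rnorm(spec$n_genes * spec$n_factors, 0, 0.3) *
                         stats::rbinom(spec$n_genes * spec$n_factors, 1, 0.3),
                       spec$n_genes, spec$n_factors)
      has_mod <- !is.na(mouse_mod_idx)
      W_gene[has_mod, ] <- W_mod[mouse_mod_idx[has_mod], ] +
        stats::rnorm(sum(has_mod) * spec$n_factors, 0, 0.15)
      W_gene <- tissue_scale[[ts]] * W_gene
      signal <- spec$factor_strength * tcrossprod(W_gene, Z)  # genes x samples
      # interaction slope expressed in within-group-SD units per step
      gene_beta3 <- spec$interaction_effect * gene_sign *
        within_group_sd(W_gene, factor_vars, spec$factor_strength,
                        spec$noise_sd$counts)
      inter <- outer(gene_beta3, ifelse(is_case, pt, 0))
      lmean <- mu0 + signal + inter +
        matrix(stats::rnorm(spec$n_genes * n_samp, 0, spec$noise_sd$counts),
               spec$n_genes, n_samp)
      sf <- exp(stats::rnorm(n_samp, 0, 0.15))
      mu <- sweep(2^lmean, 2, sf, `*`)
      counts <- matrix(stats::rnbinom(spec$n_genes * n_samp,
                                      mu = as.vector(mu),
                                      size = rep(1 / disp, n_samp)),
                       spec$n_genes, n_samp,
                       dimnames = list(uni$mouse_genes, sheet$sample_id))
      layers[[paste0("counts_", ts)]] <-
        layer_matrix(counts, "counts", tissue = ts, transform = "raw")
      loadings[[paste0("counts_", ts)]] <- W_gene
    }

    gauss_layer <- function(features, base, W, noise, int_tab, layer, tissue,
                            to_value, panel = NULL) {
      p <- length(features)
      sdw <- within_group_sd(W, factor_vars, spec$factor_strength, noise)
      if (!is.null(panel)) {
        # proportions pass through a panel-wise logistic transform before
        # measurement; calibrate the latent slope (delta method at the
        # baseline composition) so the injected effect is interaction_effect
        # within-arm SDs per step on the measured log10(percent + 1) scale
        lat_var <- sdw^2
        share <- exp(base)
        for (pn in unique(panel)) {
          sel <- panel == pn
          share[sel] <- share[sel] / (sum(share[sel]) + 1)
        }
        sdw <- vapply(seq_len(p), function(f) {
          mates <- panel == panel[f] & seq_len(p) != f
          sqrt((1 - share[f])^2 * lat_var[f] +
                 sum(share[mates]^2 * lat_var[mates])) / (1 - share[f])
        }, numeric(1))
      }
      beta3 <- rep(0, p)
      idx <- match(int_tab$feature, features)
      beta3[idx] <- spec$interaction_effect * sdw[idx] * int_tab$sign
      signal <- spec$factor_strength * tcrossprod(W, Z)
      latent <- base + signal + outer(beta3, ifelse(is_case, pt, 0)) +
        matrix(stats::rnorm(p * n_samp, 0, noise), p, n_samp)
      vals <- to_value(latent)
      dimnames(vals) <- list(features, sheet$sample_id)
      layer_matrix(vals, layer, tissue = tissue, transform = "raw",
                   unit = if (layer == "cell_proportions") "percent" else NULL)
    }
    draw_W <- function(p) matrix(stats::rnorm(p * spec$n_factors) *
                                   stats::rbinom(p * spec$n_factors, 1, 0.4),
                                 p, spec$n_factors)

    W_ct <- draw_W(spec$n_cell_types)
    panel <- rep(1:3, length.out = spec$n_cell_types)
    to_percent <- function(latent) {
      e <- exp(latent)
      for (pn in unique(panel)) {
        sel <- panel == pn
        tot <- colSums(e[sel, , drop = FALSE]) + 1  # +1: unmeasured rest mass
        e[sel, ] <- sweep(e[sel, , drop = FALSE], 2, tot, `/`)
      }
      100 * e
    }
    layers$cell_proportions <- gauss_layer(
      uni$cell_types, stats::rnorm(spec$n_cell_types, -2.5, 0.6), W_ct,
      spec$noise_sd$cell_proportions, int_ct, "cell_proportions", "spleen",
      to_percent, panel = panel)
    layers$cell_proportions$panel <- stats::setNames(panel, uni$cell_types)

    W_cyt <- draw_W(spec$n_cytokines)
    layers$cytokines <- gauss_layer(
      uni$cytokines, stats::rnorm(spec$n_cytokines, 2, 0.5), W_cyt,
      spec$noise_sd$cytokines, int_cyt, "cytokines", "none",
      function(l) 10^l)

    W_aab <- draw_W(spec$n_autoantibodies)
    layers$autoantibodies <- gauss_layer(
      uni$autoantibodies, stats::rnorm(spec$n_autoantibodies, 1.8, 0.4), W_aab,
      spec$noise_sd$autoantibodies, int_aab, "autoantibodies", "none",
      function(l) 10^l)

    loadings$modules <- W_mod
    loadings$cell_proportions <- W_ct
    loadings$cytokines <- W_cyt
    loadings$autoantibodies <- W_aab

    int_frame <- function(layer, tissue, tab) {
      if (nrow(tab) == 0) return(NULL)
      data.frame(layer = layer, tissue = tissue, feature = tab$feature,
                 sign = tab$sign, stringsAsFactors = FALSE)
    }
    interaction_features <- do.call(rbind, c(
      if (n_int_mod > 0) {
        lapply(spec$tissues, function(ts) data.frame(
          layer = "modules", tissue = ts,
          feature = names(uni$modules)[int_modules],
          sign = int_sign_mod, stringsAsFactors = FALSE))
      },
      list(int_frame("cell_proportions", "spleen", int_ct),
           int_frame("cytokines", "none", int_cyt),
           int_frame("autoantibodies", "none", int_aab))))
    if (is.null(interaction_features)) {
      interaction_features <- data.frame(layer = character(0),
                                         tissue = character(0),
                                         feature = character(0),
                                         sign = numeric(0))
    }

    truth <- list(
      factor_scores = `dimnames<-`(Z, list(sheet$sample_id, NULL)),
      loadings = loadings,
      smooth_flags = seq_len(spec$n_factors) <= spec$n_smooth_factors,
      group_activity = act,
      interaction_features = interaction_features,
      noise_sd = spec$noise_sd,
      covariate = stats::setNames(x, sheet$sample_id))
    class(truth) <- "simulation_truth"
    list(layers = layers, truth = truth)
  })

  list(sheet = sheet, layers = out$layers, truth = out$truth,
       homologs = homologs, modules = uni$modules)
}

#' Generate a synthetic human cohort
#'
#' SLE cases receive integer SLEDAI-2K scores populating all five disease
#' activity categories; shared smooth factors modulate the human views with
#' human-specific loadings; sex, age, sequencing batch and RNA-integrity
#' covariates are attached with small confounded effects so the case-control
#' preselection adjustment is exercised. Controls carry no SLEDAI-2K.
#' Module scores are generated directly on the score scale (transform
#' `"none"`), as when a precomputed module-score matrix is supplied.
#'
#' @param spec a [cohort_spec()].
#' @return list with elements `sheet`, `layers`, `domains` (per-case binary
#'   clinical-domain indicators) and `truth`.
#' @export
generate_human_cohort <- function(spec) {
  spec <- validate_cohort_spec(spec)
  uni <- feature_universe(spec)
  n_case <- spec$n_human_case
  n_ctrl <- spec$n_human_control
  n <- n_case + n_ctrl

  withr_seed(child_seed(spec$seed, 20), {
    # SLEDAI-2K: guarantee all five categories, then draw the rest
    cat_ranges <- list(0, 1:5, 6:10, 11:19, 20:30)
    cats <- c(1:5, sample.int(5, n_case - 5, replace = TRUE,
                              prob = c(0.22, 0.30, 0.25, 0.15, 0.08)))
    sledai <- vapply(cats, function(cc) {
      r <- cat_ranges[[cc]]
      if (length(r) == 1) r else sample(r, 1)
    }, numeric(1))

    sheet <- data.frame(
      sample_id = sprintf("HUM%05d", seq_len(n)),
      species = "human",
      group = rep(c("SLE", "HC"), c(n_case, n_ctrl)),
      role = rep(c("case", "control"), c(n_case, n_ctrl)),
      tissue = "blood",
      week = NA_real_, pseudotime = NA_integer_,
      sledai = c(sledai, rep(NA_real_, n_ctrl)),
      sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.85, 0.15)),
      age = round(pmin(pmax(stats::rnorm(n, 45, 12), 18), 85)),
      batch = sample(sprintf("B%d", 1:4), n, replace = TRUE),
      rin = round(pmin(pmax(stats::rnorm(n, 8.5, 0.7), 6), 10), 1),
      stringsAsFactors = FALSE)
    validate_sample_sheet(sheet)

    level <- ifelse(sheet$role == "control", 1L,
                    c(cats, rep(NA_integer_, n_ctrl)))
    x <- (level - 1) / 4
    models <- mouse_model_names(spec$n_models)
    act <- group_activity_matrix(spec, c(models, "human"))
    Z <- draw_factor_scores(x, spec, group_sign = 1, act[, "human"])

    n_diag <- round(spec$diagnosis_frac * spec$n_modules)
    diag_modules <- sort(sample.int(spec$n_modules, n_diag))
    diag_shift <- rep(0, spec$n_modules)
    diag_shift[diag_modules] <- spec$diagnosis_effect *
      sample(c(-1, 1), n_diag, replace = TRUE)

    draw_W <- function(p) matrix(stats::rnorm(p * spec$n_factors) *
                                   stats::rbinom(p * spec$n_factors, 1, 0.4),
                                 p, spec$n_factors)
    is_case <- sheet$role == "case"

    # module scores with confounded covariate effects
    W_modH <- draw_W(spec$n_modules)
    p <- spec$n_modules
    sex_eff <- stats::rnorm(p, 0, 0.03)
    age_eff <- stats::rnorm(p, 0, 0.004)
    rin_eff <- stats::rnorm(p, 0, 0.03)
    batch_eff <- matrix(stats::rnorm(p * 4, 0, 0.04), p, 4,
                        dimnames = list(NULL, sprintf("B%d", 1:4)))
    scores <- spec$factor_strength * tcrossprod(W_modH, Z) +
      outer(diag_shift, as.numeric(is_case)) +
      outer(sex_eff, as.numeric(sheet$sex == "M")) +
      outer(age_eff, sheet$age - 45) +
      outer(rin_eff, sheet$rin - 8.5) +
      batch_eff[, sheet$batch] +
      matrix(stats::rnorm(p * n, 0, spec$noise_sd$modules), p, n)
    dimnames(scores) <- list(names(uni$modules), sheet$sample_id)

    layers <- list(
      modules = layer_matrix(scores, "modules", tissue = "blood",
                             transform = "none"))

    gauss <- function(features, base, W, noise, to_value, layer, tissue,
                      unit = NULL) {
      pp <- length(features)
      latent <- base + spec$factor_strength * tcrossprod(W, Z) +
        matrix(stats::rnorm(pp * n, 0, noise), pp, n)
      vals <- to_value(latent)
      dimnames(vals) <- list(features, sheet$sample_id)
      layer_matrix(vals, layer, tissue = tissue, transform = "raw",
                   unit = unit)
    }
    W_ct <- draw_W(spec$n_cell_types)
    panel <- rep(1:3, length.out = spec$n_cell_types)
    to_percent <- function(latent) {
      e <- exp(latent)
      for (pn in unique(panel)) {
        sel <- panel == pn
        tot <- colSums(e[sel, , drop = FALSE]) + 1
        e[sel, ] <- sweep(e[sel, , drop = FALSE], 2, tot, `/`)
      }
      100 * e
    }
    layers$cell_proportions <- gauss(
      uni$cell_types, stats::rnorm(spec$n_cell_types, -2.5, 0.6), W_ct,
      spec$noise_sd$cell_proportions, to_percent, "cell_proportions", "blood",
      unit = "percent")
    layers$cell_proportions$panel <- stats::setNames(panel, uni$cell_types)
    cyt_h <- uni$cytokines[seq_len(spec$n_human_cytokines)]
    layers$cytokines <- gauss(
      cyt_h, stats::rnorm(spec$n_human_cytokines, 2, 0.5),
      draw_W(spec$n_human_cytokines), spec$noise_sd$cytokines,
      function(l) 10^l, "cytokines", "none")
    layers$autoantibodies <- gauss(
      uni$autoantibodies, stats::rnorm(spec$n_autoantibodies, 1.8, 0.4),
      draw_W(spec$n_autoantibodies), spec$noise_sd$autoantibodies,
      function(l) 10^l, "autoantibodies", "none")

    # binary SLEDAI clinical-domain indicators for cases, linked to severity
    domains <- c("renal", "cutaneous", "constitutional", "hematological")
    dom <- vapply(domains, function(d) {
      stats::rbinom(n_case, 1,
                    stats::plogis(-1.5 + 2.5 * x[is_case] +
                                    stats::rnorm(n_case, 0, 0.5)))
    }, numeric(n_case))
    rownames(dom) <- sheet$sample_id[is_case]

    truth <- list(
      factor_scores = `dimnames<-`(Z, list(sheet$sample_id, NULL)),
      loadings = list(modules = W_modH, cell_proportions = W_ct),
      smooth_flags = seq_len(spec$n_factors) <= spec$n_smooth_factors,
      diagnosis_modules = names(uni$modules)[diag_modules],
      covariate = stats::setNames(x, sheet$sample_id),
      severity_level = stats::setNames(level, sheet$sample_id))
    class(truth) <- "simulation_truth"

    list(sheet = sheet, layers = layers, domains = as.data.frame(dom),
         truth = truth)
  })
}

#' Generate the default multi-group multi-view factor scenario
#'
#' A compact generator used for factor-model recovery testing: `n_groups`
#' sample groups observed in `n_views` views, driven by three smooth
#' severity-linked factors (orthogonal response shapes) and one exchangeable
#' (non-smooth) factor. Group 2's second factor has the opposite severity
#' sign, which decorrelates the smooth factors across the pooled cohort.
#'
#' @param n_groups,n_views scenario dimensions.
#' @param n_features features per view.
#' @param n_per_level samples per severity level per group.
#' @param levels number of severity levels (equispaced covariate in `[0,1]`).
#' @param noise_sd residual SD of the observed views.
#' @param score_noise sample-level noise on the smooth factor scores.
#' @param seed RNG seed.
#' @return list with `views` (group -> view -> features x samples), `axis`
#'   (data.frame `sample_id`, `level`, `covariate`) and `truth`.
#' @export
generate_factor_views <- function(n_groups = 2, n_views = 3, n_features = 40,
                                  n_per_level = 12, levels = 5,
                                  noise_sd = 0.3, score_noise = 0.1,
                                  seed = 1) {
  spec_like <- list(n_factors = 4L, n_smooth_factors = 3L)
  withr_seed(seed, {
    W <- lapply(seq_len(n_views), function(v) {
      matrix(stats::rnorm(n_features * 4) *
               stats::rbinom(n_features * 4, 1, 0.6), n_features, 4,
             dimnames = list(sprintf("V%d_F%03d", v, seq_len(n_features)),
                             NULL))
    })
    names(W) <- sprintf("view%d", seq_len(n_views))
    views <- list()
    Zs <- list()
    axis <- list()
    for (g in seq_len(n_groups)) {
      x <- rep(seq(0, 1, length.out = levels), each = n_per_level)
      gsign <- if (g %% 2 == 1) 1 else -1
      Z <- draw_factor_scores(x, spec_like, gsign, rep(TRUE, 4),
                              score_noise = score_noise)
      ids <- sprintf("G%d_S%03d", g, seq_along(x))
      rownames(Z) <- ids
      gname <- sprintf("group%d", g)
      Zs[[gname]] <- Z
      views[[gname]] <- lapply(W, function(w) {
        y <- tcrossprod(w, Z) +
          matrix(stats::rnorm(n_features * length(x), 0, noise_sd),
                 n_features, length(x))
        colnames(y) <- ids
        y
      })
      axis[[gname]] <- data.frame(
        sample_id = ids,
        level = rep(seq_len(levels), each = n_per_level),
        covariate = x, stringsAsFactors = FALSE)
    }
    truth <- list(factor_scores = Zs, loadings = W,
                  smooth_flags = c(TRUE, TRUE, TRUE, FALSE))
    class(truth) <- "simulation_truth"
    list(views = views, axis = do.call(rbind, axis), truth = truth)
  })
}
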