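#' Synthetic cohort specification
#'
#' Collects every tunable of the synthetic-data generator. Defaults reproduce
#' the study layout the downstream analysis assumes: four spontaneous lupus
#' model strains sampled at four pseudotimes with 10 cases and 5 genetic
#' controls per time point, a human cohort of 342 SLE cases and 497 healthy
#' controls, and a homolog map covering ~69% of module genes. Molecular-layer
#' sizes are desk-scale; per-layer noise levels are free parameters of the
#' generator.
#'
#' @param n_models number of mouse case groups (strains), at most 4 named
#'   strains are available.
#' @param n_case_per_timepoint,n_control_per_timepoint animals per strain and
#'   time point.
#' @param timepoints ordinal pseudotime levels, strictly increasing, within
#'   1..4.
#' @param n_human_case,n_human_control human cohort sizes.
#' @param n_genes mouse gene universe size.
#' @param n_modules number of immunological gene modules.
#' @param module_size genes per module (modules partition the first
#'   `n_modules * module_size` human genes).
#' @param n_cell_types,n_cytokines,n_autoantibodies feature counts of the
#'   non-transcriptome layers.
#' @param n_human_cytokines size of the (narrower) human cytokine panel.
#' @param homolog_fraction proportion of module genes with a one-to-one mouse
#'   homolog.
#' @param tissues tissues profiled for mouse counts.
#' @param n_factors,n_smooth_factors latent factors linking the layers;
#'   the first `n_smooth_factors` vary smoothly with disease severity.
#' @param factor_strength scale of the factor signal on the transformed scale.
#' @param interaction_frac fraction of features per layer (and of modules for
#'   the transcriptome) given a case-only group-by-pseudotime slope; 0 yields
#'   a global-null cohort.
#' @param interaction_effect injected interaction slope, in units of the
#'   within-group noise SD per pseudotime step.
#' @param diagnosis_frac,diagnosis_effect fraction of human modules carrying a
#'   case-control shift and its size (transformed scale), exercised by the
#'   human preselection step.
#' @param noise_sd named list of per-layer residual SDs on the transformed
#'   scale.
#' @param seed integer RNG seed; the full generator is deterministic given it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_models = 4,
                        n_case_per_timepoint = 10,
                        n_control_per_timepoint = 5,
                        timepoints = 1:4,
                        n_human_case = 342,
                        n_human_control = 497,
                        n_genes = 300,
                        n_modules = 15,
                        module_size = 15,
                        n_cell_types = 20,
                        n_cytokines = 36,
                        n_autoantibodies = 8,
                        n_human_cytokines = 10,
                        homolog_fraction = 0.69,
                        tissues = c("blood", "spleen", "kidney"),
                        n_factors = 4,
                        n_smooth_factors = 3,
                        factor_strength = 0.5,
                        interaction_frac = 0.2,
                        interaction_effect = 1,
                        diagnosis_frac = 0.6,
                        diagnosis_effect = 0.3,
                        noise_sd = list(counts = 0.25, modules = 0.2,
                                        cell_proportions = 0.3,
                                        cytokines = 0.3,
                                        autoantibodies = 0.3),
                        seed = 1) {
  spec <- list(n_models = as.integer(n_models),
               n_case_per_timepoint = as.integer(n_case_per_timepoint),
               n_control_per_timepoint = as.integer(n_control_per_timepoint),
               timepoints = as.integer(timepoints),
               n_human_case = as.integer(n_human_case),
               n_human_control = as.integer(n_human_control),
               n_genes = as.integer(n_genes),
               n_modules = as.integer(n_modules),
               module_size = as.integer(module_size),
               n_cell_types = as.integer(n_cell_types),
               n_cytokines = as.integer(n_cytokines),
               n_autoantibodies = as.integer(n_autoantibodies),
               n_human_cytokines = as.integer(n_human_cytokines),
               homolog_fraction = homolog_fraction,
               tissues = match.arg(tissues, c("blood", "spleen", "kidney"),
                                   several.ok = TRUE),
               n_factors = as.integer(n_factors),
               n_smooth_factors = as.integer(n_smooth_factors),
               factor_strength = factor_strength,
               interaction_frac = interaction_frac,
               interaction_effect = interaction_effect,
               diagnosis_frac = diagnosis_frac,
               diagnosis_effect = diagnosis_effect,
               noise_sd = noise_sd,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  counts <- c("n_models", "n_case_per_timepoint", "n_control_per_timepoint",
              "n_human_case", "n_human_control", "n_genes", "n_modules",
              "module_size", "n_cell_types", "n_cytokines",
              "n_autoantibodies", "n_human_cytokines", "n_factors")
  for (f in counts) {
    stop_if(length(spec[[f]]) != 1 || is.na(spec[[f]]) || spec[[f]] < 1,
            "cohort_spec field '%s' must be a count >= 1", f)
  }
  stop_if(spec$n_case_per_timepoint < 2,
          "n_case_per_timepoint < 2: the longitudinal regression needs residual degrees of freedom")
  stop_if(spec$homolog_fraction < 0 || spec$homolog_fraction > 1,
          "homolog_fraction must lie in [0, 1]")
  stop_if(length(spec$timepoints) < 1 || any(diff(spec$timepoints) <= 0),
          "timepoints must be strictly increasing")
  stop_if(!all(spec$timepoints %in% 1:4), "timepoints must lie in 1..4")
  stop_if(spec$n_smooth_factors > spec$n_factors,
          "n_smooth_factors cannot exceed n_factors")
  stop_if(spec$n_models > 4, "at most 4 named model strains are available")
  stop_if(spec$n_modules * spec$module_size > spec$n_genes,
          "n_modules * module_size exceeds n_genes (%d > %d)",
          spec$n_modules * spec$module_size, spec$n_genes)
  stop_if(spec$n_human_cytokines > spec$n_cytokines,
          "human cytokine panel cannot exceed the mouse panel")
  stop_if(spec$n_human_case < 5,
          "n_human_case must be >= 5 so that all five severity categories can be populated")
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("<cohort_spec> %d strains x %d pseudotimes x (%d case + %d control); ",
                     "human %d/%d; %d genes, %d modules; seed %d\n"),
              x$n_models, length(x$timepoints), x$n_case_per_timepoint,
              x$n_control_per_timepoint, x$n_human_case, x$n_human_control,
              x$n_genes, x$n_modules, x$seed))
  invisible(x)
}

#' Model-specific sampling schedule
#'
#' The four spontaneous lupus strains progress at different rates, so each is
#' sampled at strain-specific weeks chosen to align phenotype progression;
#' the four sampling weeks per strain are referred to as pseudotimes 1-4.
#'
#' @return data.frame with columns `model`, `pseudotime`, `week`.
#' @export
pseudotime_weeks <- function() {
  data.frame(
    model = rep(c("MRLlpr", "NZBW", "BXSB_Yaa", "Tlr7Tg6"), each = 4),
    pseudotime = rep(1:4, times = 4),
    week = c(6, 12, 14, 16,   # MRL-lpr
             6, 12, 18, 28,   # NZB/W
             6, 12, 16, 20,   # BXSB.Yaa
             6, 12, 16, 28),  # Tlr7.Tg6
    stringsAsFactors = FALSE
  )
}

mouse_model_names <- function(n) {
  c("MRLlpr", "NZBW", "BXSB_Yaa", "Tlr7Tg6")[seq_len(n)]
}
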