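# Shared severity axis --------------------------------------------------------

sledai_level <- function(s) {
  stop_if(any(s < 0, na.rm = TRUE), "SLEDAI-2K must be non-negative")
  ifelse(s == 0, 1L,
         ifelse(s <= 5, 2L,
                ifelse(s <= 10, 3L,
                       ifelse(s <= 19, 4L, 5L))))
}

severity_labels <- c("no_activity", "mild", "moderate", "high", "very_high")

#' Map samples onto the shared disease-severity axis
#'
#' Places mice and humans on one five-level severity scale. Human cases are
#' binned by SLEDAI-2K (0 = no activity; 1-5 mild; 6-10 moderate; 11-19
#' high; >= 20 very high); mouse cases at pseudotime k sit at level k + 1
#' (pseudotime 1 aligns with human "mild": case mice never occupy "no
#' activity"); controls of either species anchor at level 1. The numeric
#' covariate used by the factor model is `(level - 1) / 4`, spanning 0 to 1.
#'
#' @param sheet sample sheet (mouse, human, or mixed).
#' @return data.frame of class `severity_axis`: `sample_id`, `level` (1-5),
#'   `label`, `covariate`.
#' @export
map_severity <- function(sheet) {
  validate_sample_sheet(sheet)
  level <- integer(nrow(sheet))
  is_ctrl <- sheet$role == "control"
  level[is_ctrl] <- 1L
  mcase <- sheet$species == "mouse" & !is_ctrl
  if (any(mcase)) {
    pt <- sheet$pseudotime[mcase]
    stop_if(any(is.na(pt)) || !all(pt %in% 1:4),
            "mouse pseudotime must lie in 1..4")
    level[mcase] <- as.integer(pt) + 1L
  }
  hcase <- sheet$species == "human" & !is_ctrl
  if (any(hcase)) {
    level[hcase] <- sledai_level(sheet$sledai[hcase])
  }
  out <- data.frame(sample_id = sheet$sample_id, level = level,
                    label = severity_labels[level],
                    covariate = (level - 1) / 4,
                    stringsAsFactors = FALSE)
  class(out) <- c("severity_axis", "data.frame")
  out
}
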