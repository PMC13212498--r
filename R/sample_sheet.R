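#' Validate a sample sheet
#'
#' Checks the per-sample metadata table used throughout the pipeline.
#' Mouse rows must carry a sampling week and a pseudotime in 1..4; human case
#' rows must carry a SLEDAI-2K score; control rows never carry SLEDAI-2K;
#' sample ids must be unique.
#'
#' @param sheet data.frame with columns `sample_id`, `species`
#'   (`"mouse"`/`"human"`), `group` (strain or diagnosis label), `role`
#'   (`"case"`/`"control"`), and the species-specific columns `week`,
#'   `pseudotime` (mouse), `sledai`, `sex`, `age`, `batch`, `rin` (human).
#' @return The sheet, invisibly, after validation.
#' @export
validate_sample_sheet <- function(sheet) {
  stop_if(!is.data.frame(sheet), "sample sheet must be a data.frame")
  required <- c("sample_id", "species", "group", "role")
  missing <- setdiff(required, names(sheet))
  stop_if(length(missing) > 0, "sample sheet lacks columns: %s",
          paste(missing, collapse = ", "))
  stop_if(anyDuplicated(sheet$sample_id) > 0,
          "duplicate sample_ids in sample sheet: %s",
          paste(unique(sheet$sample_id[duplicated(sheet$sample_id)])[1:1],
                collapse = ", "))
  stop_if(!all(sheet$species %in% c("mouse", "human")),
          "species must be 'mouse' or 'human'")
  stop_if(!all(sheet$role %in% c("case", "control")),
          "role must be 'case' or 'control'")
  mouse <- sheet[sheet$species == "mouse", , drop = FALSE]
  if (nrow(mouse) > 0) {
    stop_if(!all(c("week", "pseudotime") %in% names(sheet)),
            "mouse rows require 'week' and 'pseudotime' columns")
    stop_if(any(is.na(mouse$week)) || any(mouse$week <= 0),
            "mouse rows must have a positive sampling week")
    stop_if(any(is.na(mouse$pseudotime)) ||
              !all(mouse$pseudotime %in% 1:4),
            "mouse pseudotime must be an ordinal in 1..4")
  }
  human <- sheet[sheet$species == "human", , drop = FALSE]
  if (nrow(human) > 0) {
    stop_if(!("sledai" %in% names(sheet)),
            "human rows require a 'sledai' column")
    hcase <- human[human$role == "case", , drop = FALSE]
    stop_if(any(is.na(hcase$sledai)) || any(hcase$sledai < 0),
            "human case rows must carry a non-negative SLEDAI-2K")
    hctrl <- human[human$role == "control", , drop = FALSE]
    stop_if(any(!is.na(hctrl$sledai)),
            "control rows must not carry SLEDAI-2K")
  }
  invisible(sheet)
}

# Intersect a layer with the sheet's samples; warn about ids present on one
# side only (strict-intersection convention).
align_layer_to_sheet <- function(m, sheet) {
  common <- intersect(colnames(m$values), sheet$sample_id)
  dropped <- setdiff(colnames(m$values), common)
  if (length(dropped) > 0) {
    warning(sprintf("dropping %d samples absent from sample sheet (%s layer): %s",
                    length(dropped), m$layer,
                    paste(utils::head(dropped, 5), collapse = ", ")),
            call. = FALSE)
  }
  m$values <- m$values[, common, drop = FALSE]
  m
}
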