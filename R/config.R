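#' Pipeline configuration
#'
#' Bundles every threshold used by preprocessing and feature extraction.
#' All defaults follow the conventions of GGIR-style actigraphy processing
#' of GENEActiv wrist data in clinical cohorts; each can be overridden.
#'
#' @param valid_day_hours Minimum wear hours for a calendar day to count as
#'   valid (inclusive). Default 16.
#' @param min_valid_days Minimum number of valid days for a wear period to be
#'   usable. Default 7.
#' @param nonwear_sd_mg Stillness criterion: per-axis standard deviation
#'   threshold in milli-g over the 60-min window. Default 13.
#' @param nonwear_range_mg Per-axis value-range threshold in milli-g.
#'   Default 50.
#' @param nonwear_axes Minimum number of axes that must satisfy the stillness
#'   criterion. Default 2.
#' @param nonwear_block_min Block length in minutes to which non-wear
#'   classification is anchored. Default 15.
#' @param nonwear_window_min Length in minutes of the window centred on each
#'   block. Default 60.
#' @param low_temp_c Temperature threshold in deg C below which readings are
#'   treated as off-wrist artefacts and linearly interpolated. Default 24.
#' @param night_invalid_frac Maximum tolerated non-wear fraction of a
#'   noon-to-noon 24-h window for the night to stay valid. Default 0.10
#'   (strictly more than this excludes the night).
#' @param ma_q Half-width of the moving-average smoother applied to
#'   quarter-hour temperature series; window length is `2 * ma_q + 1` points.
#'   Default 3 (a 7-point window).
#' @param night_window_start,night_window_end Clock hours bounding the night
#'   window within which sleep may occur (19:00 to 14:00 next day).
#' @param day_window_start Clock hour starting the 24-h "day" window used for
#'   24-h temperature features (08:00 to 08:00 next day).
#' @param night_coverage_min Minimum number of quarter-hour values at or above
#'   `low_temp_c` in the 19:00-14:00 night window. Default 61.
#' @param day_coverage_min Same for the 97-point 08:00-08:00 day window.
#'   Default 77.
#' @param min_sleep_points Minimum number of quarter-hour points between sleep
#'   onset and offset. Default 15.
#' @param apen_m Embedding dimension for approximate entropy. Default 2.
#' @param apen_r_coeff Tolerance as a multiple of the series standard
#'   deviation. Default 0.2.
#' @param lr_inverse_reg Inverse regularization strength of the L2 logistic
#'   regression (larger is weaker penalty). Default 1.
#' @param m_sel Number of features retained by selection. Default 10.
#'
#' @return A named list of class `wf_config`.
#' @export
#' @examples
#' cfg <- wf_config()
#' cfg$low_temp_c
wf_config <- function(valid_day_hours = 16,
                      min_valid_days = 7,
                      nonwear_sd_mg = 13,
                      nonwear_range_mg = 50,
                      nonwear_axes = 2,
                      nonwear_block_min = 15,
                      nonwear_window_min = 60,
                      low_temp_c = 24,
                      night_invalid_frac = 0.10,
                      ma_q = 3,
                      night_window_start = 19,
                      night_window_end = 14,
                      day_window_start = 8,
                      night_coverage_min = 61,
                      day_coverage_min = 77,
                      min_sleep_points = 15,
                      apen_m = 2,
                      apen_r_coeff = 0.2,
                      lr_inverse_reg = 1,
                      m_sel = 10) {
  cfg <- as.list(environment())
  stopifnot(valid_day_hours > 0, min_valid_days >= 1,
            nonwear_sd_mg > 0, nonwear_range_mg > 0,
            nonwear_axes %in% 1:3, night_invalid_frac >= 0,
            ma_q >= 0, apen_m >= 1, apen_r_coeff >= 0, m_sel >= 1)
  structure(cfg, class = "wf_config")
}

#' @export
print.wf_config <- function(x, ...) {
  cat("<wf_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
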