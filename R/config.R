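#' Default pipeline configuration
#'
#' All tunable constants of the annotation pipeline in one nested list:
#' evaluation tolerance (50 ms), peak-detection thresholds (400 ms minimum
#' distance, 0.5 relative height), local-cyclicity settings (noise threshold
#' 1.0, 0.5-6 Hz), feature windowing (70 ms window, 5 ms step), the hHMM
#' architecture (4 internal states per phase, 3 per simple activity, 10 EM
#' iterations, 100 training iterations), the insole-to-IMU synchronization
#' grid (ratio 1.4-3.3, resolution 0.001), and the empirically calibrated
#' rest-energy threshold. Values can be overridden via a YAML/JSON file with
#' the same structure.
#'
#' @param path Optional path to a YAML or JSON override file.
#' @return Nested named list of configuration values.
#' @export
default_config <- function(path = NULL) {
  cfg <- list(
    eval = list(tolerance_s = 0.05, require_label_match = FALSE),
    features = list(window_s = 0.070, step_s = 0.005),
    lowpass = list(cutoff_hz = 15, order = 4),
    rest = list(window_s = 0.300, threshold = 0.016),
    sync = list(ratio_min = 1.4, ratio_max = 3.3, ratio_step = 0.001,
                max_lag_s = 2.0),
    edges = list(min_strength = 8.0, cluster_s = 0.100,
                 min_stance_s = 0.08, min_swing_s = 0.08),
    pd = list(min_distance_s = 0.4, min_height = 0.5, smooth_cutoff_hz = 10),
    lce = list(noise_threshold = 1.0, f_min = 0.5, f_max = 6.0),
    hhmm = list(n_internal_cyclic = 4L, n_internal_simple = 3L,
                em_iterations = 10L, train_iterations = 100L,
                emission_components = 1L, variance_floor = 1e-3,
                logdens_floor = -1e10),
    postprocess = list(outlier_k = 3)
  )
  if (!is.null(path)) {
    over <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("yaml package required to read YAML config")
      }
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = TRUE)
    }
    cfg <- modify_list_deep(cfg, over)
  }
  cfg
}

modify_list_deep <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}
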