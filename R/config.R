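#' Default run configuration
#'
#' All tunable constants of the simulator in one validated list. Printed
#' architectural constants (16x16 sensor grid, 16 iterations of 12 ms per
#' saccade, 6 video frames, component-bump sd of 1/16 of the image, map decay
#' a = 1/2) follow the modelled study; generator and reservoir settings are
#' package defaults documented in the methods vignette.
#'
#' @return A named list of class `ag_config`.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$iterations_per_saccade * cfg$ms_per_iteration  # 192 ms per saccade
default_config <- function() {
  structure(list(
    # -- scene / rendering -----------------------------------------------
    full_res          = 128L,   # full-resolution image side (pixels)
    coarse_grid       = 16L,    # sensor grid side (16 x 16 = 256 cells)
    n_frames          = 6L,     # video frames = saccade epochs per trial
    window_sd         = 0.08,   # foveal Gaussian window sd (image units)
    # -- kinematics generator --------------------------------------------
    n_actors          = 6L,
    n_moves_per_actor = 50L,
    noise_sd_pow      = 2.5,    # within-trial angle noise (deg), power grasp
    noise_sd_pre      = 2.5,    # within-trial angle noise (deg), precision grip
    approach_speed_pow = 0.85,  # transport-profile exponent; <1 = faster reach
    approach_speed_pre = 1.30,  # to the small target: slower, per Fitts law
    actor_sd          = 2.0,    # between-actor systematic angle offset sd (deg)
    pos_noise_sd      = 0.015,  # per-frame hand position jitter (image units)
    start_jitter_sd   = 0.015,  # per-trial start-position jitter (image units)
    shape_lead_pow    = 1.5,    # preshape progress exponent, power grasp (late whole-hand closure)
    shape_lead_pre    = 0.5,    # precision grip: opposition forms early in the reach
    # -- reservoir / readout ---------------------------------------------
    n_units           = 100L,
    spectral_radius   = 0.9,
    leak_rate         = 0.5,
    input_scaling     = 0.5,
    ridge_lambda      = 0.5,    # readout ridge prior precision
    novelty_scale     = 6.0,    # off-manifold prior sd, in target-sd units
    washout           = 1L,     # frames consumed before the first scored prediction
    # -- inference --------------------------------------------------------
    prior_mode        = "uniform",  # "uniform" or "biased" (Gaussian .57, var .01)
    prior_big         = 0.5,
    beta_temper       = 1.0,    # likelihood tempering exponent
    # -- salience map -----------------------------------------------------
    rho_sd            = 1 / 16, # component-bump sd (fraction of image size)
    decay_a           = 0.5,    # R_k decay weight
    sigma_obj_min     = 0.17,   # object-term sd at zero posterior entropy
    sigma_obj_max     = 0.30,   # object-term sd at maximal posterior entropy
    bg_weight         = 0.05,   # background emission weight of the foveal channel
    class_kappa       = 20,     # soft hand-symbol classification scale (deg)
    sample_c_points   = FALSE,  # if TRUE, sample c1/c2 instead of using means
    ablate_object_components = FALSE,  # diagnostic: zero the object map weights
    # -- oculomotor -------------------------------------------------------
    iterations_per_saccade = 16L,
    ms_per_iteration  = 12L,
    saccade_gain      = 0.35,
    decision_radius   = 0.06,   # image units; ~ one coarse grid cell
    hand_radius       = 0.09,   # radius for classifying HAND fixations (moving-hand AOI)
    seed              = 1L
  ), class = "ag_config")
}

ag_config_checks <- list(
  full_res          = function(x) is.numeric(x) && x >= 32 && x %% 16 == 0,
  coarse_grid       = function(x) identical(as.integer(x), 16L),
  n_frames          = function(x) is.numeric(x) && x >= 2,
  window_sd         = function(x) is.numeric(x) && x > 0 && x < 1,
  n_actors          = function(x) is.numeric(x) && x >= 1,
  n_moves_per_actor = function(x) is.numeric(x) && x >= 1,
  noise_sd_pow      = function(x) is.numeric(x) && x >= 0,
  noise_sd_pre      = function(x) is.numeric(x) && x >= 0,
  approach_speed_pow = function(x) is.numeric(x) && x > 0,
  approach_speed_pre = function(x) is.numeric(x) && x > 0,
  actor_sd          = function(x) is.numeric(x) && x >= 0,
  pos_noise_sd      = function(x) is.numeric(x) && x >= 0,
  start_jitter_sd   = function(x) is.numeric(x) && x >= 0,
  shape_lead_pow    = function(x) is.numeric(x) && x > 0,
  shape_lead_pre    = function(x) is.numeric(x) && x > 0,
  n_units           = function(x) is.numeric(x) && x >= 1,
  spectral_radius   = function(x) is.numeric(x) && x >= 0 && x < 1,
  leak_rate         = function(x) is.numeric(x) && x > 0 && x <= 1,
  input_scaling     = function(x) is.numeric(x) && x > 0,
  ridge_lambda      = function(x) is.numeric(x) && x > 0,
  novelty_scale     = function(x) is.numeric(x) && x >= 0,
  washout           = function(x) is.numeric(x) && x >= 0,
  prior_mode        = function(x) x %in% c("uniform", "biased"),
  prior_big         = function(x) is.numeric(x) && x > 0 && x < 1,
  beta_temper       = function(x) is.numeric(x) && x > 0,
  rho_sd            = function(x) is.numeric(x) && x > 0,
  decay_a           = function(x) is.numeric(x) && x >= 0 && x < 1,
  sigma_obj_min     = function(x) is.numeric(x) && x > 0,
  sigma_obj_max     = function(x) is.numeric(x) && x > 0,
  bg_weight         = function(x) is.numeric(x) && x > 0,
  class_kappa       = function(x) is.numeric(x) && x > 0,
  sample_c_points   = function(x) is.logical(x) && length(x) == 1L,
  ablate_object_components = function(x) is.logical(x) && length(x) == 1L,
  iterations_per_saccade = function(x) is.numeric(x) && x >= 1,
  ms_per_iteration  = function(x) is.numeric(x) && x >= 1,
  saccade_gain      = function(x) is.numeric(x) && x > 0 && x < 1,
  decision_radius   = function(x) is.numeric(x) && x > 0 && x < 0.1,
  hand_radius       = function(x) is.numeric(x) && x > 0,
  seed              = function(x) is.numeric(x)
)

#' Validate a configuration list
#'
#' @param cfg A list of configuration values.
#' @return The validated `ag_config` object (invisibly errors otherwise).
#' @export
validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), names(ag_config_checks))
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(cfg)) {
    if (!isTRUE(ag_config_checks[[nm]](cfg[[nm]]))) {
      stop("invalid value for config field '", nm, "'", call. = FALSE)
    }
  }
  if (cfg$sigma_obj_max < cfg$sigma_obj_min) {
    stop("invalid value for config field 'sigma_obj_max' (must be >= sigma_obj_min)",
         call. = FALSE)
  }
  structure(cfg, class = "ag_config")
}

#' Load a run configuration from YAML or JSON
#'
#' Missing fields take their defaults; unknown fields are rejected. An empty
#' file yields the full default configuration.
#'
#' @param path Path to a YAML (or JSON) configuration file.
#' @return A validated `ag_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(user)) user <- list()
  cfg <- utils::modifyList(as.list(default_config()), user)
  cfg <- validate_config(cfg)
  ag_log("effective config: ", paste(names(cfg), unlist(lapply(cfg, format)),
                                     sep = "=", collapse = " "))
  cfg
}

#' Save a configuration to YAML
#'
#' @param cfg An `ag_config` list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  cfg <- validate_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.ag_config <- function(x, ...) {
  cat("<activegaze config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
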