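#' Generative parameters of one rhythmic channel
#'
#' A channel (a clock gene's relative expression, a hormone concentration, or
#' binned swimming velocity) is generated as a fixed-period 24-h cosine
#' \deqn{x(t) = M(b) + A(b)\cos\big(2\pi (t-\phi)/24\big) D(t) + \varepsilon}
#' where `b` is the individual's boldness, mesor `M` and amplitude `A`
#' interpolate linearly between the shy (`b = 0`) and bold (`b = 1`) extremes,
#' `phi` is the acrophase (clock time of peak, hCT), `D(t)` is 1 under
#' light-dark cycling and an exponentially decaying factor under constant
#' light, and `eps` is Gaussian noise with standard deviation
#' `noise_cv * M(b)`.
#'
#' `scale_log_sd` adds a per-individual multiplicative scale (log-normal,
#' applied to mesor and amplitude alike) emulating stable individual
#' differences in overall output that are unrelated to personality; it is used
#' for the locomotor channel, where overall activity level varies strongly
#' between fish while the *relative* strength of the 24-h component tracks
#' boldness.
#'
#' @param mesor_at_bold,mesor_at_shy Mesor at the bold (`b = 1`) and shy
#'   (`b = 0`) end, in channel units.
#' @param amplitude_at_bold,amplitude_at_shy Cosine amplitude at the two
#'   extremes; must be non-negative.
#' @param acrophase Clock time of the peak, hours in `[0, 24)`.
#' @param period Rhythm period in hours; fixed at 24.
#' @param noise_cv Coefficient of variation of the additive noise (relative
#'   to the individual's mesor).
#' @param scale_log_sd Standard deviation (log scale) of the per-individual
#'   multiplicative scale; 0 disables it.
#' @param floor_at_zero Clamp generated values at 0 (concentrations and
#'   velocities are non-negative).
#' @param units Unit label carried through to outputs.
#' @return An object of class `rhythm_gen_params`.
#' @examples
#' rhythm_gen_params(10, 6, 4, 0.4, acrophase = 17)
#' @export
rhythm_gen_params <- function(mesor_at_bold, mesor_at_shy,
                              amplitude_at_bold, amplitude_at_shy,
                              acrophase, period = 24, noise_cv = 0.12,
                              scale_log_sd = 0, floor_at_zero = TRUE,
                              units = "") {
  if (!identical(period, 24) && period != 24) {
    abort("`period` is fixed at 24 h.", class = "chronocope_config_error")
  }
  if (amplitude_at_bold < 0 || amplitude_at_shy < 0) {
    abort("amplitudes must be >= 0.", class = "chronocope_config_error")
  }
  if (acrophase < 0 || acrophase >= 24) {
    abort("`acrophase` must lie in [0, 24) hCT.",
          class = "chronocope_config_error")
  }
  if (noise_cv < 0 || scale_log_sd < 0) {
    abort("noise parameters must be >= 0.", class = "chronocope_config_error")
  }
  structure(
    list(mesor_at_bold = mesor_at_bold, mesor_at_shy = mesor_at_shy,
         amplitude_at_bold = amplitude_at_bold,
         amplitude_at_shy = amplitude_at_shy,
         acrophase = acrophase, period = 24, noise_cv = noise_cv,
         scale_log_sd = scale_log_sd, floor_at_zero = floor_at_zero,
         units = units),
    class = "rhythm_gen_params")
}

#' Default channel calibration
#'
#' Generative parameters for the five clock genes (relative expression), the
#' two hormones and the locomotor-activity channel. Bold fish carry large
#' amplitudes; shy fish are nearly flat (genes keep 10% of the bold
#' amplitude, hormones none). Cortisol is constantly high in shy fish
#' (mesor 2.5x the bold mesor), melatonin sits at an intermediate flat level,
#' and clock-gene mesors fall from bold to shy -- most steeply for *bmal1a*
#' and *cipca*, whose net transcriptional output carries the clearest
#' rank trend.
#'
#' @return Named list of [rhythm_gen_params()] objects.
#' @export
default_channel_params <- function() {
  list(
    bmal1a    = rhythm_gen_params(10,   6,   4,   0.4,  acrophase = 17,
                                  units = "rel. expression"),
    clock1a   = rhythm_gen_params(8,    7.2, 2.5, 0.25, acrophase = 17,
                                  units = "rel. expression"),
    per1a     = rhythm_gen_params(10,   9,   5,   0.5,  acrophase = 1,
                                  units = "rel. expression"),
    cry1a     = rhythm_gen_params(9,    8.1, 3.5, 0.35, acrophase = 3,
                                  units = "rel. expression"),
    cipca     = rhythm_gen_params(12,   7,   6,   0.6,  acrophase = 7,
                                  units = "rel. expression"),
    cortisol  = rhythm_gen_params(10,   25,  8,   0,    acrophase = 1,
                                  units = "ng g^-1"),
    melatonin = rhythm_gen_params(100,  130, 80,  0,    acrophase = 19,
                                  units = "pg g^-1"),
    activity  = rhythm_gen_params(5,    4,   3.5, 0.2,  acrophase = 1,
                                  noise_cv = 0.5, scale_log_sd = 0.6,
                                  units = "mm s^-1")
  )
}

#' Mirror-image stimulation generative parameters
#'
#' @param agr_rate_bold,agr_rate_shy Poisson rate (events per second of
#'   mirror-directed time) of aggressive acts at the bold and shy extreme.
#' @param frz_scale,frz_onset Freezing duration grows as
#'   `frz_scale * max(0, (1 - boldness) - frz_onset)` seconds.
#' @param frz_noise_mean,lfa_noise_mean Means of exponential noise added to
#'   freezing and approach latency.
#' @param lfa_base,lfa_slope Latency to first approach:
#'   `lfa_base + lfa_slope * (1 - boldness)` seconds before noise.
#' @return Object of class `mirror_params`.
#' @export
mirror_params <- function(agr_rate_bold = 0.25, agr_rate_shy = 0.01,
                          frz_scale = 550, frz_onset = 0.35,
                          frz_noise_mean = 20, lfa_base = 5,
                          lfa_slope = 100, lfa_noise_mean = 10) {
  structure(list(agr_rate_bold = agr_rate_bold, agr_rate_shy = agr_rate_shy,
                 frz_scale = frz_scale, frz_onset = frz_onset,
                 frz_noise_mean = frz_noise_mean, lfa_base = lfa_base,
                 lfa_slope = lfa_slope, lfa_noise_mean = lfa_noise_mean),
            class = "mirror_params")
}

#' Cohort configuration
#'
#' Bundles every generative choice of a synthetic cohort: its size, the
#' latency model of the emergence test, the rhythmic channels and the
#' constant-light damping. The same configuration (including `seed`) always
#' produces byte-identical cohorts and sessions.
#'
#' The emergence latency of individual `i` in one session is
#' \deqn{L = s \exp\{\beta (1 - b_i) + u_i + e\}}
#' with scale `s = latency_scale` (seconds), boldness slope `beta`, a stable
#' individual deviation `u_i ~ N(0, latency_individual_sd^2)` and fresh
#' session noise `e ~ N(0, latency_residual_sd^2)`, both on the log scale.
#'
#' @param n_groups Number of emergence-test groups.
#' @param group_size Fish per group (>= 2; the study design uses 10).
#' @param seed Integer cohort seed; all randomness derives from it via
#'   [substream_seed()].
#' @param latency_scale Latency scale `s`, seconds.
#' @param latency_boldness_slope Log-scale slope `beta` of latency on
#'   `1 - boldness`.
#' @param latency_individual_sd,latency_residual_sd Log-scale standard
#'   deviations of the stable individual effect and of per-session noise.
#' @param emergence_cutoff Group-test emergence cutoff, seconds (fish not
#'   emerging within it are excluded from ranking).
#' @param single_cutoff Single-test cutoff, seconds.
#' @param channel_params Named list of [rhythm_gen_params()].
#' @param ll_damping_halflife Half-life (hours) of amplitude damping under
#'   constant light.
#' @param sampling_times Circadian sampling times (hCT) for gene and hormone
#'   channels.
#' @param mirror [mirror_params()] for the mirror-image stimulation test.
#' @param vmax_ceiling Escape-burst ceiling (mm s^-1, multiplied by the
#'   fish's individual activity scale); bursts make the maximum velocity
#'   personality-independent.
#' @param bursts_per_day Number of escape bursts per fish per day.
#' @param body_weight_mean,body_weight_sd Body-weight distribution (mg),
#'   independent of boldness.
#' @return Object of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n_groups = 2, seed = 7)
#' cfg$n_groups
#' @export
cohort_config <- function(n_groups = 9, group_size = 10, seed = 1,
                          latency_scale = 30, latency_boldness_slope = 4,
                          latency_individual_sd = 0.1,
                          latency_residual_sd = 0.1,
                          emergence_cutoff = 600, single_cutoff = 3600,
                          channel_params = default_channel_params(),
                          ll_damping_halflife = 20,
                          sampling_times = c(1, 7, 13, 15, 19, 23),
                          mirror = mirror_params(),
                          vmax_ceiling = 20, bursts_per_day = 3,
                          body_weight_mean = 150.61, body_weight_sd = 17.99) {
  if (n_groups < 1 || group_size < 2) {
    abort("need `n_groups` >= 1 and `group_size` >= 2.",
          class = "chronocope_config_error")
  }
  if (latency_individual_sd < 0 || latency_residual_sd < 0) {
    abort("latency standard deviations must be >= 0.",
          class = "chronocope_config_error")
  }
  if (ll_damping_halflife <= 0) {
    abort("`ll_damping_halflife` must be positive.",
          class = "chronocope_config_error")
  }
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (!all(vapply(channel_params, inherits, logical(1), "rhythm_gen_params"))) {
    abort("`channel_params` must be a list of rhythm_gen_params objects.",
          class = "chronocope_config_error")
  }
  structure(
    list(n_groups = as.integer(n_groups), group_size = as.integer(group_size),
         seed = as.integer(seed), latency_scale = latency_scale,
         latency_boldness_slope = latency_boldness_slope,
         latency_individual_sd = latency_individual_sd,
         latency_residual_sd = latency_residual_sd,
         emergence_cutoff = emergence_cutoff, single_cutoff = single_cutoff,
         channel_params = channel_params,
         ll_damping_halflife = ll_damping_halflife,
         sampling_times = sampling_times, mirror = mirror,
         vmax_ceiling = vmax_ceiling, bursts_per_day = bursts_per_day,
         body_weight_mean = body_weight_mean, body_weight_sd = body_weight_sd),
    class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> ", x$n_groups, " group(s) of ", x$group_size,
      ", seed ", x$seed, "\n", sep = "")
  cat("  latency: scale ", x$latency_scale, " s, slope ",
      x$latency_boldness_slope, ", sd(ind) ", x$latency_individual_sd,
      ", sd(res) ", x$latency_residual_sd, "\n", sep = "")
  cat("  channels:", paste(names(x$channel_params), collapse = ", "), "\n")
  invisible(x)
}

#' Noise-free copy of a configuration
#'
#' Zeroes every stochastic component (latency noise, channel noise,
#' per-individual scale) while keeping the deterministic structure; used
#' for limit-case analyses where metrics must be exact functions of
#' boldness.
#'
#' @param config A [cohort_config()].
#' @return The modified configuration.
#' @export
noise_free <- function(config) {
  config$latency_individual_sd <- 0
  config$latency_residual_sd <- 0
  config$channel_params <- lapply(config$channel_params, function(p) {
    p$noise_cv <- 0
    p$scale_log_sd <- 0
    p
  })
  config
}
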