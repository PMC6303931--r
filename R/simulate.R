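#' Generate a synthetic cohort
#'
#' Draws `n_groups * group_size` fish. Boldness is uniform on `[0, 1]`
#' (1 = maximally proactive); body weight is normal and independent of
#' boldness, so the emergence-rank-versus-weight correlation is null by
#' construction. All draws are keyed by individual id, so regenerating a
#' larger cohort leaves the fish shared with a smaller one unchanged.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per fish: `individual_id`, `group_id`,
#'   `boldness`, `sex`, `body_weight_mg`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_groups = 2, seed = 1))
#' head(cohort)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  grid <- expand.grid(fish = seq_len(config$group_size),
                      group = seq_len(config$n_groups))
  group_id <- sprintf("g%02d", grid$group)
  individual_id <- sprintf("%s_f%02d", group_id, grid$fish)
  boldness <- vapply(individual_id, function(id) {
    with_substream(config$seed, "boldness", id, expr = runif(1))
  }, numeric(1), USE.NAMES = FALSE)
  body_weight_mg <- vapply(individual_id, function(id) {
    with_substream(config$seed, "weight", id,
                   expr = rnorm(1, config$body_weight_mean,
                                config$body_weight_sd))
  }, numeric(1), USE.NAMES = FALSE)
  sex <- vapply(individual_id, function(id) {
    with_substream(config$seed, "sex", id,
                   expr = sample(c("F", "M"), 1))
  }, character(1), USE.NAMES = FALSE)
  tibble(individual_id = individual_id, group_id = group_id,
         boldness = boldness, sex = sex,
         body_weight_mg = pmax(body_weight_mg, 1))
}

#' Simulate emergence latencies for a cohort
#'
#' One emergence session per fish under the log-linear latency model of
#' [cohort_config()]. The stable individual deviation `u_i` is keyed by the
#' fish id alone (shared across sessions and contexts); the residual noise is
#' keyed by fish, context and session label, so repeating a session label
#' reproduces it exactly and a fresh label draws fresh noise.
#'
#' @param cohort Tibble from [generate_cohort()].
#' @param config The [cohort_config()] used to generate the cohort.
#' @param context `"group"` or `"single"` test context.
#' @param session Session label (e.g. `"day1"`).
#' @return Tibble `individual_id`, `group_id`, `context`, `session`,
#'   `latency_s` (always positive).
#' @examples
#' cfg <- cohort_config(n_groups = 1, seed = 1)
#' simulate_emergence_latency(generate_cohort(cfg), cfg)
#' @export
simulate_emergence_latency <- function(cohort, config,
                                       context = c("group", "single"),
                                       session = "day1") {
  context <- match.arg(context)
  stopifnot(inherits(config, "cohort_config"))
  u <- vapply(cohort$individual_id, function(id) {
    with_substream(config$seed, "latency_u", id,
                   expr = rnorm(1, 0, config$latency_individual_sd))
  }, numeric(1), USE.NAMES = FALSE)
  e <- vapply(cohort$individual_id, function(id) {
    with_substream(config$seed, "latency_e", id, context, session,
                   expr = rnorm(1, 0, config$latency_residual_sd))
  }, numeric(1), USE.NAMES = FALSE)
  latency <- config$latency_scale *
    exp(config$latency_boldness_slope * (1 - cohort$boldness) + u + e)
  tibble(individual_id = cohort$individual_id, group_id = cohort$group_id,
         context = context, session = session, latency_s = latency)
}

#' Simulate the mirror-image stimulation test
#'
#' For each fish, freezing duration (`frz_s`) grows with shyness and is
#' capped at the trial duration; latency to first approach (`lfa_s`) fills
#' part of the remainder; aggressive acts (`agr_count`) are Poisson with a
#' rate increasing in boldness over the time actually spent facing the
#' mirror. `frz_s + lfa_s <= duration` always holds.
#'
#' @inheritParams simulate_emergence_latency
#' @param duration Trial duration in seconds (default 600 s = 10 min).
#' @param session Session label.
#' @return Tibble `individual_id`, `group_id`, `agr_count`, `frz_s`,
#'   `lfa_s`, `duration_s`.
#' @examples
#' cfg <- cohort_config(n_groups = 1, seed = 1)
#' simulate_mirror_test(generate_cohort(cfg), cfg)
#' @export
simulate_mirror_test <- function(cohort, config, duration = 600,
                                 session = "mirror1") {
  stopifnot(inherits(config, "cohort_config"), duration > 0)
  mp <- config$mirror
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    id <- cohort$individual_id[i]
    b <- cohort$boldness[i]
    with_substream(config$seed, "mirror", id, session, expr = {
      frz <- min(duration,
                 mp$frz_scale * max(0, (1 - b) - mp$frz_onset) +
                   rexp(1, 1 / mp$frz_noise_mean))
      lfa <- min(max(0, duration - frz - 10),
                 mp$lfa_base + mp$lfa_slope * (1 - b) +
                   rexp(1, 1 / mp$lfa_noise_mean))
      avail <- duration - frz - lfa
      rate <- mp$agr_rate_shy + (mp$agr_rate_bold - mp$agr_rate_shy) * b
      agr <- if (avail > 0 && rate > 0) rpois(1, rate * avail) else 0L
      tibble(individual_id = id, group_id = cohort$group_id[i],
             agr_count = as.integer(agr), frz_s = frz, lfa_s = lfa,
             duration_s = duration)
    })
  })
  dplyr::bind_rows(rows)
}

# deterministic cosine core of a channel, damping included
channel_mean <- function(b, params, times, regime, ll_start, halflife) {
  M <- params$mesor_at_shy + (params$mesor_at_bold - params$mesor_at_shy) * b
  A <- params$amplitude_at_shy +
    (params$amplitude_at_bold - params$amplitude_at_shy) * b
  D <- rep(1, length(times))
  if (regime == "LL") {
    t_ll <- pmax(0, times - ll_start)
    D <- 2^(-t_ll / halflife)
  }
  list(M = M, A = A,
       mu = M + A * cos(2 * pi * (times - params$acrophase) / 24) * D)
}

#' Simulate one rhythmic channel for a cohort
#'
#' Evaluates the channel's generative cosine at the requested circadian
#' times, adds Gaussian noise (sd = `noise_cv` x mesor) and floors
#' concentration/velocity channels at zero. Under constant light (`"LL"`),
#' the oscillation is damped by `2^(-t_LL / halflife)` with `t_LL` the hours
#' since lights stopped cycling (`ll_start`).
#'
#' @inheritParams simulate_emergence_latency
#' @param channel Channel name registered in `config$channel_params`.
#' @param timepoints Sampling times (hCT hours, may span multiple days);
#'   defaults to `config$sampling_times`.
#' @param regime `"LD"` (light-dark cycling) or `"LL"` (constant light).
#' @param ll_start Time (hCT hours, same axis as `timepoints`) at which the
#'   lights stopped cycling; defaults to the first timepoint.
#' @param session Session label keying the noise substream.
#' @return Tibble `individual_id`, `channel`, `regime`, `time_hct`, `value`.
#' @examples
#' cfg <- cohort_config(n_groups = 1, seed = 1)
#' co <- generate_cohort(cfg)
#' simulate_channel_timeseries(co[1, ], cfg, "cortisol")
#' @export
simulate_channel_timeseries <- function(cohort, config, channel,
                                        timepoints = NULL,
                                        regime = c("LD", "LL"),
                                        ll_start = NULL,
                                        session = "sampling") {
  regime <- match.arg(regime)
  stopifnot(inherits(config, "cohort_config"))
  params <- config$channel_params[[channel]]
  if (is.null(params)) {
    abort(paste0("unknown channel `", channel, "`."),
          class = "chronocope_config_error")
  }
  if (is.null(timepoints)) timepoints <- config$sampling_times
  if (length(timepoints) == 0) {
    abort("`timepoints` must be non-empty.",
          class = "chronocope_config_error")
  }
  if (is.null(ll_start)) ll_start <- min(timepoints)
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    id <- cohort$individual_id[i]
    b <- cohort$boldness[i]
    scale_i <- if (params$scale_log_sd > 0) {
      with_substream(config$seed, "scale", channel, id,
                     expr = exp(rnorm(1, 0, params$scale_log_sd)))
    } else 1
    core <- channel_mean(b, params, timepoints, regime, ll_start,
                         config$ll_damping_halflife)
    eps <- if (params$noise_cv > 0) {
      with_substream(config$seed, "channel_noise", channel, id, session,
                     regime,
                     expr = rnorm(length(timepoints), 0,
                                  params$noise_cv * core$M * scale_i))
    } else rep(0, length(timepoints))
    value <- scale_i * core$mu + eps
    if (params$floor_at_zero) value <- pmax(value, 0)
    tibble(individual_id = id, channel = channel, regime = regime,
           time_hct = timepoints, value = value)
  })
  dplyr::bind_rows(rows)
}

#' Simulate a multi-day locomotor-activity recording
#'
#' Produces 30-min binned swimming velocities over `n_days_ld` days of
#' light-dark cycling followed by `n_days_ll` days of constant light,
#' starting at `start_hct` (the study design records 6 days from 7 hCT).
#' On top of the rhythmic component, every fish shows a few escape bursts
#' per day whose magnitude approaches its physiological ceiling
#' (`config$vmax_ceiling` times the fish's individual activity scale).
#' The ceiling does not depend on boldness, so maximum velocity carries no
#' personality signal by construction.
#'
#' @inheritParams simulate_emergence_latency
#' @param n_days_ld,n_days_ll Days under cycling light and constant light.
#' @param bin_h Bin width in hours (0.5 = 30 min).
#' @param start_hct Recording start, hCT hours.
#' @param bursts Logical; add the shared-ceiling escape bursts.
#' @return Tibble `individual_id`, `channel`, `regime`, `time_hct`, `value`.
#' @examples
#' cfg <- cohort_config(n_groups = 1, group_size = 2, seed = 1)
#' act <- simulate_activity(generate_cohort(cfg), cfg)
#' range(act$time_hct)
#' @export
simulate_activity <- function(cohort, config, n_days_ld = 3, n_days_ll = 3,
                              bin_h = 0.5, start_hct = 7, bursts = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  params <- config$channel_params[["activity"]]
  if (is.null(params)) {
    abort("config has no `activity` channel.",
          class = "chronocope_config_error")
  }
  n_bins <- as.integer((n_days_ld + n_days_ll) * 24 / bin_h)
  times <- start_hct + bin_h * (seq_len(n_bins) - 1)
  ll_start <- start_hct + 24 * n_days_ld
  is_ll <- times >= ll_start
  day <- floor((times - start_hct) / 24) + 1
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    id <- cohort$individual_id[i]
    b <- cohort$boldness[i]
    scale_i <- if (params$scale_log_sd > 0) {
      with_substream(config$seed, "scale", "activity", id,
                     expr = exp(rnorm(1, 0, params$scale_log_sd)))
    } else 1
    core_ld <- channel_mean(b, params, times, "LD", ll_start,
                            config$ll_damping_halflife)
    core_ll <- channel_mean(b, params, times, "LL", ll_start,
                            config$ll_damping_halflife)
    mu <- ifelse(is_ll, core_ll$mu, core_ld$mu)
    value <- with_substream(config$seed, "activity_noise", id, expr = {
      v <- scale_i * mu +
        rnorm(n_bins, 0, params$noise_cv * core_ld$M * scale_i)
      if (bursts) {
        # escape bursts toward the fish's ceiling (scale x vmax_ceiling);
        # the ceiling is independent of boldness, so Vmax carries no
        # personality signal
        for (d in unique(day)) {
          idx <- which(day == d)
          k <- min(config$bursts_per_day, length(idx))
          bi <- sample(idx, k)
          v[bi] <- pmax(v[bi],
                        scale_i * (config$vmax_ceiling - rexp(k, 1 / 2)))
        }
      }
      v
    })
    if (params$floor_at_zero) value <- pmax(value, 0)
    tibble(individual_id = id, channel = "activity",
           regime = ifelse(is_ll, "LL", "LD"),
           time_hct = times, value = value)
  })
  dplyr::bind_rows(rows)
}

#' Simulate the Ct table of a qPCR experiment
#'
#' Converts the generative relative-expression channels into a plausible
#' quantitative-PCR Ct table: the housekeeping gene (*ippA*) gets a baseline
#' Ct, each target gene a Ct of `hk - log2(expression)`, and each reaction is
#' recorded as a technical triplicate with Gaussian Ct noise. With all noise
#' switched off, `2^(-delta Ct)` reproduces the generative series exactly.
#'
#' @inheritParams simulate_emergence_latency
#' @param genes Gene channels to include (default: the five clock genes in
#'   the configuration).
#' @param timepoints Sampling times, hCT.
#' @param hk_mean Baseline Ct of the housekeeping gene.
#' @param hk_sd Between-sample sd of the housekeeping Ct.
#' @param replicate_sd Technical-replicate Ct noise sd (0 for exact
#'   triplicates).
#' @param housekeeping Housekeeping gene label.
#' @return Tibble `individual_id`, `gene`, `time_hct`, `ct1`, `ct2`, `ct3`.
#' @examples
#' cfg <- cohort_config(n_groups = 1, group_size = 2, seed = 1)
#' ct <- simulate_ct_table(generate_cohort(cfg), cfg)
#' head(ct)
#' @export
simulate_ct_table <- function(cohort, config,
                              genes = c("bmal1a", "clock1a", "per1a",
                                        "cry1a", "cipca"),
                              timepoints = NULL, hk_mean = 15, hk_sd = 0.15,
                              replicate_sd = 0.1, housekeeping = "ippA") {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(timepoints)) timepoints <- config$sampling_times
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    id <- cohort$individual_id[i]
    hk_ct <- with_substream(config$seed, "hk_ct", id, expr = {
      hk_mean + rnorm(length(timepoints), 0, hk_sd)
    })
    per_gene <- lapply(genes, function(g) {
      expr_series <- simulate_channel_timeseries(cohort[i, , drop = FALSE],
                                                 config, g,
                                                 timepoints = timepoints)
      x <- pmax(expr_series$value, 2^-20)  # keep Ct finite
      base_ct <- hk_ct - log2(x)
      reps <- with_substream(config$seed, "ct_reps", id, g, expr = {
        matrix(rnorm(3 * length(timepoints), 0, replicate_sd), ncol = 3)
      })
      tibble(individual_id = id, gene = g, time_hct = timepoints,
             ct1 = base_ct + reps[, 1], ct2 = base_ct + reps[, 2],
             ct3 = base_ct + reps[, 3])
    })
    hk_reps <- with_substream(config$seed, "ct_reps", id, housekeeping,
                              expr = {
      matrix(rnorm(3 * length(timepoints), 0, replicate_sd), ncol = 3)
    })
    hk_tbl <- tibble(individual_id = id, gene = housekeeping,
                     time_hct = timepoints,
                     ct1 = hk_ct + hk_reps[, 1], ct2 = hk_ct + hk_reps[, 2],
                     ct3 = hk_ct + hk_reps[, 3])
    dplyr::bind_rows(per_gene, list(hk_tbl))
  })
  dplyr::bind_rows(rows)
}

#' Randomly eliminate fish from each group
#'
#' The study design tests 8 of each group's 10 ranked fish; two are
#' eliminated at random. The elimination is keyed by the cohort seed and
#' group id, so it is reproducible and unaffected by other draws.
#'
#' @inheritParams simulate_emergence_latency
#' @param keep_per_group Number of fish retained per group.
#' @return The cohort tibble restricted to the retained fish.
#' @export
eliminate_random <- function(cohort, config, keep_per_group = 8) {
  keep <- unlist(lapply(split(cohort$individual_id, cohort$group_id),
                        function(ids) {
    k <- min(keep_per_group, length(ids))
    with_substream(config$seed, "eliminate", ids[1],
                   expr = sort(sample(ids, k)))
  }), use.names = FALSE)
  cohort[cohort$individual_id %in% keep, , drop = FALSE]
}
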