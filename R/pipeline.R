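# --- end-to-end study: generate -> score -> quantify -> correlate

#' Run the full synthetic study
#'
#' Orchestrates the complete analysis on one synthetic cohort: group
#' emergence ranking, single-test and retest sessions, mirror-image
#' stimulation, gene-expression / hormone sampling at the six circadian
#' timepoints, the 6-day activity recording (3 days light-dark, 3 days
#' constant light), rhythm quantification, the rank-correlation battery and
#' the rhythm-strength model selection. Everything is a pure function of the
#' configuration: the same config yields byte-identical results.
#'
#' For the physiology cohort, ranks 1..`group_size` are assigned to every
#' fish (the sampled fish all emerged) and two fish per group are then
#' eliminated at random, as in the study design; the 10-min exclusion rule
#' applies to the behavioural-validation correlations instead.
#'
#' @param config A [cohort_config()].
#' @param regimes Activity regimes to analyse (subset of `c("LD", "LL")`).
#' @param channels Channels to analyse (default: all configured).
#' @param output_dir Optional directory; when given, the result tables are
#'   written there as CSV files.
#' @param keep_per_group Fish retained per group after random elimination.
#' @return Object of class `chrono_study`: a list with `config`, `cohort`,
#'   `emergence` (scored group test), `repeatability`, `mirror`,
#'   `metrics` (per fish x channel x regime), `correlations` (rank vs
#'   metric, one row per channel x metric x regime), `selection`
#'   (a [select_rhythm_model()] result) and `analysed_ids`.
#' @examples
#' \donttest{
#' study <- run_full_study(cohort_config(n_groups = 2, seed = 1))
#' study$correlations
#' }
#' @export
run_full_study <- function(config = cohort_config(),
                           regimes = c("LD", "LL"), channels = NULL,
                           output_dir = NULL, keep_per_group = 8) {
  stopifnot(inherits(config, "cohort_config"))
  regimes <- match.arg(regimes, c("LD", "LL"), several.ok = TRUE)
  if (is.null(channels)) channels <- names(config$channel_params)
  unknown <- setdiff(channels, names(config$channel_params))
  if (length(unknown)) {
    abort(paste("unknown channel(s):", paste(unknown, collapse = ", ")),
          class = "chronocope_config_error")
  }

  cohort <- generate_cohort(config)

  # behavioural assays -----------------------------------------------------
  group_lat <- simulate_emergence_latency(cohort, config, "group", "day1")
  emergence <- rank_emergence(group_lat, cutoff = config$emergence_cutoff)
  ranks_full <- rank_emergence(group_lat, cutoff = Inf)
  single1 <- simulate_emergence_latency(cohort, config, "single", "day1")
  single2 <- simulate_emergence_latency(cohort, config, "single", "day2")
  repeatability <- repeatability_table(single1, single2)
  mirror <- agr_frequency(simulate_mirror_test(cohort, config))

  analysed <- eliminate_random(cohort, config, keep_per_group)
  ranks <- ranks_full[ranks_full$individual_id %in% analysed$individual_id, ]

  # physiology channels -----------------------------------------------------
  sampled_channels <- setdiff(channels, "activity")
  series <- dplyr::bind_rows(lapply(sampled_channels, function(ch) {
    simulate_channel_timeseries(analysed, config, ch)
  }))
  if ("activity" %in% channels) {
    act <- simulate_activity(analysed, config)
    series <- dplyr::bind_rows(series, act)
  }
  metrics <- rhythm_metrics(series)

  # rank-correlation battery ------------------------------------------------
  rk <- dplyr::select(ranks, "individual_id", "rank")
  met <- dplyr::inner_join(metrics, rk, by = "individual_id")
  cor_one <- function(d, metric) {
    v <- d[[metric]]
    ok <- is.finite(v) & is.finite(d$rank)
    if (sum(ok) < 3 || length(unique(v[ok])) < 2) return(NULL)
    ct <- spearman(d$rank[ok], v[ok])
    tibble(metric = metric, rho = ct$rho, p_value = ct$p_value, n = ct$n)
  }
  correlations <- met |>
    dplyr::group_by(.data$channel, .data$regime) |>
    dplyr::group_modify(function(d, key) {
      dplyr::bind_rows(lapply(c("auc", "amplitude", "rhythm_strength",
                                "vmax"),
                              function(m) cor_one(d, m)))
    }) |>
    dplyr::ungroup()
  # behavioural correlations on the cut cohort (10-min rule applies)
  beh <- list(
    single_latency = {
      j <- dplyr::inner_join(
        emergence[!is.na(emergence$rank), c("individual_id", "rank")],
        single1[single1$latency_s < config$single_cutoff,
                c("individual_id", "latency_s")],
        by = "individual_id")
      ct <- spearman(j$rank, j$latency_s)
      tibble(channel = "behaviour", regime = "LD",
             metric = "single_latency", rho = ct$rho, p_value = ct$p_value,
             n = ct$n)
    },
    agr_freq = {
      j <- dplyr::inner_join(
        emergence[!is.na(emergence$rank), c("individual_id", "rank")],
        mirror[!mirror$excluded, c("individual_id", "agr_freq")],
        by = "individual_id")
      ct <- spearman(j$rank, j$agr_freq)
      tibble(channel = "behaviour", regime = "LD", metric = "agr_freq",
             rho = ct$rho, p_value = ct$p_value, n = ct$n)
    },
    body_weight = {
      j <- dplyr::inner_join(
        emergence[!is.na(emergence$rank), c("individual_id", "rank")],
        cohort[c("individual_id", "body_weight_mg")],
        by = "individual_id")
      ct <- spearman(j$rank, j$body_weight_mg)
      tibble(channel = "behaviour", regime = "LD", metric = "body_weight",
             rho = ct$rho, p_value = ct$p_value, n = ct$n)
    })
  correlations <- dplyr::bind_rows(correlations, dplyr::bind_rows(beh))
  correlations <- correlations[correlations$regime %in% regimes |
                                 correlations$channel == "behaviour", ]

  # model selection on LD activity metrics ----------------------------------
  selection <- NULL
  if ("activity" %in% channels && "LD" %in% regimes) {
    seldat <- met[met$channel == "activity" & met$regime == "LD",
                  c("rank", "auc", "amplitude", "rhythm_strength", "vmax")]
    seldat <- as.data.frame(seldat)
    selection <- select_rhythm_model(seldat, response = "rank")
  }

  study <- structure(
    list(config = config, cohort = cohort, emergence = emergence,
         ranks = ranks_full, repeatability = repeatability, mirror = mirror,
         metrics = metrics, correlations = correlations,
         selection = selection,
         analysed_ids = analysed$individual_id,
         regimes = regimes),
    class = "chrono_study")
  if (!is.null(output_dir)) write_study(study, output_dir)
  study
}

# CSV bundle with stable headers (schema tested)
write_study <- function(study, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(study$cohort, file.path(output_dir, "cohort.csv"))
  readr::write_csv(study$emergence, file.path(output_dir, "emergence.csv"))
  readr::write_csv(study$mirror, file.path(output_dir, "mirror.csv"))
  readr::write_csv(study$metrics, file.path(output_dir, "metrics.csv"))
  readr::write_csv(study$correlations,
                   file.path(output_dir, "correlations.csv"))
  writeLines(make_report(study), file.path(output_dir, "report.md"))
  invisible(output_dir)
}

#' @export
print.chrono_study <- function(x, ...) {
  cat("<chrono_study> seed", x$config$seed, "-",
      length(x$analysed_ids), "analysed fish\n")
  print(x$correlations, n = 20)
  invisible(x)
}

#' @method tidy chrono_study
#' @export
tidy.chrono_study <- function(x, ...) x$correlations

#' @method glance chrono_study
#' @export
glance.chrono_study <- function(x, ...) {
  tibble(seed = x$config$seed,
         n_fish = nrow(x$cohort),
         n_analysed = length(x$analysed_ids),
         n_emerged = sum(x$emergence$emerged),
         retained = paste(if (is.null(x$selection)) character(0)
                          else x$selection$retained, collapse = ","))
}

fmt_num <- function(x, digits = 4) formatC(x, digits = digits, format = "f")

#' Render a study as a human-readable report
#'
#' Markdown summary of a [run_full_study()] result: cohort overview,
#' early-versus-late-emerger contrasts (rank 1 vs rank `group_size`), the
#' full rank-correlation table and the model-selection outcome. Numbers are
#' printed verbatim from the result tables; nothing is recomputed.
#'
#' @param study A `chrono_study`.
#' @return Character vector of markdown lines.
#' @export
make_report <- function(study) {
  stopifnot(inherits(study, "chrono_study"))
  if (is.null(study$correlations)) {
    abort("study bundle is missing its correlation table.",
          class = "chronocope_report_error")
  }
  cfg <- study$config
  lines <- c(
    "# Synthetic chronotype-coping-style study",
    "",
    sprintf("Cohort: %d groups of %d (seed %d); %d fish analysed after random elimination.",
            cfg$n_groups, cfg$group_size, cfg$seed,
            length(study$analysed_ids)),
    sprintf("Group emergence: %d of %d fish emerged within %s s.",
            sum(study$emergence$emerged), nrow(study$emergence),
            format(cfg$emergence_cutoff)),
    "")
  # EE vs LE contrast: rank 1 vs rank group_size within each group
  ee_le <- dplyr::inner_join(study$metrics,
                             study$ranks[c("individual_id", "rank")],
                             by = "individual_id")
  ee_le <- ee_le[ee_le$rank %in% c(1, cfg$group_size), ]
  if (nrow(ee_le) > 0 && length(unique(ee_le$rank)) == 2) {
    contrast <- ee_le |>
      dplyr::mutate(style = ifelse(.data$rank == 1, "EE", "LE")) |>
      dplyr::group_by(.data$channel, .data$regime, .data$style) |>
      dplyr::summarise(amplitude = mean(.data$amplitude),
                       auc = mean(.data$auc), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "style",
                         values_from = c("amplitude", "auc")) |>
      dplyr::filter(!is.na(.data$amplitude_EE), !is.na(.data$amplitude_LE))
    lines <- c(lines, "## Early versus late emergers (rank 1 vs rank 10)",
               "",
               "| channel | regime | amplitude EE | amplitude LE | AUC EE | AUC LE |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %s | %s | %s | %s | %s |",
                       contrast$channel, contrast$regime,
                       fmt_num(contrast$amplitude_EE),
                       fmt_num(contrast$amplitude_LE),
                       fmt_num(contrast$auc_EE),
                       fmt_num(contrast$auc_LE)),
               "")
  }
  co <- study$correlations
  for (reg in unique(co$regime)) {
    sub <- co[co$regime == reg, ]
    if (nrow(sub) == 0) next
    lines <- c(lines,
               sprintf("## Rank correlations (%s)", reg), "",
               "| channel | metric | rho | p | n |",
               "|---|---|---|---|---|",
               sprintf("| %s | %s | %s | %s | %d |",
                       sub$channel, sub$metric, fmt_num(sub$rho),
                       format(sub$p_value, digits = 3, scientific = TRUE),
                       sub$n),
               "")
  }
  if (!is.null(study$selection)) {
    lines <- c(lines, "## Rank model selection (LD activity)", "",
               sprintf("Retained predictors: %s.",
                       if (length(study$selection$retained))
                         paste(study$selection$retained, collapse = ", ")
                       else "(none)"),
               sprintf("Dropped by VIF: %s.",
                       if (length(study$selection$vif_dropped))
                         paste(study$selection$vif_dropped, collapse = ", ")
                       else "(none)"),
               sprintf("Points flagged by Cook's distance: %d.",
                       length(study$selection$influential)))
  }
  lines
}
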