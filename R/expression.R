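# --- qPCR relative quantification (delta-delta-Ct)

#' Housekeeping-normalised Ct difference
#'
#' `delta_ct = target_ct - housekeeping_ct`. Vectorised.
#'
#' @param target_ct,housekeeping_ct Finite Ct values (technical replicates
#'   should be averaged on the Ct scale beforehand).
#' @return `target_ct - housekeeping_ct`.
#' @examples
#' delta_ct(20, 15)
#' @export
delta_ct <- function(target_ct, housekeeping_ct) {
  if (any(!is.finite(target_ct)) || any(!is.finite(housekeeping_ct))) {
    abort("Ct values must be finite.", class = "chronocope_input_error")
  }
  target_ct - housekeeping_ct
}

#' Fold change of early versus late emergers
#'
#' The delta-delta-Ct fold change of EE (early-emerging, proactive) relative
#' to LE (late-emerging, reactive) fish: `2^(delta_ct_le - delta_ct_ee)`.
#' Values above 1 mean higher expression in EE fish.
#'
#' @param delta_ct_ee,delta_ct_le Housekeeping-normalised Ct values from
#'   [delta_ct()].
#' @return Positive fold change; `fold_change_ee_vs_le(a, b) *
#'   fold_change_ee_vs_le(b, a) == 1`.
#' @examples
#' fold_change_ee_vs_le(5, 7)  # 4-fold higher in EE
#' @export
fold_change_ee_vs_le <- function(delta_ct_ee, delta_ct_le) {
  if (any(!is.finite(delta_ct_ee)) || any(!is.finite(delta_ct_le))) {
    abort("delta-Ct values must be finite.",
          class = "chronocope_input_error")
  }
  2^(delta_ct_le - delta_ct_ee)
}

# average technical triplicates on the Ct scale
ct_means <- function(ct_table) {
  rep_cols <- intersect(c("ct1", "ct2", "ct3"), names(ct_table))
  if (length(rep_cols) == 0) {
    if (!"ct" %in% names(ct_table)) {
      abort("Ct table needs `ct1..ct3` or `ct` columns.",
            class = "chronocope_input_error")
    }
    ct_table$ct_mean <- ct_table$ct
  } else {
    ct_table$ct_mean <- rowMeans(ct_table[rep_cols])
  }
  ct_table
}

#' Per-sample relative expression from a Ct table
#'
#' Averages technical triplicates on the Ct scale, subtracts the
#' housekeeping gene's Ct within each (individual, timepoint) and returns
#' `2^(-delta Ct)` -- the housekeeping-normalised relative expression of
#' each sample. Adding a constant to every Ct (targets and housekeeping
#' alike) leaves the result unchanged.
#'
#' @param ct_table Tibble with `individual_id`, `gene`, `time_hct` and
#'   triplicate columns `ct1`, `ct2`, `ct3` (or a single `ct` column).
#' @param housekeeping Housekeeping gene label (default `"ippA"`); exactly
#'   one housekeeping record per (individual, timepoint) is required.
#' @return Tibble `individual_id`, `gene`, `time_hct`, `delta_ct`,
#'   `rel_expression`.
#' @examples
#' ct <- tibble::tibble(individual_id = "f1", gene = c("bmal1a", "ippA"),
#'                      time_hct = 1, ct1 = c(12, 15), ct2 = c(12, 15),
#'                      ct3 = c(12, 15))
#' relative_expression(ct)
#' @export
relative_expression <- function(ct_table, housekeeping = "ippA") {
  ct_table <- ct_means(ct_table)
  hk <- ct_table[ct_table$gene == housekeeping, ]
  if (nrow(hk) == 0) {
    abort("no housekeeping records found.",
          class = "chronocope_input_error")
  }
  dup <- duplicated(hk[c("individual_id", "time_hct")])
  if (any(dup)) {
    abort("more than one housekeeping record per individual/timepoint.",
          class = "chronocope_input_error")
  }
  tg <- ct_table[ct_table$gene != housekeeping, ]
  merged <- dplyr::inner_join(
    tg, dplyr::select(hk, "individual_id", "time_hct", hk_ct = "ct_mean"),
    by = c("individual_id", "time_hct"))
  if (nrow(merged) < nrow(tg)) {
    abort("target records without a matching housekeeping Ct.",
          class = "chronocope_input_error")
  }
  merged$delta_ct <- delta_ct(merged$ct_mean, merged$hk_ct)
  merged$rel_expression <- 2^(-merged$delta_ct)
  as_tibble(merged[c("individual_id", "gene", "time_hct", "delta_ct",
                     "rel_expression")])
}

#' Rank-level expression time series
#'
#' Builds the per-(gene, emergence-rank) expression time course used for
#' rhythm quantification: technical triplicates are averaged, Ct values are
#' averaged within (gene, rank, timepoint) across fish *before* the
#' housekeeping subtraction, relative expression is `2^(-delta Ct)`, and
#' each (gene, rank) series is normalised to its own mean so genes are
#' comparable.
#'
#' @inheritParams relative_expression
#' @param ranks Tibble with `individual_id` and `rank` (from
#'   [rank_emergence()]); unranked fish are dropped.
#' @return Tibble `gene`, `rank`, `time_hct`, `rel_expression` (series mean
#'   1 within each gene x rank).
#' @examples
#' cfg <- cohort_config(n_groups = 1, group_size = 4, seed = 1)
#' co <- generate_cohort(cfg)
#' lat <- simulate_emergence_latency(co, cfg)
#' rk <- rank_emergence(lat, cutoff = Inf)
#' series <- expression_series_by_rank(simulate_ct_table(co, cfg), rk)
#' head(series)
#' @export
expression_series_by_rank <- function(ct_table, ranks,
                                      housekeeping = "ippA") {
  ct_table <- ct_means(ct_table)
  ranks <- ranks[!is.na(ranks$rank), c("individual_id", "rank")]
  joined <- dplyr::inner_join(ct_table, ranks, by = "individual_id")
  mean_ct <- joined |>
    dplyr::group_by(.data$gene, .data$rank, .data$time_hct) |>
    dplyr::summarise(ct_mean = mean(.data$ct_mean), .groups = "drop")
  hk <- mean_ct[mean_ct$gene == housekeeping, ]
  tg <- mean_ct[mean_ct$gene != housekeeping, ]
  # every (gene, rank) needs the full sampling design
  expected <- unique(ct_table$time_hct)
  gaps <- tg |>
    dplyr::group_by(.data$gene, .data$rank) |>
    dplyr::summarise(missing = paste(setdiff(expected, .data$time_hct),
                                     collapse = ","), .groups = "drop") |>
    dplyr::filter(.data$missing != "")
  if (nrow(gaps) > 0) {
    abort(paste0("incomplete design; missing timepoints: ",
                 paste(sprintf("%s rank %s (t=%s)", gaps$gene, gaps$rank,
                               gaps$missing), collapse = "; ")),
          class = "chronocope_incomplete_design")
  }
  merged <- dplyr::inner_join(
    tg, dplyr::select(hk, "rank", "time_hct", hk_ct = "ct_mean"),
    by = c("rank", "time_hct"))
  merged$rel_expression <- 2^(-delta_ct(merged$ct_mean, merged$hk_ct))
  merged |>
    dplyr::group_by(.data$gene, .data$rank) |>
    dplyr::mutate(rel_expression =
                    .data$rel_expression / mean(.data$rel_expression)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$gene, .data$rank, .data$time_hct) |>
    dplyr::select("gene", "rank", "time_hct", "rel_expression")
}
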