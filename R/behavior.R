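#' Rank fish by emergence latency
#'
#' Fish emerging within the cutoff are ranked by ascending latency (rank 1 =
#' early emerger, EE; the last rank = late emerger, LE). Fish that do not
#' emerge within the cutoff are flagged `emerged = FALSE` and carry no rank,
#' mirroring the exclusion of non-emergers from further analysis. Ties are
#' broken by input order (simultaneous emergence is physically precluded by
#' the single hatch; the rule only matters for synthetic duplicates).
#'
#' @param latencies Tibble with columns `individual_id`, `latency_s` and
#'   optionally `group_id` (ranking is within group when present).
#' @param cutoff Exclusion cutoff in seconds (default 600 s = 10 min); use
#'   `Inf` to rank everyone.
#' @return Tibble `individual_id`, `group_id` (if given), `latency_s`,
#'   `emerged`, `rank` (`NA` for non-emergers).
#' @examples
#' rank_emergence(tibble::tibble(individual_id = c("a", "b", "c"),
#'                               latency_s = c(5, 60, 8)))
#' @export
rank_emergence <- function(latencies, cutoff = 600) {
  stopifnot(all(c("individual_id", "latency_s") %in% names(latencies)))
  if (anyDuplicated(latencies$individual_id)) {
    abort("duplicate `individual_id` in latency table.",
          class = "chronocope_input_error")
  }
  if (any(latencies$latency_s < 0)) {
    abort("latencies must be >= 0.", class = "chronocope_input_error")
  }
  grp <- if ("group_id" %in% names(latencies)) latencies$group_id
         else rep("all", nrow(latencies))
  emerged <- latencies$latency_s < cutoff
  rk <- rep(NA_real_, nrow(latencies))
  for (g in unique(grp)) {
    idx <- which(grp == g & emerged)
    rk[idx] <- rank(latencies$latency_s[idx], ties.method = "first")
  }
  out <- tibble(individual_id = latencies$individual_id,
                latency_s = latencies$latency_s,
                emerged = emerged, rank = rk)
  if ("group_id" %in% names(latencies)) {
    out <- tibble(individual_id = latencies$individual_id,
                  group_id = latencies$group_id,
                  latency_s = latencies$latency_s,
                  emerged = emerged, rank = rk)
  }
  out
}

#' Aggression frequency in the mirror-image stimulation test
#'
#' The number of aggressive acts is divided by the trial duration minus
#' freezing and approach-latency time, i.e. the time actually available for
#' mirror-directed interaction. Non-responders (freezing for
#' `exclusion_frz` seconds or longer, 10 min by default) are excluded:
#' their frequency is `NA` and `excluded` is `TRUE`.
#'
#' @param mirror Tibble from [simulate_mirror_test()] (columns `agr_count`,
#'   `frz_s`, `lfa_s`, `duration_s`).
#' @param exclusion_frz Freezing duration (s) at or above which a fish is a
#'   non-responder.
#' @return The input with `excluded` and `agr_freq` (s^-1) columns added.
#' @examples
#' agr_frequency(tibble::tibble(individual_id = "a", agr_count = 60L,
#'                              frz_s = 120, lfa_s = 30, duration_s = 600))
#' @export
agr_frequency <- function(mirror, exclusion_frz = 600) {
  stopifnot(all(c("agr_count", "frz_s", "lfa_s", "duration_s") %in%
                  names(mirror)))
  if (any(mirror$duration_s <= 0)) {
    abort("`duration_s` must be positive.",
          class = "chronocope_input_error")
  }
  denom <- mirror$duration_s - mirror$frz_s - mirror$lfa_s
  excluded <- mirror$frz_s >= exclusion_frz
  if (any(!excluded & denom <= 0)) {
    abort("record with no interaction time but freezing below the exclusion cutoff.",
          class = "chronocope_degenerate_record")
  }
  mirror$excluded <- excluded
  mirror$agr_freq <- ifelse(excluded, NA_real_, mirror$agr_count / denom)
  mirror
}

#' Test-retest repeatability of emergence latency
#'
#' Inner-joins two latency sessions on fish id and correlates the latencies
#' (Spearman; invariant to the log transform used for plotting).
#'
#' @param session1,session2 Tibbles with `individual_id` and `latency_s`.
#' @return Object of class `chrono_repeatability`: a list with `pairs`
#'   (tibble of paired latencies and their logs) and `correlation`
#'   (a [spearman()] result).
#' @examples
#' s1 <- tibble::tibble(individual_id = letters[1:6], latency_s = 1:6)
#' repeatability_table(s1, s1)$correlation
#' @export
repeatability_table <- function(session1, session2) {
  pairs <- dplyr::inner_join(
    dplyr::select(session1, "individual_id", latency_day1 = "latency_s"),
    dplyr::select(session2, "individual_id", latency_day2 = "latency_s"),
    by = "individual_id")
  if (nrow(pairs) < 5) {
    abort("need at least 5 shared individuals.",
          class = "chronocope_insufficient_data")
  }
  pairs$log_latency_day1 <- log(pairs$latency_day1)
  pairs$log_latency_day2 <- log(pairs$latency_day2)
  structure(list(pairs = as_tibble(pairs),
                 correlation = spearman(pairs$latency_day1,
                                        pairs$latency_day2)),
            class = "chrono_repeatability")
}

#' @export
print.chrono_repeatability <- function(x, ...) {
  cat("<chrono_repeatability> n =", x$correlation$n, "\n")
  print(x$correlation)
  invisible(x)
}

#' @method tidy chrono_repeatability
#' @export
tidy.chrono_repeatability <- function(x, ...) x$pairs

#' @method glance chrono_repeatability
#' @export
glance.chrono_repeatability <- function(x, ...) tidy(x$correlation)
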