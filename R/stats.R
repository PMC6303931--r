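# --- inferential layer: Spearman, chi-square, two-way ANOVA, model selection

# all permutations of 1..n, built iteratively (memoised)
all_perms <- function(n) {
  key <- as.character(n)
  if (!is.null(the$perms[[key]])) return(the$perms[[key]])
  P <- matrix(1L, 1, 1)
  if (n > 1) {
    for (k in 2:n) {
      m <- nrow(P)
      out <- matrix(0L, m * k, k)
      for (pos in seq_len(k)) {
        rows <- ((pos - 1) * m + 1):(pos * m)
        left <- if (pos > 1) P[, 1:(pos - 1), drop = FALSE] else NULL
        right <- if (pos < k) P[, pos:(k - 1), drop = FALSE] else NULL
        out[rows, ] <- cbind(left, k, right)
      }
      P <- out
    }
  }
  if (is.null(the$perms)) the$perms <- list()
  the$perms[[key]] <- P
  P
}

#' Spearman rank correlation
#'
#' Correlation of mid-ranks. The p-value is exact (enumeration over all
#' `n!` orderings, two-sided) for `n < 10` and uses the t approximation
#' otherwise; `p_method` can force either.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`.
#' @param p_method `"auto"`, `"exact"` (n <= 9) or `"t"`.
#' @return Object of class `chrono_cor` with `rho`, `p_value`, `n`,
#'   `method`. [tidy()] returns it as a one-row tibble.
#' @examples
#' spearman(1:6, c(2, 1, 4, 3, 6, 5))
#' @export
spearman <- function(x, y, p_method = c("auto", "exact", "t")) {
  p_method <- match.arg(p_method)
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) {
    abort("need at least 3 complete pairs.",
          class = "chronocope_insufficient_data")
  }
  rx <- rank(x)
  ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0) {
    abort("undefined correlation: zero rank variance.",
          class = "chronocope_undefined_correlation")
  }
  rho <- cor(rx, ry)
  if (p_method == "auto") p_method <- if (n < 10) "exact" else "t"
  if (p_method == "exact") {
    if (n > 9) {
      abort("exact enumeration supported for n <= 9 only.",
            class = "chronocope_config_error")
    }
    P <- all_perms(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    stats_all <- as.vector(matrix(ryc[t(P)], nrow = n) |> crossprod(rxc)) /
      denom
    p <- mean(abs(stats_all) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    p <- min(max(p, .Machine$double.xmin), 1)
  }
  structure(list(rho = rho, p_value = p, n = n,
                 method = paste0("spearman/", p_method)),
            class = "chrono_cor")
}

#' @export
print.chrono_cor <- function(x, ...) {
  cat(sprintf("<chrono_cor> rho = %.4f, p = %.4g, n = %d (%s)\n",
              x$rho, x$p_value, x$n, x$method))
  invisible(x)
}

#' @method tidy chrono_cor
#' @export
tidy.chrono_cor <- function(x, ...) {
  tibble(rho = x$rho, p_value = x$p_value, n = x$n, method = x$method)
}

#' Chi-square test of an equal strain split per emergence rank
#'
#' Pearson goodness-of-fit of the observed AB/TL counts per emergence rank
#' against a 50/50 split of that rank's total: `sum((O - E)^2 / E)` with
#' `E = rank total / 2`, one degree of freedom per rank. A non-significant
#' result means neither strain dominates any emergence rank.
#'
#' @param counts A tibble with columns `rank`, `strain`, `count`, or a
#'   matrix/table with ranks in rows and the two strains in columns.
#' @return Object of class `chrono_chisq` with `statistic`, `df`,
#'   `p_value`, `n`.
#' @examples
#' chi_square_uniform(cbind(AB = c(5, 5, 5), TL = c(5, 5, 5)))
#' @export
chi_square_uniform <- function(counts) {
  if (is.data.frame(counts)) {
    stopifnot(all(c("rank", "strain", "count") %in% names(counts)))
    counts <- tapply(counts$count, list(counts$rank, counts$strain), sum)
    counts[is.na(counts)] <- 0
  }
  counts <- as.matrix(counts)
  if (ncol(counts) != 2) {
    abort("need exactly two strain columns.",
          class = "chronocope_input_error")
  }
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    abort("degenerate design: a rank with zero expected count.",
          class = "chronocope_degenerate_design")
  }
  E <- cbind(totals / 2, totals / 2)
  statistic <- sum((counts - E)^2 / E)
  df <- nrow(counts)
  structure(list(statistic = statistic, df = df,
                 p_value = pchisq(statistic, df, lower.tail = FALSE),
                 n = sum(counts)),
            class = "chrono_chisq")
}

#' @export
print.chrono_chisq <- function(x, ...) {
  cat(sprintf("<chrono_chisq> X^2 = %.4f, df = %d, p = %.4g (n = %d)\n",
              x$statistic, x$df, x$p_value, x$n))
  invisible(x)
}

#' @method tidy chrono_chisq
#' @export
tidy.chrono_chisq <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value, n = x$n)
}

#' Two-way ANOVA with time and coping style as factors
#'
#' Linear model `value ~ f1 * f2` with type-II sums of squares (so the test
#' is well defined for unbalanced layouts too), as used to compare
#' expression, hormone and activity levels between coping styles over time.
#'
#' @param data A data frame.
#' @param value,factor1,factor2 Column names (strings) of the response and
#'   the two factors; each factor needs at least 2 levels.
#' @return Tibble `term`, `sumsq`, `df`, `statistic`, `p_value` with rows
#'   for both main effects and the interaction.
#' @examples
#' d <- expand.grid(t = factor(1:3), style = factor(c("EE", "LE")),
#'                  rep = 1:3)
#' d$v <- as.numeric(d$t) + (d$style == "EE") * 2
#' two_way_anova(d, "v", "t", "style")
#' @export
two_way_anova <- function(data, value, factor1, factor2) {
  f1 <- factor(data[[factor1]])
  f2 <- factor(data[[factor2]])
  if (nlevels(droplevels(f1)) < 2 || nlevels(droplevels(f2)) < 2) {
    abort("each factor needs at least 2 levels.",
          class = "chronocope_design_error")
  }
  d <- data.frame(.value = data[[value]], .f1 = droplevels(f1),
                  .f2 = droplevels(f2))
  fit <- lm(.value ~ .f1 * .f2, data = d)
  a2 <- car::Anova(fit, type = 2)
  tab <- as.data.frame(a2)
  term <- rownames(tab)
  term[term == ".f1"] <- factor1
  term[term == ".f2"] <- factor2
  term[term == ".f1:.f2"] <- paste0(factor1, ":", factor2)
  tibble(term = term, sumsq = tab$`Sum Sq`, df = tab$Df,
         statistic = tab$`F value`, p_value = tab$`Pr(>F)`)
}

#' Post hoc alpha adjustments
#'
#' Bonferroni (`alpha / m`) and Sidak (`1 - (1 - alpha)^(1/m)`) adjusted
#' per-comparison significance levels for `m` comparisons. For every
#' `m >= 1`, `sidak_alpha(a, m) >= bonferroni_alpha(a, m)`.
#'
#' @param alpha Familywise significance level.
#' @param m Number of comparisons (>= 1).
#' @return Adjusted per-comparison alpha.
#' @examples
#' bonferroni_alpha(0.05, 6)
#' sidak_alpha(0.05, 6)
#' @export
bonferroni_alpha <- function(alpha, m) {
  stopifnot(m >= 1, alpha > 0, alpha < 1)
  alpha / m
}

#' @rdname bonferroni_alpha
#' @export
sidak_alpha <- function(alpha, m) {
  stopifnot(m >= 1, alpha > 0, alpha < 1)
  1 - (1 - alpha)^(1 / m)
}

#' Select the rhythm metric that predicts emergence rank
#'
#' The model-selection chain behind the rhythm-strength result:
#' (1) iteratively drop predictors with variance inflation factor above
#' `vif_threshold` (highest first); (2) fit the multivariate linear model of
#' rank on the remaining predictors and flag (but never remove) points with
#' Cook's distance above `cook_threshold`; (3) backward-eliminate by AIC;
#' (4) confirm the surviving predictors with likelihood-ratio (F) tests,
#' iteratively dropping the least significant until all retained predictors
#' are significant at `alpha`.
#'
#' @param data Data frame holding the response and candidate predictors.
#' @param response Response column name (emergence rank, treated as
#'   numeric).
#' @param predictors Candidate predictor column names (>= 2).
#' @param vif_threshold Variance-inflation threshold (default 5).
#' @param cook_threshold Cook's distance flag threshold; default `4/n`.
#' @param alpha Significance level of the likelihood-ratio confirmation.
#' @return Object of class `chrono_selection`: `retained` (predictor
#'   names), `vif_dropped`, `vif` (final VIFs), `influential` (row ids with
#'   large Cook's distance), `aic_trace` (tibble of models and AIC values)
#'   and `model` (the final [lm] fit).
#' @examples
#' set.seed(1)
#' d <- data.frame(rank = 1:20 + rnorm(20), rs = 1:20,
#'                 noise = rnorm(20), noise2 = rnorm(20))
#' select_rhythm_model(d, "rank", c("rs", "noise", "noise2"))
#' @export
select_rhythm_model <- function(data, response = "rank",
                                predictors = c("auc", "amplitude",
                                               "rhythm_strength", "vmax"),
                                vif_threshold = 5, cook_threshold = NULL,
                                alpha = 0.05) {
  stopifnot(response %in% names(data), all(predictors %in% names(data)))
  if (length(predictors) < 2) {
    abort("need at least 2 candidate predictors.",
          class = "chronocope_config_error")
  }
  d <- data[c(response, predictors)]
  d <- d[complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n <= length(predictors) + 2) {
    abort("not enough observations for the candidate set.",
          class = "chronocope_insufficient_data")
  }
  if (is.null(cook_threshold)) cook_threshold <- 4 / n

  vif_of <- function(p, others) {
    if (length(others) == 0) return(1)
    r2 <- summary(lm(reformulate(others, p), data = d))$r.squared
    1 / max(1 - r2, .Machine$double.eps)
  }
  cand <- predictors
  vif_dropped <- character(0)
  repeat {
    if (length(cand) < 2) break
    vifs <- vapply(cand, function(p) vif_of(p, setdiff(cand, p)),
                   numeric(1))
    if (max(vifs) <= vif_threshold) break
    worst <- names(which.max(vifs))
    vif_dropped <- c(vif_dropped, worst)
    cand <- setdiff(cand, worst)
  }
  full <- lm(reformulate(cand, response), data = d)
  if (any(!is.finite(coef(full)))) {
    abort("degenerate model: singular design after VIF drops.",
          class = "chronocope_degenerate_model")
  }
  cook <- cooks.distance(full)
  influential <- which(cook > cook_threshold)

  stepped <- step(full, direction = "backward", trace = 0)
  aic_trace <- tibble(model = attr(stepped$anova, "heading")[1],
                      step = as.character(stepped$anova$Step),
                      aic = stepped$anova$AIC)
  retained <- setdiff(names(coef(stepped)), "(Intercept)")
  # likelihood-ratio confirmation: every retained term must matter at alpha
  while (length(retained) > 0) {
    fit_now <- lm(reformulate(retained, response), data = d)
    ps <- vapply(retained, function(p) {
      reduced <- setdiff(retained, p)
      f0 <- if (length(reduced) == 0) {
        lm(reformulate("1", response), data = d)
      } else lm(reformulate(reduced, response), data = d)
      anova(f0, fit_now)$`Pr(>F)`[2]
    }, numeric(1))
    if (max(ps) < alpha) break
    retained <- setdiff(retained, names(which.max(ps)))
  }
  final <- if (length(retained) == 0) {
    lm(reformulate("1", response), data = d)
  } else lm(reformulate(retained, response), data = d)
  final_vifs <- if (length(cand) >= 2) {
    vapply(cand, function(p) vif_of(p, setdiff(cand, p)), numeric(1))
  } else setNames(1, cand)
  structure(list(retained = retained, vif_dropped = vif_dropped,
                 vif = final_vifs,
                 influential = rownames(d)[influential],
                 cook_threshold = cook_threshold,
                 aic_trace = aic_trace, model = final, n = n),
            class = "chrono_selection")
}

#' @export
print.chrono_selection <- function(x, ...) {
  cat("<chrono_selection> retained:",
      if (length(x$retained)) paste(x$retained, collapse = ", ")
      else "(none)", "\n")
  if (length(x$vif_dropped)) {
    cat("  dropped by VIF:", paste(x$vif_dropped, collapse = ", "), "\n")
  }
  cat("  flagged points (Cook's D >", format(x$cook_threshold, digits = 3),
      "):", length(x$influential), "\n")
  invisible(x)
}

#' @method tidy chrono_selection
#' @export
tidy.chrono_selection <- function(x, ...) {
  cf <- summary(x$model)$coefficients
  tibble(term = rownames(cf), estimate = cf[, 1], std.error = cf[, 2],
         statistic = cf[, 3], p_value = cf[, 4])
}

#' @method glance chrono_selection
#' @export
glance.chrono_selection <- function(x, ...) {
  s <- summary(x$model)
  tibble(r.squared = s$r.squared, aic = AIC(x$model),
         n_retained = length(x$retained), nobs = x$n)
}
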