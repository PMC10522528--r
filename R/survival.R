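as_survival_table <- function(table) {
  need <- c("time", "event", "group")
  if (!all(need %in% names(table))) {
    stop("survival table needs columns time, event, group")
  }
  if (any(!is.finite(table$time)) || any(table$time <= 0)) {
    stop("data error: survival times must be positive")
  }
  table$group <- factor(table$group)
  table
}

#' Kaplan-Meier curves per group
#'
#' Product-limit survival estimates `S(t) = prod(1 - d_i / n_i)` for each
#' group of a survival table, with censored subjects remaining at risk
#' through tied event times (the standard convention).  Estimation is
#' delegated to [survival::survfit()].
#'
#' @param table Data frame with columns `time` (months, positive), `event`
#'   (1 = death observed, 0 = censored) and `group`.
#' @return Data frame of class `km_curves` with columns `group`, `time`,
#'   `n_risk`, `n_event`, `survival`; each group starts at `time = 0`,
#'   `survival = 1`.
#' @export
km_estimate <- function(table) {
  table <- as_survival_table(table)
  out <- do.call(rbind, lapply(levels(table$group), function(g) {
    d <- table[table$group == g, ]
    if (nrow(d) == 0L) return(NULL)
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
    data.frame(group = g,
               time = c(0, fit$time),
               n_risk = c(fit$n.risk[1L], fit$n.risk),
               n_event = c(0, fit$n.event),
               survival = c(1, fit$surv),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("km_curves", "data.frame")
  out
}

#' Log-rank comparison of survival groups
#'
#' K-group log-rank test built from observed-minus-expected event counts at
#' every event time ([survival::survdiff()]), with `k - 1` degrees of
#' freedom.
#'
#' @inheritParams km_estimate
#' @return List with `statistic` (chi-square), `df`, `p_value`, `n_groups`.
#' @export
logrank_test <- function(table) {
  table <- as_survival_table(table)
  table$group <- droplevels(table$group)
  k <- nlevels(table$group)
  if (k < 2L) stop("comparison error: need at least 2 groups")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = table)
  stat <- fit$chisq
  df <- k - 1L
  list(statistic = unname(stat), df = df,
       p_value = pchisq(unname(stat), df, lower.tail = FALSE),
       n_groups = k)
}

#' Group tests over cohort characteristics
#'
#' Chi-squared tests (without continuity correction) for categorical
#' variables and Kruskal-Wallis tests for continuous variables across the
#' three survival groups, with Benjamini-Hochberg adjusted p-values added
#' for transparency (the primary report is per-variable and unadjusted).
#'
#' @param cohort_table Data frame containing `survival_class` and the
#'   variables to test (e.g. a cohort's `subjects` table).
#' @param categorical,continuous Character vectors of column names
#'   (defaults: `sex`; `age` and `survival_months`).
#' @return Data frame with columns `variable`, `test`, `statistic`, `df`,
#'   `p_value`, `p_adjusted`.
#' @export
group_tests <- function(cohort_table, categorical = "sex",
                        continuous = c("age", "survival_months")) {
  grp <- factor(cohort_table$survival_class)
  rows <- list()
  for (v in categorical) {
    tab <- table(cohort_table[[v]], grp)
    if (all(tab == 0)) stop("degenerate table for ", v)
    ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, test = "chi-squared",
      statistic = unname(ht$statistic), df = unname(ht$parameter),
      p_value = ht$p.value, stringsAsFactors = FALSE)
  }
  for (v in continuous) {
    ht <- kruskal.test(cohort_table[[v]], grp)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, test = "kruskal-wallis",
      statistic = unname(ht$statistic), df = unname(ht$parameter),
      p_value = ht$p.value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
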