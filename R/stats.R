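#' Cohort survival percentage
#'
#' `100 x (cells present at the second timepoint, including newly
#' appeared cells) / (cells present at the first timepoint)`. Values
#' above 100 are legitimate: cells may begin expressing the reporter
#' during the observation window.
#'
#' @param table a cohort table (e.g. from [simulate_cohort()]) with
#'   logical columns `present_at_t1`, `present_at_t2`, `newly_appeared`
#'   and a `condition` column.
#' @param condition condition to summarize; default the single condition
#'   present.
#' @return object of class `survival_result`: `condition`,
#'   `pct_survival`, `n_t1`, `n_t2`.
#' @export
survival_percent <- function(table, condition = NULL) {
  if (is.null(condition)) {
    conds <- unique(table$condition)
    stop_field(length(conds) == 1L, "several conditions present; pick one")
    condition <- conds
  }
  d <- table[table$condition == condition, , drop = FALSE]
  n1 <- sum(d$present_at_t1)
  stop_field(n1 >= 1, "no cells at the first timepoint")
  n2 <- sum(d$present_at_t2)   # includes newly appeared cells
  structure(list(condition = condition, pct_survival = 100 * n2 / n1,
                 n_t1 = n1, n_t2 = n2),
            class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat(sprintf("<survival_result> %s: %.1f%% (%d -> %d cells)\n",
              x$condition, x$pct_survival, x$n_t1, x$n_t2))
  invisible(x)
}

test_result <- function(statistic, df, p_value, method, pairwise = NULL,
                        extra = list()) {
  structure(c(list(statistic = unname(statistic), df = unname(df),
                   p_value = unname(p_value), method = method,
                   pairwise = pairwise), extra),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  dfs <- paste(signif(x$df, 5), collapse = ", ")
  cat(sprintf("<test_result> %s: statistic %.4g, df %s, p = %.4g\n",
              x$method, x$statistic, dfs, x$p_value))
  if (!is.null(x$pairwise)) {
    cat("  pairwise:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Unpaired two-sample t-test (pooled variance)
#'
#' Classical Student t-test with pooled variance (the historical default
#' of the field's statistics software); set `var_equal = FALSE` for the
#' Welch variant. Two constant samples with equal means return t = 0,
#' p = 1 by convention.
#'
#' @param a,b numeric samples, each n >= 2.
#' @param var_equal pool variances (default `TRUE`).
#' @return a `test_result`.
#' @export
ttest_unpaired <- function(a, b, var_equal = TRUE) {
  stop_field(length(a) >= 2 && length(b) >= 2, "each sample needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(test_result(0, length(a) + length(b) - 2, 1, "Unpaired t-test (pooled)"))
    return(test_result(Inf, length(a) + length(b) - 2, 0, "Unpaired t-test (pooled)"))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  test_result(tt$statistic, tt$parameter, tt$p.value,
              if (var_equal) "Unpaired t-test (pooled)" else "Welch t-test")
}

#' One-way analysis of variance
#'
#' F statistic with (k - 1, N - k) degrees of freedom.
#'
#' @param groups list of numeric samples (>= 2 groups, each n >= 2).
#' @return a `test_result` with `df = c(df1, df2)`.
#' @export
anova_oneway <- function(groups) {
  stop_field(is.list(groups) && length(groups) >= 2, "need >= 2 groups")
  stop_field(all(vapply(groups, length, 0L) >= 2), "each group needs n >= 2")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  k <- length(groups); N <- length(y)
  ss_within <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 0))
  ss_between <- sum(vapply(groups, function(x) length(x) * (mean(x) - mean(y))^2, 0))
  df1 <- k - 1; df2 <- N - k
  if (ss_within == 0) {
    if (ss_between == 0) return(test_result(0, c(df1, df2), 1, "One-way ANOVA"))
    return(test_result(Inf, c(df1, df2), 0, "One-way ANOVA"))
  }
  f <- (ss_between / df1) / (ss_within / df2)
  test_result(f, c(df1, df2), stats::pf(f, df1, df2, lower.tail = FALSE),
              "One-way ANOVA",
              extra = list(mse = ss_within / df2))
}

#' Newman-Keuls stepwise multiple-comparison post-test
#'
#' Stepwise studentized-range procedure following a one-way ANOVA. Group
#' means are ordered; for a pair spanning `r` ordered means the statistic
#' `q = (m_i - m_j) / sqrt(MSE/2 * (1/n_i + 1/n_j))` is referred to the
#' studentized-range distribution with parameters `(r, df_error)`
#' (computed numerically via R's `ptukey`/`qtukey`). A non-significant
#' span blocks all comparisons nested inside it. With two groups the
#' procedure is decision-equivalent to the unpaired pooled t-test.
#'
#' @param groups list of numeric samples (>= 2 groups, each n >= 2).
#' @param alpha familywise significance level.
#' @param group_names optional labels.
#' @return a `test_result` carrying the ANOVA F and a `pairwise` table
#'   (group1, group2, diff, q, r, p_value, significant).
#' @export
newman_keuls <- function(groups, alpha = 0.05, group_names = NULL) {
  stop_field(is.list(groups) && length(groups) >= 2, "need >= 2 groups")
  an <- anova_oneway(groups)
  k <- length(groups)
  nm <- group_names %||% names(groups) %||% paste0("g", seq_len(k))
  means <- vapply(groups, mean, 0)
  ns <- vapply(groups, length, 0L)
  mse <- an$mse
  df2 <- an$df[2]
  ord <- order(means)
  sig <- matrix(FALSE, k, k)
  blocked <- matrix(FALSE, k, k)  # indices are positions in the ordered means
  rows <- list()
  for (r in k:2) {
    for (i in seq_len(k - r + 1)) {
      j <- i + r - 1
      gi <- ord[i]; gj <- ord[j]
      se <- sqrt(mse / 2 * (1 / ns[gi] + 1 / ns[gj]))
      q <- if (se > 0) (means[gj] - means[gi]) / se else
        if (means[gj] == means[gi]) 0 else Inf
      p <- if (is.infinite(q)) 0 else
        stats::ptukey(q, nmeans = r, df = df2, lower.tail = FALSE)
      significant <- !blocked[i, j] && q >= stats::qtukey(1 - alpha, r, df2)
      if (!significant) {
        # block every comparison nested within a non-significant span
        for (a in i:j) for (b in a:j) blocked[a, b] <- TRUE
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = nm[gj], group2 = nm[gi],
        diff = means[gj] - means[gi], q = q, r = r,
        p_value = p, significant = significant
      )
    }
  }
  pw <- do.call(rbind, rows)
  test_result(an$statistic, an$df, an$p_value,
              "One-way ANOVA with Newman-Keuls post-test", pairwise = pw,
              extra = list(mse = mse, alpha = alpha))
}
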