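#' One-way ANOVA with Tukey's multiple comparison
#'
#' Standard one-way ANOVA decomposition (via [stats::aov()]) with Tukey
#' HSD adjusted pairwise p-values from the studentized range
#' distribution.
#'
#' @param design Data frame with columns `value` (numeric) and `group`.
#' @return List with `F`, `df` (between, within), `p_value`, and `tukey`
#'   (data.frame: `comparison`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
anova_tukey <- function(design) {
  stopifnot(all(c("value", "group") %in% names(design)))
  g <- factor(design$group)
  if (nlevels(g) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(tabulate(g) < 2L)) stop("each group needs n >= 2", call. = FALSE)
  if (!all(is.finite(design$value))) {
    stop("values must be finite", call. = FALSE)
  }
  fit <- aov(value ~ g, data = data.frame(value = design$value, g = g))
  tab <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$g
  list(
    F = tab[["F value"]][1],
    df = c(between = tab[["Df"]][1], within = tab[["Df"]][2]),
    p_value = tab[["Pr(>F)"]][1],
    tukey = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                       lwr = tk[, "lwr"], upr = tk[, "upr"],
                       p_adj = tk[, "p adj"], row.names = NULL)
  )
}

#' Two-sided Fisher's exact test for a 2x2 table, by enumeration
#'
#' Exhaustively enumerates all tables with the observed margins; the
#' two-sided p-value is the total hypergeometric probability of tables as
#' or less probable than the observed one (probability-mass rule).  The
#' conditional maximum-likelihood odds ratio (the value under which the
#' noncentral hypergeometric expectation equals the observed cell) is
#' reported.
#'
#' @param table 2x2 matrix of nonnegative integer counts with positive
#'   row and column margins.
#' @return List with `odds_ratio`, `p_value`, and the per-table
#'   hypergeometric `support` used in the enumeration.
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L)) || any(m < 0) || any(m != round(m))) {
    stop("need a 2x2 table of nonnegative integers", call. = FALSE)
  }
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) {
    stop("all margins must be positive", call. = FALSE)
  }
  x_obs <- m[1, 1]
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(x_obs, c1, n - c1, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])

  or <- if (x_obs == min(support)) {
    0
  } else if (x_obs == max(support)) {
    Inf
  } else {
    logprobs <- dhyper(support, c1, n - c1, r1, log = TRUE)
    cond_mean <- function(logpsi) {
      lw <- logprobs + support * logpsi
      w <- exp(lw - max(lw))
      sum(support * w) / sum(w) - x_obs
    }
    exp(uniroot(cond_mean, c(-30, 30), tol = 1e-10, extendInt = "upX")$root)
  }
  list(odds_ratio = or, p_value = min(p, 1),
       support = data.frame(x = support, prob = probs))
}

#' Pearson chi-squared test on a 2 x K contingency table
#'
#' Pearson statistic `sum((O - E)^2 / E)` with `df = K - 1` and an
#' upper-tail chi-squared p-value; no continuity correction.  A flag is
#' raised when any expected count is below 5.
#'
#' @param table 2 x K matrix of nonnegative counts; every column total
#'   must be positive.
#' @return List with `statistic`, `df`, `p_value`, `expected`,
#'   `low_expected` flag.
#' @export
chi_squared <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) != 2L || any(m < 0)) {
    stop("need a 2 x K table of nonnegative counts", call. = FALSE)
  }
  if (any(colSums(m) == 0)) stop("zero column total", call. = FALSE)
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - E)^2 / E)
  df <- ncol(m) - 1L
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE),
       expected = E, low_expected = any(E < 5))
}
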