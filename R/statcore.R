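# Shared statistical toolkit: Shapiro-Wilk normality gate, gated group
# comparison (t / one-way ANOVA + Tukey, rank fallback), and the exact
# small-sample Wilcoxon rank-sum test.

#' Shapiro-Wilk normality gate
#'
#' @param x Numeric sample, `3 <= n <= 5000`, non-constant.
#' @param alpha Gate significance level.
#' @return One-row tibble: `w`, `p`, `normal` (decision at `alpha`).
#' @export
shapiro_gate <- function(x, alpha = 0.05) {
  assert_that(length(x) >= 3 && length(x) <= 5000,
              "Shapiro-Wilk requires 3 <= n <= 5000")
  assert_that(diff(range(x)) > 0, "constant sample: W undefined")
  s <- stats::shapiro.test(x)
  tibble(w = unname(s$statistic), p = s$p.value, normal = s$p.value > alpha)
}

#' Normality-gated group comparison
#'
#' Two groups: unpaired equal-variance Student t test; three or more: one-way
#' ANOVA with a Tukey HSD pairwise table (Tukey-Kramer for unequal n). When
#' the Shapiro-Wilk gate fails for any group the comparison falls back to the
#' rank-based test (exact Wilcoxon for two groups, Kruskal-Wallis otherwise)
#' with a warning.
#'
#' @param data Data frame with one observation per row.
#' @param value,group Column names (strings) of the measurement and group
#'   label.
#' @param gate Apply the Shapiro-Wilk gate?
#' @param alpha Gate significance level.
#' @return Object of class `group_comparison`: list with `test`,
#'   `statistic`, `p`, `posthoc` (tibble or `NULL`), `gate` (per-group gate
#'   table or `NULL`).
#' @export
compare_groups <- function(data, value = "value", group = "group",
                           gate = TRUE, alpha = 0.05) {
  x <- data[[value]]
  g <- factor(data[[group]])
  assert_that(nlevels(g) >= 2, "need at least two groups")
  assert_that(all(table(g) >= 2), "every group needs n >= 2")

  gate_tbl <- NULL
  normal <- TRUE
  if (gate) {
    gate_tbl <- purrr::map_dfr(levels(g), function(lev) {
      dplyr::mutate(shapiro_gate(x[g == lev], alpha), group = lev,
                    .before = 1)
    })
    normal <- all(gate_tbl$normal)
  }

  if (normal) {
    if (nlevels(g) == 2) {
      tt <- stats::t.test(x ~ g, var.equal = TRUE)
      res <- list(test = "t", statistic = unname(tt$statistic),
                  p = tt$p.value, posthoc = NULL)
    } else {
      fit <- stats::aov(x ~ g)
      an <- summary(fit)[[1]]
      tk <- stats::TukeyHSD(fit)$g
      posthoc <- tibble(
        contrast = rownames(tk), diff = tk[, "diff"],
        lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
        marks = signif_marks(tk[, "p adj"])
      )
      res <- list(test = "anova+tukey", statistic = an$`F value`[1],
                  p = an$`Pr(>F)`[1], posthoc = posthoc)
    }
  } else {
    rlang::warn("normality gate failed; falling back to a rank-based test")
    if (nlevels(g) == 2) {
      wt <- wilcoxon_exact(x[g == levels(g)[1]], x[g == levels(g)[2]])
      res <- list(test = wt$method, statistic = wt$statistic, p = wt$p,
                  posthoc = NULL)
    } else {
      kw <- stats::kruskal.test(x ~ g)
      res <- list(test = "kruskal", statistic = unname(kw$statistic),
                  p = kw$p.value, posthoc = NULL)
    }
  }
  res$gate <- gate_tbl
  res$marks <- signif_marks(res$p)
  class(res) <- "group_comparison"
  res
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g %s\n", x$test, x$statistic,
              x$p, x$marks))
  if (!is.null(x$posthoc)) print(x$posthoc)
  invisible(x)
}

#' Exact Wilcoxon rank-sum test
#'
#' The rank-sum statistic of the first sample. When the number of rank
#' assignments `choose(n + m, n)` is at most `max_enum`, the p-value is exact
#' by full enumeration of assignments (valid under ties via midranks);
#' otherwise the tie-corrected normal approximation is used.
#'
#' @param a,b Numeric samples.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (location of
#'   `a` relative to `b`).
#' @param max_enum Enumeration budget on `choose(n + m, n)`.
#' @return Object of class `rank_test`: list with `statistic` (rank sum W of
#'   `a`), `u` (Mann-Whitney U), `p`, `method` (`"wilcoxon-exact"` or
#'   `"wilcoxon-approx"`), `n` = c(n, m).
#' @export
wilcoxon_exact <- function(a, b, alternative = c("two.sided", "less",
                                                 "greater"),
                           max_enum = 1e5) {
  alternative <- match.arg(alternative)
  assert_that(length(a) > 0 && length(b) > 0, "both samples must be non-empty")
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n)])

  if (diff(range(c(a, b))) == 0) {
    rlang::warn("all values tied across both groups; p = 1")
    return(structure(list(statistic = w_obs,
                          u = w_obs - n * (n + 1) / 2, p = 1,
                          method = "wilcoxon-exact", n = c(n, m)),
                     class = "rank_test"))
  }

  if (choose(n + m, n) <= max_enum) {
    combs <- utils::combn(n + m, n)
    w_all <- colSums(matrix(r[combs], nrow = n))
    p <- switch(alternative,
      two.sided = min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))),
      less = mean(w_all <= w_obs),
      greater = mean(w_all >= w_obs)
    )
    method <- "wilcoxon-exact"
  } else {
    # Normal approximation with tie correction and continuity correction.
    N <- n + m
    mu <- n * (N + 1) / 2
    ties <- table(r)
    sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z_lo <- (w_obs - mu + 0.5) / sqrt(sigma2)
    z_hi <- (w_obs - mu - 0.5) / sqrt(sigma2)
    p <- switch(alternative,
      two.sided = min(1, 2 * min(stats::pnorm(z_lo),
                                 stats::pnorm(z_hi, lower.tail = FALSE))),
      less = stats::pnorm(z_lo),
      greater = stats::pnorm(z_hi, lower.tail = FALSE)
    )
    method <- "wilcoxon-approx"
  }
  structure(list(statistic = w_obs, u = w_obs - n * (n + 1) / 2, p = p,
                 method = method, n = c(n, m)),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("%s: W = %g, p = %.4g\n", x$method, x$statistic, x$p))
  invisible(x)
}
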