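# Lifespan statistics: Kaplan-Meier curves, logrank comparison and
# mean/maximum-lifespan summaries. Estimation is delegated to the survival
# package; this module provides the tidy cohort-level surface.

#' Kaplan-Meier survival estimate as a tidy table
#'
#' Product-limit estimator per group; censored records reduce the risk set
#' without producing steps.
#'
#' @param data Data frame with survival records.
#' @param time,event,group Column names (strings) for time (days), the event
#'   indicator (TRUE/1 = death observed) and the optional group label.
#' @return Tibble of class `km_curve`: `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`.
#' @export
km_estimate <- function(data, time = "time_days", event = "event",
                        group = "group") {
  assert_that(nrow(data) >= 1, "need at least one survival record")
  assert_that(all(data[[time]] > 0), "times must be positive")
  if (!is.null(group) && group %in% names(data)) {
    grp <- as.character(data[[group]])
  } else {
    grp <- rep("all", nrow(data))
  }
  if (!any(as.logical(data[[event]]))) {
    rlang::warn("no events: survival curve is flat at 1")
  }
  fit <- survival::survfit(
    survival::Surv(data[[time]], as.logical(data[[event]])) ~ grp,
    conf.type = "none"
  )
  strata <- if (is.null(fit$strata)) {
    rep(unique(grp), length(fit$time))
  } else {
    rep(sub("^grp=", "", names(fit$strata)), fit$strata)
  }
  out <- tibble(
    group = strata, time = fit$time, n_risk = fit$n.risk,
    n_event = fit$n.event, n_censor = fit$n.censor, surv = fit$surv
  )
  class(out) <- c("km_curve", class(out))
  out
}

#' Logrank test between two (or more) groups
#'
#' Standard logrank with hypergeometric variance at each event time.
#'
#' @inheritParams km_estimate
#' @return List of class `logrank_test`: `chisq`, `df`, `p`, `n` per group.
#' @export
logrank_test <- function(data, time = "time_days", event = "event",
                         group = "group") {
  grp <- factor(data[[group]])
  assert_that(nlevels(grp) >= 2 && all(table(grp) > 0),
              "need at least two non-empty groups")
  assert_that(any(as.logical(data[[event]])), "no events: logrank undefined")
  sd_ <- survival::survdiff(
    survival::Surv(data[[time]], as.logical(data[[event]])) ~ grp
  )
  structure(
    list(chisq = sd_$chisq, df = length(sd_$n) - 1,
         p = stats::pchisq(sd_$chisq, length(sd_$n) - 1, lower.tail = FALSE),
         n = as.integer(sd_$n), groups = levels(grp)),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Logrank test: chisq = %.4g on %d df, p = %.4g\n",
              x$chisq, x$df, x$p))
  invisible(x)
}

#' Lifespan summary with percent differences vs a reference group
#'
#' Mean and median lifespan over observed event times; the maximum-lifespan
#' estimate is the mean of the top decile of event times per group (with the
#' single longest survivor available as an alternative). Percent differences
#' are `100 * (group - reference) / reference`.
#'
#' @inheritParams km_estimate
#' @param reference Reference group label for percent differences.
#' @param max_method `"top_decile"` (mean of the top 10% longest-lived) or
#'   `"oldest"` (single longest event time).
#' @param top_frac Fraction defining the top-decile estimate.
#' @return Tibble per group: `n`, `n_events`, `mean_days`, `median_days`,
#'   `max_lifespan_days`, `pct_diff_mean`, `pct_diff_max`.
#' @export
lifespan_summary <- function(data, reference, time = "time_days",
                             event = "event", group = "group",
                             max_method = c("top_decile", "oldest"),
                             top_frac = 0.1) {
  max_method <- match.arg(max_method)
  grp <- as.character(data[[group]])
  assert_that(reference %in% grp, "reference group not present in the data")
  ev <- as.logical(data[[event]])
  assert_that(any(ev), "no events to summarize")
  tt <- data[[time]]

  per_group <- purrr::map_dfr(unique(grp), function(g) {
    tg <- tt[grp == g & ev]
    assert_that(length(tg) >= 1, paste("group has no events:", g))
    k <- max(1L, ceiling(top_frac * length(tg)))
    top <- sort(tg, decreasing = TRUE)[seq_len(k)]
    tibble(
      group = g, n = sum(grp == g), n_events = length(tg),
      mean_days = mean(tg), median_days = median(tg),
      max_lifespan_days = if (max_method == "top_decile") mean(top) else max(tg)
    )
  })
  ref <- dplyr::filter(per_group, .data$group == reference)
  dplyr::mutate(
    per_group,
    pct_diff_mean = 100 * (.data$mean_days - ref$mean_days) / ref$mean_days,
    pct_diff_max = 100 * (.data$max_lifespan_days - ref$max_lifespan_days) /
      ref$max_lifespan_days
  )
}
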