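# broom-style tidy()/glance() methods for the fitted/result objects.

#' @export
tidy.ecg_analysis <- function(x, ...) x$intervals

#' @export
glance.ecg_analysis <- function(x, ...) x$summary

#' @export
tidy.logrank_test <- function(x, ...) {
  tibble(statistic = x$chisq, df = x$df, p.value = x$p)
}

#' @export
glance.logrank_test <- tidy.logrank_test

#' @export
tidy.group_comparison <- function(x, ...) {
  if (is.null(x$posthoc)) {
    tibble(test = x$test, statistic = x$statistic, p.value = x$p)
  } else {
    dplyr::mutate(x$posthoc, test = x$test, .before = 1)
  }
}

#' @export
glance.group_comparison <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic, p.value = x$p,
         gated = !is.null(x$gate))
}

#' @export
tidy.rank_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, u = x$u, p.value = x$p)
}

#' @export
tidy.heatmap_matrix <- function(x, ...) {
  z <- x$z
  tibble(
    gene_id = rep(rownames(z), ncol(z)),
    sample_id = rep(colnames(z), each = nrow(z)),
    z = as.vector(z)
  )
}

#' @export
glance.heatmap_matrix <- function(x, ...) {
  tibble(n_genes = nrow(x$z), n_samples = ncol(x$z),
         n_excluded = length(x$excluded),
         n_categories = if (is.null(x$category_means)) 0L
                        else nrow(x$category_means))
}
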