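# Downstream transcriptome procedure on a normalized matrix: per-gene fold
# change + p-value, DE filtering, Fisher-exact gene-set enrichment, z-score
# heatmap with average-linkage clustering.

split_groups <- function(expr, groups, group_a, group_b) {
  assert_that(!anyDuplicated(expr$gene_id), "duplicate gene ids")
  sa <- groups$sample_id[groups$group == group_a]
  sb <- groups$sample_id[groups$group == group_b]
  assert_that(length(sa) >= 2 && length(sb) >= 2,
              "each group needs at least 2 samples")
  assert_that(all(c(sa, sb) %in% names(expr)),
              "sample columns missing from the expression table")
  list(a = as.matrix(expr[, sa]), b = as.matrix(expr[, sb]))
}

#' Per-gene fold change and p-value between two groups
#'
#' Fold change is the linear-scale group-mean ratio (log2 input is
#' exponentiated first); the p-value comes from a per-gene unpaired
#' two-sample test on the (log2) values: equal-variance Student t by default
#' (equivalent to two-group one-way ANOVA), Welch as an option. No
#' multiple-testing correction is applied to these per-gene p-values.
#'
#' @param expr Expression tibble: `gene_id` plus one column per sample.
#' @param groups Tibble `sample_id`, `group`.
#' @param group_a,group_b Group labels; the fold change is A over B.
#' @param scale `"log2"` (values are log2, exponentiated for FC) or
#'   `"linear"`.
#' @param var_equal Equal-variance t test (default) or Welch.
#' @return Tibble `gene_id`, `fc` (linear), `log2fc`, `p`, `direction`
#'   (`"up"`/`"down"` for A relative to B).
#' @export
fold_changes <- function(expr, groups, group_a, group_b,
                         scale = c("log2", "linear"), var_equal = TRUE) {
  scale <- match.arg(scale)
  m <- split_groups(expr, groups, group_a, group_b)
  lin_a <- if (scale == "log2") 2^m$a else m$a
  lin_b <- if (scale == "log2") 2^m$b else m$b
  assert_that(all(lin_a > 0) && all(lin_b > 0),
              "linear-scale expression values must be positive")
  fc <- rowMeans(lin_a) / rowMeans(lin_b)

  # p-values on the (log2) scale; vectorized two-sample t.
  xa <- if (scale == "log2") m$a else log2(m$a)
  xb <- if (scale == "log2") m$b else log2(m$b)
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1, stats::var); vb <- apply(xb, 1, stats::var)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- (ma - mb) / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[se == 0 & ma == mb] <- 1

  tibble(
    gene_id = expr$gene_id, fc = fc, log2fc = log2(fc), p = p,
    direction = ifelse(fc >= 1, "up", "down")
  )
}

#' Filter differentially expressed genes
#'
#' A gene passes when `FC >= fc_min` or `FC <= 1 / fc_min` (the cutoff is
#' inclusive) and `p <= p_max`.
#'
#' @param results Output of [fold_changes()].
#' @param fc_min Linear fold-change cutoff (>= 1). Reported array studies
#'   use 1.5 or 2; the default 2 matches the transcript counts this filter
#'   is usually quoted with.
#' @param p_max P-value cutoff.
#' @return Tibble of passing genes with attributes `n_up` and `n_down`; also
#'   available via [de_counts()].
#' @export
filter_de <- function(results, fc_min = 2, p_max = 0.05) {
  assert_that(fc_min >= 1, "fc_min must be >= 1")
  pass <- dplyr::filter(results,
                        (.data$fc >= fc_min | .data$fc <= 1 / fc_min) &
                          .data$p <= p_max)
  attr(pass, "n_up") <- sum(pass$direction == "up")
  attr(pass, "n_down") <- sum(pass$direction == "down")
  pass
}

#' @rdname filter_de
#' @param de Output of [filter_de()].
#' @export
de_counts <- function(de) {
  tibble(n_de = nrow(de),
         n_up = sum(de$direction == "up"),
         n_down = sum(de$direction == "down"))
}

#' One-sided Fisher-exact enrichment p-value
#'
#' Upper-tail probability of observing at least `n_overlap` DE genes inside a
#' set of size `n_set`, drawing `n_de` genes from a universe of `n_universe`
#' (the hypergeometric tail that a one-sided Fisher exact test of the 2x2
#' table reduces to).
#'
#' @param n_overlap Observed DE genes in the set.
#' @param n_set Set size.
#' @param n_universe Universe size.
#' @param n_de Number of DE genes.
#' @return The one-sided p-value.
#' @export
enrichment_p <- function(n_overlap, n_set, n_universe, n_de) {
  stats::phyper(n_overlap - 1, n_set, n_universe - n_set, n_de,
                lower.tail = FALSE)
}

#' Fisher-exact gene-set enrichment
#'
#' One-sided (enrichment direction) Fisher exact test on the 2x2 table
#' (DE vs not) x (in set vs not) for every gene set, with Benjamini-Hochberg
#' adjusted p-values reported alongside the raw ones.
#'
#' @param de_genes Character vector of DE gene ids (subset of `universe`).
#' @param universe Character vector: all genes tested.
#' @param gene_sets Tibble with columns `set_id` and `gene_id` (long format;
#'   an optional `description` column is carried through). See
#'   [read_gmt()].
#' @return Tibble per set: `set_id`, `n_set`, `n_overlap`, `p`, `p_adj`.
#' @export
enrich <- function(de_genes, universe, gene_sets) {
  assert_that(length(universe) > 0, "empty universe")
  assert_that(all(de_genes %in% universe), "de_genes must be within universe")
  gene_sets <- dplyr::filter(gene_sets, .data$gene_id %in% universe)
  n_univ <- length(unique(universe))
  n_de <- length(unique(de_genes))
  out <- gene_sets |>
    dplyr::group_by(.data$set_id) |>
    dplyr::summarise(
      description = if ("description" %in% names(gene_sets))
        dplyr::first(.data$description) else NA_character_,
      n_set = dplyr::n_distinct(.data$gene_id),
      n_overlap = sum(unique(.data$gene_id) %in% de_genes),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      p = enrichment_p(.data$n_overlap, .data$n_set, n_univ, n_de),
      p_adj = stats::p.adjust(.data$p, method = "BH")
    )
  out
}

#' Read / write gene sets in GMT format
#'
#' One set per line: id, description, then member gene ids, tab-separated.
#'
#' @param path GMT file path.
#' @return `read_gmt()`: tibble `set_id`, `description`, `gene_id` (long).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  purrr::map_dfr(lines[nzchar(lines)], function(l) {
    parts <- strsplit(l, "\t")[[1]]
    tibble(set_id = parts[1], description = parts[2],
           gene_id = parts[-(1:2)])
  })
}

#' @rdname read_gmt
#' @param gene_sets Long-format gene set tibble.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- gene_sets |>
    dplyr::group_by(.data$set_id) |>
    dplyr::summarise(
      line = paste(c(.data$set_id[1],
                     if ("description" %in% names(gene_sets))
                       .data$description[1] else "NA",
                     .data$gene_id), collapse = "\t"),
      .groups = "drop"
    )
  writeLines(lines$line, path)
  invisible(path)
}

#' Row z-scored heatmap matrix with average-linkage clustering
#'
#' Selected genes are z-scored per row (mean 0, sample sd 1; constant rows
#' are excluded with a warning), clustered by agglomerative average linkage
#' on Euclidean distance (rows and columns), and per-category mean z-scores
#' are computed when an annotation is supplied.
#'
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @param selected_genes Genes (rows) to include.
#' @param categories Optional tibble `set_id`, `gene_id` assigning genes to
#'   annotation categories.
#' @param distance Distance metric for clustering (`stats::dist` method).
#' @return Object of class `heatmap_matrix`: list with `z` (matrix),
#'   `row_order`, `col_order`, `row_hclust`, `col_hclust`,
#'   `category_means` (category x sample matrix or `NULL`), `excluded`.
#' @export
zscore_heatmap <- function(expr, selected_genes, categories = NULL,
                           distance = "euclidean") {
  assert_that(all(selected_genes %in% expr$gene_id),
              "selected genes missing from the expression table")
  m <- as.matrix(expr[match(selected_genes, expr$gene_id), -1])
  rownames(m) <- selected_genes
  sds <- apply(m, 1, sd)
  excluded <- rownames(m)[sds == 0]
  if (length(excluded) > 0) {
    rlang::warn(paste("excluding constant rows:",
                      paste(excluded, collapse = ", ")))
    m <- m[sds > 0, , drop = FALSE]
  }
  z <- t(scale(t(m)))
  assert_that(nrow(z) >= 2, "need at least 2 non-constant rows to cluster")
  row_hc <- stats::hclust(stats::dist(z, method = distance),
                          method = "average")
  col_hc <- stats::hclust(stats::dist(t(z), method = distance),
                          method = "average")
  cat_means <- NULL
  if (!is.null(categories)) {
    categories <- dplyr::filter(categories, .data$gene_id %in% rownames(z))
    sets <- unique(categories$set_id)
    cat_means <- t(vapply(sets, function(s) {
      colMeans(z[categories$gene_id[categories$set_id == s], , drop = FALSE])
    }, numeric(ncol(z))))
    rownames(cat_means) <- sets
  }
  structure(
    list(z = z, row_order = row_hc$order, col_order = col_hc$order,
         row_hclust = row_hc, col_hclust = col_hc,
         category_means = cat_means, excluded = excluded),
    class = "heatmap_matrix"
  )
}
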