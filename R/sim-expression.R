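# Synthetic normalized expression matrices with planted fold changes.

#' Simulate a log2 expression matrix with planted differential expression
#'
#' Emulates a normalized two-group microarray comparison at small n (arrays in
#' this field are typically run at n = 3 per group): per-gene baselines are
#' drawn once, a planted set of genes receives a group-mean log2 fold change,
#' and i.i.d. Gaussian residual noise is added per sample.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Samples per group (>= 2).
#' @param groups Character vector of the two group labels; the planted
#'   `log2fc` is the mean of group 1 minus the mean of group 2.
#' @param baseline_log2_mean,baseline_log2_sd Population of per-gene baseline
#'   log2 expression values.
#' @param n_de Number of planted differentially expressed genes.
#' @param planted_log2fc Magnitude of the planted log2 fold change; half of
#'   the planted genes go up, half down.
#' @param noise_sd Residual per-sample noise sd on the log2 scale.
#' @param seed Integer seed.
#' @return A list of class `expr_sim`: `expr` (tibble, `gene_id` +
#'   one column per sample, log2 scale), `groups` (tibble `sample_id`,
#'   `group`) and `truth` (tibble `gene_id`, `log2fc` for planted genes).
#' @examples
#' sim <- sim_expression(n_genes = 50, n_de = 4, seed = 1)
#' sim$truth
#' @export
sim_expression <- function(n_genes = 2000,
                           n_per_group = 3,
                           groups = c("WT_old", "KO_old"),
                           baseline_log2_mean = 7,
                           baseline_log2_sd = 1.5,
                           n_de = 100,
                           planted_log2fc = 2,
                           noise_sd = 0.1,
                           seed = 1) {
  assert_that(n_per_group >= 2, "n_per_group must be >= 2")
  assert_that(length(groups) == 2 && !anyDuplicated(groups),
              "exactly two distinct group labels required")
  assert_that(n_de <= n_genes, "planted set larger than the gene universe")
  set.seed(seed)

  gene_id <- sprintf("gene_%05d", seq_len(n_genes))
  baseline <- rnorm(n_genes, baseline_log2_mean, baseline_log2_sd)
  de_idx <- if (n_de > 0) sort(sample.int(n_genes, n_de)) else integer(0)
  sign_up <- rep_len(c(1, -1), length(de_idx))
  log2fc <- numeric(n_genes)
  log2fc[de_idx] <- sign_up * planted_log2fc

  sample_id <- c(paste0(groups[1], "_", seq_len(n_per_group)),
                 paste0(groups[2], "_", seq_len(n_per_group)))
  group <- rep(groups, each = n_per_group)

  mu <- cbind(
    matrix(baseline + log2fc / 2, n_genes, n_per_group),
    matrix(baseline - log2fc / 2, n_genes, n_per_group)
  )
  values <- mu + matrix(rnorm(length(mu), 0, noise_sd), nrow = n_genes)
  colnames(values) <- sample_id

  expr <- dplyr::bind_cols(tibble(gene_id = gene_id), as_tibble(values))
  structure(
    list(expr = expr,
         groups = tibble(sample_id = sample_id, group = group),
         truth = tibble(gene_id = gene_id[de_idx], log2fc = log2fc[de_idx]),
         scale = "log2"),
    class = "expr_sim"
  )
}

#' Write / read an expression matrix as TSV with a group header row
#'
#' First row after the header carries the group label of every sample column.
#'
#' @param sim An `expr_sim` object (or list with `expr` and `groups`).
#' @param path Output TSV path.
#' @return `path` invisibly; `read_expression_tsv()` returns a list with
#'   `expr` and `groups`.
#' @export
write_expression_tsv <- function(sim, path) {
  expr <- sim$expr
  grp <- sim$groups$group[match(names(expr)[-1], sim$groups$sample_id)]
  hdr <- rbind(c("group", grp))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(expr), collapse = "\t"), con)
  writeLines(paste(hdr, collapse = "\t"), con)
  utils::write.table(expr, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1], "\t")[[1]]
  grp_row <- strsplit(lines[2], "\t")[[1]]
  body <- utils::read.table(text = lines[-(1:2)], sep = "\t",
                            col.names = header, check.names = FALSE)
  list(expr = as_tibble(body),
       groups = tibble(sample_id = header[-1], group = grp_row[-1]))
}
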