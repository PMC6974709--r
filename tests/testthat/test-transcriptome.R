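# Fold changes, DE filtering, enrichment and z-score heatmap clustering.

mk_expr <- function(values_a, values_b, gene_id = NULL) {
  n <- nrow(values_a)
  gene_id <- gene_id %||% sprintf("g%03d", seq_len(n))
  expr <- tibble::tibble(gene_id = gene_id)
  for (j in seq_len(ncol(values_a))) expr[[paste0("A", j)]] <- values_a[, j]
  for (j in seq_len(ncol(values_b))) expr[[paste0("B", j)]] <- values_b[, j]
  groups <- tibble::tibble(
    sample_id = c(paste0("A", seq_len(ncol(values_a))),
                  paste0("B", seq_len(ncol(values_b)))),
    group = rep(c("A", "B"), c(ncol(values_a), ncol(values_b)))
  )
  list(expr = expr, groups = groups)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("fold change is the linear group-mean ratio", {
  e <- mk_expr(matrix(log2(200), 3, 3), matrix(log2(100), 3, 3))
  fc <- fold_changes(e$expr, e$groups, "A", "B")
  expect_equal(fc$fc, rep(2, 3), tolerance = 1e-12)
  expect_equal(fc$direction, rep("up", 3))
  # identical groups: FC 1, p 1
  e2 <- mk_expr(matrix(5, 2, 3), matrix(5, 2, 3))
  fc2 <- fold_changes(e2$expr, e2$groups, "A", "B")
  expect_equal(fc2$fc, rep(1, 2))
  expect_equal(fc2$p, rep(1, 2))
})

test_that("the per-gene t statistic matches the closed form and t.test", {
  e <- mk_expr(matrix(c(1, 2, 3), 1, 3, byrow = TRUE),
               matrix(c(4, 5, 6), 1, 3, byrow = TRUE))
  fc <- fold_changes(e$expr, e$groups, "A", "B")
  tt <- stats::t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(fc$p, tt$p.value, tolerance = 1e-9)
  # |t| = 3 / sqrt(2/3) = 3.674, df = 4
  expect_equal(fc$p, 2 * stats::pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-9)
  # Welch option matches t.test(var.equal = FALSE)
  ew <- mk_expr(matrix(c(1, 2, 3, 9), 1, 4, byrow = TRUE),
                matrix(c(4, 5, 6), 1, 3, byrow = TRUE))
  fw <- fold_changes(ew$expr, ew$groups, "A", "B", var_equal = FALSE)
  tw <- stats::t.test(c(1, 2, 3, 9), c(4, 5, 6))
  expect_equal(fw$p, tw$p.value, tolerance = 1e-9)
})

test_that("DE filtering applies the inclusive fold-change rule", {
  # planted noiseless matrix: 10 genes at FC 2.5, 5 at FC 1.2
  fcs <- c(rep(2.5, 10), rep(1.2, 5))
  a <- matrix(rep(log2(100 * fcs), 3), ncol = 3)
  b <- matrix(rep(log2(100), 15 * 3), ncol = 3)
  # add a hair of noise so p-values are defined, keeping means essentially at FC
  set.seed(1)
  a <- a + rnorm(length(a), 0, 1e-6)
  b <- b + rnorm(length(b), 0, 1e-6)
  e <- mk_expr(a, b)
  res <- fold_changes(e$expr, e$groups, "A", "B")
  de <- filter_de(res, fc_min = 2, p_max = 0.05)
  expect_equal(nrow(de), 10)
  expect_equal(de_counts(de)$n_up, 10)

  # a gene at exactly FC 2.0 passes ("equal to or higher")
  row <- tibble::tibble(gene_id = "x", fc = 2.0, log2fc = 1, p = 0.05,
                        direction = "up")
  expect_equal(nrow(filter_de(row, 2, 0.05)), 1)
  # empty input gives zero counts
  expect_equal(de_counts(filter_de(row[0, ], 2, 0.05))$n_de, 0)
  expect_error(filter_de(row, fc_min = 0.5), "fc_min")
})

test_that("relabeling groups inverts fold changes and swaps directions", {
  es <- sim_expression(n_genes = 200, n_de = 20, seed = 3)
  f1 <- fold_changes(es$expr, es$groups, "WT_old", "KO_old")
  f2 <- fold_changes(es$expr, es$groups, "KO_old", "WT_old")
  expect_equal(f1$fc, 1 / f2$fc, tolerance = 1e-12)
  expect_equal(f1$p, f2$p, tolerance = 1e-12)
  d1 <- filter_de(f1, 2, 0.05); d2 <- filter_de(f2, 2, 0.05)
  expect_equal(de_counts(d1)$n_up, de_counts(d2)$n_down)
  expect_equal(de_counts(d1)$n_down, de_counts(d2)$n_up)
})

test_that("enrichment p equals the hypergeometric tail", {
  sets <- tibble::tibble(set_id = "s1", description = "d",
                         gene_id = c("g1", "g2"))
  out <- enrich(c("g1", "g2"), paste0("g", 1:4), sets)
  expect_equal(out$p, 1 / 6, tolerance = 1e-12) # C(2,2) C(2,0) / C(4,2)
  expect_equal(out$n_overlap, 2)

  # zero overlap with a tiny set gives p = 1
  sets0 <- tibble::tibble(set_id = "s0", description = "d", gene_id = "g4")
  out0 <- enrich(c("g1", "g2"), paste0("g", 1:4), sets0)
  expect_equal(out0$p, 1)

  expect_error(enrich("g1", character(0), sets), "universe")
  expect_error(enrich("zz", "g1", sets), "within universe")
})

test_that("enrichment p agrees with explicit tail sums and is monotone", {
  set.seed(5)
  for (i in 1:25) {
    N <- sample(5:50, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    universe <- sprintf("u%02d", 1:N)
    sets <- tibble::tibble(set_id = "s", description = "d",
                           gene_id = universe[1:K])
    de <- sample(universe, n)
    got <- enrich(de, universe, sets)
    k <- sum(de %in% universe[1:K])
    expect_equal(got$n_overlap, k)
    expect_equal(got$p, oracle_hyper_tail(k, K, N, n), tolerance = 1e-12)
  }
  # monotone non-increasing in overlap at fixed margins
  p_at <- vapply(0:5, function(k) oracle_hyper_tail(k, 10, 30, 5), numeric(1))
  expect_true(all(diff(p_at) <= 1e-15))
})

test_that("GMT round trip preserves set membership", {
  sets <- tibble::tibble(
    set_id = rep(c("a", "b"), c(3, 2)),
    description = rep(c("first", "second"), c(3, 2)),
    gene_id = c("g1", "g2", "g3", "g2", "g9")
  )
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(dplyr::arrange(back, set_id, gene_id),
               dplyr::arrange(sets, set_id, gene_id))
})

test_that("z-scoring and average-linkage clustering are correct", {
  e <- mk_expr(matrix(c(1, 2), 2, 1), matrix(c(2, 4, 3, 6), 2, 2))
  # row (1, 2, 3): z = (-1, 0, 1)
  expr <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(1, 10), s2 = c(2, 10),
                         s3 = c(3, 10))
  expect_warning(hm <- zscore_heatmap(expr[c(1, 1, 2), ] |>
                                        dplyr::mutate(gene_id = c("g1", "g1b", "g2")),
                                      c("g1", "g1b", "g2")),
                 "constant")
  expect_equal(unname(hm$z["g1", ]), c(-1, 0, 1))
  expect_equal(hm$excluded, "g2")
  # identical rows merge first at height 0
  expect_equal(min(hm$row_hclust$height), 0)
})

test_that("average-linkage merge heights match the brute-force UPGMA oracle", {
  set.seed(8)
  for (i in 1:5) {
    n <- sample(4:8, 1)
    m <- matrix(rnorm(n * 5), n)
    expr <- dplyr::bind_cols(tibble::tibble(gene_id = sprintf("g%d", 1:n)),
                             tibble::as_tibble(m, .name_repair = "minimal") |>
                               stats::setNames(sprintf("s%d", 1:5)))
    hm <- zscore_heatmap(expr, expr$gene_id)
    expect_equal(sort(hm$row_hclust$height), oracle_upgma_heights(hm$z),
                 tolerance = 1e-9)
  }
})

test_that("category means average the z-scores of member genes", {
  expr <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                         s1 = c(1, 2, 5), s2 = c(2, 4, 4), s3 = c(3, 6, 0))
  cats <- tibble::tibble(set_id = c("c1", "c1", "c2"),
                         gene_id = c("g1", "g2", "g3"))
  hm <- zscore_heatmap(expr, expr$gene_id, categories = cats)
  expect_equal(unname(hm$category_means["c1", ]),
               unname(colMeans(hm$z[c("g1", "g2"), ])))
  expect_equal(unname(hm$category_means["c2", ]), unname(hm$z["g3", ]))
})
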