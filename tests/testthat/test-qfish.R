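# Q-FISH quantification: projection, masking, labeling, measurement,
# distribution comparison, shortening rate.

test_that("maximum projection takes the per-pixel max over z", {
  st <- array(0, dim = c(4, 4, 3, 3),
              dimnames = list(NULL, NULL, NULL, c("DAPI", "Cy3", "PCM1")))
  st[2, 3, 2, "Cy3"] <- 500
  pr <- max_project(st, "Cy3")
  expect_equal(pr[2, 3], 500)
  expect_true(all(max_project(st, "DAPI") == 0))
  # projection dominates every slice pixelwise
  st[, , , 2] <- array(runif(48, 0, 100), dim = c(4, 4, 3))
  pr2 <- max_project(st, 2)
  for (z in 1:3) expect_true(all(pr2 >= st[, , z, 2]))
})

test_that("background subtraction maps flat background to zero, clips at 0", {
  flat <- matrix(50, 20, 20)
  expect_true(all(abs(subtract_background(flat)) < 1e-12))
  spot <- flat; spot[5:8, 5:8] <- 150
  out <- subtract_background(spot)
  expect_equal(out[6, 6], 100)
  expect_true(all(out >= 0))
})

test_that("Otsu threshold separates a bimodal image exactly", {
  img <- matrix(100, 30, 30)
  img[10:20, 10:20] <- 1000
  mask <- threshold_dapi(img)
  expect_identical(as.vector(mask), as.vector(img == 1000))
  expect_equal(attr(mask, "method"), "otsu")
  # idempotent on its own 0/65535 rendering
  render <- ifelse(mask, 65535, 0)
  mask2 <- threshold_dapi(render)
  expect_identical(as.vector(mask2), as.vector(mask))
  expect_error(threshold_dapi(matrix(7, 5, 5)), "constant")
})

test_that("DAPI mask recovers true nuclear pixels with Jaccard >= 0.9", {
  sim <- sim_qfish_stack(width = 192, height = 192, n_nuclei = 15,
                         shot_noise = TRUE, seed = 21)
  mask <- threshold_dapi(max_project(sim$stack, "DAPI"))
  truth_mask <- matrix(FALSE, 192, 192)
  for (k in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[k, ]
    xs <- pmax(1, floor(tr$cx - tr$radius_px)):pmin(192, ceiling(tr$cx + tr$radius_px))
    ys <- pmax(1, floor(tr$cy - tr$radius_px)):pmin(192, ceiling(tr$cy + tr$radius_px))
    for (x in xs) for (y in ys) {
      if ((x - tr$cx)^2 + (y - tr$cy)^2 <= tr$radius_px^2) truth_mask[y, x] <- TRUE
    }
  }
  jac <- sum(mask & truth_mask) / sum(mask | truth_mask)
  expect_gte(jac, 0.9)
})

test_that("labeling is 8-connected with a minimum-area filter", {
  m <- matrix(FALSE, 10, 10)
  m[2:4, 2:4] <- TRUE          # blob A (9 px)
  m[7:9, 7:9] <- TRUE          # blob B (9 px)
  lab <- label_nuclei(m, min_area = 1)
  expect_equal(max(lab), 2)
  # diagonal touch merges under 8-connectivity
  md <- matrix(FALSE, 6, 6); md[2, 2] <- TRUE; md[3, 3] <- TRUE
  expect_equal(max(label_nuclei(md, min_area = 1)), 1)
  # a 3-px blob is removed at min_area 5
  m3 <- matrix(FALSE, 6, 6); m3[2, 2:4] <- TRUE
  expect_equal(max(label_nuclei(m3, min_area = 5)), 0)
  # empty mask: empty map, not an error
  expect_equal(max(label_nuclei(matrix(FALSE, 5, 5))), 0)
})

test_that("all generated nuclei are labeled on a synthetic stack", {
  sim <- sim_qfish_stack(width = 256, height = 256, n_nuclei = 40, seed = 5)
  mask <- threshold_dapi(max_project(sim$stack, "DAPI"))
  lab <- label_nuclei(mask, min_area = 50)
  expect_equal(max(lab), 40)
})

test_that("per-nucleus measurement is exact on noiseless input", {
  lab <- matrix(0L, 10, 10)
  lab[2:4, 2:4] <- 1L; lab[7:9, 7:9] <- 2L
  cy3 <- matrix(0, 10, 10); cy3[lab == 1] <- 100; cy3[lab == 2] <- 40
  pcm1 <- matrix(10, 10, 10); pcm1[lab == 1] <- 900
  cy3_before <- cy3
  meas <- measure_nuclei(lab, cy3, pcm1, pcm1_threshold = 500)
  expect_equal(meas$mean_cy3_auf, c(100, 40))
  expect_equal(meas$area_px, c(9L, 9L))
  expect_identical(meas$is_cardiomyocyte, c(TRUE, FALSE))
  # measurement is read-only
  expect_identical(cy3, cy3_before)
  # manual override wins
  meas2 <- measure_nuclei(lab, cy3, pcm1, manual_cardiomyocytes = 2L)
  expect_identical(meas2$is_cardiomyocyte, c(FALSE, TRUE))
  expect_error(measure_nuclei(lab, cy3[1:5, ], pcm1), "shape")
})

test_that("per-nucleus means are invariant to label relabeling order", {
  lab <- matrix(0L, 8, 8)
  lab[2:3, 2:3] <- 1L; lab[6:7, 6:7] <- 2L
  img <- matrix(runif(64, 0, 50), 8, 8)
  m1 <- measure_nuclei(lab, img, img, pcm1_threshold = 1e9)
  swapped <- lab
  swapped[lab == 1L] <- 2L; swapped[lab == 2L] <- 1L
  m2 <- measure_nuclei(swapped, img, img, pcm1_threshold = 1e9)
  expect_equal(sort(m1$mean_cy3_auf), sort(m2$mean_cy3_auf))
})

test_that("full pipeline recovers planted per-nucleus means within 5%", {
  sim <- sim_qfish_stack(width = 256, height = 256, n_nuclei = 40, seed = 7)
  meas <- qfish_quantify(sim$stack)
  expect_equal(nrow(meas), nrow(sim$truth))
  # match measured nuclei to truth by position via the label map
  dapi <- max_project(sim$stack, "DAPI")
  lab <- label_nuclei(threshold_dapi(dapi))
  lab_at_truth <- vapply(seq_len(nrow(sim$truth)), function(k) {
    lab[round(sim$truth$cy[k]), round(sim$truth$cx[k])]
  }, integer(1))
  expect_true(all(lab_at_truth > 0))
  rel_err <- abs(meas$mean_cy3_auf[lab_at_truth] - sim$truth$cy3_auf) /
    sim$truth$cy3_auf
  expect_lt(max(rel_err), 0.05)
  # PCM1 classification agrees with the planted flags
  expect_identical(meas$is_cardiomyocyte[lab_at_truth],
                   sim$truth$is_cardiomyocyte)
})

test_that("group-mean intensity ratio is recovered within 5% of planted", {
  young <- sim_qfish_stack(width = 224, height = 224, n_nuclei = 30,
                           cy3_mean_auf = 600, seed = 13)
  old <- sim_qfish_stack(width = 224, height = 224, n_nuclei = 30,
                         cy3_mean_auf = 480, seed = 14)
  my <- qfish_quantify(young$stack)
  mo <- qfish_quantify(old$stack)
  planted_ratio <- mean(old$truth$cy3_auf) / mean(young$truth$cy3_auf)
  measured_ratio <- mean(mo$mean_cy3_auf) / mean(my$mean_cy3_auf)
  expect_lt(abs(measured_ratio / planted_ratio - 1), 0.05)
})

test_that("TIFF round trip preserves the stack", {
  sim <- sim_qfish_stack(width = 96, height = 96, n_nuclei = 4, n_z = 5,
                         seed = 2)
  path <- withr::local_tempfile(fileext = ".tif")
  write_qfish_tiff(sim$stack, path)
  back <- read_qfish_tiff(path, n_z = 5)
  expect_equal(unname(back[, , , ]), unname(sim$stack[, , , ]),
               tolerance = 1)
})

test_that("distribution comparison and degenerate ties behave as stated", {
  r <- compare_telomere_distributions(c(1, 2), c(3, 4))
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  same <- compare_telomere_distributions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  expect_warning(compare_telomere_distributions(c(5, 5), c(5, 5)), "tied")
  expect_error(compare_telomere_distributions(numeric(0), 1), "non-empty")
})

test_that("shortening rate follows its definition and scaling", {
  r <- shortening_rate(rep(1000, 10), rep(600, 10), 21)
  expect_equal(r$rate_auf_per_month, 400 / 21, tolerance = 1e-12)
  expect_equal(shortening_rate(1:10, 1:10, 5)$rate_auf_per_month, 0)
  r2 <- shortening_rate(rep(1000, 10), rep(600, 10), 42)
  expect_equal(r2$rate_auf_per_month, r$rate_auf_per_month / 2)
  expect_error(shortening_rate(1, 1, 0), "positive")
})
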