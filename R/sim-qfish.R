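# Synthetic Q-FISH confocal stacks (DAPI / Cy3-telomere / PCM1) with
# per-nucleus ground truth.

#' Simulate a three-channel 16-bit Q-FISH z-stack
#'
#' Nuclei are non-overlapping discs placed by rejection sampling; each nucleus
#' carries a uniform true Cy3 (telomere probe) intensity, a DAPI signal and a
#' PCM1 signal that is high only for nuclei flagged as cardiomyocytes. A
#' nucleus occupies a contiguous run of z sections at full intensity, so the
#' noise-free maximum projection recovers the planted per-nucleus value
#' exactly. Shot noise is Poisson on every voxel.
#'
#' @param width,height Image size in pixels.
#' @param n_z Number of z sections (confocal stacks here use 15).
#' @param z_step_um Section spacing in micrometres.
#' @param n_nuclei Number of nuclei to place.
#' @param radius_px Inclusive range of nucleus radii (pixels).
#' @param cy3_mean_auf,cy3_sd_auf Population mean/sd of the planted
#'   per-nucleus Cy3 intensity (arbitrary units of fluorescence).
#' @param cardiomyocyte_fraction Probability that a nucleus is PCM1-positive.
#' @param background Named vector of per-channel background levels.
#' @param dapi_auf,pcm1_pos_auf,pcm1_neg_auf Channel signal levels.
#' @param shot_noise Apply Poisson shot noise?
#' @param min_gap_px Minimum empty margin enforced between nuclei.
#' @param seed Integer seed.
#' @return A list of class `qfish_sim` with `stack` (numeric array
#'   `[height, width, n_z, 3]`, dimnames channel = DAPI/Cy3/PCM1, values in
#'   0..65535, attribute `z_step_um`) and `truth` (tibble: `nucleus`, `cx`,
#'   `cy`, `radius_px`, `area_px`, `cy3_auf`, `is_cardiomyocyte`).
#' @examples
#' sim <- sim_qfish_stack(width = 96, height = 96, n_nuclei = 4, seed = 2)
#' dim(sim$stack)
#' @export
sim_qfish_stack <- function(width = 256, height = 256,
                            n_z = 15, z_step_um = 1.0,
                            n_nuclei = 40,
                            radius_px = c(6, 10),
                            cy3_mean_auf = 600, cy3_sd_auf = 120,
                            cardiomyocyte_fraction = 0.3,
                            background = c(dapi = 200, cy3 = 150, pcm1 = 150),
                            dapi_auf = 3000,
                            pcm1_pos_auf = 1500, pcm1_neg_auf = 300,
                            shot_noise = TRUE,
                            min_gap_px = 3,
                            seed = 1) {
  assert_that(n_z >= 1 && z_step_um > 0, "n_z and z_step_um must be positive")
  assert_that(n_nuclei >= 1, "need at least one nucleus")
  assert_that(cardiomyocyte_fraction >= 0 && cardiomyocyte_fraction <= 1,
              "cardiomyocyte_fraction must be in [0, 1]")
  set.seed(seed)

  rmin <- radius_px[1]; rmax <- radius_px[length(radius_px)]
  cx <- cy <- rad <- numeric(0)
  attempts <- 0L; max_attempts <- 400L * n_nuclei
  while (length(cx) < n_nuclei) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop_cardioage(sprintf(
        "could not place %d non-overlapping nuclei in a %dx%d image", n_nuclei,
        width, height))
    }
    r <- runif(1, rmin, rmax)
    x <- runif(1, r + 1, width - r)
    y <- runif(1, r + 1, height - r)
    if (length(cx) == 0 ||
        all(sqrt((cx - x)^2 + (cy - y)^2) >= rad + r + min_gap_px)) {
      cx <- c(cx, x); cy <- c(cy, y); rad <- c(rad, r)
    }
  }

  is_cm <- runif(n_nuclei) < cardiomyocyte_fraction
  cy3_val <- pmax(rnorm(n_nuclei, cy3_mean_auf, cy3_sd_auf), 50)

  # Contiguous in-focus z run per nucleus (full intensity inside it).
  z_c <- sample.int(n_z, n_nuclei, replace = TRUE)
  z_half <- sample(1:3, n_nuclei, replace = TRUE)
  z_lo <- pmax(1L, z_c - z_half)
  z_hi <- pmin(n_z, z_c + z_half)

  # Per-nucleus pixel index list (column-major into a height x width matrix).
  px <- vector("list", n_nuclei)
  area <- integer(n_nuclei)
  for (k in seq_len(n_nuclei)) {
    xr <- max(1L, floor(cx[k] - rad[k])):min(width, ceiling(cx[k] + rad[k]))
    yr <- max(1L, floor(cy[k] - rad[k])):min(height, ceiling(cy[k] + rad[k]))
    gg <- expand.grid(y = yr, x = xr)
    inside <- (gg$x - cx[k])^2 + (gg$y - cy[k])^2 <= rad[k]^2
    gg <- gg[inside, , drop = FALSE]
    px[[k]] <- gg$y + (gg$x - 1L) * height
    area[k] <- nrow(gg)
  }

  channels <- c("DAPI", "Cy3", "PCM1")
  stack <- array(0, dim = c(height, width, n_z, 3),
                 dimnames = list(NULL, NULL, NULL, channels))
  val_by_channel <- cbind(
    DAPI = rep(dapi_auf, n_nuclei),
    Cy3 = cy3_val,
    PCM1 = ifelse(is_cm, pcm1_pos_auf, pcm1_neg_auf)
  )
  for (ch in 1:3) {
    plane0 <- matrix(background[[ch]], height, width)
    for (z in seq_len(n_z)) {
      plane <- plane0
      for (k in which(z_lo <= z & z <= z_hi)) {
        plane[px[[k]]] <- background[[ch]] + val_by_channel[k, ch]
      }
      stack[, , z, ch] <- plane
    }
  }
  if (shot_noise) {
    stack[] <- rpois(length(stack), lambda = stack)
  }
  stack[stack > 65535] <- 65535
  attr(stack, "z_step_um") <- z_step_um

  truth <- tibble(
    nucleus = seq_len(n_nuclei), cx = cx, cy = cy, radius_px = rad,
    area_px = area, cy3_auf = cy3_val, is_cardiomyocyte = is_cm
  )
  structure(list(stack = stack, truth = truth), class = "qfish_sim")
}

#' Write / read a Q-FISH stack as multi-page TIFF
#'
#' Pages are ordered z-within-channel, channel order DAPI, Cy3, PCM1; pixel
#' values are stored as 16-bit.
#'
#' @param stack A `[height, width, n_z, 3]` array as from [sim_qfish_stack()].
#' @param path Output TIFF path.
#' @param n_z Number of z sections per channel (needed when reading).
#' @param z_step_um Section spacing recorded on the returned array.
#' @return `path` invisibly; `read_qfish_tiff()` returns the array.
#' @export
write_qfish_tiff <- function(stack, path) {
  n_z <- dim(stack)[3]
  pages <- list()
  for (ch in 1:3) {
    for (z in seq_len(n_z)) {
      pages[[length(pages) + 1]] <- stack[, , z, ch] / 65535
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_qfish_tiff
#' @export
read_qfish_tiff <- function(path, n_z, z_step_um = 1.0) {
  pages <- tiff::readTIFF(path, all = TRUE)
  assert_that(length(pages) == 3 * n_z,
              "TIFF page count does not match 3 channels x n_z sections")
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  stack <- array(0, dim = c(h, w, n_z, 3),
                 dimnames = list(NULL, NULL, NULL, c("DAPI", "Cy3", "PCM1")))
  i <- 1L
  for (ch in 1:3) {
    for (z in seq_len(n_z)) {
      stack[, , z, ch] <- round(pages[[i]] * 65535)
      i <- i + 1L
    }
  }
  attr(stack, "z_step_um") <- z_step_um
  stack
}
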