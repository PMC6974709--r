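# Q-FISH telomere-intensity quantification: projection, background
# subtraction, nuclear masking, per-nucleus measurement, cardiomyocyte
# classification, distribution comparison and shortening rate.

#' Maximum-intensity projection of one channel
#'
#' @param stack `[height, width, n_z, channel]` array (see
#'   [sim_qfish_stack()] / [read_qfish_tiff()]).
#' @param channel Channel name (`"DAPI"`, `"Cy3"`, `"PCM1"`) or index.
#' @return 2D matrix: per-pixel maximum over z.
#' @export
max_project <- function(stack, channel) {
  assert_that(length(dim(stack)) == 4 && dim(stack)[3] >= 1,
              "stack must be a [h, w, z, channel] array with >= 1 section")
  if (is.character(channel)) {
    channel <- match(channel, dimnames(stack)[[4]])
    assert_that(!is.na(channel), "unknown channel name")
  }
  out <- stack[, , 1, channel]
  for (z in seq_len(dim(stack)[3])[-1]) {
    out <- pmax(out, stack[, , z, channel])
  }
  out
}

#' Subtract image background
#'
#' Estimates the background as a low quantile of the pixel intensities
#' (default: the median, appropriate when most of the field is background)
#' and subtracts it, clipping at zero.
#'
#' @param img 2D intensity matrix.
#' @param probs Quantile used as the background estimate.
#' @return Non-negative matrix with the background level removed.
#' @export
subtract_background <- function(img, probs = 0.5) {
  bg <- quantile(img, probs, names = FALSE)
  out <- img - bg
  out[out < 0] <- 0
  out
}

#' Otsu threshold of a DAPI projection
#'
#' Maximizes between-class variance on a 256-bin histogram of the intensity
#' range; returns a logical nuclear mask. The threshold value and method are
#' recorded as attributes.
#'
#' @param img 2D intensity matrix with nonzero variance.
#' @param threshold Optional fixed threshold overriding Otsu.
#' @return Logical matrix (`TRUE` = nuclear signal) with attributes
#'   `threshold` and `method`.
#' @export
threshold_dapi <- function(img, threshold = NULL) {
  rng <- range(img)
  assert_that(diff(rng) > 0, "constant image: threshold undefined")
  if (is.null(threshold)) {
    nbins <- 256L
    breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
    counts <- tabulate(findInterval(img, breaks, all.inside = TRUE), nbins)
    p <- counts / sum(counts)
    mids <- (breaks[-1] + breaks[-(nbins + 1L)]) / 2
    w0 <- cumsum(p)
    mu <- cumsum(p * mids)
    mu_tot <- mu[nbins]
    between <- (mu_tot * w0 - mu)^2 / (w0 * (1 - w0))
    between[!is.finite(between)] <- -Inf
    k <- which.max(between)
    threshold <- breaks[k + 1L]
    method <- "otsu"
  } else {
    method <- "fixed"
  }
  mask <- img > threshold
  attr(mask, "threshold") <- threshold
  attr(mask, "method") <- method
  mask
}

#' Label connected nuclei (8-connectivity)
#'
#' Connected components of the binary mask under 8-connectivity, computed by
#' vectorized minimum-label propagation; components smaller than `min_area`
#' pixels are removed and labels are renumbered 1..K.
#'
#' @param mask Logical matrix from [threshold_dapi()].
#' @param min_area Minimum component area in pixels.
#' @return Integer label matrix (0 = background) with attribute `areas`
#'   (pixel count per label).
#' @export
label_nuclei <- function(mask, min_area = 50) {
  mask <- mask & !is.na(mask)
  h <- nrow(mask); w <- ncol(mask)

  # Column-wise run-length decomposition, then union-find over runs in
  # adjacent columns whose row ranges touch (row overlap extended by 1 on
  # each side gives 8-connectivity).
  v <- as.vector(mask)
  col_start <- rep(c(TRUE, rep(FALSE, h - 1L)), w)
  starts <- v & (col_start | !c(FALSE, v[-length(v)]))
  run_of_px <- cumsum(starts)
  n_runs <- run_of_px[length(run_of_px)]
  if (n_runs == 0 || !any(v)) {
    out <- matrix(0L, h, w)
    attr(out, "areas") <- integer(0)
    return(out)
  }
  idx <- which(v)
  run_id <- run_of_px[idx]
  run_r0 <- tapply((idx - 1L) %% h + 1L, run_id, min)
  run_r1 <- tapply((idx - 1L) %% h + 1L, run_id, max)
  run_col <- tapply((idx - 1L) %/% h + 1L, run_id, min)

  parent <- seq_len(n_runs)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  runs_by_col <- split(seq_len(n_runs), run_col)
  cols <- as.integer(names(runs_by_col))
  for (ci in seq_along(cols)[-1]) {
    if (cols[ci] - cols[ci - 1] != 1L) next
    left <- runs_by_col[[ci - 1]]; right <- runs_by_col[[ci]]
    for (a in right) {
      touching <- left[run_r0[left] <= run_r1[a] + 1L &
                         run_r1[left] >= run_r0[a] - 1L]
      for (b in touching) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  comp_of_run <- vapply(seq_len(n_runs), find, integer(1))

  px_comp <- comp_of_run[run_of_px[idx]]
  sizes <- table(px_comp)
  keep <- sort(as.integer(names(sizes)[sizes >= min_area]))
  new_id <- match(px_comp, keep, nomatch = 0L)
  out <- matrix(0L, h, w)
  out[idx] <- new_id
  attr(out, "areas") <- as.integer(table(factor(new_id[new_id > 0],
                                                levels = seq_along(keep))))
  out
}

#' Measure per-nucleus telomere intensity and classify cardiomyocytes
#'
#' The nuclear label map is applied to the background-subtracted Cy3
#' projection (read-only: pixel values are never modified); per nucleus the
#' mean Cy3 gray value (auf) and mean PCM1 value are computed.
#' `is_cardiomyocyte` is `mean PCM1 > pcm1_threshold` (Otsu over the
#' per-nucleus PCM1 means when `NULL`); a manual selection vector of nucleus
#' ids overrides the automatic call, mirroring manual cardiomyocyte
#' selection on real data.
#'
#' @param labels Label matrix from [label_nuclei()].
#' @param cy3_bgsub Background-subtracted Cy3 projection.
#' @param pcm1_projection PCM1 channel projection (same shape).
#' @param pcm1_threshold Numeric threshold on mean nuclear PCM1; `NULL` for
#'   Otsu on the per-nucleus means.
#' @param manual_cardiomyocytes Optional integer vector of nucleus ids to
#'   flag as cardiomyocytes (overrides the threshold rule).
#' @return Tibble: `nucleus`, `area_px`, `mean_cy3_auf`, `mean_pcm1`,
#'   `is_cardiomyocyte`.
#' @export
measure_nuclei <- function(labels, cy3_bgsub, pcm1_projection,
                           pcm1_threshold = NULL,
                           manual_cardiomyocytes = NULL) {
  assert_that(all(dim(labels) == dim(cy3_bgsub)) &&
                all(dim(labels) == dim(pcm1_projection)),
              "label map and intensity images must have identical shape")
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) {
    return(tibble(nucleus = integer(), area_px = integer(),
                  mean_cy3_auf = numeric(), mean_pcm1 = numeric(),
                  is_cardiomyocyte = logical()))
  }
  f <- factor(labels[labels > 0], levels = ids)
  mean_cy3 <- as.numeric(tapply(cy3_bgsub[labels > 0], f, mean))
  mean_pcm1 <- as.numeric(tapply(pcm1_projection[labels > 0], f, mean))
  area <- as.integer(table(f))
  if (!is.null(manual_cardiomyocytes)) {
    is_cm <- ids %in% manual_cardiomyocytes
  } else {
    if (is.null(pcm1_threshold)) {
      pcm1_threshold <- otsu_1d(mean_pcm1)
    }
    is_cm <- mean_pcm1 > pcm1_threshold
  }
  tibble(nucleus = as.integer(ids), area_px = area, mean_cy3_auf = mean_cy3,
         mean_pcm1 = mean_pcm1, is_cardiomyocyte = is_cm)
}

# Otsu on a small 1D sample (used for per-nucleus PCM1 means).
otsu_1d <- function(x, nbins = 64L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  counts <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins)
  p <- counts / sum(counts)
  mids <- (breaks[-1] + breaks[-(nbins + 1L)]) / 2
  w0 <- cumsum(p); mu <- cumsum(p * mids); mu_tot <- mu[nbins]
  between <- (mu_tot * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  breaks[which.max(between) + 1L]
}

#' Full Q-FISH stack quantification
#'
#' Projection, background subtraction, DAPI masking, labeling and per-nucleus
#' measurement in one call.
#'
#' @param stack `[h, w, z, channel]` array with DAPI/Cy3/PCM1 channels.
#' @param min_area Minimum nuclear area (px).
#' @param background_probs Quantile for Cy3 background estimation.
#' @param pcm1_threshold,manual_cardiomyocytes See [measure_nuclei()].
#' @return Tibble of per-nucleus measurements (see [measure_nuclei()]).
#' @export
qfish_quantify <- function(stack, min_area = 50, background_probs = 0.5,
                           pcm1_threshold = NULL,
                           manual_cardiomyocytes = NULL) {
  dapi <- max_project(stack, "DAPI")
  cy3 <- subtract_background(max_project(stack, "Cy3"), background_probs)
  pcm1 <- max_project(stack, "PCM1")
  mask <- threshold_dapi(dapi)
  labels <- label_nuclei(mask, min_area)
  measure_nuclei(labels, cy3, pcm1, pcm1_threshold, manual_cardiomyocytes)
}

#' Compare two telomere-intensity distributions (rank-sum test)
#'
#' Wilcoxon rank-sum comparison of per-nucleus mean intensities, exact by
#' full enumeration for small samples (delegates to [wilcoxon_exact()]).
#'
#' @param a,b Numeric vectors of per-nucleus mean intensities (auf).
#' @param alternative Test sidedness.
#' @return A `rank_test` object (see [wilcoxon_exact()]).
#' @export
compare_telomere_distributions <- function(a, b,
                                           alternative = "two.sided") {
  assert_that(length(a) > 0 && length(b) > 0,
              "both distributions must be non-empty")
  wilcoxon_exact(a, b, alternative = alternative)
}

#' Telomere shortening rate between age groups
#'
#' `(mean_young - mean_old) / delta_age_months`, in auf per month.
#'
#' @param young,old Per-nucleus mean intensities (auf) for the two ages.
#' @param delta_age_months Age difference in months (> 0).
#' @return One-row tibble: `mean_young_auf`, `mean_old_auf`,
#'   `delta_age_months`, `rate_auf_per_month`.
#' @export
shortening_rate <- function(young, old, delta_age_months) {
  assert_that(delta_age_months > 0, "delta_age_months must be positive")
  my <- mean(young); mo <- mean(old)
  tibble(mean_young_auf = my, mean_old_auf = mo,
         delta_age_months = delta_age_months,
         rate_auf_per_month = (my - mo) / delta_age_months)
}
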