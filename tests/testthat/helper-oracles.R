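# Independent oracles used across tests. These deliberately re-derive the
# quantities from first principles (brute force / closed form) and never call
# the package's implementation paths.

# Product-limit estimator by direct product over event times.
oracle_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- as.logical(event[ord])
  ut <- sort(unique(time[event]))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = ut, surv = surv)
}

# Two-group logrank by direct O - E / V summation with hypergeometric
# variance at each distinct event time.
oracle_logrank <- function(time1, event1, time2, event2) {
  time <- c(time1, time2); event <- as.logical(c(event1, event2))
  grp <- rep(1:2, c(length(time1), length(time2)))
  ut <- sort(unique(time[event]))
  O <- E <- V <- 0
  for (t in ut) {
    n1 <- sum(time >= t & grp == 1); n2 <- sum(time >= t & grp == 2)
    n <- n1 + n2
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & grp == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# Upper-tail hypergeometric probability by explicit binomial-coefficient sum:
# P(X >= k) for k successes among n draws from K whites in a population N.
oracle_hyper_tail <- function(k, K, N, n) {
  j <- max(0, k):min(K, n)
  if (k <= max(0, n - (N - K))) return(1)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Brute-force UPGMA (average linkage): cluster distance is the mean of all
# pairwise point distances; returns sorted merge heights.
oracle_upgma_heights <- function(x) {
  clusters <- as.list(seq_len(nrow(x)))
  d <- as.matrix(stats::dist(x))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d) { best_d <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# Energy-weighted centroid (first moment of x^2) of a pulse, in samples;
# squaring keeps far-field filter tails from dominating the moment.
centroid <- function(x) sum(seq_along(x) * x^2) / sum(x^2)

# Match detected R times to true R times within a tolerance; returns index of
# the matched detection per truth beat (NA when missed).
match_r <- function(detected, truth_ms, tol_ms = 10) {
  vapply(truth_ms, function(r) {
    d <- abs(detected - r)
    if (min(d) < tol_ms) which.min(d) else NA_integer_
  }, integer(1))
}
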