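# Independent reference implementations used as oracles. These deliberately
# use different code paths (naive loops, fft, direct formulas) from the
# package functions they check.

# Naive O(n^3) Ward agglomeration via the Lance-Williams update on squared
# Euclidean distances; returns labels for a cut at k clusters.
ward_lw_oracle <- function(X, k) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  diag(D2) <- Inf
  members <- as.list(seq_len(n))
  sizes <- rep(1, n)
  active <- rep(TRUE, n)
  n_clusters <- n
  while (n_clusters > k) {
    idx <- which(active)
    best <- c(NA, NA); bestd <- Inf
    for (i in idx) for (j in idx) if (j > i && D2[i, j] < bestd) {
      bestd <- D2[i, j]; best <- c(i, j)
    }
    i <- best[1]; j <- best[2]
    for (l in idx) {
      if (l == i || l == j) next
      D2[i, l] <- D2[l, i] <-
        ((sizes[i] + sizes[l]) * D2[i, l] + (sizes[j] + sizes[l]) * D2[j, l] -
           sizes[l] * D2[i, j]) / (sizes[i] + sizes[j] + sizes[l])
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
    D2[j, ] <- D2[, j] <- Inf
    n_clusters <- n_clusters - 1
  }
  labels <- integer(n)
  g <- 0
  for (i in which(active)) {
    g <- g + 1
    labels[members[[i]]] <- g
  }
  labels
}

# two-group log-rank chi-square by direct hypergeometric accumulation
logrank_oracle <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d_t <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O <- O + d1
    E <- E + d_t * n1 / n_t
    if (n_t > 1)
      V <- V + d_t * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d_t) / (n_t - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# RURE by per-frame fft (vs the package's explicit phase-vector sums)
rure_oracle <- function(S) {
  a0 <- a1 <- numeric(ncol(S))
  for (t in seq_len(ncol(S))) {
    co <- stats::fft(S[, t])
    a0[t] <- Mod(co[1])
    a1[t] <- Mod(co[2])
  }
  keep <- (a0 + a1) > 0
  sum(a0[keep]) / sum(a0[keep] + a1[keep])
}

# brute-force circular cross-correlation lag (explicit shift loop)
xcorr_lag_oracle <- function(a, b) {
  n <- length(a)
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(NA_real_)
  lags <- -floor(n / 2):floor(n / 2)
  best <- NA; bestc <- -Inf
  for (l in lags[order(abs(lags), -sign(lags))]) {
    bs <- b[((seq_len(n) - 1 + l) %% n) + 1]
    cc <- sum(a * bs) / den
    if (cc > bestc) { bestc <- cc; best <- l }
  }
  best
}

# mean of a Gaussian clipped to [lo, hi] (closed form)
clipped_normal_mean <- function(mu, sigma, lo = -Inf, hi = Inf) {
  if (sigma == 0) return(min(max(mu, lo), hi))
  zl <- (lo - mu) / sigma
  zh <- (hi - mu) / sigma
  # E[clip(X)] = lo*P(X<lo) + hi*P(X>hi) + E[X; lo<X<hi]
  p_lo <- stats::pnorm(zl)
  p_hi <- 1 - stats::pnorm(zh)
  mid <- mu * (stats::pnorm(zh) - stats::pnorm(zl)) -
    sigma * (stats::dnorm(zh) - stats::dnorm(zl))
  ifelse(is.finite(lo), lo, 0) * p_lo + ifelse(is.finite(hi), hi, 0) * p_hi + mid
}

# partition agreement ignoring label names
same_partition <- function(a, b) {
  mclust::adjustedRandIndex(a, b) == 1
}
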