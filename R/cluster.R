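# Phenotype discovery: z-scoring, Ward agglomerative clustering, majority
# vote over a suite of cluster-validity indices, and cluster
# characterization statistics.

#' Z-score a feature matrix
#'
#' Standardizes every feature to mean 0 and (population, divisor n) standard
#' deviation 1 so each metric carries equal weight in clustering. Rows with
#' any missing feature value are dropped (with a message); a constant
#' feature is an error naming the feature.
#'
#' @param x data frame or matrix of features (numeric columns only).
#' @return list of class `lv_standardized`: `z` (matrix), `center`, `scale`,
#'   `kept` (logical row filter applied to the input).
#' @export
standardize_features <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) .stopf("feature matrix must be numeric")
  kept <- stats::complete.cases(x)
  if (!all(kept))
    message(sum(!kept), " rows with missing feature values dropped")
  x <- x[kept, , drop = FALSE]
  center <- colMeans(x)
  scale <- apply(x, 2, .sd_pop)
  if (any(scale == 0))
    .stopf("constant feature(s): %s",
           paste(colnames(x)[scale == 0], collapse = ", "))
  z <- sweep(sweep(x, 2, center), 2, scale, "/")
  structure(list(z = z, center = center, scale = scale, kept = kept),
            class = "lv_standardized")
}

#' Ward hierarchical clustering
#'
#' Agglomerative clustering with Ward's minimum-variance criterion on
#' Euclidean distances (the `ward.D2` form of the Lance-Williams update, in
#' which merge heights are Euclidean and monotone non-decreasing).
#'
#' @param z numeric matrix (e.g. `standardize_features(x)$z`).
#' @param k number of clusters (`2 <= k <= n - 1`).
#' @return list of class `ward_result`: integer `labels` (1..k, in order of
#'   first appearance in the tree cut), the `hclust` tree, and `k`.
#' @export
ward_cluster <- function(z, k) {
  z <- as.matrix(z)
  n <- nrow(z)
  if (n < 3L) .stopf("clustering needs at least 3 observations (got %d)", n)
  if (k < 2L || k > n - 1L) .stopf("k = %d outside [2, n-1 = %d]", k, n - 1L)
  tree <- stats::hclust(stats::dist(z), method = "ward.D2")
  labels <- stats::cutree(tree, k = k)
  structure(list(labels = as.integer(labels), tree = tree, k = as.integer(k)),
            class = "ward_result")
}

# ---- cluster-validity indices -------------------------------------------
# Each index is computed on the Ward labels for a given k. Votes follow the
# index's own optimality rule:
#   maximize:  calinski_harabasz, silhouette, dunn, krzanowski_lai,
#              point_biserial, ratkowsky_lance
#   minimize:  davies_bouldin, c_index, mcclain_rao
#   elbow:     ball_hall (largest successive drop), hartigan (smallest k
#              with H(k) <= 10, else largest successive drop)
#   gap:       Tibshirani's gap statistic with the first-SE rule

.within_ss <- function(z, labels) {
  sum(vapply(split(seq_len(nrow(z)), labels), function(ix) {
    zz <- z[ix, , drop = FALSE]
    sum(sweep(zz, 2, colMeans(zz))^2)
  }, numeric(1)))
}

.cluster_stats <- function(z, labels) {
  n <- nrow(z)
  tot <- sum(sweep(z, 2, colMeans(z))^2)
  w <- .within_ss(z, labels)
  list(n = n, k = length(unique(labels)), wss = w, bss = tot - w, tss = tot)
}

.idx_calinski_harabasz <- function(z, labels, d) {
  s <- .cluster_stats(z, labels)
  (s$bss / (s$k - 1)) / (s$wss / (s$n - s$k))
}

.idx_silhouette <- function(z, labels, d)
  mean(cluster::silhouette(labels, d)[, "sil_width"])

.idx_davies_bouldin <- function(z, labels, d) {
  ks <- sort(unique(labels))
  cent <- t(vapply(ks, function(g) colMeans(z[labels == g, , drop = FALSE]),
                   numeric(ncol(z))))
  s <- vapply(seq_along(ks), function(i) {
    zz <- z[labels == ks[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(zz, 2, cent[i, ])^2)))
  }, numeric(1))
  M <- as.matrix(stats::dist(cent))
  mean(vapply(seq_along(ks), function(i) {
    max(((s[i] + s[-i]) / M[i, -i]))
  }, numeric(1)))
}

.idx_dunn <- function(z, labels, d) {
  dm <- as.matrix(d)
  ks <- sort(unique(labels))
  sep <- Inf; diam <- 0
  for (i in seq_along(ks)) {
    ii <- labels == ks[i]
    diam <- max(diam, max(dm[ii, ii]))
    for (j in seq_along(ks)) if (j > i)
      sep <- min(sep, min(dm[ii, labels == ks[j]]))
  }
  sep / diam
}

.idx_c_index <- function(z, labels, d) {
  dv <- as.vector(d)
  same <- as.vector(stats::dist(matrix(as.numeric(labels)))) == 0
  nw <- sum(same)
  s <- sum(dv[same])
  sorted <- sort(dv)
  smin <- sum(sorted[seq_len(nw)])
  smax <- sum(sorted[seq(length(sorted) - nw + 1, length(sorted))])
  (s - smin) / (smax - smin)
}

.idx_point_biserial <- function(z, labels, d) {
  dv <- as.vector(d)
  between <- as.vector(stats::dist(matrix(as.numeric(labels)))) != 0
  stats::cor(dv, as.numeric(between))  # between-pairs should be the far ones
}

.idx_mcclain_rao <- function(z, labels, d) {
  dv <- as.vector(d)
  same <- as.vector(stats::dist(matrix(as.numeric(labels)))) == 0
  mean(dv[same]) / mean(dv[!same])
}

.idx_ratkowsky_lance <- function(z, labels, d) {
  k <- length(unique(labels))
  bg <- vapply(seq_len(ncol(z)), function(j) {
    m <- tapply(z[, j], labels, mean)
    n <- tabulate(labels)[sort(unique(labels))]
    sum(n * (m - mean(z[, j]))^2) / sum((z[, j] - mean(z[, j]))^2)
  }, numeric(1))
  mean(sqrt(bg)) / sqrt(k)
}

# W(k) over a k range (Ward labels), shared by the elbow-style indices
.wss_over_range <- function(z, tree, kr) {
  vapply(kr, function(k) {
    if (k <= 1) .within_ss(z, rep(1L, nrow(z)))
    else .within_ss(z, stats::cutree(tree, k = k))
  }, numeric(1))
}

#' Majority-vote selection of the number of clusters
#'
#' For each `k` in `k_range`, Ward labels are computed and a suite of
#' cluster-validity indices is evaluated; each index votes for its optimal
#' `k` by its own rule (documented in the source: maximize, minimize, elbow,
#' or the gap first-SE rule). The chosen `k` is the modal vote, with ties
#' broken to the smallest `k`.
#'
#' @param z numeric matrix of standardized features.
#' @param k_range candidate cluster counts (default `2:8`).
#' @param indices character vector naming the index suite; default all 12.
#' @param gap_B number of uniform reference datasets for the gap statistic.
#' @param seed seed for the gap statistic's reference draws.
#' @return list of class `k_selection`: `chosen_k`, `votes` (named integer
#'   per index), `values` (index x k matrix), `tally`.
#' @export
select_k <- function(z, k_range = 2:8,
                     indices = c("calinski_harabasz", "silhouette",
                                 "davies_bouldin", "dunn", "c_index",
                                 "gap", "hartigan", "krzanowski_lai",
                                 "ball_hall", "point_biserial",
                                 "mcclain_rao", "ratkowsky_lance"),
                     gap_B = 25L, seed = 42L) {
  z <- as.matrix(z)
  n <- nrow(z)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(indices) == 0L) .stopf("empty index suite")
  if (min(k_range) < 2L || max(k_range) > n - 1L)
    .stopf("k_range must lie within [2, n-1]")
  d <- stats::dist(z)
  tree <- stats::hclust(d, method = "ward.D2")
  labs <- lapply(k_range, function(k) stats::cutree(tree, k = k))
  names(labs) <- k_range

  point_idx <- list(
    calinski_harabasz = list(f = .idx_calinski_harabasz, rule = "max"),
    silhouette = list(f = .idx_silhouette, rule = "max"),
    davies_bouldin = list(f = .idx_davies_bouldin, rule = "min"),
    dunn = list(f = .idx_dunn, rule = "max"),
    c_index = list(f = .idx_c_index, rule = "min"),
    point_biserial = list(f = .idx_point_biserial, rule = "max"),
    mcclain_rao = list(f = .idx_mcclain_rao, rule = "min"),
    ratkowsky_lance = list(f = .idx_ratkowsky_lance, rule = "max")
  )

  values <- matrix(NA_real_, length(indices), length(k_range),
                   dimnames = list(indices, k_range))
  votes <- stats::setNames(integer(length(indices)), indices)

  # W(k) on an extended range for elbow/difference indices
  kr_ext <- (min(k_range) - 1):(max(k_range) + 1)
  kr_ext <- kr_ext[kr_ext >= 1 & kr_ext <= n - 1]
  wss <- .wss_over_range(z, tree, kr_ext)
  names(wss) <- kr_ext
  wk <- function(k) unname(wss[as.character(k)])

  for (ix in indices) {
    if (ix %in% names(point_idx)) {
      v <- vapply(seq_along(k_range), function(i)
        point_idx[[ix]]$f(z, labs[[i]], d), numeric(1))
      values[ix, ] <- v
      votes[ix] <- k_range[if (point_idx[[ix]]$rule == "max")
        which.max(v) else which.min(v)]
    } else if (ix == "hartigan") {
      h <- vapply(k_range, function(k) {
        if (is.na(wk(k + 1))) return(NA_real_)
        (wk(k) / wk(k + 1) - 1) * (n - k - 1)
      }, numeric(1))
      values[ix, ] <- h
      ok <- which(!is.na(h) & h <= 10)
      votes[ix] <- if (length(ok)) k_range[min(ok)] else {
        drops <- -diff(h)
        k_range[which.max(c(drops, -Inf))]
      }
    } else if (ix == "krzanowski_lai") {
      p <- ncol(z)
      diffk <- function(k) {
        if (k < 2 || is.na(wk(k - 1))) return(NA_real_)
        (k - 1)^(2 / p) * wk(k - 1) - k^(2 / p) * wk(k)
      }
      kl <- vapply(k_range, function(k) {
        d1 <- diffk(k); d2 <- diffk(k + 1)
        if (is.na(d1) || is.na(d2) || d2 == 0) return(NA_real_)
        abs(d1 / d2)
      }, numeric(1))
      values[ix, ] <- kl
      votes[ix] <- k_range[which.max(replace(kl, is.na(kl), -Inf))]
    } else if (ix == "ball_hall") {
      bh <- vapply(k_range, function(k) wk(k) / k, numeric(1))
      values[ix, ] <- bh
      bh_prev <- vapply(k_range - 1, function(k)
        if (k >= 1) wk(k) / max(k, 1) else NA_real_, numeric(1))
      drop <- bh_prev - bh
      votes[ix] <- k_range[which.max(replace(drop, is.na(drop), -Inf))]
    } else if (ix == "gap") {
      gap <- .gap_statistic(z, tree, k_range, B = gap_B, seed = seed)
      values[ix, ] <- gap$gap
      votes[ix] <- gap$k
    } else {
      .stopf("unknown validity index '%s'", ix)
    }
  }

  tally <- table(factor(votes, levels = k_range))
  chosen <- as.integer(names(tally)[which.max(tally)])  # ties -> smallest k
  structure(list(chosen_k = chosen, votes = votes, values = values,
                 tally = tally, k_range = k_range),
            class = "k_selection")
}

# Tibshirani gap statistic on Ward labels; uniform reference over the
# per-column ranges; vote = smallest k with Gap(k) >= Gap(k+1) - s(k+1),
# falling back to the global maximum.
.gap_statistic <- function(z, tree, k_range, B = 25L, seed = 42L) {
  n <- nrow(z)
  lw <- log(.wss_over_range(z, tree, k_range))
  rng <- apply(z, 2, range)
  ref <- .with_seed(seed, {
    vapply(seq_len(B), function(b) {
      zb <- sapply(seq_len(ncol(z)), function(j)
        stats::runif(n, rng[1, j], rng[2, j]))
      tb <- stats::hclust(stats::dist(zb), method = "ward.D2")
      log(.wss_over_range(zb, tb, k_range))
    }, numeric(length(k_range)))
  })
  ref <- matrix(ref, nrow = length(k_range))
  gap <- rowMeans(ref) - lw
  sk <- apply(ref, 1, stats::sd) * sqrt(1 + 1 / B)
  k <- NA_integer_
  for (i in seq_len(length(k_range) - 1)) {
    if (gap[i] >= gap[i + 1] - sk[i + 1]) { k <- k_range[i]; break }
  }
  if (is.na(k)) k <- k_range[which.max(gap)]
  list(gap = gap, sk = sk, k = k)
}

#' @export
print.k_selection <- function(x, ...) {
  cat("majority-vote cluster count:", x$chosen_k, "\n")
  print(x$votes)
  invisible(x)
}

#' Per-cluster summaries and comparison statistics
#'
#' For every numeric variable: per-cluster mean and SD, plus a one-way
#' equal-variance ANOVA p-value across clusters and pairwise equal-variance
#' two-sided t-tests. For every categorical (factor/logical/binary integer)
#' variable: per-cluster counts and a Pearson chi-square p-value.
#' Significance is flagged at a fixed `alpha` (default 0.01, a Bonferroni-
#' style threshold).
#'
#' @param table data frame of features/covariates.
#' @param labels integer cluster labels aligned with `table` rows.
#' @param vars columns to summarize (default: all except `patient_id` and
#'   `true_label`).
#' @param alpha significance threshold.
#' @return list of class `cluster_characterization`: `summary` data frame
#'   (variable, per-cluster `mean_g`/`sd_g`, `p_value`, `test`,
#'   `significant`) and `pairwise` (named list of pairwise t-test p-value
#'   matrices for continuous variables).
#' @export
characterize_clusters <- function(table, labels, vars = NULL, alpha = 0.01) {
  if (nrow(table) != length(labels)) .stopf("labels do not align with table")
  if (is.null(vars))
    vars <- setdiff(names(table), c("patient_id", "true_label"))
  ks <- sort(unique(labels))
  out <- list(); pairwise <- list()
  for (v in vars) {
    x <- table[[v]]
    categorical <- is.factor(x) || is.logical(x) ||
      (length(unique(x[!is.na(x)])) <= 2 && all(x %in% c(0, 1, NA)))
    row <- list(variable = v)
    if (!categorical) {
      for (g in ks) {
        row[[paste0("mean_", g)]] <- mean(x[labels == g], na.rm = TRUE)
        row[[paste0("sd_", g)]] <- stats::sd(x[labels == g], na.rm = TRUE)
      }
      p <- tryCatch(
        summary(stats::aov(x ~ factor(labels)))[[1]][["Pr(>F)"]][1],
        error = function(e) NA_real_)
      row$p_value <- p
      row$test <- "anova"
      pm <- matrix(NA_real_, length(ks), length(ks),
                   dimnames = list(ks, ks))
      for (i in seq_along(ks)) for (j in seq_along(ks)) if (j > i) {
        pm[i, j] <- pm[j, i] <- tryCatch(
          stats::t.test(x[labels == ks[i]], x[labels == ks[j]],
                        var.equal = TRUE)$p.value,
          error = function(e) NA_real_)
      }
      pairwise[[v]] <- pm
    } else {
      xf <- factor(x)
      for (g in ks) {
        row[[paste0("mean_", g)]] <- mean(as.numeric(as.character(xf[labels == g])
                                                     %in% c("1", "TRUE")))
        row[[paste0("sd_", g)]] <- NA_real_
      }
      row$p_value <- tryCatch(
        suppressWarnings(stats::chisq.test(table(xf, labels))$p.value),
        error = function(e) NA_real_)
      row$test <- "chi_square"
    }
    row$significant <- !is.na(row$p_value) && row$p_value < alpha
    out[[v]] <- as.data.frame(row)
  }
  structure(list(summary = do.call(rbind, out), pairwise = pairwise,
                 alpha = alpha),
            class = "cluster_characterization")
}

#' Pearson correlations for named variable pairs
#'
#' @param table data frame.
#' @param pairs two-column matrix or data frame of variable names.
#' @return data frame: `var1`, `var2`, `r`, `p_value` (two-sided, via the t
#'   transform of `stats::cor.test`).
#' @export
correlate_features <- function(table, pairs) {
  pairs <- as.matrix(pairs)
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    ct <- stats::cor.test(table[[pairs[i, 1]]], table[[pairs[i, 2]]],
                          method = "pearson")
    data.frame(var1 = pairs[i, 1], var2 = pairs[i, 2],
               r = unname(ct$estimate), p_value = ct$p.value)
  })
  do.call(rbind, out)
}
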