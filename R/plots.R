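# Report figures: AHA bulls-eye polar maps, dendrogram-heatmap of the
# standardized feature matrix, Kaplan-Meier curves, and a hazard-ratio
# forest plot. All figures are deterministic base-graphics drawings.

#' 16-segment AHA bulls-eye plot
#'
#' Draws the standard three-ring polar map: 6 basal segments on the outer
#' ring, 6 mid segments in the middle, 4 apical segments innermost, with the
#' anterior wall at the top and the septum at image left. Each cell is
#' colored by its value and annotated; missing segments are hatched.
#'
#' @param values named numeric vector of length 16; names must be the
#'   `peakRS_<slice>_<segment>`-style feature names (any common prefix is
#'   allowed, e.g. `TTP_mid_anterior`), or a data frame with columns
#'   `slice`, `segment`, `value`.
#' @param title plot title.
#' @param palette function(n) returning n colors (default blue-white-red).
#' @param digits annotation digits.
#' @param zlim value range mapped onto the palette (default data range).
#' @return invisibly, the data frame of cell values drawn.
#' @export
plot_bullseye <- function(values, title = "", palette = NULL, digits = 0,
                          zlim = NULL) {
  df <- if (is.data.frame(values)) values else {
    parts <- regmatches(names(values),
                        regexec("_(apical|mid|basal)_([a-z]+)$", names(values)))
    if (any(lengths(parts) != 3))
      .stopf("cannot parse slice/segment from names: %s",
             paste(names(values)[lengths(parts) != 3], collapse = ", "))
    data.frame(slice = vapply(parts, `[`, "", 2),
               segment = vapply(parts, `[`, "", 3),
               value = as.numeric(values))
  }
  if (is.null(palette))
    palette <- function(n) grDevices::hcl.colors(n, "Blue-Red 2")
  cols <- palette(101)
  rng <- if (is.null(zlim)) range(df$value, na.rm = TRUE) else zlim
  if (diff(rng) == 0) rng <- rng + c(-1, 1)

  rings <- list(basal = c(2, 3), mid = c(1, 2), apical = c(0.35, 1))
  op <- graphics::par(mar = c(1, 1, 3, 1), pty = "s")
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(-3.2, 3.2), ylim = c(-3.2, 3.2), axes = FALSE,
                 xlab = "", ylab = "", main = title, asp = 1)
  ref <- pi / 2
  for (lv in names(rings)) {
    segs <- aha_segments(lv)
    m <- length(segs)
    width <- 2 * pi / m
    for (s in seq_len(m)) {
      a0 <- ref + (s - 1) * width
      a1 <- ref + s * width
      th <- seq(a0, a1, length.out = 30)
      r0 <- rings[[lv]][1]; r1 <- rings[[lv]][2]
      xx <- c(r0 * cos(th), rev(r1 * cos(th)))
      yy <- c(r0 * sin(th), rev(r1 * sin(th)))
      v <- df$value[df$slice == lv & df$segment == segs[s]]
      if (length(v) == 1 && is.finite(v)) {
        ci <- 1 + round(100 * (min(max(v, rng[1]), rng[2]) - rng[1]) / diff(rng))
        graphics::polygon(xx, yy, col = cols[ci], border = "grey30")
        rm_ <- (r0 + r1) / 2; am <- (a0 + a1) / 2
        graphics::text(rm_ * cos(am), rm_ * sin(am),
                       formatC(v, digits = digits, format = "f"), cex = 0.7)
      } else {
        graphics::polygon(xx, yy, col = "grey85", border = "grey30",
                          density = 12, angle = 45)
      }
    }
  }
  invisible(df)
}

#' Dendrogram-plus-heatmap of the standardized feature matrix
#'
#' Patients (columns) are ordered by the Ward tree; features (rows) keep the
#' canonical order. Values are shown blue (below the cohort mean) to red
#' (above); a color strip under the dendrogram marks the cluster labels.
#'
#' @param z standardized feature matrix (patients x features).
#' @param tree an `hclust` object over the rows of `z`.
#' @param labels integer cluster labels aligned with rows of `z`.
#' @return invisibly, the column order used.
#' @export
plot_cluster_heatmap <- function(z, tree, labels) {
  ord <- tree$order
  zc <- t(z[ord, , drop = FALSE])      # features x patients
  zc[zc > 3] <- 3; zc[zc < -3] <- -3
  lay <- graphics::layout(matrix(1:3, 3), heights = c(2, 0.3, 5))
  op <- graphics::par(mar = c(0, 8, 1, 1))
  on.exit({graphics::par(op); graphics::layout(1)})
  graphics::plot(stats::as.dendrogram(tree), leaflab = "none",
                 axes = FALSE, xaxs = "i")
  graphics::par(mar = c(0, 8, 0, 1))
  pal <- grDevices::hcl.colors(max(labels), "Dark 3")
  graphics::image(matrix(labels[ord], ncol = 1), col = pal, axes = FALSE)
  graphics::par(mar = c(2, 8, 0, 1))
  graphics::image(seq_len(ncol(zc)), seq_len(nrow(zc)), t(zc[rev(seq_len(nrow(zc))), ]),
                  col = grDevices::hcl.colors(101, "Blue-Red 2"),
                  zlim = c(-3, 3), axes = FALSE, xlab = "", ylab = "")
  graphics::axis(2, at = seq_len(nrow(zc)), labels = rev(rownames(zc)),
                 las = 2, cex.axis = 0.5, tick = FALSE)
  invisible(ord)
}

#' Kaplan-Meier survival curves per group
#'
#' @param km a [km_estimate()] result.
#' @param xlab,ylab,main plot labels.
#' @return invisibly, `NULL`.
#' @export
plot_km <- function(km, xlab = "Months since examination",
                    ylab = "PVR-free survival", main = "") {
  groups <- unique(km$group)
  pal <- grDevices::hcl.colors(max(2L, length(groups)), "Dark 3")
  graphics::plot(NA, xlim = c(0, max(km$time)), ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, main = main)
  for (i in seq_along(groups)) {
    b <- km[km$group == groups[i], ]
    graphics::lines(stats::stepfun(b$time, c(1, b$surv)), col = pal[i],
                    do.points = FALSE, lwd = 2)
    cens <- b[b$n_censor > 0, ]
    if (nrow(cens))
      graphics::points(cens$time, cens$surv, pch = 3, col = pal[i], cex = 0.6)
  }
  graphics::legend("bottomleft", legend = groups, col = pal[seq_along(groups)],
                   lwd = 2, bty = "n")
  invisible(NULL)
}

#' Forest plot of Cox hazard ratios
#'
#' @param fit a [cox_fit()].
#' @param main plot title.
#' @return invisibly, the plotted [forest_table()].
#' @export
plot_forest <- function(fit, main = "Cox proportional hazards") {
  tab <- forest_table(fit)
  n <- nrow(tab)
  op <- graphics::par(mar = c(4, 10, 3, 2))
  on.exit(graphics::par(op))
  xlim <- range(c(tab$ci_low, tab$ci_high, 1))
  graphics::plot(NA, xlim = xlim, ylim = c(0.5, n + 0.5), log = "x",
                 yaxt = "n", xlab = "Hazard ratio (95% CI)", ylab = "",
                 main = main)
  graphics::abline(v = 1, lty = 2, col = "grey50")
  ys <- rev(seq_len(n))
  graphics::segments(tab$ci_low, ys, tab$ci_high, ys)
  graphics::points(tab$hr, ys, pch = 15)
  graphics::axis(2, at = ys, labels = tab$covariate, las = 2, cex.axis = 0.8)
  invisible(tab)
}
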