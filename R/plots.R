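# Simple static figures: bean-style entropy distributions, PC scatter with
# group hulls, and Kaplan-Meier curves.

#' Bean-style plot of entropy distributions by group
#'
#' Mirrored density polygons per group with a line at each group mean.
#'
#' @param entropy Per-sample numeric values.
#' @param groups Group factor.
#' @param main Plot title.
#' @return Invisibly, the per-group densities.
#' @export
plot_entropy_beans <- function(entropy, groups,
                               main = "DNA copy number entropy by group") {
  groups <- as.factor(groups)
  dens <- lapply(levels(groups), function(g) stats::density(entropy[groups == g]))
  names(dens) <- levels(groups)
  max_w <- max(vapply(dens, function(d) max(d$y), numeric(1)))
  k <- length(dens)
  graphics::plot(NULL, xlim = c(0.5, k + 0.5), ylim = range(entropy),
                 xaxt = "n", xlab = "", ylab = "Entropy (nats)", main = main)
  graphics::axis(1, at = seq_len(k), labels = names(dens))
  for (i in seq_len(k)) {
    d <- dens[[i]]
    w <- d$y / max_w * 0.4
    graphics::polygon(c(i - w, rev(i + w)), c(d$x, rev(d$x)),
                      col = "grey85", border = "grey40")
    mu <- mean(entropy[groups == names(dens)[i]])
    graphics::segments(i - 0.45, mu, i + 0.45, mu, lwd = 2)
  }
  invisible(dens)
}

#' @export
plot.dispersion_result <- function(x, ...) {
  labs <- x$labels
  cols <- seq_len(nlevels(labs)) + 1L
  graphics::plot(x$scores, col = cols[as.integer(labs)], pch = 17,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$variance_explained[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$variance_explained[2]),
                 ...)
  for (i in seq_len(nlevels(labs))) {
    pts <- x$scores[labs == levels(labs)[i], , drop = FALSE]
    if (nrow(unique(pts)) >= 3) {
      h <- grDevices::chull(pts)
      graphics::polygon(pts[h, ], border = cols[i],
                        col = grDevices::adjustcolor(cols[i], 0.15))
    }
  }
  graphics::legend("topright", legend = levels(labs), col = cols, pch = 17)
  invisible(x)
}

#' @export
plot.km_result <- function(x, ...) {
  graphics::plot(x$fit, col = seq_len(nrow(x$table)) + 1L,
                 xlab = "Years", ylab = "Survival probability", ...)
  graphics::legend("topright", legend = x$table$group,
                   col = seq_len(nrow(x$table)) + 1L, lty = 1)
  graphics::mtext(sprintf("log-rank p = %.3g", x$p), side = 3, line = 0.2,
                  cex = 0.8)
  invisible(x)
}
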