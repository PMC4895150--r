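# CSV serialization of placements and traces, and a base-graphics rendering
# of the spatial threshold map.

rotation_to_quaternion <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    c(w = s / 4, x = (R[3, 2] - R[2, 3]) / s,
      y = (R[1, 3] - R[3, 1]) / s, z = (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    j <- i %% 3 + 1L; k <- j %% 3 + 1L
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
    setNames(q, c("w", "x", "y", "z"))
  }
}

#' Write a placement set as CSV
#'
#' Columns: id, x, y, z (mm), layer, region, plane, side and the orientation
#' frame as a unit quaternion (qw, qx, qy, qz; columns of the frame are
#' tangent, apical, third axis).
#'
#' @param set A `sucs_placement`.
#' @param path Output file.
#' @export
write_placement_csv <- function(set, path) {
  q <- t(vapply(seq_len(nrow(set)),
                function(i) rotation_to_quaternion(placement_frame(set, i)),
                numeric(4)))
  out <- data.frame(id = set$id, x = set$x, y = set$y, z = set$z,
                    layer = set$layer, region = set$region,
                    plane = set$plane, side = set$side,
                    qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4])
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a membrane trace as CSV (time x compartment)
#'
#' @param trace A `sucs_trace`.
#' @param path Output file.
#' @export
write_trace_csv <- function(trace, path) {
  out <- data.frame(time_ms = trace$t, trace$v)
  names(out) <- c("time_ms", sprintf("comp_%03d", seq_len(ncol(trace$v))))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Plot a spatial threshold map
#'
#' Thresholds along the cortical path per layer/polarity, with the sub-20 mA
#' clinical contour marked.
#'
#' @param x A `sucs_spatial_map` from [spatial_extent_map()].
#' @param clinical_cap Contour level (mA).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sucs_spatial_map <- function(x, clinical_cap = 20, ...) {
  d <- x[!is.na(x$threshold), ]
  if (!nrow(d)) {
    graphics::plot(0, 0, type = "n", xlab = "path arc length (mm)",
                   ylab = "threshold (mA)", ...)
    return(invisible(x))
  }
  grp <- interaction(d$layer, d$polarity, drop = TRUE)
  graphics::plot(range(x$sw), range(d$threshold), type = "n",
                 xlab = "path arc length (mm)", ylab = "threshold (mA)", ...)
  for (k in seq_along(levels(grp))) {
    dd <- d[grp == levels(grp)[k], ]
    dd <- dd[order(dd$sw), ]
    graphics::lines(dd$sw, dd$threshold, col = k)
    graphics::points(dd$sw, dd$threshold, col = k, pch = 16, cex = 0.5)
  }
  graphics::abline(h = clinical_cap, lty = 2)
  graphics::legend("topleft", legend = levels(grp), col = seq_along(levels(grp)),
                   lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}
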