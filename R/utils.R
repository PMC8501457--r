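# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pf <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "phasorflim_error")))
}

assert_that <- function(ok, fmt, ..., class = "validation_error") {
  if (!isTRUE(ok)) stop_pf(fmt, ..., class = class)
  invisible(TRUE)
}

rel_diff <- function(a, b) abs(a - b) / max(abs(a), abs(b), .Machine$double.eps)

#' @noRd
#' Even-odd (ray casting) point-in-polygon test with boundary inclusion.
#' Points exactly on a polygon edge or vertex count as inside; this keeps
#' rasterized ROIs deterministic regardless of vertex orientation.
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # boundary: point on segment (x1,y1)-(x2,y2)
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    within <- px >= pmin(x1, x2) - 1e-12 & px <= pmax(x1, x2) + 1e-12 &
      py >= pmin(y1, y2) - 1e-12 & py <= pmax(y1, y2) + 1e-12
    on_edge <- on_edge | (abs(cross) < 1e-9 & within)
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' @noRd
#' TRUE if any two non-adjacent edges of the polygon intersect.
polygon_self_intersects <- function(vx, vy) {
  n <- length(vx)
  seg <- cbind(vx, vy, c(vx[-1], vx[1]), c(vy[-1], vy[1]))
  ccw <- function(ax, ay, bx, by, cx, cy) (cx - ax) * (by - ay) - (bx - ax) * (cy - ay)
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- ccw(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- ccw(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- ccw(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- ccw(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' @noRd
#' Otsu threshold on a non-negative integer-valued intensity image:
#' maximizes between-class variance over candidate cuts.  Returns a value
#' such that pixels with intensity < threshold are background.
otsu_threshold <- function(x) {
  v <- sort(unique(as.vector(x)))
  if (length(v) < 2) return(v[1] %||% 0)
  best <- -Inf; thr <- v[2]
  n <- length(x)
  for (cut in v[-1]) {
    bg <- x < cut
    n0 <- sum(bg)
    if (n0 == 0L || n0 == n) next
    m0 <- mean(x[bg]); m1 <- mean(x[!bg])
    bc <- (n0 / n) * (1 - n0 / n) * (m1 - m0)^2
    if (bc > best) { best <- bc; thr <- cut }
  }
  thr
}

sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  sd(x) / sqrt(length(x))
}
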