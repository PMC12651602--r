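# Internal geometry and numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# Pixel coordinates (1-based, column `x` = first matrix index) covered by a
# disk of radius r centred at (cx, cy), clipped to a canvas of dimension dim.
#' @noRd
disk_pixels <- function(cx, cy, r, dim) {
  x0 <- max(1L, floor(cx - r)); x1 <- min(dim[1L], ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(dim[2L], ceiling(cy + r))
  if (x0 > x1 || y0 > y1) {
    return(cbind(x = integer(0), y = integer(0)))
  }
  g <- expand.grid(x = x0:x1, y = y0:y1)
  keep <- (g$x - cx)^2 + (g$y - cy)^2 <= r^2
  cbind(x = g$x[keep], y = g$y[keep])
}

# Annulus r_in < d <= r_out.
#' @noRd
annulus_pixels <- function(cx, cy, r_in, r_out, dim) {
  px <- disk_pixels(cx, cy, r_out, dim)
  if (nrow(px) == 0L) return(px)
  d2 <- (px[, "x"] - cx)^2 + (px[, "y"] - cy)^2
  px[d2 > r_in^2, , drop = FALSE]
}

# Absolute angular difference in [0, pi].
#' @noRd
angle_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

#' @noRd
mask_from_disk <- function(cx, cy, r, dim) {
  m <- matrix(0L, dim[1L], dim[2L])
  px <- disk_pixels(cx, cy, r, dim)
  if (nrow(px)) m[px] <- 1L
  m
}

# Greedy nearest-neighbour matching of two point sets under a distance cap.
# Returns a data.frame with one row per accepted match, ordered assignment:
# candidate pairs sorted by (distance, id_a, id_b); each side used once.
#' @noRd
greedy_match <- function(xy_a, xy_b, id_a, id_b, max_dist) {
  if (length(id_a) == 0L || length(id_b) == 0L) {
    return(data.frame(id_a = id_a[0], id_b = id_b[0], dist = numeric(0)))
  }
  dmat <- sqrt(outer(xy_a[, 1L], xy_b[, 1L], "-")^2 +
               outer(xy_a[, 2L], xy_b[, 2L], "-")^2)
  cand <- which(dmat <= max_dist, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    return(data.frame(id_a = id_a[0], id_b = id_b[0], dist = numeric(0)))
  }
  ord <- order(dmat[cand], id_a[cand[, 1L]], id_b[cand[, 2L]])
  cand <- cand[ord, , drop = FALSE]
  used_a <- logical(length(id_a)); used_b <- logical(length(id_b))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ia <- cand[i, 1L]; ib <- cand[i, 2L]
    if (!used_a[ia] && !used_b[ib]) {
      keep[i] <- TRUE
      used_a[ia] <- TRUE; used_b[ib] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(id_a = id_a[cand[, 1L]], id_b = id_b[cand[, 2L]],
             dist = dmat[cand])
}
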