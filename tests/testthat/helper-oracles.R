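# Independent brute-force oracles used across tests.

# Two-sided Mann-Whitney p by full enumeration of all group labelings.
mw_enum_p <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- apply(utils::combn(N, n1), 2L, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Two-sided Fisher p by direct hypergeometric counting with choose().
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (n == 0) return(1)
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- choose(c1, xs) * choose(n - c1, r1 - xs) / choose(n, r1)
  p0 <- choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1)
  min(1, sum(pr[pr <= p0 * (1 + 1e-7)]))
}

# Boundary pixels of a mask: object pixels with a 4-neighbour background
# (or image edge).
boundary_count <- function(mask) {
  mask <- mask > 0
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  inner <- pad[2:(nr + 1L), 2:(nc + 1L)]
  up <- pad[1:nr, 2:(nc + 1L)]; down <- pad[3:(nr + 2L), 2:(nc + 1L)]
  left <- pad[2:(nr + 1L), 1:nc]; right <- pad[2:(nr + 1L), 3:(nc + 2L)]
  sum(inner & !(up & down & left & right))
}

# Brute-force neighbor pairs: all (tumor, wbc) label combinations whose
# pixel sets overlap or come within chessboard distance 1.
brute_force_neighbors <- function(tumor_labels, wbc_labels) {
  coords <- function(labels, l) {
    idx <- which(labels == l)
    cbind((idx - 1L) %% nrow(labels) + 1L, (idx - 1L) %/% nrow(labels) + 1L)
  }
  out <- NULL
  for (t in setdiff(unique(as.vector(tumor_labels)), 0L)) {
    pt <- coords(tumor_labels, t)
    for (w in setdiff(unique(as.vector(wbc_labels)), 0L)) {
      pw <- coords(wbc_labels, w)
      dx <- abs(outer(pt[, 1L], pw[, 1L], "-"))
      dy <- abs(outer(pt[, 2L], pw[, 2L], "-"))
      cheb <- pmax(dx, dy)
      if (any(cheb <= 1L)) {
        rel <- if (any(cheb == 0L)) "overlap" else "contact"
        out <- rbind(out, data.frame(tumor_id = t, wbc_id = w,
                                     relationship = rel))
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(tumor_id = integer(0), wbc_id = integer(0),
                      relationship = character(0))
  }
  out[order(out$tumor_id, out$wbc_id), ]
}

# Background-only simulation config on a small canvas.
empty_sim_config <- function(...) {
  sim_config(width = 64, height = 64, n_wbc = 0, n_epi_ctc = 0, n_im_ctc = 0,
             n_lev = 0, n_debris = 0, n_pic = 0, n_overlap = 0,
             n_gap_pair = 0, ...)
}
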