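#' Find tumor-immune neighbor pairs from label masks
#'
#' A tumor event and a WBC are neighbors when their segmented masks overlap
#' or are adjacent (8-connectivity by default, configurable to 4). The
#' result is symmetric in input order.
#'
#' @param tumor_labels,wbc_labels integer label matrices on the same raster
#'   (they may overlap, e.g. ground-truth disks).
#' @param connectivity 8 (default) or 4.
#' @return data.frame with one row per pair: `tumor_id`, `wbc_id`,
#'   `relationship` (`"overlap"` or `"contact"`), `overlap_px` and
#'   `boundary_px` (adjacency pixel count).
#' @export
find_neighbors <- function(tumor_labels, wbc_labels, connectivity = 8) {
  tumor_labels <- imageData(tumor_labels)
  wbc_labels <- imageData(wbc_labels)
  if (!all(dim(tumor_labels) == dim(wbc_labels))) {
    stop("geometry error: label masks have different raster shapes")
  }
  offsets <- expand.grid(dx = -1:1, dy = -1:1)
  if (connectivity == 4) {
    offsets <- offsets[abs(offsets$dx) + abs(offsets$dy) <= 1, ]
  } else if (connectivity != 8) {
    stop("connectivity must be 4 or 8")
  }
  nr <- nrow(tumor_labels); nc <- ncol(tumor_labels)
  shift <- function(m, dx, dy) {
    out <- matrix(0L, nr, nc)
    xs <- max(1, 1 + dx):min(nr, nr + dx)
    ys <- max(1, 1 + dy):min(nc, nc + dy)
    out[xs, ys] <- m[xs - dx, ys - dy]
    out
  }
  pair_counts <- function(w) {
    sel <- tumor_labels > 0 & w > 0
    if (!any(sel)) {
      return(data.frame(tumor = integer(0), wbc = integer(0), n = integer(0)))
    }
    tab <- table(tumor = tumor_labels[sel], wbc = w[sel])
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    df <- df[df$Freq > 0, , drop = FALSE]
    data.frame(tumor = as.integer(df$tumor), wbc = as.integer(df$wbc),
               n = df$Freq)
  }
  overlap <- pair_counts(wbc_labels)
  near <- do.call(rbind, lapply(seq_len(nrow(offsets)), function(i) {
    pair_counts(shift(wbc_labels, offsets$dx[i], offsets$dy[i]))
  }))
  if (nrow(near) == 0L) {
    return(data.frame(tumor_id = integer(0), wbc_id = integer(0),
                      relationship = character(0), overlap_px = integer(0),
                      boundary_px = integer(0)))
  }
  key <- function(d) paste(d$tumor, d$wbc)
  agg <- stats::aggregate(n ~ tumor + wbc, data = near, FUN = max)
  pairs <- data.frame(tumor_id = agg$tumor, wbc_id = agg$wbc,
                      boundary_px = agg$n)
  ov_px <- overlap$n[match(key(agg), key(overlap))]
  pairs$overlap_px <- ifelse(is.na(ov_px), 0L, ov_px)
  pairs$relationship <- ifelse(pairs$overlap_px > 0, "overlap", "contact")
  rownames(pairs) <- NULL
  pairs[order(pairs$tumor_id, pairs$wbc_id),
        c("tumor_id", "wbc_id", "relationship", "overlap_px", "boundary_px")]
}

#' Relationship between two single-object masks
#'
#' Classifies a pair of masks as `overlap` (shared pixels), `contact`
#' (adjacent under the connectivity) or `gap`, and reports the overlap area
#' and minimum mask separation in pixels.
#'
#' @param mask_a,mask_b 0/1 mask matrices on the same raster.
#' @param connectivity 8 (default) or 4.
#' @return list with `relationship`, `overlap_px`, `separation_px`.
#' @export
pair_relationship <- function(mask_a, mask_b, connectivity = 8) {
  mask_a <- imageData(mask_a) > 0
  mask_b <- imageData(mask_b) > 0
  if (!all(dim(mask_a) == dim(mask_b))) {
    stop("geometry error: masks have different raster shapes")
  }
  overlap_px <- sum(mask_a & mask_b)
  if (overlap_px > 0) {
    return(list(relationship = "overlap", overlap_px = overlap_px,
                separation_px = 0))
  }
  kern <- if (connectivity == 8) matrix(1, 3, 3) else
    matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3)
  bdil <- imageData(EBImage::dilate(mask_b * 1, kern)) > 0
  if (any(mask_a & bdil)) {
    return(list(relationship = "contact", overlap_px = 0L, separation_px = 0))
  }
  # euclidean distance from every non-b pixel to the nearest b pixel
  dt <- imageData(EBImage::distmap(1 - mask_b))
  list(relationship = "gap", overlap_px = 0L,
       separation_px = min(dt[mask_a]))
}

#' Density-normalized neighbor abundance
#'
#' Neighbor counts scale with how densely cells were plated; they are
#' reported per million nucleated cells on the analyzed slide to control
#' for that.
#'
#' @param n_pairs number of neighbor pairs.
#' @param n_cells_on_slide nucleated cells on the analyzed slide (> 0).
#' @return Pairs per 10^6 cells.
#' @export
normalize_neighbor_count <- function(n_pairs, n_cells_on_slide) {
  if (any(n_cells_on_slide <= 0)) {
    stop("division error: n_cells_on_slide must be > 0")
  }
  n_pairs / n_cells_on_slide * 1e6
}

#' Expected chance adjacencies under random plating
#'
#' Null reference for neighbor counts: with homogeneous random placement,
#' a tumor event and a WBC are adjacent when their centres fall within
#' `r_t + r_w`, so the Poisson-approximation expectation of chance pairs is
#' `n_t * n_w * pi * (r_t + r_w)^2 / A`. This null model is part of the
#' synthetic workflow, used to show that planted interacting pairs exceed
#' chance co-location.
#'
#' @param n_tumor,n_wbc object counts.
#' @param r_tumor,r_wbc radii (any common length unit).
#' @param area slide area in the square of that unit (> 0).
#' @return Expected number of chance adjacencies.
#' @export
expected_random_overlaps <- function(n_tumor, n_wbc, r_tumor, r_wbc, area) {
  if (area <= 0) stop("validation error: area must be > 0")
  if (n_tumor < 0 || n_wbc < 0) stop("counts must be >= 0")
  n_tumor * n_wbc * pi * (r_tumor + r_wbc)^2 / area
}
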