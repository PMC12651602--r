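#' Detection configuration
#'
#' Parameters for the CTC/LEV identification rules. The defaults encode the
#' platform's filtering constants: nucleated events with DAPI more than
#' `k_dapi_low` (3) standard deviations below the mean of all nucleated
#' cells are excluded; CTC candidates must exceed the CK mean by `k_ck` (6)
#' standard deviations, computed across all segmented cells; LEVs must have
#' an equivalent diameter of at least `min_lev_diameter_um` (2.5 um), DAPI
#' below the nucleated-cell cutoff, and a visible brightfield membrane ring
#' (`tau_ring`).
#'
#' @param k_dapi_low SD multiplier for the low-DAPI exclusion (> 0).
#' @param k_ck SD multiplier for the CK threshold (> 0).
#' @param min_lev_diameter_um minimum LEV equivalent diameter in um (> 0).
#' @param tau_ring minimum brightfield ring score (interior-minus-boundary
#'   contrast in background-SD units).
#' @param smooth_sigma Gaussian smoothing sigma (px) before nuclear
#'   segmentation.
#' @param min_nucleus_area minimum nucleus area in px^2.
#' @param watershed_tolerance tolerance of the distance-transform watershed.
#' @param cd45_statistic per-event CD45 summary the positivity rule is
#'   anchored on: `"q90"` (upper quantile, ring-sensitive and
#'   size-invariant) or `"mean"`.
#' @param cd45_quantile quantile used when `cd45_statistic = "q90"`.
#' @param cd45_k SD multiplier of the CD45 rule: an event is immune-like
#'   when its CD45 statistic exceeds the WBC mean minus `cd45_k` WBC SDs
#'   (strict inequality; boundary values are epithelial).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(k_dapi_low = 3, k_ck = 6,
                             min_lev_diameter_um = 2.5, tau_ring = 2,
                             smooth_sigma = 2, min_nucleus_area = 40,
                             watershed_tolerance = 2,
                             cd45_statistic = c("q90", "mean"),
                             cd45_quantile = 0.9, cd45_k = 3) {
  cd45_statistic <- match.arg(cd45_statistic)
  if (k_dapi_low <= 0 || k_ck <= 0) stop("SD multipliers must be > 0")
  if (min_lev_diameter_um <= 0) stop("min_lev_diameter_um must be > 0")
  structure(as.list(environment()), class = "detection_config")
}

# Robust global threshold for sparse bright objects on a flat background:
# Otsu, floored at median + 5 mad so a blank image yields no foreground.
#' @noRd
robust_threshold <- function(m) {
  max(EBImage::otsu(m, range = range(0, 1)),
      stats::median(m) + 5 * stats::mad(m))
}

#' Segment nucleated cells
#'
#' Classical stand-in for a learned nuclear segmenter: Gaussian smoothing of
#' the DAPI channel, a global Otsu threshold (floored at median + 5 MAD so a
#' blank image yields nothing), hole filling, and a distance-transform
#' watershed to split touching nuclei. Components below `min_nucleus_area`
#' are dropped. Cell bodies are then recovered by Voronoi propagation of the
#' nuclear seeds over the combined fluorescence foreground, so membrane
#' rings belong to their cell's mask. The segmenter sits behind this
#' function's interface and can be swapped for a learned model.
#'
#' @param image a [slide_image()] with a `dapi` channel.
#' @param config a [detection_config()].
#' @return List with `nuclei` (nuclear label mask), `cells` (cell-body label
#'   mask, same labels) and `events` (per-event measurement table from
#'   [measure_events()], kind `"cell"`).
#' @export
segment_nucleated_cells <- function(image, config = detection_config()) {
  stopifnot(inherits(image, "slide_image"))
  if (!"dapi" %in% names(image$channels)) {
    stop("configuration error: DAPI channel missing")
  }
  dapi <- get_channel(image, "dapi") / 65535
  sm <- EBImage::gblur(dapi, sigma = config$smooth_sigma)
  bw <- EBImage::fillHull(sm > robust_threshold(sm))
  nuclei <- EBImage::watershed(EBImage::distmap(bw),
                               tolerance = config$watershed_tolerance)
  nuclei <- imageData(nuclei)
  areas <- tabulate(nuclei[nuclei > 0])
  small <- which(areas < config$min_nucleus_area)
  if (length(small)) {
    nuclei[nuclei %in% small] <- 0L
    nuclei <- relabel_sequential(nuclei)
  }
  cells <- expand_to_cells(image, nuclei, config)
  events <- measure_events(image, cells, kind = "cell")
  # the DAPI filter reasons about nuclear signal: use the nuclear-mask DAPI
  # mean, not the cell-mask mean (which scales with cytoplasm area)
  nuc_meas <- measure_events(image, nuclei, kind = "cell")
  events$mean_dapi <- nuc_meas$mean_dapi[match(events$label, nuc_meas$label)]
  list(nuclei = nuclei, cells = cells, events = events)
}

#' @noRd
imageData <- function(x) {
  if (inherits(x, "Image")) EBImage::imageData(x) else x
}

#' @noRd
relabel_sequential <- function(labels) {
  u <- sort(unique(labels[labels > 0]))
  if (!length(u)) return(labels)
  map <- integer(max(u)); map[u] <- seq_along(u)
  out <- labels
  out[out > 0] <- map[out[out > 0]]
  out
}

# Voronoi propagation of nuclear seeds over the filled fluorescence
# foreground (max of DAPI/CD45/CK), so each cell mask reaches its membrane
# ring and touching cells split along a shared boundary. The foreground is
# thresholded on the unsmoothed composite (median + 5 MAD above background)
# because smoothing would wash out 1-2 px membrane rings; fillHull closes
# the dim cytoplasm between nucleus and ring.
#' @noRd
expand_to_cells <- function(image, nuclei, config) {
  comp <- pmax(get_channel(image, "dapi"),
               if ("cd45" %in% names(image$channels)) get_channel(image, "cd45") else 0,
               if ("ck" %in% names(image$channels)) get_channel(image, "ck") else 0) / 65535
  fg <- EBImage::fillHull((comp > stats::median(comp) + 5 * stats::mad(comp)) |
                            (nuclei > 0))
  sm <- EBImage::gblur(comp, sigma = 1)
  imageData(EBImage::propagate(sm, seeds = nuclei, mask = fg))
}

#' Measure per-event channel statistics over a label mask
#'
#' @param image a [slide_image()].
#' @param labels integer label matrix (0 = background).
#' @param kind event kind recorded in the table (`"cell"` or `"lev"`).
#' @param cd45_quantile upper quantile of within-mask CD45 reported as
#'   `q_cd45`.
#' @return A data.frame with one row per label: `event_id`, `label`, `kind`,
#'   centroid (`cx`, `cy`), `area_px`, `equiv_diameter_um`
#'   (`2 sqrt(area/pi) * pixel_scale`), per-channel `mean_*` columns and
#'   `q_cd45`.
#' @export
measure_events <- function(image, labels, kind = "cell", cd45_quantile = 0.9) {
  stopifnot(inherits(image, "slide_image"))
  labels <- imageData(labels)
  idx <- which(labels > 0)
  lab <- labels[idx]
  n <- if (length(lab)) max(lab) else 0L
  if (n == 0L) {
    out <- data.frame(event_id = integer(0), label = integer(0),
                      kind = character(0), cx = numeric(0), cy = numeric(0),
                      area_px = numeric(0), equiv_diameter_um = numeric(0))
    for (nm in names(image$channels)) out[[paste0("mean_", nm)]] <- numeric(0)
    out$q_cd45 <- numeric(0)
    return(out)
  }
  area <- tabulate(lab, nbins = n)
  xs <- (idx - 1L) %% nrow(labels) + 1L
  ys <- (idx - 1L) %/% nrow(labels) + 1L
  keep <- which(area > 0)
  out <- data.frame(
    event_id = seq_along(keep), label = keep, kind = kind,
    cx = rowsum(xs, lab)[as.character(keep), 1L] / area[keep],
    cy = rowsum(ys, lab)[as.character(keep), 1L] / area[keep],
    area_px = area[keep],
    equiv_diameter_um = 2 * sqrt(area[keep] / pi) * image$pixel_scale)
  for (nm in names(image$channels)) {
    v <- image$channels[[nm]][idx]
    out[[paste0("mean_", nm)]] <-
      rowsum(v, lab)[as.character(keep), 1L] / area[keep]
  }
  for (qn in intersect(c("cd45", "dapi"), names(image$channels))) {
    v <- image$channels[[qn]][idx]
    out[[paste0("q_", qn)]] <- vapply(split(v, lab)[as.character(keep)],
                                      stats::quantile, numeric(1L),
                                      probs = cd45_quantile, names = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Mean and SD of a per-event channel statistic
#'
#' Arithmetic mean and sample standard deviation of the per-event mean
#' intensities of `channel`, across all events supplied (the population the
#' SD-based thresholds are anchored on).
#'
#' @param events event table from [measure_events()].
#' @param channel channel name (`"dapi"`, `"ck"`, ...).
#' @return `c(mean = ..., sd = ...)`.
#' @export
channel_stats <- function(events, channel) {
  col <- paste0("mean_", channel)
  if (!col %in% names(events)) stop(sprintf("no column '%s' in events", col))
  x <- events[[col]]
  if (length(x) < 2L) stop("insufficient data: need >= 2 events for channel stats")
  c(mean = mean(x), sd = stats::sd(x))
}

#' Exclude low-DAPI events
#'
#' Flags events whose mean DAPI falls more than `k` standard deviations
#' below the mean of all nucleated events (acellular structures, artifacts).
#' Exclusions are flags, not deletions: the returned table carries
#' `dapi_low_excluded` and `retained`.
#'
#' @param events event table with a `mean_dapi` column.
#' @param k SD multiplier (default 3).
#' @return The table with `dapi_low_excluded`/`retained` columns; the cutoff
#'   is attached as attribute `"dapi_cutoff"`.
#' @export
filter_dapi_low <- function(events, k = 3) {
  st <- channel_stats(events, "dapi")
  if (st[["sd"]] == 0) {
    stop("degenerate DAPI distribution (sd = 0): exclusion threshold undefined")
  }
  cutoff <- st[["mean"]] - k * st[["sd"]]
  events$dapi_low_excluded <- events$mean_dapi < cutoff
  events$retained <- !events$dapi_low_excluded
  attr(events, "dapi_cutoff") <- cutoff
  events
}

#' Detect CTC candidates by the CK threshold
#'
#' A retained nucleated event is a CTC candidate when its mean CK exceeds
#' the mean of the CK distribution of all retained cells by `k_ck` standard
#' deviations. Raising `k_ck` never adds candidates.
#'
#' @param events output of [filter_dapi_low()].
#' @param k_ck SD multiplier (default 6).
#' @return The table with an `is_ctc` column; the scalar CK threshold is
#'   attached as attribute `"ck_threshold"`.
#' @export
detect_ctc_candidates <- function(events, k_ck = 6) {
  if (is.null(events$retained)) {
    stop("apply filter_dapi_low() before CTC detection")
  }
  st <- channel_stats(events[events$retained, , drop = FALSE], "ck")
  if (st[["sd"]] == 0) {
    stop("degenerate CK distribution (sd = 0): threshold undefined")
  }
  thr <- st[["mean"]] + k_ck * st[["sd"]]
  events$is_ctc <- events$retained & events$mean_ck > thr
  attr(events, "ck_threshold") <- thr
  events
}

#' Detect LEV candidates
#'
#' Segments the CK channel at the scalar CK threshold derived from the CTC
#' analysis, then filters connected components: equivalent diameter at least
#' `min_lev_diameter_um`, DAPI below the nucleated-cell cutoff (so CK+
#' nucleated cells are excluded as cells, not LEVs), and a brightfield
#' membrane ring score of at least `tau_ring`. Every rejection reason is
#' flagged (`size_excluded`, `dapi_high_excluded`, `ring_failed`), never
#' deleted. When the brightfield channel is missing the ring check is
#' skipped with a warning and `ring_checked = FALSE`.
#'
#' @param image a [slide_image()] with a `ck` channel.
#' @param ck_threshold scalar CK pixel threshold (attribute of
#'   [detect_ctc_candidates()]).
#' @param dapi_cutoff nucleated-cell DAPI cutoff (attribute of
#'   [filter_dapi_low()]).
#' @param config a [detection_config()].
#' @return List with `labels` (CK component label mask) and `events` (table
#'   with filter flags and `retained`).
#' @export
detect_lev_candidates <- function(image, ck_threshold, dapi_cutoff,
                                  config = detection_config()) {
  stopifnot(inherits(image, "slide_image"))
  ck <- get_channel(image, "ck")
  labels <- imageData(EBImage::bwlabel(ck > ck_threshold))
  events <- measure_events(image, labels, kind = "lev")
  if (nrow(events) == 0L) return(list(labels = labels, events = events))
  events$size_excluded <- events$equiv_diameter_um < config$min_lev_diameter_um
  # "high DAPI" means nucleus-level signal somewhere in the component; the
  # upper within-mask quantile sees a nucleus regardless of how much CK+
  # cytoplasm dilutes the component mean
  events$dapi_high_excluded <- events$q_dapi >= dapi_cutoff
  has_bf <- "bf" %in% names(image$channels)
  events$ring_checked <- has_bf
  if (has_bf) {
    bf <- get_channel(image, "bf")
    bg_sd <- stats::mad(bf[labels == 0])
    events$ring_score <- vapply(events$label, function(l) {
      ring_score_for_label(labels, l, bf, bg_sd)
    }, numeric(1L))
    events$ring_failed <- is.na(events$ring_score) |
      events$ring_score < config$tau_ring
  } else {
    warning("brightfield channel missing: membrane ring check skipped")
    events$ring_score <- NA_real_
    events$ring_failed <- FALSE
  }
  events$retained <- !events$size_excluded & !events$dapi_high_excluded &
    !events$ring_failed
  list(labels = labels, events = events)
}

# Brightfield membrane ring score of one labelled component: contrast
# between the object interior and its 1-px boundary band, in units of the
# background SD. A dark membrane ring gives a positive score.
#' @noRd
ring_score_for_label <- function(labels, label, bf, bg_sd) {
  mask <- labels == label
  interior <- imageData(EBImage::erode(mask, EBImage::makeBrush(3, "box")))
  band <- mask & !interior
  if (!any(interior) || !any(band) || bg_sd <= 0) return(NA_real_)
  (mean(bf[interior]) - mean(bf[band])) / bg_sd
}

#' Classify tumor events as epithelial or immune-like
#'
#' Anchors CD45 positivity to the observed leukocyte distribution: an event
#' is `im` when its per-event CD45 statistic (upper quantile by default)
#' strictly exceeds `mean(WBC) - cd45_k * sd(WBC)` computed over the
#' detected WBCs; boundary values and everything below are `epi`.
#'
#' @param events table of CTC or LEV candidates (needs `q_cd45` or
#'   `mean_cd45` depending on the configured statistic).
#' @param wbc_events table of detected WBCs providing the reference
#'   distribution (>= 2 rows).
#' @param config a [detection_config()].
#' @return `events` with a `phenotype` column (`"epi"`/`"im"`); the rule
#'   cutoff is attached as attribute `"cd45_cutoff"`.
#' @export
classify_phenotype <- function(events, wbc_events,
                               config = detection_config()) {
  col <- if (config$cd45_statistic == "q90") "q_cd45" else "mean_cd45"
  if (nrow(wbc_events) < 2L) {
    stop("insufficient data: need >= 2 WBCs for the CD45 reference")
  }
  ref <- wbc_events[[col]]
  cutoff <- mean(ref) - config$cd45_k * stats::sd(ref)
  events$phenotype <- ifelse(events[[col]] > cutoff, "im", "epi")
  attr(events, "cd45_cutoff") <- cutoff
  events
}

#' Run the full detection pipeline on one slide
#'
#' Nuclear segmentation, low-DAPI exclusion, CK thresholding for CTC
#' candidates, CK-channel segmentation with size/DAPI/brightfield filters
#' for LEV candidates, and CD45-based epi/im phenotyping of both. Events
#' failing a filter stay in the tables with their flags.
#'
#' @param image a [slide_image()].
#' @param config a [detection_config()].
#' @return List with `cells` (nucleated-event table: `phenotype` of
#'   `"wbc"`, `"epi"`, `"im"` or `"excluded"`), `levs` (LEV table),
#'   `masks` (`nuclei`, `cells`, `levs` label matrices) and `thresholds`.
#' @export
detect_events <- function(image, config = detection_config()) {
  seg <- segment_nucleated_cells(image, config)
  cells <- filter_dapi_low(seg$events, config$k_dapi_low)
  dapi_cutoff <- attr(cells, "dapi_cutoff")
  cells <- detect_ctc_candidates(cells, config$k_ck)
  ck_threshold <- attr(cells, "ck_threshold")
  wbc <- cells[cells$retained & !cells$is_ctc, , drop = FALSE]
  cells$phenotype <- ifelse(!cells$retained, "excluded", "wbc")
  if (any(cells$is_ctc)) {
    ctc <- classify_phenotype(cells[cells$is_ctc, , drop = FALSE], wbc, config)
    cells$phenotype[cells$is_ctc] <- ctc$phenotype
  }
  lev <- detect_lev_candidates(image, ck_threshold, dapi_cutoff, config)
  if (nrow(lev$events) && any(lev$events$retained)) {
    lev$events$phenotype <- "unclassified"
    cl <- classify_phenotype(lev$events[lev$events$retained, , drop = FALSE],
                             wbc, config)
    lev$events$phenotype[lev$events$retained] <- cl$phenotype
  } else if (nrow(lev$events)) {
    lev$events$phenotype <- "unclassified"
  }
  list(cells = cells, levs = lev$events,
       masks = list(nuclei = seg$nuclei, cells = seg$cells,
                    levs = lev$labels),
       thresholds = list(dapi_cutoff = dapi_cutoff,
                         ck_threshold = ck_threshold))
}

#' Match detected events to planted ground truth
#'
#' Greedy nearest-centroid matching between a detection table and a
#' ground-truth table, within `max_dist_px`.
#'
#' @param events detection table with `cx`, `cy`, `event_id`.
#' @param truth ground-truth table with `cx`, `cy`, `id`.
#' @param max_dist_px matching radius in pixels.
#' @return data.frame with `event_id`, `truth_id`, `dist`.
#' @export
match_events <- function(events, truth, max_dist_px = 3) {
  m <- greedy_match(cbind(events$cx, events$cy), cbind(truth$cx, truth$cy),
                    events$event_id, truth$id, max_dist_px)
  names(m) <- c("event_id", "truth_id", "dist")
  m
}

#' Per-class precision and recall of a detection run against ground truth
#'
#' Detected events are labelled with the planted class they match; precision
#' and recall are then computed per planted class. Detected classes are
#' derived as `wbc`, `epi_ctc`/`im_ctc` (retained cells) and
#' `epi_lev`/`im_lev` (retained LEVs).
#'
#' @param detection result of [detect_events()].
#' @param truth ground-truth table of a `synthetic_slide`.
#' @param max_dist_px centroid matching radius.
#' @return data.frame with one row per class: `n_truth`, `n_detected`,
#'   `tp`, `precision`, `recall`.
#' @export
evaluate_detection <- function(detection, truth, max_dist_px = 5) {
  cells <- detection$cells
  levs <- detection$levs
  det <- rbind(
    data.frame(cx = cells$cx, cy = cells$cy,
               class = ifelse(cells$phenotype == "wbc", "wbc",
                       ifelse(cells$phenotype == "im", "im_ctc",
                       ifelse(cells$phenotype == "epi", "epi_ctc", "excluded"))))[
                 cells$retained, , drop = FALSE],
    if (nrow(levs)) {
      data.frame(cx = levs$cx, cy = levs$cy,
                 class = paste0(levs$phenotype, "_lev"))[
                   levs$retained, , drop = FALSE]
    })
  det$det_id <- seq_len(nrow(det))
  truth_obj <- truth[truth$class != "debris", , drop = FALSE]
  m <- greedy_match(cbind(det$cx, det$cy),
                    cbind(truth_obj$cx, truth_obj$cy),
                    det$det_id, truth_obj$id, max_dist_px)
  det$truth_class <- NA_character_
  det$truth_class[match(m$id_a, det$det_id)] <-
    truth_obj$class[match(m$id_b, truth_obj$id)]
  classes <- sort(unique(truth_obj$class))
  do.call(rbind, lapply(classes, function(cl) {
    n_truth <- sum(truth_obj$class == cl)
    n_det <- sum(det$class == cl)
    tp <- sum(det$class == cl & !is.na(det$truth_class) &
                det$truth_class == cl)
    data.frame(class = cl, n_truth = n_truth, n_detected = n_det, tp = tp,
               precision = if (n_det > 0) tp / n_det else NA_real_,
               recall = if (n_truth > 0) tp / n_truth else NA_real_)
  }))
}
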