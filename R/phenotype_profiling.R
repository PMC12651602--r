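#' Log-transform an ion-count matrix
#'
#' Mean ion counts are log-transformed to stabilize the variance; since ion
#' counts include zeros the offset form `log(1 + x)` is used, which is
#' monotone and invertible (`expm1`).
#'
#' @param raw numeric matrix or data.frame of non-negative mean ion counts.
#' @return Matrix of `log1p` values.
#' @export
log_transform <- function(raw) {
  raw <- as.matrix(raw)
  if (!is.numeric(raw)) stop("validation error: counts must be numeric")
  if (any(raw < 0)) stop("validation error: negative ion counts")
  log1p(raw)
}

#' Hierarchical clustering of event phenotypes
#'
#' Agglomerative clustering (Ward linkage on Euclidean distance over
#' column-standardized log values) cut at `k` clusters. With `k = 2` and
#' CD3/CD4 columns present, cluster 1 is relabelled to the cluster with the
#' higher mean CD3 + CD4 signature, so "cluster 1 = CD4 T-cell-like" is
#' stable across runs.
#'
#' @param mat log-scale phenotype matrix (rows = events, columns =
#'   markers).
#' @param k number of clusters (1 <= k <= rows).
#' @param signature_markers markers whose joint mean anchors the cluster-1
#'   label.
#' @return Integer cluster labels (1..k) with the `hclust` tree attached as
#'   attribute `"tree"`.
#' @export
hierarchical_cluster <- function(mat, k = 2,
                                 signature_markers = c("CD3", "CD4")) {
  mat <- as.matrix(mat)
  if (k > nrow(mat) || k < 1) {
    stop("validation error: need 1 <= k <= number of rows")
  }
  if (k == 1L) {
    labels <- rep(1L, nrow(mat))
    return(labels)
  }
  z <- scale(mat)
  z[, attr(z, "scaled:scale") == 0] <- 0
  tree <- stats::hclust(stats::dist(z), method = "ward.D2")
  labels <- stats::cutree(tree, k = k)
  if (k == 2L && all(signature_markers %in% colnames(mat))) {
    sig <- rowMeans(mat[, signature_markers, drop = FALSE])
    if (mean(sig[labels == 2L]) > mean(sig[labels == 1L])) {
      labels <- 3L - labels
    }
  }
  attr(labels, "tree") <- tree
  labels
}

#' Gating configuration
#'
#' Per-marker positivity thresholds on the log scale. When derived with
#' [derive_gate_thresholds()] each threshold is the midpoint between the
#' two cluster means of that marker.
#'
#' @param thresholds named numeric vector of log-scale thresholds; a marker
#'   is positive when its log value strictly exceeds its threshold.
#' @return An object of class `gate_config`.
#' @export
gate_config <- function(thresholds) {
  stopifnot(is.numeric(thresholds), !is.null(names(thresholds)))
  structure(list(thresholds = thresholds), class = "gate_config")
}

#' Default gating configuration
#'
#' A fixed positivity cutoff on raw mean ion counts, applied on the log
#' scale: a marker is positive above `count_threshold` ion counts (default
#' 10, between the background counts of negative populations, typically
#' 1-3, and genuinely expressing ones, typically 20+). Unlike the
#' cluster-midpoint rule of [derive_gate_thresholds()], a fixed cutoff
#' behaves sensibly for markers with no positive population in the cohort.
#'
#' @param markers marker names to threshold.
#' @param count_threshold raw ion-count positivity cutoff.
#' @return A [gate_config()].
#' @export
default_gate_config <- function(markers = c("CD45", "CD3", "CD4", "CD8a",
                                            "CD20", "CD56", "CD14", "CD68"),
                                count_threshold = 10) {
  gate_config(stats::setNames(rep(log1p(count_threshold), length(markers)),
                              markers))
}

#' Derive gate thresholds from a clustered matrix
#'
#' Midpoint between the two cluster means per marker. Appropriate when both
#' a positive and a negative population are present; for markers negative
#' in both clusters the midpoint splits noise, and [default_gate_config()]
#' is the safer choice.
#'
#' @param mat log-scale phenotype matrix.
#' @param labels two-cluster labels for its rows.
#' @return A [gate_config()] with per-marker midpoints between cluster
#'   means.
#' @export
derive_gate_thresholds <- function(mat, labels) {
  mat <- as.matrix(mat)
  stopifnot(length(labels) == nrow(mat), length(unique(labels)) == 2L)
  thr <- vapply(colnames(mat), function(mk) {
    mean(c(mean(mat[labels == unique(labels)[1L], mk]),
           mean(mat[labels == unique(labels)[2L], mk])))
  }, numeric(1L))
  gate_config(thr)
}

#' Gate immune subtypes from marker positivity
#'
#' Decision tree over the canonical immune panel (CD45, CD3, CD4, CD8a,
#' CD20, CD56, CD14, CD68): CD45- events are `non_immune`;
#' CD45+CD3+CD8a+ is `cd8_t` (taking precedence over the CD4 branch for
#' double positives); CD45+CD3+CD4+CD8a- is `cd4_t`; CD45+CD3-CD20+ is
#' `b_cell`; CD45+CD3-CD56+ is `nk`; CD45+ with CD14 or CD68 is
#' `monocyte_macrophage`; anything else CD45+ is `unclassified`.
#'
#' @param mat log-scale phenotype matrix containing all gate markers.
#' @param config a [gate_config()] with thresholds for every gate marker.
#' @return Character vector of subtype labels, one per row.
#' @export
gate_immune_subtype <- function(mat, config) {
  stopifnot(inherits(config, "gate_config"))
  mat <- as.matrix(mat)
  markers <- c("CD45", "CD3", "CD4", "CD8a", "CD20", "CD56", "CD14", "CD68")
  missing <- setdiff(markers, colnames(mat))
  if (length(missing)) {
    stop(sprintf("configuration error: missing gate markers: %s",
                 paste(missing, collapse = ", ")))
  }
  missing_thr <- setdiff(markers, names(config$thresholds))
  if (length(missing_thr)) {
    stop(sprintf("configuration error: no threshold for: %s",
                 paste(missing_thr, collapse = ", ")))
  }
  pos <- vapply(markers, function(mk) {
    mat[, mk] > config$thresholds[[mk]]
  }, logical(nrow(mat)))
  if (nrow(mat) == 1L) pos <- matrix(pos, nrow = 1L, dimnames = list(NULL, markers))
  apply(pos, 1L, function(p) {
    if (!p[["CD45"]]) return("non_immune")
    if (p[["CD3"]] && p[["CD8a"]]) return("cd8_t")
    if (p[["CD3"]] && p[["CD4"]] && !p[["CD8a"]]) return("cd4_t")
    if (!p[["CD3"]] && p[["CD20"]]) return("b_cell")
    if (!p[["CD3"]] && p[["CD56"]]) return("nk")
    if (p[["CD14"]] || p[["CD68"]]) return("monocyte_macrophage")
    "unclassified"
  })
}

#' Match immunofluorescence events to mass-cytometry ROIs by coordinates
#'
#' Greedy nearest-neighbour matching under a distance tolerance, after an
#' optional affine transform of the ROI coordinates into the IF frame. Each
#' ROI is matched at most once; among equidistant candidates the lowest
#' event id wins, and ambiguous (tied) configurations raise a warning.
#'
#' @param if_events data.frame with `id`, `x`, `y` (um).
#' @param imc_rois data.frame with `id`, `x`, `y` (um).
#' @param tolerance_um maximum matching distance in um.
#' @param transform optional 2x3 affine matrix `A | b`: ROI coordinates are
#'   mapped as `A %*% c(x, y) + b` before matching.
#' @return list with `matches` (data.frame `event_id`, `roi_id`, `dist`),
#'   `unmatched_events`, `unmatched_rois`.
#' @export
match_coordinates <- function(if_events, imc_rois, tolerance_um,
                              transform = NULL) {
  stopifnot(all(c("id", "x", "y") %in% names(if_events)),
            all(c("id", "x", "y") %in% names(imc_rois)))
  roi_xy <- cbind(imc_rois$x, imc_rois$y)
  if (!is.null(transform)) {
    stopifnot(is.matrix(transform), all(dim(transform) == c(2L, 3L)))
    roi_xy <- t(transform[, 1:2] %*% t(roi_xy) + transform[, 3L])
  }
  ev_xy <- cbind(if_events$x, if_events$y)
  if (nrow(if_events) && nrow(imc_rois)) {
    dmat <- sqrt(outer(ev_xy[, 1L], roi_xy[, 1L], "-")^2 +
                 outer(ev_xy[, 2L], roi_xy[, 2L], "-")^2)
    within <- dmat <= tolerance_um
    tied <- any(apply(dmat, 2L, function(col) {
      cand <- col[col <= tolerance_um]
      length(cand) > 1L && sum(cand == min(cand)) > 1L
    }))
    if (tied) {
      warning("ambiguous coordinate match: equidistant candidates, lowest id wins")
    }
  }
  m <- greedy_match(ev_xy, roi_xy, if_events$id, imc_rois$id, tolerance_um)
  names(m) <- c("event_id", "roi_id", "dist")
  list(matches = m,
       unmatched_events = setdiff(if_events$id, m$event_id),
       unmatched_rois = setdiff(imc_rois$id, m$roi_id))
}

#' Differential marker comparison between two event groups
#'
#' Mann-Whitney comparison of a marker's log values between two groups
#' (e.g. tumor events vs WBCs for HLA-DR or cleaved Caspase-3), plus the
#' difference of group medians on the log scale.
#'
#' @param group_a,group_b log-scale phenotype matrices (rows = events).
#' @param marker marker column name.
#' @return A `group_comparison` (see [mann_whitney()]) with an added
#'   `median_diff` element (median A minus median B).
#' @export
differential_marker <- function(group_a, group_b, marker) {
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  if (!marker %in% colnames(group_a) || !marker %in% colnames(group_b)) {
    stop(sprintf("marker '%s' missing from a group", marker))
  }
  cmp <- mann_whitney(group_a[, marker], group_b[, marker])
  cmp$median_diff <- stats::median(group_a[, marker]) -
    stats::median(group_b[, marker])
  cmp
}

#' Default class means of the synthetic phenotype generator
#'
#' Mean ion counts per marker for the two simulated components: a CD4
#' T-cell-like profile (high CD45/CD3/CD4, low CD8a, no CK) and an
#' epithelial-like profile (CK-high, immune-low).
#'
#' @return A 2-row matrix (rows `cd4t`, `epithelial`) of mean counts.
#' @export
phenotype_class_means <- function() {
  markers <- c("CD45", "CD3", "CD4", "CD8a", "CD20", "CD56", "CD14", "CD68",
               "CK", "HLA-DR", "cCaspase3")
  rbind(
    cd4t       = c(CD45 = 150, CD3 = 80, CD4 = 60, CD8a = 2, CD20 = 2,
                   CD56 = 2, CD14 = 3, CD68 = 3, CK = 1, `HLA-DR` = 20,
                   cCaspase3 = 5),
    epithelial = c(CD45 = 3, CD3 = 1, CD4 = 1, CD8a = 1, CD20 = 1,
                   CD56 = 1, CD14 = 1, CD68 = 1, CK = 120, `HLA-DR` = 8,
                   cCaspase3 = 10))[, markers]
}

#' Simulate a per-event marker-count matrix
#'
#' Negative-binomial ion counts standing in for imaging-mass-cytometry
#' measurements of in-contact and standalone events. Each event is drawn
#' from the CD4 T-cell-like or the epithelial-like component; in-contact
#' events favour the CD4 T-cell-like component (the qualitative pattern
#' under study), standalone events the epithelial one.
#'
#' @param n_contact,n_standalone event counts per group.
#' @param p_contact_cd4 probability that an in-contact event is CD4
#'   T-cell-like.
#' @param p_standalone_cd4 same for standalone events.
#' @param dispersion negative-binomial size parameter (common to all
#'   markers).
#' @param class_means 2-row matrix of per-class marker means
#'   ([phenotype_class_means()] by default).
#' @param seed integer seed.
#' @return list with `raw` (count matrix), `log` (log1p matrix) and `meta`
#'   (data.frame: `contact` flag and planted `true_class`).
#' @export
simulate_phenotype_matrix <- function(n_contact = 42, n_standalone = 143,
                                      p_contact_cd4 = 0.8,
                                      p_standalone_cd4 = 0.15,
                                      dispersion = 8,
                                      class_means = phenotype_class_means(),
                                      seed = 1) {
  stopifnot(n_contact >= 0, n_standalone >= 0, dispersion > 0)
  withr::with_seed(seed, {
    contact <- rep(c(TRUE, FALSE), c(n_contact, n_standalone))
    p_cd4 <- ifelse(contact, p_contact_cd4, p_standalone_cd4)
    true_class <- ifelse(stats::runif(length(p_cd4)) < p_cd4,
                         "cd4t", "epithelial")
    raw <- t(vapply(true_class, function(cl) {
      mu <- class_means[cl, ]
      stats::rnbinom(length(mu), mu = mu, size = dispersion)
    }, numeric(ncol(class_means))))
    colnames(raw) <- colnames(class_means)
    rownames(raw) <- NULL
    list(raw = raw, log = log_transform(raw),
         meta = data.frame(contact = contact, true_class = true_class))
  })
}

#' Contingency table of contact status against cluster membership
#'
#' @param contact logical vector (in-contact vs standalone).
#' @param cluster cluster labels (1 = CD4 T-cell-like by convention).
#' @return 2x2 integer matrix: rows in_contact/standalone, columns
#'   cluster1/cluster2.
#' @export
contact_cluster_table <- function(contact, cluster) {
  stopifnot(length(contact) == length(cluster))
  tab <- rbind(
    in_contact = c(sum(contact & cluster == 1L), sum(contact & cluster != 1L)),
    standalone = c(sum(!contact & cluster == 1L), sum(!contact & cluster != 1L)))
  colnames(tab) <- c("cluster1", "cluster2")
  tab
}
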