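#' Simulation configuration for synthetic slides
#'
#' Builds the parameter set for [generate_slide()]. The defaults describe a
#' desk-scale stand-in for an enrichment-free liquid-biopsy slide: a dense
#' background of CD45+ white blood cells (WBCs), a handful of cytokeratin
#' (CK)-bright circulating tumor cells (CTCs, with or without CD45), CK+/
#' DAPI- large extracellular vesicles (LEVs) with a dark brightfield
#' membrane ring, sub-threshold CK debris, and planted tumor-immune pairs in
#' three relationships: `pic` (contact with membrane-marker enrichment on
#' the arc facing the partner), `overlap` (contact, circumferentially
#' uniform ring) and `gap` (physically separated).
#'
#' Cells are rendered as disks with an annular membrane ring; per-object
#' brightness is drawn log-normally around the class mean and pixel noise is
#' additive Gaussian, clipped to the 16-bit range.
#'
#' @param width,height canvas size in pixels.
#' @param pixel_scale micrometres per pixel.
#' @param n_wbc,n_epi_ctc,n_im_ctc,n_lev,n_debris standalone object counts.
#' @param prop_im_lev fraction of LEVs carrying CD45 (immune-like).
#' @param n_pic,n_overlap,n_gap_pair planted tumor-WBC pair counts.
#' @param pic_tumor_class,overlap_tumor_class,gap_tumor_class class of the
#'   tumor partner in planted pairs; one of `"epi_ctc"`, `"im_ctc"`,
#'   `"epi_lev"`, `"im_lev"`.
#' @param r_wbc_um,r_ctc_um,r_lev_um,r_debris_um radius ranges (um).
#' @param ring_width_px membrane ring width in pixels.
#' @param nucleus_frac nucleus radius as a fraction of the cell radius.
#' @param baseline,noise_sd named per-channel background level and Gaussian
#'   pixel noise SD (16-bit intensity units).
#' @param i_dapi,i_ck,i_mem class mean intensities for nuclear DAPI, CK and
#'   the CD45 membrane ring; `bf_ring_depth` is how far the LEV membrane
#'   ring dips below the brightfield background.
#' @param cv_dapi,cv_ck,cv_mem per-object log-normal coefficients of
#'   variation.
#' @param fold planted contact-interface enrichment fold (>= 1; > 1 for
#'   `pic` pairs).
#' @param contact_arc_deg full angular width of the contact wedge, degrees.
#' @param gap_um mask separation for `gap` pairs (um, > 0).
#' @param hot_pixel_rate fraction of pixels replaced by bright heavy-tailed
#'   artifacts (0 disables).
#' @param margin_px placement margin kept free around every object.
#' @param max_place_tries bounded retries for rejection-sampling placement.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   slides.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(width = 1536, height = 1536, pixel_scale = 0.5,
                       n_wbc = 500, n_epi_ctc = 2, n_im_ctc = 2,
                       n_lev = 6, prop_im_lev = 0.5, n_debris = 4,
                       n_pic = 2, n_overlap = 1, n_gap_pair = 1,
                       pic_tumor_class = "im_ctc",
                       overlap_tumor_class = "epi_ctc",
                       gap_tumor_class = "epi_ctc",
                       r_wbc_um = c(4, 6), r_ctc_um = c(5, 8),
                       r_lev_um = c(1.5, 4), r_debris_um = c(0.5, 1.1),
                       ring_width_px = 2, nucleus_frac = 0.7,
                       baseline = c(dapi = 200, ck = 200, cd45 = 200, bf = 10000),
                       noise_sd = c(dapi = 30, ck = 30, cd45 = 30, bf = 200),
                       i_dapi = 3000, i_ck = 25000, i_mem = 5000,
                       bf_ring_depth = 2000,
                       cv_dapi = 0.2, cv_ck = 0.06, cv_mem = 0.1,
                       fold = 2, contact_arc_deg = 60, gap_um = 1,
                       hot_pixel_rate = 0,
                       margin_px = 6, max_place_tries = 100, seed = 1) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' @noRd
validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_wbc, cfg$n_epi_ctc, cfg$n_im_ctc, cfg$n_lev, cfg$n_debris,
              cfg$n_pic, cfg$n_overlap, cfg$n_gap_pair)
  if (any(counts < 0)) stop("object counts must be >= 0")
  if (cfg$fold < 1) stop("contact enrichment fold must be >= 1")
  if (cfg$n_pic > 0 && cfg$fold <= 1) {
    stop("pic pairs require fold > 1; use overlap pairs for fold = 1")
  }
  if (cfg$contact_arc_deg <= 0 || cfg$contact_arc_deg > 180) {
    stop("contact_arc_deg must be in (0, 180]")
  }
  if (cfg$pixel_scale <= 0) stop("pixel_scale must be > 0")
  if (cfg$gap_um <= 0) stop("gap_um must be > 0")
  if (cfg$prop_im_lev < 0 || cfg$prop_im_lev > 1) stop("prop_im_lev in [0,1]")
  need <- c("dapi", "ck", "cd45", "bf")
  if (!all(need %in% names(cfg$baseline)) || !all(need %in% names(cfg$noise_sd))) {
    stop("baseline and noise_sd must name channels dapi, ck, cd45, bf")
  }
  invisible(cfg)
}

#' Blank simulation canvas
#'
#' A canvas holds the noise-free foreground fields (one per channel, zero
#' where nothing is planted), the accumulating ground-truth table and the
#' configuration. [plant_cell()] and [plant_pair()] paint into it;
#' [render_slide()] adds background and noise.
#'
#' @param config a [sim_config()].
#' @return An object of class `slide_canvas`.
#' @export
blank_canvas <- function(config) {
  validate_sim_config(config)
  dim <- c(config$width, config$height)
  zero <- function() matrix(0, dim[1L], dim[2L])
  structure(list(
    fg = list(dapi = zero(), ck = zero(), cd45 = zero(), bf_dark = zero()),
    truth = empty_truth(),
    config = config
  ), class = "slide_canvas")
}

#' @noRd
empty_truth <- function() {
  data.frame(id = integer(0), class = character(0), kind = character(0),
             cx = numeric(0), cy = numeric(0),
             radius_px = numeric(0), radius_um = numeric(0),
             i_dapi = numeric(0), i_ck = numeric(0), i_cd45 = numeric(0),
             fold = numeric(0), contact_arc_deg = numeric(0),
             orient = numeric(0), pair_id = integer(0),
             relationship = character(0), partner_id = integer(0))
}

#' @noRd
class_is_cell <- function(class) class %in% c("wbc", "epi_ctc", "im_ctc")

#' @noRd
class_has_cd45 <- function(class) class %in% c("wbc", "im_ctc", "im_lev")

#' @noRd
class_has_ck <- function(class) {
  class %in% c("epi_ctc", "im_ctc", "epi_lev", "im_lev", "debris")
}

# Draw per-object intensities for a class from the configured log-normal
# brightness distributions (uses the current RNG stream).
#' @noRd
draw_intensities <- function(class, cfg) {
  ln <- function(m, cv) {
    if (cv <= 0) return(m)
    s <- sqrt(log(1 + cv^2))
    stats::rlnorm(1L, meanlog = log(m) - s^2 / 2, sdlog = s)
  }
  list(
    dapi = if (class_is_cell(class)) ln(cfg$i_dapi, cfg$cv_dapi) else 0,
    ck   = if (class_has_ck(class)) ln(cfg$i_ck, cfg$cv_ck) else 0,
    cd45 = if (class_has_cd45(class)) ln(cfg$i_mem, cfg$cv_mem) else 0
  )
}

#' Plant one object on a canvas
#'
#' Paints the noise-free footprint of a single object (disk body, nuclear
#' disk for cells, annular CD45 membrane ring, dark brightfield ring for
#' LEVs) and appends its ground-truth row. For `pic`-side WBCs the membrane
#' ring is multiplied by `fold` on the wedge of width `contact_arc_deg`
#' centred on `orient`.
#'
#' @param canvas a [blank_canvas()].
#' @param class one of `"wbc"`, `"epi_ctc"`, `"im_ctc"`, `"epi_lev"`,
#'   `"im_lev"`, `"debris"`.
#' @param cx,cy centre in pixels.
#' @param r_px radius in pixels.
#' @param fold membrane enrichment fold applied on the contact wedge.
#' @param orient wedge direction in radians (toward the partner).
#' @param contact_arc_deg full wedge width in degrees.
#' @param pair_id,relationship,partner_id pair bookkeeping (NA for
#'   standalone objects).
#' @param ints optional pre-drawn intensity list (`dapi`, `ck`, `cd45`);
#'   drawn from the configured distributions when `NULL`.
#' @return The updated canvas.
#' @export
plant_cell <- function(canvas, class, cx, cy, r_px,
                       fold = 1, orient = NA_real_, contact_arc_deg = NA_real_,
                       pair_id = NA_integer_, relationship = NA_character_,
                       partner_id = NA_integer_, ints = NULL) {
  stopifnot(inherits(canvas, "slide_canvas"))
  cfg <- canvas$config
  dim <- c(cfg$width, cfg$height)
  classes <- c("wbc", "epi_ctc", "im_ctc", "epi_lev", "im_lev", "debris")
  class <- match.arg(class, classes)
  if (is.null(ints)) ints <- draw_intensities(class, cfg)
  paint_max <- function(m, px, val) {
    if (nrow(px)) m[px] <- pmax(m[px], val)
    m
  }
  if (class_is_cell(class)) {
    npx <- disk_pixels(cx, cy, cfg$nucleus_frac * r_px, dim)
    canvas$fg$dapi <- paint_max(canvas$fg$dapi, npx, ints$dapi)
  }
  if (class_has_ck(class)) {
    canvas$fg$ck <- paint_max(canvas$fg$ck, disk_pixels(cx, cy, r_px, dim),
                              ints$ck)
  }
  if (class_has_cd45(class)) {
    ring <- annulus_pixels(cx, cy, r_px - cfg$ring_width_px, r_px, dim)
    val <- rep(ints$cd45, nrow(ring))
    if (fold > 1 && is.finite(orient) && nrow(ring)) {
      ang <- atan2(ring[, "y"] - cy, ring[, "x"] - cx)
      half <- contact_arc_deg / 2 * pi / 180
      val[angle_diff(ang, orient) <= half] <- ints$cd45 * fold
    }
    canvas$fg$cd45 <- paint_max(canvas$fg$cd45, ring, val)
  }
  if (class %in% c("epi_lev", "im_lev")) {
    ring <- annulus_pixels(cx, cy, r_px - cfg$ring_width_px, r_px, dim)
    canvas$fg$bf_dark <- paint_max(canvas$fg$bf_dark, ring, cfg$bf_ring_depth)
  }
  kind <- if (class_is_cell(class)) "cell" else if (class == "debris") "debris" else "lev"
  canvas$truth <- rbind(canvas$truth, data.frame(
    id = nrow(canvas$truth) + 1L, class = class, kind = kind,
    cx = cx, cy = cy, radius_px = r_px,
    radius_um = r_px * cfg$pixel_scale,
    i_dapi = ints$dapi, i_ck = ints$ck, i_cd45 = ints$cd45,
    fold = fold, contact_arc_deg = contact_arc_deg, orient = orient,
    pair_id = pair_id, relationship = relationship, partner_id = partner_id))
  canvas
}

# Centre distance for a touching pair whose contact arc subtends the
# requested full width arc_deg on the WBC perimeter. "Contact" downstream
# means perimeter-trace pixels within 1 px adjacency of the partner mask;
# the trace runs on the inner boundary (~0.5 px inside the disk edge) and
# the adjacency adds ~1.5 px of reach, so the geometry solves for those
# effective radii rather than the ideal circles - otherwise the labelled
# contact arc is systematically wider than the planted enrichment wedge and
# the recovered fold is diluted.
#' @noRd
pair_center_distance <- function(r_wbc, r_tumor, arc_deg,
                                 trace_offset = 0.5, adjacency_slack = 1.5) {
  half <- arc_deg / 2 * pi / 180
  rho <- r_wbc - trace_offset
  r_eff <- r_tumor + adjacency_slack
  if (r_eff <= rho * sin(half)) {
    stop(sprintf(
      "contact arc of %.0f deg infeasible: tumor radius %.1f px too small vs WBC %.1f px",
      arc_deg, r_tumor, r_wbc))
  }
  rho * cos(half) + sqrt(r_eff^2 - (rho * sin(half))^2)
}

#' Plant a tumor-WBC pair
#'
#' Places a WBC at `(cx, cy)` and its tumor partner along direction
#' `orient`. For `pic` and `overlap` relationships the centre distance is
#' chosen so the overlap chord subtends `contact_arc_deg` on the WBC
#' perimeter (masks overlap); `pic` pairs additionally multiply the WBC
#' membrane ring by `fold` on that wedge. `gap` pairs are separated by
#' `gap_px` of background so their rasterized masks share no boundary.
#'
#' @param canvas a [blank_canvas()].
#' @param relationship `"pic"`, `"overlap"` or `"gap"`.
#' @param tumor_class class of the tumor partner (`"epi_ctc"`, `"im_ctc"`,
#'   `"epi_lev"`, `"im_lev"`).
#' @param cx,cy WBC centre in pixels.
#' @param orient direction from WBC to partner, radians.
#' @param r_wbc_px,r_tumor_px radii in pixels.
#' @param fold enrichment fold (> 1 required for `pic`, forced to 1 for
#'   `overlap`/`gap`).
#' @param contact_arc_deg full contact arc width, degrees.
#' @param gap_px mask separation for `gap` pairs (> 0).
#' @param pair_id integer pair identifier recorded in the ground truth.
#' @return The updated canvas; the two new ground-truth rows reference each
#'   other through `partner_id`.
#' @export
plant_pair <- function(canvas, relationship, tumor_class, cx, cy, orient,
                       r_wbc_px, r_tumor_px, fold = 2,
                       contact_arc_deg = 60, gap_px = 2,
                       pair_id = NA_integer_) {
  stopifnot(inherits(canvas, "slide_canvas"))
  relationship <- match.arg(relationship, c("pic", "overlap", "gap"))
  tumor_class <- match.arg(tumor_class,
                           c("epi_ctc", "im_ctc", "epi_lev", "im_lev"))
  cfg <- canvas$config
  if (is.na(pair_id)) pair_id <- max(0L, canvas$truth$pair_id, na.rm = TRUE) + 1L
  if (relationship == "gap") {
    if (gap_px <= 0) stop("gap relationship requires gap_px > 0")
    d <- r_wbc_px + r_tumor_px + gap_px
    fold <- 1
  } else {
    d <- pair_center_distance(r_wbc_px, r_tumor_px, contact_arc_deg)
    if (relationship == "overlap") fold <- 1
    if (relationship == "pic" && fold <= 1) stop("pic pairs require fold > 1")
  }
  tx <- cx + d * cos(orient); ty <- cy + d * sin(orient)
  reach <- function(x, y, r) {
    x - r < 1 || x + r > cfg$width || y - r < 1 || y + r > cfg$height
  }
  if (reach(cx, cy, r_wbc_px) || reach(tx, ty, r_tumor_px)) {
    stop(sprintf("placement failure for %s pair %d: object extends beyond canvas",
                 relationship, pair_id))
  }
  id0 <- nrow(canvas$truth)
  canvas <- plant_cell(canvas, "wbc", cx, cy, r_wbc_px,
                       fold = if (relationship == "pic") fold else 1,
                       orient = orient, contact_arc_deg = contact_arc_deg,
                       pair_id = pair_id, relationship = relationship,
                       partner_id = id0 + 2L)
  canvas <- plant_cell(canvas, tumor_class, tx, ty, r_tumor_px,
                       pair_id = pair_id, relationship = relationship,
                       partner_id = id0 + 1L)
  canvas
}

#' Render a canvas into a slide image
#'
#' Adds the per-channel background baseline, converts the dark brightfield
#' foreground into a dip below the brightfield baseline, then (optionally)
#' adds Gaussian pixel noise and heavy-tailed hot pixels, clipping to the
#' 16-bit range. Uses the current RNG stream.
#'
#' @param canvas a planted [blank_canvas()].
#' @param noise add pixel noise (`TRUE`) or return the noise-free image.
#' @return A `synthetic_slide`: list with elements `image` (noisy
#'   [slide_image()]), `clean` (noise-free channel matrices), `truth` and
#'   `config`.
#' @export
render_slide <- function(canvas, noise = TRUE) {
  stopifnot(inherits(canvas, "slide_canvas"))
  cfg <- canvas$config
  b <- cfg$baseline
  clean <- list(
    dapi = b[["dapi"]] + canvas$fg$dapi,
    ck   = b[["ck"]] + canvas$fg$ck,
    cd45 = b[["cd45"]] + canvas$fg$cd45,
    bf   = b[["bf"]] - canvas$fg$bf_dark
  )
  clean <- lapply(clean, function(m) pmin(pmax(m, 0), 65535))
  channels <- clean
  if (noise) {
    n <- cfg$width * cfg$height
    for (nm in names(channels)) {
      ch <- channels[[nm]] + stats::rnorm(n, 0, cfg$noise_sd[[nm]])
      if (cfg$hot_pixel_rate > 0) {
        nhot <- stats::rbinom(1L, n, cfg$hot_pixel_rate)
        if (nhot > 0) {
          idx <- sample.int(n, nhot)
          ch[idx] <- ch[idx] + stats::rcauchy(nhot, 0, 20)^2
        }
      }
      channels[[nm]] <- pmin(pmax(ch, 0), 65535)
    }
  }
  structure(list(
    image = slide_image(channels, cfg$pixel_scale),
    clean = clean, truth = canvas$truth, config = cfg
  ), class = "synthetic_slide")
}

#' Generate a synthetic slide with planted ground truth
#'
#' Places all configured standalone objects and pairs by rejection sampling
#' (objects keep `margin_px` of clearance so only planted pairs touch),
#' paints them, and renders the noisy image. Identical `config` (including
#' `seed`) yields bit-identical output.
#'
#' @param config a [sim_config()].
#' @return A `synthetic_slide` (see [render_slide()]).
#' @export
generate_slide <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, generate_slide_impl(config))
}

#' @noRd
generate_slide_impl <- function(cfg) {
  canvas <- blank_canvas(cfg)
  placed <- data.frame(cx = numeric(0), cy = numeric(0), reach = numeric(0))
  runif_r <- function(range_um) {
    stats::runif(1L, range_um[1L], range_um[2L]) / cfg$pixel_scale
  }
  try_place <- function(reach, what) {
    lo_x <- reach + 1; hi_x <- cfg$width - reach
    lo_y <- reach + 1; hi_y <- cfg$height - reach
    if (lo_x >= hi_x || lo_y >= hi_y) {
      stop(sprintf("placement failure for %s: canvas too small", what))
    }
    for (i in seq_len(cfg$max_place_tries)) {
      cx <- stats::runif(1L, lo_x, hi_x)
      cy <- stats::runif(1L, lo_y, hi_y)
      if (nrow(placed) == 0L ||
          all((placed$cx - cx)^2 + (placed$cy - cy)^2 >
              (placed$reach + reach)^2)) {
        return(c(cx, cy))
      }
    }
    stop(sprintf("placement failure for %s after %d tries", what,
                 cfg$max_place_tries))
  }
  tumor_radius <- function(class) {
    if (grepl("ctc$", class)) runif_r(cfg$r_ctc_um) else runif_r(cfg$r_lev_um)
  }
  # pairs first: they need the most clearance
  pair_plan <- c(rep("pic", cfg$n_pic), rep("overlap", cfg$n_overlap),
                 rep("gap", cfg$n_gap_pair))
  pair_class <- c(rep(cfg$pic_tumor_class, cfg$n_pic),
                  rep(cfg$overlap_tumor_class, cfg$n_overlap),
                  rep(cfg$gap_tumor_class, cfg$n_gap_pair))
  for (i in seq_along(pair_plan)) {
    rel <- pair_plan[i]
    r_w <- runif_r(cfg$r_wbc_um)
    r_t <- tumor_radius(pair_class[i])
    orient <- stats::runif(1L, 0, 2 * pi)
    gap_px <- cfg$gap_um / cfg$pixel_scale
    d <- if (rel == "gap") r_w + r_t + gap_px
         else pair_center_distance(r_w, r_t, cfg$contact_arc_deg)
    reach <- d + r_t + cfg$margin_px
    ctr <- try_place(reach, sprintf("%s pair %d", rel, i))
    canvas <- plant_pair(canvas, rel, pair_class[i], ctr[1L], ctr[2L], orient,
                         r_w, r_t, fold = cfg$fold,
                         contact_arc_deg = cfg$contact_arc_deg,
                         gap_px = gap_px, pair_id = i)
    placed <- rbind(placed, data.frame(cx = ctr[1L], cy = ctr[2L], reach = reach))
  }
  singles <- c(rep("wbc", cfg$n_wbc), rep("epi_ctc", cfg$n_epi_ctc),
               rep("im_ctc", cfg$n_im_ctc),
               rep("im_lev", round(cfg$n_lev * cfg$prop_im_lev)),
               rep("epi_lev", cfg$n_lev - round(cfg$n_lev * cfg$prop_im_lev)),
               rep("debris", cfg$n_debris))
  for (class in singles) {
    r <- switch(class,
                wbc = runif_r(cfg$r_wbc_um),
                epi_ctc = , im_ctc = runif_r(cfg$r_ctc_um),
                epi_lev = , im_lev = runif_r(cfg$r_lev_um),
                debris = runif_r(cfg$r_debris_um))
    reach <- r + cfg$margin_px
    ctr <- try_place(reach, class)
    canvas <- plant_cell(canvas, class, ctr[1L], ctr[2L], r)
    placed <- rbind(placed, data.frame(cx = ctr[1L], cy = ctr[2L], reach = reach))
  }
  render_slide(canvas, noise = TRUE)
}

#' Rasterize the planted footprint of a ground-truth object
#'
#' @param truth_row one row of a ground-truth table.
#' @param dim canvas dimension `c(width, height)` in pixels.
#' @return A 0/1 integer mask matrix.
#' @export
truth_mask <- function(truth_row, dim) {
  mask_from_disk(truth_row$cx, truth_row$cy, truth_row$radius_px, dim)
}
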