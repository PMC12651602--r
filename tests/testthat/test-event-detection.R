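greedy_match_public <- function(events, truth) {
  if (nrow(events) == 0L || nrow(truth) == 0L) return(data.frame())
  match_events(events, truth, max_dist_px = 3)
}

make_events <- function(dapi = NULL, ck = NULL) {
  n <- max(length(dapi), length(ck))
  data.frame(event_id = seq_len(n),
             mean_dapi = if (is.null(dapi)) rep(1000, n) else dapi,
             mean_ck = if (is.null(ck)) rep(100, n) else ck)
}

test_that("channel_stats computes mean and sample SD", {
  ev <- make_events(ck = c(90, 100, 110))
  st <- channel_stats(ev, "ck")
  expect_equal(st[["mean"]], 100)
  expect_equal(st[["sd"]], 10)
  expect_error(channel_stats(ev[1, ], "ck"), "insufficient")
  expect_equal(channel_stats(make_events(ck = c(5, 5, 5)), "ck")[["sd"]], 0)
})

test_that("channel_stats estimates recover simulated population moments", {
  set.seed(14)
  ev <- make_events(ck = rnorm(10000, 100, 10))
  st <- channel_stats(ev, "ck")
  expect_lt(abs(st[["mean"]] - 100), 3 * 10 / sqrt(10000))
  expect_lt(abs(st[["sd"]] - 10), 3 * 10 / sqrt(2 * 10000))
})

test_that("low-DAPI exclusion flags below mean - k sd and never deletes", {
  ev <- make_events(dapi = c(100, 200, 300))  # mean 200, sd 100
  out <- filter_dapi_low(ev, k = 1)           # cutoff 100
  expect_equal(attr(out, "dapi_cutoff"), 100)
  expect_equal(out$dapi_low_excluded, c(FALSE, FALSE, FALSE))
  out <- filter_dapi_low(ev, k = 0.5)         # cutoff 150
  expect_equal(out$dapi_low_excluded, c(TRUE, FALSE, FALSE))
  expect_equal(nrow(out), 3L)                 # flagged, not removed
  out <- filter_dapi_low(ev, k = 0)           # retains only >= mean
  expect_equal(out$retained, c(FALSE, TRUE, TRUE))
  expect_error(filter_dapi_low(make_events(dapi = c(5, 5, 5))), "degenerate")
})

test_that("low-DAPI exclusion removes planted near-zero-DAPI artifacts", {
  set.seed(15)
  n <- 2000
  artifact <- runif(n) < 0.05
  ev <- make_events(dapi = ifelse(artifact, runif(n, 0, 50),
                                  rnorm(n, 1500, 250)))
  out <- filter_dapi_low(ev, k = 3)
  expect_gte(mean(out$dapi_low_excluded[artifact]), 0.95)
  expect_lte(mean(out$dapi_low_excluded[!artifact]), 0.05)
})

test_that("CK threshold is mean + k sd with strict exceedance, monotone in k", {
  set.seed(16)
  ev <- make_events(dapi = rnorm(202, 1500, 200),
                    ck = c(rnorm(200, 100, 10), 500, 800))
  ev <- filter_dapi_low(ev, k = 3)
  prev <- NULL
  for (k in c(2, 4, 6, 8)) {
    out <- detect_ctc_candidates(ev, k_ck = k)
    st <- channel_stats(ev[ev$retained, ], "ck")
    expect_equal(attr(out, "ck_threshold"), st[["mean"]] + k * st[["sd"]])
    expect_equal(out$is_ctc, ev$retained & ev$mean_ck > attr(out, "ck_threshold"))
    if (!is.null(prev)) expect_true(all(which(out$is_ctc) %in% prev))
    prev <- which(out$is_ctc)
  }
  expect_error(detect_ctc_candidates(make_events(ck = 1:3)), "filter_dapi_low")
  ev0 <- make_events(ck = c(7, 7, 7)); ev0$retained <- TRUE
  expect_error(detect_ctc_candidates(ev0), "degenerate")
})

test_that("segmentation recovers planted WBCs one-to-one", {
  cfg <- sim_config(width = 512, height = 512, n_wbc = 50, n_epi_ctc = 0,
                    n_im_ctc = 0, n_lev = 0, n_debris = 0, n_pic = 0,
                    n_overlap = 0, n_gap_pair = 0, seed = 31)
  sim <- generate_slide(cfg)
  seg <- segment_nucleated_cells(sim$image)
  expect_equal(nrow(seg$events), 50L)
  m <- match_events(seg$events, sim$truth, max_dist_px = 2)
  expect_equal(nrow(m), 50L)
})

test_that("a blank slide yields zero segmented regions", {
  sim <- generate_slide(empty_sim_config(seed = 32))
  seg <- segment_nucleated_cells(sim$image)
  expect_equal(nrow(seg$events), 0L)
})

test_that("nuclei separated by background get distinct labels", {
  ch <- list(dapi = matrix(200, 64, 64), ck = matrix(200, 64, 64),
             cd45 = matrix(200, 64, 64))
  for (ctr in list(c(20, 32), c(35, 32))) {  # 3 px of background between
    px <- which((row(ch$dapi) - ctr[1])^2 + (col(ch$dapi) - ctr[2])^2 <= 36)
    ch$dapi[px] <- 3000
  }
  seg <- segment_nucleated_cells(slide_image(ch, 0.5))
  expect_equal(nrow(seg$events), 2L)
  expect_error(
    segment_nucleated_cells(slide_image(ch["ck"], 0.5)), "DAPI")
})

test_that("LEV size filter applies the equivalent-diameter cutoff at >=", {
  # pixel scale 0.5: 20 px -> 2.52 um (pass), 19 px -> 2.46 um (fail)
  ck <- matrix(200, 64, 64)
  ck[10:13, 10:14] <- 25000        # 20 px
  ck[30:48, 30] <- 25000           # 19 px (line; area is what matters)
  img <- slide_image(list(dapi = matrix(200, 64, 64), ck = ck), 0.5)
  expect_warning(
    out <- detect_lev_candidates(img, ck_threshold = 10000, dapi_cutoff = 1000),
    "brightfield")
  ev <- out$events[order(-out$events$area_px), ]
  expect_equal(ev$area_px, c(20, 19))
  expect_equal(ev$equiv_diameter_um, 2 * sqrt(c(20, 19) / pi) * 0.5)
  expect_equal(ev$size_excluded, c(FALSE, TRUE))
  expect_false(ev$ring_checked[1])
  expect_equal(ev$retained, c(TRUE, FALSE))
})

test_that("nucleus-level DAPI excludes CK+ cells from the LEV pool", {
  sim <- generate_slide(sim_config(width = 768, height = 768, n_wbc = 100,
                                   n_epi_ctc = 1, n_im_ctc = 0, n_lev = 2,
                                   n_debris = 2, n_pic = 0, n_overlap = 0,
                                   n_gap_pair = 0, seed = 33))
  det <- detect_events(sim$image)
  lev_truth <- sim$truth[sim$truth$kind == "lev", ]
  ctc_truth <- sim$truth[sim$truth$class == "epi_ctc", ]
  retained <- det$levs[det$levs$retained, ]
  m_ctc <- greedy_match_public(retained, ctc_truth)
  expect_equal(nrow(m_ctc), 0L)  # the CTC is a cell, not a LEV
  m_lev <- greedy_match_public(retained, lev_truth)
  expect_equal(nrow(m_lev), nrow(lev_truth))
  # debris rejected by size
  expect_true(all(det$levs$size_excluded[det$levs$area_px < 10]))
})

test_that("CD45 phenotype rule is anchored on WBCs with strict boundary", {
  wbc <- data.frame(q_cd45 = c(4000, 5000, 6000))  # mean 5000, sd 1000
  cfg <- detection_config(cd45_k = 2)              # cutoff 3000
  ev <- data.frame(q_cd45 = c(3000, 3000.1, 240, 5200))
  out <- classify_phenotype(ev, wbc, cfg)
  expect_equal(attr(out, "cd45_cutoff"), 3000)
  expect_equal(out$phenotype, c("epi", "im", "epi", "im"))
  expect_error(classify_phenotype(ev, wbc[1, , drop = FALSE], cfg),
               "insufficient")
})

test_that("end-to-end detection separates all planted classes", {
  cfg <- sim_config(width = 1024, height = 1024, n_wbc = 150, n_epi_ctc = 1,
                    n_im_ctc = 1, n_lev = 4, n_debris = 2, n_pic = 1,
                    n_overlap = 0, n_gap_pair = 0, seed = 34)
  sim <- generate_slide(cfg)
  det <- detect_events(sim$image)
  ev <- evaluate_detection(det, sim$truth)
  expect_true(all(ev$recall >= 0.9))
  expect_true(all(ev$precision >= 0.9))
  # nucleated vs non-nucleated partition: no event is both CTC and LEV
  ctc_xy <- det$cells[det$cells$retained & det$cells$is_ctc, c("cx", "cy")]
  lev_xy <- det$levs[det$levs$retained, c("cx", "cy")]
  if (nrow(ctc_xy) && nrow(lev_xy)) {
    d <- sqrt(outer(ctc_xy$cx, lev_xy$cx, "-")^2 +
              outer(ctc_xy$cy, lev_xy$cy, "-")^2)
    expect_gt(min(d), 3)
  }
})
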