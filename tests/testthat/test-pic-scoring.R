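disk_mask <- function(cx, cy, r, dim) {
  m <- matrix(0L, dim[1], dim[2])
  m[which((row(m) - cx)^2 + (col(m) - cy)^2 <= r^2)] <- 1L
  m
}

planted_pair_fixture <- function(seed = 5, relationship = "pic", fold = 2,
                                 arc = 60, noise = TRUE) {
  set.seed(seed)
  canvas <- blank_canvas(sim_config(width = 128, height = 128, n_wbc = 0,
                                    n_epi_ctc = 0, n_im_ctc = 0, n_lev = 0,
                                    n_debris = 0, n_pic = 0, n_overlap = 0,
                                    n_gap_pair = 0, seed = seed))
  canvas <- plant_pair(canvas, relationship, "epi_ctc", cx = 55, cy = 64,
                       orient = runif(1, 0, 2 * pi), r_wbc_px = 10,
                       r_tumor_px = 13, fold = fold, contact_arc_deg = arc)
  sim <- render_slide(canvas, noise = noise)
  dims <- dim(sim$image)
  list(sim = sim,
       wbc = truth_mask(sim$truth[1L, ], dims),
       partner = truth_mask(sim$truth[2L, ], dims))
}

test_that("perimeter extraction yields a closed, duplicate-free trace", {
  one <- matrix(0L, 5, 5); one[3, 3] <- 1L
  p <- extract_perimeter(one)
  expect_equal(nrow(p$coords), 1L)
  disk <- disk_mask(15, 15, 10, c(30, 30))
  p <- extract_perimeter(disk)
  expect_false(any(duplicated(p$coords)))
  # closed: consecutive (and wrap-around) positions are 8-adjacent
  steps <- rbind(diff(p$coords), p$coords[1, ] - p$coords[nrow(p$coords), ])
  expect_true(all(pmax(abs(steps[, 1]), abs(steps[, 2])) <= 1))
  # length agrees with brute-force boundary enumeration within 10%
  expect_lt(abs(nrow(p$coords) - boundary_count(disk)) / boundary_count(disk),
            0.1)
})

test_that("degenerate masks are rejected by perimeter extraction", {
  expect_error(extract_perimeter(matrix(0L, 5, 5)), "empty")
  two <- matrix(0L, 10, 10); two[2, 2] <- 1L; two[8, 8] <- 1L
  expect_error(extract_perimeter(two), "one connected")
  donut <- disk_mask(10, 10, 6, c(20, 20)) - disk_mask(10, 10, 2, c(20, 20))
  expect_error(extract_perimeter(donut), "multiply-connected")
})

test_that("contact labelling matches the planted arc and flags degeneracies", {
  fx <- planted_pair_fixture(seed = 6, arc = 60)
  prof <- extract_perimeter(fx$wbc)
  prof <- label_contact_regions(prof, fx$partner)
  expect_equal(sum(prof$region == "contact") + sum(prof$region == "non_contact"),
               nrow(prof$coords))
  expect_gt(prof$contact_fraction, 60 / 360 - 0.06)
  expect_lt(prof$contact_fraction, 60 / 360 + 0.06)
  # gap pair: no contact positions
  gx <- planted_pair_fixture(seed = 7, relationship = "gap")
  gprof <- extract_perimeter(gx$wbc)
  expect_error(label_contact_regions(gprof, gx$partner), "no contact")
  # engulfing partner: every position in contact
  small <- disk_mask(30, 30, 5, c(60, 60))
  big <- disk_mask(30, 30, 12, c(60, 60))
  expect_error(label_contact_regions(extract_perimeter(small), big),
               "all positions")
})

test_that("fold change is 1 for uniform rings and recovers planted folds", {
  ux <- planted_pair_fixture(seed = 8, relationship = "overlap")
  sc <- score_pic_pair(ux$wbc, ux$partner, get_channel(ux$sim$image, "cd45"))
  expect_lt(abs(sc$enrichment$fold_change - 1), 0.05)
  folds <- vapply(1:10, function(s) {
    fx <- planted_pair_fixture(seed = 100 + s, fold = 2)
    score_pic_pair(fx$wbc, fx$partner,
                   get_channel(fx$sim$image, "cd45"))$enrichment$fold_change
  }, numeric(1))
  expect_lt(abs(mean(folds) - 2) / 2, 0.1)
})

test_that("fold change is invariant under multiplicative intensity gain", {
  fx <- planted_pair_fixture(seed = 9, fold = 2)
  ch <- get_channel(fx$sim$image, "cd45")
  a <- score_pic_pair(fx$wbc, fx$partner, ch)$enrichment
  b <- score_pic_pair(fx$wbc, fx$partner, ch * 7.3)$enrichment
  expect_equal(a$fold_change, b$fold_change, tolerance = 1e-12)
  expect_equal(a$asymmetry, b$asymmetry, tolerance = 1e-12)
})

test_that("zero non-contact intensity raises the undefined-ratio error", {
  fx <- planted_pair_fixture(seed = 10, noise = FALSE)
  prof <- extract_perimeter(fx$wbc)
  prof <- label_contact_regions(prof, fx$partner)
  expect_error(enrichment_fold_change(prof, matrix(0, 128, 128)),
               "undefined-ratio")
})

test_that("asymmetry follows the resultant-vector oracle", {
  dim <- c(40, 40)
  mask <- disk_mask(20, 20, 10, dim)
  prof <- extract_perimeter(mask)
  prof <- label_contact_regions(prof, disk_mask(34, 20, 4, dim))
  # all intensity on one boundary pixel: direct vector-sum oracle
  ch <- matrix(0, dim[1], dim[2])
  target <- prof$coords[1, ]
  ch[target[1], target[2]] <- 1000
  enr <- enrichment_fold_change(prof, ch, band_width = 1)
  intens <- enr$trace$intensity
  dirs <- sweep(prof$coords, 2, prof$centroid)
  u <- dirs / sqrt(rowSums(dirs^2))
  oracle <- sqrt(sum(colSums(u * intens)^2)) / sum(intens)
  expect_equal(enr$asymmetry, oracle, tolerance = 1e-12)
  expect_gt(enr$asymmetry, 0.95)
  # uniform intensity: asymmetry near zero
  enr0 <- enrichment_fold_change(prof, matrix(100, dim[1], dim[2]))
  expect_lt(enr0$asymmetry, 0.05)
})

test_that("planted pairs are classified pic / passive_overlap / gap", {
  pic <- simulate_pair_folds(10, "pic", fold = 2, seed = 61)
  expect_true(all(pic$class == "pic"))
  ovl <- simulate_pair_folds(10, "overlap", seed = 62)
  expect_true(all(ovl$class == "passive_overlap"))
  gap <- simulate_pair_folds(4, "gap", seed = 63)
  expect_true(all(gap$class == "gap"))
  expect_error(classify_pic("overlap", NULL), "enrichment")
})

test_that("Mann-Whitney results match frozen worked examples", {
  m <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(m$U, 0)
  expect_equal(m$p_value, 0.1)
  expect_equal(m$method, "exact")
  # forced normal approximation on fully separated groups
  m2 <- mann_whitney(c(1, 2, 3), c(4, 5, 6), exact = FALSE)
  expect_equal(abs(m2$z), 4.5 / sqrt(5.25), tolerance = 1e-6)
  expect_equal(m2$r, abs(m2$z) / sqrt(6), tolerance = 1e-12)
  expect_equal(m2$r, 0.8018, tolerance = 1e-3)
  # all tied
  m3 <- mann_whitney(c(5, 5, 5), c(5, 5, 5))
  expect_equal(m3$p_value, 1)
  expect_equal(m3$r, 0)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney agrees with wilcox.test on both p-value paths", {
  set.seed(71)
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(8) + 0.5
    m <- mann_whitney(x, y)
    w <- wilcox.test(x, y, exact = TRUE)
    expect_equal(m$p_value, w$p.value, tolerance = 1e-12)
    expect_equal(m$U, unname(w$statistic))
    # tied data forces the corrected normal approximation in both
    xt <- round(rnorm(10)); yt <- round(rnorm(10) + 0.5)
    mt <- mann_whitney(xt, yt)
    wt <- suppressWarnings(wilcox.test(xt, yt, correct = TRUE))
    expect_equal(mt$p_value, wt$p.value, tolerance = 1e-10)
  }
})

test_that("U stays within [0, n1 n2] and flips under group exchange", {
  set.seed(72)
  for (i in 1:10) {
    x <- rnorm(sample(2:7, 1)); y <- rnorm(sample(2:7, 1))
    m <- mann_whitney(x, y); m2 <- mann_whitney(y, x)
    expect_gte(m$U, 0)
    expect_lte(m$U, m$n1 * m$n2)
    expect_equal(m$U + m2$U, m$n1 * m$n2)
    expect_equal(m$p_value, m2$p_value, tolerance = 1e-12)
  }
})
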