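test_that("positive_mask thresholds strictly inside the section", {
  sec <- disc_mask(21, 8)
  zero <- matrix(0, 21, 21)
  pm <- positive_mask(pixel_image(zero), sec, threshold = 10)
  expect_false(any(pm))

  img <- matrix(100, 21, 21)
  pm2 <- positive_mask(pixel_image(img), sec, threshold = 50)
  expect_identical(unclass(pm2), sec, ignore_attr = TRUE)

  # strictness at the threshold and exhaustive pixel-by-pixel agreement
  set.seed(4)
  img3 <- matrix(sample(c(40, 180), 21 * 21, replace = TRUE), 21)
  pm3 <- positive_mask(pixel_image(img3), sec, threshold = 40)
  expect_identical(as.vector(pm3), as.vector(sec & img3 > 40))

  expect_error(positive_mask(pixel_image(matrix(0, 5, 5)), sec), "shape")
})

test_that("depth_map matches the all-pairs nearest-background oracle", {
  # single-pixel mask: depth 1
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(depth_map(one)[3, 3], 1)

  # 5x5 block in a 9x9 frame: centre depth 3, corner depths 1
  blk <- matrix(FALSE, 9, 9); blk[3:7, 3:7] <- TRUE
  d <- depth_map(blk)
  expect_equal(d[5, 5], 3)
  expect_equal(d[3, 3], 1)
  expect_equal(d, brute_depth(blk))

  # disc: maximum depth within 1 px of the analytic radius
  dm <- disc_mask(101, 40)
  expect_lt(abs(max(depth_map(dm)) - 40), 1)

  expect_error(depth_map(matrix(FALSE, 4, 4)), "empty")
})

test_that("assign_regions partitions the mask at depths R/3 and 2R/3", {
  dm <- disc_mask(201, 90)
  rm <- assign_regions(dm)
  expect_equal(rm$max_depth_px, max(rm$depth_map))
  # a pixel at depth ~45 lies in the intermediate region
  idx <- which(abs(rm$depth_map - 45) < 0.5 & dm, arr.ind = TRUE)[1, ]
  expect_equal(rm$labels[idx[1], idx[2]], 2L)
  # partition: region union is exactly the mask, each pixel labelled once
  expect_identical(rm$labels > 0, dm)

  # brute-force equality on small irregular blobs
  for (s in 1:5) {
    blob <- random_blob(32, seed = s)
    expect_identical(assign_regions(blob)$labels, brute_regions(blob))
  }
})

test_that("uniform positive disc splits as the annulus-area ratios", {
  n <- 351
  sec <- disc_mask(n, 160)
  img <- matrix(0, n, n); img[sec] <- 200
  r <- radial_signal_distribution(pixel_image(img), sec, threshold = 100)
  expect_equal(r$pct_periphery, 100 * 5 / 9, tolerance = 0.02)
  expect_equal(r$pct_intermediate, 100 * 3 / 9, tolerance = 0.02)
  expect_equal(r$pct_core, 100 * 1 / 9, tolerance = 0.02)
  expect_equal(r$pct_periphery + r$pct_intermediate + r$pct_core, 100,
               tolerance = 1e-9)
})

test_that("radial distribution reproduces generator truth and flags empty signal", {
  # proliferation-rim emulation: quantification at the generation threshold
  # reproduces the recorded truth sums exactly
  rim <- function(f) 0.1 + 0.85 * (f <= 1 / 3)
  s <- gen_stained_section(70, depth_profile = rim, seed = 6)
  r <- radial_signal_distribution(s$image, s$mask,
                                  threshold = s$truth$params$threshold)
  expect_equal(unname(r$region_sums),
               unname(s$truth$params$region_pos_sums))
  expect_equal(r$total_positive_signal, s$truth$params$total_pos_sum)
  expect_equal(r$pct_periphery,
               100 * s$truth$params$region_pos_sums[["periphery"]] /
                 s$truth$params$total_pos_sum)

  # step profile: all positive signal in the periphery
  st <- gen_stained_section(60,
    depth_profile = function(f) as.numeric(f <= 1 / 3), seed = 2)
  rs <- radial_signal_distribution(st$image, st$mask,
                                   threshold = st$truth$params$threshold)
  expect_equal(rs$pct_periphery, 100)

  # no positive signal: flagged, not an error
  sec <- disc_mask(31, 12)
  dark <- matrix(0, 31, 31); dark[sec] <- 5
  r0 <- radial_signal_distribution(pixel_image(dark), sec, threshold = 50)
  expect_false(r0$defined)
  expect_true(is.na(r0$pct_periphery))
  expect_equal(r0$total_positive_signal, 0)
})

test_that("distribution is invariant under rotation and translation", {
  s <- gen_stained_section(50, depth_profile = function(f) 1 - 0.8 * f,
                           seed = 8)
  img <- unclass(s$image); sec <- s$mask$mask
  thr <- s$truth$params$threshold
  base <- radial_signal_distribution(pixel_image(img), sec, thr)

  rot90 <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
  r90 <- radial_signal_distribution(pixel_image(rot90(img)), rot90(sec), thr)
  r180 <- radial_signal_distribution(pixel_image(rot90(rot90(img))),
                                     rot90(rot90(sec)), thr)
  for (r in list(r90, r180)) {
    expect_equal(r$pct_periphery, base$pct_periphery)
    expect_equal(r$pct_intermediate, base$pct_intermediate)
    expect_equal(r$pct_core, base$pct_core)
  }

  # translate the section within a larger frame
  n <- nrow(img); big <- 2 * n
  place <- function(m, at, fill = 0) {
    out <- matrix(fill, big, big)
    out[at[1]:(at[1] + n - 1), at[2]:(at[2] + n - 1)] <- m
    out
  }
  t1 <- radial_signal_distribution(
    pixel_image(place(img, c(3, 3))), place(sec, c(3, 3), FALSE) > 0, thr)
  t2 <- radial_signal_distribution(
    pixel_image(place(img, c(40, 25))), place(sec, c(40, 25), FALSE) > 0, thr)
  expect_equal(t1$pct_periphery, t2$pct_periphery)
  expect_equal(t1$pct_core, t2$pct_core)
  expect_equal(t1$pct_periphery, base$pct_periphery)
})

test_that("raising the threshold never increases total positive signal", {
  s <- gen_stained_section(50, depth_profile = function(f) rep(0.5, length(f)),
                           seed = 10)
  totals <- vapply(seq(0, 250, by = 25), function(thr) {
    radial_signal_distribution(s$image, s$mask, threshold = thr)$
      total_positive_signal
  }, numeric(1))
  expect_true(all(diff(totals) <= 0))
})

test_that("binary mode counts pixels instead of summing intensities", {
  sec <- disc_mask(41, 18)
  img <- matrix(0, 41, 41); img[sec] <- 200
  rb <- radial_signal_distribution(pixel_image(img), sec, threshold = 100,
                                   binary = TRUE)
  rw <- radial_signal_distribution(pixel_image(img), sec, threshold = 100)
  expect_equal(rb$total_positive_signal, sum(sec))
  expect_equal(rw$total_positive_signal, 200 * sum(sec))
  # constant intensity: both modes give identical percentages
  expect_equal(rb$pct_periphery, rw$pct_periphery)
})
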