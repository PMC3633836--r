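test_that("generators are deterministic in (params, seed) and leave global RNG alone", {
  set.seed(999); before <- .Random.seed
  a <- gen_brightfield_spheroid(400, 1.25, 512L, noise_sd = 5, seed = 11)
  b <- gen_brightfield_spheroid(400, 1.25, 512L, noise_sd = 5, seed = 11)
  expect_identical(unclass(a$image), unclass(b$image))
  c <- gen_brightfield_spheroid(400, 1.25, 512L, noise_sd = 5, seed = 12)
  expect_false(identical(unclass(a$image), unclass(c$image)))

  s1 <- gen_stained_section(40, seed = 3)
  s2 <- gen_stained_section(40, seed = 3)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$truth$params, s2$truth$params)

  g1 <- gen_growth_series(1e6, 0.8, 0.2, days = 0:7, cv = 0.1, seed = 5)
  g2 <- gen_growth_series(1e6, 0.8, 0.2, days = 0:7, cv = 0.1, seed = 5)
  expect_identical(g1$data, g2$data)

  d1 <- gen_dose_response(10, concentrations = 10^(0:4), seed = 5)
  d2 <- gen_dose_response(10, concentrations = 10^(0:4), seed = 5)
  expect_identical(d1$data, d2$data)

  r1 <- gen_release(0.1, times = 0:10, noise_sd = 0.02, seed = 5)
  r2 <- gen_release(0.1, times = 0:10, noise_sd = 0.02, seed = 5)
  expect_identical(r1$data, r2$data)

  k1 <- gen_clonogenic(500, 0.8, 0.5, seed = 5)
  k2 <- gen_clonogenic(500, 0.8, 0.5, seed = 5)
  expect_identical(k1$record, k2$record)

  expect_identical(.Random.seed, before)
})

test_that("brightfield generator: noise-free geometry matches the stated diameter", {
  g <- gen_brightfield_spheroid(500, 1.25, 512L, edge_softness_px = 0,
                                noise_sd = 0, seed = 1)
  expect_equal(g$truth$params$radius_px, 200)
  expect_equal(g$truth$params$diameter_um, 500)
  m <- unclass(g$image)
  # dark pixel count equals the analytic disc area within pixelation error
  dark <- sum(m < 125)
  expect_lt(abs(dark - pi * 200^2) / (pi * 200^2), 0.01)
  # bright background, dark centre
  expect_gt(m[1, 1], 200)
  expect_lt(m[256, 256], 50)
})

test_that("brightfield generator rejects discs exceeding the frame", {
  expect_error(gen_brightfield_spheroid(500, 1.25, image_size_px = 256L),
               "exceeds")
})

test_that("stained section truth records exact per-region positive sums", {
  s <- gen_stained_section(60, depth_profile = function(f) rep(0.6, length(f)),
                           seed = 7)
  regions <- assign_regions(s$mask)
  img <- unclass(s$image)
  thr <- s$truth$params$threshold
  # with well-separated intensity distributions the generation threshold
  # recovers the generated positive pixels exactly
  sums <- vapply(1:3, function(k) {
    sum(img[regions$labels == k & img > thr])
  }, numeric(1))
  expect_equal(unname(s$truth$params$region_pos_sums), sums)
  expect_equal(s$truth$params$total_pos_sum, sum(sums))
})

test_that("stained section: degenerate depth profiles behave by construction", {
  # profile identically 0: no positive signal at all
  s0 <- gen_stained_section(40, depth_profile = function(f) rep(0, length(f)),
                            seed = 2)
  expect_equal(s0$truth$params$total_pos_sum, 0)
  expect_equal(s0$truth$params$n_positive, 0)

  # step profile: positive only in the outer third -> all signal peripheral
  st <- gen_stained_section(60,
    depth_profile = function(f) as.numeric(f <= 1 / 3), seed = 2)
  sums <- st$truth$params$region_pos_sums
  expect_gt(sums["periphery"], 0)
  expect_equal(unname(sums["intermediate"]), 0)
  expect_equal(unname(sums["core"]), 0)

  # uniformly positive disc: regional fractions equal annulus-area ratios
  # within pixelation error (areas 5/9, 3/9, 1/9 of the disc)
  su <- gen_stained_section(80,
    depth_profile = function(f) rep(1, length(f)),
    pos_intensity = c(180, 0), seed = 2)
  counts <- su$truth$params$region_pos_counts
  frac <- counts / sum(counts)
  expect_equal(unname(frac), c(5, 3, 1) / 9, tolerance = 0.05)

  expect_error(gen_stained_section(40, depth_profile = function(f) f * 2),
               "depth_profile")
})

test_that("growth generator lies on the Gompertz curve when noise-free", {
  days <- seq(0, 14, length.out = 8)
  g <- gen_growth_series(2e6, 0.9, 0.3, days = days, n_replicates = 3,
                         cv = 0, seed = 1)
  expected <- gompertz_volume(g$data$day, 2e6, 0.9, 0.3)
  expect_equal(g$data$volume_um3, expected)
  expect_equal(g$data$volume_um3[g$data$day == 0], rep(2e6, 3))
  # alpha/beta = ln(100) puts the plateau at exactly 100 x V0
  g2 <- gen_growth_series(1e5, log(100) * 0.5, 0.5, days = days, cv = 0,
                          seed = 1)
  expect_equal(g2$truth$params$plateau, 100 * 1e5)
})

test_that("dose-response generator hits the Hill identities", {
  concs <- c(0.01, 0.1, 1, 10, 100, 1000)
  p <- gen_dose_response(10, hill_slope = 1, bottom = 0,
                         concentrations = concs, noise_sd = 0, seed = 1)
  df <- p$data
  a_c <- mean(df$absorbance[df$role == "control"])
  a_m <- mean(df$absorbance[df$role == "media"])
  at_ic50 <- df$absorbance[df$role == "treatment" &
                             df$concentration_ng_ml == 10]
  expect_equal(normalize_viability(at_ic50, a_c, a_m), rep(50, 3))
  # far below the midpoint viability approaches the top plateau
  at_low <- df$absorbance[df$role == "treatment" &
                            df$concentration_ng_ml == 0.01]
  expect_equal(normalize_viability(at_low, a_c, a_m), rep(100, 3),
               tolerance = 1e-2)
  # resistant-culture emulation: bottom = 80 keeps viability near 80% at
  # saturating dose
  p80 <- gen_dose_response(10, bottom = 80, concentrations = concs,
                           noise_sd = 0, seed = 1)
  at_high <- p80$data$absorbance[p80$data$role == "treatment" &
                                   p80$data$concentration_ng_ml == 1000]
  expect_equal(normalize_viability(at_high, a_c, a_m), rep(80, 3),
               tolerance = 1e-2)
})

test_that("clonogenic generator follows the binomial colony model", {
  expect_equal(gen_clonogenic(500, 0.8, sf_true = 0, seed = 1)$record$colonies,
               0)
  expect_equal(gen_clonogenic(500, 1, sf_true = 1, seed = 1)$record$colonies,
               500)
  g <- gen_clonogenic(10000, 0.8, sf_true = 0.25, seed = 42)
  p <- 0.8 * 0.25
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(g$record$colonies / (10000 * 0.8) - 0.25), 3 * se / 0.8)
})

test_that("release generator: first-order profile and half-life construction", {
  times <- c(0, 2, 4, 6, 8, 12, 24)
  r <- gen_release(k = log(2) / 6, f_inf = 1, times = times, noise_sd = 0,
                   seed = 1)
  expect_equal(r$data$cumulative_fraction[r$data$time_h == 0], 0)
  expect_equal(r$data$cumulative_fraction[r$data$time_h == 6], 0.5)
  r_long <- gen_release(k = 1, f_inf = 0.9, times = c(0, 50), noise_sd = 0,
                        seed = 1)
  expect_equal(r_long$data$cumulative_fraction[2], 0.9, tolerance = 1e-12)
  # monotone enforcement
  rn <- gen_release(0.2, 1, times = 0:24, noise_sd = 0.1, monotone = TRUE,
                    seed = 3)
  expect_true(all(diff(rn$data$cumulative_fraction) >= 0))
  expect_true(all(rn$data$cumulative_fraction >= 0 &
                    rn$data$cumulative_fraction <= 1))
})
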