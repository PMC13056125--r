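circle_track <- function(rho, k, radius = 1.25) {
  ang <- seq(0, 2 * pi, length.out = k + 1)
  tracked_platelet(t = seq_len(k + 1), x = rho * cos(ang), y = rho * sin(ang),
                   orientation = rep(0, k + 1), radius = radius)
}

test_that("displacement series accumulates Euclidean path length", {
  still <- tracked_platelet(1:10, rep(0, 10), rep(0, 10), rep(0, 10))
  expect_true(all(displacement_series(still) == 0))
  line <- tracked_platelet(1:10, 0:9, rep(0, 10), rep(0, 10))
  expect_equal(displacement_series(line), 0:9)
  # chord sum of a k-gon approaches the circumference
  circ <- circle_track(5, 200)
  final <- tail(displacement_series(circ), 1)
  expect_lt(abs(final - 2 * pi * 5) / (2 * pi * 5), 0.01)
})

test_that("rotation unwrapping resolves wrap jumps by minimal change", {
  const <- tracked_platelet(1:10, 0:9, rep(0, 10), rep(45, 10))
  expect_true(all(rotation_series(const) == 0))
  steady <- tracked_platelet(1:37, 0:36, rep(0, 37),
                             ((10 * (0:36) + 180) %% 360) - 180)
  expect_equal(tail(rotation_series(steady), 1), 2 * pi, tolerance = 1e-9)
  # brute-force oracle: pick the +/-360 k branch of minimal absolute change
  set.seed(31)
  raw <- cumsum(rnorm(50, 8, 25))
  wrapped <- ((raw + 180) %% 360) - 180
  tr <- tracked_platelet(1:50, 0:49, rep(0, 50), wrapped)
  got <- diff(rotation_series(tr)) * 180 / pi
  oracle <- vapply(diff(wrapped), function(d) {
    cand <- d + c(-360, 0, 360)
    cand[which.min(abs(cand))]
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-9)
  # no 2 pi jumps survive unwrapping
  expect_true(all(abs(got) < 180))
})

test_that("reversing a track negates the accumulated rotation", {
  tr <- gen_track(track_spec("rolling", slip = 0.8), seed = 6)
  rev_tr <- tracked_platelet(tr$t, rev(tr$x), rev(tr$y), rev(tr$orientation),
                             radius = tr$radius)
  expect_equal(tail(rotation_series(rev_tr), 1),
               -tail(rotation_series(tr), 1), tolerance = 1e-9)
})

test_that("rolling index separates rolling from sliding and handles degeneracy", {
  expect_equal(rolling_index(gen_track(track_spec("rolling", slip = 1))), 1,
               tolerance = 1e-12)
  expect_equal(rolling_index(gen_track(track_spec("sliding"))), 0)
  noisy <- gen_track(track_spec("rolling", noise_sd_angle = 2), seed = 17)
  ri <- rolling_index(noisy)
  expect_gt(ri, 0.85); expect_lt(ri, 1.15)
  still <- tracked_platelet(1:5, rep(0, 5), rep(0, 5), rep(0, 5))
  expect_true(is.na(rolling_index(still)))
  expect_identical(classify_motion(still), "unclassified")
})

test_that("rolling index is invariant under rigid motions of the lab frame", {
  tr <- gen_track(track_spec("rolling", slip = 0.7, noise_sd_pos = 0.05,
                             noise_sd_angle = 1), seed = 9)
  ri0 <- rolling_index(tr)
  phi <- 0.83
  moved <- tracked_platelet(tr$t,
                            cos(phi) * tr$x - sin(phi) * tr$y + 12,
                            sin(phi) * tr$x + cos(phi) * tr$y - 7,
                            tr$orientation + phi * 180 / pi,
                            radius = tr$radius)
  expect_equal(rolling_index(moved), ri0, tolerance = 1e-12)
})

test_that("motion classification recovers the generator's kind at zero noise", {
  kinds <- rep(c("rolling", "sliding"), 100)
  got <- vapply(seq_along(kinds), function(i)
    classify_motion(gen_track(track_spec(kinds[i]), seed = i)), character(1))
  expect_identical(got, kinds)
  # threshold boundary counts as rolling: an index exactly at the threshold
  half <- gen_track(track_spec("rolling", slip = 0.5))
  expect_equal(rolling_index(half), 0.5, tolerance = 1e-12)
  expect_identical(classify_motion(half, threshold = rolling_index(half)),
                   "rolling")
})

test_that("group rolling ratios follow the Katz interval and its edge cases", {
  a <- group_motion_stats(lapply(1:10, function(i)
    gen_track(track_spec("rolling"), seed = i)), "spherical")
  expect_equal(a$rolling_fraction, 1)
  mk <- function(n, k) structure(list(group = "g", n = n, n_rolling = k,
                                      rolling_fraction = k / n),
                                 class = "group_motion_stats")
  r <- group_rolling_ratio(mk(100, 70), mk(100, 20))
  expect_equal(r$ratio, 3.5)
  expect_false(r$undefined)
  expect_true(r$ci_lower < 3.5 && 3.5 < r$ci_upper)
  same <- group_rolling_ratio(mk(50, 20), mk(50, 20))
  expect_equal(same$ratio, 1)
  expect_true(group_rolling_ratio(mk(50, 20), mk(50, 0))$undefined)
})

test_that("velocity trend reads the sign of the speed slope", {
  acc <- tracked_platelet(0:20, cumsum(c(0, seq(0.1, 2, length.out = 20))),
                          rep(0, 21), rep(0, 21))
  expect_identical(velocity_trend(acc), "accelerating")
  steady <- tracked_platelet(0:20, seq(0, 20, by = 1), rep(0, 21), rep(0, 21))
  expect_identical(velocity_trend(steady), "steady")
  dec <- vapply(1:20, function(i)
    velocity_trend(gen_track(track_spec("sliding",
                                        speed_profile = "decelerating"),
                             seed = i)), character(1))
  expect_true(all(dec == "decelerating"))
})

test_that("discoid fraction series tracks per-frame counts and phases", {
  all_d <- data.frame(t_min = 0:5, n_discoid = 10, n_total = 10)
  expect_true(all(discoid_fraction_series(all_d)$discoid_fraction == 1))
  alt <- data.frame(t_min = 0:5, n_discoid = 5, n_total = 10)
  expect_true(all(discoid_fraction_series(alt)$discoid_fraction == 0.5))
  miss <- data.frame(t_min = 0:2, n_discoid = c(5, 0, 5), n_total = c(10, 0, 10))
  expect_true(is.na(discoid_fraction_series(miss)$discoid_fraction[2]))

  # binomial sampling around the spherification/recovery time course
  truth <- gen_shape_kinetics(kinetics_spec())
  counts <- sample_shape_labels(truth, 500, seed = 12)
  ser <- discoid_fraction_series(counts, switch_times = c(30, 60))
  at <- function(t) ser$discoid_fraction[ser$t_min == t]
  expect_lt(abs(at(0) - 0.90), 0.03)
  expect_lte(at(30), 0.13)
  expect_lt(abs(at(120) - 0.65), 0.04)
  expect_identical(unique(ser$phase[ser$t_min < 30]), "treatment")
  expect_identical(unique(ser$phase[ser$t_min >= 60]), "recovery")
})

test_that("aspect-ratio shape classification uses the >= cutoff convention", {
  expect_identical(classify_shape(1.0), "spherical")
  expect_identical(classify_shape(2.0), "discoid")
  expect_identical(classify_shape(1.3), "discoid")
  expect_error(classify_shape(0.8), ">= 1")
})

test_that("conformational switch timing: 15 nm at 0.8 um/s takes 18.75 ms", {
  expect_equal(conformational_switch_time(15, 0.8), 18.75)
  expect_equal(conformational_switch_time(0, 1), 0)
})
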