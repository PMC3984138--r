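test_that("integer counts reproduce all preset association levels", {
  hi <- solve_counts(0.7477, 0.8557, 111)
  expect_equal(hi[c("m_shared", "n_ch1", "n_ch2")],
               list(m_shared = 83L, n_ch1 = 111L, n_ch2 = 97L),
               ignore_attr = TRUE)
  mid <- solve_counts(0.5225, 0.4715, 111)
  expect_equal(unlist(mid[1:3]), c(m_shared = 58, n_ch1 = 111, n_ch2 = 123))
  lo <- solve_counts(0.2072, 0.2805, 111)
  expect_equal(unlist(lo[1:3]), c(m_shared = 23, n_ch1 = 111, n_ch2 = 82))
  # all six fractions exact to 4 decimals
  for (cnt in list(hi, mid, lo)) {
    expect_equal(round(cnt$achieved_ch1, 4),
                 round(cnt$m_shared / cnt$n_ch1, 4))
    expect_equal(round(cnt$achieved_ch2, 4),
                 round(cnt$m_shared / cnt$n_ch2, 4))
  }
  full <- solve_counts(1, 1, 50)
  expect_equal(unlist(full[1:3]), c(m_shared = 50, n_ch1 = 50, n_ch2 = 50))
})

test_that("unreachable targets report the nearest achievable fractions", {
  expect_error(solve_counts(0.12345, 0.9, 10, window = 2),
               "nearest achievable")
})

test_that("ground-truth association is exact by construction", {
  for (sc_name in names(scenario_presets())) {
    tgt <- scenario_presets()[[sc_name]]
    p <- sim_params(assoc_ch1 = tgt[1], assoc_ch2 = tgt[2], seed = 99)
    scene <- generate_scene(p, render = FALSE)
    m <- nrow(scene$gt_shared)
    expect_equal(round(m / (m + nrow(scene$gt_unique_ch1)), 4),
                 unname(tgt[1]))
    expect_equal(round(m / (m + nrow(scene$gt_unique_ch2)), 4),
                 unname(tgt[2]))
  }
})

test_that("degenerate settings give coincident channels", {
  p <- sim_params(assoc_ch1 = 1, assoc_ch2 = 1, n_base = 30,
                  shift_magnitude = 0, jitter_sigma = 0, seed = 5,
                  image_size = c(128, 128))
  scene <- generate_scene(p, render = TRUE)
  expect_equal(unclass(scene$ch1), unclass(scene$ch2),
               ignore_attr = TRUE)
  expect_false(isTRUE(all.equal(scene$images$ch1, scene$images$ch2)))
})

test_that("the applied shift separates every true pair exactly", {
  p <- sim_params(shift_magnitude = 3, jitter_sigma = 0, seed = 31)
  scene <- generate_scene(p, render = FALSE)
  dif <- scene$ch2[scene$true_pairs[, 2], ] -
    scene$ch1[scene$true_pairs[, 1], ]
  expect_equal(sqrt(rowSums(dif^2)), rep(3, nrow(dif)),
               ignore_attr = TRUE, tolerance = 1e-9)
  # one common direction
  expect_lt(max(dif[, 1]) - min(dif[, 1]), 1e-9)
  expect_equal(unname(sqrt(sum(as.numeric(scene$applied_shift)^2))), 3)
})

test_that("jitter statistics match the requested deviation", {
  p <- sim_params(n_base = 1100, assoc_ch1 = 1, assoc_ch2 = 1,
                  image_size = c(512, 512), shift_magnitude = 2,
                  jitter_sigma = 1.5, seed = 77)
  scene <- generate_scene(p, render = FALSE)
  res <- scene$ch2[scene$true_pairs[, 2], ] -
    scene$ch1[scene$true_pairs[, 1], ] -
    matrix(as.numeric(scene$applied_shift), nrow(scene$true_pairs), 2,
           byrow = TRUE)
  expect_gte(nrow(res), 1000)
  expect_equal(sd(res[, 1]), 1.5, tolerance = 0.05 * 1.5)
  expect_equal(sd(res[, 2]), 1.5, tolerance = 0.05 * 1.5)
})

test_that("the matcher recovers the applied shift from ground truth", {
  for (L in c(1, 2, 3)) {
    p <- sim_params(shift_magnitude = L, jitter_sigma = 0,
                    seed = 40 + L)
    scene <- generate_scene(p, render = FALSE)
    M <- ppm_match(scene$ch1, scene$ch2, ppm_params(delta = 2))
    expect_true(M$accepted)
    expect_lt(point_distance(as.numeric(M$translation),
                             as.numeric(scene$applied_shift)), 2)
  }
})

test_that("identical seeds reproduce scenes bitwise", {
  p <- sim_params(shift_magnitude = 2, jitter_sigma = 1, seed = 123)
  s1 <- generate_scene(p, render = TRUE)
  s2 <- generate_scene(p, render = TRUE)
  expect_identical(unclass(s1$ch1), unclass(s1$ch1))
  expect_identical(s1$images$ch1, s2$images$ch1)
  expect_identical(as.numeric(s1$applied_shift),
                   as.numeric(s2$applied_shift))
})

test_that("grids enumerate the full factorial design", {
  g <- generate_grid(replicates = 1, shifts = 0, sigmas = 0,
                     scenarios = "high")
  expect_length(g, 1)
  g2 <- generate_grid(replicates = 2, shifts = c(0, 3),
                      sigmas = c(0, 1), scenarios = c("high", "low"),
                      seed = 9)
  expect_length(g2, 2 * 2 * 2 * 2)
  g3 <- generate_grid(replicates = 2, shifts = c(0, 3),
                      sigmas = c(0, 1), scenarios = c("high", "low"),
                      seed = 9)
  s_a <- realize_scene(g2[[5]])
  s_b <- realize_scene(g3[[5]])
  expect_identical(unclass(s_a$ch1), unclass(s_b$ch1))
})

test_that("overfull images are refused", {
  expect_error(generate_scene(sim_params(n_base = 400, assoc_ch1 = 1,
                                         assoc_ch2 = 1,
                                         image_size = c(32, 32),
                                         seed = 1), render = FALSE),
               "too small")
})

test_that("time-lapse objects diffuse at the requested step size", {
  tl <- simulate_timelapse(n_objects = 200, n_frames = 6,
                           step_sigma = 0.8, image_size = c(512, 512),
                           render = FALSE, seed = 55)
  steps <- do.call(rbind, lapply(2:6, function(f)
    tl$tracks[[f]] - tl$tracks[[f - 1]]))
  expect_equal(sd(steps[, 1]), 0.8, tolerance = 0.05 * 0.8)
  expect_equal(sd(steps[, 2]), 0.8, tolerance = 0.05 * 0.8)
  # static movie when the step is zero
  tl0 <- simulate_timelapse(n_objects = 10, n_frames = 3,
                            step_sigma = 0, image_size = c(64, 64),
                            render = FALSE, seed = 56)
  expect_identical(tl0$tracks[[1]], tl0$tracks[[3]])
})

test_that("scenes serialize to TIFF, CSV and JSON", {
  p <- sim_params(n_base = 20, assoc_ch1 = 0.8, assoc_ch2 = 0.8,
                  image_size = c(96, 96), seed = 2)
  scene <- generate_scene(p, render = TRUE)
  tp <- withr::local_tempfile(fileext = ".tif")
  cp <- withr::local_tempfile(fileext = ".csv")
  jp <- withr::local_tempfile(fileext = ".json")
  write_scene(scene, tp, cp, jp)
  expect_length(tiff::readTIFF(tp, all = TRUE), 2)
  df <- read.csv(cp)
  expect_equal(names(df), c("x", "y", "channel", "shared_id"))
  expect_equal(sum(df$channel == 1), nrow(scene$ch1))
  js <- jsonlite::read_json(jp)
  expect_equal(js$counts$m_shared, scene$counts$m_shared)
})
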