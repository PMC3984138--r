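test_that("bias is zero for symmetric residuals and one for directed ones", {
  P <- point_set(c(0, 10), c(0, 0))
  delta <- 2
  # perfect alignment
  Q <- P
  expect_equal(matching_bias(rbind(c(1, 1), c(2, 2)), P, Q,
                             translation(0, 0), delta), 0)
  # residuals (+delta, 0) and (-delta, 0) cancel
  Q2 <- point_set(c(0 + delta, 10 - delta), c(0, 0))
  expect_equal(matching_bias(rbind(c(1, 1), c(2, 2)), P, Q2,
                             translation(0, 0), delta), 0)
  # all residuals equal to (delta, 0)
  Q3 <- point_set(c(0 + delta, 10 + delta), c(0, 0))
  expect_equal(matching_bias(rbind(c(1, 1), c(2, 2)), P, Q3,
                             translation(0, 0), delta), 1)
  expect_error(matching_bias(matrix(integer(0), ncol = 2), P, Q,
                             translation(0, 0), delta), "empty")
})

test_that("a single candidate translation is evaluated faithfully", {
  set.seed(5)
  P <- point_set(runif(12, 0, 100), runif(12, 0, 100))
  Q <- translate_points(P, c(2, 1))
  prm <- ppm_params(delta = 0.5, max_translation = 3)
  M <- try_translation(P, Q, c(2, 1), prm)
  expect_equal(nrow(M$pairs), 12)
  expect_equal(M$bias, 0)
  expect_true(M$accepted)
  validate_matching(M, P, Q, prm)
  # wrong translation: no point within delta
  M0 <- try_translation(P, Q, c(0, 0), prm)
  expect_equal(nrow(M0$pairs), 0)
  expect_false(M0$accepted)
  # empty inputs give an empty, non-accepted matching
  E <- point_set(numeric(0), numeric(0))
  expect_false(try_translation(E, Q, c(0, 0), prm)$accepted)
})

test_that("one evaluated translation equals the brute-force assignment", {
  set.seed(31)
  for (case in 1:25) {
    fix <- planted_sets(5, shift = c(1.5, -1), jitter = 0.3,
                        extra_q = 1, span = 60)
    prm <- ppm_params(delta = 1.5, max_translation = 5, k = 8,
                      alpha = 0, max_bias = Inf)
    M <- try_translation(fix$P, fix$Q, c(1.5, -1), prm)
    # edges of the threshold graph at this translation, brute force
    edges <- NULL
    for (a in seq_len(nrow(fix$P))) {
      for (b in seq_len(nrow(fix$Q))) {
        d <- sqrt((fix$P[a, 1] + 1.5 - fix$Q[b, 1])^2 +
                    (fix$P[a, 2] - 1 - fix$Q[b, 2])^2)
        if (d <= 1.5) edges <- rbind(edges, c(a, b))
      }
    }
    expect_equal(nrow(M$pairs),
                 brute_max_matching(edges, nrow(fix$P), nrow(fix$Q)))
  }
})

test_that("the matcher recovers a planted correspondence", {
  set.seed(9)
  fix <- planted_sets(30, shift = c(1.5, -2), jitter = 0.1,
                      extra_p = 3, extra_q = 5)
  prm <- ppm_params(delta = 1, max_translation = 3)
  M <- ppm_match(fix$P, fix$Q, prm)
  expect_true(M$accepted)
  expect_equal(nrow(M$pairs), 30)
  # recovered translation within delta of the true shift
  expect_lt(point_distance(as.numeric(M$translation), c(1.5, -2)), 1)
  # every recovered pair is a true correspondence
  expect_true(all(M$pairs[, 1] == M$pairs[, 2]))
  validate_matching(M, fix$P, fix$Q, prm)
})

test_that("no match is reported for incompatible clouds", {
  set.seed(13)
  P <- point_set(runif(20, 0, 50), runif(20, 0, 50))
  Q <- point_set(runif(20, 500, 550), runif(20, 500, 550))
  M <- ppm_match(P, Q, ppm_params(delta = 1, max_translation = 3))
  expect_false(M$accepted)
  expect_equal(nrow(M$pairs), 0)
})

test_that("large normal clouds with missing points match at the kept fraction", {
  # 300 points, each surviving to the other set with probability 0.8,
  # moderate jitter well below delta
  set.seed(17)
  base <- cbind(rnorm(300, 0, 40), rnorm(300, 0, 40))
  keep <- runif(300) < 0.8
  Q <- base[keep, , drop = FALSE] +
    matrix(rnorm(2 * sum(keep), 0, 0.2), ncol = 2)
  Q <- sweep(Q, 2, -c(2, 1))
  P <- point_set(base)
  Qs <- point_set(Q)
  M <- ppm_match(P, Qs, ppm_params(delta = 1.5, max_translation = 3))
  expect_true(M$accepted)
  # matched fraction of the smaller set close to 1 (all survivors pair)
  expect_gt(nrow(M$pairs) / sum(keep), 0.95)
  # essentially all matched pairs are true correspondences
  correct <- M$pairs[, 2] == match(M$pairs[, 1], which(keep))
  expect_gt(mean(correct, na.rm = TRUE), 0.95)
  # matched fraction of the full set tracks the realized survival rate
  expect_equal(nrow(M$pairs) / nrow(P), sum(keep) / 300,
               tolerance = 0.02)
})

test_that("matcher cardinality equals exhaustive search on small instances", {
  set.seed(23)
  prm <- ppm_params(delta = 1, alpha = 0, max_bias = Inf,
                    max_translation = 100, k = 10)
  for (case in 1:50) {
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    P <- point_set(runif(n, 0, 12), runif(n, 0, 12))
    Q <- point_set(runif(m, 0, 12), runif(m, 0, 12))
    M <- ppm_match(P, Q, prm)
    expect_equal(nrow(M$pairs),
                 brute_ppm_cardinality(P, Q, delta = 1,
                                       max_translation = 100))
  }
})

test_that("association is invariant to common and compensable shifts", {
  set.seed(27)
  fix <- planted_sets(25, shift = c(0, 0), jitter = 0, extra_q = 4)
  prm <- ppm_params(delta = 1, max_translation = 3)
  a0 <- association(fix$P, fix$Q, prm)
  # common shift of both channels
  v <- c(17.3, -42.1)
  a1 <- association(translate_points(fix$P, v),
                    translate_points(fix$Q, v), prm)
  expect_equal(a1$assoc_ch1, a0$assoc_ch1)
  expect_equal(a1$assoc_ch2, a0$assoc_ch2)
  # channel-2-only shift within the allowed translation magnitude
  for (mag in c(0.5, 1.5, 2.9)) {
    a2 <- association(fix$P, translate_points(fix$Q, c(mag, 0)), prm)
    expect_equal(a2$assoc_ch1, a0$assoc_ch1)
  }
})

test_that("matching cardinality is symmetric on planted data", {
  set.seed(29)
  fix <- planted_sets(20, shift = c(2, -1), jitter = 0,
                      extra_p = 4, extra_q = 6)
  prm <- ppm_params(delta = 1, max_translation = 3)
  M12 <- ppm_match(fix$P, fix$Q, prm)
  M21 <- ppm_match(fix$Q, fix$P, prm)
  expect_equal(nrow(M12$pairs), nrow(M21$pairs))
})

test_that("association handles identical and empty channels", {
  P <- point_set(c(1, 5, 9), c(1, 5, 9))
  a <- association(P, P, ppm_params(delta = 1))
  expect_equal(a$assoc_ch1, 1)
  expect_equal(a$assoc_ch2, 1)
  E <- point_set(numeric(0), numeric(0))
  a0 <- association(P, E)
  expect_equal(a0$assoc_ch1, 0)
  expect_equal(a0$assoc_ch2, 0)
})

test_that("preset-style integer construction yields the preset fractions", {
  set.seed(33)
  # 83 shared objects of 111 in channel 1 and 97 in channel 2
  fix <- planted_sets(83, shift = c(1, 1), jitter = 0,
                      extra_p = 28, extra_q = 14, span = 400)
  a <- association(fix$P, fix$Q, ppm_params(delta = 1, max_translation = 3))
  expect_equal(round(a$assoc_ch1, 4), 0.7477)
  expect_equal(round(a$assoc_ch2, 4), 0.8557)
})

test_that("accepted matchings always satisfy their constraints", {
  set.seed(37)
  for (case in 1:20) {
    fix <- planted_sets(sample(10:40, 1), shift = runif(2, -2, 2),
                        jitter = runif(1, 0, 1),
                        extra_p = sample(0:10, 1),
                        extra_q = sample(0:10, 1))
    prm <- ppm_params(delta = 2, alpha = 0.3, max_bias = 0.2,
                      max_translation = 3)
    M <- ppm_match(fix$P, fix$Q, prm)
    if (M$accepted) {
      validate_matching(M, fix$P, fix$Q, prm)
      expect_gte(nrow(M$pairs),
                 prm$alpha * min(nrow(fix$P), nrow(fix$Q)))
      expect_lte(M$bias, prm$max_bias)
      expect_lte(translation_magnitude(M$translation),
                 prm$max_translation)
    }
  }
})
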