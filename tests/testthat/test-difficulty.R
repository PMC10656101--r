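test_that("serial paths share time equally and swap with the stimuli", {
  pars <- ref_difficulty_params()
  # variance of a driftless serial DV is half of elapsed real time
  zero <- difficulty_params(kappa = 1e-6, bound = ref_bound(),
                            tnd_mean = 0.35)
  ends <- vapply(1:400, function(i) {
    pth <- serial_dv_paths(zero, list(c1 = 0, c2 = 0), dt = 0.005,
                           horizon = 2, seed = i)
    c(pth$dv1[nrow(pth)], pth$dv2[nrow(pth)])
  }, numeric(2))
  expect_equal(var(ends[1, ]), 1, tolerance = 0.25)   # t/2 = 1 at t = 2
  expect_equal(var(ends[2, ]), 1, tolerance = 0.25)
  # same rng stream, different drift: the noise cancels in the path
  # difference, leaving exactly the drift gap times the sampled time
  a <- serial_dv_paths(pars, list(c1 = 0.64, c2 = 0), seed = 42)
  b <- serial_dv_paths(pars, list(c1 = -0.256, c2 = 0), seed = 42)
  n <- nrow(a)
  sampled_t <- n %/% 2 * 0.005 + (n %% 2) * 0.005  # S1 time at the end
  expect_equal(a$dv1[n] - b$dv1[n],
               pars$kappa * (0.64 - (-0.256)) * sampled_t, tolerance = 1e-8)
  expect_equal(a$dv2, b$dv2, tolerance = 1e-12)
})

test_that("race model favors the stronger stimulus and speeds up with it", {
  pars <- ref_difficulty_params()
  easy <- simulate_difficulty("race", pars, pair_block(0.64, 0, 4000),
                              seed = 1)
  expect_gt(mean(easy$choice == "S1"), 0.9)
  grid <- c(0, 0.256, 0.64)
  rts <- sapply(grid, function(s2)
    mean(simulate_difficulty("race", pars, pair_block(0.64, s2, 3000),
                             seed = 100 + round(1000 * s2))$rt))
  expect_true(all(diff(rts) < 0))  # RT decreases as S2 gets stronger
})

test_that("difference model shows symmetry, magnitude effect, criss-cross", {
  pars <- ref_difficulty_params()
  eq <- simulate_difficulty("difference", pars, pair_block(0.384, -0.384, 4000),
                            seed = 2)
  expect_equal(mean(eq$choice == "S1"), 0.5, tolerance = 0.025)
  hh <- mean(simulate_difficulty("difference", pars, pair_block(0, 0, 4000),
                                 seed = 3)$rt)
  ee <- mean(simulate_difficulty("difference", pars,
                                 pair_block(0.64, 0.64, 4000), seed = 4)$rt)
  he <- mean(simulate_difficulty("difference", pars, pair_block(0, 0.64, 4000),
                                 seed = 5)$rt)
  eh <- mean(simulate_difficulty("difference", pars, pair_block(0.64, 0, 4000),
                                 seed = 6)$rt)
  expect_gt(hh, ee)        # magnitude effect
  expect_lt(he, hh)        # criss-cross, hard-S1 end
  expect_gt(ee, eh)        # criss-cross, easy-S1 end
})

test_that("two-step model needs b_mini and respects the 2 s collapse", {
  pars <- ref_difficulty_params()
  expect_error(simulate_difficulty("two_step", pars, pair_block(0, 0, 5)),
               "b_mini")
  # unreachable mini-bound: mini-decision forced at the 2 s collapse
  big <- ref_difficulty_params(b_mini = 50)
  sim <- simulate_difficulty("two_step", big, pair_block(0, 0, 300), seed = 7)
  expect_true(all(sim$t_mini[!is.na(sim$t_mini)] >= 2))
  expect_true(all(sim$decision_time >= sim$t_mini, na.rm = TRUE))
  # small mini-bound: signs fixed early; the S1-first alternation leaves a
  # slight S1 edge on equal-strength pairs, so the tolerance is loose
  tiny <- ref_difficulty_params(b_mini = 0.2)
  s2 <- simulate_difficulty("two_step", tiny, pair_block(0.256, -0.256, 4000),
                            seed = 8)
  expect_equal(mean(s2$choice == "S1"), 0.5, tolerance = 0.06)
  expect_lt(median(s2$t_mini), 0.3)
})

test_that("absolute model accumulates non-negative increasing DVs", {
  pars <- ref_difficulty_params()
  eq <- simulate_difficulty("absolute", pars, pair_block(0.128, -0.128, 4000),
                            seed = 9)
  expect_equal(mean(eq$choice == "S1"), 0.5, tolerance = 0.025)
})

test_that("left/right exchange flips choices and keeps RTs (all models)", {
  pars <- ref_difficulty_params(b_mini = 0.8)
  for (model in c("race", "difference", "two_step", "absolute")) {
    ab <- simulate_difficulty(model, pars, pair_block(0.512, 0.128, 2500),
                              seed = 20)
    ba <- simulate_difficulty(model, pars, pair_block(0.128, 0.512, 2500),
                              seed = 21)
    p1 <- mean(ab$choice == "S1")
    p2 <- mean(ba$choice == "S2")
    se <- sqrt(p1 * (1 - p1) / 2500 + p2 * (1 - p2) / 2500)
    expect_lt(abs(p1 - p2), 4 * max(se, 0.005))
    expect_gt(suppressWarnings(ks.test(ab$rt, ba$rt))$p.value, 0.001)
  }
})

test_that("color-flip leaves unknown-color models invariant", {
  pars <- ref_difficulty_params()
  a <- simulate_difficulty("difference", pars, pair_block(0.384, -0.128, 3000),
                           seed = 22)
  b <- simulate_difficulty("difference", pars, pair_block(-0.384, 0.128, 3000),
                           seed = 23)
  expect_equal(mean(a$choice == "S1"), mean(b$choice == "S1"),
               tolerance = 0.035)
  expect_gt(suppressWarnings(ks.test(a$rt, b$rt))$p.value, 0.001)
})

test_that("known-color statistic depends on the pair only through delta-C", {
  pars <- ref_difficulty_params()
  a <- simulate_difficulty("known", pars, pair_block(0.128, 0, 8000),
                           seed = 24)
  b <- simulate_difficulty("known", pars, pair_block(0.64, 0.512, 8000),
                           seed = 25)
  expect_lt(suppressWarnings(ks.test(a$rt, b$rt))$statistic, 0.03)
  expect_equal(mean(a$choice == "S1"), mean(b$choice == "S1"),
               tolerance = 0.04)
})

test_that("serial and parallel integration agree under the derived mapping", {
  pars <- difficulty_params(kappa = 10, bound = collapsing_bound(2, 1, 1.5),
                            tnd_mean = 0.35, tnd_sd = 0)
  pp <- pair_block(0.256, -0.128, 20000)
  s <- simulate_difficulty("difference", pars, pp, seed = 26)
  p <- simulate_difficulty("difference", serial_to_parallel(pars), pp,
                           serial = FALSE, seed = 27)
  expect_lt(suppressWarnings(ks.test(s$rt, p$rt))$statistic, 0.02)
  # the naive exponent-1 reading (kappa/2, 2u) is not equivalent
  p1 <- simulate_difficulty("difference", serial_to_parallel(pars, 1), pp,
                            serial = FALSE, seed = 28)
  expect_gt(suppressWarnings(ks.test(s$rt, p1$rt))$statistic, 0.1)
})

test_that("confidence map is antisymmetric, zero at t=0, bleeds with time", {
  cm <- build_confidence_map(10, t_max = 3)
  expect_equal(confidence_logodds(cm, 0, 1), 0, tolerance = 1e-8)
  expect_equal(confidence_logodds(cm, 1.2, 0.8),
               -confidence_logodds(cm, -1.2, 0.8), tolerance = 1e-8)
  expect_equal(confidence_logodds(cm, 0.7, 0), 0)
  # fixed dv, growing t: P(correct) falls toward the prior-weighted limit
  lo <- confidence_logodds(cm, 1, c(0.2, 0.5, 1, 2))
  expect_true(all(diff(lo) < 0))
  expect_true(all(abs(cm$logodds) <= cm$clip + 1e-12))
  expect_error(build_confidence_map(10, coherence_set = numeric(0)), "empty")
})

test_that("confidence map matches a brute-force posterior at spot points", {
  kappa <- 8
  set <- signed_coherence_set()$value
  cm <- build_confidence_map(kappa, coherence_set = set, t_max = 2)
  for (probe in list(c(0.6, 0.8), c(-1.1, 1.5), c(2.0, 0.4))) {
    dv <- probe[1]; t <- probe[2]
    lik <- dnorm(dv, kappa * set * t, sqrt(t))
    post <- lik / sum(lik)
    p_blue <- sum(post * ifelse(set > 0, 1, ifelse(set == 0, 0.5, 0)))
    expect_equal(confidence_logodds(cm, dv, t), log(p_blue / (1 - p_blue)),
                 tolerance = 1e-3)
  }
})

test_that("confidence-difference model collapses RT range vs difference", {
  pars <- ref_difficulty_params()
  cm <- build_confidence_map(pars$kappa)
  ee <- mean(simulate_difficulty("confidence", pars,
                                 pair_block(0.64, 0.64, 2500),
                                 conf_map = cm, seed = 30)$rt)
  hh <- mean(simulate_difficulty("confidence", pars, pair_block(0, 0, 2500),
                                 conf_map = cm, seed = 31)$rt)
  eq <- simulate_difficulty("confidence", pars, pair_block(0.384, 0.384, 2500),
                            conf_map = cm, seed = 32)
  expect_equal(mean(eq$choice == "S1"), 0.5, tolerance = 0.03)
  expect_lt(ee, hh - 0.4)  # much shorter easy-easy RTs
})

test_that("the sensory buffer caps then halves the sampling time", {
  expect_equal(effective_duration(0.05, 0.08), 0.05)
  expect_equal(effective_duration(1.65, 0.08), 0.865)
  expect_equal(effective_duration(0.08, 0.08), 0.08)
  expect_equal(effective_duration(0.5, 0), 0.25)  # no buffer: pure sharing
  expect_error(effective_duration(-1), "t_stim")
})

test_that("controlled-duration accuracy grows with duration; known >= unknown", {
  pars <- ref_difficulty_params()
  durs <- c(0.1, 0.25, 0.85)
  acc <- sapply(durs, function(ts) {
    k <- simulate_controlled("known", pars, pair_block(0.384, 0.128, 2500),
                             ts, seed = 40 + round(100 * ts))
    u <- simulate_controlled("difference", pars,
                             pair_block(0.384, 0.128, 2500), ts,
                             seed = 50 + round(100 * ts))
    c(known = mean(k$choice == "S1"), unknown = mean(u$choice == "S1"))
  })
  expect_true(all(diff(acc["known", ]) > 0))
  expect_true(all(diff(acc["unknown", ]) > 0))
  expect_true(all(acc["known", ] >= acc["unknown", ] - 0.02))
  expect_error(simulate_controlled("race", pars, pair_block(0, 0, 5), 0.5),
               "controlled")
})
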