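# coarse configuration for quick policy computations
coarse_config <- function(...) {
  optimal_config(kappa = 8, dt = 0.1, ddv = 0.25, dv_range = 3,
                 horizon = 3, ...)
}

test_that("omega scores the easier stimulus with half credit for ties", {
  expect_equal(omega_easier(0.512, 0.256), 1)
  expect_equal(omega_easier(0.256, 0.512), 0)
  expect_equal(omega_easier(0.384, -0.384), 0.5)
  expect_equal(omega_easier(-0.64, 0.128), 1)
  expect_equal(omega_easier(0, 0), 0.5)
})

test_that("coherence posterior starts at the prior and normalizes", {
  cfg <- optimal_config(kappa = 13)
  expect_equal(coherence_posterior(0, 0, cfg), cfg$prior)
  for (dv in c(-3, -0.5, 0, 1.7)) {
    for (t in c(0.05, 0.5, 2)) {
      p <- coherence_posterior(dv, t, cfg)
      expect_equal(sum(p), 1, tolerance = 1e-10)
      expect_true(all(p >= 0))
    }
  }
  # strong consistent evidence concentrates on the generating coherence
  t <- 3
  p <- coherence_posterior(13 * 0.64 * t, t, cfg)
  expect_equal(cfg$coherences[which.max(p)], 0.64)
})

test_that("belief in S1 is 0.5 at the start and matches a brute-force sum", {
  cfg <- optimal_config(kappa = 13)
  s0 <- list(t1 = 0, t2 = 0, dv1 = 0, dv2 = 0)
  expect_equal(belief_correct(s0, cfg), 0.5, tolerance = 1e-12)
  st <- list(t1 = 0.6, t2 = 0.55, dv1 = 1.3, dv2 = -0.2)
  p1 <- coherence_posterior(st$dv1, st$t1, cfg)
  p2 <- coherence_posterior(st$dv2, st$t2, cfg)
  brute <- 0
  for (i in seq_along(cfg$coherences))
    for (j in seq_along(cfg$coherences))
      brute <- brute + p1[i] * p2[j] *
        omega_easier(cfg$coherences[i], cfg$coherences[j])
  expect_equal(belief_correct(st, cfg), brute, tolerance = 1e-12)
})

test_that("belief transitions conserve mass and collapse correctly", {
  cfg <- coarse_config()
  tr <- sample_transition(list(t1 = 0.5, t2 = 0.5, dv1 = 0.4, dv2 = 0),
                          "S1", cfg)
  expect_equal(sum(tr$prob), 1, tolerance = 1e-8)
  # symmetric prior state: kernel symmetric about the current dv
  tr0 <- sample_transition(list(t1 = 0, t2 = 0, dv1 = 0, dv2 = 0), "S1", cfg)
  expect_equal(tr0$prob, rev(tr0$prob), tolerance = 1e-10)
  # posterior concentrated on one coherence: kernel is a single Gaussian
  cfg1 <- optimal_config(kappa = 8, coherences = 0.64, dt = 0.1, ddv = 0.25,
                         dv_range = 3, horizon = 3)
  tr1 <- sample_transition(list(t1 = 1, t2 = 0, dv1 = 0, dv2 = 0), "S1", cfg1)
  mean_dv <- sum(tr1$dv * tr1$prob)
  expect_equal(mean_dv, 8 * 0.64 * 0.1, tolerance = 1e-3)
})

test_that("degenerate rewards make stopping immediately optimal", {
  cfg <- coarse_config(Rc = 1, Rn = 1, tp = 0)
  sol <- backward_induction(cfg, rho = 0.1)
  g <- diffjudge:::dv_grid(cfg)
  j0 <- which.min(abs(g))
  expect_equal(sol$policy[[1]][j0, j0] %in% c(1L, 2L), TRUE)
  expect_equal(sol$V0, 1 - (cfg$tnd + cfg$tw) * 0.1, tolerance = 1e-9)
})

test_that("the value function dominates both terminal actions", {
  cfg <- coarse_config()
  sol <- backward_induction(cfg, rho = 0.3)
  n <- 5  # mid slice
  k1 <- (n + 1) %/% 2; k2 <- n %/% 2
  pre <- diffjudge:::optimal_precompute(cfg)
  b1 <- pre$post[[k1 + 1]] %*% pre$W %*% t(pre$post[[k2 + 1]])
  term <- (cfg$tnd + cfg$tw) * 0.3
  VS1 <- b1 * cfg$Rc + (1 - b1) * (cfg$Rn - cfg$tp * 0.3) - term
  VS2 <- (1 - b1) * cfg$Rc + b1 * (cfg$Rn - cfg$tp * 0.3) - term
  V <- sol$values[[n + 1]]
  expect_true(all(V >= VS1 - 1e-10))
  expect_true(all(V >= VS2 - 1e-10))
  # terminal slice allows only terminal actions
  expect_true(all(sol$policy[[length(sol$policy)]] %in% c(1L, 2L)))
})

test_that("policy regions mirror under exchanging the two DVs", {
  cfg <- coarse_config()
  sol <- backward_induction(cfg, rho = 0.3)
  # at an even slice S1 is about to be sampled; compare with the mirrored
  # odd-slice state where S2 has the same role
  a10 <- sol$policy[[11]]  # slice 10: t1 = t2 = 0.5
  swapped <- t(a10)
  remap <- a10
  remap[] <- c(2L, 1L, 3L)[swapped]
  # terminal actions mirror exactly; the sampled stimulus differs by the
  # alternation schedule so compare only the terminal-action cells
  term_cells <- a10 %in% c(1L, 2L) & swapped %in% c(1L, 2L)
  expect_true(all((a10 == remap)[term_cells]))
})

test_that("Bellman backward pass is self-consistent from any slice", {
  cfg <- coarse_config()
  pre <- diffjudge:::optimal_precompute(cfg)
  sol <- backward_induction(cfg, rho = 0.3, precomp = pre)
  # recompute slice n from stored slice n+1 values
  n <- 8
  k1 <- (n + 1) %/% 2; k2 <- n %/% 2
  b1 <- pre$post[[k1 + 1]] %*% pre$W %*% t(pre$post[[k2 + 1]])
  term <- (cfg$tnd + cfg$tw) * 0.3
  VS1 <- b1 * cfg$Rc + (1 - b1) * (cfg$Rn - cfg$tp * 0.3) - term
  VS2 <- (1 - b1) * cfg$Rc + b1 * (cfg$Rn - cfg$tp * 0.3) - term
  cont <- if (n %% 2 == 0) pre$kern[[k1 + 1]] %*% sol$values[[n + 2]]
          else sol$values[[n + 2]] %*% t(pre$kern[[k2 + 1]])
  V <- pmax(VS1, VS2, cont - 0.3 * cfg$dt)
  expect_equal(max(abs(V - sol$values[[n + 1]])), 0, tolerance = 1e-10)
})

test_that("reward-rate bisection converges and moves as task economics do", {
  cfg <- coarse_config()
  sol <- solve_reward_rate(cfg, keep_values = FALSE)
  expect_lt(abs(sol$V0), 1e-3)
  slow <- solve_reward_rate(coarse_config(tw = 2), keep_values = FALSE)
  expect_lt(slow$rho, sol$rho)  # longer dead time lowers the reward rate
  sharp <- solve_reward_rate(
    optimal_config(kappa = 16, dt = 0.1, ddv = 0.25, dv_range = 3,
                   horizon = 3), keep_values = FALSE)
  expect_gt(sharp$rho, sol$rho)  # higher sensitivity raises it
  expect_error(solve_reward_rate(cfg, bracket = c(5, 6)), "bracket")
})

test_that("known-color configuration restricts to unsigned coherences", {
  cfg <- optimal_config(kappa = 13)
  kc <- known_color_config(cfg)
  expect_equal(length(kc$coherences), 6)
  expect_true(all(kc$coherences >= 0))
  expect_equal(belief_correct(list(t1 = 0, t2 = 0, dv1 = 0, dv2 = 0), kc),
               0.5)
  # strongly negative evidence points to the lowest coherence, not a
  # negative one
  p <- coherence_posterior(-2, 1, kc)
  expect_equal(kc$coherences[which.max(p)], 0)
})

test_that("optimal-policy simulation respects the policy grid and prior", {
  cfg <- coarse_config()
  sol <- solve_reward_rate(cfg)
  sim <- simulate_optimal(sol$solution, 4000, seed = 1)
  expect_equal(nrow(sim), 4000)
  expect_true(all(sim$rt == sim$decision_time + cfg$tnd))
  expect_true(all(sim$decision_time <= cfg$horizon))
  expect_setequal(unique(abs(sim$c1)), coherence_levels())
  # accuracy rises with the strength difference
  acc <- tapply(sim$correct, abs(abs(sim$c1) - abs(sim$c2)) > 0.3, mean)
  expect_gt(acc[["TRUE"]], acc[["FALSE"]])
})
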