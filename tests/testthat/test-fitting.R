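small_design <- function() {
  g <- expand.grid(c1 = c(-0.512, -0.128, 0.128, 0.512),
                   c2 = c(-0.512, -0.128, 0.128, 0.512))
  g
}

test_that("smoothed likelihood tables normalize, scale and floor", {
  pars <- ref_difficulty_params()
  des <- small_design()
  tab <- simulate_likelihood_table("difference", pars, des, n_sim = 400,
                                   sim_seed = 5)
  # per condition the choice masses sum to 1
  for (cell in tab$cells) {
    expect_equal(cell$S1$p + cell$S2$p, 1, tolerance = 1e-9)
    expect_gte(cell$S1$bw, 2 * tab$dt)
  }
  # density integrates to the choice mass (kernel mass = 1)
  cell <- tab$cells[[1]]
  rr <- seq(0, 8, by = 0.005)
  dens <- vapply(rr, function(x)
    mean(diffjudge:::kernel_epanechnikov((x - cell$S1$rts) / cell$S1$bw)) /
      cell$S1$bw, numeric(1))
  expect_equal(sum(dens) * 0.005, 1, tolerance = 1e-2)
  # an RT far outside the simulated support hits the floor, not zero
  far <- diffjudge:::likelihood_at(tab, "S1", 4000, des$c1[1], des$c2[1],
                                   sign(des$c1[1]), sign(des$c2[1]))
  expect_equal(far, tab$floor)
})

test_that("negative log-likelihood contracts hold", {
  pars <- ref_difficulty_params()
  des <- small_design()
  tab <- simulate_likelihood_table("difference", pars, des, n_sim = 400,
                                   sim_seed = 6)
  empty <- data.frame(c1 = numeric(0), c2 = numeric(0),
                      choice = character(0), rt = numeric(0))
  expect_identical(negative_log_likelihood(empty, tab), 0)
  one <- data.frame(c1 = des$c1[1], c2 = des$c2[1], choice = "S1", rt = 4000)
  expect_equal(negative_log_likelihood(one, tab), -log(tab$floor))
  bad <- data.frame(c1 = 0.99, c2 = 0, choice = "S1", rt = 1)
  expect_error(negative_log_likelihood(bad, tab), "absent")
})

test_that("the true parameters beat mismatched ones in likelihood", {
  pars <- ref_difficulty_params()
  des <- small_design()
  wins <- 0L
  for (s in 1:5) {
    pairs <- des[rep(seq_len(nrow(des)), 8), ]
    sim <- simulate_difficulty("difference", pars, pairs, seed = 300 + s)
    dat <- cbind(pairs, choice = as.character(sim$choice), rt = sim$rt)
    tab_true <- simulate_likelihood_table("difference", pars, des,
                                          n_sim = 400, sim_seed = 50 + s)
    bad <- difficulty_params(kappa = 20, bound = ref_bound(),
                             tnd_mean = 0.35)
    tab_bad <- simulate_likelihood_table("difference", bad, des,
                                         n_sim = 400, sim_seed = 50 + s)
    if (negative_log_likelihood(dat, tab_true) <
        negative_log_likelihood(dat, tab_bad)) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("the simulation-based objective is deterministic under CRN", {
  pars <- ref_difficulty_params()
  des <- small_design()
  pairs <- des[rep(seq_len(nrow(des)), 4), ]
  sim <- simulate_difficulty("difference", pars, pairs, seed = 1)
  dat <- cbind(pairs, choice = as.character(sim$choice), rt = sim$rt)
  key <- paste(dat$c1, dat$c2)
  uk <- which(!duplicated(key))
  args <- list(2L, dat$c1[uk], dat$c2[uk], as.integer(sign(dat$c1[uk])),
               as.integer(sign(dat$c2[uk])), 200L,
               match(key, key[uk]) - 1L,
               ifelse(dat$choice == "S1", 1L, 2L), dat$rt,
               10, 2.5, 1.5, 1.5, 0, seq(0.1, 1, 0.01), 0.05,
               0.005, 5, 1e-5, 77L, matrix(0, 1, 1), 0, 1, 1)
  a <- do.call(diffjudge:::cpp_difficulty_nll, args)
  b <- do.call(diffjudge:::cpp_difficulty_nll, args)
  expect_identical(a$nll, b$nll)
  expect_identical(a$tnd, b$tnd)
  # R-path table likelihood is bit-reproducible under a fixed sim seed
  t1 <- simulate_likelihood_table("difference", pars, des, n_sim = 300,
                                  sim_seed = 42)
  t2 <- simulate_likelihood_table("difference", pars, des, n_sim = 300,
                                  sim_seed = 42)
  expect_identical(negative_log_likelihood(dat, t1),
                   negative_log_likelihood(dat, t2))
})

test_that("C++ objective agrees with the R likelihood path per trial", {
  pars <- ref_difficulty_params()
  des <- small_design()
  pairs <- des[rep(seq_len(nrow(des)), 20), ]
  sim <- simulate_difficulty("difference", pars, pairs, seed = 2)
  dat <- cbind(pairs, choice = as.character(sim$choice), rt = sim$rt)
  tab <- simulate_likelihood_table("difference", pars, des, n_sim = 2000,
                                   sim_seed = 9)
  nll_r <- negative_log_likelihood(dat, tab)
  key <- paste(dat$c1, dat$c2)
  uk <- which(!duplicated(key))
  nll_c <- diffjudge:::cpp_difficulty_nll(
    2L, dat$c1[uk], dat$c2[uk], as.integer(sign(dat$c1[uk])),
    as.integer(sign(dat$c2[uk])), 2000L, match(key, key[uk]) - 1L,
    ifelse(dat$choice == "S1", 1L, 2L), dat$rt,
    pars$kappa, 2.5, 1.5, 1.5, 0, 0.35, 0.05, 0.005, 5, 1e-5, 123L,
    matrix(0, 1, 1), 0, 1, 1)$nll
  # independent simulation streams: agreement per trial within MC noise
  expect_equal(nll_c / nrow(dat), nll_r / nrow(dat), tolerance = 0.05)
})

test_that("likelihood stabilizes as the number of simulations grows", {
  pars <- ref_difficulty_params()
  des <- small_design()
  pairs <- des[rep(seq_len(nrow(des)), 10), ]
  sim <- simulate_difficulty("difference", pars, pairs, seed = 3)
  dat <- cbind(pairs, choice = as.character(sim$choice), rt = sim$rt)
  # the kernel bandwidth shrinks as n_sim grows, so the per-trial NLL
  # drifts slightly with scale; between 2000 and 4000 simulations it is
  # stable to a couple of percent
  per_trial <- vapply(c(2000, 4000), function(ns) {
    tab <- simulate_likelihood_table("difference", pars, des, n_sim = ns,
                                     sim_seed = 11)
    negative_log_likelihood(dat, tab) / nrow(dat)
  }, numeric(1))
  expect_lt(abs(per_trial[2] - per_trial[1]) / per_trial[1], 0.02)
})

test_that("the box optimizer solves a smooth deterministic problem", {
  fn <- function(p) (p[["x"]] - 0.7)^2 + 3 * (p[["y"]] + 1.2)^2
  res <- optimize_box(fn, lower = c(x = -5, y = -5), upper = c(x = 5, y = 5),
                      n_starts = 2, maxit = 300, seed = 1)
  expect_equal(unname(res$par["x"]), 0.7, tolerance = 1e-3)
  expect_equal(unname(res$par["y"]), -1.2, tolerance = 1e-3)
  # respects the box
  res2 <- optimize_box(fn, lower = c(x = 1, y = 0), upper = c(x = 5, y = 5),
                       n_starts = 2, maxit = 300, seed = 2)
  expect_gte(unname(res2$par["x"]), 1)
})

test_that("BIC and group BIC follow their definitions", {
  expect_equal(bic(0, 0, 10), 0)
  expect_equal(bic(-50, 4, 100) - bic(-50, 3, 100), log(100))
  expect_error(bic(0, 1, 0), "n_trials")
  m <- rbind(c(10, 12), c(10, 12), c(10, 12))
  expect_equal(unname(group_bic(m)), c(30, 36))
})

test_that("exceedance probabilities behave under symmetry and dominance", {
  ex <- exceedance_probabilities(matrix(0, 12, 4), seed = 1)
  expect_equal(sum(ex$exceedance), 1, tolerance = 1e-6)
  expect_true(all(abs(ex$exceedance - 0.25) < 0.02))
  E <- matrix(0, 20, 4)
  E[, 3] <- 5  # delta-BIC of 10 in favor of model 3 for everyone
  ex2 <- exceedance_probabilities(E, seed = 2)
  expect_gt(ex2$exceedance[3], 0.95)
  expect_error(exceedance_probabilities(matrix(c(1, NA), 1, 2)), "finite")
  expect_error(exceedance_probabilities(matrix(0, 5, 1)), "2 models")
})

test_that("fitting the generating model recovers it at small scale", {
  pars <- ref_difficulty_params()
  des <- small_design()
  pairs <- des[rep(seq_len(nrow(des)), 25), ]  # 400 trials
  sim <- simulate_difficulty("difference", pars, pairs, seed = 4)
  dat <- cbind(pairs, choice = as.character(sim$choice), rt = sim$rt)
  ft <- fit_difficulty_model("difference", dat, n_starts = 2, n_sim = 150,
                             maxit = 80, seed = 5)
  expect_s3_class(ft, "fit_result")
  expect_equal(ft$bic, -2 * ft$logLik + 5 * log(nrow(dat)))
  expect_lt(abs(ft$par$kappa - pars$kappa) / pars$kappa, 0.4)
  # a start at the truth cannot do worse than the truth's own objective
  ft0 <- fit_difficulty_model("difference", dat, n_starts = 1, n_sim = 150,
                              maxit = 40, seed = 6,
                              start = c(kappa = 10, u = 2.5, a = 1.5, d = 1.5))
  expect_s3_class(ft0, "fit_result")
})

test_that("color DDM fitting recovers kappa and the bias sign", {
  pars <- ref_color_params(c0 = 0.05)
  cohs <- signed_coherence_set()
  design <- data.frame(c1_signed = rep(cohs$value, 36),
                       c1_sign = rep(cohs$sign, 36))
  design$task <- "color"; design$paradigm <- "rt"
  dat <- generate_dataset("color_ddm", pars, design, dt = 0.001, seed = 7)
  fd <- data.frame(c1 = dat$c1_signed, choice = dat$choice, rt = dat$rt)
  ft <- fit_color_ddm(fd, n_starts = 1, dt = 0.005, maxit = 60, seed = 8)
  expect_lt(abs(ft$par$kappa - pars$kappa) / pars$kappa, 0.25)
  expect_equal(ft$n_params, 6)
})

test_that("controlled-duration joint fit runs and recovers kappa roughly", {
  pars <- ref_difficulty_params()
  durs <- c(0.15, 0.45, 1.65)
  grid <- expand.grid(s1 = c(0.128, 0.384, 0.64), s2 = c(0.128, 0.384, 0.64),
                      duration = durs)
  grid <- grid[grid$s1 != grid$s2, ]
  mk <- function(signit) {
    d <- grid[rep(seq_len(nrow(grid)), 25), ]
    data.frame(c1 = signit * d$s1, c2 = signit * d$s2,
               c1_sign = signit, c2_sign = signit, duration = d$duration)
  }
  du <- mk(1L); dk <- mk(1L)
  su <- simulate_controlled("difference", pars, du, du$duration, seed = 9)
  sk <- simulate_controlled("known", pars, dk, dk$duration, seed = 10)
  du$choice <- as.character(su$choice); dk$choice <- as.character(sk$choice)
  ft <- fit_controlled_duration(du, dk, n_sim = 150, n_starts = 2,
                                maxit = 30, seed = 11)
  expect_equal(ft$n_params, 4)
  expect_lt(abs(ft$par$kappa - pars$kappa) / pars$kappa, 0.5)
  ft2 <- fit_controlled_duration(du, dk, single_kappa = FALSE, n_sim = 100,
                                 n_starts = 1, maxit = 25, seed = 12)
  expect_equal(ft2$n_params, 5)
})
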