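#' Configuration of the reward-rate-optimal difficulty policy
#'
#' Bundles the task and discretization parameters of the belief-state MDP
#' whose solution is the reward-rate-optimal stopping policy for
#' difficulty judgments. The belief state is the tuple
#' \eqn{\langle t_{S1}, t_{S2}, DV_{S1}, DV_{S2} \rangle}; stimuli are
#' sampled in strict alternation (S1 on even slices), and the prior over
#' each stimulus's signed coherence is uniform over the discrete set.
#'
#' @param kappa drift coefficient.
#' @param coherences signed coherence set (default the experimental
#'   12-level set; use [known_color_config()] for the unsigned variant).
#' @param prior prior weights over `coherences` (default uniform).
#' @param Rc reward for a correct choice.
#' @param Rn reward for an error.
#' @param tp time penalty after an error (s).
#' @param tnd non-decision time added to every trial (s).
#' @param tw inter-trial interval (s).
#' @param dt sampling time step (s).
#' @param ddv DV grid step.
#' @param dv_range half-range of the DV grid (mass beyond it accumulates
#'   in the edge bins).
#' @param horizon total sampling time allowed (s); the terminal slice
#'   forces the better terminal choice.
#' @return an object of class `optimal_config`.
#' @export
optimal_config <- function(kappa = 13, coherences = signed_coherence_set()$value,
                           prior = NULL, Rc = 1, Rn = 0, tp = 1, tnd = 0.4,
                           tw = 0.5, dt = 0.05, ddv = 0.1, dv_range = 6,
                           horizon = 5) {
  stopifnot_scalar(kappa, "kappa", positive = TRUE)
  stopifnot_scalar(dt, "dt", positive = TRUE)
  stopifnot_scalar(ddv, "ddv", positive = TRUE)
  stopifnot_scalar(horizon, "horizon", positive = TRUE)
  if (ddv > sqrt(dt))
    stop(sprintf("grid too coarse: ddv = %g exceeds sqrt(dt) = %g, the ",
                 ddv, sqrt(dt)),
         "one-step transition kernel is not resolved", call. = FALSE)
  if (is.null(prior)) prior <- rep(1 / length(coherences), length(coherences))
  if (length(prior) != length(coherences) || any(prior < 0))
    stop("'prior' must be nonnegative weights over 'coherences'", call. = FALSE)
  prior <- prior / sum(prior)
  structure(list(kappa = kappa, coherences = coherences, prior = prior,
                 Rc = Rc, Rn = Rn, tp = tp, tnd = tnd, tw = tw, dt = dt,
                 ddv = ddv, dv_range = dv_range, horizon = horizon),
            class = "optimal_config")
}

#' Known-color variant of an optimal-policy configuration
#'
#' Replaces the signed coherence set by the unsigned strengths (uniform
#' prior): when color dominance is known, evidence is appropriately
#' signed, so a strongly negative DV indicates a very low coherence
#' rather than a negative one.
#'
#' @param config an [optimal_config()].
#' @return an [optimal_config()] with the unsigned coherence set.
#' @export
known_color_config <- function(config) {
  stopifnot(inherits(config, "optimal_config"))
  coh <- sort(unique(abs(config$coherences)))
  optimal_config(kappa = config$kappa, coherences = coh, prior = NULL,
                 Rc = config$Rc, Rn = config$Rn, tp = config$tp,
                 tnd = config$tnd, tw = config$tw, dt = config$dt,
                 ddv = config$ddv, dv_range = config$dv_range,
                 horizon = config$horizon)
}

#' Tie-aware easier-stimulus indicator
#'
#' \eqn{\omega(a, b)} is 1 when \eqn{|a| > |b|}, 0 when \eqn{|a| < |b|}
#' and 0.5 on ties; it scores choosing S1 (coherence `a`) as correct,
#' counting half of the ties.
#'
#' @param a,b signed coherences (vectorized).
#' @return values in \{0, 0.5, 1\}.
#' @export
omega_easier <- function(a, b) {
  ifelse(abs(a) > abs(b), 1, ifelse(abs(a) < abs(b), 0, 0.5))
}

#' Posterior over the coherence set given accumulated evidence
#'
#' \eqn{P(C \mid dv, t) \propto N(dv \mid \kappa C t, t) P(C)}; at
#' \eqn{t = 0} the prior is returned.
#'
#' @param dv accumulated evidence (scalar).
#' @param t elapsed sampling time of that stimulus (s), >= 0.
#' @param config an [optimal_config()].
#' @return probability vector over `config$coherences`.
#' @export
coherence_posterior <- function(dv, t, config) {
  stopifnot(inherits(config, "optimal_config"))
  if (t < 0) stop("'t' must be >= 0", call. = FALSE)
  if (t == 0) return(config$prior)
  lik <- dnorm(dv, mean = config$kappa * config$coherences * t, sd = sqrt(t))
  p <- lik * config$prior
  s <- sum(p)
  if (s <= 0) {
    # extreme dv: all likelihoods underflow; fall back to the nearest mean
    p <- as.numeric(seq_along(p) ==
                      which.min(abs(config$kappa * config$coherences * t - dv)))
    return(p)
  }
  p / s
}

# posterior matrix over a dv grid (rows) at sampling time t
posterior_matrix <- function(g, t, config) {
  nco <- length(config$coherences)
  if (t == 0)
    return(matrix(config$prior, nrow = length(g), ncol = nco, byrow = TRUE))
  lik <- vapply(config$coherences,
                function(C) dnorm(g, mean = config$kappa * C * t, sd = sqrt(t)),
                numeric(length(g)))
  p <- sweep(lik, 2, config$prior, `*`)
  rs <- rowSums(p)
  und <- rs <= 0
  if (any(und)) {
    means <- config$kappa * config$coherences * t
    for (i in which(und)) p[i, which.min(abs(means - g[i]))] <- 1
    rs[und] <- 1
  }
  p / rs
}

dv_grid <- function(config) {
  seq(-config$dv_range, config$dv_range, by = config$ddv)
}

# binned one-step Gaussian kernel for a fixed coherence; rows = current dv,
# cols = next dv; tail mass accumulates in the edge bins (conserves mass)
kernel_for_coherence <- function(g, C, config) {
  dt <- config$dt
  shift <- g + config$kappa * C * dt
  edges <- c(g[1] - config$ddv / 2, g + config$ddv / 2)
  P <- outer(shift, edges, function(s, e) pnorm(e, mean = s, sd = sqrt(dt)))
  K <- P[, -1, drop = FALSE] - P[, -length(edges), drop = FALSE]
  K[, 1] <- K[, 1] + P[, 1]
  K[, ncol(K)] <- K[, ncol(K)] + 1 - P[, length(edges)]
  K
}

# belief-weighted transition kernel at sampling time t (mixture over the
# posterior for the sampled stimulus)
transition_kernel <- function(g, t, config, G_list = NULL) {
  post <- posterior_matrix(g, t, config)
  if (is.null(G_list))
    G_list <- lapply(config$coherences, kernel_for_coherence, g = g,
                     config = config)
  K <- matrix(0, length(g), length(g))
  for (c_i in seq_along(config$coherences))
    K <- K + post[, c_i] * G_list[[c_i]]
  K
}

#' One-step belief transition for the sampled stimulus
#'
#' Marginal distribution of the next DV value after sampling one
#' stimulus: a mixture of binned Gaussians \eqn{N(dv' - dv \mid \kappa C
#' \Delta t, \Delta t)} weighted by the current coherence posterior of
#' that stimulus. Only the sampled stimulus's time and DV advance.
#'
#' @param state list with `t1`, `t2`, `dv1`, `dv2`.
#' @param which_stimulus `"S1"` or `"S2"`.
#' @param config an [optimal_config()].
#' @return data.frame with `dv` (grid) and `prob` (sums to 1).
#' @export
sample_transition <- function(state, which_stimulus = c("S1", "S2"), config) {
  which_stimulus <- match.arg(which_stimulus)
  g <- dv_grid(config)
  dv <- if (which_stimulus == "S1") state$dv1 else state$dv2
  t <- if (which_stimulus == "S1") state$t1 else state$t2
  post <- coherence_posterior(dv, t, config)
  edges <- c(g[1] - config$ddv / 2, g + config$ddv / 2)
  prob <- numeric(length(g))
  for (c_i in seq_along(config$coherences)) {
    m <- dv + config$kappa * config$coherences[c_i] * config$dt
    p <- diff(pnorm(edges, mean = m, sd = sqrt(config$dt)))
    p[1] <- p[1] + pnorm(edges[1], mean = m, sd = sqrt(config$dt))
    p[length(p)] <- p[length(p)] +
      1 - pnorm(edges[length(edges)], mean = m, sd = sqrt(config$dt))
    prob <- prob + post[c_i] * p
  }
  data.frame(dv = g, prob = prob)
}

#' Probability that choosing S1 is correct in a belief state
#'
#' \eqn{b(s, S1) = \sum_{C_1} \sum_{C_2} P(C_1 \mid s) P(C_2 \mid s)\,
#' \omega(C_1, C_2)} with [omega_easier()] counting half of the ties;
#' \eqn{b(s, S2) = 1 - b(s, S1)}.
#'
#' @inheritParams sample_transition
#' @return probability that S1 is the easier stimulus.
#' @export
belief_correct <- function(state, config) {
  p1 <- coherence_posterior(state$dv1, state$t1, config)
  p2 <- coherence_posterior(state$dv2, state$t2, config)
  W <- outer(config$coherences, config$coherences, omega_easier)
  as.numeric(p1 %*% W %*% p2)
}

# rho-independent precomputations shared by backward passes
optimal_precompute <- function(config) {
  g <- dv_grid(config)
  N <- as.integer(round(config$horizon / config$dt))
  n_half <- N %/% 2L + 1L
  G_list <- lapply(config$coherences, kernel_for_coherence, g = g,
                   config = config)
  post <- vector("list", n_half + 1L)   # posterior matrices at t = k*dt
  kern <- vector("list", n_half + 1L)   # transition kernels at t = k*dt
  for (k in 0:n_half) {
    t <- k * config$dt
    post[[k + 1L]] <- posterior_matrix(g, t, config)
    kern[[k + 1L]] <- transition_kernel(g, t, config, G_list)
  }
  W <- outer(config$coherences, config$coherences, omega_easier)
  # b(s, S1) per slice-pair of times: depends on (t1, t2) only through the
  # two posterior matrices; computed on demand in the backward pass
  list(g = g, N = N, post = post, kern = kern, W = W)
}

#' Backward induction of the optimal value function and policy
#'
#' Solves the Bellman equations for a given reward rate `rho` by one
#' backward pass over time slices. At each slice the value of a state is
#' the maximum over choosing S1, choosing S2 (terminal values
#' \eqn{b R_c + (1 - b)(R_n - t_p \rho) - (t_{nd} + t_w)\rho}) and
#' sampling the scheduled stimulus (expected next-slice value minus
#' \eqn{\rho \Delta t}). The terminal slice allows only the terminal
#' actions.
#'
#' @param config an [optimal_config()].
#' @param rho assumed reward rate (1/s).
#' @param precomp optional result of the internal precomputation (reused
#'   across bisection iterations).
#' @param keep_values store the full value function (default TRUE).
#' @return list with `V0` (value of the initial state), `policy` (list of
#'   integer matrices per slice; 1 = choose S1, 2 = choose S2,
#'   3 = sample), `values` (optional list of value matrices), `config`,
#'   `rho`.
#' @export
backward_induction <- function(config, rho, precomp = NULL,
                               keep_values = TRUE) {
  stopifnot(inherits(config, "optimal_config"))
  if (is.null(precomp)) precomp <- optimal_precompute(config)
  g <- precomp$g; N <- precomp$N
  m <- length(g)
  j0 <- which.min(abs(g))
  term_cost <- (config$tnd + config$tw) * rho
  err_val <- config$Rn - config$tp * rho

  policy <- vector("list", N + 1L)
  values <- if (keep_values) vector("list", N + 1L) else NULL
  Vnext <- NULL
  for (n in N:0) {
    k1 <- (n + 1L) %/% 2L   # t_S1 index (S1 sampled on even slices, first)
    k2 <- n %/% 2L          # t_S2 index
    b1 <- precomp$post[[k1 + 1L]] %*% precomp$W %*% t(precomp$post[[k2 + 1L]])
    VS1 <- b1 * config$Rc + (1 - b1) * err_val - term_cost
    VS2 <- (1 - b1) * config$Rc + b1 * err_val - term_cost
    V <- pmax(VS1, VS2)
    act <- ifelse(VS1 >= VS2, 1L, 2L)
    if (n < N) {
      cont <- if (n %% 2L == 0L) {
        precomp$kern[[k1 + 1L]] %*% Vnext
      } else {
        Vnext %*% t(precomp$kern[[k2 + 1L]])
      }
      cont <- cont - rho * config$dt
      samp <- cont > V
      V[samp] <- cont[samp]
      act[samp] <- 3L
    }
    dim(act) <- c(m, m)
    policy[[n + 1L]] <- act
    if (keep_values) values[[n + 1L]] <- V
    Vnext <- V
  }
  list(V0 = Vnext[j0, j0], policy = policy, values = values,
       config = config, rho = rho)
}

#' Reward rate of the optimal policy by bisection
#'
#' The optimal reward rate \eqn{\rho^*} is the root of
#' \eqn{V(s_0; \rho) = 0}: backward induction is run at bracketing values
#' of \eqn{\rho} and the bracket is halved until the value of the initial
#' state is within `tol` of zero.
#'
#' @param config an [optimal_config()].
#' @param bracket initial interval for `rho`; default
#'   `c(0, Rc / (tnd + tw))`.
#' @param tol tolerance on \eqn{|V(s_0)|}; default 1e-3.
#' @param max_iter maximum bisection iterations.
#' @param keep_values keep the final value function.
#' @return list with `rho` (the reward rate), `V0`, `solution` (the
#'   converged [backward_induction()] result), `iterations`.
#' @export
solve_reward_rate <- function(config, bracket = NULL, tol = 1e-3,
                              max_iter = 40, keep_values = TRUE) {
  stopifnot(inherits(config, "optimal_config"))
  if (is.null(bracket))
    bracket <- c(0, config$Rc / (config$tnd + config$tw))
  precomp <- optimal_precompute(config)
  v_at <- function(r) backward_induction(config, r, precomp,
                                         keep_values = FALSE)$V0
  v_lo <- v_at(bracket[1])
  v_hi <- v_at(bracket[2])
  if (v_lo < 0 || v_hi > 0)
    stop(sprintf(paste0("bracket [%g, %g] does not straddle the root ",
                        "(V = %.3g, %.3g); widen the bracket"),
                 bracket[1], bracket[2], v_lo, v_hi), call. = FALSE)
  lo <- bracket[1]; hi <- bracket[2]
  it <- 0L
  rho <- (lo + hi) / 2
  v <- v_at(rho)
  while (abs(v) > tol && it < max_iter) {
    if (v > 0) lo <- rho else hi <- rho
    rho <- (lo + hi) / 2
    v <- v_at(rho)
    it <- it + 1L
  }
  sol <- backward_induction(config, rho, precomp, keep_values = keep_values)
  list(rho = rho, V0 = sol$V0, solution = sol, iterations = it)
}

#' Simulate trials under the optimal policy
#'
#' Draws coherences for the two stimuli independently from the design
#' prior, evolves the belief state by alternate sampling of the stimuli,
#' and follows the deterministic policy (states are snapped to the
#' nearest DV grid node for the lookup). RT is the total sampling time
#' plus the constant non-decision time.
#'
#' @param solution a [backward_induction()] result (or the `solution`
#'   element of [solve_reward_rate()]).
#' @param n_trials number of trials.
#' @param seed optional integer seed.
#' @return data.frame with `c1`, `c2`, `choice` (factor S1/S2),
#'   `decision_time`, `rt`, `correct`.
#' @export
simulate_optimal <- function(solution, n_trials, seed = NULL) {
  config <- solution$config
  g <- dv_grid(config)
  m <- length(g)
  N <- length(solution$policy) - 1L
  with_seed(seed, {
    c1 <- sample(config$coherences, n_trials, replace = TRUE,
                 prob = config$prior)
    c2 <- sample(config$coherences, n_trials, replace = TRUE,
                 prob = config$prior)
    dv1 <- numeric(n_trials); dv2 <- numeric(n_trials)
    choice <- integer(n_trials); dtime <- numeric(n_trials)
    active <- rep(TRUE, n_trials)
    sdt <- sqrt(config$dt)
    for (n in 0:N) {
      if (!any(active)) break
      i1 <- pmin(pmax(round((dv1[active] + config$dv_range) / config$ddv), 0),
                 m - 1L) + 1L
      i2 <- pmin(pmax(round((dv2[active] + config$dv_range) / config$ddv), 0),
                 m - 1L) + 1L
      act <- solution$policy[[n + 1L]][cbind(i1, i2)]
      stopnow <- act != 3L
      idx <- which(active)
      if (any(stopnow)) {
        st <- idx[stopnow]
        choice[st] <- act[stopnow]
        dtime[st] <- n * config$dt
        active[st] <- FALSE
      }
      still <- idx[!stopnow]
      if (n < N && length(still) > 0) {
        if (n %% 2L == 0L) {
          dv1[still] <- dv1[still] + config$kappa * c1[still] * config$dt +
            sdt * rnorm(length(still))
        } else {
          dv2[still] <- dv2[still] + config$kappa * c2[still] * config$dt +
            sdt * rnorm(length(still))
        }
      }
    }
    # the terminal slice forces a terminal action, so none remain active
    w <- omega_easier(c1, c2)
    chose1 <- choice == 1L
    correct <- ifelse(w == 0.5, runif(n_trials) < 0.5,
                      ifelse(chose1, w == 1, w == 0))
    data.frame(c1 = c1, c2 = c2,
               choice = factor(c("S1", "S2")[choice], levels = c("S1", "S2")),
               decision_time = dtime, rt = dtime + config$tnd,
               correct = correct)
  })
}
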