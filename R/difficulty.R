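#' Parameters of the difficulty-judgment models
#'
#' Parameter bundle shared by the four difficulty models (race, difference,
#' two-step, absolute momentary evidence) and their variants. The drift of
#' each stimulus's accumulator is \eqn{\mu_x = \kappa C_x^\pm}; there is no
#' color-bias term in the difficulty models. `b_mini` is the low-threshold
#' mini-decision bound used only by the two-step model.
#'
#' @param kappa drift coefficient, > 0.
#' @param bound a [collapsing_bound()] applied to the model's decision
#'   statistic.
#' @param tnd_mean mean non-decision time (s), > 0.
#' @param tnd_sd SD of the non-decision time (s); default 0.05.
#' @param b_mini mini-decision bound (evidence units), > 0; two-step only.
#' @return an object of class `difficulty_params`.
#' @export
difficulty_params <- function(kappa, bound, tnd_mean, tnd_sd = 0.05,
                              b_mini = NULL) {
  stopifnot_scalar(kappa, "kappa", positive = TRUE)
  stopifnot(inherits(bound, "collapsing_bound"))
  stopifnot_scalar(tnd_mean, "tnd_mean", positive = TRUE)
  stopifnot_scalar(tnd_sd, "tnd_sd")
  if (!is.null(b_mini)) stopifnot_scalar(b_mini, "b_mini", positive = TRUE)
  structure(list(kappa = kappa, bound = bound, tnd_mean = tnd_mean,
                 tnd_sd = tnd_sd, b_mini = b_mini),
            class = "difficulty_params")
}

difficulty_model_codes <- c(race = 1L, difference = 2L, two_step = 3L,
                            absolute = 4L, known = 5L,
                            confidence = 6L, confidence_known = 7L)

#' Names of the difficulty-judgment models
#' @return character vector of model identifiers accepted by the
#'   simulators and fitters.
#' @export
difficulty_models <- function() names(difficulty_model_codes)

empty_conf_matrix <- function() matrix(0, 1, 1)

# resolve signs for pairs: use given tags, else sign of coherence with a
# random tag on zero
resolve_signs <- function(pairs) {
  s1 <- if ("c1_sign" %in% names(pairs)) pairs$c1_sign else rand_sign(pairs$c1)
  s2 <- if ("c2_sign" %in% names(pairs)) pairs$c2_sign else rand_sign(pairs$c2)
  list(s1 = as.integer(s1), s2 = as.integer(s2))
}

#' Simulate difficulty-judgment trials (reaction-time paradigm)
#'
#' Simulates the serial, time-multiplexed 2D accumulation process for one
#' of the difficulty models. Evidence updates alternate between the two
#' stimuli every `dt` (S1 first), so each stimulus is sampled for half of
#' elapsed real time; the collapsing bound is evaluated at real time.
#' Reaction time is the bound-crossing time plus a Gaussian non-decision
#' draw (truncated at 0). Trials still unresolved at `horizon` are
#' assigned the choice favored by the sign of the decision statistic and
#' flagged `terminated_by = "horizon"`.
#'
#' Models: `"race"` (first DV at its own bound wins), `"difference"`
#' (bound on \eqn{|DV_{S1}| - |DV_{S2}|}), `"two_step"` (mini color
#' decisions at `b_mini`, then bound on the sign-corrected difference),
#' `"absolute"` (rectified momentary-evidence accumulation, bound on
#' \eqn{DV_{S1} - DV_{S2}}), `"known"` (signed difference using the true
#' dominance tags), `"confidence"` / `"confidence_known"` (bound on the
#' difference of log-odds confidence; requires `conf_map`).
#'
#' @param model one of [difficulty_models()].
#' @param params a [difficulty_params()].
#' @param pairs data.frame with signed coherences `c1`, `c2` (one row per
#'   trial), optionally sign tags `c1_sign`, `c2_sign` (needed to
#'   disambiguate the two zero-coherence levels; defaults to the coherence
#'   sign with random tags on 0).
#' @param dt simulation step (s); default 5 ms.
#' @param horizon response deadline (s); default 5 s.
#' @param conf_map a [build_confidence_map()] result (confidence models).
#' @param serial logical; `FALSE` runs parallel integration (both DVs
#'   updated every step), used for the serial/parallel equivalence check.
#' @param seed optional integer seed (local to this call).
#' @return data.frame with columns `choice` (factor S1/S2),
#'   `decision_time`, `rt`, `terminated_by` (factor bound/horizon),
#'   `t_mini` (two-step only, else NA).
#' @export
simulate_difficulty <- function(model, params, pairs, dt = 0.005,
                                horizon = 5, conf_map = NULL, serial = TRUE,
                                seed = NULL) {
  model <- match.arg(model, difficulty_models())
  stopifnot(inherits(params, "difficulty_params"))
  stopifnot_scalar(dt, "dt", positive = TRUE)
  stopifnot_scalar(horizon, "horizon", positive = TRUE)
  if (!all(c("c1", "c2") %in% names(pairs)))
    stop("'pairs' must have columns c1 and c2 (signed coherences)",
         call. = FALSE)
  code <- difficulty_model_codes[[model]]
  if (model == "two_step" && is.null(params$b_mini))
    stop("two-step model requires 'b_mini' in the parameters", call. = FALSE)
  if (model %in% c("confidence", "confidence_known")) {
    if (!inherits(conf_map, "confidence_map"))
      stop("confidence models require 'conf_map' from build_confidence_map()",
           call. = FALSE)
    conf <- conf_map$logodds
    conf_dv_min <- conf_map$dv[1]
    conf_dv_step <- conf_map$dv[2] - conf_map$dv[1]
    conf_t_step <- conf_map$t_step
  } else {
    conf <- empty_conf_matrix(); conf_dv_min <- 0
    conf_dv_step <- 1; conf_t_step <- 1
  }
  b <- params$bound
  with_seed(seed, {
    sg <- resolve_signs(pairs)
    res <- cpp_sim_difficulty(code, pairs$c1, pairs$c2, sg$s1, sg$s2,
                              params$kappa, b$u, b$a, b$d,
                              if (is.null(params$b_mini)) 0 else params$b_mini,
                              dt, horizon, serial,
                              conf, conf_dv_min, conf_dv_step, conf_t_step)
    n <- length(res$choice)
    tnd <- pmax(0, rnorm(n, params$tnd_mean, params$tnd_sd))
    data.frame(
      choice = factor(c("S1", "S2")[res$choice], levels = c("S1", "S2")),
      decision_time = res$decision_time,
      rt = res$decision_time + tnd,
      terminated_by = factor(c("bound", "horizon")[res$terminated_by + 1L],
                             levels = c("bound", "horizon", "stimulus_offset")),
      t_mini = res$t_mini
    )
  })
}

#' Effective per-stimulus sampling time under a sensory buffer
#'
#' In the controlled-duration paradigm a short sensory buffer `t_buf`
#' (default 80 ms) holds both stimulus streams in parallel; beyond it the
#' two stimuli share accumulation time equally:
#' \deqn{T_{dur} = T_{stim} \ \mathrm{if}\ T_{stim} \le T_{buf};\quad
#'       T_{buf} + (T_{stim} - T_{buf})/2 \ \mathrm{otherwise.}}
#'
#' @param t_stim stimulus duration(s) (s), > 0.
#' @param t_buf buffer duration (s); `0` removes the buffer (pure serial
#'   time sharing).
#' @return effective per-stimulus sampling time(s) (s).
#' @examples
#' effective_duration(1.65)  # 0.865
#' @export
effective_duration <- function(t_stim, t_buf = 0.08) {
  if (any(t_stim <= 0)) stop("'t_stim' must be > 0", call. = FALSE)
  if (t_buf < 0) stop("'t_buf' must be >= 0", call. = FALSE)
  ifelse(t_stim <= t_buf, t_stim, t_buf + (t_stim - t_buf) / 2)
}

#' Simulate controlled-duration difficulty trials
#'
#' Runs the model's decision statistic over the effective per-stimulus
#' sampling time [effective_duration()] with the collapsing bound on that
#' shared clock. If no bound is crossed by stimulus offset, the choice is
#' the sign of the statistic at the end of accumulation (ties random).
#'
#' @inheritParams simulate_difficulty
#' @param durations stimulus durations (s), one per row of `pairs` or a
#'   scalar.
#' @param t_buf sensory buffer (s); default 0.08.
#' @return data.frame with `choice`, `decision_time` (sampling time at
#'   termination, on the per-stimulus clock) and `terminated_by`
#'   (bound/stimulus_offset).
#' @export
simulate_controlled <- function(model, params, pairs, durations,
                                t_buf = 0.08, dt = 0.005, conf_map = NULL,
                                seed = NULL) {
  model <- match.arg(model, difficulty_models())
  if (model %in% c("race", "two_step"))
    stop("controlled-duration simulation supports the difference, absolute, ",
         "known and confidence statistics", call. = FALSE)
  stopifnot(inherits(params, "difficulty_params"))
  durations <- rep_len(durations, nrow(pairs))
  tdur <- effective_duration(durations, t_buf)
  code <- difficulty_model_codes[[model]]
  if (model %in% c("confidence", "confidence_known")) {
    if (!inherits(conf_map, "confidence_map"))
      stop("confidence models require 'conf_map'", call. = FALSE)
    conf <- conf_map$logodds
    conf_dv_min <- conf_map$dv[1]
    conf_dv_step <- conf_map$dv[2] - conf_map$dv[1]
    conf_t_step <- conf_map$t_step
  } else {
    conf <- empty_conf_matrix(); conf_dv_min <- 0
    conf_dv_step <- 1; conf_t_step <- 1
  }
  b <- params$bound
  with_seed(seed, {
    sg <- resolve_signs(pairs)
    res <- cpp_sim_controlled(code, pairs$c1, pairs$c2, sg$s1, sg$s2,
                              params$kappa, b$u, b$a, b$d, tdur, dt,
                              conf, conf_dv_min, conf_dv_step, conf_t_step)
    data.frame(
      choice = factor(c("S1", "S2")[res$choice], levels = c("S1", "S2")),
      decision_time = res$decision_time,
      terminated_by = factor(c("bound", "stimulus_offset")[
        ifelse(res$terminated_by == 0L, 1L, 2L)],
        levels = c("bound", "horizon", "stimulus_offset"))
    )
  })
}

#' Serial decision-variable trajectories for one trial
#'
#' Returns the two DV paths of the serial, time-multiplexed accumulator on
#' the shared real-time grid (S1 updated on odd steps). Useful for
#' inspecting the accumulation process; the batch simulators are the
#' interface for behavior.
#'
#' @inheritParams simulate_difficulty
#' @param pair list or one-row data.frame with `c1`, `c2`.
#' @return data.frame with `t`, `dv1`, `dv2`, `sampled` ("S1"/"S2").
#' @export
serial_dv_paths <- function(params, pair, dt = 0.005, horizon = 5,
                            seed = NULL) {
  stopifnot(inherits(params, "difficulty_params"))
  n <- as.integer(ceiling(horizon / dt))
  with_seed(seed, {
    k <- seq_len(n)
    odd <- k %% 2L == 1L
    inc <- rnorm(n, mean = 0, sd = sqrt(dt))
    inc[odd] <- inc[odd] + params$kappa * pair$c1 * dt
    inc[!odd] <- inc[!odd] + params$kappa * pair$c2 * dt
    dv1 <- cumsum(ifelse(odd, inc, 0))
    dv2 <- cumsum(ifelse(odd, 0, inc))
    data.frame(t = k * dt, dv1 = dv1, dv2 = dv2,
               sampled = ifelse(odd, "S1", "S2"))
  })
}

#' Parallel-model parameters equivalent to a serial model
#'
#' Serial time-multiplexing gives each stimulus half of real time, so a
#' parallel integrator (both DVs sampled every step, unit variance per
#' second each) reproduces the serial model's choice/RT distributions on
#' the same real-time axis after rescaling the DV space: with exponent
#' \eqn{e}, \eqn{\kappa_p = \kappa_s 2^{-e}} and \eqn{u_p = u_s 2^{e}}
#' while `a` and `d` are unchanged. The default \eqn{e = 1/2} (i.e.
#' \eqn{\kappa_s/\sqrt2}, \eqn{u_s\sqrt2}) is the value for which the
#' equivalence is exact (each serial DV at real time \eqn{t} is a
#' \eqn{1/\sqrt2}-scaled unit-variance diffusion); the exponent is exposed
#' so the equivalence can be probed empirically.
#'
#' @param params a [difficulty_params()] of the serial model.
#' @param u_exponent exponent \eqn{e}; default 0.5.
#' @return a [difficulty_params()] for the parallel integrator (use
#'   `serial = FALSE` in [simulate_difficulty()]).
#' @export
serial_to_parallel <- function(params, u_exponent = 0.5) {
  stopifnot(inherits(params, "difficulty_params"))
  f <- 2^u_exponent
  difficulty_params(kappa = params$kappa / f,
                    bound = collapsing_bound(params$bound$u * f,
                                             params$bound$a, params$bound$d),
                    tnd_mean = params$tnd_mean, tnd_sd = params$tnd_sd,
                    b_mini = if (is.null(params$b_mini)) NULL
                             else params$b_mini * f)
}

#' Log-odds confidence map for sign-based color choices
#'
#' Builds a lookup table over (DV, accumulation time) of the log-odds that
#' the stimulus is blue-dominant given the DV: \eqn{P(C^\pm > 0 \mid dv,
#' t)} computed by marginalizing Gaussian likelihoods
#' \eqn{N(dv \mid \kappa C t, t)} over the discrete signed coherence set
#' with a uniform prior (zero-coherence levels contribute half their
#' posterior mass to each color). The log-odds is antisymmetric in DV and
#' 0 at \eqn{t = 0}; its absolute value is the log-odds that a
#' sign(DV)-based color choice is correct. Values are clipped at
#' `+/- clip`.
#'
#' @param kappa drift coefficient used to interpret the DV.
#' @param coherence_set signed coherence values with uniform prior;
#'   default the experimental 12-level set.
#' @param t_step time grid step (s); default 5 ms.
#' @param t_max largest tabulated accumulation time (s).
#' @param dv_max half-range of the DV grid.
#' @param dv_step DV grid step; default 0.025.
#' @param clip log-odds ceiling; default 10.
#' @return an object of class `confidence_map`.
#' @export
build_confidence_map <- function(kappa, coherence_set = signed_coherence_set()$value,
                                 t_step = 0.005, t_max = 5, dv_max = 6,
                                 dv_step = 0.025, clip = 10) {
  stopifnot_scalar(kappa, "kappa", positive = TRUE)
  if (length(coherence_set) < 1) stop("empty coherence set", call. = FALSE)
  dv <- seq(-dv_max, dv_max, by = dv_step)
  tt <- seq(0, t_max, by = t_step)
  nt <- length(tt)
  L <- matrix(0, nrow = length(dv), ncol = nt)
  w_blue <- ifelse(coherence_set > 0, 1, ifelse(coherence_set == 0, 0.5, 0))
  for (j in 2:nt) {
    t <- tt[j]
    lik <- vapply(coherence_set,
                  function(C) dnorm(dv, mean = kappa * C * t, sd = sqrt(t)),
                  numeric(length(dv)))
    post <- lik / pmax(rowSums(lik), .Machine$double.xmin)
    p_blue <- pmin(pmax(as.vector(post %*% w_blue), 1e-12), 1 - 1e-12)
    L[, j] <- pmin(pmax(log(p_blue / (1 - p_blue)), -clip), clip)
  }
  structure(list(logodds = L, dv = dv, t_step = t_step, t = tt,
                 clip = clip, kappa = kappa, coherence_set = coherence_set),
            class = "confidence_map")
}

#' Evaluate a confidence map
#'
#' Bilinear interpolation of the signed log-odds at (dv, t).
#'
#' @param map a `confidence_map`.
#' @param dv decision-variable value(s).
#' @param t accumulation time(s) (s).
#' @return signed log-odds that the stimulus is blue-dominant; take the
#'   absolute value for the log-odds of a sign(DV)-based choice being
#'   correct.
#' @export
confidence_logodds <- function(map, dv, t) {
  stopifnot(inherits(map, "confidence_map"))
  n <- max(length(dv), length(t))
  dv <- rep_len(dv, n); t <- rep_len(t, n)
  dv_min <- map$dv[1]
  dv_step <- map$dv[2] - map$dv[1]
  nr <- length(map$dv); nc <- ncol(map$logodds)
  ri <- pmin(pmax((dv - dv_min) / dv_step, 0), nr - 1)
  ci <- pmin(pmax(t / map$t_step, 0), nc - 1)
  r0 <- floor(ri); c0 <- floor(ci)
  r1 <- pmin(r0 + 1, nr - 1); c1 <- pmin(c0 + 1, nc - 1)
  fr <- ri - r0; fc <- ci - c0
  M <- map$logodds
  (1 - fr) * ((1 - fc) * M[cbind(r0 + 1, c0 + 1)] + fc * M[cbind(r0 + 1, c1 + 1)]) +
    fr * ((1 - fc) * M[cbind(r1 + 1, c0 + 1)] + fc * M[cbind(r1 + 1, c1 + 1)])
}
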