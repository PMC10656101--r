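#' Logistic collapsing decision bound
#'
#' The upper decision bound is parameterized as a logistic function of
#' elapsed decision time, \eqn{B(t) = u / (1 + e^{a(t - d)})}: it starts
#' near \eqn{u}, collapses at a rate governed by \eqn{a}, reaches
#' \eqn{u/2} at \eqn{t = d} and approaches 0 as \eqn{t \to \infty}.
#' The lower bound is its negation. `a = 0` gives a flat bound at `u/2`.
#'
#' @param u bound scale (evidence units), > 0.
#' @param a collapse rate (1/s), >= 0.
#' @param d half-height time (s).
#' @return an object of class `collapsing_bound`.
#' @examples
#' b <- collapsing_bound(u = 2, a = 3, d = 1)
#' bound_height(b, 1)  # u/2 = 1
#' @export
collapsing_bound <- function(u, a, d) {
  stopifnot_scalar(u, "u", positive = TRUE)
  stopifnot_scalar(a, "a")
  stopifnot_scalar(d, "d")
  if (a < 0) stop("'a' must be >= 0", call. = FALSE)
  structure(list(u = u, a = a, d = d), class = "collapsing_bound")
}

#' @rdname collapsing_bound
#' @param bound a `collapsing_bound`.
#' @param t time (s), vectorized.
#' @export
bound_height <- function(bound, t) {
  stopifnot(inherits(bound, "collapsing_bound"))
  z <- bound$a * (t - bound$d)
  ifelse(z > 0,
         bound$u * exp(-z) / (1 + exp(-z)),
         bound$u / (1 + exp(z)))
}

#' @export
print.collapsing_bound <- function(x, ...) {
  cat(sprintf("Logistic collapsing bound: u = %g, a = %g /s, d = %g s\n",
              x$u, x$a, x$d))
  invisible(x)
}

#' Parameters of the color drift diffusion model
#'
#' Bundles the parameters of the single-accumulator color DDM: drift
#' coefficient `kappa` (the drift is \eqn{\mu = \kappa (C^\pm + C_0)}),
#' coherence-bias offset `c0`, the collapsing bound, and the Gaussian
#' non-decision time. The diffusion variance is fixed at 1 per second by
#' convention.
#'
#' @param kappa drift coefficient (evidence/s per unit coherence), > 0.
#' @param c0 coherence-bias offset (dimensionless); modeled as an offset in
#'   coherence rather than a starting-point shift.
#' @param bound a [collapsing_bound()].
#' @param tnd_mean mean non-decision time (s), > 0.
#' @param tnd_sd SD of the non-decision time (s); fixed default 0.05.
#' @return an object of class `color_ddm_params`.
#' @export
color_ddm_params <- function(kappa, c0 = 0, bound, tnd_mean, tnd_sd = 0.05) {
  stopifnot_scalar(kappa, "kappa", positive = TRUE)
  stopifnot_scalar(c0, "c0")
  stopifnot(inherits(bound, "collapsing_bound"))
  stopifnot_scalar(tnd_mean, "tnd_mean", positive = TRUE)
  stopifnot_scalar(tnd_sd, "tnd_sd")
  if (tnd_sd < 0) stop("'tnd_sd' must be >= 0", call. = FALSE)
  structure(list(kappa = kappa, c0 = c0, bound = bound,
                 tnd_mean = tnd_mean, tnd_sd = tnd_sd),
            class = "color_ddm_params")
}

#' Drift rate for a signed coherence
#'
#' @param params a [color_ddm_params()].
#' @param coherence signed coherence(s).
#' @return drift \eqn{\mu = \kappa (C^\pm + C_0)} (evidence/s).
#' @export
drift_rate <- function(params, coherence) {
  stopifnot(inherits(params, "color_ddm_params"))
  params$kappa * (coherence + params$c0)
}

#' Simulate first-passage trials of the color DDM
#'
#' Euler simulation of the accumulation process
#' \eqn{\Delta DV = \mu \Delta t + N(0, \Delta t)} with absorbing logistic
#' collapsing bounds. Crossings are registered on the step grid (no
#' sub-step interpolation). Trials that never cross within `horizon`
#' return boundary `"none"` with `decision_time = horizon`.
#'
#' @param params a [color_ddm_params()].
#' @param coherence signed coherence (scalar).
#' @param n number of trials.
#' @param dt time step (s), default 0.5 ms.
#' @param horizon maximum accumulation time (s).
#' @param seed optional integer seed (local to this call).
#' @return data.frame with columns `boundary` (factor upper/lower/none)
#'   and `decision_time` (s).
#' @export
simulate_first_passage <- function(params, coherence, n = 1L, dt = 5e-4,
                                   horizon = 6, seed = NULL) {
  stopifnot(inherits(params, "color_ddm_params"))
  stopifnot_scalar(dt, "dt", positive = TRUE)
  stopifnot_scalar(horizon, "horizon", positive = TRUE)
  mu <- drift_rate(params, coherence)
  b <- params$bound
  res <- with_seed(seed, cpp_sim_fp(as.integer(n), mu, dt, horizon,
                                    b$u, b$a, b$d))
  data.frame(
    boundary = factor(c("lower", "none", "upper")[res$hit + 2L],
                      levels = c("upper", "lower", "none")),
    decision_time = res$time
  )
}

#' Choice and decision-time densities by density propagation
#'
#' Computes the joint defect densities over (choice boundary, decision
#' time) for the color DDM by forward propagation of the discrete-time
#' accumulation density on a uniform DV grid with absorbing collapsing
#' bounds (the grid analogue of solving the Fokker-Planck equation for the
#' drift-diffusion process). Each step applies the exactly-binned Gaussian
#' step kernel and absorbs the mass at or beyond \eqn{\pm B(t)}.
#'
#' @inheritParams simulate_first_passage
#' @param dv_step DV grid step; default `u/200` (at least 200 cells per
#'   bound height, and capped at `sqrt(dt)/2` so the step kernel is
#'   resolved). Values above `sqrt(dt)` are a configuration error.
#' @return an object of class `choice_rt_distribution`: list with `t`
#'   (time grid, step `dt`), `density_upper`, `density_lower` (defect
#'   densities, 1/s), `surviving` (unabsorbed mass at the horizon) and
#'   `dt`.
#' @export
fp_choice_rt_density <- function(params, coherence, dt = 5e-4,
                                 dv_step = NULL, horizon = 6) {
  stopifnot(inherits(params, "color_ddm_params"))
  stopifnot_scalar(dt, "dt", positive = TRUE)
  stopifnot_scalar(horizon, "horizon", positive = TRUE)
  b <- params$bound
  if (is.null(dv_step)) dv_step <- min(b$u / 200, sqrt(dt) / 2)
  stopifnot_scalar(dv_step, "dv_step", positive = TRUE)
  if (dv_step > sqrt(dt))
    stop(sprintf(paste0("grid too coarse: dv_step = %g exceeds sqrt(dt) = %g; ",
                        "the one-step kernel is not resolved. Decrease dv_step ",
                        "or increase dt."), dv_step, sqrt(dt)), call. = FALSE)
  mu <- drift_rate(params, coherence)
  res <- cpp_fp_propagate(mu, dt, dv_step, horizon, b$u, b$a, b$d)
  structure(list(t = res$t, density_upper = res$up, density_lower = res$lo,
                 surviving = res$surviving, dt = dt),
            class = "choice_rt_distribution")
}

#' @export
print.choice_rt_distribution <- function(x, ...) {
  pu <- sum(x$density_upper) * x$dt
  pl <- sum(x$density_lower) * x$dt
  cat(sprintf(paste0("Choice/RT distribution on [%g, %g] s (dt = %g s)\n",
                     "  P(upper) = %.4f, P(lower) = %.4f, surviving = %.2e\n"),
              x$t[1], x$t[length(x$t)], x$dt, pu, pl, x$surviving))
  invisible(x)
}

#' @export
as.data.frame.choice_rt_distribution <- function(x, ...) {
  data.frame(t = x$t, density_upper = x$density_upper,
             density_lower = x$density_lower)
}

#' Summary statistics of a choice/RT distribution
#'
#' @param object a `choice_rt_distribution`.
#' @param ... unused.
#' @return list with choice probabilities and mean times per boundary.
#' @export
summary.choice_rt_distribution <- function(object, ...) {
  dt <- object$dt
  pu <- sum(object$density_upper) * dt
  pl <- sum(object$density_lower) * dt
  list(p_upper = pu, p_lower = pl, surviving = object$surviving,
       mean_t_upper = if (pu > 0) sum(object$t * object$density_upper) * dt / pu else NA_real_,
       mean_t_lower = if (pl > 0) sum(object$t * object$density_lower) * dt / pl else NA_real_)
}

#' Add Gaussian non-decision time to a decision-time distribution
#'
#' Convolves both defect densities with a Gaussian of mean `tnd_mean` and
#' SD `tnd_sd`. Mass carried to negative RT by the convolution is
#' truncated and renormalized away (for realistic settings, e.g.
#' `tnd_mean >= 0.2`, `tnd_sd = 0.05`, that mass is below 1e-6). With
#' `tnd_sd = 0` the densities are shifted by `tnd_mean` (rounded to the
#' time grid).
#'
#' @param dist a `choice_rt_distribution` over decision time.
#' @param tnd_mean mean non-decision time (s), > 0.
#' @param tnd_sd SD of the non-decision time (s), >= 0.
#' @return a `choice_rt_distribution` over reaction time; the time grid is
#'   extended to cover the shifted support.
#' @export
add_nondecision <- function(dist, tnd_mean, tnd_sd = 0.05) {
  stopifnot(inherits(dist, "choice_rt_distribution"))
  stopifnot_scalar(tnd_mean, "tnd_mean", positive = TRUE)
  stopifnot_scalar(tnd_sd, "tnd_sd")
  dt <- dist$dt
  n <- length(dist$t)

  if (tnd_sd == 0) {
    shift <- as.integer(round(tnd_mean / dt))
    t_new <- seq_len(n + shift) * dt
    pad <- function(x) c(rep(0, shift), x)
    return(structure(list(t = t_new, density_upper = pad(dist$density_upper),
                          density_lower = pad(dist$density_lower),
                          surviving = dist$surviving, dt = dt),
                     class = "choice_rt_distribution"))
  }

  # binned Gaussian kernel centred on tnd_mean, offsets in steps of dt
  k_lo <- as.integer(floor((tnd_mean - 5 * tnd_sd) / dt))
  k_hi <- as.integer(ceiling((tnd_mean + 5 * tnd_sd) / dt))
  off <- k_lo:k_hi
  edges <- (c(off, k_hi + 1L) - 0.5) * dt
  w <- diff(pnorm(edges, mean = tnd_mean, sd = tnd_sd))
  w <- w / sum(w)

  conv_one <- function(dens) {
    out <- rep(0, n + k_hi)
    mass_neg <- 0
    for (j in seq_along(off)) {
      idx <- seq_len(n) + off[j]
      keep <- idx >= 1L
      out[idx[keep]] <- out[idx[keep]] + dens[keep] * w[j]
      if (any(!keep)) mass_neg <- mass_neg + sum(dens[!keep]) * w[j]
    }
    list(dens = out, lost = mass_neg * dt)
  }
  up <- conv_one(dist$density_upper)
  lo <- conv_one(dist$density_lower)
  lost <- up$lost + lo$lost
  total_before <- (sum(dist$density_upper) + sum(dist$density_lower)) * dt
  scale <- if (total_before - lost > 0) total_before / (total_before - lost) else 1
  structure(list(t = seq_len(n + k_hi) * dt,
                 density_upper = up$dens * scale,
                 density_lower = lo$dens * scale,
                 surviving = dist$surviving, dt = dt),
            class = "choice_rt_distribution")
}

#' Export a choice/RT density to CSV
#'
#' Writes columns `t`, `density_upper`, `density_lower`.
#'
#' @param dist a `choice_rt_distribution`.
#' @param path output file path.
#' @export
write_density_csv <- function(dist, path) {
  write.csv(as.data.frame(dist), path, row.names = FALSE)
  invisible(path)
}
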