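#' Default parameter box for model fitting
#'
#' Box bounds used by the bounded derivative-free optimizer. Strictly
#' positive parameters are searched on the log scale internally.
#'
#' @param model one of [difficulty_models()] or "color_ddm".
#' @return named list of c(lower, upper) pairs.
#' @export
default_param_bounds <- function(model = "difference") {
  b <- list(kappa = c(1e-3, 40), u = c(1e-3, 10), a = c(0, 10),
            d = c(0, 5), tnd = c(0.1, 1))
  if (model == "two_step") b$b_mini <- c(1e-3, 3)
  if (model == "color_ddm") b$c0 <- c(-0.3, 0.3)
  b
}

kernel_epanechnikov <- function(x) ifelse(abs(x) < 1, 0.75 * (1 - x^2), 0)

# Silverman-style bandwidth with a floor of 2*dt
epanechnikov_bw <- function(x, dt) {
  n <- length(x)
  if (n < 2) return(2 * dt)
  s <- sd(x)
  iqr <- diff(quantile(x, c(0.25, 0.75), names = FALSE)) / 1.34
  sig <- min(s, if (iqr > 0) iqr else s)
  if (!is.finite(sig) || sig <= 0) sig <- dt
  max(2 * dt, 2.34 * sig * n^(-1 / 5))
}

condition_key <- function(c1, c2, s1 = NULL, s2 = NULL, use_signs = FALSE) {
  if (use_signs) paste(c1, s1, c2, s2, sep = "|") else paste(c1, c2, sep = "|")
}

model_uses_signs <- function(model) {
  model %in% c("known", "confidence_known")
}

#' Simulation-based smoothed likelihood table
#'
#' For every unique signed-coherence pair in `design`, simulates
#' `n_sim` trials of the model and summarizes them as a choice-probability
#' mass times an Epanechnikov-kernel smoothed RT density per choice. The
#' bandwidth is a Silverman-style rule per (condition, choice) cell with a
#' floor of `2 * dt`; evaluated likelihoods are floored at `floor` so a
#' data RT outside the simulated support never contributes -Inf.
#'
#' @inheritParams simulate_difficulty
#' @param design data.frame of conditions with columns `c1`, `c2` (and
#'   sign tags for sign-using models); duplicated rows are collapsed.
#' @param n_sim simulated trials per condition; default 1000.
#' @param floor density floor (1/s); default 1e-5.
#' @param sim_seed integer seed for the simulation stream (common random
#'   numbers across repeated calls).
#' @return an object of class `smoothed_likelihood`.
#' @export
simulate_likelihood_table <- function(model, params, design, n_sim = 1000,
                                      dt = 0.005, horizon = 5,
                                      conf_map = NULL, floor = 1e-5,
                                      sim_seed = 1L) {
  model <- match.arg(model, difficulty_models())
  use_signs <- model_uses_signs(model)
  sg <- list(s1 = if ("c1_sign" %in% names(design)) design$c1_sign else sign(design$c1),
             s2 = if ("c2_sign" %in% names(design)) design$c2_sign else sign(design$c2))
  key <- condition_key(design$c1, design$c2, sg$s1, sg$s2, use_signs)
  conds <- !duplicated(key)
  cond_df <- data.frame(c1 = design$c1[conds], c2 = design$c2[conds],
                        c1_sign = sg$s1[conds], c2_sign = sg$s2[conds],
                        key = key[conds], stringsAsFactors = FALSE)
  if (use_signs && any(cond_df$c1_sign == 0 | cond_df$c2_sign == 0))
    stop("sign-using models need nonzero sign tags (c1_sign/c2_sign)",
         call. = FALSE)

  big <- cond_df[rep(seq_len(nrow(cond_df)), each = n_sim), ]
  sim <- simulate_difficulty(model, params, big, dt = dt, horizon = horizon,
                             conf_map = conf_map, seed = sim_seed)
  idx <- rep(seq_len(nrow(cond_df)), each = n_sim)
  cells <- vector("list", nrow(cond_df))
  names(cells) <- cond_df$key
  for (i in seq_len(nrow(cond_df))) {
    rows <- idx == i
    ch <- sim$choice[rows]
    rt <- sim$rt[rows]
    cell <- list()
    for (cc in c("S1", "S2")) {
      r <- rt[ch == cc]
      cell[[cc]] <- list(p = length(r) / n_sim, rts = r,
                         bw = epanechnikov_bw(r, dt))
    }
    cells[[i]] <- cell
  }
  structure(list(cells = cells, conditions = cond_df, model = model,
                 n_sim = n_sim, dt = dt, floor = floor,
                 use_signs = use_signs, sim_seed = sim_seed),
            class = "smoothed_likelihood")
}

#' Evaluate the smoothed likelihood of (choice, RT) observations
#'
#' @param table a [simulate_likelihood_table()] result.
#' @param key condition keys (internal format) or NULL to build from
#'   `c1`, `c2`.
#' @param choice factor/character vector of choices ("S1"/"S2").
#' @param rt reaction times (s).
#' @param c1,c2,s1,s2 condition descriptors used when `key` is NULL.
#' @return per-trial likelihood values (1/s), floored.
#' @keywords internal
likelihood_at <- function(table, choice, rt, c1, c2, s1 = NULL, s2 = NULL) {
  key <- condition_key(c1, c2, s1, s2, table$use_signs)
  miss <- !(key %in% names(table$cells))
  if (any(miss))
    stop("data contain conditions absent from the likelihood table: ",
         paste(unique(key[miss]), collapse = ", "), call. = FALSE)
  out <- numeric(length(rt))
  choice <- as.character(choice)
  for (k in unique(key)) {
    cell <- table$cells[[k]]
    rows <- key == k
    for (cc in c("S1", "S2")) {
      rr <- rows & choice == cc
      if (!any(rr)) next
      sub <- cell[[cc]]
      if (length(sub$rts) == 0) {
        warning("condition ", k, " choice ", cc, " has no simulated ",
                "trials; likelihood floored", call. = FALSE)
        out[rr] <- table$floor
        next
      }
      h <- sub$bw
      dens <- vapply(rt[rr], function(x)
        mean(kernel_epanechnikov((x - sub$rts) / h)) / h, numeric(1))
      out[rr] <- pmax(sub$p * dens, table$floor)
    }
  }
  out
}

#' Negative log-likelihood of a trial table under a likelihood table
#'
#' Sums \eqn{-\log f(\mathrm{choice}, \mathrm{RT})} over trials using the
#' smoothed simulation-based likelihood. Empty data give 0.
#'
#' @param data data.frame with `choice`, `rt`, `c1`, `c2` (and sign tags
#'   for sign-using models).
#' @param table a `smoothed_likelihood`.
#' @return scalar negative log-likelihood.
#' @export
negative_log_likelihood <- function(data, table) {
  stopifnot(inherits(table, "smoothed_likelihood"))
  if (nrow(data) == 0) return(0)
  s1 <- if ("c1_sign" %in% names(data)) data$c1_sign else sign(data$c1)
  s2 <- if ("c2_sign" %in% names(data)) data$c2_sign else sign(data$c2)
  lik <- likelihood_at(table, data$choice, data$rt, data$c1, data$c2, s1, s2)
  -sum(log(lik))
}

# ---- bounded derivative-free optimizer (multi-start Nelder-Mead on a
# logit-transformed box) ----

box_to_unbounded <- function(p, lower, upper) {
  z <- (p - lower) / (upper - lower)
  z <- pmin(pmax(z, 1e-8), 1 - 1e-8)
  log(z / (1 - z))
}

unbounded_to_box <- function(z, lower, upper) {
  lower + (upper - lower) / (1 + exp(-z))
}

#' Minimize a function over a box without derivatives
#'
#' Multi-start Nelder-Mead on a logistic transformation of the box. The
#' objective must be deterministic (use common random numbers for
#' simulation-based objectives). Start points are drawn uniformly from the
#' central 80% of the box; the first start can be supplied.
#'
#' @param fn objective taking a named parameter vector on the natural
#'   scale.
#' @param lower,upper named numeric vectors of box bounds.
#' @param n_starts number of local-search starts.
#' @param start optional first start (natural scale).
#' @param maxit Nelder-Mead iteration cap per start (a restart from the
#'   interim optimum with a fresh simplex, at half the cap, guards
#'   against simplex collapse).
#' @param presearch number of random presearch evaluations; the best
#'   points seed the local searches.
#' @param seed seed for drawing starts.
#' @return list with `par`, `value`, `starts` (per-start trace).
#' @export
optimize_box <- function(fn, lower, upper, n_starts = 10, start = NULL,
                         maxit = 300, presearch = 12 * length(lower),
                         seed = NULL) {
  stopifnot(length(lower) == length(upper), all(upper > lower))
  nm <- names(lower)
  obj <- function(z) fn(setNames(unbounded_to_box(z, lower, upper), nm))
  cand <- with_seed(seed, {
    # Latin-hypercube presearch over the central 90% of the box
    np <- max(presearch, n_starts)
    k <- length(lower)
    u <- vapply(seq_len(k), function(j) (sample(np) - runif(np)) / np,
                numeric(np))
    lapply(seq_len(np), function(i)
      lower + (0.05 + 0.9 * u[i, ]) * (upper - lower))
  })
  if (!is.null(start)) cand <- c(list(start), cand)
  cand_val <- vapply(cand, function(p) {
    v <- tryCatch(fn(setNames(p, nm)), error = function(e) NA_real_)
    if (is.finite(v)) v else Inf
  }, numeric(1))
  # greedy selection of good but mutually distant starts (normalized box
  # coordinates), so separate likelihood basins each get a local search
  ord <- order(cand_val)
  norm01 <- function(p) (p - lower) / (upper - lower)
  starts <- list()
  for (i in ord) {
    if (!is.finite(cand_val[i])) break
    pz <- norm01(cand[[i]])
    far <- all(vapply(starts, function(q)
      sqrt(sum((norm01(q) - pz)^2)), numeric(1)) >= 0.25)
    if (length(starts) == 0 || far) starts <- c(starts, list(cand[[i]]))
    if (length(starts) == n_starts) break
  }
  for (i in ord) {  # fill up if the diversity filter was too strict
    if (length(starts) == n_starts) break
    starts <- c(starts, list(cand[[i]]))
  }

  traces <- vector("list", n_starts)
  best <- NULL
  for (i in seq_len(n_starts)) {
    z0 <- box_to_unbounded(starts[[i]], lower, upper)
    res <- tryCatch({
      r1 <- optim(z0, obj, method = "Nelder-Mead",
                  control = list(maxit = maxit, reltol = 1e-7))
      r2 <- optim(r1$par, obj, method = "Nelder-Mead",
                  control = list(maxit = ceiling(maxit / 2), reltol = 1e-7))
      if (r2$value < r1$value) r2 else r1
    }, error = function(e) NULL)
    if (is.null(res)) {
      traces[[i]] <- list(start = starts[[i]], value = NA_real_,
                          error = TRUE)
      next
    }
    par <- setNames(unbounded_to_box(res$par, lower, upper), nm)
    traces[[i]] <- list(start = starts[[i]], par = par, value = res$value,
                        error = FALSE)
    if (is.null(best) || res$value < best$value)
      best <- list(par = par, value = res$value)
  }
  if (is.null(best))
    stop("optimizer failed on all starts; traces attached",
         call. = FALSE)
  list(par = best$par, value = best$value, starts = traces)
}

new_fit_result <- function(model, par, logLik, n_trials, n_params, starts,
                           seed) {
  structure(list(model = model, par = par, logLik = logLik,
                 n_trials = n_trials, n_params = n_params,
                 bic = bic(logLik, n_params, n_trials),
                 starts = starts, seed = seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit of the %s model: logLik = %.2f, BIC = %.2f (k = %d, n = %d)\n",
              x$model, x$logLik, x$bic, x$n_params, x$n_trials))
  print(round(unlist(x$par), 4))
  invisible(x)
}

params_from_vector <- function(model, p) {
  difficulty_params(kappa = p[["kappa"]],
                    bound = collapsing_bound(p[["u"]], p[["a"]], p[["d"]]),
                    tnd_mean = p[["tnd"]],
                    b_mini = if (model == "two_step") p[["b_mini"]] else NULL)
}

#' Fit a difficulty model by simulation-based maximum likelihood
#'
#' Minimizes [negative_log_likelihood()] of the data under
#' [simulate_likelihood_table()] regenerated at each candidate parameter
#' vector with a fixed simulation seed (common random numbers), so the
#' objective is deterministic. Free parameters: kappa, u, a, d, tnd
#' (+ b_mini for the two-step model).
#'
#' @param model one of [difficulty_models()].
#' @param data trial table with `choice`, `rt`, `c1`, `c2` (+ sign tags).
#' @param n_starts optimizer starts; default 10.
#' @param n_sim simulated trials per condition per objective evaluation.
#' @param dt simulation step (s).
#' @param horizon response deadline (s).
#' @param param_bounds named list of c(lower, upper); default
#'   [default_param_bounds()].
#' @param maxit Nelder-Mead iteration cap per start.
#' @param seed seed controlling the starts and the common-random-number
#'   simulation stream.
#' @param start optional first start.
#' @param tnd_step grid step (s) for the profiled non-decision mean.
#' @param presearch random presearch evaluations before the local
#'   searches (see [optimize_box()]); NULL for the optimizer default.
#' @return a `fit_result`.
#' @export
fit_difficulty_model <- function(model, data, n_starts = 10, n_sim = 1000,
                                 dt = 0.005, horizon = 5,
                                 param_bounds = default_param_bounds(model),
                                 maxit = 300, seed = 1L, start = NULL,
                                 tnd_step = 0.01, presearch = NULL) {
  model <- match.arg(model, difficulty_models())
  code <- difficulty_model_codes[[model]]
  use_signs <- model_uses_signs(model)
  s1 <- if ("c1_sign" %in% names(data)) data$c1_sign else sign(data$c1)
  s2 <- if ("c2_sign" %in% names(data)) data$c2_sign else sign(data$c2)
  key <- condition_key(data$c1, data$c2, s1, s2, use_signs)
  uk <- which(!duplicated(key))
  cond_idx <- match(key, key[uk]) - 1L
  choice_int <- ifelse(as.character(data$choice) == "S1", 1L, 2L)
  cc1 <- data$c1[uk]; cc2 <- data$c2[uk]
  ss1 <- as.integer(s1[uk]); ss2 <- as.integer(s2[uk])
  # the non-decision mean only shifts simulated RTs, so it is profiled out
  # on a grid inside the objective; the optimizer searches the remaining
  # dimensions
  tnd_box <- param_bounds$tnd
  tnd_grid <- seq(tnd_box[1], tnd_box[2], by = tnd_step)
  search_bounds <- param_bounds[setdiff(names(param_bounds), "tnd")]
  lower <- vapply(search_bounds, `[`, numeric(1), 1)
  upper <- vapply(search_bounds, `[`, numeric(1), 2)
  sim_seed <- sub_seed(seed, 7L)
  is_conf <- model %in% c("confidence", "confidence_known")
  eval_nll <- function(p) {
    conf <- if (is_conf) {
      build_confidence_map(p[["kappa"]], dv_step = 0.05, t_step = 0.02)
    } else NULL
    cpp_difficulty_nll(code, cc1, cc2, ss1, ss2, as.integer(n_sim),
                       cond_idx, choice_int, data$rt,
                       p[["kappa"]], p[["u"]], p[["a"]], p[["d"]],
                       if (model == "two_step") p[["b_mini"]] else 0,
                       tnd_grid, 0.05, dt, horizon, 1e-5, sim_seed,
                       if (is_conf) conf$logodds else empty_conf_matrix(),
                       if (is_conf) conf$dv[1] else 0,
                       if (is_conf) conf$dv[2] - conf$dv[1] else 1,
                       if (is_conf) conf$t_step else 1)
  }
  fn <- function(p) eval_nll(p)$nll
  if (!is.null(start)) start <- start[setdiff(names(start), "tnd")]
  if (is.null(presearch)) presearch <- 12 * length(lower)
  res <- optimize_box(fn, lower, upper, n_starts = n_starts, start = start,
                      maxit = maxit, presearch = presearch,
                      seed = sub_seed(seed, 11L))
  par <- as.list(res$par)
  par$tnd <- eval_nll(res$par)$tnd
  new_fit_result(model, par, -res$value, nrow(data),
                 length(param_bounds), res$starts, seed)
}

#' Fit the color drift diffusion model
#'
#' Maximum-likelihood fit of the single-stimulus color DDM
#' (parameters kappa, c0, u, a, d, tnd) using the propagated choice/RT
#' densities of [fp_choice_rt_density()] convolved with the Gaussian
#' non-decision time. Choices must be coded "blue" (upper boundary) or
#' "yellow" (lower).
#'
#' @param data data.frame with `c1` (signed coherence), `choice`
#'   ("blue"/"yellow") and `rt` (s).
#' @param n_starts optimizer starts.
#' @param dt density time step for fitting (s); coarser than the default
#'   simulation step to keep refitting affordable.
#' @param horizon density horizon (s).
#' @param tnd_sd fixed non-decision SD (s).
#' @param param_bounds named list of box bounds.
#' @param maxit iteration cap per start.
#' @param seed seed for the optimizer starts.
#' @param start optional first start.
#' @return a `fit_result`.
#' @export
fit_color_ddm <- function(data, n_starts = 10, dt = 0.002, horizon = 6,
                          tnd_sd = 0.05,
                          param_bounds = default_param_bounds("color_ddm"),
                          maxit = 300, seed = 1L, start = NULL) {
  stopifnot(all(c("c1", "choice", "rt") %in% names(data)))
  cohs <- sort(unique(data$c1))
  ch <- as.character(data$choice)
  floor_d <- 1e-5
  fn <- function(p) {
    params <- color_ddm_params(p[["kappa"]], p[["c0"]],
                               collapsing_bound(p[["u"]], p[["a"]], p[["d"]]),
                               tnd_mean = p[["tnd"]], tnd_sd = tnd_sd)
    nll <- 0
    for (co in cohs) {
      dens <- add_nondecision(
        fp_choice_rt_density(params, co, dt = dt, horizon = horizon),
        p[["tnd"]], tnd_sd)
      rows <- data$c1 == co
      idx <- pmin(pmax(round(data$rt[rows] / dt), 1L), length(dens$t))
      li <- ifelse(ch[rows] == "blue",
                   dens$density_upper[idx], dens$density_lower[idx])
      nll <- nll - sum(log(pmax(li, floor_d)))
    }
    nll
  }
  lower <- vapply(param_bounds, `[`, numeric(1), 1)
  upper <- vapply(param_bounds, `[`, numeric(1), 2)
  res <- optimize_box(fn, lower, upper, n_starts = n_starts, start = start,
                      maxit = maxit, seed = sub_seed(seed, 13L))
  new_fit_result("color_ddm", as.list(res$par), -res$value, nrow(data),
                 length(lower), res$starts, seed)
}

#' Joint fit of controlled-duration choices (unknown + known color)
#'
#' Choice-only maximum likelihood for the controlled-duration paradigm:
#' for each (coherence pair, duration) cell the model's choice probability
#' is estimated from `n_sim` simulated trials (difference statistic for
#' the unknown-color condition, signed difference for known color) and the
#' binomial likelihood of the observed choices is maximized. Free
#' parameters: kappa, u, a, d (plus a second kappa for the known condition
#' when `single_kappa = FALSE`). The sensory buffer enters through
#' [effective_duration()]; `use_buffer = FALSE` sets the buffer to 0.
#'
#' Equal-strength trials and different-dominance pairs must be excluded
#' from the unknown-color data (see [exp2_analysis_filter()]); rows
#' violating this are dropped with a warning.
#'
#' @param data_unknown,data_known trial tables with `c1`, `c2`, sign tags,
#'   `duration`, `choice`.
#' @param single_kappa share kappa across conditions (default TRUE).
#' @param use_buffer include the 80 ms buffer (default TRUE).
#' @param n_sim simulated trials per cell per objective evaluation.
#' @param dt simulation step (s).
#' @param n_starts,maxit,seed optimizer controls.
#' @param param_bounds box bounds for kappa, u, a, d (kappa_known added
#'   automatically when `single_kappa = FALSE`).
#' @return a `fit_result` (n_params 4 or 5).
#' @export
fit_controlled_duration <- function(data_unknown, data_known,
                                    single_kappa = TRUE, use_buffer = TRUE,
                                    n_sim = 2000, dt = 0.005, n_starts = 10,
                                    maxit = 300, seed = 1L,
                                    param_bounds = NULL) {
  t_buf <- if (use_buffer) 0.08 else 0
  keep <- abs(data_unknown$c1) != abs(data_unknown$c2) &
    sign_tag(data_unknown, "c1") == sign_tag(data_unknown, "c2")
  if (!all(keep)) {
    warning("dropping equal-strength or different-dominance rows from the ",
            "unknown-color data (", sum(!keep), " trials)")
    data_unknown <- data_unknown[keep, ]
  }
  gu <- sort(unique(abs(c(data_unknown$c1, data_unknown$c2))))
  gk <- sort(unique(abs(c(data_known$c1, data_known$c2))))
  if (!all(gk %in% gu) && !all(gu %in% gk))
    stop("unknown and known conditions must share the coherence grid",
         call. = FALSE)
  if (is.null(param_bounds))
    param_bounds <- default_param_bounds("difference")[c("kappa", "u", "a", "d")]
  if (!single_kappa) param_bounds$kappa_known <- param_bounds$kappa
  sim_seed <- sub_seed(seed, 17L)

  prep <- function(dat, model) {
    key <- paste(dat$c1, sign_tag(dat, "c1"), dat$c2, sign_tag(dat, "c2"),
                 dat$duration, sep = "|")
    uk <- which(!duplicated(key))
    list(code = difficulty_model_codes[[model]],
         c1 = dat$c1[uk], c2 = dat$c2[uk],
         s1 = as.integer(sign_tag(dat, "c1")[uk]),
         s2 = as.integer(sign_tag(dat, "c2")[uk]),
         tdur = effective_duration(dat$duration[uk], t_buf),
         idx = match(key, key[uk]) - 1L,
         choice = ifelse(as.character(dat$choice) == "S1", 1L, 2L))
  }
  pu <- prep(data_unknown, "difference")
  pk <- prep(data_known, "known")

  cell_nll <- function(pp, kappa, u, a, d, seed_k) {
    cpp_controlled_nll(pp$code, pp$c1, pp$c2, pp$s1, pp$s2, pp$tdur,
                       as.integer(n_sim), pp$idx, pp$choice,
                       kappa, u, a, d, dt, seed_k)
  }
  fn <- function(p) {
    ku <- p[["kappa"]]
    kk <- if (single_kappa) ku else p[["kappa_known"]]
    cell_nll(pu, ku, p[["u"]], p[["a"]], p[["d"]], sim_seed) +
      cell_nll(pk, kk, p[["u"]], p[["a"]], p[["d"]], sim_seed + 1L)
  }
  lower <- vapply(param_bounds, `[`, numeric(1), 1)
  upper <- vapply(param_bounds, `[`, numeric(1), 2)
  res <- optimize_box(fn, lower, upper, n_starts = n_starts, maxit = maxit,
                      seed = sub_seed(seed, 19L))
  n_tot <- nrow(data_unknown) + nrow(data_known)
  new_fit_result(if (single_kappa) "controlled_single_kappa"
                 else "controlled_two_kappa",
                 as.list(res$par), -res$value, n_tot, length(lower),
                 res$starts, seed)
}

sign_tag <- function(dat, col) {
  tag <- paste0(col, "_sign")
  if (tag %in% names(dat)) dat[[tag]] else sign(dat[[col]])
}

#' Bayesian information criterion
#'
#' \eqn{BIC = -2 \log L + k \log n}.
#'
#' @param logL maximized log-likelihood.
#' @param n_params number of free parameters.
#' @param n_trials number of observations; must be >= 1.
#' @return BIC value.
#' @export
bic <- function(logL, n_params, n_trials) {
  if (n_trials < 1) stop("'n_trials' must be >= 1", call. = FALSE)
  -2 * logL + n_params * log(n_trials)
}

#' Group-level BIC
#'
#' Sums per-participant BICs for each model.
#'
#' @param bic_matrix participants x models matrix of BIC values.
#' @return named vector of group BICs (one per model).
#' @export
group_bic <- function(bic_matrix) {
  colSums(as.matrix(bic_matrix))
}

#' Random-effects exceedance probabilities
#'
#' Random-effects Bayesian model selection over a group: model identities
#' are treated as draws from a Dirichlet-distributed population frequency
#' vector, whose parameters are estimated by variational-Bayes fixed-point
#' iteration from per-participant log model evidences (here approximated
#' by \eqn{-BIC/2}). The exceedance probability of a model is the
#' posterior probability that its population frequency exceeds all
#' others, estimated by Monte Carlo sampling from the fitted Dirichlet.
#'
#' @param log_evidence participants x models matrix of log model
#'   evidences (use `-bic/2`).
#' @param alpha0 Dirichlet prior count per model; default 1.
#' @param n_samples Monte Carlo samples for the exceedance step.
#' @param max_iter,tol fixed-point controls.
#' @param seed optional seed for the Monte Carlo step.
#' @return list with `alpha` (Dirichlet parameters), `model_freq`
#'   (expected frequencies), `exceedance` (probabilities, sum 1).
#' @export
exceedance_probabilities <- function(log_evidence, alpha0 = 1,
                                     n_samples = 1e5, max_iter = 200,
                                     tol = 1e-8, seed = NULL) {
  E <- as.matrix(log_evidence)
  if (any(!is.finite(E))) stop("non-finite log evidences", call. = FALSE)
  n <- nrow(E); m <- ncol(E)
  if (m < 2) stop("need at least 2 models", call. = FALSE)
  alpha <- rep(alpha0, m)
  for (it in seq_len(max_iter)) {
    lw <- sweep(E, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lw <- lw - apply(lw, 1, max)
    u <- exp(lw)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  ex <- with_seed(seed, {
    g <- matrix(rgamma(n_samples * m, shape = rep(alpha, each = n_samples)),
                nrow = n_samples)
    tabulate(max.col(g), nbins = m) / n_samples
  })
  names(ex) <- colnames(E)
  list(alpha = alpha, model_freq = alpha / sum(alpha), exceedance = ex)
}
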