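#' Behavioral summaries of a difficulty trial table
#'
#' Aggregates choices and RTs of a difficulty-task table: per
#' (strength S1, strength S2) cell the proportion of S1 choices, mean RT
#' and SEM; collapsed over the difficulty difference
#' \eqn{\Delta C = |C_1| - |C_2|}; and per-duration accuracy for
#' controlled-duration tables. An `included` column (see
#' [exp2_analysis_filter()]) is honored when present.
#'
#' @param table a difficulty trial table with behavior.
#' @return list with data.frames `by_pair`, `by_delta` and (controlled
#'   tables) `by_duration`.
#' @export
summarize_behavior <- function(table) {
  if ("included" %in% names(table)) table <- table[table$included, ]
  table <- table[table$task == "difficulty" & !is.na(table$choice), ]
  s1 <- abs(table$c1_signed); s2 <- abs(table$c2_signed)
  chose1 <- table$choice == "S1"

  by_pair <- aggregate_cells(data.frame(s1 = s1, s2 = s2),
                             chose1, table$rt)
  by_delta <- aggregate_cells(data.frame(delta = round(s1 - s2, 3)),
                              chose1, table$rt)
  out <- list(by_pair = by_pair, by_delta = by_delta)
  if (any(table$paradigm == "controlled_duration")) {
    cd <- table[table$paradigm == "controlled_duration", ]
    acc <- !is.na(cd$correct) & cd$correct
    by_duration <- aggregate(acc, by = list(duration = cd$duration), FUN = mean)
    names(by_duration)[2] <- "p_correct"
    by_duration$n <- as.numeric(table(cd$duration)[as.character(by_duration$duration)])
    out$by_duration <- by_duration
  }
  out
}

aggregate_cells <- function(keys, chose1, rt) {
  df <- cbind(keys, chose1 = chose1, rt = rt)
  agg <- aggregate(df[, c("chose1", "rt")], by = as.list(keys), FUN = mean)
  names(agg)[names(agg) == "chose1"] <- "p_choose_s1"
  names(agg)[names(agg) == "rt"] <- "mean_rt"
  nn <- aggregate(rep(1, nrow(df)), by = as.list(keys), FUN = sum)
  sdr <- aggregate(df$rt, by = as.list(keys), FUN = sd)
  agg$n <- nn$x
  agg$sem_rt <- sdr$x / sqrt(nn$x)
  agg
}

#' Variance in RT explained by the difficulty difference
#'
#' Compares a cell-means model of RT in the six unique
#' \eqn{\Delta C = |C_1| - |C_2|} levels against a model that adds
#' S2-strength cell means: reports both R-squared values and the
#' increment. For known-color data, whose RTs depend on the pair only
#' through \eqn{\Delta C}, the increment is at noise level; unknown-color
#' data from a difference-type model show a positive increment (the
#' magnitude effect).
#'
#' @param table a difficulty RT trial table (an `included` column is
#'   honored).
#' @return list with `r2_delta`, `r2_delta_cs2`, `increment`,
#'   `n_delta_levels`, `degenerate` (TRUE when R2 is undefined).
#' @export
rt_variance_explained <- function(table) {
  if ("included" %in% names(table)) table <- table[table$included, ]
  table <- table[table$task == "difficulty" & table$paradigm == "rt" &
                   !is.na(table$rt), ]
  delta <- round(abs(table$c1_signed) - abs(table$c2_signed), 3)
  cs2 <- round(abs(table$c2_signed), 3)
  if (length(unique(delta)) < 2)
    return(list(r2_delta = NA_real_, r2_delta_cs2 = NA_real_,
                increment = NA_real_, n_delta_levels = length(unique(delta)),
                degenerate = TRUE))
  m1 <- lm(rt ~ factor(delta), data = data.frame(rt = table$rt, delta = delta))
  m2 <- lm(rt ~ factor(delta) + factor(cs2),
           data = data.frame(rt = table$rt, delta = delta, cs2 = cs2))
  r1 <- summary(m1)$r.squared
  r2 <- summary(m2)$r.squared
  list(r2_delta = r1, r2_delta_cs2 = r2, increment = r2 - r1,
       n_delta_levels = length(unique(delta)), degenerate = FALSE)
}

#' Fit several models to several participants and compare
#'
#' Fits each model to each participant's table, assembles the BIC matrix,
#' per-participant delta-BIC against the best model, group BIC (column
#' sums) and random-effects exceedance probabilities (log evidence
#' approximated by -BIC/2).
#'
#' @param datasets list of per-participant difficulty trial tables
#'   (columns `c1`, `c2`, `choice`, `rt`; see
#'   [trials_to_fit_data()] to convert a trial table).
#' @param models character vector of models to fit.
#' @param fit_config named list of arguments forwarded to
#'   [fit_difficulty_model()] (e.g. `n_starts`, `n_sim`, `maxit`).
#' @param seed integer seed; participant and model specific sub-seeds are
#'   derived from it.
#' @return list with `bic` (matrix), `delta_bic`, `group_bic`,
#'   `exceedance`, `fits` (nested list).
#' @export
run_model_comparison <- function(datasets,
                                 models = c("race", "difference",
                                            "two_step", "absolute"),
                                 fit_config = list(), seed = 1L) {
  n_p <- length(datasets)
  bic_mat <- matrix(NA_real_, n_p, length(models),
                    dimnames = list(paste0("p", seq_len(n_p)), models))
  fits <- vector("list", n_p)
  for (p in seq_len(n_p)) {
    fits[[p]] <- list()
    for (mi in seq_along(models)) {
      args <- c(list(model = models[mi], data = datasets[[p]],
                     seed = sub_seed(seed, p * 31L + mi)), fit_config)
      ft <- try(do.call(fit_difficulty_model, args), silent = TRUE)
      if (inherits(ft, "try-error")) {
        fits[[p]][[models[mi]]] <- ft
        next
      }
      fits[[p]][[models[mi]]] <- ft
      bic_mat[p, mi] <- ft$bic
    }
  }
  delta <- sweep(bic_mat, 1, apply(bic_mat, 1, min, na.rm = TRUE), `-`)
  ex <- exceedance_probabilities(-bic_mat / 2, seed = sub_seed(seed, 997L))
  list(bic = bic_mat, delta_bic = delta, group_bic = group_bic(bic_mat),
       exceedance = ex$exceedance, fits = fits)
}

#' Convert a trial table to the fitting format
#'
#' Extracts the columns the fitters need (`c1`, `c2`, sign tags,
#' `choice`, `rt`, `duration`) from a full trial table.
#'
#' @param table a trial table with behavior.
#' @return data.frame ready for [fit_difficulty_model()] or
#'   [fit_controlled_duration()].
#' @export
trials_to_fit_data <- function(table) {
  df <- data.frame(c1 = table$c1_signed, c2 = table$c2_signed,
                   c1_sign = table$c1_sign, c2_sign = table$c2_sign,
                   choice = as.character(table$choice), rt = table$rt)
  if ("duration" %in% names(table)) df$duration <- table$duration
  df
}

#' Model recovery by refitting synthetic datasets
#'
#' Generates datasets from each generating model at the given parameters,
#' fits every candidate model to every dataset, and classifies each
#' dataset by the lowest BIC. Returns the confusion matrix (rows:
#' generating model, columns: best-fitting model) and, optionally, the
#' stricter classification counting only wins by more than `delta_win`
#' BIC points.
#'
#' @param gen_models character vector of generating models.
#' @param params_list named list of [difficulty_params()] per generating
#'   model.
#' @param n_datasets datasets per generating model.
#' @param design design trial table used for every dataset.
#' @param fit_models models fitted to each dataset (default: the four
#'   core models).
#' @param fit_config arguments forwarded to [fit_difficulty_model()].
#' @param delta_win BIC margin for the strict classification (default 10).
#' @param seed integer seed.
#' @return list with `confusion`, `confusion_strict`, `bics` (array).
#' @export
run_model_recovery <- function(gen_models, params_list, n_datasets = 5,
                               design,
                               fit_models = c("race", "difference",
                                              "two_step", "absolute"),
                               fit_config = list(), delta_win = 10,
                               seed = 1L) {
  pairs <- data.frame(c1 = design$c1_signed, c2 = design$c2_signed,
                      c1_sign = design$c1_sign, c2_sign = design$c2_sign)
  confusion <- matrix(0L, length(gen_models), length(fit_models),
                      dimnames = list(gen_models, fit_models))
  strict <- confusion
  bics <- array(NA_real_, dim = c(length(gen_models), n_datasets,
                                  length(fit_models)),
                dimnames = list(gen_models, NULL, fit_models))
  for (gi in seq_along(gen_models)) {
    gm <- gen_models[gi]
    for (ds in seq_len(n_datasets)) {
      sim <- simulate_difficulty(gm, params_list[[gm]], pairs,
                                 seed = sub_seed(seed, gi * 101L + ds))
      dat <- cbind(pairs, choice = as.character(sim$choice), rt = sim$rt)
      for (mi in seq_along(fit_models)) {
        args <- c(list(model = fit_models[mi], data = dat,
                       seed = sub_seed(seed, gi * 1009L + ds * 37L + mi)),
                  fit_config)
        ft <- try(do.call(fit_difficulty_model, args), silent = TRUE)
        if (!inherits(ft, "try-error")) bics[gi, ds, mi] <- ft$bic
      }
      if (all(is.na(bics[gi, ds, ]))) next
      best <- which.min(bics[gi, ds, ])
      confusion[gi, best] <- confusion[gi, best] + 1L
      margin <- sort(bics[gi, ds, ])[2] - bics[gi, ds, best]
      if (isTRUE(margin > delta_win))
        strict[gi, best] <- strict[gi, best] + 1L
    }
  }
  list(confusion = confusion, confusion_strict = strict, bics = bics)
}

#' Which fitted model best mimics the optimal policy?
#'
#' Simulates trials from the reward-rate-optimal policy and fits the four
#' difficulty models to the simulated (choice, RT) data, ranking them by
#' BIC.
#'
#' @param solution a solved policy ([solve_reward_rate()] result or its
#'   `solution` element).
#' @param n_sim_trials number of optimal-policy trials to simulate.
#' @param fit_models models to fit.
#' @param fit_config arguments forwarded to [fit_difficulty_model()].
#' @param seed integer seed.
#' @return list with `bic` (named, ascending order), `ranking` (model
#'   names best to worst), `data` (the simulated trials).
#' @export
run_optimal_fit_comparison <- function(solution, n_sim_trials = 20000,
                                       fit_models = c("race", "difference",
                                                      "two_step", "absolute"),
                                       fit_config = list(), seed = 1L) {
  if (!is.null(solution$solution)) solution <- solution$solution
  sim <- simulate_optimal(solution, n_sim_trials, seed = sub_seed(seed, 3L))
  dat <- data.frame(c1 = sim$c1, c2 = sim$c2,
                    choice = as.character(sim$choice), rt = sim$rt)
  bics <- setNames(rep(NA_real_, length(fit_models)), fit_models)
  fits <- list()
  for (mi in seq_along(fit_models)) {
    args <- c(list(model = fit_models[mi], data = dat,
                   seed = sub_seed(seed, 71L + mi)), fit_config)
    ft <- try(do.call(fit_difficulty_model, args), silent = TRUE)
    if (!inherits(ft, "try-error")) {
      bics[mi] <- ft$bic
      fits[[fit_models[mi]]] <- ft
    }
  }
  ord <- order(bics)
  list(bic = bics[ord], ranking = names(bics)[ord], fits = fits, data = dat)
}
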