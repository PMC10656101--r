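trial_table_columns <- c("participant", "session", "block", "task",
                         "paradigm", "color_knowledge", "c1_signed",
                         "c2_signed", "c1_sign", "c2_sign", "duration",
                         "choice", "rt", "decision_time", "terminated_by",
                         "correct", "feedback")

required_trial_columns <- c("task", "paradigm", "color_knowledge",
                            "c1_signed", "c1_sign")

# normalize a design/trial data.frame to the full column set
as_trial_table <- function(df) {
  for (col in setdiff(trial_table_columns, names(df))) df[[col]] <- NA
  df[, c(trial_table_columns, setdiff(names(df), trial_table_columns))]
}

#' Balanced two-stimulus design for the reaction-time experiment
#'
#' Builds the trial list of a session of the reaction-time difficulty
#' task: all 12 x 12 signed-coherence combinations of the two stimuli
#' (six strengths with both dominance tags each, including tagged zeros)
#' appear equally often across the session, shuffled within the session
#' and chunked into blocks. The default 12 blocks of 96 trials give 1152
#' trials, 8 per signed pair; the first three blocks are labelled
#' session 1 and the rest session 2.
#'
#' @param n_blocks number of blocks.
#' @param trials_per_block trials per block; `n_blocks * trials_per_block`
#'   must be divisible by 144.
#' @param seed integer seed for the shuffling.
#' @param participant participant id.
#' @return a trial table (design only: behavioral columns NA).
#' @export
design_exp1_difficulty <- function(n_blocks = 12, trials_per_block = 96,
                                   seed = 1L, participant = 1L) {
  total <- n_blocks * trials_per_block
  if (total %% 144L != 0L)
    stop("total trial count must be divisible by the 144 signed pairs",
         call. = FALSE)
  set12 <- signed_coherence_set()
  grid <- expand.grid(i = seq_len(nrow(set12)), j = seq_len(nrow(set12)))
  reps <- total %/% 144L
  rows <- rep(seq_len(nrow(grid)), each = reps)
  df <- data.frame(
    participant = participant,
    c1_signed = set12$value[grid$i[rows]],
    c1_sign = set12$sign[grid$i[rows]],
    c2_signed = set12$value[grid$j[rows]],
    c2_sign = set12$sign[grid$j[rows]]
  )
  df <- with_seed(seed, df[sample.int(nrow(df)), ])
  df$block <- rep(seq_len(n_blocks), each = trials_per_block)
  df$session <- ifelse(df$block <= 3L, 1L, 2L)
  df$task <- "difficulty"
  df$paradigm <- "rt"
  df$color_knowledge <- "unknown"
  rownames(df) <- NULL
  as_trial_table(df)
}

#' Designs of the unknown- vs known-color experiment
#'
#' Builds trial lists for the second experiment's conditions. Unknown
#' color uses the full 12 x 12 signed grid; known color restricts to
#' same-sign 6 x 6 pairings (half the blocks blue-dominant, half
#' yellow-dominant). Cells in which both stimuli have the same strength
#' are presented at one third the frequency of other cells (exact by
#' construction). Controlled-duration designs attach durations from
#' \{0.1, 0.15, 0.25, 0.45, 0.85, 1.65\} s with an exactly uniform
#' marginal, randomized within the session.
#'
#' @param condition `"rt"` or `"controlled"`.
#' @param color `"unknown"` or `"known"`.
#' @param n_reps multiplier on the base design (base counts: 1 per
#'   equal-strength cell, 3 per other cell).
#' @param seed integer seed.
#' @param participant participant id.
#' @return a trial table (design only).
#' @export
design_exp2 <- function(condition = c("rt", "controlled"),
                        color = c("unknown", "known"), n_reps = 1L,
                        seed = 1L, participant = 1L) {
  condition <- match.arg(condition)
  color <- match.arg(color)
  set12 <- signed_coherence_set()
  build_cells <- function(set, knowledge) {
    grid <- expand.grid(i = seq_len(nrow(set)), j = seq_len(nrow(set)))
    eq <- abs(set$value[grid$i]) == abs(set$value[grid$j])
    counts <- ifelse(eq, 1L, 3L) * n_reps
    rows <- rep(seq_len(nrow(grid)), times = counts)
    data.frame(
      participant = participant,
      c1_signed = set$value[grid$i[rows]],
      c1_sign = set$sign[grid$i[rows]],
      c2_signed = set$value[grid$j[rows]],
      c2_sign = set$sign[grid$j[rows]],
      color_knowledge = knowledge
    )
  }
  df <- if (color == "unknown") {
    build_cells(set12, "unknown")
  } else {
    blue <- set12[set12$sign > 0, ]
    yellow <- set12[set12$sign < 0, ]
    rbind(build_cells(blue, "known_blue"), build_cells(yellow, "known_yellow"))
  }
  df <- with_seed(seed, {
    df <- df[sample.int(nrow(df)), ]
    if (condition == "controlled") {
      durs <- c(0.1, 0.15, 0.25, 0.45, 0.85, 1.65)
      if (nrow(df) %% 6L != 0L)
        stop("controlled design size must be divisible by the 6 durations",
             call. = FALSE)
      df$duration <- sample(rep(durs, each = nrow(df) %/% 6L))
    }
    df
  })
  df$task <- "difficulty"
  df$paradigm <- if (condition == "rt") "rt" else "controlled_duration"
  n_blocks <- max(1L, nrow(df) %/% 96L)
  df$block <- rep(seq_len(n_blocks), length.out = nrow(df))
  df$session <- 1L
  rownames(df) <- NULL
  as_trial_table(df)
}

#' Generate model behavior for a design
#'
#' Fills the behavioral columns of a design trial table by simulating the
#' given model: the 1D color DDM for color-task rows, the 2D difficulty
#' models for difficulty rows (RT or controlled-duration paradigm).
#' The `correct` flag compares the chosen stimulus's strength with the
#' other's; equal-strength trials are randomly designated correct on half
#' of the trials, mirroring the feedback rule of the task. `feedback` is
#' +1 for correct and -1 otherwise.
#'
#' @param model a difficulty model name (difficulty rows) or
#'   `"color_ddm"` (color rows).
#' @param params a [difficulty_params()] or [color_ddm_params()] matching
#'   the model.
#' @param design a design trial table (see [design_exp1_difficulty()]).
#' @param dt simulation step (s); default 5 ms.
#' @param horizon response deadline (s).
#' @param conf_map confidence map for the confidence models.
#' @param t_buf sensory buffer for controlled-duration rows (s).
#' @param seed integer seed.
#' @return the design with `choice`, `rt`, `decision_time`,
#'   `terminated_by`, `correct`, `feedback` filled in.
#' @export
generate_dataset <- function(model, params, design, dt = 0.005, horizon = 5,
                             conf_map = NULL, t_buf = 0.08, seed = NULL) {
  design <- as_trial_table(design)
  task <- unique(design$task)
  if (length(task) != 1L)
    stop("mixed-task designs are not supported; split by task", call. = FALSE)

  if (task == "color") {
    if (!inherits(params, "color_ddm_params"))
      stop("color-task designs require color_ddm_params", call. = FALSE)
    return(with_seed(seed, generate_color_rows(params, design, dt, horizon)))
  }
  if (!inherits(params, "difficulty_params"))
    stop("difficulty designs require difficulty_params", call. = FALSE)
  paradigm <- unique(design$paradigm)
  if (length(paradigm) != 1L)
    stop("mixed-paradigm designs are not supported; split by paradigm",
         call. = FALSE)
  with_seed(seed, {
    pairs <- data.frame(c1 = design$c1_signed, c2 = design$c2_signed,
                        c1_sign = design$c1_sign, c2_sign = design$c2_sign)
    if (paradigm == "rt") {
      sim <- simulate_difficulty(model, params, pairs, dt = dt,
                                 horizon = horizon, conf_map = conf_map)
      design$choice <- as.character(sim$choice)
      design$rt <- sim$rt
      design$decision_time <- sim$decision_time
      design$terminated_by <- as.character(sim$terminated_by)
    } else {
      sim <- simulate_controlled(model, params, pairs, design$duration,
                                 t_buf = t_buf, dt = dt, conf_map = conf_map)
      design$choice <- as.character(sim$choice)
      design$decision_time <- sim$decision_time
      design$terminated_by <- as.character(sim$terminated_by)
    }
    s1 <- abs(design$c1_signed); s2 <- abs(design$c2_signed)
    tie <- s1 == s2
    chose1 <- design$choice == "S1"
    design$correct <- ifelse(tie, runif(nrow(design)) < 0.5,
                             ifelse(chose1, s1 > s2, s2 > s1))
    design$feedback <- ifelse(design$correct, 1L, -1L)
    design
  })
}

generate_color_rows <- function(params, design, dt, horizon) {
  design$choice <- NA_character_
  design$rt <- NA_real_
  design$decision_time <- NA_real_
  design$terminated_by <- NA_character_
  for (co in unique(design$c1_signed)) {
    rows <- which(design$c1_signed == co)
    sim <- simulate_first_passage(params, co, n = length(rows), dt = dt,
                                  horizon = horizon)
    resolved <- as.character(sim$boundary)
    none <- resolved == "none"
    if (any(none)) resolved[none] <- ifelse(runif(sum(none)) < 0.5,
                                            "upper", "lower")
    design$choice[rows] <- ifelse(resolved == "upper", "blue", "yellow")
    design$decision_time[rows] <- sim$decision_time
    design$rt[rows] <- sim$decision_time +
      pmax(0, rnorm(length(rows), params$tnd_mean, params$tnd_sd))
    design$terminated_by[rows] <- ifelse(none, "horizon", "bound")
  }
  # rewarded response: dominance tag of the patch (tag decides on 0)
  rewarded <- ifelse(design$c1_sign > 0, "blue", "yellow")
  design$correct <- design$choice == rewarded
  design$feedback <- ifelse(design$correct, 1L, -1L)
  design
}

#' Read and write trial tables
#'
#' Trial tables are plain CSV (comma separator, '.' decimal, header
#' required, UTF-8) with the documented schema; unknown columns are
#' preserved, NA encodes missing values. `read_trials()` validates the
#' required columns and coherence ranges.
#'
#' @param path CSV file path.
#' @return `read_trials()`: a validated trial table data.frame.
#' @export
read_trials <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required_trial_columns, names(df))
  if (length(missing_cols) > 0)
    stop("trial table is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in c("c1_signed", "c2_signed")) {
    if (col %in% names(df)) {
      v <- df[[col]]
      bad <- !is.na(v) & (abs(v) > 1)
      if (any(bad))
        stop(sprintf("column '%s' contains coherences outside [-1, 1]", col),
             call. = FALSE)
    }
  }
  as_trial_table(df)
}

#' @rdname read_trials
#' @param table a trial table.
#' @export
write_trials <- function(table, path) {
  write.csv(table, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Analysis inclusion flags for the two-color experiment
#'
#' Applies the analysis inclusion rules of the unknown/known-color
#' experiment as a logical `included` column (rows are flagged, never
#' deleted). Contexts: `"rt"` keeps only same-dominance pairs (unknown
#' color blocks present all 12 x 12 combinations but analyses use
#' same-color pairs for comparability with the known-color blocks);
#' `"controlled_accuracy"` additionally excludes equal-strength pairs
#' (no objectively correct answer); `"fitting_unknown"` applies both
#' rules (the fitting exclusions for unknown-color choice data).
#' Color-task rows are always included.
#'
#' @param table a trial table.
#' @param context one of `"rt"`, `"controlled_accuracy"`,
#'   `"fitting_unknown"`.
#' @return the table with an `included` logical column.
#' @export
exp2_analysis_filter <- function(table,
                                 context = c("rt", "controlled_accuracy",
                                             "fitting_unknown")) {
  context <- match.arg(context)
  same_dom <- table$c1_sign == table$c2_sign
  eq_strength <- abs(table$c1_signed) == abs(table$c2_signed)
  inc <- switch(context,
                rt = same_dom,
                controlled_accuracy = same_dom & !eq_strength,
                fitting_unknown = same_dom & !eq_strength)
  inc[table$task == "color"] <- TRUE
  table$included <- inc
  table
}
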