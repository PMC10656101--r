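# Reference parameters and small design helpers shared across tests.
# The difficulty reference parameters are mid-range values of the fitting
# box at which all four models produce the qualitative RT signatures.

ref_bound <- function() collapsing_bound(u = 2.5, a = 1.5, d = 1.5)

ref_difficulty_params <- function(b_mini = NULL) {
  difficulty_params(kappa = 10, bound = ref_bound(), tnd_mean = 0.35,
                    b_mini = b_mini)
}

ref_color_params <- function(c0 = 0) {
  color_ddm_params(kappa = 10, c0 = c0, bound = collapsing_bound(2, 1, 1.2),
                   tnd_mean = 0.35)
}

# n identical coherence pairs (tags default to the sign, +1 on zero)
pair_block <- function(c1, c2, n) {
  data.frame(c1 = rep(c1, n), c2 = rep(c2, n),
             c1_sign = rep(ifelse(sign(c1) == 0, 1, sign(c1)), n),
             c2_sign = rep(ifelse(sign(c2) == 0, 1, sign(c2)), n))
}

# maximum distance between the two pairs of boundary sub-distribution
# functions (defect CDFs); `fp` is a choice_rt_distribution, `mc` a
# simulate_first_passage data.frame on the same process
defect_ks <- function(fp, mc) {
  tg <- fp$t
  Fup <- cumsum(fp$density_upper) * fp$dt
  Flo <- cumsum(fp$density_lower) * fp$dt
  up_t <- sort(mc$decision_time[mc$boundary == "upper"])
  lo_t <- sort(mc$decision_time[mc$boundary == "lower"])
  n <- nrow(mc)
  Gup <- findInterval(tg, up_t) / n
  Glo <- findInterval(tg, lo_t) / n
  max(abs(Fup - Gup), abs(Flo - Glo))
}
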