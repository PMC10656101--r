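# The solved optimal policies at the headline parameters are reused by
# several acceptance blocks; solve once per session.
.policy_cache <- new.env(parent = emptyenv())

headline_optimal_config <- function() {
  optimal_config(kappa = 13, Rc = 1, Rn = 0, tp = 1, tnd = 0.4, tw = 0.5,
                 dt = 0.05, ddv = 0.1, dv_range = 6, horizon = 5)
}

get_solved_policy <- function(which = c("unknown", "known")) {
  which <- match.arg(which)
  if (is.null(.policy_cache[[which]])) {
    cfg <- headline_optimal_config()
    if (which == "known") cfg <- known_color_config(cfg)
    .policy_cache[[which]] <- solve_reward_rate(cfg)
  }
  .policy_cache[[which]]
}
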