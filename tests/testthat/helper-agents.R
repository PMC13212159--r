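# Shared fixtures and independent oracles for the test suite.

# Slow, transparent R-loop negative log-likelihood through the agent step
# interface; independent of the C++ fitting kernels it cross-checks.
oracle_nll <- function(model, blocks) {
  if (inherits(model, "ann_weights")) model <- ann_agent(model)
  total <- 0
  for (b in blocks) {
    state <- agent_init(model)
    for (t in seq_len(b$n_trials)) {
      if (!b$valid[t]) next
      p <- agent_policy(model, state)
      total <- total - log(p[b$actions[t] + 1])
      state <- agent_observe(model, state, b$actions[t],
                             scale_rewards(b$rewards[t]))
    }
  }
  total
}

# Build a session block directly from action/reward vectors (no schedule).
raw_block <- function(actions, rewards, valid = !is.na(actions),
                      participant_id = "p1", block_id = "b1") {
  session_block(participant_id, block_id, actions, rewards, valid)
}

# Simulated blocks from a given agent on fresh schedules.
sim_blocks <- function(agent, n_blocks, n_trials = 150, miss_rate = 0,
                       seed = 1, participant_per_block = TRUE) {
  lapply(seq_len(n_blocks), function(i) {
    simulate_block(agent, generate_schedule(n_trials = n_trials,
                                            seed = seed + i),
                   miss_rate = miss_rate, seed = seed + 10000 + i,
                   participant_id = if (participant_per_block)
                     sprintf("p%03d", i) else "p001",
                   block_id = sprintf("b%03d", i))
  })
}

# iid uniform-choice blocks (reward-blind agent) for chance baselines.
uniform_blocks <- function(n_blocks, n_trials = 150, seed = 1) {
  agent <- rl_agent(simple_rl(), rl_params(alpha = 0.3, beta = 0))
  sim_blocks(agent, n_blocks, n_trials = n_trials, seed = seed)
}

# Central-difference gradient of a C++ NLL kernel for one weight entry.
numeric_grad_entry <- function(w, mats, eval_fun, nm, idx, eps = 1e-6) {
  wp <- w; wp[[nm]][idx] <- wp[[nm]][idx] + eps
  wm <- w; wm[[nm]][idx] <- wm[[nm]][idx] - eps
  (eval_fun(wp, mats) - eval_fun(wm, mats)) / (2 * eps)
}

cpp_eval_fun <- function(arch) {
  code <- c(rl_ann = 0L, context_ann = 1L, memory_ann = 2L)
  if (arch == "vanilla_rnn") {
    function(w, mats) hybridrl:::cpp_rnn_nll_grad(w, mats$actions,
                                                  mats$rewards, FALSE)$total
  } else {
    function(w, mats) hybridrl:::cpp_modular_nll_grad(
      w, mats$actions, mats$rewards, code[[arch]], FALSE)$total
  }
}
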