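#' Teacher-forced (closed-loop) latent trajectories
#'
#' Replays each block through a model, forcing the model to take the
#' observed actions and rewards instead of sampling its own, and records
#' the latent state going into every trial: values `q`, perseveration `c`,
#' memory states `s_r` / `s_a` where the architecture has them, and the
#' current learning rate for variable-learning-rate tabular agents. Missed
#' trials carry the state forward unchanged, matching the fitting kernels.
#'
#' @param model Any agent-interface model (`rl_agent`, `ann_agent`,
#'   `ann_weights`, `memory_teacher`).
#' @param blocks List of `session_block`s.
#' @return List of `latent_trajectory` objects; each holds per-trial
#'   matrices plus the block's actions and scaled rewards.
#' @export
closed_loop_latents <- function(model, blocks) {
  if (inherits(model, "ann_weights")) model <- ann_agent(model)
  lapply(blocks, function(b) {
    n <- b$n_trials
    state <- agent_init(model)
    grab <- function(st, nm) if (!is.null(st[[nm]])) st[[nm]] else NULL
    q <- matrix(NA_real_, n, 4); cv <- matrix(NA_real_, n, 4)
    H_r <- length(grab(state, "s_r")); H_a <- length(grab(state, "s_a"))
    s_r <- if (H_r) matrix(NA_real_, n, H_r) else NULL
    s_a <- if (H_a) matrix(NA_real_, n, H_a) else NULL
    alpha <- if (!is.null(state$alpha)) rep(NA_real_, n) else NULL
    for (t in seq_len(n)) {
      if (!is.null(state$q)) { q[t, ] <- state$q; cv[t, ] <- state$c }
      if (H_r) s_r[t, ] <- state$s_r
      if (H_a) s_a[t, ] <- state$s_a
      if (!is.null(alpha)) alpha[t] <- state$alpha
      if (b$valid[t]) {
        if (b$actions[t] < 0 || b$actions[t] > 3) stop("action outside 0..3")
        state <- agent_observe(model, state, b$actions[t],
                               scale_rewards(b$rewards[t]))
      }
    }
    structure(list(participant_id = b$participant_id, block_id = b$block_id,
                   q = q, c = cv, s_r = s_r, s_a = s_a, alpha = alpha,
                   actions = b$actions, rewards = scale_rewards(b$rewards),
                   valid = b$valid),
              class = "latent_trajectory")
  })
}

.pool_states <- function(trajectories, module = c("reward", "action")) {
  module <- match.arg(module)
  nm <- if (module == "reward") "s_r" else "s_a"
  mats <- lapply(trajectories, `[[`, nm)
  if (any(vapply(mats, is.null, logical(1))))
    stop("trajectories carry no memory states for this module")
  do.call(rbind, mats)
}

#' Principal components of memory states
#'
#' Mean-centred PCA over all pooled per-trial memory states of one module.
#' Component signs are fixed so that each PC score correlates
#' non-negatively with the previous trial's reward, giving "PC1 = reward
#' sensitivity" a reproducible orientation; components with (near) zero
#' variance are flagged via `rank`.
#'
#' @param trajectories Output of [closed_loop_latents()].
#' @param module `"reward"` or `"action"`.
#' @return Object of class `pc_basis`: `rotation`, `center`, `sdev`,
#'   `explained` (variance fractions) and `rank`.
#' @export
pca_states <- function(trajectories, module = "reward") {
  S <- .pool_states(trajectories, module)
  if (nrow(S) < 2) stop("need at least two pooled states")
  pc <- stats::prcomp(S, center = TRUE, scale. = FALSE)
  # previous-trial reward aligned with each pooled state row
  prev_r <- unlist(lapply(trajectories, function(tr) {
    r <- tr$rewards; r[!tr$valid] <- NA
    c(NA, r[-length(r)])
  }))
  scores <- pc$x
  for (j in seq_len(ncol(scores))) {
    ok <- !is.na(prev_r)
    if (sum(ok) > 2 && stats::sd(scores[ok, j]) > 0) {
      rho <- suppressWarnings(stats::cor(scores[ok, j], prev_r[ok]))
      if (!is.na(rho) && rho < 0) pc$rotation[, j] <- -pc$rotation[, j]
    }
  }
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(rotation = pc$rotation, center = pc$center, sdev = pc$sdev,
                 explained = expl, rank = sum(pc$sdev > 1e-10)),
            class = "pc_basis")
}

#' Project states onto a PC basis
#'
#' @param basis A `pc_basis`.
#' @param states Matrix of states (rows) or a single state vector.
#' @return Score matrix.
#' @export
pc_scores <- function(basis, states) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  sweep(states, 2, basis$center) %*% basis$rotation
}

#' State samples along one principal component
#'
#' Returns `n` states spaced along a PC between `-sd_range` and `+sd_range`
#' standard deviations from the mean (the probing convention).
#'
#' @param basis A `pc_basis`.
#' @param pc PC index.
#' @param n Number of samples (default 11).
#' @param sd_range Range in standard deviations (default 1.5).
#' @return n x hidden matrix of states.
#' @export
sample_states_along_pc <- function(basis, pc = 1, n = 11, sd_range = 1.5) {
  if (pc > ncol(basis$rotation)) stop("pc index beyond basis rank")
  coefs <- seq(-sd_range, sd_range, length.out = n) * basis$sdev[pc]
  t(vapply(coefs, function(k) basis$center + k * basis$rotation[, pc],
           numeric(length(basis$center))))
}

# one reward-module application for the memory architecture
.reward_module_step <- function(weights, r, s) {
  h <- tanh(as.vector(weights$W1r %*% c(r, s)) + weights$b1r)
  list(q = as.vector(weights$W2r %*% h) + as.numeric(weights$b2r), s = h)
}

#' Probe a model's reward module over its input range
#'
#' Evaluates the value-update mapping on a grid of scaled rewards crossed
#' with state samples. For a tabular agent the probe returns the exact
#' update plane `q + alpha (r - q) + b` over the supplied previous values;
#' for RL-ANN / Context-ANN the state axis is the previous value of the
#' chosen arm (context inputs held at their supplied values or zero); for
#' Memory-ANN the state axis is a matrix of hidden-state samples, usually
#' from [sample_states_along_pc()].
#'
#' @param model `rl_agent` or `ann_weights`.
#' @param reward_grid Scaled rewards (default 21 points over \[0.01, 1\]).
#' @param state_samples Numeric vector of previous values (tabular,
#'   RL-ANN, Context-ANN) or a state matrix (Memory-ANN).
#' @param context For Context-ANN, the fixed Q context vector (default
#'   the probed value replicated over arms).
#' @return data.frame with `reward`, `state_index`, `state_value` (value
#'   axis or PC coordinate where applicable) and `q_next`; for Memory-ANN
#'   also the next state as attribute `state_next`.
#' @export
probe_reward_module <- function(model,
                                reward_grid = seq(0.01, 1, length.out = 21),
                                state_samples = seq(0.2, 0.8, length.out = 11),
                                context = NULL) {
  if (length(reward_grid) == 0 ||
      (is.null(dim(state_samples)) && length(state_samples) == 0) ||
      (!is.null(dim(state_samples)) && nrow(state_samples) == 0))
    stop("empty probe grid")
  if (inherits(model, "rl_agent")) {
    p <- model$params
    grid <- expand.grid(state_index = seq_along(state_samples),
                        reward = reward_grid)
    qprev <- state_samples[grid$state_index]
    return(data.frame(reward = grid$reward, state_index = grid$state_index,
                      state_value = qprev,
                      q_next = q_update(qprev, grid$reward, p$alpha, p$b)))
  }
  w <- model
  if (!inherits(w, "ann_weights")) stop("unsupported model for probing")
  if (w$arch %in% c("rl_ann", "context_ann")) {
    grid <- expand.grid(state_index = seq_along(state_samples),
                        reward = reward_grid)
    qn <- vapply(seq_len(nrow(grid)), function(i) {
      qa <- state_samples[grid$state_index[i]]
      x <- if (w$arch == "rl_ann") c(qa, grid$reward[i]) else
        c(qa, grid$reward[i], if (is.null(context)) rep(qa, 4) else context)
      mlp_forward(w$W1r, w$b1r, w$W2r, w$b2r, x)$output
    }, numeric(1))
    return(data.frame(reward = grid$reward, state_index = grid$state_index,
                      state_value = state_samples[grid$state_index],
                      q_next = qn))
  }
  if (w$arch != "memory_ann") stop("no reward module in this architecture")
  if (is.null(dim(state_samples)))
    stop("Memory-ANN probes need a matrix of state samples")
  grid <- expand.grid(state_index = seq_len(nrow(state_samples)),
                      reward = reward_grid)
  qn <- numeric(nrow(grid)); sn <- matrix(NA_real_, nrow(grid), w$hidden)
  for (i in seq_len(nrow(grid))) {
    st <- .reward_module_step(w, grid$reward[i],
                              state_samples[grid$state_index[i], ])
    qn[i] <- st$q; sn[i, ] <- st$s
  }
  out <- data.frame(reward = grid$reward, state_index = grid$state_index,
                    state_value = NA_real_, q_next = qn)
  attr(out, "state_next") <- sn
  out
}

#' Decode reward history from memory-state principal components
#'
#' For each PC and each lag i, regresses the reward observed i trials back
#' on the PC score of the current state (one univariate linear regression
#' per cell, pooled over blocks); the coefficient pattern over lags shows
#' which timescales of reward history each PC carries.
#'
#' @param trajectories Output of [closed_loop_latents()] (Memory-ANN).
#' @param basis A `pc_basis` for the reward module.
#' @param max_lag Maximum lag (default 20).
#' @param n_pcs Number of PCs (default: all with explained variance >= 1%).
#' @return Matrix \[PC x lag\] of regression coefficients (NA where a lag
#'   has insufficient overlap).
#' @export
decode_history <- function(trajectories, basis, max_lag = 20, n_pcs = NULL) {
  if (is.null(n_pcs)) n_pcs <- max(1, sum(basis$explained >= 0.01))
  n_pcs <- min(n_pcs, ncol(basis$rotation))
  out <- matrix(NA_real_, n_pcs, max_lag,
                dimnames = list(paste0("PC", seq_len(n_pcs)),
                                paste0("lag", seq_len(max_lag))))
  scores <- lapply(trajectories, function(tr) pc_scores(basis, tr$s_r))
  for (lag in seq_len(max_lag)) {
    xs <- list(); ys <- list()
    for (bi in seq_along(trajectories)) {
      tr <- trajectories[[bi]]
      n <- nrow(tr$s_r)
      if (n <= lag) next
      tt <- (lag + 1):n
      keep <- tr$valid[tt - lag]
      xs[[length(xs) + 1]] <- scores[[bi]][tt[keep], seq_len(n_pcs), drop = FALSE]
      ys[[length(ys) + 1]] <- tr$rewards[tt - lag][keep]
    }
    if (!length(ys)) next
    X <- do.call(rbind, xs); y <- unlist(ys)
    if (length(y) < 3) next
    for (j in seq_len(n_pcs)) {
      if (stats::sd(X[, j]) == 0) next
      out[j, lag] <- stats::coef(stats::lm(y ~ X[, j]))[2]
    }
  }
  out
}

#' Prime a fresh reward module, then probe it with a fixed reward
#'
#' Starts the reward module from the zero state, feeds it `r_prime` for
#' `n_prime` steps, then `r_test` for `n_test` steps, recording the value
#' output at every step. Different priming levels force the module into
#' different memory states whose influence on the response to `r_test`
#' decays over subsequent steps.
#'
#' @param weights Memory-ANN `ann_weights`.
#' @param r_prime,r_test Scaled rewards.
#' @param n_prime,n_test Step counts.
#' @return data.frame with `phase` ("prime"/"test"), `step`, `q`.
#' @export
prime_and_probe <- function(weights, r_prime, n_prime, r_test, n_test) {
  if (weights$arch != "memory_ann") stop("priming needs a memory architecture")
  s <- numeric(weights$hidden)
  qs <- numeric(n_prime + n_test)
  for (i in seq_len(n_prime)) {
    st <- .reward_module_step(weights, r_prime, s); s <- st$s; qs[i] <- st$q
  }
  for (i in seq_len(n_test)) {
    st <- .reward_module_step(weights, r_test, s); s <- st$s
    qs[n_prime + i] <- st$q
  }
  data.frame(phase = rep(c("prime", "test"), c(n_prime, n_test)),
             step = c(seq_len(n_prime), seq_len(n_test)), q = qs)
}

#' Inject activity along a principal component and track the perturbation
#'
#' Runs the reward module along a reward sequence twice from the zero
#' state; in the perturbed run, `magnitude` times the PC vector is added
#' to the state right before the designated step. Returns both value
#' trajectories and their difference for causal-perturbation analyses.
#'
#' @param weights Memory-ANN `ann_weights`.
#' @param basis A `pc_basis`.
#' @param pc_index PC to inject along.
#' @param magnitude Injection size (state units).
#' @param r_sequence Scaled reward sequence to drive the module.
#' @param inject_at Step index at which to inject (default 1).
#' @return List with `baseline`, `perturbed` (value sequences) and `delta`.
#' @export
inject_pc_activity <- function(weights, basis, pc_index, magnitude,
                               r_sequence, inject_at = 1) {
  if (weights$arch != "memory_ann") stop("injection needs a memory architecture")
  if (pc_index > ncol(basis$rotation)) stop("pc index beyond basis rank")
  run <- function(perturb) {
    s <- numeric(weights$hidden)
    qs <- numeric(length(r_sequence))
    for (i in seq_along(r_sequence)) {
      if (perturb && i == inject_at)
        s <- s + magnitude * basis$rotation[, pc_index]
      st <- .reward_module_step(weights, r_sequence[i], s)
      s <- st$s; qs[i] <- st$q
    }
    qs
  }
  base <- run(FALSE); pert <- run(TRUE)
  list(baseline = base, perturbed = pert, delta = pert - base)
}
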