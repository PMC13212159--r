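#' Parameter priors for heterogeneous synthetic agents
#'
#' A prior is a named list mapping parameter names to distribution specs,
#' each a list with a `family` (`"point"`, `"beta"`, `"gamma"`, `"uniform"`
#' or `"normal"`) and its parameters. Families are validated against each
#' parameter's support: unit-interval parameters (`alpha`, `alpha_init`,
#' `f`, `w`) accept beta/point/uniform within (0,1); `b` and `kappa` accept
#' point/uniform within (-1,1); `beta` accepts gamma/point/uniform on
#' (0, Inf); `q_init` additionally accepts normal.
#'
#' The default prior describes a plausible Best-RL population on the scaled
#' reward scale: learning rates around 0.3, inverse temperatures around 10
#' (value differences are a few tenths on this scale), mild positive
#' perseveration, slow forgetting and mid-scale initial values.
#'
#' @return Named list of distribution specs.
#' @export
default_param_prior <- function() {
  list(alpha = list(family = "beta", shape1 = 6, shape2 = 14),
       beta = list(family = "gamma", shape = 25, rate = 2.5),
       b = list(family = "uniform", min = -0.03, max = 0.03),
       kappa = list(family = "uniform", min = 0, max = 0.25),
       f = list(family = "beta", shape1 = 2, shape2 = 18),
       q_init = list(family = "normal", mean = 0.5, sd = 0.08))
}

.param_support <- list(
  alpha = c(0, 1), alpha_init = c(0, 1), f = c(0, 1), w = c(0, 1),
  b = c(-1, 1), kappa = c(-1, 1), beta = c(0, Inf), q_init = c(-Inf, Inf))

.check_prior_entry <- function(name, spec) {
  sup <- .param_support[[name]]
  if (is.null(sup)) stop(sprintf("unknown parameter '%s' in prior", name))
  fam <- spec$family
  ok <- switch(fam,
    point = spec$value > sup[1] && spec$value < sup[2] ||
            (name %in% c("f", "w") && spec$value >= 0 && spec$value < 1),
    beta = all(sup == c(0, 1)),
    gamma = sup[1] == 0 && is.infinite(sup[2]),
    uniform = spec$min >= sup[1] && spec$max <= sup[2] && spec$min < spec$max,
    normal = all(is.infinite(sup)),
    stop(sprintf("unknown prior family '%s'", fam)))
  if (!isTRUE(ok))
    stop(sprintf("prior family '%s' puts mass outside the support of '%s'",
                 fam, name))
  invisible(TRUE)
}

.draw_prior <- function(spec) {
  switch(spec$family,
         point = spec$value,
         beta = stats::rbeta(1, spec$shape1, spec$shape2),
         gamma = stats::rgamma(1, shape = spec$shape, rate = spec$rate),
         uniform = stats::runif(1, spec$min, spec$max),
         normal = stats::rnorm(1, spec$mean, spec$sd))
}

#' Sample constrained agent parameters from a prior
#'
#' @param param_prior Prior as in [default_param_prior()].
#' @param seed Integer seed.
#' @return An `rl_params` object (unspecified parameters keep their neutral
#'   defaults).
#' @export
sample_agent_params <- function(param_prior = default_param_prior(), seed = 1) {
  for (nm in names(param_prior)) .check_prior_entry(nm, param_prior[[nm]])
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  vals <- lapply(param_prior, .draw_prior)
  do.call(rl_params, vals)
}

#' Open-loop simulation of one block
#'
#' The agent samples each action from its own softmax policy, observes the
#' schedule's reward for the chosen arm (scaled internally to \[0.01, 1\])
#' and updates its latent state. With probability `miss_rate` a trial is
#' missed: the action is not taken, the trial is marked invalid and the
#' agent's latent update is skipped entirely (state carried forward
#' unchanged).
#'
#' @param agent Any object implementing the [agent_init()] interface.
#' @param schedule A `bandit_schedule`.
#' @param miss_rate Per-trial miss probability.
#' @param seed Integer seed.
#' @param participant_id,block_id Identifiers for the resulting block.
#' @return A `session_block` (with the schedule attached).
#' @export
simulate_block <- function(agent, schedule, miss_rate = 0, seed = 1,
                           participant_id = "sim", block_id = "b1") {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- schedule$n_trials
  actions <- rep(NA_integer_, n); rewards <- rep(NA_integer_, n)
  valid <- rep(FALSE, n)
  state <- agent_init(agent)
  for (t in seq_len(n)) {
    if (miss_rate > 0 && stats::runif(1) < miss_rate) next
    p <- agent_policy(agent, state)
    a <- sample.int(schedule$n_arms, 1, prob = p) - 1L
    r <- schedule$rewards[t, a + 1L]
    actions[t] <- a; rewards[t] <- as.integer(r); valid[t] <- TRUE
    state <- agent_observe(agent, state, a, scale_rewards(r))
  }
  session_block(participant_id, block_id, actions, rewards, valid, schedule)
}

#' Cohort specification
#'
#' Describes a full synthetic dataset: number of participants, blocks per
#' participant, trial count, the teacher model generating behaviour, the
#' per-participant parameter prior, miss rate, split fractions and seed.
#' The desk-scale default (200 participants x 2 blocks x 150 trials,
#' Best-RL teacher, 0.5% missed trials, 80/10/10 participant-level splits)
#' mirrors the structure of the human corpus at reduced size.
#'
#' @param n_participants,blocks_per_participant,n_trials Cohort shape.
#' @param generator `"best_rl"` (heterogeneous Best-RL agents drawn from
#'   `param_prior`), `"rich_memory"` (the hand-constructed memory-state
#'   teacher, see [memory_teacher()]), or a function `(params_seed) ->
#'   agent` for custom teachers.
#' @param param_prior Prior for per-participant parameters (ignored by
#'   custom generator functions).
#' @param miss_rate Per-trial miss probability.
#' @param split_fracs Train/validation/test fractions (must sum to 1).
#' @param seed Integer master seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_participants = 200, blocks_per_participant = 2,
                        n_trials = 150, generator = "best_rl",
                        param_prior = default_param_prior(),
                        miss_rate = 0.005,
                        split_fracs = c(train = 0.8, validation = 0.1, test = 0.1),
                        seed = 1) {
  if (abs(sum(split_fracs) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (n_participants < 3 && all(split_fracs > 0))
    stop("too few participants for non-empty splits")
  structure(list(n_participants = as.integer(n_participants),
                 blocks_per_participant = as.integer(blocks_per_participant),
                 n_trials = as.integer(n_trials), generator = generator,
                 param_prior = param_prior, miss_rate = miss_rate,
                 split_fracs = split_fracs, seed = as.integer(seed)),
            class = "cohort_spec")
}

.split_participants <- function(ids, fracs, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- length(ids)
  perm <- sample(ids)
  n_val <- if (fracs[2] > 0) max(1L, round(fracs[2] * n)) else 0L
  n_test <- if (fracs[3] > 0) max(1L, round(fracs[3] * n)) else 0L
  if (n_val + n_test >= n) stop("too few participants for non-empty splits")
  split <- c(rep("train", n - n_val - n_test), rep("validation", n_val),
             rep("test", n_test))
  stats::setNames(split, perm)
}

.make_agent <- function(spec, params_seed) {
  if (is.function(spec$generator)) return(spec$generator(params_seed))
  switch(spec$generator,
         best_rl = rl_agent(best_rl(),
                            sample_agent_params(spec$param_prior, params_seed)),
         rich_memory = memory_teacher(seed = params_seed),
         stop("unknown generator"))
}

#' Build a full synthetic dataset
#'
#' Draws one agent per participant from the cohort's generator, simulates
#' every block open-loop on a fresh per-participant-per-block reward
#' schedule, and assigns participants (never single blocks) to
#' train/validation/test splits by a seeded permutation.
#'
#' @param spec A [cohort_spec()].
#' @return A `bandit_dataset`: list with `blocks` (list of
#'   `session_block`), `split` (named participant -> split assignment),
#'   `spec` and `seed`.
#' @export
build_dataset <- function(spec) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  seeds <- matrix(sample.int(2^31 - 2, spec$n_participants * (2 * spec$blocks_per_participant + 1)),
                  nrow = spec$n_participants)
  ids <- sprintf("p%03d", seq_len(spec$n_participants))
  blocks <- vector("list", spec$n_participants * spec$blocks_per_participant)
  k <- 0
  for (i in seq_len(spec$n_participants)) {
    agent <- .make_agent(spec, seeds[i, 1])
    for (jb in seq_len(spec$blocks_per_participant)) {
      sch <- generate_schedule(n_trials = spec$n_trials,
                               seed = seeds[i, 2 * jb])
      k <- k + 1
      blocks[[k]] <- simulate_block(agent, sch, miss_rate = spec$miss_rate,
                                    seed = seeds[i, 2 * jb + 1],
                                    participant_id = ids[i],
                                    block_id = sprintf("%s_b%d", ids[i], jb))
    }
  }
  split <- .split_participants(ids, spec$split_fracs, spec$seed + 1L)
  structure(list(blocks = blocks, split = split, spec = spec,
                 seed = spec$seed, provenance = "synthetic"),
            class = "bandit_dataset")
}

#' Extract the blocks of one split
#'
#' @param dataset A `bandit_dataset` (or a plain list with `train` /
#'   `validation` / `test` block lists).
#' @param split One of `"train"`, `"validation"`, `"test"`, `"all"`.
#' @return List of `session_block`s.
#' @export
dataset_blocks <- function(dataset, split = "all") {
  if (!inherits(dataset, "bandit_dataset")) {
    if (!is.null(dataset[[split]])) return(dataset[[split]])
    stop("not a bandit_dataset")
  }
  if (split == "all") return(dataset$blocks)
  keep <- names(dataset$split)[dataset$split == split]
  Filter(function(b) b$participant_id %in% keep, dataset$blocks)
}

#' Write / read a dataset directory
#'
#' `blocks.csv` holds `participant_id,block_id,trial,action,reward,valid`
#' (0-based trials and arms, empty action/reward on missed trials);
#' `schedules.csv` holds the per-block latent means and arm rewards; and
#' `manifest.json` records the cohort spec, seed and split assignment.
#' The round trip is lossless.
#'
#' @param dataset A `bandit_dataset`.
#' @param dir Directory (created if missing).
#' @return `read_dataset` returns a `bandit_dataset` with
#'   `provenance = "external"`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(dataset$blocks, function(b) data.frame(
    participant_id = b$participant_id, block_id = b$block_id,
    trial = seq_len(b$n_trials) - 1L, action = b$actions,
    reward = b$rewards, valid = b$valid))
  utils::write.csv(do.call(rbind, rows), file.path(dir, "blocks.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  sch <- lapply(dataset$blocks, function(b) {
    s <- b$schedule
    data.frame(participant_id = b$participant_id, block_id = b$block_id,
               trial = rep(seq_len(s$n_trials) - 1L, s$n_arms),
               arm = rep(seq_len(s$n_arms) - 1L, each = s$n_trials),
               mu = sprintf("%.17g", as.vector(s$mu)),
               reward = as.integer(s$rewards))
  })
  utils::write.csv(do.call(rbind, sch), file.path(dir, "schedules.csv"),
                   row.names = FALSE, quote = FALSE)
  spec <- dataset$spec
  manifest <- list(
    n_participants = spec$n_participants,
    blocks_per_participant = spec$blocks_per_participant,
    n_trials = spec$n_trials,
    generator = if (is.function(spec$generator)) "custom" else spec$generator,
    miss_rate = spec$miss_rate, split_fracs = as.list(spec$split_fracs),
    seed = dataset$seed, split = as.list(dataset$split),
    schedule_params = list(lam = dataset$blocks[[1]]$schedule$lam,
                           sigma_d = dataset$blocks[[1]]$schedule$sigma_d,
                           sigma_o = dataset$blocks[[1]]$schedule$sigma_o))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  bl <- utils::read.csv(file.path(dir, "blocks.csv"),
                        colClasses = c(participant_id = "character",
                                       block_id = "character"))
  sc <- utils::read.csv(file.path(dir, "schedules.csv"),
                        colClasses = c(participant_id = "character",
                                       block_id = "character", mu = "character"))
  sc$mu <- as.numeric(sc$mu)
  sp <- man$schedule_params
  blocks <- lapply(split(bl, bl$block_id), function(d) {
    d <- d[order(d$trial), ]
    s <- sc[sc$block_id == d$block_id[1], ]
    n <- max(s$trial) + 1L
    mu <- matrix(NA_real_, n, 4); rw <- matrix(NA_real_, n, 4)
    mu[cbind(s$trial + 1L, s$arm + 1L)] <- s$mu
    rw[cbind(s$trial + 1L, s$arm + 1L)] <- s$reward
    sch <- structure(list(mu = mu, rewards = rw, lam = sp$lam,
                          sigma_d = sp$sigma_d, sigma_o = sp$sigma_o,
                          n_trials = n, n_arms = 4L, seed = NA_integer_),
                     class = "bandit_schedule")
    session_block(d$participant_id[1], d$block_id[1], d$action, d$reward,
                  as.logical(d$valid), sch)
  })
  order_ids <- unique(bl$block_id)
  blocks <- blocks[order_ids]
  names(blocks) <- NULL
  split_vec <- unlist(man$split)
  structure(list(blocks = blocks, split = split_vec,
                 spec = man[setdiff(names(man), "split")],
                 seed = man$seed, provenance = "external"),
            class = "bandit_dataset")
}

#' Hand-constructed rich-memory teacher
#'
#' A generator in the Memory-ANN architecture class, used to exercise the
#' model-comparison ordering. Three mechanisms, each aimed at one rung of
#' the architecture ladder:
#'
#' * Reward side: the value written to the chosen arm ignores that arm's
#'   previous value and maps the observed reward around a slowly drifting
#'   reward-level reference `m` (exponential mean of obtained scaled
#'   rewards, rate `tau_m`): `Q(a) <- 0.5 + gain (r - m)`. Unchosen values
#'   decay towards `q_init`.
#' * Action side: a normalised multi-lag choice kernel
#'   `ck <- rho ck + (1 - rho) onehot(a)` contributing `kappa ck` to the
#'   logits. A single-lag perseveration term (Best RL / RL-ANN) can only
#'   approximate it; the kernel recurrence is expressible by Context-ANN's
#'   `c`-context input.
#' * Choice sharpness ramps within each block from `beta0` to `beta1`
#'   (exploration early, exploitation late). Time-on-task is observable to
#'   no model input except a recurrent memory state, which can integrate a
#'   trial counter, so this component separates Memory-ANN from
#'   Context-ANN.
#'
#' Choices follow `softmax(beta_t (Q + kappa ck))`. The default gain of 1
#' makes the static part of the reward map (`Q = r - mean(m)`, plus an
#' offset) exactly expressible by the linear delta rule, so Best RL and
#' RL-ANN sit at the same rung of the ladder.
#'
#' @param beta0,beta1 Inverse temperature at the first and last trial of a
#'   150-trial block (linear ramp).
#' @param kappa Total kernel weight (logit units at kernel saturation).
#' @param rho Kernel decay per trial.
#' @param tau_m Reward-level trace rate.
#' @param gain Reward-to-value gain (kept below 1 so the static part of
#'   the map stays inside the linear model class).
#' @param f,q_init Forgetting of unchosen values.
#' @param n_trials Block length used to scale the sharpness ramp.
#' @param seed Seed for mild per-participant jitter of the sharpness and
#'   kernel weight.
#' @return An object of class `memory_teacher` implementing the agent
#'   interface.
#' @export
memory_teacher <- function(beta0 = 4, beta1 = 10, kappa = 0.35, rho = 0.75,
                           tau_m = 0.08, gain = 1.0, f = 0.05, q_init = 0.5,
                           n_trials = 150, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    sc <- stats::runif(1, 0.85, 1.15)
    beta0 <- beta0 * sc; beta1 <- beta1 * sc
    kappa <- kappa * stats::runif(1, 0.85, 1.15)
  }
  structure(list(beta0 = beta0, beta1 = beta1, kappa = kappa, rho = rho,
                 tau_m = tau_m, gain = gain, f = f, q_init = q_init,
                 n_trials = n_trials),
            class = c("memory_teacher", "hybridrl_agent"))
}

#' @export
agent_init.memory_teacher <- function(agent) {
  list(q = rep(agent$q_init, 4), c = numeric(4), m = 0.5, t = 0L)
}

#' @export
agent_policy.memory_teacher <- function(agent, state) {
  frac <- min(1, state$t / (agent$n_trials - 1))
  beta_t <- agent$beta0 + (agent$beta1 - agent$beta0) * frac
  softmax_policy(state$q, agent$kappa * state$c, beta_t)
}

#' @export
agent_observe.memory_teacher <- function(agent, state, action, reward) {
  qa <- 0.5 + agent$gain * (reward - state$m)
  q <- apply_forgetting(state$q, action, agent$f, agent$q_init)
  q[action + 1L] <- qa
  ck <- agent$rho * state$c
  ck[action + 1L] <- ck[action + 1L] + (1 - agent$rho)
  m_new <- state$m + agent$tau_m * (reward - state$m)
  list(q = q, c = ck, m = m_new, t = state$t + 1L)
}
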