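#' Elementary Q-learning update
#'
#' Delta-rule update with an additive bias:
#' \eqn{Q \leftarrow Q + \alpha (r - Q) + b}.
#'
#' @param q_a Current value of the chosen action.
#' @param r Observed reward (scaled).
#' @param alpha Learning rate.
#' @param b Update bias.
#' @return Updated value.
#' @export
q_update <- function(q_a, r, alpha, b = 0) q_a + alpha * (r - q_a) + b

#' Exponential forgetting of action values
#'
#' Decays action values towards the reference value `q_init`:
#' \eqn{Q \leftarrow (1-f) Q + f Q_{init}} for every arm in scope. The
#' default scope decays only unchosen arms; `"all"` also decays the chosen
#' arm (which then gets updated from its post-decay value).
#'
#' @param q Value vector.
#' @param chosen_arm 0-based index of the chosen arm (ignored for scope
#'   `"all"`); may be `NA` for a missed trial, in which case scope
#'   `"unchosen"` decays every arm.
#' @param f Forgetting rate in \[0, 1\].
#' @param q_init Reference value.
#' @param scope `"unchosen"` or `"all"`.
#' @return Decayed value vector.
#' @export
apply_forgetting <- function(q, chosen_arm, f, q_init, scope = c("unchosen", "all")) {
  scope <- match.arg(scope)
  if (f < 0 || f > 1) stop("`f` must lie in [0, 1]")
  idx <- if (scope == "all" || is.na(chosen_arm)) seq_along(q) else
    setdiff(seq_along(q), chosen_arm + 1L)
  q[idx] <- (1 - f) * q[idx] + f * q_init
  q
}

#' Perseveration (choice-kernel) update
#'
#' Sets the perseveration indicator of the previously chosen action to
#' `kappa` and all others to 0. Negative `kappa` expresses switching.
#'
#' @param chosen_arm 0-based arm index.
#' @param kappa Perseveration strength.
#' @param n_arms Number of arms (default 4).
#' @return Perseveration vector.
#' @export
perseveration_update <- function(chosen_arm, kappa, n_arms = 4) {
  c_vec <- numeric(n_arms)
  c_vec[chosen_arm + 1L] <- kappa
  c_vec
}

#' Pearce-Hall variable-learning-rate step
#'
#' The learning rate tracks the absolute prediction error ("surprise"):
#' \eqn{\delta = r - Q}, \eqn{Q \leftarrow Q + \alpha_t \delta},
#' \eqn{\alpha_{t+1} = w |\delta| + (1-w) \alpha_t}. Rewards must be on the
#' \[0.01, 1\] scale so that \eqn{|\delta| \le 1} keeps \eqn{\alpha} in
#' \[0, 1\]. At `w = 0` the learning rate is constant.
#'
#' @param q_a Current value of the chosen action.
#' @param r Scaled reward.
#' @param alpha_t Current learning rate.
#' @param w Weighting parameter in \[0, 1\].
#' @param b Update bias (default 0).
#' @return List with `q` (updated value), `alpha` (next learning rate) and
#'   `delta` (prediction error).
#' @export
variable_lr_step <- function(q_a, r, alpha_t, w, b = 0) {
  delta <- r - q_a
  list(q = q_a + alpha_t * delta + b,
       alpha = w * abs(delta) + (1 - w) * alpha_t,
       delta = delta)
}

#' Softmax choice policy
#'
#' \eqn{p = \mathrm{softmax}(\beta (Q + c))}, guarded against overflow by
#' subtracting the maximum logit (the result is invariant to adding any
#' constant to all logits). `beta = 0` yields the uniform policy.
#'
#' @param q Value vector.
#' @param c_vec Perseveration vector (default zeros).
#' @param beta Inverse temperature (default 1; ANN models fold the scale
#'   into their weights and call this with `beta = 1`).
#' @return Probability vector summing to 1, strictly positive.
#' @export
softmax_policy <- function(q, c_vec = numeric(length(q)), beta = 1) {
  if (beta < 0) stop("`beta` must be non-negative")
  z <- beta * (q + c_vec)
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Tabular Q-learning agent
#'
#' Bundles a `variant_spec` and `rl_params` into an agent exposing the
#' unified step interface ([agent_init()], [agent_policy()],
#' [agent_observe()]) shared with the neural architectures.
#'
#' @param variant A `variant_spec`.
#' @param params An `rl_params` object.
#' @param n_arms Number of arms.
#' @return An object of class `rl_agent`.
#' @export
rl_agent <- function(variant, params, n_arms = 4) {
  structure(list(variant = variant, params = params, n_arms = n_arms),
            class = c("rl_agent", "hybridrl_agent"))
}

#' Unified agent step interface
#'
#' Every model (tabular, hand-constructed teacher or neural) implements
#' three generics: `agent_init` returns the pre-trial-1 latent state,
#' `agent_policy` maps a state to a choice-probability vector, and
#' `agent_observe` consumes the trial's (action, scaled reward) and returns
#' the next state. Missed trials skip `agent_observe` entirely, carrying the
#' state forward unchanged.
#'
#' @param agent A model object.
#' @param state A latent state as returned by `agent_init`/`agent_observe`.
#' @param action 0-based chosen arm.
#' @param reward Scaled reward in \[0.01, 1\].
#' @return `agent_init`/`agent_observe`: a state list; `agent_policy`: a
#'   probability vector.
#' @export
agent_init <- function(agent) UseMethod("agent_init")

#' @rdname agent_init
#' @export
agent_policy <- function(agent, state) UseMethod("agent_policy")

#' @rdname agent_init
#' @export
agent_observe <- function(agent, state, action, reward) UseMethod("agent_observe")

#' @export
agent_init.rl_agent <- function(agent) {
  p <- agent$params
  list(q = rep(p$q_init, agent$n_arms),
       c = numeric(agent$n_arms),
       alpha = if (agent$variant$variable_lr) p$alpha_init else p$alpha)
}

#' @export
agent_policy.rl_agent <- function(agent, state) {
  softmax_policy(state$q, state$c, agent$params$beta)
}

#' @export
agent_observe.rl_agent <- function(agent, state, action, reward) {
  v <- agent$variant; p <- agent$params
  q <- state$q
  if (v$forgetting != "off")
    q <- apply_forgetting(q, action, p$f, p$q_init,
                          scope = if (v$forgetting == "all") "all" else "unchosen")
  if (v$variable_lr) {
    st <- variable_lr_step(q[action + 1L], reward, state$alpha, p$w, p$b)
    q[action + 1L] <- st$q
    alpha_next <- st$alpha
  } else {
    q[action + 1L] <- q_update(q[action + 1L], reward, p$alpha, p$b)
    alpha_next <- state$alpha
  }
  c_vec <- if (v$perseveration) perseveration_update(action, p$kappa, agent$n_arms)
           else numeric(agent$n_arms)
  list(q = q, c = c_vec, alpha = alpha_next)
}
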