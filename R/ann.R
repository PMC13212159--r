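#' Initialise weights for a neural architecture
#'
#' Supported architectures: `"rl_ann"` (reward module input
#' \[Q(a), r\], action module input the scalar previous action),
#' `"context_ann"` (reward input additionally carries the full Q vector,
#' action input the full perseveration vector), `"memory_ann"` (module
#' inputs are \[r, s^(r)\] and \[a, s^(a)\]; the hidden layer activations
#' are the recurrent memory state) and `"vanilla_rnn"` (one-hot action +
#' reward + recurrent state into a single tanh layer). The two-module
#' architectures retain a trainable forgetting rate (stored raw, sigmoid
#' transformed) and reference value `q_init` for the exponential decay of
#' unchosen action values.
#'
#' Weight matrices are drawn uniformly on the Glorot interval
#' \eqn{\pm\sqrt{6/(fan_{in}+fan_{out})}}; biases start at zero, the raw
#' forgetting rate at sigmoid^-1(0.1) and `q_init` at mid scale (0.5).
#'
#' @param arch Architecture tag.
#' @param hidden Hidden layer size (shared by both modules).
#' @param n_arms Number of arms (fixed at 4 for this task).
#' @param seed Integer seed; initialisation is deterministic given the seed.
#' @return An object of class `ann_weights`.
#' @export
init_weights <- function(arch = c("rl_ann", "context_ann", "memory_ann",
                                  "vanilla_rnn"),
                         hidden = 16, n_arms = 4, seed = 1) {
  arch <- match.arg(arch)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  glorot <- function(nout, nin) {
    lim <- sqrt(6 / (nin + nout))
    matrix(stats::runif(nout * nin, -lim, lim), nout, nin)
  }
  w <- switch(arch,
    rl_ann = , context_ann = , memory_ann = {
      nin_r <- switch(arch, rl_ann = 2L, context_ann = 2L + n_arms,
                      memory_ann = 1L + hidden)
      nin_a <- switch(arch, rl_ann = 1L, context_ann = 1L + n_arms,
                      memory_ann = 1L + hidden)
      list(W1r = glorot(hidden, nin_r), b1r = numeric(hidden),
           W2r = glorot(1, hidden), b2r = numeric(1),
           W1a = glorot(hidden, nin_a), b1a = numeric(hidden),
           W2a = glorot(n_arms, hidden), b2a = numeric(n_arms),
           f_raw = .logit(0.1), q_init = 0.5)
    },
    vanilla_rnn = {
      nin <- n_arms + 1L + hidden
      list(W1 = glorot(hidden, nin), b1 = numeric(hidden),
           W2 = glorot(n_arms, hidden), b2 = numeric(n_arms))
    })
  structure(c(list(arch = arch, hidden = as.integer(hidden),
                   n_arms = as.integer(n_arms), seed = as.integer(seed)), w),
            class = "ann_weights")
}

#' Two-layer perceptron forward pass
#'
#' `hidden = tanh(W1 x + b1)`; `output = W2 hidden + b2` (no output
#' nonlinearity, so outputs can be read as logits/values).
#'
#' @param W1,b1,W2,b2 Layer parameters.
#' @param x Input vector.
#' @return List with `output` and `hidden` vectors.
#' @export
mlp_forward <- function(W1, b1, W2, b2, x) {
  if (ncol(W1) != length(x)) stop("input length does not match W1")
  h <- tanh(as.vector(W1 %*% x) + b1)
  list(output = as.vector(W2 %*% h) + b2, hidden = h)
}

.ann_f <- function(weights) .sigmoid(weights$f_raw)

# Decay unchosen arms towards q_init, then overwrite the chosen arm.
.decay_and_set <- function(q, action, qa_new, f, q_init) {
  q_next <- (1 - f) * q + f * q_init
  q_next[action + 1L] <- qa_new
  q_next
}

#' Single-trial step of the RL-ANN architecture
#'
#' The reward module consumes \[Q(a), r\] of the previous trial and
#' overwrites the chosen arm's value; unchosen values decay exponentially
#' towards `q_init`. The action module consumes the scalar previous action
#' and emits the perseveration vector. Logits are `Q + c`; no inverse
#' temperature is applied (the scale lives in the weights).
#'
#' @param state List with value vector `q` and perseveration `c` (plus
#'   memory states for the recurrent architectures).
#' @param prev_action 0-based previous action.
#' @param prev_reward Previous scaled reward.
#' @param weights An `ann_weights` of the matching architecture.
#' @return List with `state` (updated) and `logits`.
#' @export
step_rl_ann <- function(state, prev_action, prev_reward, weights) {
  if (is.na(prev_action) || prev_action < 0 || prev_action > weights$n_arms - 1)
    stop("`prev_action` must lie in 0..3")
  r_mod <- mlp_forward(weights$W1r, weights$b1r, weights$W2r, weights$b2r,
                       c(state$q[prev_action + 1L], prev_reward))
  q <- .decay_and_set(state$q, prev_action, r_mod$output,
                      .ann_f(weights), weights$q_init)
  a_mod <- mlp_forward(weights$W1a, weights$b1a, weights$W2a, weights$b2a,
                       prev_action)
  st <- list(q = q, c = a_mod$output)
  list(state = st, logits = st$q + st$c)
}

#' @rdname step_rl_ann
#' @export
step_context_ann <- function(state, prev_action, prev_reward, weights) {
  if (is.na(prev_action) || prev_action < 0 || prev_action > weights$n_arms - 1)
    stop("`prev_action` must lie in 0..3")
  r_mod <- mlp_forward(weights$W1r, weights$b1r, weights$W2r, weights$b2r,
                       c(state$q[prev_action + 1L], prev_reward, state$q))
  q <- .decay_and_set(state$q, prev_action, r_mod$output,
                      .ann_f(weights), weights$q_init)
  a_mod <- mlp_forward(weights$W1a, weights$b1a, weights$W2a, weights$b2a,
                       c(prev_action, state$c))
  st <- list(q = q, c = a_mod$output)
  list(state = st, logits = st$q + st$c)
}

#' @rdname step_rl_ann
#' @export
step_memory_ann <- function(state, prev_action, prev_reward, weights) {
  if (is.na(prev_action) || prev_action < 0 || prev_action > weights$n_arms - 1)
    stop("`prev_action` must lie in 0..3")
  if (length(state$s_r) != weights$hidden || length(state$s_a) != weights$hidden)
    stop("memory state size does not match the architecture's hidden size")
  r_mod <- mlp_forward(weights$W1r, weights$b1r, weights$W2r, weights$b2r,
                       c(prev_reward, state$s_r))
  q <- .decay_and_set(state$q, prev_action, r_mod$output,
                      .ann_f(weights), weights$q_init)
  a_mod <- mlp_forward(weights$W1a, weights$b1a, weights$W2a, weights$b2a,
                       c(prev_action, state$s_a))
  st <- list(q = q, c = a_mod$output, s_r = r_mod$hidden, s_a = a_mod$hidden)
  list(state = st, logits = st$q + st$c)
}

#' @rdname step_rl_ann
#' @param prev_action_onehot For the vanilla RNN, the previous action as a
#'   one-hot vector (all zeros before the first trial).
#' @export
step_vanilla_rnn <- function(state, prev_action_onehot, prev_reward, weights) {
  if (length(prev_action_onehot) != weights$n_arms)
    stop("one-hot action has the wrong length")
  x <- c(prev_action_onehot, prev_reward, state$s)
  out <- mlp_forward(weights$W1, weights$b1, weights$W2, weights$b2, x)
  list(state = list(s = out$hidden), logits = out$output)
}

#' Neural agent wrapper
#'
#' Exposes an `ann_weights` object through the unified step interface so
#' that open-loop simulation and teacher forcing work identically for
#' tabular and neural models. Before the first observed trial the value
#' vector sits at `q_init`, perseveration and memory states at zero; for
#' the vanilla RNN the first-trial logits are computed from the all-zero
#' one-hot action and mid-scale reward 0.5.
#'
#' @param weights An `ann_weights` object.
#' @return An object of class `ann_agent`.
#' @export
ann_agent <- function(weights) {
  structure(list(weights = weights),
            class = c("ann_agent", "hybridrl_agent"))
}

#' @export
agent_init.ann_agent <- function(agent) {
  w <- agent$weights
  if (w$arch == "vanilla_rnn") {
    st <- step_vanilla_rnn(list(s = numeric(w$hidden)),
                           numeric(w$n_arms), 0.5, w)
    c(st["state"], list(logits = st$logits))
  } else {
    st <- list(q = rep(w$q_init, w$n_arms), c = numeric(w$n_arms))
    if (w$arch == "memory_ann") {
      st$s_r <- numeric(w$hidden); st$s_a <- numeric(w$hidden)
    }
    st
  }
}

#' @export
agent_policy.ann_agent <- function(agent, state) {
  if (agent$weights$arch == "vanilla_rnn") softmax_policy(state$logits)
  else softmax_policy(state$q, state$c)
}

#' @export
agent_observe.ann_agent <- function(agent, state, action, reward) {
  w <- agent$weights
  if (w$arch == "vanilla_rnn") {
    onehot <- numeric(w$n_arms); onehot[action + 1L] <- 1
    st <- step_vanilla_rnn(state$state, onehot, reward, w)
    c(st["state"], list(logits = st$logits))
  } else {
    step <- switch(w$arch, rl_ann = step_rl_ann, context_ann = step_context_ann,
                   memory_ann = step_memory_ann)
    step(state, action, reward, w)$state
  }
}

#' Serialize network weights to JSON
#'
#' Writes architecture tag, shapes, seed and all arrays to a single JSON
#' file at 17 significant digits; [read_weights()] restores an
#' `ann_weights` object equal to the original to full double precision
#' (relative error below 1e-15).
#'
#' @param weights An `ann_weights`.
#' @param path File path.
#' @export
write_weights <- function(weights, path) {
  payload <- unclass(weights)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- raw
  for (nm in names(w)) {
    if (is.matrix(raw[[nm]])) w[[nm]] <- raw[[nm]]
  }
  # vectors of length 1 come back as scalars; matrices stay matrices
  for (nm in c("b1r", "b2r", "b1a", "b2a", "b1", "b2"))
    if (!is.null(w[[nm]])) w[[nm]] <- as.numeric(w[[nm]])
  w$hidden <- as.integer(w$hidden); w$n_arms <- as.integer(w$n_arms)
  w$seed <- as.integer(w$seed)
  structure(w, class = "ann_weights")
}
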