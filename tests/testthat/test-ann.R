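test_that("mlp_forward matches a hand-coded matrix-product oracle", {
  set.seed(1)
  W1 <- matrix(rnorm(12), 4, 3); b1 <- rnorm(4)
  W2 <- matrix(rnorm(8), 2, 4); b2 <- rnorm(2)
  x <- rnorm(3)
  out <- mlp_forward(W1, b1, W2, b2, x)
  h_hand <- tanh(c(
    W1[1, 1] * x[1] + W1[1, 2] * x[2] + W1[1, 3] * x[3] + b1[1],
    W1[2, 1] * x[1] + W1[2, 2] * x[2] + W1[2, 3] * x[3] + b1[2],
    W1[3, 1] * x[1] + W1[3, 2] * x[2] + W1[3, 3] * x[3] + b1[3],
    W1[4, 1] * x[1] + W1[4, 2] * x[2] + W1[4, 3] * x[3] + b1[4]))
  o_hand <- c(sum(W2[1, ] * h_hand) + b2[1], sum(W2[2, ] * h_hand) + b2[2])
  expect_equal(out$hidden, h_hand, tolerance = 1e-12)
  expect_equal(out$output, o_hand, tolerance = 1e-12)
  # degenerate weights
  expect_equal(mlp_forward(W1 * 0, b1 * 0, W2 * 0, b2 * 0, x)$output, c(0, 0))
  hb <- mlp_forward(W1 * 0, b1, W2, b2, x)
  expect_equal(hb$hidden, tanh(b1))  # input-independent
  expect_error(mlp_forward(W1, b1, W2, b2, rnorm(5)), "match")
})

test_that("all architectures' C++ likelihoods equal the R step-function oracle", {
  teacher <- rl_agent(best_rl(), rl_params(alpha = 0.3, beta = 6, kappa = 0.2,
                                           f = 0.1, q_init = 0.55))
  blocks <- sim_blocks(teacher, 3, n_trials = 30, miss_rate = 0.15, seed = 21)
  for (arch in c("rl_ann", "context_ann", "memory_ann", "vanilla_rnn")) {
    w <- init_weights(arch, hidden = 5, seed = 13)
    expect_equal(nll_loss(w, blocks)$total, oracle_nll(w, blocks),
                 tolerance = 1e-10, info = arch)
  }
})

test_that("backpropagation-through-time gradients match central differences", {
  teacher <- rl_agent(simple_rl(), rl_params(alpha = 0.3, beta = 4))
  blocks <- sim_blocks(teacher, 2, n_trials = 8, miss_rate = 0.2, seed = 31)
  mats <- blocks_to_matrices(blocks)
  code <- c(rl_ann = 0L, context_ann = 1L, memory_ann = 2L)
  for (arch in c("rl_ann", "context_ann", "memory_ann", "vanilla_rnn")) {
    w <- init_weights(arch, hidden = 3, seed = 17)
    res <- if (arch == "vanilla_rnn") {
      hybridrl:::cpp_rnn_nll_grad(w, mats$actions, mats$rewards, TRUE)
    } else {
      hybridrl:::cpp_modular_nll_grad(w, mats$actions, mats$rewards,
                                      code[[arch]], TRUE)
    }
    ef <- cpp_eval_fun(arch)
    set.seed(5)
    for (nm in names(res$grads)) {
      g <- as.numeric(res$grads[[nm]])
      idx <- if (length(g) > 6) sort(sample.int(length(g), 6)) else
        seq_along(g)
      for (i in idx) {
        ng <- numeric_grad_entry(w, mats, ef, nm, i)
        expect_equal(g[i], ng, tolerance = 1e-5,
                     info = sprintf("%s %s[%d]", arch, nm, i))
      }
    }
  }
})

test_that("zero reward-module weights write the output bias into the chosen arm", {
  w <- init_weights("rl_ann", hidden = 4, seed = 2)
  w$W1r <- w$W1r * 0; w$b1r <- w$b1r * 0; w$W2r <- w$W2r * 0
  w$b2r <- 0.73
  st <- step_rl_ann(list(q = rep(0.5, 4), c = rep(0, 4)), 2L, 0.6, w)
  expect_equal(st$state$q[3], 0.73)
  f <- 1 / (1 + exp(-w$f_raw))
  expect_equal(st$state$q[1], (1 - f) * 0.5 + f * w$q_init)
})

test_that("a Context-ANN with zeroed context columns reproduces RL-ANN exactly", {
  teacher <- rl_agent(best_rl(), rl_params(alpha = 0.3, beta = 6, kappa = 0.2))
  blocks <- sim_blocks(teacher, 3, n_trials = 40, seed = 41)
  w0 <- init_weights("rl_ann", hidden = 6, seed = 19)
  wc <- init_weights("context_ann", hidden = 6, seed = 19)
  wc$W1r <- cbind(w0$W1r, matrix(0, 6, 4))
  wc$W1a <- cbind(w0$W1a, matrix(0, 6, 4))
  for (nm in c("b1r", "W2r", "b2r", "b1a", "W2a", "b2a", "f_raw", "q_init"))
    wc[[nm]] <- w0[[nm]]
  expect_equal(nll_loss(wc, blocks)$per_block, nll_loss(w0, blocks)$per_block,
               tolerance = 1e-10)
  # non-zero context columns react to differing unchosen-arm values
  wc2 <- init_weights("context_ann", hidden = 6, seed = 23)
  s1 <- step_context_ann(list(q = c(0.5, 0.2, 0.2, 0.2), c = rep(0, 4)),
                         0L, 0.7, wc2)
  s2 <- step_context_ann(list(q = c(0.5, 0.9, 0.2, 0.2), c = rep(0, 4)),
                         0L, 0.7, wc2)
  expect_gt(abs(s1$state$q[1] - s2$state$q[1]), 1e-8)
})

test_that("Memory-ANN separates reward and action processing architecturally", {
  w <- init_weights("memory_ann", hidden = 6, seed = 29)
  st0 <- function() list(q = rep(0.5, 4), c = rep(0, 4),
                         s_r = rep(0, 6), s_a = rep(0, 6))
  rewards <- c(0.9, 0.2, 0.6, 0.4)
  acts_a <- c(0L, 1L, 2L, 1L); acts_b <- c(3L, 0L, 1L, 2L)
  run <- function(acts) {
    s <- st0(); out <- list()
    for (i in seq_along(acts)) {
      step <- step_memory_ann(s, acts[i], rewards[i], w)
      s <- step$state; out[[i]] <- s
    }
    s
  }
  sa <- run(acts_a); sb <- run(acts_b)
  expect_equal(sa$s_r, sb$s_r, tolerance = 1e-12)   # reward side blind to actions
  expect_false(isTRUE(all.equal(sa$s_a, sb$s_a)))   # action side is not
  # action side blind to rewards
  runr <- function(rews) {
    s <- st0()
    for (i in seq_along(rews)) s <- step_memory_ann(s, acts_a[i], rews[i], w)$state
    s
  }
  expect_equal(runr(rewards)$s_a, runr(rev(rewards))$s_a, tolerance = 1e-12)
  # state dependence: different priming histories change the response
  s_hi <- st0(); s_lo <- st0()
  for (i in 1:10) {
    s_hi <- step_memory_ann(s_hi, 0L, 0.95, w)$state
    s_lo <- step_memory_ann(s_lo, 0L, 0.05, w)$state
  }
  q_hi <- step_memory_ann(s_hi, 0L, 0.5, w)$state$q[1]
  q_lo <- step_memory_ann(s_lo, 0L, 0.5, w)$state$q[1]
  expect_gt(abs(q_hi - q_lo), 1e-6)
  expect_error(step_memory_ann(list(q = rep(0.5, 4), c = rep(0, 4),
                                    s_r = rep(0, 3), s_a = rep(0, 6)),
                               0L, 0.5, w), "hidden size")
})

test_that("the vanilla RNN step matches a hand-unrolled recurrence over 5 trials", {
  w <- init_weights("vanilla_rnn", hidden = 4, seed = 37)
  acts <- c(2L, 0L, 3L, 1L, 2L); rews <- c(0.7, 0.3, 0.9, 0.5, 0.2)
  # package path
  st <- list(s = rep(0, 4)); logits_pkg <- matrix(NA_real_, 5, 4)
  for (i in 1:5) {
    onehot <- rep(0, 4); onehot[acts[i] + 1] <- 1
    out <- step_vanilla_rnn(st, onehot, rews[i], w)
    st <- out$state; logits_pkg[i, ] <- out$logits
  }
  # independent unrolled oracle
  s <- rep(0, 4); logits_hand <- matrix(NA_real_, 5, 4)
  for (i in 1:5) {
    onehot <- rep(0, 4); onehot[acts[i] + 1] <- 1
    x <- c(onehot, rews[i], s)
    s <- tanh(drop(w$W1 %*% x) + w$b1)
    logits_hand[i, ] <- drop(w$W2 %*% s) + w$b2
  }
  expect_equal(logits_pkg, logits_hand, tolerance = 1e-12)
  # zero weights: logits pinned at the output bias
  wz <- w; wz$W1 <- wz$W1 * 0; wz$b1 <- wz$b1 * 0; wz$W2 <- wz$W2 * 0
  out <- step_vanilla_rnn(list(s = rep(0, 4)), c(1, 0, 0, 0), 0.8, wz)
  expect_equal(out$logits, wz$b2)
})

test_that("steps are pure functions and weights round-trip through JSON", {
  w <- init_weights("memory_ann", hidden = 5, seed = 43)
  st <- list(q = runif(4), c = runif(4), s_r = runif(5), s_a = runif(5))
  a <- step_memory_ann(st, 1L, 0.4, w)
  b <- step_memory_ann(st, 1L, 0.4, w)
  expect_identical(a, b)
  path <- withr::local_tempfile(fileext = ".json")
  write_weights(w, path)
  w2 <- read_weights(path)
  expect_equal(w2$W1r, w$W1r, tolerance = 1e-15)
  expect_equal(dim(w2$W2a), dim(w$W2a))
  expect_equal(w2$arch, w$arch)
  blocks <- uniform_blocks(2, n_trials = 20, seed = 3)
  expect_equal(nll_loss(w, blocks)$total, nll_loss(w2, blocks)$total,
               tolerance = 1e-12)
})
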