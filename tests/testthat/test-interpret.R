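test_that("teacher forcing a model on its own open-loop data replays its latents", {
  ag <- rl_agent(best_rl(), rl_params(alpha = 0.3, beta = 6, kappa = 0.2,
                                      f = 0.08, q_init = 0.55))
  sch <- generate_schedule(seed = 3, n_trials = 60)
  blk <- simulate_block(ag, sch, seed = 4)
  # independent record of the generating run's Q trajectory
  state <- agent_init(ag)
  q_gen <- matrix(NA_real_, 60, 4)
  for (t in 1:60) {
    q_gen[t, ] <- state$q
    state <- agent_observe(ag, state, blk$actions[t],
                           scale_rewards(blk$rewards[t]))
  }
  traj <- closed_loop_latents(ag, list(blk))[[1]]
  expect_equal(traj$q, q_gen, tolerance = 1e-12)
  # determinism
  traj2 <- closed_loop_latents(ag, list(blk))[[1]]
  expect_identical(traj, traj2)
})

test_that("closed-loop latents for neural models align with the step oracle", {
  w <- init_weights("memory_ann", hidden = 5, seed = 3)
  blocks <- sim_blocks(rl_agent(simple_rl(), rl_params(alpha = 0.3, beta = 4)),
                       2, n_trials = 30, miss_rate = 0.1, seed = 9)
  trajs <- closed_loop_latents(w, blocks)
  expect_length(trajs, 2)
  tr <- trajs[[1]]
  expect_equal(nrow(tr$s_r), 30)
  expect_equal(tr$s_r[1, ], rep(0, 5))         # zero initial memory state
  expect_equal(tr$q[1, ], rep(w$q_init, 4))
  # a missed trial carries the state forward unchanged
  miss <- which(!blocks[[1]]$valid)
  if (length(miss) > 0 && miss[1] < 30) {
    t0 <- miss[1]
    expect_equal(tr$s_r[t0 + 1, ], tr$s_r[t0, ])
    expect_equal(tr$q[t0 + 1, ], tr$q[t0, ])
  }
})

test_that("the PCA basis is orthonormal, ordered and complete", {
  w <- init_weights("memory_ann", hidden = 6, seed = 5)
  blocks <- sim_blocks(ann_agent(w), 4, n_trials = 50, seed = 15)
  trajs <- closed_loop_latents(w, blocks)
  basis <- pca_states(trajs, "reward")
  R <- basis$rotation
  expect_equal(t(R) %*% R, diag(ncol(R)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(basis$sdev) <= 1e-12))
  expect_equal(sum(basis$explained), 1, tolerance = 1e-12)
  # reconstruction with all components restores every state
  S <- do.call(rbind, lapply(trajs, `[[`, "s_r"))
  scores <- pc_scores(basis, S)
  recon <- sweep(scores %*% t(R), 2, basis$center, "+")
  expect_equal(recon, S, tolerance = 1e-10, ignore_attr = TRUE)
  # states on an exact line have one non-trivial component
  line <- outer(seq(-1, 1, length.out = 20), c(1, 2, 0.5))
  fake <- list(list(s_r = line, rewards = runif(20), valid = rep(TRUE, 20)))
  b2 <- pca_states(fake, "reward")
  expect_equal(b2$rank, 1)
})

test_that("probing Best RL recovers the delta-rule plane exactly", {
  ag <- rl_agent(best_rl(), rl_params(alpha = 0.27, beta = 5, b = 0.04,
                                      kappa = 0.1, f = 0.05, q_init = 0.5))
  pr <- probe_reward_module(ag, reward_grid = seq(0.01, 1, length.out = 21),
                            state_samples = seq(0.1, 0.9, length.out = 9))
  expect_equal(pr$q_next,
               pr$state_value + 0.27 * (pr$reward - pr$state_value) + 0.04,
               tolerance = 1e-12)
  expect_equal(nrow(pr), 21 * 9)
  expect_error(probe_reward_module(ag, reward_grid = numeric(0)), "empty")
})

test_that("probing a linear-regime network recovers its effective linear map", {
  w <- init_weights("rl_ann", hidden = 8, seed = 7)
  eps <- 1e-3  # tiny inputs keep tanh in its linear regime
  pr <- probe_reward_module(w, reward_grid = c(-eps, 0, eps),
                            state_samples = c(-eps, 0, eps))
  A <- with(list(W = w$W2r %*% diag(1 - tanh(w$b1r)^2) %*% w$W1r),
            W) # effective input weights at the operating point b1r
  base <- pr$q_next[pr$reward == 0 & pr$state_value == 0]
  slope_r <- (pr$q_next[pr$reward == eps & pr$state_value == 0] - base) / eps
  expect_equal(slope_r, A[1, 2], tolerance = 1e-4)
  slope_q <- (pr$q_next[pr$reward == 0 & pr$state_value == eps] - base) / eps
  expect_equal(slope_q, A[1, 1], tolerance = 1e-4)
})

test_that("history decoding recovers constructed memory kernels", {
  set.seed(13)
  n <- 400
  r <- runif(n)
  # states carrying only the previous reward in the first coordinate
  s_lag1 <- cbind(c(0, r[-n]), matrix(rnorm(2 * n, 0, 0.01), n, 2))
  tr1 <- list(list(s_r = s_lag1, rewards = r, valid = rep(TRUE, n)))
  basis1 <- pca_states(tr1, "reward")
  dec1 <- decode_history(tr1, basis1, max_lag = 5, n_pcs = 1)
  expect_gt(abs(dec1[1, 1]), 5 * max(abs(dec1[1, 2:5])))
  # reward-independent states decode nothing
  s_null <- matrix(rnorm(3 * n), n, 3)
  tr0 <- list(list(s_r = s_null, rewards = r, valid = rep(TRUE, n)))
  dec0 <- decode_history(tr0, pca_states(tr0, "reward"), max_lag = 5, n_pcs = 2)
  expect_lt(max(abs(dec0)), 0.08)
  # running-mean states decode slowly decaying coefficients
  trace <- numeric(n); acc <- 0.5
  for (i in 1:n) { acc <- acc + 0.15 * (r[i] - acc); trace[i] <- acc }
  s_run <- cbind(c(0.5, trace[-n]), matrix(rnorm(2 * n, 0, 0.01), n, 2))
  trm <- list(list(s_r = s_run, rewards = r, valid = rep(TRUE, n)))
  decm <- decode_history(trm, pca_states(trm, "reward"), max_lag = 8,
                         n_pcs = 1)
  expect_true(all(decm[1, 1:6] > 0))
  expect_gt(decm[1, 1], decm[1, 6])
})

test_that("priming drives lasting but decaying state effects", {
  w <- init_weights("memory_ann", hidden = 6, seed = 11)
  # identical priming and test rewards: the switch leaves no trace
  same <- prime_and_probe(w, 0.6, 10, 0.6, 10)
  unbroken <- prime_and_probe(w, 0.6, 20, 0.6, 0)
  expect_equal(same$q, unbroken$q, tolerance = 1e-12)
  hi <- prime_and_probe(w, 0.95, 15, 0.5, 30)
  lo <- prime_and_probe(w, 0.05, 15, 0.5, 30)
  gap_first <- abs(hi$q[16] - lo$q[16])
  gap_late <- abs(hi$q[45] - lo$q[45])
  expect_gt(gap_first, 1e-6)
  expect_lt(gap_late, gap_first)
  # zero-weight module is constant throughout
  wz <- w
  for (nm in c("W1r", "b1r", "W2r")) wz[[nm]] <- wz[[nm]] * 0
  flat <- prime_and_probe(wz, 0.9, 5, 0.1, 5)
  expect_equal(var(flat$q), 0)
})

test_that("PC activity injection perturbs and relaxes as a local linear system", {
  w <- init_weights("memory_ann", hidden = 6, seed = 17)
  blocks <- sim_blocks(ann_agent(w), 3, n_trials = 40, seed = 25)
  basis <- pca_states(closed_loop_latents(w, blocks), "reward")
  rseq <- rep(0.5, 30)
  z <- inject_pc_activity(w, basis, 1, 0, rseq)
  expect_equal(z$delta, rep(0, 30), tolerance = 1e-14)
  small <- 1e-4
  up <- inject_pc_activity(w, basis, 1, small, rseq, inject_at = 5)
  dn <- inject_pc_activity(w, basis, 1, -small, rseq, inject_at = 5)
  # antisymmetry up to second-order (O(magnitude^2)) curvature terms
  expect_lt(max(abs(up$delta + dn$delta)), small^2 * 10)
  expect_equal(up$delta[1:4], rep(0, 4))
  expect_gt(abs(up$delta[5]), 0)
})
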