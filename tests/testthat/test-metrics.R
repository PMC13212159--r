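test_that("stay probabilities separate repeaters from random choosers", {
  rep_blk <- raw_block(rep(2L, 30), rep(50L, 30))
  tab <- stay_vs_reward_change(list(rep_blk))
  expect_true(all(tab$stay == 1))
  set.seed(8)
  rand_blocks <- uniform_blocks(60, n_trials = 150, seed = 12)
  tab2 <- stay_vs_reward_change(rand_blocks)
  pooled <- sum(tab2$stay * tab2$n) / sum(tab2$n)
  expect_lt(abs(pooled - 0.25), 3 * sqrt(0.25 * 0.75 / sum(tab2$n)))
  expect_equal(nrow(stay_vs_reward_change(list(raw_block(c(0L, 1L, 0L),
                                                         c(10L, 20L, 30L))))),
               0)
})

test_that("repeat streaks match direct run decompositions and chance 4/3", {
  blk <- raw_block(c(0L, 0L, 0L, 0L, 1L, 1L, 1L), rep(50L, 7))
  expect_equal(repeat_streaks(list(blk))$mean_run_length, 3.5)
  blk2 <- raw_block(c(0L, 1L, 2L, 3L), rep(50L, 4))
  expect_equal(repeat_streaks(list(blk2))$mean_run_length, 1)
  # iid uniform chance level: geometric run length, mean 4/3
  blocks <- uniform_blocks(300, n_trials = 150, seed = 21)
  m <- mean(repeat_streaks(blocks)$mean_run_length)
  expect_lt(abs(m - 4 / 3), 0.02)
})

test_that("cyclic windows count overlapping permutations of the four arms", {
  expect_equal(cyclic_responses(list(raw_block(c(0L, 1L, 2L, 3L),
                                               rep(50L, 4))))$cycles, 1L)
  expect_equal(cyclic_responses(list(raw_block(rep(0L, 10),
                                               rep(50L, 10))))$cycles, 0L)
  # ABCDA contains two overlapping cycles
  expect_equal(cyclic_responses(list(raw_block(c(0L, 1L, 2L, 3L, 0L),
                                               rep(50L, 5))))$cycles, 2L)
  # iid uniform expectation: 147 * 4!/4^4
  blocks <- uniform_blocks(300, n_trials = 150, seed = 31)
  m <- mean(cyclic_responses(blocks)$cycles)
  expected <- 147 * factorial(4) / 4^4
  expect_lt(abs(m - expected), 0.5)
})

test_that("LZW compression round-trips and orders structure as expected", {
  set.seed(9)
  # randomized round-trip property over alphabets and lengths
  for (i in 1:25) {
    k <- sample(2:6, 1)
    n <- sample(1:200, 1)
    alphabet <- as.character(seq_len(k) - 1)
    x <- sample(alphabet, n, replace = TRUE)
    codes <- lzw_compress(x, alphabet)
    expect_identical(lzw_decompress(codes), x)
  }
  expect_length(lzw_compress(character(0), alphabet = as.character(0:3)), 0)
  # constant sequences compress far below their length
  const <- rep("0", 64)
  n_codes <- length(lzw_compress(const, as.character(0:3)))
  expect_lt(n_codes, 64 / 4)
  expect_identical(lzw_decompress(lzw_compress(const, as.character(0:3))),
                   const)
  # structured < random code counts, in expectation
  set.seed(10)
  rand_len <- mean(replicate(40, length(lzw_compress(
    sample(as.character(0:3), 150, replace = TRUE), as.character(0:3)))))
  ab_len <- length(lzw_compress(rep(c("0", "1"), 75), as.character(0:3)))
  const_len <- length(lzw_compress(rep("0", 150), as.character(0:3)))
  expect_lt(ab_len, rand_len)
  expect_lt(const_len, ab_len)
})

test_that("compressibility ratios sit at 1 for noise and above 1 for structure", {
  set.seed(11)
  ratios <- replicate(30, compressibility_ratio(
    sample(0:3, 150, replace = TRUE), n_random = 40,
    seed = sample.int(1e6, 1))$ratio)
  expect_lt(abs(mean(ratios) - 1), 0.03)
  r_const <- compressibility_ratio(rep(0L, 150), n_random = 40, seed = 3)
  r_alt <- compressibility_ratio(rep(c(0L, 1L), 75), n_random = 40, seed = 3)
  expect_gt(r_const$ratio, r_alt$ratio)
  expect_gt(r_alt$ratio, 1.1)
  expect_equal(r_const$b_lzw / r_const$l_lzw, r_const$ratio)
})

test_that("the lagged design has 40 columns with the stated structure", {
  blocks <- uniform_blocks(2, n_trials = 60, seed = 41)
  d <- build_lagged_design(blocks, bandit = 1, n_lags = 20)
  expect_equal(ncol(d$X), 40)
  expect_equal(sum(startsWith(colnames(d$X), "bandit_reward")), 20)
  expect_equal(sum(startsWith(colnames(d$X), "other_reward")), 20)
  expect_equal(nrow(d$X), length(d$y))
  # zero padding: first row has no history
  expect_equal(unname(d$X[1, ]), rep(0, 40))
  # a lag-1 bandit-reward entry equals the previous trial's scaled reward
  b <- blocks[[1]]
  t_idx <- which(b$actions[-60] == 1)[1] + 1L
  expect_equal(unname(d$X[t_idx, "bandit_reward_lag1"]),
               scale_rewards(b$rewards[t_idx - 1]))
})

# choices sampled from a softmax whose logits are exactly a lagged reward
# kernel over the chosen-bandit history; the regression's model class
make_kernel_blocks <- function(n_participants, blocks_per, w_kernel, seed) {
  set.seed(seed)
  out <- list()
  for (p in seq_len(n_participants)) for (bi in seq_len(blocks_per)) {
    n <- 150
    acts <- integer(n); rews <- integer(n)
    for (t in 1:n) {
      z <- numeric(4)
      for (i in seq_along(w_kernel)) {
        if (t - i >= 1)
          z[acts[t - i] + 1] <- z[acts[t - i] + 1] +
            w_kernel[i] * rews[t - i] / 100
      }
      pr <- exp(z - max(z)); pr <- pr / sum(pr)
      acts[t] <- sample.int(4, 1, prob = pr) - 1L
      rews[t] <- sample(1:100, 1)
    }
    out[[length(out) + 1]] <- session_block(sprintf("p%02d", p),
                                            sprintf("p%02d_b%d", p, bi),
                                            acts, rews)
  }
  out
}

test_that("lagged regression recovers the generating kernels", {
  # reward-blind uniform agent: all reward coefficients near zero
  blocks <- uniform_blocks(20, n_trials = 150, seed = 51)
  null_fit <- lagged_choice_regression(blocks, n_lags = 10)
  expect_lt(max(abs(null_fit$coef)), 0.35)
  expect_equal(dim(null_fit$coef), c(2, 10))
  # known geometric kernel: coefficients recover positive decaying weights
  wk <- 3 * 0.55^(0:4)
  kb <- make_kernel_blocks(10, 2, wk, seed = 5)
  fit <- lagged_choice_regression(kb, n_lags = 10)
  br <- fit$coef["bandit_reward", ]
  expect_true(all(br[1:4] > 0))
  expect_gt(br[1], br[2]); expect_gt(br[2], br[3]); expect_gt(br[3], br[4])
  expect_gt(br[1], 1.5)
  expect_lt(max(abs(br[7:10])), br[1] / 5)  # no mass beyond the true kernel
  # rewards on the unchosen side push choices away (softmax competition)
  expect_lt(fit$coef["other_reward", 1], 0)
  # a pure lag-1 repeater: the weight concentrates at lag 1
  rep_blocks <- make_kernel_blocks(8, 2, c(6), seed = 7)
  fit1 <- lagged_choice_regression(rep_blocks, n_lags = 6)
  br1 <- fit1$coef["bandit_reward", ]
  expect_gt(br1[1], 3 * max(abs(br1[2:6])))
  # Simple RL data carry a positive recent-reward signature
  ag <- rl_agent(simple_rl(), rl_params(alpha = 0.35, beta = 6))
  rl_blocks <- sim_blocks(ag, 30, seed = 61)
  fit2 <- lagged_choice_regression(rl_blocks, n_lags = 10)
  expect_gt(fit2$coef["bandit_reward", 1], 0)
})

test_that("behaviour metrics are invariant to relabelling the arms", {
  blocks <- sim_blocks(rl_agent(best_rl(),
                                rl_params(alpha = 0.3, beta = 6, kappa = 0.3)),
                       6, n_trials = 100, seed = 71)
  perm <- c(2L, 3L, 0L, 1L)
  relabel <- lapply(blocks, function(b) {
    b$actions <- perm[b$actions + 1L]
    b$schedule <- NULL
    b
  })
  expect_equal(repeat_streaks(relabel)$mean_run_length,
               repeat_streaks(blocks)$mean_run_length)
  expect_equal(cyclic_responses(relabel)$cycles, cyclic_responses(blocks)$cycles)
  expect_equal(stay_vs_reward_change(relabel), stay_vs_reward_change(blocks))
  r1 <- compressibility_ratio(blocks[[1]], n_random = 30, seed = 5)
  r2 <- compressibility_ratio(relabel[[1]], n_random = 30, seed = 5)
  expect_equal(r1$l_lzw, r2$l_lzw)
})
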