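test_that("agent parameters sample from their priors with the right support", {
  pp <- list(alpha = list(family = "point", value = 0.3),
             beta = list(family = "point", value = 5))
  a1 <- sample_agent_params(pp, seed = 1)
  a2 <- sample_agent_params(pp, seed = 99)
  expect_equal(a1$alpha, 0.3); expect_equal(a2$beta, 5)
  expect_identical(a1, a2)  # point mass: every agent identical
  # Beta prior with mean 0.3: Monte-Carlo mean over 1e4 draws
  bp <- list(alpha = list(family = "beta", shape1 = 6, shape2 = 14))
  draws <- vapply(1:10000, function(i)
    sample_agent_params(bp, seed = i)$alpha, numeric(1))
  se <- sqrt(0.3 * 0.7 / (6 + 14 + 1)) / sqrt(10000)
  expect_lt(abs(mean(draws) - 0.3), 4 * se)
  # unsupported mass is rejected
  expect_error(sample_agent_params(
    list(alpha = list(family = "normal", mean = 0.3, sd = 0.1))), "support")
  expect_error(sample_agent_params(
    list(alpha = list(family = "uniform", min = -0.5, max = 0.5))), "support")
})

test_that("open-loop simulation respects the policy and the schedule", {
  sch <- generate_schedule(seed = 5)
  # beta = 0: uniform action frequencies
  unif <- rl_agent(simple_rl(), rl_params(alpha = 0.3, beta = 0))
  blk <- simulate_block(unif, sch, seed = 2)
  expect_true(all(blk$valid))
  freqs <- tabulate(blk$actions + 1L, 4) / 150
  expect_true(all(abs(freqs - 0.25) < 0.15))
  expect_equal(blk$rewards, sch$rewards[cbind(1:150, blk$actions + 1L)])
  # determinism
  expect_identical(simulate_block(unif, sch, seed = 2)$actions, blk$actions)
  # near-greedy agent tracks its own running argmax
  greedy <- rl_agent(simple_rl(), rl_params(alpha = 0.5, beta = 400))
  gb <- simulate_block(greedy, sch, seed = 3)
  state <- agent_init(greedy); hits <- 0
  for (t in 1:150) {
    if (which.max(state$q) - 1L == gb$actions[t]) hits <- hits + 1
    state <- agent_observe(greedy, state, gb$actions[t],
                           scale_rewards(gb$rewards[t]))
  }
  expect_gt(hits / 150, 0.95) # rare early ties break differently
})

test_that("a Simple RL agent earns clearly above-chance relative reward", {
  ag <- rl_agent(simple_rl(), rl_params(alpha = 0.3, beta = 5))
  rr <- vapply(sim_blocks(ag, 30, seed = 61), relative_reward, numeric(1))
  tt <- t.test(rr, mu = 0, alternative = "greater")
  expect_lt(tt$p.value, 1e-6)
  expect_gt(mean(rr), 0.2)
})

test_that("missed trials are invalid, skipped by the agent and carried in files", {
  ag <- rl_agent(simple_rl(), rl_params(alpha = 0.3, beta = 5))
  blk <- simulate_block(ag, generate_schedule(seed = 6), miss_rate = 0.3,
                        seed = 4)
  expect_true(any(!blk$valid))
  expect_true(all(is.na(blk$actions[!blk$valid])))
  expect_true(all(!is.na(blk$actions[blk$valid])))
})

test_that("datasets have the requested shape, splits and determinism", {
  spec <- cohort_spec(n_participants = 10, blocks_per_participant = 2,
                      n_trials = 30, miss_rate = 0, seed = 9)
  ds <- build_dataset(spec)
  expect_length(ds$blocks, 20)
  expect_equal(unname(table(ds$split)[c("train", "validation", "test")]),
               c(8L, 1L, 1L), ignore_attr = TRUE)
  # splits partition participants; no participant straddles splits
  pid_split <- vapply(ds$blocks, function(b) ds$split[[b$participant_id]],
                      character(1))
  pid <- vapply(ds$blocks, `[[`, character(1), "participant_id")
  expect_true(all(tapply(pid_split, pid, function(x) length(unique(x)) == 1)))
  expect_length(dataset_blocks(ds, "train"), 16)
  expect_length(dataset_blocks(ds, "test"), 2)
  # schedules are fresh per participant-block
  sch_seeds <- vapply(ds$blocks, function(b) b$schedule$seed, integer(1))
  expect_length(unique(sch_seeds), 20)
  # same seed reproduces the dataset exactly
  ds2 <- build_dataset(spec)
  expect_identical(lapply(ds$blocks, `[`, c("actions", "rewards", "valid")),
                   lapply(ds2$blocks, `[`, c("actions", "rewards", "valid")))
  expect_error(build_dataset(cohort_spec(n_participants = 2)), "participants")
})

test_that("with zero miss rate every simulated trial is valid", {
  spec <- cohort_spec(n_participants = 4, blocks_per_participant = 1,
                      n_trials = 40, miss_rate = 0, seed = 3)
  ds <- build_dataset(spec)
  expect_true(all(vapply(ds$blocks, function(b) all(b$valid), logical(1))))
})

test_that("datasets round-trip losslessly through the directory format", {
  spec <- cohort_spec(n_participants = 5, blocks_per_participant = 2,
                      n_trials = 25, miss_rate = 0.1, seed = 14)
  ds <- build_dataset(spec)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$provenance, "external")
  expect_length(back$blocks, 10)
  expect_identical(sort(names(back$split)), sort(names(ds$split)))
  for (b in ds$blocks) {
    b2 <- Filter(function(x) x$block_id == b$block_id, back$blocks)[[1]]
    expect_identical(b2$actions, b$actions)
    expect_identical(b2$rewards, b$rewards)
    expect_identical(b2$valid, b$valid)
    expect_identical(b2$schedule$mu, b$schedule$mu)
    expect_equal(ds$split[[b$participant_id]], back$split[[b$participant_id]])
  }
})

test_that("the rich-memory teacher behaves like a learner with deep history", {
  t1 <- memory_teacher()
  st <- agent_init(t1)
  # multi-lag kernel: two different actions both leave kernel mass
  st <- agent_observe(t1, st, 0L, 0.6)
  st <- agent_observe(t1, st, 1L, 0.6)
  expect_gt(st$c[1], 0); expect_gt(st$c[2], st$c[1])
  # reward-level trace shifts the value written for the same reward
  lo <- agent_init(t1); hi <- agent_init(t1)
  for (i in 1:20) {
    lo <- agent_observe(t1, lo, 0L, 0.2)
    hi <- agent_observe(t1, hi, 0L, 0.8)
  }
  lo2 <- agent_observe(t1, lo, 0L, 0.5)
  hi2 <- agent_observe(t1, hi, 0L, 0.5)
  expect_gt(lo2$q[1], hi2$q[1])  # same reward looks better after lean times
  # sharpness ramps with time-on-task: later policies are more deterministic
  stt <- agent_init(t1)
  stt$q <- c(0.7, 0.5, 0.5, 0.5)
  early <- agent_policy(t1, stt)
  stt$t <- 149L
  late <- agent_policy(t1, stt)
  expect_gt(late[1], early[1])
  # above-chance task performance
  rr <- vapply(sim_blocks(memory_teacher(), 20, seed = 77), relative_reward,
               numeric(1))
  expect_gt(mean(rr), 0.3)
})
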