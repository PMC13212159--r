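#' Generate a restless four-armed bandit reward schedule
#'
#' Per-arm mean rewards follow a mean-reverting Gaussian random walk,
#' \eqn{\mu_{t,i} \sim N(\lambda \mu_{t-1,i} + (1-\lambda) 50, \sigma_d)},
#' initialised independently and uniformly between 1 and 100 points. The
#' reward actually shown for arm i on trial t is drawn as
#' \eqn{r_{t,i} \sim N(\mu_{t,i}, \sigma_o)}, rounded to an integer and
#' clipped to \[1, 100\]. The latent means are not clipped.
#'
#' @param lam Walk centrality \eqn{\lambda} in \[0, 1\]; the default 0.9836
#'   keeps arms slowly mean-reverting towards 50 points.
#' @param sigma_d Drift standard deviation in points (default 2.8).
#' @param sigma_o Observation standard deviation in points (default 4).
#' @param n_trials Number of trials (default 150).
#' @param n_arms Number of arms (default 4).
#' @param seed Integer seed; regeneration with the same seed is bit-identical.
#' @param mu0 Optional numeric vector of length `n_arms` overriding the
#'   uniform initialisation of the latent means (used mainly for testing
#'   degenerate walks).
#' @return An object of class `bandit_schedule`: a list with matrices `mu`
#'   and `rewards` (`n_trials` x `n_arms`, 0-based arm index corresponds to
#'   column `arm + 1`) plus the walk parameters and seed.
#' @examples
#' sch <- generate_schedule(seed = 1)
#' dim(sch$mu)
#' @export
generate_schedule <- function(lam = 0.9836, sigma_d = 2.8, sigma_o = 4,
                              n_trials = 150, n_arms = 4, seed = 1,
                              mu0 = NULL) {
  if (!is.numeric(lam) || length(lam) != 1 || lam < 0 || lam > 1)
    stop("`lam` must be a single number in [0, 1]")
  if (sigma_d < 0 || sigma_o < 0)
    stop("`sigma_d` and `sigma_o` must be non-negative")
  if (n_trials < 1 || n_arms < 1)
    stop("`n_trials` and `n_arms` must be at least 1")
  if (!is.null(mu0) && length(mu0) != n_arms)
    stop("`mu0` must have length `n_arms`")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  mu <- matrix(NA_real_, n_trials, n_arms)
  mu[1, ] <- if (is.null(mu0)) stats::runif(n_arms, 1, 100) else as.numeric(mu0)
  if (n_trials > 1) {
    for (t in 2:n_trials) {
      mu[t, ] <- stats::rnorm(n_arms, lam * mu[t - 1, ] + (1 - lam) * 50, sigma_d)
    }
  }
  rewards <- matrix(stats::rnorm(n_trials * n_arms, mu, sigma_o), n_trials, n_arms)
  rewards <- pmin(pmax(round(rewards), 1), 100)

  structure(
    list(mu = mu, rewards = rewards, lam = lam, sigma_d = sigma_d,
         sigma_o = sigma_o, n_trials = n_trials, n_arms = n_arms,
         seed = as.integer(seed)),
    class = "bandit_schedule")
}

# Save/restore the global RNG state so seeded generators do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Construct a session block
#'
#' A session block holds one participant-block of trial data: 0-based actions,
#' integer point rewards and a validity mask (missed trials are invalid and
#' carry `NA` action/reward).
#'
#' @param participant_id,block_id Identifier strings.
#' @param actions Integer vector of chosen arms in `0:(n_arms-1)`; `NA` for
#'   missed trials.
#' @param rewards Integer vector of obtained points (1-100); `NA` for missed
#'   trials.
#' @param valid Logical mask, same length; defaults to `!is.na(actions)`.
#' @param schedule Optional `bandit_schedule` the block was played on.
#' @return An object of class `session_block`.
#' @export
session_block <- function(participant_id, block_id, actions, rewards,
                          valid = !is.na(actions), schedule = NULL) {
  n <- length(actions)
  if (length(rewards) != n || length(valid) != n)
    stop("`actions`, `rewards` and `valid` must have equal length")
  if (any(valid & (is.na(actions) | is.na(rewards))))
    stop("valid trials must have non-missing action and reward")
  if (any(!is.na(actions) & (actions < 0 | actions > 3)))
    stop("actions must lie in 0..3")
  if (!is.null(schedule)) {
    if (schedule$n_trials != n)
      stop("schedule length does not match block length")
    idx <- which(valid)
    got <- schedule$rewards[cbind(idx, actions[idx] + 1L)]
    if (any(got != rewards[idx]))
      stop("valid trial rewards must equal the schedule rewards of the chosen arm")
  }
  structure(
    list(participant_id = as.character(participant_id),
         block_id = as.character(block_id),
         actions = as.integer(actions), rewards = as.integer(rewards),
         valid = as.logical(valid), n_trials = n, schedule = schedule),
    class = "session_block")
}

#' Scale point rewards to the model reward scale
#'
#' All models operate on rewards divided by 100, i.e. in \[0.01, 1\], which
#' bounds prediction errors to at most 1 in magnitude (required for the
#' Pearce-Hall variable-learning-rate rule).
#'
#' @param rewards Numeric vector of point rewards (1-100).
#' @return Rewards divided by 100.
#' @export
scale_rewards <- function(rewards) rewards / 100

#' Relative reward of a block
#'
#' Per-trial performance normalised between random choice (0) and the best
#' available arm (1): \eqn{(r_t - \mathrm{mean}(p_t)) / (\max(p_t) -
#' \mathrm{mean}(p_t))}, where \eqn{p_t} is the trial's four-arm reward
#' vector, averaged over valid trials. Trials on which all arms pay the same
#' (max equal to mean) are skipped.
#'
#' @param block A `session_block`.
#' @param schedule The `bandit_schedule` the block was played on; defaults to
#'   the one attached to the block.
#' @return Mean relative reward (scalar).
#' @export
relative_reward <- function(block, schedule = block$schedule) {
  if (is.null(schedule)) stop("a schedule is required")
  if (schedule$n_trials != block$n_trials)
    stop("schedule and block lengths differ")
  keep <- which(block$valid)
  if (length(keep) == 0) stop("relative reward is undefined without valid trials")
  p <- schedule$rewards[keep, , drop = FALSE]
  mx <- apply(p, 1, max)
  mn <- rowMeans(p)
  ok <- mx > mn
  if (!any(ok)) stop("relative reward is undefined: all trials degenerate")
  r <- block$rewards[keep]
  mean((r[ok] - mn[ok]) / (mx[ok] - mn[ok]))
}

#' Write / read a schedule as CSV
#'
#' Long format with columns `trial,arm,mu,reward`, both indices 0-based.
#' Latent means are written with 17 significant digits so a round trip is
#' lossless.
#'
#' @param schedule A `bandit_schedule`.
#' @param path File path.
#' @return `read_schedule_csv` returns a data.frame (the walk parameters are
#'   not stored in the CSV; see [write_dataset()] for full-provenance I/O).
#' @export
write_schedule_csv <- function(schedule, path) {
  df <- data.frame(
    trial = rep(seq_len(schedule$n_trials) - 1L, schedule$n_arms),
    arm = rep(seq_len(schedule$n_arms) - 1L, each = schedule$n_trials),
    mu = sprintf("%.17g", as.vector(schedule$mu)),
    reward = as.integer(as.vector(schedule$rewards)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  df <- utils::read.csv(path)
  df$mu <- as.numeric(df$mu)
  df
}
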