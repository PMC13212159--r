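#' Stay probability as a function of reward change
#'
#' Considers triplets of consecutive valid trials (t-1, t, t+1) in which
#' the same action was chosen at t-1 and t, and tabulates the probability
#' of choosing it again at t+1 ("stay") against the change in reward
#' magnitude r_t - r_{t-1} (points), binned at `bin_width`.
#'
#' @param blocks List of `session_block`s.
#' @param bin_width Bin width in points (default 10).
#' @return data.frame with `bin` (centre), `n` and `stay`.
#' @export
stay_vs_reward_change <- function(blocks, bin_width = 10) {
  ch <- numeric(0); st <- numeric(0)
  for (b in blocks) {
    a <- b$actions; r <- b$rewards; v <- b$valid
    n <- b$n_trials
    if (n < 3) next
    for (t in 2:(n - 1)) {
      if (!v[t - 1] || !v[t] || !v[t + 1]) next
      if (a[t - 1] != a[t]) next
      ch <- c(ch, r[t] - r[t - 1])
      st <- c(st, as.numeric(a[t + 1] == a[t]))
    }
  }
  if (length(ch) == 0)
    return(data.frame(bin = numeric(0), n = integer(0), stay = numeric(0)))
  bin <- round(ch / bin_width) * bin_width
  agg <- stats::aggregate(st, by = list(bin = bin),
                          FUN = function(x) c(n = length(x), stay = mean(x)))
  data.frame(bin = agg$bin, n = as.integer(agg$x[, "n"]),
             stay = agg$x[, "stay"])
}

.valid_actions <- function(block) block$actions[block$valid]

#' Mean length of repeat streaks
#'
#' Decomposes each block's (valid-trial) action sequence into maximal runs
#' of the same action -- runs of length 1 included -- and averages the run
#' length, first within blocks, then over each participant's blocks. For
#' independent uniform choice over four arms, run lengths are geometric
#' with mean 4/3 (about 1.3).
#'
#' @param blocks List of `session_block`s.
#' @return data.frame with `participant_id` and `mean_run_length`.
#' @export
repeat_streaks <- function(blocks) {
  per_block <- vapply(blocks, function(b) {
    a <- .valid_actions(b)
    if (length(a) == 0) return(NA_real_)
    mean(rle(a)$lengths)
  }, numeric(1))
  pid <- vapply(blocks, `[[`, character(1), "participant_id")
  agg <- tapply(per_block, pid, mean, na.rm = TRUE)
  data.frame(participant_id = names(agg),
             mean_run_length = as.numeric(agg), row.names = NULL)
}

#' Count cyclic response patterns
#'
#' Counts overlapping windows of four consecutive (valid) trials in which
#' each of the four actions is chosen exactly once (e.g. ABCD, BDCA). For
#' an independent uniform length-150 sequence the expected count is
#' 147 x 4!/4^4 (about 13.8).
#'
#' @param blocks List of `session_block`s.
#' @return data.frame with `participant_id`, `block_id`, `cycles`.
#' @export
cyclic_responses <- function(blocks) {
  cnt <- vapply(blocks, function(b) {
    a <- .valid_actions(b)
    n <- length(a)
    if (n < 4) return(0L)
    k <- 0L
    for (t in 1:(n - 3)) {
      w <- a[t:(t + 3)]
      if (length(unique(w)) == 4L) k <- k + 1L
    }
    k
  }, integer(1))
  data.frame(participant_id = vapply(blocks, `[[`, character(1), "participant_id"),
             block_id = vapply(blocks, `[[`, character(1), "block_id"),
             cycles = cnt)
}

#' Lempel-Ziv-Welch compression of a symbol sequence
#'
#' Standard LZW with the initial dictionary containing each single symbol
#' of the alphabet. `lzw_compress` returns the emitted code sequence (the
#' compressed "length" used throughout is the number of codes);
#' `lzw_decompress` inverts it exactly.
#'
#' @param x Vector of symbols (coerced to character).
#' @param alphabet Symbol alphabet; defaults to the sorted unique symbols
#'   of `x`. Must cover `x`.
#' @param codes Integer codes from `lzw_compress`.
#' @return `lzw_compress`: integer vector of codes with the alphabet as
#'   attribute; `lzw_decompress`: the original character vector.
#' @export
lzw_compress <- function(x, alphabet = sort(unique(as.character(x)))) {
  x <- as.character(x)
  if (length(x) == 0)
    return(structure(integer(0), alphabet = alphabet))
  if (!all(x %in% alphabet)) stop("sequence contains symbols outside the alphabet")
  dict <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(alphabet)) assign(alphabet[i], i, envir = dict)
  nxt <- length(alphabet) + 1L
  codes <- integer(0)
  wkey <- x[1]
  for (i in seq_along(x)[-1]) {
    key <- paste0(wkey, "\x1f", x[i])
    if (exists(key, envir = dict, inherits = FALSE)) {
      wkey <- key
    } else {
      codes <- c(codes, get(wkey, envir = dict, inherits = FALSE))
      assign(key, nxt, envir = dict)
      nxt <- nxt + 1L
      wkey <- x[i]
    }
  }
  codes <- c(codes, get(wkey, envir = dict, inherits = FALSE))
  structure(codes, alphabet = alphabet)
}

#' @rdname lzw_compress
#' @export
lzw_decompress <- function(codes, alphabet = attr(codes, "alphabet")) {
  if (length(codes) == 0) return(character(0))
  entries <- as.list(alphabet)
  out <- entries[[codes[1]]]
  prev <- entries[[codes[1]]]
  for (i in seq_along(codes)[-1]) {
    code <- codes[i]
    entry <- if (code <= length(entries)) {
      entries[[code]]
    } else if (code == length(entries) + 1L) {
      c(prev, prev[1]) # cScSc case: phrase defined by its own emission
    } else stop("invalid LZW code stream")
    out <- c(out, entry)
    entries[[length(entries) + 1L]] <- c(prev, entry[1])
    prev <- entry
  }
  out
}

# internal: phrases are stored as character vectors in lzw_decompress;
# lzw_compress stores keys joined with a non-symbol separator.

#' Compressibility ratio of a choice sequence
#'
#' Ratio between the mean LZW code count of `n_random` independent uniform
#' sequences of the same length and alphabet and the code count of the
#' observed sequence; values above 1 indicate temporal structure.
#'
#' @param block A `session_block` or a bare action vector.
#' @param n_random Number of random baseline sequences (default 100).
#' @param seed Seed for the baseline draws.
#' @return List of class `compressibility_result` with `l_lzw`, `b_lzw`,
#'   `ratio`, `n_random`, `seed`.
#' @export
compressibility_ratio <- function(block, n_random = 100, seed = 1) {
  a <- if (inherits(block, "session_block")) .valid_actions(block) else block
  a <- as.character(a)
  if (length(a) == 0) stop("empty sequence")
  alphabet <- as.character(0:3)
  if (!all(a %in% alphabet)) alphabet <- sort(unique(a))
  l <- length(lzw_compress(a, alphabet))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  b <- mean(vapply(seq_len(n_random), function(i) {
    length(lzw_compress(sample(alphabet, length(a), replace = TRUE), alphabet))
  }, numeric(1)))
  structure(list(l_lzw = l, b_lzw = b, ratio = b / l,
                 n_random = n_random, seed = seed),
            class = "compressibility_result")
}

#' Design matrix for the lagged choice regression
#'
#' For one target bandit: 20 "bandit-reward" columns (the scaled reward at
#' lag i where the target bandit was chosen, 0 otherwise) and 20
#' "other-reward" columns (the scaled reward at lag i where another bandit
#' was chosen), i = 1..`n_lags`; pre-block lags are zero-padded and missed
#' past trials contribute 0. Rows with a missed target trial are dropped.
#'
#' @param blocks List of `session_block`s (rows are stacked over blocks).
#' @param bandit Target bandit (0-based).
#' @param n_lags Number of lags (default 20).
#' @return List with `X` (n x 2*n_lags matrix) and `y` (0/1 target).
#' @export
build_lagged_design <- function(blocks, bandit, n_lags = 20) {
  Xs <- list(); ys <- list()
  for (b in blocks) {
    n <- b$n_trials
    r <- scale_rewards(b$rewards); r[!b$valid] <- 0
    a <- b$actions
    own <- ifelse(b$valid & a == bandit, r, 0)
    oth <- ifelse(b$valid & a != bandit, r, 0)
    X <- matrix(0, n, 2 * n_lags)
    for (i in seq_len(n_lags)) {
      if (i < n) {
        X[(i + 1):n, i] <- own[1:(n - i)]
        X[(i + 1):n, n_lags + i] <- oth[1:(n - i)]
      }
    }
    keep <- b$valid
    Xs[[length(Xs) + 1]] <- X[keep, , drop = FALSE]
    ys[[length(ys) + 1]] <- as.numeric(a[keep] == bandit)
  }
  X <- do.call(rbind, Xs)
  colnames(X) <- c(paste0("bandit_reward_lag", seq_len(n_lags)),
                   paste0("other_reward_lag", seq_len(n_lags)))
  list(X = X, y = unlist(ys))
}

#' Lagged logistic regression of choices on past rewards
#'
#' Fits, per participant and per bandit, a ridge-penalised logistic
#' regression of the bandit's choice indicator on the 40 lagged reward
#' regressors (see [build_lagged_design()]), then averages coefficients
#' over the four per-bandit models and over participants. The small ridge
#' penalty guards against perfect separation.
#'
#' @param blocks List of `session_block`s.
#' @param n_lags Number of lags (default 20).
#' @param lambda Ridge penalty passed to glmnet (default 1e-3).
#' @return Object of class `lagged_regression`: list with `coef` (2 x
#'   n_lags matrix, rows `bandit_reward` / `other_reward`, mean over
#'   participants), `per_participant` (participants x 2*n_lags matrix) and
#'   `n_lags`.
#' @export
lagged_choice_regression <- function(blocks, n_lags = 20, lambda = 1e-3) {
  pid <- vapply(blocks, `[[`, character(1), "participant_id")
  groups <- split(blocks, pid)
  rows <- lapply(groups, function(bl) {
    cf <- matrix(NA_real_, 4, 2 * n_lags)
    for (k in 0:3) {
      d <- build_lagged_design(bl, k, n_lags)
      # a bandit this participant (almost) never or always chose carries no
      # usable contrast; glmnet refuses classes with < 2 observations
      if (length(unique(d$y)) < 2 || min(table(d$y)) < 2) next
      # rare-class warnings are expected for seldom-chosen bandits; the
      # ridge penalty is what keeps those fits stable
      fit <- suppressWarnings(
        glmnet::glmnet(d$X, d$y, family = "binomial", alpha = 0,
                       lambda = lambda, standardize = FALSE))
      cf[k + 1, ] <- as.numeric(fit$beta)
    }
    colMeans(cf, na.rm = TRUE)
  })
  per <- do.call(rbind, rows)
  colnames(per) <- c(paste0("bandit_reward_lag", seq_len(n_lags)),
                     paste0("other_reward_lag", seq_len(n_lags)))
  co <- rbind(bandit_reward = colMeans(per[, seq_len(n_lags), drop = FALSE],
                                       na.rm = TRUE),
              other_reward = colMeans(per[, n_lags + seq_len(n_lags),
                                          drop = FALSE], na.rm = TRUE))
  colnames(co) <- paste0("lag", seq_len(n_lags))
  structure(list(coef = co, per_participant = per, n_lags = n_lags),
            class = "lagged_regression")
}
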