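#' Pack session blocks into trial-by-block matrices
#'
#' All fitting kernels consume a trials x blocks integer action matrix
#' (0-based arms, -1 for missed trials) and a matching matrix of scaled
#' rewards. Blocks must share the same trial count.
#'
#' @param blocks A list of `session_block` objects.
#' @return List with `actions`, `rewards` (scaled), `n_valid` per block and
#'   the block/participant ids.
#' @export
blocks_to_matrices <- function(blocks) {
  stopifnot(length(blocks) > 0)
  n_trials <- unique(vapply(blocks, function(b) b$n_trials, integer(1)))
  if (length(n_trials) != 1) stop("all blocks must have the same trial count")
  A <- vapply(blocks, function(b) {
    a <- b$actions; a[!b$valid | is.na(a)] <- -1L; as.integer(a)
  }, integer(n_trials))
  R <- vapply(blocks, function(b) {
    r <- scale_rewards(b$rewards); r[!b$valid | is.na(r)] <- 0; as.numeric(r)
  }, numeric(n_trials))
  A <- matrix(A, nrow = n_trials); R <- matrix(R, nrow = n_trials)
  list(actions = A, rewards = R,
       n_valid = colSums(A >= 0),
       participant_id = vapply(blocks, `[[`, character(1), "participant_id"),
       block_id = vapply(blocks, `[[`, character(1), "block_id"))
}

.tabular_cpp_params <- function(variant, params) {
  list(alpha = params$alpha, beta = params$beta, b = params$b,
       kappa = params$kappa, f = params$f, q_init = params$q_init,
       alpha_init = params$alpha_init, w = params$w,
       variable_lr = variant$variable_lr,
       perseveration = variant$perseveration,
       forgetting = switch(variant$forgetting, off = 0L, unchosen = 1L, all = 2L))
}

.arch_code <- function(arch) {
  switch(arch, rl_ann = 0L, context_ann = 1L, memory_ann = 2L,
         stop("unknown architecture"))
}

.ann_cpp_eval <- function(weights, mats, want_grad = FALSE) {
  if (weights$arch == "vanilla_rnn") {
    cpp_rnn_nll_grad(weights, mats$actions, mats$rewards, want_grad)
  } else {
    cpp_modular_nll_grad(weights, mats$actions, mats$rewards,
                         .arch_code(weights$arch), want_grad)
  }
}

#' Negative log-likelihood of observed choices under a model
#'
#' \eqn{L = -\sum_{blocks}\sum_{valid\,trials} \log p(a_t)}, where the
#' choice probabilities come from the model's softmax policy conditioned on
#' the block's history up to each trial. Missed trials are masked from the
#' loss and from all state updates.
#'
#' @param model An `rl_agent`, an `ann_weights` or an `ann_agent`.
#' @param blocks List of `session_block`s, or a pre-packed matrix set from
#'   [blocks_to_matrices()].
#' @return List with `total`, `per_block` and `n_valid` (valid-trial count
#'   per block).
#' @export
nll_loss <- function(model, blocks) {
  mats <- if (is.list(blocks) && !is.null(blocks$actions)) blocks
          else blocks_to_matrices(blocks)
  if (inherits(model, "ann_agent")) model <- model$weights
  res <- if (inherits(model, "rl_agent")) {
    cpp_tabular_nll(mats$actions, mats$rewards,
                    .tabular_cpp_params(model$variant, model$params))
  } else if (inherits(model, "ann_weights")) {
    .ann_cpp_eval(model, mats, want_grad = FALSE)
  } else stop("unsupported model type")
  if (any(!is.finite(res$per_block))) {
    bad <- which(!is.finite(res$per_block))[1]
    stop(sprintf("non-finite likelihood in block %d", bad))
  }
  list(total = res$total, per_block = as.numeric(res$per_block),
       n_valid = mats$n_valid)
}

#' Trial-wise prediction accuracy from a loss
#'
#' The geometric-mean probability assigned to the observed choices,
#' expressed as a percentage: \eqn{100 \exp(-L/n)}. A uniform policy over
#' four arms gives exactly 25.
#'
#' @param L Total negative log-likelihood.
#' @param n_trials_total Number of (valid) trials the loss sums over.
#' @return Accuracy in percent.
#' @export
accuracy_from_loss <- function(L, n_trials_total) {
  if (any(n_trials_total < 1)) stop("`n_trials_total` must be at least 1")
  100 * exp(-L / n_trials_total)
}

#' Training configuration
#'
#' Desk-scale defaults; the full-scale preset
#' (`training_config(full_scale = TRUE)`) records the original study
#' protocol's sweep centre (batch 32, hidden 32, up to 1e6 steps) without
#' making it a default.
#'
#' @param step_size Adam step size.
#' @param weight_decay Decoupled L2 weight decay on the weight matrices.
#' @param batch_size Blocks per training batch (sampled with replacement).
#' @param max_steps Number of optimizer steps.
#' @param hidden Hidden units per module (neural models only).
#' @param seed Integer seed for initialisation and batch sampling.
#' @param eval_every Validation-loss evaluation period (steps).
#' @param n_starts Multi-start count for tabular quasi-Newton fits.
#' @param full_scale Use the full-scale preset instead of desk defaults.
#' @return A `training_config` list.
#' @export
training_config <- function(step_size = 1e-3, weight_decay = 1e-4,
                            batch_size = 16, max_steps = 3000, hidden = 12,
                            seed = 1, eval_every = 100, n_starts = 5,
                            full_scale = FALSE) {
  if (full_scale) {
    step_size <- 1e-3; weight_decay <- 1e-4; batch_size <- 32
    max_steps <- 1e6; hidden <- 32; eval_every <- 1e4
  }
  stopifnot(step_size > 0, weight_decay >= 0, batch_size >= 1,
            max_steps >= 1, hidden >= 1, eval_every >= 1)
  structure(list(step_size = step_size, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_steps = as.integer(max_steps),
                 hidden = as.integer(hidden), seed = as.integer(seed),
                 eval_every = as.integer(eval_every),
                 n_starts = as.integer(n_starts)),
            class = "training_config")
}

#' Fit a tabular Q-learning variant by maximum likelihood
#'
#' Minimises the choice negative log-likelihood over the variant's raw
#' (unconstrained) parameters with multi-start L-BFGS-B; parameters are
#' pushed through [transform_params()] inside the objective so constraints
#' hold by construction.
#'
#' @param variant A `variant_spec`.
#' @param blocks Training blocks (list or packed matrices).
#' @param n_starts Number of random restarts.
#' @param seed Seed for the restart draws.
#' @return List with `params` (`rl_params`), `raw`, `nll` (training loss)
#'   and the `variant`.
#' @export
fit_rl_variant <- function(variant, blocks, n_starts = 5, seed = 1) {
  mats <- if (is.list(blocks) && !is.null(blocks$actions)) blocks
          else blocks_to_matrices(blocks)
  nm <- free_params(variant)
  centre <- vapply(nm, function(p) switch(p,
    alpha = .logit(0.3), alpha_init = .logit(0.3), beta = .softplus_inv(5),
    b = 0, kappa = 0, f = .logit(0.1), q_init = 0.5, w = .logit(0.2)),
    numeric(1))
  obj <- function(raw) {
    p <- transform_params(raw, variant)
    cpp_tabular_nll(mats$actions, mats$rewards,
                    .tabular_cpp_params(variant, p))$total
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- if (s == 1) centre else centre + stats::rnorm(length(centre), 0, 1)
    fit <- tryCatch(
      stats::optim(start, obj, method = "L-BFGS-B",
                   control = list(maxit = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimisation starts failed")
  list(params = transform_params(best$par, variant), raw = best$par,
       nll = best$value, variant = variant)
}

# One Adam step with decoupled weight decay on the weight matrices.
.adam_step <- function(wts, grads, mstate, vstate, step, cfg, decayed) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  corr1 <- 1 - b1^step; corr2 <- 1 - b2^step
  for (nm in names(grads)) {
    g <- grads[[nm]]
    mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g
    vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g * g
    upd <- (mstate[[nm]] / corr1) / (sqrt(vstate[[nm]] / corr2) + eps)
    wts[[nm]] <- wts[[nm]] - cfg$step_size * upd
    if (nm %in% decayed)
      wts[[nm]] <- wts[[nm]] - cfg$step_size * cfg$weight_decay * wts[[nm]]
  }
  list(w = wts, m = mstate, v = vstate)
}

.trainable_names <- function(weights) {
  setdiff(names(unclass(weights)), c("arch", "hidden", "n_arms", "seed"))
}

#' Train a neural architecture by stochastic gradient behavioural cloning
#'
#' Adam over the summed negative log-likelihood of training batches sampled
#' with replacement, with decoupled L2 weight decay on the weight matrices
#' and checkpoint selection by validation loss (the returned weights are
#' the best-on-validation checkpoint, mirroring "number of training steps"
#' selection).
#'
#' @param arch Architecture tag (see [init_weights()]).
#' @param train_blocks,val_blocks Training and validation blocks.
#' @param config A [training_config()].
#' @return A `fit_result`: list with `weights` (best checkpoint), `model`
#'   (alias), `val_curve` (data.frame step/val_nll), `config`, `train_nll`
#'   of the final batch and `seed`.
#' @export
train_ann <- function(arch, train_blocks, val_blocks, config = training_config()) {
  tr <- if (!is.null(train_blocks$actions)) train_blocks else blocks_to_matrices(train_blocks)
  va <- if (!is.null(val_blocks$actions)) val_blocks else blocks_to_matrices(val_blocks)
  n_train <- ncol(tr$actions)
  if (config$batch_size > n_train)
    stop("batch size exceeds the number of training blocks")

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  init_seed <- sample.int(2^31 - 1, 1)
  w <- init_weights(arch, hidden = config$hidden, seed = init_seed)
  tn <- .trainable_names(w)
  decayed <- intersect(tn, c("W1r", "W2r", "W1a", "W2a", "W1", "W2"))
  zero_like <- lapply(unclass(w)[tn], function(x) x * 0)
  mstate <- zero_like; vstate <- zero_like

  best_val <- Inf; best_w <- w
  curve_step <- integer(0); curve_val <- numeric(0)
  last_nll <- NA_real_
  for (step in seq_len(config$max_steps)) {
    idx <- sample.int(n_train, config$batch_size, replace = TRUE)
    batch <- list(actions = tr$actions[, idx, drop = FALSE],
                  rewards = tr$rewards[, idx, drop = FALSE])
    res <- .ann_cpp_eval(w, batch, want_grad = TRUE)
    if (!is.finite(res$total))
      stop(sprintf("training diverged (non-finite loss) at step %d", step))
    last_nll <- res$total
    upd <- .adam_step(unclass(w)[tn], res$grads, mstate, vstate, step, config,
                      decayed)
    for (nm in tn) w[[nm]] <- upd$w[[nm]]
    mstate <- upd$m; vstate <- upd$v
    if (step %% config$eval_every == 0 || step == config$max_steps) {
      vl <- .ann_cpp_eval(w, va, want_grad = FALSE)$total
      curve_step <- c(curve_step, step); curve_val <- c(curve_val, vl)
      if (vl < best_val) { best_val <- vl; best_w <- w }
    }
  }
  structure(list(weights = best_w, model = best_w, kind = "ann", arch = arch,
                 val_nll = best_val,
                 val_curve = data.frame(step = curve_step, val_nll = curve_val),
                 train_nll = last_nll, config = config, seed = config$seed),
            class = "fit_result")
}

#' Unified training entry point
#'
#' Dispatches to [fit_rl_variant()] for tabular specifications and to
#' [train_ann()] for neural ones, always returning a `fit_result` whose
#' `model` evaluates through [nll_loss()].
#'
#' @param spec Either a `variant_spec` or an architecture tag string.
#' @param dataset A `bandit_dataset` (see [build_dataset()]), or a list with
#'   `train` and `validation` block lists.
#' @param config A [training_config()].
#' @return A `fit_result`.
#' @export
train <- function(spec, dataset, config = training_config()) {
  tr <- dataset_blocks(dataset, "train")
  va <- dataset_blocks(dataset, "validation")
  if (inherits(spec, "variant_spec")) {
    fit <- fit_rl_variant(spec, tr, n_starts = config$n_starts,
                          seed = config$seed)
    model <- rl_agent(spec, fit$params)
    val <- nll_loss(model, va)
    structure(list(weights = NULL, model = model, kind = "tabular",
                   arch = spec$name, params = fit$params, raw = fit$raw,
                   train_nll = fit$nll, val_nll = val$total,
                   val_curve = data.frame(step = 1L, val_nll = val$total),
                   config = config, seed = config$seed),
              class = "fit_result")
  } else {
    train_ann(spec, tr, va, config)
  }
}

#' Hyperparameter sweep
#'
#' Trains `k` replicate fits (distinct seeds) per grid cell and returns the
#' cell and replicate with the lowest validation loss.
#'
#' @param spec Model specification as in [train()].
#' @param dataset A `bandit_dataset`.
#' @param grid List of [training_config()]s.
#' @param k Replicates per cell.
#' @return List with `best_config`, `best_fit` and a `table` of validation
#'   losses per cell/replicate.
#' @export
sweep_hyperparams <- function(spec, dataset, grid, k = 2) {
  if (length(grid) == 0) stop("empty hyperparameter grid")
  rows <- list(); best <- NULL; best_cfg <- NULL
  for (ci in seq_along(grid)) {
    for (rep in seq_len(k)) {
      cfg <- grid[[ci]]
      cfg$seed <- cfg$seed + (rep - 1L) * 1000L
      fit <- tryCatch(train(spec, dataset, cfg), error = function(e) NULL)
      vl <- if (is.null(fit)) Inf else fit$val_nll
      rows[[length(rows) + 1]] <- data.frame(cell = ci, rep = rep, val_nll = vl)
      if (is.finite(vl) && (is.null(best) || vl < best$val_nll)) {
        best <- fit; best_cfg <- cfg
      }
    }
  }
  if (is.null(best)) stop("all sweep cells diverged")
  list(best_config = best_cfg, best_fit = best, table = do.call(rbind, rows))
}

#' Evaluate fitted models on shared held-out blocks and compare them
#'
#' Computes per-block test loss and trial-wise accuracy for every fit, plus
#' all pairwise paired t-tests on per-block accuracies (mean difference,
#' 95% CI, t, df, p).
#'
#' @param fits Named list of `fit_result`s (or bare models).
#' @param test_blocks Blocks shared by all models.
#' @return List with `per_block` (long data.frame), `summary` (mean
#'   loss/accuracy per model) and `pairwise` (paired comparisons).
#' @export
evaluate_and_compare <- function(fits, test_blocks) {
  mats <- if (!is.null(test_blocks$actions)) test_blocks else blocks_to_matrices(test_blocks)
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("model", seq_along(fits))
  per <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    model <- if (inherits(f, "fit_result")) f$model else f
    ll <- nll_loss(model, mats)
    data.frame(model = nm, block = seq_along(ll$per_block),
               nll = ll$per_block, n_valid = ll$n_valid,
               accuracy = accuracy_from_loss(ll$per_block, ll$n_valid))
  })
  per <- do.call(rbind, per)
  summ <- do.call(rbind, lapply(split(per, per$model), function(d)
    data.frame(model = d$model[1], mean_nll = mean(d$nll),
               mean_accuracy = mean(d$accuracy),
               se_accuracy = stats::sd(d$accuracy) / sqrt(nrow(d)))))
  nms <- names(fits)
  pw <- list()
  if (length(nms) >= 2) {
    for (i in seq_len(length(nms) - 1)) for (j in seq(i + 1, length(nms))) {
      a <- per$accuracy[per$model == nms[i]]
      b <- per$accuracy[per$model == nms[j]]
      if (length(a) != length(b)) stop("block sets differ across models")
      if (stats::sd(a - b) == 0) {
        tt <- list(statistic = c(t = 0), parameter = c(df = length(a) - 1),
                   p.value = 1, conf.int = c(0, 0), estimate = 0)
      } else tt <- stats::t.test(a, b, paired = TRUE)
      pw[[length(pw) + 1]] <- data.frame(
        model_a = nms[i], model_b = nms[j],
        mean_diff = mean(a - b), ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
        t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value)
    }
  }
  list(per_block = per, summary = summ,
       pairwise = if (length(pw)) do.call(rbind, pw) else NULL)
}
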