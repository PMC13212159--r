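#' Resolve a model specification string
#'
#' `"simple_rl"`, `"best_rl"` and `"variant:<name>"` map to tabular
#' variants; `"rl_ann"`, `"context_ann"`, `"memory_ann"`, `"vanilla_rnn"`
#' stay architecture tags.
#'
#' @param name Specification string.
#' @return A `variant_spec` or an architecture tag.
#' @export
resolve_model_spec <- function(name) {
  if (name == "simple_rl") return(simple_rl())
  if (name == "best_rl") return(best_rl())
  if (startsWith(name, "variant:")) {
    vn <- sub("^variant:", "", name)
    vs <- enumerate_variants()
    if (is.null(vs[[vn]])) stop(sprintf("unknown variant '%s'", vn))
    return(vs[[vn]])
  }
  if (name %in% c("rl_ann", "context_ann", "memory_ann", "vanilla_rnn"))
    return(name)
  stop(sprintf("unknown model '%s'", name))
}

# FNV-1a hash of a serialized object; stamps outputs with their provenance.
# Arithmetic stays in doubles (exact below 2^53); the xor only touches the
# low byte, where the input bytes live.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

#' Experiment configuration
#'
#' @param cohort A [cohort_spec()].
#' @param models Character vector of model names (see
#'   [resolve_model_spec()]).
#' @param training A [training_config()] shared by all models, or a named
#'   list of per-model configs.
#' @param metrics Behavioural metrics to run on test data and open-loop
#'   simulations (subset of `"stay"`, `"streaks"`, `"cycles"`, `"lzw"`,
#'   `"lagreg"`).
#' @param inspect Run the Memory-ANN inspection battery if a Memory-ANN was
#'   fitted?
#' @param seed Global seed.
#' @param out_dir Output directory (NULL to skip writing).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(cohort = cohort_spec(),
                              models = c("simple_rl", "best_rl"),
                              training = training_config(),
                              metrics = c("stay", "streaks", "cycles", "lzw"),
                              inspect = FALSE, seed = 1, out_dir = NULL) {
  structure(list(cohort = cohort, models = models, training = training,
                 metrics = metrics, inspect = inspect,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

.metrics_battery <- function(blocks, metrics, seed = 1) {
  out <- list()
  if ("stay" %in% metrics) out$stay <- stay_vs_reward_change(blocks)
  if ("streaks" %in% metrics) out$streaks <- repeat_streaks(blocks)
  if ("cycles" %in% metrics) out$cycles <- cyclic_responses(blocks)
  if ("lzw" %in% metrics) {
    ratios <- vapply(seq_along(blocks), function(i)
      compressibility_ratio(blocks[[i]], n_random = 50,
                            seed = seed + i)$ratio, numeric(1))
    out$lzw <- data.frame(
      block_id = vapply(blocks, `[[`, character(1), "block_id"),
      ratio = ratios)
  }
  if ("lagreg" %in% metrics) out$lagreg <- lagged_choice_regression(blocks)
  out
}

.fit_to_agent <- function(fit) {
  if (fit$kind == "tabular") fit$model else ann_agent(fit$weights)
}

#' Run a full simulate / fit / compare / analyse experiment
#'
#' Builds the synthetic cohort, fits every requested model on the training
#' split (validation-checkpointed for neural models), evaluates all fits
#' on the shared test split, runs the behavioural battery on the test data
#' and on open-loop simulations from each fitted model (same schedules),
#' and optionally runs the Memory-ANN inspection battery. All stage
#' outputs carry the config hash and seed; tables are written as CSV and
#' the report as JSON when `out_dir` is set.
#'
#' @param config An [experiment_config()].
#' @return List with `dataset`, `fits`, `comparison`, `behaviour` (per
#'   source), `inspection` (or NULL), `hash`, `timing`.
#' @export
run_experiment <- function(config) {
  t0 <- Sys.time()
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  timing <- c()
  stage <- function(nm, expr) {
    s <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", nm, conditionMessage(e))))
    timing[[nm]] <<- as.numeric(difftime(Sys.time(), s, units = "secs"))
    out
  }

  dataset <- stage("simulate", build_dataset(config$cohort))
  test_blocks <- dataset_blocks(dataset, "test")

  fits <- stage("fit", {
    out <- list()
    for (m in config$models) {
      cfg <- if (inherits(config$training, "training_config")) config$training
             else config$training[[m]]
      cfg$seed <- cfg$seed + config$seed
      out[[m]] <- train(resolve_model_spec(m), dataset, cfg)
    }
    out
  })

  comparison <- stage("evaluate", evaluate_and_compare(fits, test_blocks))

  behaviour <- stage("analyze", {
    out <- list(data = .metrics_battery(test_blocks, config$metrics,
                                        config$seed))
    for (m in names(fits)) {
      agent <- .fit_to_agent(fits[[m]])
      sim <- lapply(seq_along(test_blocks), function(i)
        simulate_block(agent, test_blocks[[i]]$schedule,
                       miss_rate = 0, seed = config$seed + 7000L + i,
                       participant_id = test_blocks[[i]]$participant_id,
                       block_id = test_blocks[[i]]$block_id))
      out[[m]] <- .metrics_battery(sim, config$metrics, config$seed + 500L)
    }
    out
  })

  inspection <- NULL
  if (isTRUE(config$inspect) && "memory_ann" %in% names(fits)) {
    inspection <- stage("inspect", {
      w <- fits$memory_ann$weights
      traj <- closed_loop_latents(w, test_blocks)
      basis <- pca_states(traj, "reward")
      list(basis = basis,
           probe = probe_reward_module(w, state_samples =
             sample_states_along_pc(basis, 1)),
           decode = decode_history(traj, basis, max_lag = 10))
    })
  }

  result <- list(dataset = dataset, fits = fits, comparison = comparison,
                 behaviour = behaviour, inspection = inspection,
                 hash = hash, seed = config$seed, timing = timing,
                 elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_dataset(dataset, file.path(config$out_dir, "dataset"))
    utils::write.csv(cbind(hash = hash, comparison$per_block),
                     file.path(config$out_dir, "per_block.csv"),
                     row.names = FALSE)
    utils::write.csv(cbind(hash = hash, comparison$summary),
                     file.path(config$out_dir, "summary.csv"),
                     row.names = FALSE)
    if (!is.null(comparison$pairwise))
      utils::write.csv(cbind(hash = hash, comparison$pairwise),
                       file.path(config$out_dir, "pairwise.csv"),
                       row.names = FALSE)
    report <- list(hash = hash, seed = config$seed, models = config$models,
                   timing = as.list(timing),
                   summary = comparison$summary)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
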