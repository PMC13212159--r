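#' Constrained Q-learning parameters
#'
#' Container for the tabular model family's parameters, each constrained to
#' its interpretable range: learning rates `alpha`/`alpha_init` and the
#' Pearce-Hall weighting `w` in (0,1), forgetting `f` in \[0,1\], update bias
#' `b` and perseveration `kappa` in (-1,1), inverse temperature `beta` in
#' (0, Inf), initial value `q_init` unrestricted (on the \[0.01, 1\] scaled
#' reward scale, mid-scale 0.5 by default).
#'
#' @param alpha Learning rate.
#' @param beta Inverse decision temperature.
#' @param b Update bias (default 0).
#' @param kappa Perseveration strength (default 0; negative values express
#'   switching).
#' @param f Forgetting rate (default 0).
#' @param q_init Initial action value (default 0.5, mid scale).
#' @param alpha_init Initial learning rate for variable-learning-rate
#'   variants (default `alpha`).
#' @param w Pearce-Hall weighting parameter (default 0; at 0 the learning
#'   rate is constant and the model nests the fixed-alpha variants).
#' @return An object of class `rl_params`.
#' @export
rl_params <- function(alpha = 0.3, beta = 5, b = 0, kappa = 0, f = 0,
                      q_init = 0.5, alpha_init = alpha, w = 0) {
  chk <- function(x, lo, hi, nm, lo_open = TRUE, hi_open = TRUE) {
    bad <- if (lo_open) x <= lo else x < lo
    bad <- bad || (if (hi_open) x >= hi else x > hi)
    if (!is.finite(x) || bad) stop(sprintf("`%s` = %g outside its range", nm, x))
  }
  chk(alpha, 0, 1, "alpha"); chk(alpha_init, 0, 1, "alpha_init")
  chk(beta, 0, Inf, "beta", lo_open = FALSE) # beta = 0 is the uniform policy
  chk(b, -1, 1, "b"); chk(kappa, -1, 1, "kappa")
  chk(f, 0, 1, "f", lo_open = FALSE, hi_open = FALSE)
  chk(w, 0, 1, "w", lo_open = FALSE)
  if (!is.finite(q_init)) stop("`q_init` must be finite")
  structure(list(alpha = alpha, beta = beta, b = b, kappa = kappa, f = f,
                 q_init = q_init, alpha_init = alpha_init, w = w),
            class = "rl_params")
}

# parameter -> transform map (raw real line -> constrained range)
.param_transforms <- c(
  alpha = "sigmoid", alpha_init = "sigmoid", f = "sigmoid", w = "sigmoid",
  b = "tanh", kappa = "tanh", beta = "softplus", q_init = "identity")

.sigmoid <- function(x) 1 / (1 + exp(-x))
.logit <- function(p) log(p / (1 - p))
.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
.softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(y)))

.apply_transform <- function(x, kind) {
  switch(kind,
         sigmoid = .sigmoid(x), tanh = tanh(x), softplus = .softplus(x),
         identity = x, stop("unknown transform"))
}
.apply_inverse <- function(y, kind) {
  switch(kind,
         sigmoid = .logit(y), tanh = atanh(y), softplus = .softplus_inv(y),
         identity = y, stop("unknown transform"))
}

#' Variant specification for the Q-learning model family
#'
#' Flags marking which mechanisms are active. The forgetting mechanism has
#' three settings (`"off"`, `"unchosen"`, `"all"`): decay of unchosen action
#' values only, or of all values (the chosen arm decaying before its update).
#'
#' @param bias Include the update bias `b`?
#' @param perseveration Include the choice kernel `kappa`?
#' @param forgetting One of `"off"`, `"unchosen"`, `"all"`.
#' @param free_q_init Fit the initial value `q_init` (otherwise fixed at 0.5)?
#' @param variable_lr Use the Pearce-Hall variable learning rate
#'   (`alpha_init`, `w` replace `alpha`)?
#' @param name Optional variant name; derived from the flags if omitted.
#' @return An object of class `variant_spec`.
#' @export
variant_spec <- function(bias = FALSE, perseveration = FALSE,
                         forgetting = c("off", "unchosen", "all"),
                         free_q_init = FALSE, variable_lr = FALSE,
                         name = NULL) {
  forgetting <- match.arg(forgetting)
  if (is.null(name)) {
    bits <- c(if (bias) "b", if (perseveration) "kappa",
              if (forgetting != "off") paste0("f.", forgetting),
              if (free_q_init) "qinit", if (variable_lr) "varlr")
    name <- if (length(bits)) paste0("rl+", paste(bits, collapse = "+")) else "simple_rl"
    if (bias && perseveration && forgetting == "unchosen" && free_q_init &&
        !variable_lr) name <- "best_rl"
  }
  structure(list(name = name, bias = bias, perseveration = perseveration,
                 forgetting = forgetting, free_q_init = free_q_init,
                 variable_lr = variable_lr),
            class = "variant_spec")
}

#' Free parameters of a variant, in canonical order
#'
#' @param variant A `variant_spec`.
#' @return Character vector of free parameter names.
#' @export
free_params <- function(variant) {
  c(if (variant$variable_lr) c("alpha_init", "w") else "alpha",
    "beta",
    if (variant$bias) "b",
    if (variant$perseveration) "kappa",
    if (variant$forgetting != "off") "f",
    if (variant$free_q_init) "q_init")
}

#' Simple RL and Best RL shortcuts
#'
#' Simple RL frees only `alpha` and `beta`; Best RL adds bias, perseveration,
#' forgetting of unchosen values and a free initial value, for six free
#' parameters.
#' @return A `variant_spec`.
#' @export
simple_rl <- function() variant_spec()

#' @rdname simple_rl
#' @export
best_rl <- function() variant_spec(bias = TRUE, perseveration = TRUE,
                                   forgetting = "unchosen",
                                   free_q_init = TRUE)

#' Map a raw parameter vector to constrained parameters
#'
#' Sigmoid maps for `alpha`, `alpha_init`, `f`, `w`; tanh for `b`, `kappa`;
#' softplus (a smooth strictly monotone map onto (0, Inf), keeping gradients
#' informative near zero) for `beta`; identity for `q_init`. Inactive
#' mechanisms are pinned at their neutral values (`b = kappa = f = w = 0`,
#' `q_init = 0.5`).
#'
#' @param raw Numeric vector whose length equals the variant's free-parameter
#'   count, ordered as [free_params()].
#' @param variant A `variant_spec`.
#' @return An `rl_params` object.
#' @seealso [inverse_transform_params()]
#' @export
transform_params <- function(raw, variant) {
  nm <- free_params(variant)
  if (length(raw) != length(nm))
    stop(sprintf("raw vector has length %d but variant '%s' has %d free parameters",
                 length(raw), variant$name, length(nm)))
  vals <- list(alpha = 0.3, beta = 1, b = 0, kappa = 0, f = 0, q_init = 0.5,
               alpha_init = 0.3, w = 0)
  for (i in seq_along(nm)) {
    vals[[nm[i]]] <- .apply_transform(raw[i], .param_transforms[[nm[i]]])
  }
  if (!variant$variable_lr) vals$alpha_init <- vals$alpha
  if (variant$variable_lr) vals$alpha <- vals$alpha_init
  do.call(rl_params, vals)
}

#' Recover the raw vector from constrained parameters
#'
#' Exact inverse of [transform_params()] on the variant's free parameters.
#'
#' @param params An `rl_params` object.
#' @param variant A `variant_spec`.
#' @return Numeric raw vector.
#' @export
inverse_transform_params <- function(params, variant) {
  nm <- free_params(variant)
  vapply(nm, function(p) .apply_inverse(params[[p]], .param_transforms[[p]]),
         numeric(1))
}

#' Enumerate the default Q-learning variant grid
#'
#' The full combinatorial family: bias x perseveration x variable learning
#' rate x free initial value x forgetting (off / decay of unchosen values /
#' decay of all values), i.e. 2 x 2 x 2 x 2 x 3 = 48 variants, containing
#' Simple RL (two free parameters) and Best RL (six free parameters).
#'
#' @return A list of 48 `variant_spec` objects, named by variant name.
#' @export
enumerate_variants <- function() {
  out <- list()
  for (fg in c("off", "unchosen", "all"))
    for (vl in c(FALSE, TRUE))
      for (qi in c(FALSE, TRUE))
        for (pv in c(FALSE, TRUE))
          for (bs in c(FALSE, TRUE)) {
            v <- variant_spec(bias = bs, perseveration = pv, forgetting = fg,
                              free_q_init = qi, variable_lr = vl)
            out[[v$name]] <- v
          }
  out
}
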