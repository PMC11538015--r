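# Minimal dense-network machinery used by the classifier, selector and the
# autoencoder backends. Parameters live in flat named lists of matrices /
# vectors; gradients mirror the names, which lets the optimizer update an
# arbitrary subset (needed for branch freezing).

relu <- function(x) {
  x * (x > 0)
}

sigmoid_mat <- function(x) {
  # plogis is numerically stable for large |x|
  matrix(stats::plogis(x), nrow = nrow(x), ncol = ncol(x))
}

# Glorot-uniform weight matrix
glorot <- function(d_in, d_out) {
  limit <- sqrt(6 / (d_in + d_out))
  matrix(stats::runif(d_in * d_out, -limit, limit), d_in, d_out)
}

# mean binary cross-entropy of probabilities p against targets y in [0,1]
bce_loss <- function(p, y, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# d(bce)/dp, same averaging
bce_grad <- function(p, y, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  (-(y / p) + (1 - y) / (1 - p)) / length(p)
}

adam_init <- function() {
  list(m = list(), v = list(), t = 0L)
}

# One Adam step on the parameters named in `grads`; untouched names keep both
# their values and their optimizer state, so freezing a branch is simply not
# passing its gradients.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Deterministic fingerprint of a numeric parameter subset (used to assert
# bit-identity of frozen branches): full-precision position-weighted sums.
param_hash <- function(params, names = NULL) {
  if (is.null(names)) names <- base::names(params)
  vals <- unlist(lapply(params[names], as.numeric), use.names = FALSE)
  paste(format(sum(vals), digits = 22),
        format(sum(vals^2), digits = 22),
        format(sum(vals * seq_along(vals)), digits = 22),
        length(vals))
}
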