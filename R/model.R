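# The dual network: a Classifier (one projection MLP per feature matrix plus
# a shared two-layer prediction head, trained with the asymmetric loss) and a
# Selector (a two-layer surrogate MLP mapping a feature-matrix mask to the
# Classifier's validation loss, whose input gradients rank matrix importance).

#' Asymmetric-loss configuration
#'
#' Focusing parameters of the asymmetric focal loss for imbalanced
#' multi-label classification: `gamma_pos` down-weights easy positives,
#' `gamma_neg` down-weights easy negatives. The defaults (0 and 2) follow
#' common practice for GO prediction. `eps` clips probabilities before logs.
#'
#' @param gamma_pos,gamma_neg Non-negative focusing exponents.
#' @param eps Clipping constant, `0 < eps < 0.5`.
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(gamma_pos = 0, gamma_neg = 2, eps = 1e-7) {
  stopifnot(gamma_pos >= 0, gamma_neg >= 0, eps > 0, eps < 0.5)
  structure(list(gamma_pos = gamma_pos, gamma_neg = gamma_neg, eps = eps),
            class = "loss_config")
}

#' Asymmetric loss (ASL) for multi-label scores
#'
#' Mean over all (protein, term) entries of
#' `-y (1-p)^gamma_pos log(p) - (1-y) p^gamma_neg log(1-p)`.
#' With both focusing parameters 0 this is exactly mean binary
#' cross-entropy. Probabilities are clipped to `[eps, 1-eps]` first.
#'
#' @param p Score matrix with entries in `(0, 1)`.
#' @param y Binary label matrix of the same shape.
#' @param cfg A [loss_config()].
#' @return Non-negative scalar loss.
#' @export
#' @examples
#' asl_loss(matrix(0.5), matrix(1), loss_config(0, 0))  # -log(0.5)
asl_loss <- function(p, y, cfg = loss_config()) {
  stopifnot(inherits(cfg, "loss_config"))
  if (!all(dim(p) == dim(y))) stop("score and label matrices differ in shape")
  p <- pmin(pmax(p, cfg$eps), 1 - cfg$eps)
  lpos <- if (cfg$gamma_pos == 0) -log(p) else -(1 - p)^cfg$gamma_pos * log(p)
  lneg <- if (cfg$gamma_neg == 0) -log(1 - p) else -p^cfg$gamma_neg * log(1 - p)
  mean(y * lpos + (1 - y) * lneg)
}

# d(asl)/dp including the 1/(N*K) averaging; used by the classifier backward
asl_grad <- function(p, y, cfg) {
  p <- pmin(pmax(p, cfg$eps), 1 - cfg$eps)
  gp <- cfg$gamma_pos; gn <- cfg$gamma_neg
  dpos <- if (gp == 0) -1 / p else gp * (1 - p)^(gp - 1) * log(p) - (1 - p)^gp / p
  dneg <- if (gn == 0) 1 / (1 - p) else
    -gn * p^(gn - 1) * log(1 - p) + p^gn / (1 - p)
  (y * dpos + (1 - y) * dneg) / length(p)
}

#' Initialize Classifier parameters
#'
#' One single-layer ReLU projection per feature matrix (mapping each `d_f` to
#' the common width `d_c`) plus a two-layer prediction head (`d_c` -> `d_c`
#' -> `K`). The head's output activation is per-term logistic by default so
#' each GO term gets an independent probability, with a softmax option.
#'
#' @param d_fs Integer vector of input widths, one per feature matrix.
#' @param K Number of GO terms.
#' @param d_c Common branch output width (also the head's hidden width).
#' @param seed RNG seed for the Glorot initialization.
#' @param output `"sigmoid"` (default) or `"softmax"` head activation.
#' @return An object of class `classifier` holding parameters and the Adam
#'   state.
#' @export
classifier_init <- function(d_fs, K, d_c = 64, seed = 1,
                            output = c("sigmoid", "softmax")) {
  output <- match.arg(output)
  set.seed(seed)
  p <- list()
  for (j in seq_along(d_fs)) {
    p[[paste0("branch", j, ".W")]] <- glorot(d_fs[j], d_c)
    p[[paste0("branch", j, ".b")]] <- rep(0, d_c)
  }
  p$head.W1 <- glorot(d_c, d_c)
  p$head.b1 <- rep(0, d_c)
  p$head.W2 <- glorot(d_c, K)
  p$head.b2 <- rep(0, K)
  structure(list(params = p, opt = adam_init(), n_branch = length(d_fs),
                 d_c = d_c, K = K, output = output),
            class = "classifier")
}

branch_names <- function(j) paste0("branch", j, ".", c("W", "b"))
head_names <- c("head.W1", "head.b1", "head.W2", "head.b2")

classifier_forward_cache <- function(model, mats, mask) {
  sel <- which(mask == 1)
  if (length(sel) == 0) stop("all-zero mask: at least one matrix must be selected")
  p <- model$params
  n <- nrow(mats[[sel[1]]])
  H <- matrix(0, n, model$d_c)
  Z <- list()
  for (j in sel) {
    Zj <- sweep(mats[[j]] %*% p[[paste0("branch", j, ".W")]], 2,
                p[[paste0("branch", j, ".b")]], "+")
    Z[[as.character(j)]] <- Zj
    H <- H + relu(Zj)
  }
  H <- H / length(sel)
  Z1 <- sweep(H %*% p$head.W1, 2, p$head.b1, "+")
  A1 <- relu(Z1)
  Z2 <- sweep(A1 %*% p$head.W2, 2, p$head.b2, "+")
  P <- if (model$output == "softmax") {
    e <- exp(Z2 - apply(Z2, 1, max))
    e / rowSums(e)
  } else {
    sigmoid_mat(Z2)
  }
  list(P = P, H = H, Z = Z, Z1 = Z1, A1 = A1, Z2 = Z2, sel = sel)
}

#' Classifier forward pass
#'
#' Runs the selected feature matrices through their projection branches,
#' averages the branch outputs (unweighted mean), and applies the prediction
#' head. The output depends only on matrices with mask bit 1.
#'
#' @param space A [feature_space()] (or plain list of matrices).
#' @param mask Binary vector of length `length(space)` with at least one 1.
#' @param model A [classifier_init()] object.
#' @param rows Optional integer row subset (e.g. the training split).
#' @return n x K score matrix with entries in `[0, 1]`.
#' @export
classifier_forward <- function(space, mask, model, rows = NULL) {
  mats <- space_matrices(space, rows)
  check_mask(mask, length(mats))
  classifier_forward_cache(model, mats, mask)$P
}

space_matrices <- function(space, rows = NULL) {
  mats <- if (inherits(space, "feature_space")) space$matrices else space
  if (!is.null(rows)) mats <- lapply(mats, function(m) m[rows, , drop = FALSE])
  mats
}

check_mask <- function(mask, m) {
  if (length(mask) != m) {
    stop("mask has length ", length(mask), "; feature space has ", m, " matrices")
  }
  if (!all(mask %in% c(0, 1))) stop("mask entries must be 0 or 1")
  invisible(TRUE)
}

#' One Classifier training step
#'
#' Full-batch forward on the given rows, asymmetric-loss gradient, and one
#' Adam update of the selected branches and the prediction head. Unselected
#' branches receive no gradient and keep their parameters and optimizer
#' state untouched.
#'
#' @inheritParams classifier_forward
#' @param y Binary label matrix aligned with `rows`.
#' @param loss_cfg A [loss_config()].
#' @param lr Adam learning rate.
#' @param weight_decay L2 penalty on the updated parameters.
#' @return List with the updated `model` and the pre-update training `loss`.
#' @export
classifier_train_step <- function(space, mask, model, y, rows = NULL,
                                  loss_cfg = loss_config(), lr = 1e-3,
                                  weight_decay = 0) {
  mats <- space_matrices(space, rows)
  check_mask(mask, length(mats))
  fw <- classifier_forward_cache(model, mats, mask)
  loss <- asl_loss(fw$P, y, loss_cfg)
  dP <- asl_grad(fw$P, y, loss_cfg)
  if (model$output == "softmax") {
    # dZ2 = P * (dP - rowSums(dP * P))
    dZ2 <- fw$P * (dP - rowSums(dP * fw$P))
  } else {
    dZ2 <- dP * fw$P * (1 - fw$P)
  }
  p <- model$params
  g <- list()
  g$head.W2 <- t(fw$A1) %*% dZ2
  g$head.b2 <- colSums(dZ2)
  dA1 <- dZ2 %*% t(p$head.W2)
  dZ1 <- dA1 * (fw$Z1 > 0)
  g$head.W1 <- t(fw$H) %*% dZ1
  g$head.b1 <- colSums(dZ1)
  dH <- dZ1 %*% t(p$head.W1)
  k <- length(fw$sel)
  for (j in fw$sel) {
    dZj <- (dH / k) * (fw$Z[[as.character(j)]] > 0)
    g[[paste0("branch", j, ".W")]] <- t(mats[[j]]) %*% dZj
    g[[paste0("branch", j, ".b")]] <- colSums(dZj)
  }
  st <- adam_step(p, g, model$opt, lr, weight_decay = weight_decay)
  model$params <- st$params
  model$opt <- st$state
  list(model = model, loss = loss)
}

#' Initialize Selector parameters
#'
#' A two-layer MLP (smooth tanh hidden layer, linear scalar output) from an
#' `m`-length mask vector to a predicted Classifier validation loss. The
#' hidden activation is tanh rather than a rectifier because the Selector's
#' purpose is gradient-based importance scoring at an off-data probe point:
#' a smooth, everywhere-active hidden layer gives probe gradients that track
#' the fitted surface's global slopes instead of a ReLU activation pattern.
#'
#' @param m Length of the mask (number of feature matrices).
#' @param d_hidden Hidden width.
#' @param seed RNG seed.
#' @param activation `"tanh"` (default) or `"relu"`.
#' @return An object of class `selector`.
#' @export
selector_init <- function(m, d_hidden = 32, seed = 1,
                          activation = c("tanh", "relu")) {
  activation <- match.arg(activation)
  set.seed(seed)
  p <- list(W1 = glorot(m, d_hidden), b1 = rep(0, d_hidden),
            W2 = glorot(d_hidden, 1), b2 = 0)
  structure(list(params = p, opt = adam_init(), m = m, d_hidden = d_hidden,
                 activation = activation),
            class = "selector")
}

sel_act <- function(z, activation) {
  if (activation == "tanh") tanh(z) else relu(z)
}

# derivative of the hidden activation given pre-activation z
sel_act_grad <- function(z, activation) {
  if (activation == "tanh") 1 - tanh(z)^2 else (z > 0) * 1
}

#' Selector forward pass
#'
#' @param x Real vector of length `m` (a binary mask during training; the
#'   all-0.5 probe during importance scoring).
#' @param model A [selector_init()] object.
#' @return A single finite scalar: the predicted validation loss.
#' @export
selector_forward <- function(x, model) {
  stopifnot(inherits(model, "selector"))
  if (length(x) != model$m) {
    stop("input has length ", length(x), "; selector expects ", model$m)
  }
  if (!all(is.finite(x))) stop("selector input must be finite")
  p <- model$params
  h <- sel_act(as.numeric(x %*% p$W1) + p$b1, model$activation)
  as.numeric(h %*% p$W2) + p$b2
}

#' One Selector fitting step
#'
#' Single Adam step on the squared error between the predicted and observed
#' Classifier validation loss.
#'
#' @param mask Binary mask the Classifier was evaluated with.
#' @param true_loss Observed validation loss (finite scalar).
#' @param model A [selector_init()] object.
#' @param lr Adam learning rate.
#' @return List with the updated `model` and `mse`, the pre-step squared
#'   error.
#' @export
selector_fit_step <- function(mask, true_loss, model, lr = 1e-2) {
  stopifnot(is.finite(true_loss))
  p <- model$params
  x <- as.numeric(mask)
  z1 <- as.numeric(x %*% p$W1) + p$b1
  h <- sel_act(z1, model$activation)
  pred <- as.numeric(h %*% p$W2) + p$b2
  resid <- pred - true_loss
  mse <- resid^2
  dout <- 2 * resid
  g <- list(W2 = matrix(h * dout, ncol = 1), b2 = dout)
  dh <- as.numeric(p$W2) * dout
  dz1 <- dh * sel_act_grad(z1, model$activation)
  g$W1 <- outer(x, dz1)
  g$b1 <- dz1
  st <- adam_step(p, g, model$opt, lr)
  model$params <- st$params
  model$opt <- st$state
  list(model = model, mse = mse)
}

#' Refit the Selector on a batch of recorded (mask, loss) pairs
#'
#' Takes `steps` full-batch Adam steps on the mean squared error over the
#' supplied pairs, with weight decay. The training loop calls this every
#' epoch on a sliding window of the most recent record entries, so the
#' surrogate converges on the mask -> validation-loss landscape of the
#' current (near-stationary) Classifier instead of chasing single samples;
#' the weight decay keeps the fitted surface smooth enough for its input
#' gradients to reflect marginal matrix effects rather than interpolation
#' wiggles.
#'
#' @param model A [selector_init()] object.
#' @param masks Matrix of masks (rows) or list of mask vectors.
#' @param losses Numeric vector of observed validation losses.
#' @param lr Adam learning rate.
#' @param weight_decay L2 penalty coefficient.
#' @param steps Number of full-batch gradient steps.
#' @return List with the updated `model` and `mse`, the pre-update mean
#'   squared error over the batch.
#' @export
selector_update <- function(model, masks, losses, lr = 1e-3,
                            weight_decay = 1e-2, steps = 20) {
  stopifnot(inherits(model, "selector"))
  X <- if (is.list(masks)) do.call(rbind, masks) else as.matrix(masks)
  if (ncol(X) != model$m) stop("mask width must equal the selector input size")
  stopifnot(nrow(X) == length(losses), all(is.finite(losses)))
  p <- model$params
  opt <- model$opt
  mse0 <- NULL
  for (it in seq_len(steps)) {
    Z1 <- sweep(X %*% p$W1, 2, p$b1, "+")
    H <- sel_act(Z1, model$activation)
    pred <- as.numeric(H %*% p$W2) + p$b2
    if (is.null(mse0)) mse0 <- mean((pred - losses)^2)
    dout <- 2 * (pred - losses) / length(losses)
    g <- list(W2 = t(H) %*% matrix(dout), b2 = sum(dout))
    dZ1 <- (matrix(dout) %*% t(p$W2)) * sel_act_grad(Z1, model$activation)
    g$W1 <- t(X) %*% dZ1
    g$b1 <- colSums(dZ1)
    st <- adam_step(p, g, opt, lr, weight_decay = weight_decay)
    p <- st$params
    opt <- st$state
  }
  model$params <- p
  model$opt <- opt
  list(model = model, mse = if (is.null(mse0)) NA_real_ else mse0)
}

#' Gradient-based feature-matrix importance
#'
#' Absolute gradient of the Selector's output with respect to each element
#' of a probe input (default: the all-0.5 vector, giving every matrix an
#' equal starting chance). Larger values mean the predicted validation loss
#' is more sensitive to that matrix's inclusion.
#'
#' @param model A [selector_init()] object (typically after Stage-1
#'   training).
#' @param probe Real probe vector, defaults to `rep(0.5, m)`.
#' @return Non-negative numeric vector of length `m`.
#' @export
gradient_importance <- function(model, probe = NULL) {
  stopifnot(inherits(model, "selector"))
  if (is.null(probe)) probe <- rep(0.5, model$m)
  if (length(probe) != model$m) stop("probe length must equal the mask length")
  p <- model$params
  z1 <- as.numeric(probe %*% p$W1) + p$b1
  act <- sel_act_grad(z1, model$activation)
  grad <- as.numeric(p$W1 %*% (act * as.numeric(p$W2)))
  abs(grad)
}
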