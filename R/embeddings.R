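# Graph-embedding backends turning each evidence network (plus the protein
# attribute matrix) into a per-protein feature matrix, and the ordered
# feature matrix space consumed by the classifier/selector pair.

#' Min-max normalize a matrix to [0, 1]
#'
#' Global (whole-matrix) normalization `(x - min) / (max - min)`. A constant
#' matrix maps to all zeros, preserving "no signal" without dividing by zero.
#'
#' @param x Numeric matrix with finite entries.
#' @return Matrix of the same shape with range within `[0, 1]`.
#' @export
#' @examples
#' minmax_normalize(matrix(c(0, 2, 4, 8), 2, 2))
minmax_normalize <- function(x) {
  stopifnot(is.matrix(x), all(is.finite(x)))
  rng <- range(x)
  if (rng[1] == rng[2]) {
    return(matrix(0, nrow(x), ncol(x), dimnames = dimnames(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Autoencoder configuration
#'
#' Settings shared by the MLP and transformer autoencoder backends. The
#' transformer uses `layers` attention layers for the encoder and the same
#' number for the decoder, with `heads` attention heads at internal width
#' `d_hidden` (so `heads` must divide `d_hidden`).
#'
#' @param d_hidden Latent (bottleneck) dimension, >= 1.
#' @param layers Encoder depth (= decoder depth) for the transformer backend.
#' @param heads Attention-head count; must divide `d_hidden`.
#' @param epochs Full-batch training epochs.
#' @param lr Adam learning rate.
#' @param seed RNG seed; embeddings are bit-reproducible given the seed.
#' @return An object of class `ae_config`.
#' @export
ae_config <- function(d_hidden = 64, layers = 2, heads = 4, epochs = 200,
                      lr = 1e-3, seed = 1) {
  stopifnot(d_hidden >= 1, layers >= 1, heads >= 1, epochs >= 0, lr > 0)
  if (d_hidden %% heads != 0) {
    stop("heads (", heads, ") must divide d_hidden (", d_hidden, ")")
  }
  structure(list(d_hidden = as.integer(d_hidden), layers = as.integer(layers),
                 heads = as.integer(heads), epochs = as.integer(epochs),
                 lr = lr, seed = as.integer(seed)),
            class = "ae_config")
}

#' Raw-adjacency features (no embedding)
#'
#' The NoEmbed backend: each protein's feature vector is its (normalized)
#' adjacency row, so `d_f = n`.
#'
#' @param net An [evidence_network()] whose adjacency is already normalized.
#' @return Numeric n x n feature matrix.
#' @export
embed_noembed <- function(net) {
  stopifnot(inherits(net, "evidence_network"))
  net$adjacency
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V` with the softmax taken over rows of the
#' score matrix. `d_k` is the key dimension `ncol(K)`.
#'
#' @param Q,K,V Numeric matrices; `Q` is t_q x d_k, `K` is t_k x d_k,
#'   `V` is t_k x d_v.
#' @return t_q x d_v matrix of attention outputs.
#' @export
scaled_dot_attention <- function(Q, K, V) {
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  s <- Q %*% t(K) / sqrt(ncol(K))
  s <- s - apply(s, 1, max)
  e <- exp(s)
  a <- e / rowSums(e)
  a %*% V
}

# ---- 2-token multi-head self-attention layer (network token, attribute
# token per protein), with residual connection. Forward returns a cache for
# the hand-derived backward pass. ----

attn2_forward <- function(X1, X2, Wq, Wk, Wv, Wo, heads) {
  d <- ncol(X1)
  dk <- d %/% heads
  scale <- 1 / sqrt(dk)
  Q1 <- X1 %*% Wq; Q2 <- X2 %*% Wq
  K1 <- X1 %*% Wk; K2 <- X2 %*% Wk
  V1 <- X1 %*% Wv; V2 <- X2 %*% Wv
  O1 <- matrix(0, nrow(X1), d)
  O2 <- matrix(0, nrow(X1), d)
  A <- vector("list", heads)
  for (h in seq_len(heads)) {
    cl <- ((h - 1) * dk + 1):(h * dk)
    s11 <- rowSums(Q1[, cl, drop = FALSE] * K1[, cl, drop = FALSE]) * scale
    s12 <- rowSums(Q1[, cl, drop = FALSE] * K2[, cl, drop = FALSE]) * scale
    s21 <- rowSums(Q2[, cl, drop = FALSE] * K1[, cl, drop = FALSE]) * scale
    s22 <- rowSums(Q2[, cl, drop = FALSE] * K2[, cl, drop = FALSE]) * scale
    m1 <- pmax(s11, s12); e11 <- exp(s11 - m1); e12 <- exp(s12 - m1)
    a11 <- e11 / (e11 + e12); a12 <- 1 - a11
    m2 <- pmax(s21, s22); e21 <- exp(s21 - m2); e22 <- exp(s22 - m2)
    a21 <- e21 / (e21 + e22); a22 <- 1 - a21
    O1[, cl] <- a11 * V1[, cl, drop = FALSE] + a12 * V2[, cl, drop = FALSE]
    O2[, cl] <- a21 * V1[, cl, drop = FALSE] + a22 * V2[, cl, drop = FALSE]
    A[[h]] <- list(a11 = a11, a12 = a12, a21 = a21, a22 = a22)
  }
  Y1 <- X1 + O1 %*% Wo
  Y2 <- X2 + O2 %*% Wo
  list(Y1 = Y1, Y2 = Y2,
       cache = list(X1 = X1, X2 = X2, Q1 = Q1, Q2 = Q2, K1 = K1, K2 = K2,
                    V1 = V1, V2 = V2, O1 = O1, O2 = O2, A = A,
                    heads = heads, dk = dk, scale = scale))
}

attn2_backward <- function(dY1, dY2, cache, Wq, Wk, Wv, Wo) {
  ch <- cache
  d <- ncol(ch$X1)
  heads <- ch$heads; dk <- ch$dk; scale <- ch$scale
  dO1 <- dY1 %*% t(Wo)
  dO2 <- dY2 %*% t(Wo)
  dWo <- t(ch$O1) %*% dY1 + t(ch$O2) %*% dY2
  dQ1 <- matrix(0, nrow(dY1), d); dQ2 <- dQ1
  dK1 <- dQ1; dK2 <- dQ1; dV1 <- dQ1; dV2 <- dQ1
  for (h in seq_len(heads)) {
    cl <- ((h - 1) * dk + 1):(h * dk)
    a <- ch$A[[h]]
    dO1h <- dO1[, cl, drop = FALSE]; dO2h <- dO2[, cl, drop = FALSE]
    V1h <- ch$V1[, cl, drop = FALSE]; V2h <- ch$V2[, cl, drop = FALSE]
    dV1[, cl] <- a$a11 * dO1h + a$a21 * dO2h
    dV2[, cl] <- a$a12 * dO1h + a$a22 * dO2h
    da11 <- rowSums(dO1h * V1h); da12 <- rowSums(dO1h * V2h)
    da21 <- rowSums(dO2h * V1h); da22 <- rowSums(dO2h * V2h)
    # softmax Jacobian over the 2-element rows
    dot1 <- a$a11 * da11 + a$a12 * da12
    ds11 <- a$a11 * (da11 - dot1); ds12 <- a$a12 * (da12 - dot1)
    dot2 <- a$a21 * da21 + a$a22 * da22
    ds21 <- a$a21 * (da21 - dot2); ds22 <- a$a22 * (da22 - dot2)
    Q1h <- ch$Q1[, cl, drop = FALSE]; Q2h <- ch$Q2[, cl, drop = FALSE]
    K1h <- ch$K1[, cl, drop = FALSE]; K2h <- ch$K2[, cl, drop = FALSE]
    dQ1[, cl] <- (ds11 * K1h + ds12 * K2h) * scale
    dQ2[, cl] <- (ds21 * K1h + ds22 * K2h) * scale
    dK1[, cl] <- (ds11 * Q1h + ds21 * Q2h) * scale
    dK2[, cl] <- (ds12 * Q1h + ds22 * Q2h) * scale
  }
  dWq <- t(ch$X1) %*% dQ1 + t(ch$X2) %*% dQ2
  dWk <- t(ch$X1) %*% dK1 + t(ch$X2) %*% dK2
  dWv <- t(ch$X1) %*% dV1 + t(ch$X2) %*% dV2
  dX1 <- dY1 + dQ1 %*% t(Wq) + dK1 %*% t(Wk) + dV1 %*% t(Wv)
  dX2 <- dY2 + dQ2 %*% t(Wq) + dK2 %*% t(Wk) + dV2 %*% t(Wv)
  list(dX1 = dX1, dX2 = dX2, dWq = dWq, dWk = dWk, dWv = dWv, dWo = dWo)
}

transformer_ae_init <- function(n_in, d_attr, cfg) {
  d <- cfg$d_hidden
  p <- list(
    Win_net = glorot(n_in, d), bin_net = rep(0, d),
    Win_attr = glorot(d_attr, d), bin_attr = rep(0, d),
    Wout_net = glorot(d, n_in), bout_net = rep(0, n_in),
    Wout_attr = glorot(d, d_attr), bout_attr = rep(0, d_attr))
  for (side in c("enc", "dec")) {
    for (l in seq_len(cfg$layers)) {
      for (w in c("Wq", "Wk", "Wv", "Wo")) {
        p[[paste0(side, l, ".", w)]] <- glorot(d, d)
      }
    }
  }
  p
}

transformer_ae_forward <- function(p, A, attrs, cfg) {
  X1 <- sweep(A %*% p$Win_net, 2, p$bin_net, "+")
  X2 <- sweep(attrs %*% p$Win_attr, 2, p$bin_attr, "+")
  caches <- list()
  for (side in c("enc", "dec")) {
    for (l in seq_len(cfg$layers)) {
      key <- paste0(side, l)
      out <- attn2_forward(X1, X2, p[[paste0(key, ".Wq")]],
                           p[[paste0(key, ".Wk")]], p[[paste0(key, ".Wv")]],
                           p[[paste0(key, ".Wo")]], cfg$heads)
      caches[[key]] <- out$cache
      X1 <- out$Y1; X2 <- out$Y2
      if (side == "enc" && l == cfg$layers) {
        hidden_net <- X1  # network-side hidden state = the embedding
      }
    }
  }
  Z1 <- sweep(X1 %*% p$Wout_net, 2, p$bout_net, "+")
  Z2 <- sweep(X2 %*% p$Wout_attr, 2, p$bout_attr, "+")
  R1 <- sigmoid_mat(Z1)
  R2 <- sigmoid_mat(Z2)
  list(R1 = R1, R2 = R2, hidden_net = hidden_net,
       Xd1 = X1, Xd2 = X2, caches = caches)
}

#' Transformer autoencoder embedding of one evidence network
#'
#' Fuses a protein's (normalized) adjacency row and its attribute row as a
#' two-token sequence: both are projected to a common width `d_hidden`, pass
#' through `layers` multi-head self-attention encoder layers (scaled
#' dot-product attention with residual connections), then through the same
#' number of decoder layers, and both inputs are reconstructed under binary
#' cross-entropy. Only the network-side hidden state after the encoder is
#' returned as the embedding; the attribute-side state is discarded.
#'
#' @param adjacency Normalized (entries in `[0, 1]`) symmetric n x n matrix.
#' @param attributes Filtered binary/`[0,1]` attribute matrix, n x d_a.
#' @param cfg An [ae_config()].
#' @return n x `d_hidden` embedding matrix with attribute `loss_trace`
#'   (per-epoch reconstruction loss, element 1 being the untrained loss).
#' @export
train_transformer_autoencoder <- function(adjacency, attributes, cfg = ae_config()) {
  stopifnot(inherits(cfg, "ae_config"), is.matrix(adjacency),
            is.matrix(attributes), nrow(adjacency) == nrow(attributes))
  if (min(adjacency) < 0 || max(adjacency) > 1 ||
      min(attributes) < 0 || max(attributes) > 1) {
    stop("transformer autoencoder inputs must lie in [0, 1] (normalize first)")
  }
  set.seed(cfg$seed)
  p <- transformer_ae_init(ncol(adjacency), ncol(attributes), cfg)
  opt <- adam_init()
  trace <- numeric(cfg$epochs + 1)
  fwd <- transformer_ae_forward(p, adjacency, attributes, cfg)
  trace[1] <- bce_loss(fwd$R1, adjacency) + bce_loss(fwd$R2, attributes)
  for (ep in seq_len(cfg$epochs)) {
    g <- list()
    dZ1 <- bce_grad(fwd$R1, adjacency) * fwd$R1 * (1 - fwd$R1)
    dZ2 <- bce_grad(fwd$R2, attributes) * fwd$R2 * (1 - fwd$R2)
    g$Wout_net <- t(fwd$Xd1) %*% dZ1
    g$bout_net <- colSums(dZ1)
    g$Wout_attr <- t(fwd$Xd2) %*% dZ2
    g$bout_attr <- colSums(dZ2)
    dX1 <- dZ1 %*% t(p$Wout_net)
    dX2 <- dZ2 %*% t(p$Wout_attr)
    for (side in c("dec", "enc")) {
      for (l in rev(seq_len(cfg$layers))) {
        key <- paste0(side, l)
        bk <- attn2_backward(dX1, dX2, fwd$caches[[key]],
                             p[[paste0(key, ".Wq")]], p[[paste0(key, ".Wk")]],
                             p[[paste0(key, ".Wv")]], p[[paste0(key, ".Wo")]])
        g[[paste0(key, ".Wq")]] <- bk$dWq
        g[[paste0(key, ".Wk")]] <- bk$dWk
        g[[paste0(key, ".Wv")]] <- bk$dWv
        g[[paste0(key, ".Wo")]] <- bk$dWo
        dX1 <- bk$dX1; dX2 <- bk$dX2
      }
    }
    g$Win_net <- t(adjacency) %*% dX1
    g$bin_net <- colSums(dX1)
    g$Win_attr <- t(attributes) %*% dX2
    g$bin_attr <- colSums(dX2)
    st <- adam_step(p, g, opt, cfg$lr)
    p <- st$params; opt <- st$state
    fwd <- transformer_ae_forward(p, adjacency, attributes, cfg)
    trace[ep + 1] <- bce_loss(fwd$R1, adjacency) + bce_loss(fwd$R2, attributes)
  }
  out <- fwd$hidden_net
  rownames(out) <- rownames(adjacency)
  attr(out, "loss_trace") <- trace
  out
}

#' MLP autoencoder embedding
#'
#' A plain two-layer autoencoder: tanh bottleneck of width `d_hidden`,
#' sigmoid reconstruction, binary cross-entropy loss (inputs must lie in
#' `[0, 1]`). Returns the bottleneck activations.
#'
#' @param x n x d input matrix (rows are per-protein inputs, entries in
#'   `[0, 1]`).
#' @param cfg An [ae_config()] (only `d_hidden`, `epochs`, `lr`, `seed`
#'   apply).
#' @return n x `d_hidden` matrix with attribute `loss_trace`.
#' @export
train_mlp_autoencoder <- function(x, cfg = ae_config()) {
  stopifnot(inherits(cfg, "ae_config"), is.matrix(x))
  if (min(x) < 0 || max(x) > 1) {
    stop("autoencoder inputs must lie in [0, 1] (normalize first)")
  }
  if (cfg$d_hidden >= ncol(x)) {
    warning("d_hidden (", cfg$d_hidden, ") >= input dimension (", ncol(x),
            "); the bottleneck does not compress")
  }
  set.seed(cfg$seed)
  p <- list(We = glorot(ncol(x), cfg$d_hidden), be = rep(0, cfg$d_hidden),
            Wd = glorot(cfg$d_hidden, ncol(x)), bd = rep(0, ncol(x)))
  opt <- adam_init()
  trace <- numeric(cfg$epochs + 1)
  fwd <- function(p) {
    H <- tanh(sweep(x %*% p$We, 2, p$be, "+"))
    R <- sigmoid_mat(sweep(H %*% p$Wd, 2, p$bd, "+"))
    list(H = H, R = R)
  }
  f <- fwd(p)
  trace[1] <- bce_loss(f$R, x)
  for (ep in seq_len(cfg$epochs)) {
    dZ2 <- bce_grad(f$R, x) * f$R * (1 - f$R)
    dH <- dZ2 %*% t(p$Wd)
    dZ1 <- dH * (1 - f$H^2)
    g <- list(We = t(x) %*% dZ1, be = colSums(dZ1),
              Wd = t(f$H) %*% dZ2, bd = colSums(dZ2))
    st <- adam_step(p, g, opt, cfg$lr)
    p <- st$params; opt <- st$state
    f <- fwd(p)
    trace[ep + 1] <- bce_loss(f$R, x)
  }
  out <- f$H
  rownames(out) <- rownames(x)
  attr(out, "loss_trace") <- trace
  out
}

#' Feature matrix space
#'
#' The ordered collection of per-protein feature matrices from which the
#' selector picks a subset: seven evidence-channel embeddings in canonical
#' order, then the attribute matrix, then any extra matrices.
#'
#' @param matrices List of numeric matrices sharing the same row count.
#' @param sources Character vector naming each matrix's origin.
#' @return An object of class `feature_space`.
#' @export
feature_space <- function(matrices, sources = names(matrices)) {
  stopifnot(is.list(matrices), length(matrices) >= 1)
  if (is.null(sources)) sources <- paste0("matrix", seq_along(matrices))
  stopifnot(length(sources) == length(matrices))
  n <- nrow(matrices[[1]])
  for (i in seq_along(matrices)) {
    m <- matrices[[i]]
    if (!is.matrix(m) || !all(is.finite(m))) {
      stop("feature matrix '", sources[i], "' must be a finite numeric matrix")
    }
    if (nrow(m) != n) {
      stop("feature matrix '", sources[i], "' has ", nrow(m),
           " rows; expected ", n)
    }
  }
  structure(list(matrices = matrices, sources = sources, n = n),
            class = "feature_space")
}

#' @export
length.feature_space <- function(x) length(x$matrices)

#' @export
print.feature_space <- function(x, ...) {
  cat("feature_space over", x$n, "proteins:\n")
  for (i in seq_along(x$matrices)) {
    cat(sprintf("  [%d] %-14s d_f = %d\n", i, x$sources[i],
                ncol(x$matrices[[i]])))
  }
  invisible(x)
}

#' Build the full feature matrix space from networks and attributes
#'
#' Normalizes each evidence network, embeds it with the chosen backend, and
#' assembles the ordered space: the seven channel embeddings (canonical
#' STRING order), then the attribute matrix, then any extra matrices (for
#' example precomputed sequence embeddings).
#'
#' @param networks List of seven [evidence_network()] objects, one per
#'   channel.
#' @param attrs Filtered binary attribute matrix (same protein rows).
#' @param backend One of `"transformerae"`, `"mlpae"`, `"noembed"`.
#' @param cfg [ae_config()] for the trainable backends; the per-channel seed
#'   is `cfg$seed + channel position` so channels get distinct but
#'   reproducible initializations.
#' @param extras Optional named list of additional feature matrices.
#' @return A [feature_space()] with `7 + 1 + length(extras)` matrices.
#' @export
build_feature_space <- function(networks, attrs,
                                backend = c("transformerae", "mlpae", "noembed"),
                                cfg = ae_config(), extras = NULL) {
  backend <- match.arg(backend)
  stopifnot(is.list(networks), is.matrix(attrs))
  chans <- vapply(networks, function(x) x$channel, character(1))
  if (!setequal(chans, STRING_CHANNELS) || length(chans) != 7) {
    stop("networks must contain each of the 7 STRING channels exactly once; got: ",
         paste(chans, collapse = ", "))
  }
  networks <- networks[match(STRING_CHANNELS, chans)]
  mats <- vector("list", 7)
  for (i in seq_len(7)) {
    net <- networks[[i]]
    if (nrow(net$adjacency) != nrow(attrs)) {
      stop("network '", net$channel, "' has ", nrow(net$adjacency),
           " proteins; attributes have ", nrow(attrs))
    }
    adj <- minmax_normalize(net$adjacency)
    ccfg <- cfg
    ccfg$seed <- cfg$seed + i
    mats[[i]] <- switch(backend,
      noembed = adj,
      mlpae = train_mlp_autoencoder(adj, ccfg),
      transformerae = train_transformer_autoencoder(adj, attrs, ccfg))
  }
  sources <- c(STRING_CHANNELS, "attributes")
  mats <- c(mats, list(attrs))
  if (!is.null(extras)) {
    if (is.null(names(extras)) || any(names(extras) == "")) {
      stop("extras must be a named list of matrices")
    }
    mats <- c(mats, extras)
    sources <- c(sources, paste0("extra:", names(extras)))
  }
  feature_space(mats, sources)
}
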