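test_that("minmax normalization has the stated closed form and edge cases", {
  expect_equal(minmax_normalize(matrix(c(0, 4, 2, 8), 2, 2)),
               matrix(c(0, 0.5, 0.25, 1), 2, 2))
  expect_equal(minmax_normalize(matrix(3, 2, 2)), matrix(0, 2, 2))
  m <- matrix(runif(20), 4, 5)
  m <- minmax_normalize(m)
  expect_equal(minmax_normalize(m), m)  # idempotent once in [0, 1] with 0/1 attained
})

test_that("minmax normalization is monotone", {
  set.seed(31)
  x <- matrix(runif(30, 0, 10), 5, 6)
  y <- x + matrix(runif(30, 0, 2), 5, 6)
  y[1, 1] <- x[1, 1]  # keep the shared min so both maps use comparable ranges
  nx <- minmax_normalize(x)
  for (i in seq_len(30)) {
    xi <- x; xi[i] <- xi[i] + 0.5
    if (max(xi) == max(x) && min(xi) == min(x)) {
      expect_true(all(minmax_normalize(xi) >= nx - 1e-12))
    }
  }
})

test_that("raw-adjacency backend returns the adjacency as features", {
  ids <- c("A", "B", "C")
  adj <- matrix(c(0, .5, 0, .5, 0, 1, 0, 1, 0), 3, 3,
                dimnames = list(ids, ids))
  net <- evidence_network(adj, "neighborhood")
  f <- embed_noembed(net)
  expect_identical(f, adj)
  zero <- evidence_network(matrix(0, 3, 3, dimnames = list(ids, ids)), "fusion")
  expect_true(all(embed_noembed(zero) == 0))
})

test_that("scaled dot-product attention matches direct arithmetic", {
  set.seed(32)
  for (i in 1:5) {
    Q <- matrix(rnorm(12), 3, 4)
    K <- matrix(rnorm(12), 3, 4)
    V <- matrix(rnorm(15), 3, 5)
    s <- Q %*% t(K) / sqrt(4)
    a <- t(apply(s, 1, function(r) exp(r) / sum(exp(r))))
    expect_lt(max(abs(scaled_dot_attention(Q, K, V) - a %*% V)), 1e-6)
    expect_equal(rowSums(a), rep(1, 3))  # attention rows are distributions
  }
})

test_that("attention on a 2-token toy matches a hand-computed softmax", {
  # single protein, two tokens, d_k = 2: work Eq.-style arithmetic by hand
  Q <- rbind(c(1, 0), c(0, 1))
  K <- Q  # Q = K
  V <- rbind(c(2, 0), c(0, 4))
  s <- Q %*% t(K) / sqrt(2)  # [[.707, 0], [0, .707]]
  e <- exp(s)
  a <- e / rowSums(e)
  want <- a %*% V
  expect_equal(scaled_dot_attention(Q, K, V), want, tolerance = 1e-12)
  # explicit value of one attention weight
  expect_equal(a[1, 1], exp(1 / sqrt(2)) / (exp(1 / sqrt(2)) + 1))
})

test_that("the 2-token attention layer agrees with the generic oracle", {
  set.seed(33)
  d <- 8; n <- 5; heads <- 2
  X1 <- matrix(rnorm(n * d), n, d)
  X2 <- matrix(rnorm(n * d), n, d)
  Wq <- matrix(rnorm(d * d, 0, .3), d, d); Wk <- matrix(rnorm(d * d, 0, .3), d, d)
  Wv <- matrix(rnorm(d * d, 0, .3), d, d); Wo <- matrix(rnorm(d * d, 0, .3), d, d)
  out <- dualnetgo:::attn2_forward(X1, X2, Wq, Wk, Wv, Wo, heads)
  dk <- d / heads
  for (i in seq_len(n)) {
    X <- rbind(X1[i, ], X2[i, ])
    O <- matrix(0, 2, d)
    for (h in seq_len(heads)) {
      cl <- ((h - 1) * dk + 1):(h * dk)
      O[, cl] <- scaled_dot_attention((X %*% Wq)[, cl], (X %*% Wk)[, cl],
                                      (X %*% Wv)[, cl])
    }
    Y <- X + O %*% Wo
    expect_lt(max(abs(c(out$Y1[i, ], out$Y2[i, ]) - c(Y[1, ], Y[2, ]))), 1e-9)
  }
})

test_that("transformer autoencoder gradients match finite differences", {
  set.seed(34)
  n <- 5; da <- 4
  A <- matrix(runif(n * n), n, n); A <- minmax_normalize((A + t(A)) / 2)
  At <- matrix(rbinom(n * da, 1, 0.5), n, da)
  cfg <- ae_config(d_hidden = 4, layers = 2, heads = 2, epochs = 0, seed = 3)
  p <- dualnetgo:::transformer_ae_init(n, da, cfg)
  lossfn <- function(p) {
    f <- dualnetgo:::transformer_ae_forward(p, A, At, cfg)
    dualnetgo:::bce_loss(f$R1, A) + dualnetgo:::bce_loss(f$R2, At)
  }
  f <- dualnetgo:::transformer_ae_forward(p, A, At, cfg)
  dZ1 <- dualnetgo:::bce_grad(f$R1, A) * f$R1 * (1 - f$R1)
  dZ2 <- dualnetgo:::bce_grad(f$R2, At) * f$R2 * (1 - f$R2)
  g <- list(Wout_net = t(f$Xd1) %*% dZ1, Win_check = NULL)
  dX1 <- dZ1 %*% t(p$Wout_net); dX2 <- dZ2 %*% t(p$Wout_attr)
  for (side in c("dec", "enc")) for (l in 2:1) {
    key <- paste0(side, l)
    bk <- dualnetgo:::attn2_backward(dX1, dX2, f$caches[[key]],
      p[[paste0(key, ".Wq")]], p[[paste0(key, ".Wk")]],
      p[[paste0(key, ".Wv")]], p[[paste0(key, ".Wo")]])
    g[[paste0(key, ".Wq")]] <- bk$dWq
    g[[paste0(key, ".Wo")]] <- bk$dWo
    dX1 <- bk$dX1; dX2 <- bk$dX2
  }
  g$Win_net <- t(A) %*% dX1
  g$Win_attr <- t(At) %*% dX2
  for (nm in c("Wout_net", "enc1.Wq", "dec2.Wo", "Win_net", "Win_attr")) {
    for (i in sample(length(g[[nm]]), 3)) {
      ph <- p; ph[[nm]][i] <- ph[[nm]][i] + 1e-6
      up <- lossfn(ph)
      ph[[nm]][i] <- ph[[nm]][i] - 2e-6
      dn <- lossfn(ph)
      expect_lt(abs((up - dn) / 2e-6 - g[[nm]][i]), 1e-6)
    }
  }
})

test_that("transformer autoencoder trains, is deterministic, and returns the network-side state", {
  set.seed(35)
  n <- 12; da <- 6
  A <- matrix(runif(n * n), n, n); A <- minmax_normalize((A + t(A)) / 2)
  rownames(A) <- sprintf("P%02d", 1:n)
  At <- matrix(rbinom(n * da, 1, 0.4), n, da)
  cfg <- ae_config(d_hidden = 4, layers = 2, heads = 2, epochs = 60,
                   lr = 1e-2, seed = 9)
  e1 <- train_transformer_autoencoder(A, At, cfg)
  e2 <- train_transformer_autoencoder(A, At, cfg)
  expect_identical(e1, e2)                       # same seed, bit-identical
  expect_equal(dim(e1), c(n, 4L))                # n x d_hidden, network side only
  tr <- attr(e1, "loss_trace")
  expect_lt(tr[length(tr)], tr[1])               # reconstruction improves
  expect_gt(stats::var(as.numeric(e1)), 0)       # non-constant embedding
  expect_error(ae_config(d_hidden = 6, heads = 4), "divide")
})

test_that("MLP autoencoder compresses a rank-2 input", {
  set.seed(36)
  # two distinct (near-binary) row patterns: rank-2 signal, low entropy floor
  base <- matrix(rbinom(2 * 10, 1, 0.5), 2, 10)
  x <- base[rep(1:2, each = 8), ] + matrix(runif(16 * 10, 0, 0.05), 16, 10)
  x <- minmax_normalize(x)
  cfg <- ae_config(d_hidden = 2, heads = 1, epochs = 500, lr = 1e-2, seed = 4)
  h <- train_mlp_autoencoder(x, cfg)
  expect_equal(dim(h), c(16L, 2L))
  tr <- attr(h, "loss_trace")
  expect_lt(tr[length(tr)], 0.5 * tr[1])  # >= 50% below the untrained loss
  expect_identical(train_mlp_autoencoder(x, cfg), h)
  expect_warning(train_mlp_autoencoder(x, ae_config(d_hidden = 10, heads = 1, epochs = 1)),
                 "bottleneck")
})

test_that("feature space assembly orders channels canonically and checks shapes", {
  set.seed(37)
  n <- 10
  ids <- sprintf("P%02d", 1:n)
  nets <- lapply(rev(string_channels()), function(ch) {  # deliberately reversed
    a <- matrix(runif(n * n), n, n); a <- (a + t(a)) / 2; diag(a) <- 0
    dimnames(a) <- list(ids, ids)
    evidence_network(a, ch)
  })
  attrs <- matrix(rbinom(n * 4, 1, .5), n, 4, dimnames = list(ids, paste0("a", 1:4)))
  sp <- build_feature_space(nets, attrs, backend = "noembed")
  expect_length(sp, 8)
  expect_equal(sp$sources, c(string_channels(), "attributes"))
  extra <- matrix(rnorm(n * 3), n, 3, dimnames = list(ids, NULL))
  sp9 <- build_feature_space(nets, attrs, backend = "noembed",
                             extras = list(esm = extra))
  expect_length(sp9, 9)
  expect_equal(sp9$sources[9], "extra:esm")
  bad <- matrix(0, n + 1, 2)
  expect_error(feature_space(list(a = sp$matrices[[1]], b = bad)), "rows")
  expect_error(build_feature_space(nets[1:6], attrs, backend = "noembed"),
               "7 STRING channels")
})
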