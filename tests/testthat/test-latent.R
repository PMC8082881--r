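test_that("original features are the rows and columns of Y", {
  Y <- matrix(c(1, 0, 1, 0, 0, 0), 2, 3, byrow = TRUE)
  ds <- association_dataset(Y, c("m1", "m2"), c("d1", "d2", "d3"))
  sp <- split_original_features(ds)
  expect_equal(dim(sp$M), c(2L, 3L))
  expect_equal(dim(sp$D), c(3L, 2L))
  expect_equal(unname(unclass(sp$D)), unname(t(Y)))
  Y2 <- matrix(c(1, 0, 0, 0), 2, 2)
  sp2 <- split_original_features(
    association_dataset(Y2, c("m1", "m2"), c("d1", "d2")))
  expect_equal(unname(sp2$M[1, ]), c(1, 0))
  expect_equal(unname(sp2$D[1, ]), c(1, 0))
})

test_that("encoding has the configured width and is reproducible", {
  synth <- small_synth(seed = 1)
  X <- split_original_features(synth$dataset)$M
  cfg <- tiny_ae_cfg(seed = 11)
  m1 <- train_stacked_autoencoder(X, cfg)
  m2 <- train_stacked_autoencoder(X, cfg)
  z1 <- encode(m1, X)
  z2 <- encode(m2, X)
  expect_equal(dim(z1), c(nrow(X), cfg$latent_dim))
  expect_identical(z1, z2)
  expect_error(encode(m1, X[, -1]), "width")
})

test_that("encoder output is row-order equivariant", {
  synth <- small_synth(seed = 2)
  X <- split_original_features(synth$dataset)$M
  m <- train_stacked_autoencoder(X, tiny_ae_cfg(seed = 3))
  perm <- withr::with_seed(8, sample(nrow(X)))
  expect_equal(encode(m, X[perm, ]), encode(m, X)[perm, ], tolerance = 1e-12)
})

test_that("a zero-weight encoder maps everything to the zero code", {
  model <- structure(list(
    encoder = list(list(W = matrix(0, 5, 3), b = numeric(3), act = "sigmoid"),
                   list(W = matrix(0, 3, 2), b = numeric(2), act = "linear")),
    decoder = list(list(W = matrix(0, 2, 3), b = numeric(3), act = "sigmoid"),
                   list(W = matrix(0, 3, 5), b = numeric(5), act = "tanh")),
    config = ae_config(latent_dim = 2, hidden_dims = c(3, 2)),
    input_dim = 5L, ids = NULL), class = "encoder_model")
  Z <- encode(model, matrix(rnorm(20), 4, 5))
  expect_equal(unname(Z), matrix(0, 4, 2))
})

test_that("encoder forward pass matches a hand-rolled matrix-multiply oracle", {
  set.seed(42)
  W1 <- matrix(rnorm(6 * 4, sd = 0.5), 6, 4)
  b1 <- rnorm(4)
  W2 <- matrix(rnorm(4 * 2, sd = 0.5), 4, 2)
  b2 <- rnorm(2)
  model <- structure(list(
    encoder = list(list(W = W1, b = b1, act = "sigmoid"),
                   list(W = W2, b = b2, act = "linear")),
    decoder = list(), config = ae_config(latent_dim = 2, hidden_dims = c(4, 2)),
    input_dim = 6L, ids = NULL), class = "encoder_model")
  X <- matrix(rnorm(60), 10, 6)
  H <- 1 / (1 + exp(-(X %*% W1 + matrix(b1, 10, 4, byrow = TRUE))))
  Zo <- H %*% W2 + matrix(b2, 10, 2, byrow = TRUE)
  expect_lt(max(abs(encode(model, X) - Zo)), 1e-5)
})

test_that("reconstruction loss matches definition and finite differences", {
  set.seed(7)
  p <- 3; h <- 2
  mk <- function(sd) list(
    list(W = matrix(rnorm(p * h, sd = sd), p, h), b = rnorm(h), act = "sigmoid"),
    list(W = matrix(rnorm(h * 2, sd = sd), h, 2), b = rnorm(2), act = "linear"))
  enc <- mk(0.8)
  dec <- list(
    list(W = matrix(rnorm(2 * h, sd = 0.8), 2, h), b = rnorm(h), act = "sigmoid"),
    list(W = matrix(rnorm(h * p, sd = 0.8), h, p), b = rnorm(p), act = "tanh"))
  model <- structure(list(encoder = enc, decoder = dec,
                          config = ae_config(latent_dim = 2,
                                             hidden_dims = c(h, 2)),
                          input_dim = p, ids = NULL),
                     class = "encoder_model")
  X <- matrix(runif(2 * p), 2, p)
  # lambda = 0: plain summed squared reconstruction error
  fwd <- function(x) {
    h1 <- 1 / (1 + exp(-(x %*% enc[[1]]$W + matrix(enc[[1]]$b, nrow(x), h, byrow = TRUE))))
    z <- h1 %*% enc[[2]]$W + matrix(enc[[2]]$b, nrow(x), 2, byrow = TRUE)
    hd <- 1 / (1 + exp(-(z %*% dec[[1]]$W + matrix(dec[[1]]$b, nrow(x), h, byrow = TRUE))))
    tanh(hd %*% dec[[2]]$W + matrix(dec[[2]]$b, nrow(x), p, byrow = TRUE))
  }
  expect_equal(reconstruction_loss(model, X, lambda = 0),
               sum((X - fwd(X))^2), tolerance = 1e-12)
  # Jacobian penalty against central finite differences of the first layer
  h_of <- function(x) 1 / (1 + exp(-(as.numeric(x %*% enc[[1]]$W) + enc[[1]]$b)))
  jac_fd <- 0
  eps <- 1e-5
  for (i in seq_len(nrow(X))) {
    J <- matrix(0, h, p)
    for (k in seq_len(p)) {
      e <- rep(0, p); e[k] <- eps
      J[, k] <- (h_of(rbind(X[i, ] + e)) - h_of(rbind(X[i, ] - e))) / (2 * eps)
    }
    jac_fd <- jac_fd + sum(J^2)
  }
  lam <- 1
  expect_lt(abs(reconstruction_loss(model, X, lambda = lam) -
                  (sum((X - fwd(X))^2) + lam * jac_fd)), 1e-4)
})

test_that("training reduces the fine-tuning loss", {
  synth <- small_synth(seed = 4)
  X <- split_original_features(synth$dataset)$M
  m <- train_stacked_autoencoder(X, tiny_ae_cfg(seed = 5, pre = 20, fine = 40))
  hist <- m$history$finetune
  expect_lt(hist[length(hist)], hist[1])
  expect_lt(median(utils::tail(hist, 10)), median(utils::head(hist, 10)))
})

test_that("same-block miRNAs are closer in latent space than cross-block", {
  gaps <- sapply(1:5, function(s) {
    synth <- generate_synthetic_dataset(synthetic_config(seed = s))
    X <- split_original_features(synth$dataset)$M
    Z <- encode(train_stacked_autoencoder(X, ae_cfg_synth(seed = s)), X)
    Zn <- Z / sqrt(rowSums(Z^2) + 1e-12)
    C <- Zn %*% t(Zn)
    b <- synth$mirna_block
    same <- outer(b, b, "==") & upper.tri(C)
    diff <- outer(b, b, "!=") & upper.tri(C)
    mean(C[same]) - mean(C[diff])
  })
  expect_gt(mean(gaps), 0)
})

test_that("no-compression configurations warn", {
  X <- matrix(rbinom(40, 1, 0.3), 10, 4)
  expect_warning(
    train_stacked_autoencoder(X, ae_config(latent_dim = 4,
                                           hidden_dims = c(6, 4),
                                           epochs_pretrain = 2,
                                           epochs_finetune = 2)),
    "no compression")
})
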