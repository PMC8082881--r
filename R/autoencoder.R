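#' Stacked autoencoder configuration
#'
#' The encoder is a two-hidden-layer network: a sigmoid layer of width
#' `hidden_dims[1]` followed by a linear code layer of width `latent_dim`
#' (`hidden_dims[2]`). The decoder mirrors it with a sigmoid hidden layer
#' and a hyperbolic-tangent output layer. Training is greedy layerwise
#' pretraining of each constituent autoencoder followed by end-to-end
#' fine-tuning of the full stack, minimizing the summed squared
#' reconstruction error plus a contractive penalty
#' `lambda * ||J_h(x)||^2`, the squared Frobenius norm of the Jacobian of
#' the first hidden layer with respect to the input.
#'
#' @param latent_dim width of the latent code (default 64).
#' @param hidden_dims encoder layer widths; must end in `latent_dim`.
#' @param lambda weight of the contractive Jacobian penalty (default 1e-4).
#' @param learning_rate Adam step size (default 1e-3).
#' @param epochs_pretrain full-batch epochs per layerwise pretraining stage.
#' @param epochs_finetune full-batch epochs of end-to-end fine-tuning.
#' @param seed integer seed controlling weight initialization.
#' @return A list of class `ae_config`.
#' @export
ae_config <- function(latent_dim = 64,
                      hidden_dims = c(256, latent_dim),
                      lambda = 1e-4,
                      learning_rate = 1e-3,
                      epochs_pretrain = 100,
                      epochs_finetune = 200,
                      seed = 1L) {
  if (latent_dim < 1) stop("latent_dim must be positive")
  if (length(hidden_dims) != 2) stop("exactly two encoder layers are used")
  if (hidden_dims[length(hidden_dims)] != latent_dim) {
    stop("last hidden width must equal latent_dim")
  }
  if (lambda < 0) stop("lambda must be non-negative")
  structure(list(latent_dim = as.integer(latent_dim),
                 hidden_dims = as.integer(hidden_dims),
                 lambda = lambda, learning_rate = learning_rate,
                 epochs_pretrain = as.integer(epochs_pretrain),
                 epochs_finetune = as.integer(epochs_finetune),
                 seed = as.integer(seed)),
            class = "ae_config")
}

#' Split an association matrix into original feature matrices
#'
#' Each miRNA's original feature is its row of `Y` (length `n_disease`);
#' each disease's is its column (length `n_mirna`).
#'
#' @param dataset an [association_dataset()].
#' @return List with `M` (`n_mirna` x `n_disease`) and `D`
#'   (`n_disease` x `n_mirna`, the transpose of `Y`).
#' @export
split_original_features <- function(dataset) {
  list(M = dataset$Y, D = t(dataset$Y))
}

sigm <- function(a) 1 / (1 + exp(-a))

# --- parameter containers -------------------------------------------------
# A layer is list(W = in x out matrix, b = length-out vector, act = name).
ae_layer <- function(n_in, n_out, act) {
  # Glorot-uniform initialization
  r <- sqrt(6 / (n_in + n_out))
  list(W = matrix(stats::runif(n_in * n_out, -r, r), n_in, n_out),
       b = numeric(n_out), act = act)
}

layer_forward <- function(layer, X) {
  A <- X %*% layer$W + rep(layer$b, each = nrow(X))
  switch(layer$act,
         sigmoid = sigm(A),
         tanh = tanh(A),
         linear = A)
}

# derivative of the activation given its output H
act_deriv <- function(layer, H) {
  switch(layer$act,
         sigmoid = H * (1 - H),
         tanh = 1 - H^2,
         linear = matrix(1, nrow(H), ncol(H)))
}

# Contractive penalty of a sigmoid first layer: per sample,
# ||J||_F^2 = sum_j h_j^2 (1-h_j)^2 * ||W_.j||^2, summed over samples.
contractive_penalty <- function(layer, H) {
  S2 <- (H * (1 - H))^2
  sum(S2 %*% colSums(layer$W^2))
}

# Forward pass through a list of layers, keeping activations.
stack_forward <- function(layers, X) {
  acts <- vector("list", length(layers) + 1)
  acts[[1]] <- X
  for (l in seq_along(layers)) {
    acts[[l + 1]] <- layer_forward(layers[[l]], acts[[l]])
  }
  acts
}

# Full-batch loss + analytic gradients for an arbitrary layer stack whose
# target is `X_target` (reconstruction). The contractive penalty, when
# lambda > 0, attaches to layer `pen_layer` (the first encoder layer).
stack_loss_grad <- function(layers, X, X_target, lambda = 0, pen_layer = 1L) {
  acts <- stack_forward(layers, X)
  Xhat <- acts[[length(acts)]]
  R <- Xhat - X_target
  loss <- sum(R^2)
  grads <- vector("list", length(layers))
  delta <- 2 * R * act_deriv(layers[[length(layers)]], Xhat)
  for (l in rev(seq_along(layers))) {
    inp <- acts[[l]]
    grads[[l]] <- list(W = crossprod(inp, delta), b = colSums(delta))
    if (l > 1) {
      delta <- (delta %*% t(layers[[l]]$W)) * act_deriv(layers[[l - 1]], acts[[l]])
    }
  }
  if (lambda > 0) {
    lay <- layers[[pen_layer]]
    H <- acts[[pen_layer + 1]]
    S <- H * (1 - H)
    w2 <- colSums(lay$W^2)
    loss <- loss + lambda * sum((S^2) %*% w2)
    # d/dA of the penalty, A the pre-activation of the penalized layer
    dA <- 2 * (S^2) * (1 - 2 * H) * rep(w2, each = nrow(H))
    gW <- 2 * lay$W * rep(colSums(S^2), each = nrow(lay$W)) +
      crossprod(acts[[pen_layer]], dA)
    grads[[pen_layer]]$W <- grads[[pen_layer]]$W + lambda * gW
    grads[[pen_layer]]$b <- grads[[pen_layer]]$b + lambda * colSums(dA)
  }
  list(loss = loss, grads = grads)
}

# Adam on a layer stack; returns layers and per-epoch loss trajectory.
adam_train <- function(layers, X, X_target, epochs, lr, lambda = 0,
                       pen_layer = 1L, stage = "train") {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  m <- lapply(layers, function(l) list(W = 0 * l$W, b = 0 * l$b))
  v <- m
  hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    lg <- stack_loss_grad(layers, X, X_target, lambda, pen_layer)
    if (!is.finite(lg$loss)) {
      stop(sprintf("non-finite loss at %s epoch %d", stage, ep))
    }
    hist[ep] <- lg$loss
    corr1 <- 1 - b1^ep; corr2 <- 1 - b2^ep
    for (l in seq_along(layers)) {
      for (p in c("W", "b")) {
        g <- lg$grads[[l]][[p]]
        m[[l]][[p]] <- b1 * m[[l]][[p]] + (1 - b1) * g
        v[[l]][[p]] <- b2 * v[[l]][[p]] + (1 - b2) * g^2
        layers[[l]][[p]] <- layers[[l]][[p]] -
          lr * (m[[l]][[p]] / corr1) / (sqrt(v[[l]][[p]] / corr2) + eps)
      }
    }
  }
  list(layers = layers, history = hist)
}

#' Train a stacked autoencoder on original feature rows
#'
#' Greedy layerwise pretraining: the first autoencoder (sigmoid encoder,
#' tanh decoder output) is trained on `X` with the contractive penalty; the
#' second (linear code, sigmoid decoder) on the first encoder's output.
#' The stacked network is then fine-tuned end-to-end by backpropagation on
#' the full reconstruction loss. All training is full batch and entirely
#' reproducible from `config$seed`.
#'
#' @param X numeric matrix, one entity (miRNA or disease) per row; row
#'   names, when present, become the latent feature ids.
#' @param config an [ae_config()].
#' @return Object of class `encoder_model`: list with `encoder` and
#'   `decoder` layer stacks, `config`, `input_dim`, `ids`, and `history`
#'   (per-epoch loss for `pretrain1`, `pretrain2`, `finetune`).
#' @export
train_stacked_autoencoder <- function(X, config = ae_config()) {
  X <- as.matrix(X)
  if (!nrow(X) || !ncol(X)) stop("X must be non-empty")
  p <- ncol(X)
  h1 <- config$hidden_dims[1]
  k <- config$latent_dim
  if (k >= p) {
    warning(sprintf("latent_dim (%d) >= input width (%d): no compression", k, p))
  }
  withr::with_seed(config$seed, {
    # --- pretrain AE1: x -> sigmoid(h1) -> tanh(xhat)
    ae1 <- list(ae_layer(p, h1, "sigmoid"), ae_layer(h1, p, "tanh"))
    r1 <- adam_train(ae1, X, X, config$epochs_pretrain, config$learning_rate,
                     lambda = config$lambda, stage = "pretrain1")
    H1 <- layer_forward(r1$layers[[1]], X)
    # --- pretrain AE2: h1 -> linear(k) -> sigmoid(h1hat)
    ae2 <- list(ae_layer(h1, k, "linear"), ae_layer(k, h1, "sigmoid"))
    r2 <- adam_train(ae2, H1, H1, config$epochs_pretrain,
                     config$learning_rate, stage = "pretrain2")
    # --- fine-tune the full stack end-to-end
    stack <- list(r1$layers[[1]], r2$layers[[1]],   # encoder
                  r2$layers[[2]], r1$layers[[2]])   # decoder
    rf <- adam_train(stack, X, X, config$epochs_finetune,
                     config$learning_rate, lambda = config$lambda,
                     stage = "finetune")
  })
  structure(list(encoder = rf$layers[1:2], decoder = rf$layers[3:4],
                 config = config, input_dim = p, ids = rownames(X),
                 history = list(pretrain1 = r1$history,
                                pretrain2 = r2$history,
                                finetune = rf$history)),
            class = "encoder_model")
}

#' @export
print.encoder_model <- function(x, ...) {
  cat(sprintf("encoder_model: %d -> %d -> %d (sigmoid, linear code); final loss %.4g\n",
              x$input_dim, x$config$hidden_dims[1], x$config$latent_dim,
              utils::tail(x$history$finetune, 1)))
  invisible(x)
}

#' Encode rows into latent features
#'
#' Applies the trained encoder (sigmoid hidden layer, linear code layer) to
#' each row of `X`.
#'
#' @param model an `encoder_model`.
#' @param X matrix whose column count equals the model's input width.
#' @return Matrix `nrow(X)` x `latent_dim` of latent features, rownames
#'   carried over from `X`.
#' @export
encode <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$input_dim) {
    stop(sprintf("input width %d does not match model input width %d",
                 ncol(X), model$input_dim))
  }
  Z <- stack_forward(model$encoder, X)[[3]]
  rownames(Z) <- rownames(X)
  Z
}

#' Reconstruction loss with contractive penalty
#'
#' Evaluates `sum_i ||x_i - xhat_i||^2 + lambda * ||J_h(x_i)||^2`, where
#' `xhat` is the decoder output and `J_h` the Jacobian of the first encoder
#' layer's activations with respect to the input.
#'
#' @param model an `encoder_model`.
#' @param X input matrix.
#' @param lambda penalty weight; defaults to the model's configured value.
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(model, X, lambda = model$config$lambda) {
  X <- as.matrix(X)
  layers <- c(model$encoder, model$decoder)
  acts <- stack_forward(layers, X)
  loss <- sum((acts[[length(acts)]] - X)^2)
  if (lambda > 0) {
    loss <- loss + lambda * contractive_penalty(model$encoder[[1]], acts[[2]])
  }
  loss
}
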