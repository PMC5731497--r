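# Layer-wise pretraining, stacking and supervised fine-tuning.
#
# The network is built in three steps: the architecture is laid out, each
# auto-encoder layer is greedily pretrained to reconstruct (corrupted copies
# of) its own inputs, and the whole stack plus a sigmoid output unit is then
# fine-tuned on binary labels with a held-out validation subset monitored.

#' Training configuration
#'
#' @param epochs Number of passes over the data (same for pretraining and
#'   fine-tuning).
#' @param learning_rate Pretraining SGD step size.
#' @param finetune_learning_rate Fine-tuning SGD step size.
#' @param batch_size Mini-batch size.
#' @param corruption_fraction Fraction of input positions masked to zero
#'   before encoding during pretraining, in [0, 1].
#' @param loss Reconstruction loss: \code{"squared_error"} or
#'   \code{"cross_entropy"} (the latter requires inputs in [0, 1]).
#' @param seed Integer seed; every stochastic step derives from it.
#' @param validation_fraction Fraction of fine-tuning samples held out to
#'   select the best epoch; ignored when \code{n_validation} is given.
#' @param n_validation Optional fixed held-out sample count.
#' @param s_f,s_g Encoder/decoder activations for pretrained layers.
#' @return Object of class \code{train_config}.
#' @export
train_config <- function(epochs = 30L, learning_rate = 0.1,
                         finetune_learning_rate = 0.3, batch_size = 32L,
                         corruption_fraction = 0.1,
                         loss = c("squared_error", "cross_entropy"),
                         seed = 1L, validation_fraction = 0.1,
                         n_validation = NULL,
                         s_f = "sigmoid", s_g = "sigmoid") {
  loss <- match.arg(loss)
  if (corruption_fraction < 0 || corruption_fraction > 1)
    stop("corruption_fraction must be in [0, 1]")
  if (epochs < 0) stop("epochs must be >= 0")
  if (learning_rate <= 0 || finetune_learning_rate <= 0)
    stop("learning rates must be positive")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 finetune_learning_rate = finetune_learning_rate,
                 batch_size = as.integer(batch_size),
                 corruption_fraction = corruption_fraction, loss = loss,
                 seed = as.integer(seed),
                 validation_fraction = validation_fraction,
                 n_validation = n_validation, s_f = s_f, s_g = s_g),
            class = "train_config")
}

# Mini-batch SGD epochs on one layer. Runs inside an active RNG stream.
sgd_epochs <- function(params, data, config) {
  n <- nrow(data)
  trace <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    batch_costs <- numeric(length(starts))
    for (j in seq_along(starts)) {
      idx <- ord[starts[j]:min(starts[j] + config$batch_size - 1L, n)]
      B <- data[idx, , drop = FALSE]
      M <- draw_masks(nrow(B), ncol(B), config$corruption_fraction)
      cg <- ae_cost_grad_masked(B, M, params, config$loss)
      batch_costs[j] <- cg$cost
      params <- apply_ae_grad(params, cg$grad, config$learning_rate)
    }
    trace[epoch] <- mean(batch_costs)
  }
  list(params = params, trace = trace)
}

#' Pretrain a single denoising auto-encoder layer
#'
#' Seeded initialization followed by \code{config$epochs} passes of
#' mini-batch gradient descent on the denoising reconstruction cost.
#' Deterministic given \code{config$seed}.
#'
#' @param data Numeric matrix, one sample per row.
#' @param d_hidden Hidden-layer width (>= 1).
#' @param config A \code{\link{train_config}}.
#' @return List with \code{params} (\code{\link{ae_layer}}) and
#'   \code{trace} (mean cost per epoch; empty when \code{epochs = 0}).
#' @export
pretrain_layer <- function(data, d_hidden, config = train_config()) {
  data <- as.matrix(data)
  if (!nrow(data)) stop("data must be non-empty")
  if (d_hidden < 1L) stop("d_hidden must be >= 1")
  with_seed(config$seed, {
    params <- init_ae_layer(ncol(data), d_hidden, config$s_f, config$s_g)
    sgd_epochs(params, data, config)
  })
}

#' Build an untrained stacked network
#'
#' Chains seeded-initialized auto-encoder layers (two by default) and a
#' single sigmoid output unit over the last hidden layer.
#'
#' @param d_input Input width (encoded window length).
#' @param hidden_sizes Hidden-layer widths, outermost first; default
#'   \code{c(64, 32)}.
#' @param seed Seed for parameter initialization.
#' @param threshold Decision cutoff in (0, 1); a probability equal to the
#'   threshold classifies positive.
#' @param s_f,s_g Layer activations.
#' @return Object of class \code{stacked_network}.
#' @export
build_network <- function(d_input, hidden_sizes = c(64L, 32L), seed = 1L,
                          threshold = 0.5, s_f = "sigmoid", s_g = "sigmoid") {
  if (!length(hidden_sizes)) stop("hidden_sizes must be non-empty")
  if (any(hidden_sizes < 1L) || d_input < 1L) stop("zero-size layers not allowed")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  with_seed(seed, {
    dims <- c(d_input, as.integer(hidden_sizes))
    layers <- lapply(seq_along(hidden_sizes), function(k)
      init_ae_layer(dims[k], dims[k + 1L], s_f, s_g))
    d_last <- dims[length(dims)]
    r <- 4 * sqrt(6 / (d_last + 1))
    output <- list(w = runif(d_last, -r, r), b = 0)
    structure(list(layers = layers, output = output, threshold = threshold,
                   d_input = as.integer(d_input),
                   pretrain_trace = NULL, finetune_trace = NULL),
              class = "stacked_network")
  })
}

#' @export
print.stacked_network <- function(x, ...) {
  dims <- c(x$d_input, vapply(x$layers, function(l) nrow(l$W), integer(1L)))
  cat("<stacked_network>", paste(dims, collapse = " -> "), "-> 1 (sigmoid)\n")
  cat("  threshold:", x$threshold,
      "| pretrained:", !is.null(x$pretrain_trace),
      "| fine-tuned:", !is.null(x$finetune_trace), "\n")
  invisible(x)
}

# Hidden representations of X after the first k encoder layers.
encode_through <- function(network, X, k = length(network$layers)) {
  H <- X
  for (i in seq_len(k)) {
    p <- network$layers[[i]]
    f <- activation(p$s_f)
    H <- f$f(sweep(H %*% t(p$W), 2L, p$b_h, "+"))
  }
  H
}

#' Greedy layer-wise pretraining of a stacked network
#'
#' Layer k is pretrained as a denoising auto-encoder on the hidden outputs
#' of layers 1..k-1; the supervised output unit is untouched. Per-layer cost
#' traces are stored in \code{network$pretrain_trace}.
#'
#' @param network A \code{\link{build_network}} result.
#' @param data Numeric matrix of encoded windows (width = \code{d_input}).
#' @param config A \code{\link{train_config}}.
#' @return The pretrained network.
#' @export
pretrain_stack <- function(network, data, config = train_config()) {
  data <- as.matrix(data)
  if (ncol(data) != network$d_input)
    stop("data width ", ncol(data), " does not match network input ",
         network$d_input)
  traces <- vector("list", length(network$layers))
  H <- data
  for (k in seq_along(network$layers)) {
    cfg_k <- config
    cfg_k$seed <- config$seed + k - 1L
    res <- pretrain_layer(H, nrow(network$layers[[k]]$W), cfg_k)
    res$params$s_f <- network$layers[[k]]$s_f
    res$params$s_g <- network$layers[[k]]$s_g
    network$layers[[k]] <- res$params
    traces[[k]] <- res$trace
    H <- encode_through(network, data, k)
  }
  network$pretrain_trace <- traces
  network
}

# Forward pass keeping per-layer activations for backpropagation.
supervised_forward <- function(network, X) {
  Hs <- vector("list", length(network$layers) + 1L)
  Hs[[1L]] <- X
  for (k in seq_along(network$layers)) {
    p <- network$layers[[k]]
    f <- activation(p$s_f)
    Hs[[k + 1L]] <- f$f(sweep(Hs[[k]] %*% t(p$W), 2L, p$b_h, "+"))
  }
  a <- drop(Hs[[length(Hs)]] %*% network$output$w) + network$output$b
  list(Hs = Hs, proba = 1 / (1 + exp(-a)))
}

binary_cross_entropy <- function(p, y) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Supervised fine-tuning of the whole stack
#'
#' Gradient descent on binary cross-entropy through all encoder layers and
#' the sigmoid output unit. A held-out validation subset (size from
#' \code{config$n_validation} or \code{config$validation_fraction}) is
#' scored after every epoch and the best-validation parameters are returned.
#'
#' @param network A (typically pretrained) \code{stacked_network}.
#' @param X Encoded window matrix.
#' @param y Binary labels (0/1), one per row of \code{X}; both classes must
#'   be present.
#' @param config A \code{\link{train_config}}.
#' @return Fine-tuned network; \code{finetune_trace} holds per-epoch train
#'   and validation cross-entropy.
#' @export
finetune <- function(network, X, y, config = train_config()) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("label length must match rows of X")
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(y)) < 2L) stop("training set contains a single class")
  if (config$epochs == 0L) return(network)
  lr <- config$finetune_learning_rate
  with_seed(config$seed + 1000L, {
    n <- nrow(X)
    n_val <- if (!is.null(config$n_validation)) min(config$n_validation, n - 2L)
             else floor(config$validation_fraction * n)
    val_idx <- if (n_val > 0L) sample.int(n, n_val) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xt <- X[tr_idx, , drop = FALSE]; yt <- y[tr_idx]
    Xv <- X[val_idx, , drop = FALSE]; yv <- y[val_idx]
    best <- list(layers = network$layers, output = network$output,
                 val = if (n_val > 0L)
                   binary_cross_entropy(supervised_forward(network, Xv)$proba, yv)
                 else Inf)
    trace <- matrix(NA_real_, config$epochs, 2L,
                    dimnames = list(NULL, c("train", "validation")))
    nt <- nrow(Xt)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(nt)
      starts <- seq(1L, nt, by = config$batch_size)
      costs <- numeric(length(starts))
      for (j in seq_along(starts)) {
        idx <- ord[starts[j]:min(starts[j] + config$batch_size - 1L, nt)]
        B <- Xt[idx, , drop = FALSE]; yb <- yt[idx]
        fw <- supervised_forward(network, B)
        costs[j] <- binary_cross_entropy(fw$proba, yb)
        m <- length(yb)
        H_last <- fw$Hs[[length(fw$Hs)]]
        delta <- (fw$proba - yb) / m            # sigmoid + BCE
        gw <- drop(crossprod(H_last, delta))
        gb <- sum(delta)
        D <- outer(delta, network$output$w)
        network$output$w <- network$output$w - lr * gw
        network$output$b <- network$output$b - lr * gb
        for (k in rev(seq_along(network$layers))) {
          p <- network$layers[[k]]
          f <- activation(p$s_f)
          Hk <- fw$Hs[[k + 1L]]
          D <- D * f$dfda(NULL, Hk)
          gW <- crossprod(D, fw$Hs[[k]])
          gbh <- colSums(D)
          if (k > 1L) D <- D %*% p$W
          network$layers[[k]]$W <- p$W - lr * gW
          network$layers[[k]]$b_h <- p$b_h - lr * gbh
        }
      }
      val <- if (n_val > 0L)
        binary_cross_entropy(supervised_forward(network, Xv)$proba, yv)
      else mean(costs)
      trace[epoch, ] <- c(mean(costs), if (n_val > 0L) val else NA_real_)
      if (val <= best$val)
        best <- list(layers = network$layers, output = network$output, val = val)
    }
    network$layers <- best$layers
    network$output <- best$output
    network$finetune_trace <- trace
    network
  })
}

#' Predict splice-site probability / class
#'
#' @param network A \code{stacked_network}.
#' @param x Encoded window: numeric vector of length \code{d_input}, or a
#'   matrix with one window per row.
#' @return \code{predict_proba}: sigmoid output in (0, 1);
#'   \code{classify}: integer 0/1, where a probability greater than or equal
#'   to the network threshold (ties included) classifies positive.
#' @export
predict_proba <- function(network, x) {
  X <- if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1L)
  if (ncol(X) != network$d_input)
    stop("input width ", ncol(X), " does not match network input ",
         network$d_input)
  p <- supervised_forward(network, X)$proba
  if (is.matrix(x)) p else p[1L]
}

#' @rdname predict_proba
#' @export
classify <- function(network, x) {
  as.integer(predict_proba(network, x) >= network$threshold)
}
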