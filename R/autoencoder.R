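# Denoising auto-encoder layer: encoder h = S_f(W x + b_h), decoder
# x* = S_g(W' h + b_x). W and W' are untied. Training minimises the mean
# reconstruction loss of the clean input from a corrupted copy.

activation <- function(name) {
  switch(name,
         sigmoid = list(f = function(a) 1 / (1 + exp(-a)),
                        # derivative in terms of the activation value
                        dfda = function(a, v) v * (1 - v)),
         linear = list(f = function(a) a,
                       dfda = function(a, v) array(1, dim = dim(v) %||% length(v))),
         stop("unknown activation: ", name))
}

#' Create auto-encoder layer parameters
#'
#' @param W Encoder weight matrix, hidden x input.
#' @param W_prime Decoder weight matrix, input x hidden.
#' @param b_h Hidden bias (length = hidden width).
#' @param b_x Reconstruction bias (length = input width).
#' @param s_f,s_g Activation selectors for encoder/decoder:
#'   \code{"sigmoid"} or \code{"linear"}.
#' @return Object of class \code{ae_layer}.
#' @export
ae_layer <- function(W, W_prime, b_h, b_x, s_f = "sigmoid", s_g = "sigmoid") {
  W <- as.matrix(W); W_prime <- as.matrix(W_prime)
  b_h <- as.numeric(b_h); b_x <- as.numeric(b_x)
  d_h <- nrow(W); d_in <- ncol(W)
  if (!identical(dim(W_prime), c(d_in, d_h)))
    stop("W_prime must be input x hidden (transposed shape of W)")
  if (length(b_h) != d_h || length(b_x) != d_in)
    stop("bias lengths must match layer widths")
  if (!all(is.finite(W), is.finite(W_prime), is.finite(b_h), is.finite(b_x)))
    stop("layer parameters must be finite")
  s_f <- match.arg(s_f, c("sigmoid", "linear"))
  s_g <- match.arg(s_g, c("sigmoid", "linear"))
  structure(list(W = W, W_prime = W_prime, b_h = b_h, b_x = b_x,
                 s_f = s_f, s_g = s_g),
            class = "ae_layer")
}

# Sigmoid-appropriate seeded initialization: uniform in
# +/- 4*sqrt(6/(fan_in+fan_out)); biases zero. Assumes an active RNG stream.
init_ae_layer <- function(d_in, d_hidden, s_f = "sigmoid", s_g = "sigmoid") {
  r <- 4 * sqrt(6 / (d_in + d_hidden))
  W <- matrix(runif(d_hidden * d_in, -r, r), nrow = d_hidden)
  W_prime <- matrix(runif(d_in * d_hidden, -r, r), nrow = d_in)
  ae_layer(W, W_prime, numeric(d_hidden), numeric(d_in), s_f, s_g)
}

# Batch encoder/decoder over a n x d matrix; returns activations too for
# backpropagation.
ae_forward_batch <- function(X, params) {
  f <- activation(params$s_f); g <- activation(params$s_g)
  A_h <- sweep(X %*% t(params$W), 2L, params$b_h, "+")
  H <- f$f(A_h)
  A_x <- sweep(H %*% t(params$W_prime), 2L, params$b_x, "+")
  X_star <- g$f(A_x)
  list(A_h = A_h, H = H, A_x = A_x, X_star = X_star)
}

#' Auto-encoder forward pass
#'
#' Computes the hidden code \code{h = S_f(W x + b_h)} and the reconstruction
#' \code{x_star = S_g(W' h + b_x)}.
#'
#' @param x Numeric input vector of length \code{ncol(W)}.
#' @param params An \code{\link{ae_layer}}.
#' @return List with \code{h} and \code{x_star} (same length as \code{x}).
#' @export
ae_forward <- function(x, params) {
  x <- as.numeric(x)
  if (length(x) != ncol(params$W))
    stop("input length ", length(x), " does not match layer width ",
         ncol(params$W))
  fw <- ae_forward_batch(matrix(x, nrow = 1L), params)
  list(h = as.numeric(fw$H), x_star = as.numeric(fw$X_star))
}

#' Mask-to-zero input corruption
#'
#' Sets exactly \code{round(fraction * length(x))} positions, chosen
#' uniformly without replacement from the current RNG stream, to zero.
#'
#' @param x Numeric vector.
#' @param fraction Corruption fraction in [0, 1].
#' @param seed Optional seed; when \code{NULL} the current RNG state is used.
#' @return Corrupted copy of \code{x}.
#' @export
corrupt <- function(x, fraction, seed = NULL) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  with_seed(seed, {
    k <- round(fraction * length(x))
    if (k > 0L) x[sample.int(length(x), k)] <- 0
    x
  })
}

# Multiplicative 0/1 masks for a whole batch, one row per sample, each row
# zeroing exactly round(fraction*d) positions. Draws from the active stream.
draw_masks <- function(n, d, fraction) {
  M <- matrix(1, n, d)
  k <- round(fraction * d)
  if (k > 0L) for (i in seq_len(n)) M[i, sample.int(d, k)] <- 0
  M
}

loss_and_dcost <- function(X, X_star, loss, n) {
  if (loss == "squared_error") {
    list(value = sum((X - X_star)^2) / n,
         dXs = -2 * (X - X_star) / n)
  } else if (loss == "cross_entropy") {
    if (any(X < 0 | X > 1))
      stop("cross-entropy loss requires inputs in [0, 1]")
    eps <- 1e-12
    Xs <- pmin(pmax(X_star, eps), 1 - eps)
    list(value = -sum(X * log(Xs) + (1 - X) * log(1 - Xs)) / n,
         dXs = (-(X / Xs) + (1 - X) / (1 - Xs)) / n)
  } else stop("unknown loss: ", loss)
}

# Cost and analytic parameter gradients for fixed corruption masks M.
ae_cost_grad_masked <- function(X, M, params, loss, want_grad = TRUE) {
  n <- nrow(X)
  Xc <- X * M
  f <- activation(params$s_f); g <- activation(params$s_g)
  fw <- ae_forward_batch(Xc, params)
  ld <- loss_and_dcost(X, fw$X_star, loss, n)
  out <- list(cost = ld$value)
  if (want_grad) {
    D_x <- ld$dXs * g$dfda(fw$A_x, fw$X_star)
    D_h <- (D_x %*% params$W_prime) * f$dfda(fw$A_h, fw$H)
    out$grad <- list(W = t(D_h) %*% Xc,
                     W_prime = t(D_x) %*% fw$H,
                     b_h = colSums(D_h),
                     b_x = colSums(D_x))
  }
  out
}

#' Denoising reconstruction cost of a batch
#'
#' Mean over rows of the loss L(x, x*) where x* reconstructs a corrupted
#' copy of x: squared error \code{sum((x - x*)^2)} or cross-entropy
#' (inputs must lie in [0, 1]). Corruption masks are drawn from
#' \code{config$seed}, so the value is deterministic for a fixed config.
#'
#' @param batch Numeric matrix, one sample per row.
#' @param params An \code{\link{ae_layer}}.
#' @param config A \code{\link{train_config}}.
#' @return Non-negative scalar cost.
#' @export
ae_cost <- function(batch, params, config = train_config()) {
  batch <- as.matrix(batch)
  if (!nrow(batch)) stop("batch must be non-empty")
  M <- with_seed(config$seed,
                 draw_masks(nrow(batch), ncol(batch), config$corruption_fraction))
  ae_cost_grad_masked(batch, M, params, config$loss, want_grad = FALSE)$cost
}

#' One gradient-descent step on the denoising cost
#'
#' Updates W, W', b_h and b_x by one step of size
#' \code{config$learning_rate} on the analytic gradient of
#' \code{\link{ae_cost}} (corruption masks drawn from \code{config$seed}).
#' The input \code{params} object is not modified.
#'
#' @inheritParams ae_cost
#' @return Updated \code{\link{ae_layer}}.
#' @export
cost_update <- function(params, batch, config = train_config()) {
  batch <- as.matrix(batch)
  M <- with_seed(config$seed,
                 draw_masks(nrow(batch), ncol(batch), config$corruption_fraction))
  g <- ae_cost_grad_masked(batch, M, params, config$loss)$grad
  apply_ae_grad(params, g, config$learning_rate)
}

apply_ae_grad <- function(params, g, lr) {
  if (!all(vapply(g, function(x) all(is.finite(x)), logical(1L))))
    stop("non-finite gradient encountered")
  params$W <- params$W - lr * g$W
  params$W_prime <- params$W_prime - lr * g$W_prime
  params$b_h <- params$b_h - lr * g$b_h
  params$b_x <- params$b_x - lr * g$b_x
  params
}
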