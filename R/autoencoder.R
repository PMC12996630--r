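# A small fully connected autoencoder trained by backpropagation.
#
# Default architecture: p -> ceil(p/2) -> ceil(p/4) -> ceil(p/2) -> p with
# tanh hidden activations and a linear output layer, mean-squared-error
# objective, full-batch Adam, 50 epochs. The per-sample mean squared
# reconstruction error is the anomaly score.

ae_init <- function(widths) {
  L <- length(widths) - 1
  weights <- vector("list", L)
  biases <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- widths[l]
    weights[[l]] <- matrix(stats::rnorm(fan_in * widths[l + 1],
                                        sd = sqrt(1 / fan_in)),
                           fan_in, widths[l + 1])
    biases[[l]] <- rep(0, widths[l + 1])
  }
  list(weights = weights, biases = biases)
}

ae_forward <- function(par, x) {
  L <- length(par$weights)
  acts <- vector("list", L + 1)
  acts[[1]] <- x
  for (l in seq_len(L)) {
    z <- sweep(acts[[l]] %*% par$weights[[l]], 2, par$biases[[l]], "+")
    acts[[l + 1]] <- if (l < L) tanh(z) else z
  }
  acts
}

ae_gradients <- function(par, acts, x) {
  L <- length(par$weights)
  n <- nrow(x)
  p <- ncol(x)
  gw <- vector("list", L)
  gb <- vector("list", L)
  # d(loss)/d(output) for loss = mean over samples and dims of squared error
  delta <- 2 * (acts[[L + 1]] - x) / (n * p)
  for (l in L:1) {
    gw[[l]] <- crossprod(acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(par$weights[[l]])) * (1 - acts[[l]]^2)
    }
  }
  list(weights = gw, biases = gb)
}

#' Fit an autoencoder on a feature matrix
#'
#' @param train numeric matrix (n >= 2); typically standardized features or
#'   PCA scores.
#' @param hidden integer vector of hidden-layer widths (the middle entry is
#'   the bottleneck); default `c(ceil(p/2), ceil(p/4), ceil(p/2))`. The
#'   bottleneck must be narrower than the input.
#' @param epochs training epochs (default 50).
#' @param learning_rate Adam step size (default 0.02, the largest of the
#'   tried steps for which the full-batch training loss still decreases
#'   monotonically on typical standardized inputs).
#' @param seed integer seed for weight initialization; training is
#'   full-batch and deterministic given seed + data.
#' @return Object of class `autoencoder_model` carrying the weights, the
#'   per-epoch training loss and the configuration.
#' @export
fit_autoencoder <- function(train, hidden = NULL, epochs = 50,
                            learning_rate = 0.02, seed = 1) {
  if (nrow(train) < 2) stop("need >= 2 samples", call. = FALSE)
  p <- ncol(train)
  if (is.null(hidden)) {
    hidden <- c(max(1, ceiling(p / 2)), max(1, ceiling(p / 4)),
                max(1, ceiling(p / 2)))
  }
  if (min(hidden) >= p) {
    stop("bottleneck width must be smaller than the input width",
         call. = FALSE)
  }
  widths <- c(p, hidden, p)
  par <- with_seed(seed, ae_init(widths))
  # Adam state
  m <- lapply(par$weights, function(w) w * 0)
  v <- m
  mb <- lapply(par$biases, function(b) b * 0)
  vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  loss <- numeric(epochs)
  for (e in seq_len(epochs)) {
    acts <- ae_forward(par, train)
    loss[e] <- mean((acts[[length(acts)]] - train)^2)
    g <- ae_gradients(par, acts, train)
    for (l in seq_along(par$weights)) {
      m[[l]] <- b1 * m[[l]] + (1 - b1) * g$weights[[l]]
      v[[l]] <- b2 * v[[l]] + (1 - b2) * g$weights[[l]]^2
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * g$biases[[l]]
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * g$biases[[l]]^2
      mh <- m[[l]] / (1 - b1^e); vh <- v[[l]] / (1 - b2^e)
      mbh <- mb[[l]] / (1 - b1^e); vbh <- vb[[l]] / (1 - b2^e)
      par$weights[[l]] <- par$weights[[l]] - learning_rate * mh / (sqrt(vh) + eps)
      par$biases[[l]] <- par$biases[[l]] - learning_rate * mbh / (sqrt(vbh) + eps)
    }
  }
  structure(list(par = par, widths = widths, epochs = epochs,
                 learning_rate = learning_rate, seed = seed,
                 training_loss = loss, p = p),
            class = c("autoencoder_model", "anomaly_model"))
}

#' @export
anomaly_scores.autoencoder_model <- function(model, matrix) {
  if (ncol(matrix) != model$p) stop("feature dimension mismatch", call. = FALSE)
  acts <- ae_forward(model$par, matrix)
  err <- rowMeans((acts[[length(acts)]] - matrix)^2)
  stats::setNames(err, rownames(matrix))
}

#' Score a matrix with a fitted autoencoder
#'
#' Raw score = per-sample mean squared reconstruction error.
#' @param model an `autoencoder_model`.
#' @param matrix matrix over the model's feature space.
#' @return An [anomaly_score_set].
#' @export
score_autoencoder <- function(model, matrix) {
  anomaly_score_set("autoencoder", anomaly_scores(model, matrix))
}

#' Bottleneck encodings of a fitted autoencoder
#'
#' Activations of the narrowest hidden layer; used e.g. as learned features
#' for a downstream classification head.
#' @param model an `autoencoder_model`.
#' @param matrix matrix over the model's feature space.
#' @export
autoencoder_encode <- function(model, matrix) {
  if (ncol(matrix) != model$p) stop("feature dimension mismatch", call. = FALSE)
  hidden <- model$widths[-c(1, length(model$widths))]
  bn_layer <- which.min(hidden) + 1L  # index into activation list
  acts <- ae_forward(model$par, matrix)
  acts[[bn_layer]]
}
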