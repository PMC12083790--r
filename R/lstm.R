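# A small LSTM classifier written in base R.
#
# Single LSTM layer followed by a dense softmax head, trained with
# cross-entropy loss and Adam by full backpropagation through time. Tabular
# feature vectors are presented as sequences: by default one feature per
# timestep (sequence length = feature count, input dimension 1), optionally
# as a single timestep carrying all features.
#
# Gate layout inside the packed weight matrices is (input, forget, cell,
# output), each block of width `hidden`.

sigmoid <- function(z) 1 / (1 + exp(-z))

lstm_init <- function(input_dim, hidden, n_classes) {
  s <- 1 / sqrt(hidden)
  W <- matrix(stats::runif(input_dim * 4 * hidden, -s, s), input_dim, 4 * hidden)
  U <- matrix(stats::runif(hidden * 4 * hidden, -s, s), hidden, 4 * hidden)
  b <- rep(0, 4 * hidden)
  b[(hidden + 1):(2 * hidden)] <- 1  # forget-gate bias starts open
  Wp <- matrix(stats::runif(hidden * n_classes, -s, s), hidden, n_classes)
  bp <- rep(0, n_classes)
  list(W = W, U = U, b = b, Wp = Wp, bp = bp, hidden = hidden)
}

# forward pass over a batch; returns cache when training
lstm_forward <- function(par, seqs, cache = FALSE) {
  H <- par$hidden
  Tlen <- dim(seqs)[3L]
  B <- nrow(seqs)
  h <- matrix(0, B, H)
  cc <- matrix(0, B, H)
  steps <- if (cache) vector("list", Tlen) else NULL
  idx_i <- seq_len(H); idx_f <- H + idx_i; idx_g <- 2 * H + idx_i; idx_o <- 3 * H + idx_i
  for (t in seq_len(Tlen)) {
    xt <- seqs[, , t, drop = FALSE]
    dim(xt) <- c(B, dim(seqs)[2L])
    z <- xt %*% par$W + h %*% par$U
    z <- sweep(z, 2L, par$b, "+")
    i <- sigmoid(z[, idx_i, drop = FALSE])
    f <- sigmoid(z[, idx_f, drop = FALSE])
    g <- tanh(z[, idx_g, drop = FALSE])
    o <- sigmoid(z[, idx_o, drop = FALSE])
    c_prev <- cc
    h_prev <- h
    cc <- f * c_prev + i * g
    h <- o * tanh(cc)
    if (cache) {
      steps[[t]] <- list(x = xt, h_prev = h_prev, c_prev = c_prev,
                         i = i, f = f, g = g, o = o, c = cc)
    }
  }
  logits <- sweep(h %*% par$Wp, 2L, par$bp, "+")
  list(h = h, logits = logits, steps = steps)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

lstm_backward <- function(par, fw, y_onehot) {
  H <- par$hidden
  B <- nrow(y_onehot)
  p <- softmax_rows(fw$logits)
  dlogits <- (p - y_onehot) / B
  g <- list(W = 0 * par$W, U = 0 * par$U, b = 0 * par$b,
            Wp = crossprod(fw$h, dlogits), bp = colSums(dlogits))
  dh <- tcrossprod(dlogits, par$Wp)
  dc <- matrix(0, B, H)
  for (t in rev(seq_along(fw$steps))) {
    st <- fw$steps[[t]]
    tc <- tanh(st$c)
    do <- dh * tc
    dc <- dc + dh * st$o * (1 - tc^2)
    di <- dc * st$g
    df <- dc * st$c_prev
    dg <- dc * st$i
    dz <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do * st$o * (1 - st$o))
    g$W <- g$W + crossprod(st$x, dz)
    g$U <- g$U + crossprod(st$h_prev, dz)
    g$b <- g$b + colSums(dz)
    dh <- tcrossprod(dz, par$U)
    dc <- dc * st$f
  }
  g
}

lstm_to_seq <- function(x, input_mode) {
  n <- nrow(x); p <- ncol(x)
  if (identical(input_mode, "per_feature")) {
    array(x, dim = c(n, 1L, p))  # T = p timesteps of 1 feature
  } else {
    array(x, dim = c(n, p, 1L))  # one timestep of p features
  }
}

#' Train the built-in LSTM classifier
#'
#' Single-layer LSTM with a dense softmax output head, cross-entropy loss,
#' and Adam, implemented in base R with full backpropagation through time.
#' Feature vectors are presented one feature per timestep by default.
#'
#' @param x numeric matrix (samples x features).
#' @param y factor of class labels.
#' @param hidden hidden state size. Default 64.
#' @param epochs training epochs. Default 100.
#' @param learning_rate Adam step size. Default 1e-3.
#' @param batch_size minibatch size. Default 8.
#' @param input_mode `"per_feature"` (sequence length = feature count,
#'   input dimension 1) or `"single_step"` (one timestep of all features).
#' @param seed integer seed for initialization and batch shuffling.
#' @return An `lstm_model` list carrying the trained parameters, the class
#'   levels, the input geometry, and the per-epoch loss/accuracy history.
#' @export
lstm_fit <- function(x, y, hidden = 64L, epochs = 100L, learning_rate = 1e-3,
                     batch_size = 8L, input_mode = c("per_feature", "single_step"),
                     seed = 1L) {
  input_mode <- match.arg(input_mode)
  y <- droplevels(as.factor(y))
  stopifnot(is.matrix(x), nrow(x) == length(y), nlevels(y) >= 2L)
  set.seed(seed)
  n <- nrow(x)
  n_classes <- nlevels(y)
  input_dim <- if (input_mode == "per_feature") 1L else ncol(x)
  par <- lstm_init(input_dim, hidden, n_classes)
  seqs <- lstm_to_seq(x, input_mode)
  Y <- matrix(0, n, n_classes)
  Y[cbind(seq_len(n), as.integer(y))] <- 1

  adam_m <- lapply(par[c("W", "U", "b", "Wp", "bp")], function(p) 0 * p)
  adam_v <- adam_m
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0), accuracy = numeric(0))

  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    ep_correct <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      bseq <- seqs[idx, , , drop = FALSE]
      fw <- lstm_forward(par, bseq, cache = TRUE)
      pr <- softmax_rows(fw$logits)
      ll <- -sum(log(pmax(pr[cbind(seq_along(idx), as.integer(y)[idx])], 1e-300)))
      if (!is.finite(ll)) stop("LSTM training diverged (non-finite loss)", call. = FALSE)
      ep_loss <- ep_loss + ll
      ep_correct <- ep_correct + sum(max.col(pr, ties.method = "first") == as.integer(y)[idx])
      grads <- lstm_backward(par, fw, Y[idx, , drop = FALSE])
      step <- step + 1L
      for (nm in names(adam_m)) {
        adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * grads[[nm]]
        adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * grads[[nm]]^2
        mhat <- adam_m[[nm]] / (1 - beta1^step)
        vhat <- adam_v[[nm]] / (1 - beta2^step)
        par[[nm]] <- par[[nm]] - learning_rate * mhat / (sqrt(vhat) + eps)
      }
    }
    history <- rbind(history,
                     data.frame(epoch = ep, loss = ep_loss / n,
                                accuracy = ep_correct / n))
  }
  structure(list(par = par, classes = levels(y), input_mode = input_mode,
                 n_features = ncol(x), history = history),
            class = "lstm_model")
}

#' Predict with the built-in LSTM classifier
#'
#' @param model an `lstm_model` from [lstm_fit()].
#' @param x numeric matrix with the training feature count.
#' @return Character vector of predicted class labels.
#' @export
lstm_predict <- function(model, x) {
  stopifnot(inherits(model, "lstm_model"), ncol(x) == model$n_features)
  fw <- lstm_forward(model$par, lstm_to_seq(x, model$input_mode))
  model$classes[max.col(softmax_rows(fw$logits), ties.method = "first")]
}
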