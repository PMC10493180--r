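# A small fully connected network mapping a pair encoding to a probability
# distribution over n DDI event types. Architecture (best grid point):
# input -> 512 (ReLU) -> dropout -> 256 (sigmoid) -> dropout -> 128
# (sigmoid) -> dropout -> softmax. Trained with Adam on cross-entropy for
# 100 epochs, batch size 128. Everything (weight init, epoch shuffles,
# dropout masks) draws from one seeded RNG stream, so a fixed seed gives
# bit-identical training runs. Implemented directly on BLAS matrix ops: no
# deep-learning framework dependency, and exact replay is cheap to audit.

#' Network hyperparameter configuration
#'
#' Defaults are the selected grid point: three hidden layers of 512/256/128
#' units, dropout 0.3 after every hidden layer, ReLU on the first hidden
#' layer and logistic sigmoid on the others, softmax output, Adam with step
#' size 1e-3, 100 epochs, batch size 128.
#'
#' @param hidden_sizes integer vector of hidden-layer widths (may be empty:
#'   the model degenerates to multinomial logistic regression).
#' @param dropout_rate dropout probability in \[0, 1) applied after each
#'   hidden layer during training.
#' @param epochs number of full passes over the training pairs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size (unstated upstream; 1e-3 convention).
#' @param loss `"categorical"` (cross-entropy of softmax vs one-hot, the
#'   default) or `"bce"` (per-class binary cross-entropy on the softmax
#'   output; the framework idiom some implementations actually compute).
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout masks.
#' @return Object of class `model_config`.
#' @export
model_config <- function(hidden_sizes = c(512L, 256L, 128L),
                         dropout_rate = 0.3,
                         epochs = 100L,
                         batch_size = 128L,
                         learning_rate = 1e-3,
                         loss = c("categorical", "bce"),
                         seed = 1L) {
  loss <- match.arg(loss)
  hidden_sizes <- as.integer(hidden_sizes)
  if (length(hidden_sizes) && any(hidden_sizes < 1L))
    stop("model_config: hidden sizes must be positive")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("model_config: dropout_rate must be in [0, 1)")
  if (epochs < 1L || batch_size < 1L) stop("model_config: epochs and batch_size must be >= 1")
  structure(list(hidden_sizes = hidden_sizes, dropout_rate = dropout_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, loss = loss, seed = as.integer(seed)),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config: hidden [%s], dropout %.2f, %d epochs, batch %d, lr %g, loss %s, seed %d>\n",
              paste(x$hidden_sizes, collapse = ", "), x$dropout_rate, x$epochs,
              x$batch_size, x$learning_rate, x$loss, x$seed))
  invisible(x)
}

# Run code with a temporary RNG state seeded by `seed`; restores the
# caller's stream afterwards so library calls never perturb user RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Build an untrained network
#'
#' Weight initialization is variance-scaled Gaussian (He scaling
#' `sqrt(2/fan_in)` for the ReLU layer, Glorot `sqrt(2/(fan_in+fan_out))`
#' elsewhere), drawn from the config seed; biases start at zero.
#'
#' @param config a [model_config].
#' @param input_width length of the pair encoding vector.
#' @param n_events number of event classes.
#' @return Object of class `ddi_net` (untrained).
#' @export
build_model <- function(config, input_width, n_events) {
  if (input_width < 1L || n_events < 1L)
    stop("build_model: input_width and n_events must be >= 1")
  sizes <- c(input_width, config$hidden_sizes, n_events)
  L <- length(sizes) - 1L
  with_seed(config$seed, {
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
      sd <- if (l == 1L && length(config$hidden_sizes))
        sqrt(2 / fan_in) else sqrt(2 / (fan_in + fan_out))
      W[[l]] <- matrix(stats::rnorm(fan_in * fan_out, sd = sd), fan_in, fan_out)
      b[[l]] <- numeric(fan_out)
    }
    structure(list(config = config, input_width = as.integer(input_width),
                   n_events = as.integer(n_events), W = W, b = b,
                   trained = FALSE, loss_history = numeric(0)),
              class = "ddi_net")
  })
}

#' @export
print.ddi_net <- function(x, ...) {
  cat(sprintf("<ddi_net: %d -> [%s] -> %d, %s, %s>\n",
              x$input_width, paste(x$config$hidden_sizes, collapse = ", "),
              x$n_events, x$config$loss,
              if (x$trained) sprintf("trained (final loss %.4f)", utils::tail(x$loss_history, 1))
              else "untrained"))
  invisible(x)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass. Hidden activation: ReLU on layer 1, sigmoid on deeper
# hidden layers; softmax on the output. Returns, per layer, the input it
# consumed (post-dropout), its pre-dropout activation (needed for the
# activation derivative), and the inverted-dropout mask when training.
net_forward <- function(model, X, training = FALSE) {
  L <- length(model$W)
  nh <- length(model$config$hidden_sizes)
  rate <- model$config$dropout_rate
  inputs <- vector("list", L); acts <- vector("list", L); masks <- vector("list", L)
  cur <- X
  for (l in seq_len(L)) {
    inputs[[l]] <- cur
    Z <- cur %*% model$W[[l]]
    Z <- sweep(Z, 2L, model$b[[l]], `+`)
    if (l <= nh) {
      H <- if (l == 1L) pmax(Z, 0) else sigmoid(Z)
      acts[[l]] <- H
      if (training && rate > 0) {
        mask <- matrix(stats::rbinom(length(H), 1L, 1 - rate), nrow(H), ncol(H)) / (1 - rate)
        H <- H * mask
        masks[[l]] <- mask
      }
      cur <- H
    } else {
      cur <- softmax_rows(Z)
      acts[[l]] <- cur
    }
  }
  list(inputs = inputs, acts = acts, masks = masks, out = cur)
}

# Loss and gradient at the softmax output. Y is one-hot (n x k), P the
# predicted probabilities. categorical: standard CE; bce: mean per-class
# binary CE of the softmax output (gradient routed through the softmax
# Jacobian).
output_grad <- function(P, Y, loss) {
  n <- nrow(P)
  eps <- 1e-12
  if (loss == "categorical") {
    value <- -sum(Y * log(P + eps)) / n
    grad <- (P - Y) / n                      # d(CE)/d(logits)
  } else {
    value <- -sum(Y * log(P + eps) + (1 - Y) * log(1 - P + eps)) / (n * ncol(P))
    dP <- (-(Y / (P + eps)) + (1 - Y) / (1 - P + eps)) / (n * ncol(P))
    grad <- P * (dP - rowSums(dP * P))       # softmax Jacobian applied rowwise
  }
  list(value = value, grad = grad)
}

#' Train a network on encoded drug pairs
#'
#' Minibatch Adam on (by default) categorical cross-entropy against one-hot
#' event targets, for exactly `config$epochs` passes — no early stopping, no
#' validation checkpointing. With a fixed config seed, two runs on identical
#' inputs produce identical parameters, loss trajectories and predictions.
#'
#' @param model an untrained [build_model()] network (or one to keep training).
#' @param X numeric matrix of encoded pairs (rows) matching `input_width`.
#' @param y integer event indices in `1..n_events`.
#' @param log_file optional path; per-epoch loss lines are appended.
#' @return The trained `ddi_net` (with `loss_history`).
#' @export
train_model <- function(model, X, y, log_file = NULL) {
  if (ncol(X) != model$input_width)
    stop("train_model: X has ", ncol(X), " columns, model expects ", model$input_width)
  y <- as.integer(y)
  if (any(y < 1L | y > model$n_events)) stop("train_model: event index out of range")
  absent <- setdiff(seq_len(model$n_events), unique(y))
  if (length(absent))
    warning("train_model: event(s) ", paste(absent, collapse = ", "),
            " absent from training labels; unlearnable this fold")
  cfg <- model$config
  n <- nrow(X)
  Y <- matrix(0, n, model$n_events); Y[cbind(seq_len(n), y)] <- 1
  L <- length(model$W)
  nh <- length(cfg$hidden_sizes)
  # Adam state
  mW <- lapply(model$W, function(w) w * 0); vW <- mW
  mb <- lapply(model$b, function(b) b * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0L
  lr <- cfg$learning_rate
  # train-phase RNG offset so retraining a built model does not replay the
  # initialization stream
  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      starts <- seq.int(1L, n, by = cfg$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        idx <- perm[s:min(s + cfg$batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
        fw <- net_forward(model, Xb, training = TRUE)
        og <- output_grad(fw$out, Yb, cfg$loss)
        epoch_loss <- epoch_loss + og$value * length(idx)
        delta <- og$grad                       # gradient wrt layer-L logits
        for (l in rev(seq_len(L))) {
          gW <- crossprod(fw$inputs[[l]], delta)
          gb <- colSums(delta)
          if (l > 1L) {
            back <- delta %*% t(model$W[[l]])
            h <- l - 1L                        # hidden layer feeding this one
            if (!is.null(fw$masks[[h]])) back <- back * fw$masks[[h]]
            act <- fw$acts[[h]]                # pre-dropout activation
            delta <- if (h == 1L) back * (act > 0) else back * act * (1 - act)
          }
          t_here <- t + 1L
          mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
          vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
          mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
          vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
          mhW <- mW[[l]] / (1 - b1^t_here); vhW <- vW[[l]] / (1 - b2^t_here)
          mhb <- mb[[l]] / (1 - b1^t_here); vhb <- vb[[l]] / (1 - b2^t_here)
          model$W[[l]] <- model$W[[l]] - lr * mhW / (sqrt(vhW) + eps)
          model$b[[l]] <- model$b[[l]] - lr * mhb / (sqrt(vhb) + eps)
        }
        t <- t + 1L
      }
      model$loss_history <- c(model$loss_history, epoch_loss / n)
      if (!is.null(log_file))
        cat(sprintf("epoch %d loss %.6f seed %d\n", epoch, epoch_loss / n, cfg$seed),
            file = log_file, append = TRUE)
    }
  })
  model$trained <- TRUE
  model
}

#' Build and train in one call
#' @inheritParams train_model
#' @param config a [model_config].
#' @param n_events number of event classes (defaults to `max(y)`).
#' @return Trained `ddi_net`.
#' @export
fit_ddi_net <- function(X, y, config = model_config(), n_events = max(y), log_file = NULL) {
  train_model(build_model(config, ncol(X), n_events), X, y, log_file = log_file)
}

#' Predict event probabilities
#'
#' Dropout is disabled at inference; each output row is a probability
#' distribution over the n event types (sums to 1 within 1e-6).
#'
#' @param model a trained `ddi_net`.
#' @param X encoded pair matrix.
#' @return Row-stochastic matrix, one row per pair, `n_events` columns.
#' @export
predict_proba <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != model$input_width)
    stop("predict_proba: X has ", ncol(X), " columns, model expects ", model$input_width)
  net_forward(model, X, training = FALSE)$out
}

#' Hard event call from a probability matrix
#'
#' Argmax per row; ties broken by the lowest event index.
#'
#' @param probas row-stochastic matrix.
#' @return Integer vector of event indices (1-based).
#' @export
predict_event <- function(probas) {
  if (is.null(dim(probas))) probas <- matrix(probas, nrow = 1L)
  max.col(probas, ties.method = "first")
}

#' Save / load a trained model as plain JSON-like text
#'
#' A single self-describing text file holding the config and all parameters
#' at full precision (via [dput()] serialization of a plain list).
#'
#' @param model a `ddi_net`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  x <- unclass(model)
  x$config <- unclass(x$config)
  dput(x, file = path, control = c("exact", "showAttributes"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- dget(path)
  x$config <- structure(x$config, class = "model_config")
  structure(x, class = "ddi_net")
}
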