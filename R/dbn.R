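#' Fine-tuning (backpropagation) configuration
#'
#' @param learning_rate positive step size for mini-batch gradient descent.
#' @param epochs passes over the training data (0 leaves the network
#'   unchanged).
#' @param batch_size mini-batch size.
#' @param seed integer controlling shuffling and output-layer
#'   initialization.
#' @param patience early-stop patience in epochs on the training loss;
#'   \code{Inf} (default) disables early stopping.
#' @return object of class \code{finetune_config}.
#' @export
finetune_config <- function(learning_rate = 0.5, epochs = 200, batch_size = 32,
                            seed = 1L, patience = Inf) {
  stopifnot(learning_rate >= 0, epochs >= 0, batch_size >= 1, patience > 0)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 patience = patience),
            class = "finetune_config")
}

#' Greedy layer-wise pretraining of a deep belief network
#'
#' Trains a stack of RBMs bottom-up: the first on the scaled feature rows,
#' each subsequent RBM on the hidden activation probabilities of the layer
#' below. Layer seeds are derived from \code{rbm_cfg$seed} so the whole
#' stack is deterministic.
#'
#' @param data matrix of rows in \code{[0, 1]} (scaled features).
#' @param hidden_sizes integer vector of hidden-layer widths, e.g.
#'   \code{c(50, 50, 200)} for the 276-50-50-200 architecture on
#'   276-dimensional input.
#' @param rbm_cfg an \code{\link{rbm_config}} shared by all layers.
#' @return object of class \code{dbn}: list with \code{layers} (trained
#'   \code{rbm} objects), \code{layer_sizes} and \code{state =
#'   "pretrained"}.
#' @export
pretrain_dbn <- function(data, hidden_sizes, rbm_cfg = rbm_config()) {
  data <- as.matrix(data)
  stopifnot(length(hidden_sizes) >= 1, all(hidden_sizes >= 1))
  layers <- vector("list", length(hidden_sizes))
  input <- data
  for (l in seq_along(hidden_sizes)) {
    cfg_l <- rbm_cfg
    cfg_l$seed <- derive_seed(rbm_cfg$seed, l)
    layers[[l]] <- train_rbm(input, hidden_sizes[l], cfg_l)
    input <- rbm_hidden_prob(input, layers[[l]])
  }
  structure(list(layers = layers,
                 layer_sizes = c(ncol(data), as.integer(hidden_sizes)),
                 state = "pretrained"),
            class = "dbn")
}

#' @export
print.dbn <- function(x, ...) {
  cat(sprintf("<dbn: %s (%s)>\n", paste(x$layer_sizes, collapse = "-"), x$state))
  invisible(x)
}

#' Attach a sigmoid output unit to a pretrained DBN
#'
#' Builds the classifier network: the DBN's weights and hidden biases
#' become the hidden layers of a feed-forward sigmoid network, topped by a
#' single sigmoid output unit (small seeded random weights) whose output is
#' read as the enhancer probability.
#'
#' @param dbn a pretrained \code{\link{pretrain_dbn}} stack, or \code{NULL}
#'   together with \code{layer_sizes} for a randomly initialized network of
#'   the same shape (the no-pretraining baseline).
#' @param seed seed for the output-layer (and, without a DBN, hidden-layer)
#'   initialization.
#' @param layer_sizes required when \code{dbn} is \code{NULL}.
#' @return object of class \code{dbn_classifier} with weights \code{W}
#'   (list, one matrix per layer plus the output column), biases \code{bias},
#'   \code{state = "initialized"} and an empty training history.
#' @export
build_classifier <- function(dbn = NULL, seed = 1L, layer_sizes = NULL) {
  if (!is.null(dbn)) {
    stopifnot(inherits(dbn, "dbn"))
    sizes <- dbn$layer_sizes
    W <- lapply(dbn$layers, function(r) r$W)
    bias <- lapply(dbn$layers, function(r) r$a)
    pretrained <- TRUE
  } else {
    stopifnot(!is.null(layer_sizes), length(layer_sizes) >= 2)
    sizes <- as.integer(layer_sizes)
    with_seed(derive_seed(seed, 777L), {
      W <- lapply(seq_len(length(sizes) - 1), function(l) {
        matrix(rnorm(sizes[l] * sizes[l + 1], sd = 0.01), sizes[l], sizes[l + 1])
      })
    })
    bias <- lapply(sizes[-1], function(n) rep(0, n))
    pretrained <- FALSE
  }
  top <- sizes[length(sizes)]
  with_seed(derive_seed(seed, 778L), {
    W[[length(W) + 1]] <- matrix(rnorm(top, sd = 0.01), top, 1)
  })
  bias[[length(bias) + 1]] <- 0
  structure(list(W = W, bias = bias, layer_sizes = c(sizes, 1L),
                 pretrained = pretrained, state = "initialized",
                 history = numeric(0)),
            class = "dbn_classifier")
}

#' @export
print.dbn_classifier <- function(x, ...) {
  cat(sprintf("<dbn_classifier: %s (%s%s)>\n",
              paste(x$layer_sizes, collapse = "-"), x$state,
              if (x$pretrained) ", pretrained" else ", random init"))
  invisible(x)
}

#' Deterministic forward pass
#'
#' Propagates rows through every sigmoid layer and the sigmoid output unit;
#' no sampling, so identical inputs give identical outputs.
#'
#' @param net a \code{\link{build_classifier}} network.
#' @param X matrix of rows in \code{[0, 1]} matching the input width.
#' @return numeric vector of enhancer probabilities in \code{(0, 1)}.
#' @export
dbn_forward <- function(net, X) {
  stopifnot(inherits(net, "dbn_classifier"))
  X <- as.matrix(X)
  if (ncol(X) != net$layer_sizes[1]) {
    stopf("input has %d columns; network expects %d", ncol(X), net$layer_sizes[1])
  }
  act <- X
  for (l in seq_along(net$W)) {
    act <- sigmoid(sweep(act %*% net$W[[l]], 2, net$bias[[l]], "+"))
  }
  as.numeric(act)
}

# Forward pass keeping all layer activations (needed by backprop).
forward_activations <- function(net, X) {
  acts <- vector("list", length(net$W) + 1)
  acts[[1]] <- as.matrix(X)
  for (l in seq_along(net$W)) {
    acts[[l + 1]] <- sigmoid(sweep(acts[[l]] %*% net$W[[l]], 2, net$bias[[l]], "+"))
  }
  acts
}

# Mean binary cross-entropy and its analytic gradients for one batch.
# With sigmoid output p and BCE loss, the output delta is (p - y)/n; hidden
# deltas follow the chain rule through a * (1 - a).
bp_gradients <- function(net, X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  acts <- forward_activations(net, X)
  p <- acts[[length(acts)]]
  eps <- 1e-12
  loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  gW <- vector("list", length(net$W))
  gb <- vector("list", length(net$W))
  delta <- (p - y) / n
  for (l in rev(seq_along(net$W))) {
    gW[[l]] <- t(acts[[l]]) %*% delta
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      a_prev <- acts[[l]]
      delta <- (delta %*% t(net$W[[l]])) * a_prev * (1 - a_prev)
    }
  }
  list(loss = loss, gW = gW, gb = gb)
}

#' Supervised fine-tuning by backpropagation
#'
#' Minimizes binary cross-entropy by mini-batch gradient descent, updating
#' every layer (pretrained weights are a starting point, not frozen).
#' Records per-epoch mean training loss; deterministic given
#' \code{config$seed}.
#'
#' @param net a \code{\link{build_classifier}} network.
#' @param X matrix of training rows in \code{[0, 1]}.
#' @param y binary labels (0/1), one per row.
#' @param config a \code{\link{finetune_config}}.
#' @return the fine-tuned network (\code{state = "finetuned"}, per-epoch
#'   loss in \code{$history}).
#' @export
finetune <- function(net, X, y, config = finetune_config()) {
  stopifnot(inherits(net, "dbn_classifier"), inherits(config, "finetune_config"))
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stopf("labels (%d) do not match rows (%d)",
                                  length(y), nrow(X))
  if (!all(y %in% c(0, 1))) stopf("labels must be binary 0/1")
  with_seed(config$seed, {
    history <- numeric(config$epochs)
    best <- Inf; stall <- 0
    for (epoch in seq_len(config$epochs)) {
      idx <- sample.int(nrow(X))
      starts <- seq(1, nrow(X), by = config$batch_size)
      losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        rows <- idx[starts[bi]:min(starts[bi] + config$batch_size - 1, nrow(X))]
        g <- bp_gradients(net, X[rows, , drop = FALSE], y[rows])
        for (l in seq_along(net$W)) {
          net$W[[l]] <- net$W[[l]] - config$learning_rate * g$gW[[l]]
          net$bias[[l]] <- net$bias[[l]] - config$learning_rate * g$gb[[l]]
        }
        losses[bi] <- g$loss
      }
      history[epoch] <- mean(losses)
      if (history[epoch] < best - 1e-6) { best <- history[epoch]; stall <- 0 }
      else stall <- stall + 1
      if (stall >= config$patience) { history <- history[seq_len(epoch)]; break }
    }
    net$history <- history
    net$state <- "finetuned"
    net
  })
}

#' Predict enhancer labels
#'
#' @param object a fine-tuned \code{dbn_classifier}.
#' @param X matrix of rows in \code{[0, 1]}.
#' @param threshold probability cut-off; a row is called positive when its
#'   probability is \eqn{\ge} the threshold (boundary counts as positive).
#' @param ... unused.
#' @return data.frame with \code{id} (rownames of \code{X} if present),
#'   \code{probability} and \code{label} (0/1).
#' @export
predict.dbn_classifier <- function(object, X, threshold = 0.5, ...) {
  if (!identical(object$state, "finetuned")) {
    stopf("network must be fine-tuned before prediction")
  }
  p <- dbn_forward(object, X)
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("row_%05d", seq_along(p))
  data.frame(id = ids, probability = p,
             label = as.integer(p >= threshold),
             stringsAsFactors = FALSE)
}
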