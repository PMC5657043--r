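#' Restricted Boltzmann machine parameters
#'
#' An RBM over binary visible units \eqn{v} and binary hidden units \eqn{h}
#' with energy
#' \deqn{E(v, h) = -v^\top W h - b^\top v - a^\top h,}
#' where \code{W} holds the symmetric visible-hidden interactions, \code{b}
#' the visible biases and \code{a} the hidden biases. The conditionals are
#' \eqn{P(h_j = 1 | v) = \sigma(\sum_i W_{ij} v_i + a_j)} and
#' \eqn{P(v_i = 1 | h) = \sigma(\sum_j W_{ij} h_j + b_i)}.
#'
#' @param W numeric matrix, \code{n_visible x n_hidden}.
#' @param b visible biases (length \code{n_visible}).
#' @param a hidden biases (length \code{n_hidden}).
#' @return object of class \code{rbm}.
#' @export
rbm_params <- function(W, b, a) {
  W <- as.matrix(W)
  if (length(b) != nrow(W) || length(a) != ncol(W)) {
    stopf("rbm shapes inconsistent: W is %dx%d, length(b)=%d, length(a)=%d",
          nrow(W), ncol(W), length(b), length(a))
  }
  if (!all(is.finite(W)) || !all(is.finite(b)) || !all(is.finite(a))) {
    stopf("rbm parameters must be finite")
  }
  structure(list(W = W, b = as.numeric(b), a = as.numeric(a)), class = "rbm")
}

# Seeded small-random initialization: weights ~ N(0, 0.01^2), biases zero.
init_rbm <- function(n_visible, n_hidden, seed = 1L) {
  with_seed(seed, {
    rbm_params(matrix(rnorm(n_visible * n_hidden, sd = 0.01), n_visible, n_hidden),
               b = rep(0, n_visible), a = rep(0, n_hidden))
  })
}

#' @export
print.rbm <- function(x, ...) {
  cat(sprintf("<rbm: %d visible x %d hidden>\n", nrow(x$W), ncol(x$W)))
  invisible(x)
}

#' RBM training configuration
#'
#' Hyperparameters for contrastive-divergence training. Defaults follow
#' common small-RBM practice: CD-1, learning rate 0.1, 50 epochs,
#' mini-batches of 32, momentum 0.5 on the weights, weight decay 1e-4.
#'
#' @param learning_rate positive step size.
#' @param epochs full passes over the data.
#' @param batch_size mini-batch size.
#' @param cd_steps Gibbs rounds per update (k in CD-k).
#' @param momentum in \code{[0, 1)}, applied to all parameter updates.
#' @param weight_decay L2 penalty on \code{W} only.
#' @param seed integer controlling initialization, shuffling and sampling.
#' @return object of class \code{rbm_config}.
#' @export
rbm_config <- function(learning_rate = 0.1, epochs = 50, batch_size = 32,
                       cd_steps = 1, momentum = 0.5, weight_decay = 1e-4,
                       seed = 1L) {
  stopifnot(learning_rate >= 0, epochs >= 0, batch_size >= 1, cd_steps >= 1,
            momentum >= 0, momentum < 1, weight_decay >= 0)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 cd_steps = as.integer(cd_steps), momentum = momentum,
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "rbm_config")
}

#' RBM energy of a joint configuration
#'
#' @param v visible vector (binary or in \code{[0, 1]}).
#' @param h hidden binary vector.
#' @param params an \code{\link{rbm_params}}.
#' @return \eqn{-v^\top W h - b^\top v - a^\top h}.
#' @export
rbm_energy <- function(v, h, params) {
  stopifnot(inherits(params, "rbm"))
  if (length(v) != nrow(params$W) || length(h) != ncol(params$W)) {
    stopf("configuration shape does not match the model")
  }
  -as.numeric(t(v) %*% params$W %*% h) - sum(params$b * v) - sum(params$a * h)
}

# All binary vectors of length n as rows of a 2^n x n matrix (test oracle).
binary_configs <- function(n) {
  if (n == 0) return(matrix(numeric(0), nrow = 1, ncol = 0))
  as.matrix(expand.grid(rep(list(c(0, 1)), n)))[, n:1, drop = FALSE]
}

#' Exact partition function by enumeration
#'
#' Sums \eqn{\exp(-E(v, h))} over all \eqn{2^{n_v + n_h}} binary
#' configurations. Exponential in the model size; intended as an exactness
#' oracle for tiny models and refused above 20 total units.
#'
#' @param params an \code{\link{rbm_params}} with
#'   \code{n_visible + n_hidden <= 20}.
#' @return the positive normalizer \eqn{Z}.
#' @export
rbm_partition_function <- function(params) {
  stopifnot(inherits(params, "rbm"))
  n_v <- nrow(params$W); n_h <- ncol(params$W)
  if (n_v + n_h > 20) {
    stopf("refusing exact enumeration for %d total units (limit 20)", n_v + n_h)
  }
  V <- binary_configs(n_v); H <- binary_configs(n_h)
  # E over all pairs: -(V W) H' - b V' - a H'
  inter <- (V %*% params$W) %*% t(H)
  z <- exp(sweep(sweep(inter, 1, as.numeric(V %*% params$b), "+"),
                 2, as.numeric(H %*% params$a), "+"))
  sum(z)
}

#' Exact joint probability of a configuration
#'
#' \eqn{P(v, h) = \exp(-E(v, h)) / Z}; tiny models only (see
#' \code{\link{rbm_partition_function}}).
#'
#' @inheritParams rbm_energy
#' @return probability in \code{(0, 1]}.
#' @export
rbm_joint_probability <- function(v, h, params) {
  exp(-rbm_energy(v, h, params)) / rbm_partition_function(params)
}

#' Hidden-unit activation probabilities given visibles
#'
#' \eqn{P(h_j = 1 | v) = \sigma(\sum_i W_{ij} v_i + a_j)}. Accepts a single
#' visible vector or a matrix with one configuration per row.
#'
#' @param v visible vector, or matrix of rows.
#' @param params an \code{\link{rbm_params}}.
#' @return vector (or matrix of rows) of probabilities in \code{(0, 1)}.
#' @export
rbm_hidden_prob <- function(v, params) {
  stopifnot(inherits(params, "rbm"))
  if (is.matrix(v)) {
    if (ncol(v) != nrow(params$W)) stopf("visible dimension mismatch")
    sigmoid(sweep(v %*% params$W, 2, params$a, "+"))
  } else {
    if (length(v) != nrow(params$W)) stopf("visible dimension mismatch")
    as.numeric(sigmoid(as.numeric(v %*% params$W) + params$a))
  }
}

#' Visible-unit activation probabilities given hiddens
#'
#' \eqn{P(v_i = 1 | h) = \sigma(\sum_j W_{ij} h_j + b_i)}; the mirror of
#' \code{\link{rbm_hidden_prob}}.
#'
#' @param h hidden vector, or matrix of rows.
#' @param params an \code{\link{rbm_params}}.
#' @return vector (or matrix of rows) of probabilities in \code{(0, 1)}.
#' @export
rbm_visible_prob <- function(h, params) {
  stopifnot(inherits(params, "rbm"))
  if (is.matrix(h)) {
    if (ncol(h) != ncol(params$W)) stopf("hidden dimension mismatch")
    sigmoid(sweep(h %*% t(params$W), 2, params$b, "+"))
  } else {
    if (length(h) != ncol(params$W)) stopf("hidden dimension mismatch")
    as.numeric(sigmoid(as.numeric(params$W %*% h) + params$b))
  }
}

#' One contrastive-divergence parameter update
#'
#' Runs CD-k on one mini-batch. The positive phase uses hidden
#' probabilities; the negative phase alternates sampled hidden states with
#' mean-field visible reconstructions for \code{cd_steps} rounds. Gradients
#' (data minus reconstruction statistics, averaged over the batch) update
#' \code{W, a, b} by gradient ascent with momentum and L2 weight decay on
#' \code{W}. The caller controls the RNG; within
#' \code{\link{train_rbm}} the config seed fixes the full stream.
#'
#' @param batch matrix of visible rows, values in \code{[0, 1]}.
#' @param params an \code{\link{rbm_params}}.
#' @param config an \code{\link{rbm_config}}.
#' @param velocity optional momentum state from the previous update (list
#'   \code{W}, \code{b}, \code{a}).
#' @return list with \code{params} (updated), \code{velocity}, \code{grad}
#'   (the raw CD gradient of \code{W}, before decay/momentum) and
#'   \code{recon_error} (mean squared reconstruction error).
#' @export
cd_update <- function(batch, params, config, velocity = NULL) {
  stopifnot(inherits(params, "rbm"), inherits(config, "rbm_config"))
  batch <- as.matrix(batch)
  if (any(batch < 0) || any(batch > 1)) {
    stopf("visible data must lie in [0, 1]; scale features first")
  }
  n <- nrow(batch)
  if (is.null(velocity)) {
    velocity <- list(W = params$W * 0, b = params$b * 0, a = params$a * 0)
  }

  ph_data <- rbm_hidden_prob(batch, params)
  h_state <- matrix(as.numeric(runif(length(ph_data)) < ph_data), nrow = n)
  v_model <- batch
  for (step in seq_len(config$cd_steps)) {
    v_model <- rbm_visible_prob(h_state, params)
    ph_model <- rbm_hidden_prob(v_model, params)
    if (step < config$cd_steps) {
      h_state <- matrix(as.numeric(runif(length(ph_model)) < ph_model), nrow = n)
    }
  }

  grad_W <- (t(batch) %*% ph_data - t(v_model) %*% ph_model) / n
  grad_b <- colMeans(batch) - colMeans(v_model)
  grad_a <- colMeans(ph_data) - colMeans(ph_model)

  eps <- config$learning_rate
  velocity$W <- config$momentum * velocity$W +
    eps * (grad_W - config$weight_decay * params$W)
  velocity$b <- config$momentum * velocity$b + eps * grad_b
  velocity$a <- config$momentum * velocity$a + eps * grad_a

  params <- rbm_params(params$W + velocity$W, params$b + velocity$b,
                       params$a + velocity$a)
  list(params = params, velocity = velocity, grad = grad_W,
       recon_error = mean((batch - v_model)^2))
}

#' Train an RBM by contrastive divergence
#'
#' Seeded small-random initialization followed by \code{epochs} passes of
#' shuffled mini-batch CD-k updates. Deterministic given
#' \code{config$seed}.
#'
#' @param data matrix of visible rows in \code{[0, 1]}.
#' @param n_hidden number of hidden units.
#' @param config an \code{\link{rbm_config}}.
#' @return trained \code{\link{rbm_params}} with attribute
#'   \code{"recon_error"}: per-epoch mean squared reconstruction error.
#' @export
train_rbm <- function(data, n_hidden, config = rbm_config()) {
  data <- as.matrix(data)
  if (nrow(data) == 0) stopf("cannot train an RBM on empty data")
  if (any(data < 0) || any(data > 1)) stopf("training data must lie in [0, 1]")
  with_seed(config$seed, {
    params <- rbm_params(
      matrix(rnorm(ncol(data) * n_hidden, sd = 0.01), ncol(data), n_hidden),
      b = rep(0, ncol(data)), a = rep(0, n_hidden)
    )
    velocity <- NULL
    epoch_err <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      idx <- sample.int(nrow(data))
      starts <- seq(1, nrow(data), by = config$batch_size)
      errs <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        rows <- idx[starts[bi]:min(starts[bi] + config$batch_size - 1, nrow(data))]
        upd <- cd_update(data[rows, , drop = FALSE], params, config, velocity)
        params <- upd$params
        velocity <- upd$velocity
        errs[bi] <- upd$recon_error
      }
      epoch_err[epoch] <- mean(errs)
    }
    attr(params, "recon_error") <- epoch_err
    params
  })
}

# Exact mean log-likelihood of visible rows under a tiny RBM (enumeration).
# log P(v) = log sum_h exp(-E(v,h)) - log Z. Oracle for training dynamics.
rbm_exact_loglik <- function(data, params) {
  n_h <- ncol(params$W)
  H <- binary_configs(n_h)
  logZ <- log(rbm_partition_function(params))
  data <- as.matrix(data)
  inter <- sweep((data %*% params$W) %*% t(H), 2,
                 as.numeric(H %*% params$a), "+")
  unnorm <- inter + as.numeric(data %*% params$b)
  mean(log(rowSums(exp(unnorm))) - logZ)
}
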