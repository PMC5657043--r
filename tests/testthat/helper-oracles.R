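# Independent oracles used across the suite. These deliberately avoid the
# package's own linear-algebra paths: plain loops and full enumeration only,
# so agreement is evidence, not tautology.

# energy by elementwise loops
oracle_energy <- function(v, h, W, b, a) {
  e <- 0
  for (i in seq_along(v)) for (j in seq_along(h)) e <- e - W[i, j] * v[i] * h[j]
  for (i in seq_along(v)) e <- e - b[i] * v[i]
  for (j in seq_along(h)) e <- e - a[j] * h[j]
  e
}

# all binary vectors of length n, as a list
oracle_configs <- function(n) {
  lapply(seq_len(2^n) - 1, function(x) as.integer(intToBits(x)[seq_len(n)]))
}

oracle_partition <- function(W, b, a) {
  z <- 0
  for (v in oracle_configs(nrow(W))) for (h in oracle_configs(ncol(W))) {
    z <- z + exp(-oracle_energy(v, h, W, b, a))
  }
  z
}

# P(h_j = 1 | v) from the joint by enumeration over h
oracle_hidden_conditional <- function(v, W, b, a) {
  n_h <- ncol(W)
  num <- numeric(n_h); den <- 0
  for (h in oracle_configs(n_h)) {
    p <- exp(-oracle_energy(v, h, W, b, a))
    den <- den + p
    num <- num + p * h
  }
  num / den
}

oracle_visible_conditional <- function(h, W, b, a) {
  n_v <- nrow(W)
  num <- numeric(n_v); den <- 0
  for (v in oracle_configs(n_v)) {
    p <- exp(-oracle_energy(v, h, W, b, a))
    den <- den + p
    num <- num + p * v
  }
  num / den
}

# exact gradient of the mean log-likelihood w.r.t. W:
# dL/dW_ij = <v_i P(h_j=1|v)>_data - <v_i h_j>_model
oracle_loglik_gradient <- function(data, W, b, a) {
  n_v <- nrow(W); n_h <- ncol(W)
  pos <- matrix(0, n_v, n_h)
  for (r in seq_len(nrow(data))) {
    v <- data[r, ]
    ph <- oracle_hidden_conditional(v, W, b, a)
    pos <- pos + outer(v, ph)
  }
  pos <- pos / nrow(data)
  z <- oracle_partition(W, b, a)
  neg <- matrix(0, n_v, n_h)
  for (v in oracle_configs(n_v)) for (h in oracle_configs(n_h)) {
    p <- exp(-oracle_energy(v, h, W, b, a)) / z
    neg <- neg + p * outer(as.numeric(v), as.numeric(h))
  }
  pos - neg
}

# per-base signal sum by brute force
oracle_signal_sum <- function(track_df, chrom, start, end) {
  total <- 0
  for (base in seq(start, end - 1)) {
    hit <- track_df$chrom == chrom & track_df$start <= base & track_df$end > base
    if (any(hit)) total <- total + track_df$value[hit][1]
  }
  total
}

# AUC as the fraction of concordant positive/negative pairs (ties = 0.5)
oracle_auc <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# naive layer-by-layer forward pass with scalar loops
oracle_forward <- function(Wlist, blist, x) {
  act <- x
  for (l in seq_along(Wlist)) {
    nxt <- numeric(ncol(Wlist[[l]]))
    for (j in seq_len(ncol(Wlist[[l]]))) {
      s <- blist[[l]][j]
      for (i in seq_along(act)) s <- s + act[i] * Wlist[[l]][i, j]
      nxt[j] <- 1 / (1 + exp(-s))
    }
    act <- nxt
  }
  act
}

# small random RBM for oracle comparisons
random_tiny_rbm <- function(n_v, n_h, seed, scale = 0.8) {
  set.seed(seed)
  rbm_params(matrix(rnorm(n_v * n_h, sd = scale), n_v, n_h),
             b = rnorm(n_v, sd = scale), a = rnorm(n_h, sd = scale))
}
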