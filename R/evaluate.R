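#' DBN classifier configuration
#'
#' Bundles the architecture and training hyperparameters used by
#' \code{\link{train_enhancer_model}} and \code{\link{cross_validate}}.
#'
#' @param hidden_sizes hidden-layer widths; the default \code{c(50, 50,
#'   200)} gives the 276-50-50-200 stack on the full 276-feature input.
#' @param rbm an \code{\link{rbm_config}} for pretraining.
#' @param bp a \code{\link{finetune_config}} for backpropagation.
#' @param pretrain logical; \code{FALSE} skips pretraining (random-init
#'   baseline).
#' @param seed master seed; per-stage seeds are derived from it.
#' @return object of class \code{dbn_model_config}.
#' @export
dbn_model_config <- function(hidden_sizes = c(50, 50, 200),
                             rbm = rbm_config(), bp = finetune_config(),
                             pretrain = TRUE, seed = 1L) {
  structure(list(hidden_sizes = as.integer(hidden_sizes), rbm = rbm, bp = bp,
                 pretrain = isTRUE(pretrain), seed = as.integer(seed)),
            class = "dbn_model_config")
}

#' Train the full enhancer classifier on scaled features
#'
#' Pretrains the DBN (unless disabled), attaches the output layer and
#' fine-tunes with backpropagation.
#'
#' @param X matrix of rows in \code{[0, 1]}.
#' @param y binary labels.
#' @param config a \code{\link{dbn_model_config}}.
#' @return a fine-tuned \code{dbn_classifier}.
#' @export
train_enhancer_model <- function(X, y, config = dbn_model_config()) {
  stopifnot(inherits(config, "dbn_model_config"))
  rbm_cfg <- config$rbm; rbm_cfg$seed <- derive_seed(config$seed, 1L)
  bp_cfg <- config$bp; bp_cfg$seed <- derive_seed(config$seed, 2L)
  if (config$pretrain) {
    dbn <- pretrain_dbn(X, config$hidden_sizes, rbm_cfg)
    net <- build_classifier(dbn, seed = derive_seed(config$seed, 3L))
  } else {
    net <- build_classifier(NULL, seed = derive_seed(config$seed, 3L),
                            layer_sizes = c(ncol(X), config$hidden_sizes))
  }
  finetune(net, X, y, bp_cfg)
}

#' Stratified fold assignment for cross-validation
#'
#' Assigns every sample to exactly one of \code{n_folds} folds, shuffling
#' within each label class under the seed and dealing class members out in
#' a global round-robin so fold sizes differ by at most one overall and per
#' class. With the canonical 741 + 741 = 1482 balanced samples and 10
#' folds, eight folds hold 148 samples and two hold 149; training on the
#' complement of a floor-size fold uses 1334 samples.
#'
#' @param labels 0/1 vector.
#' @param n_folds number of folds (>= 2).
#' @param seed integer.
#' @return object of class \code{fold_plan}: list with \code{n_samples},
#'   \code{n_folds}, \code{assignments} (fold index per sample) and
#'   \code{seed}.
#' @export
make_folds <- function(labels, n_folds = 10, seed = 1L) {
  labels <- as.integer(labels)
  n <- length(labels)
  if (n_folds < 2) stopf("n_folds must be at least 2")
  tab <- table(labels)
  if (any(tab < n_folds)) {
    stopf("every class needs at least n_folds members (smallest class: %d)",
          min(tab))
  }
  assignments <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (cls in sort(unique(labels))) {
      members <- sample(which(labels == cls))
      folds <- ((offset + seq_along(members) - 1L) %% n_folds) + 1L
      assignments[members] <- folds
      offset <- (offset + length(members)) %% n_folds
    }
  })
  structure(list(n_samples = n, n_folds = as.integer(n_folds),
                 assignments = assignments, seed = as.integer(seed)),
            class = "fold_plan")
}

#' Classification metrics
#'
#' Error rate and accuracy at a probability threshold (boundary counts as
#' positive), plus the ROC AUC computed as the Wilcoxon rank statistic with
#' midrank tie handling (ties credit 0.5), equal to the fraction of
#' concordant positive/negative pairs.
#'
#' @param y_true 0/1 labels.
#' @param y_prob probabilities in \code{[0, 1]}.
#' @param threshold decision threshold (default 0.5).
#' @return list with \code{error_rate}, \code{accuracy}, \code{auc}.
#' @export
classification_metrics <- function(y_true, y_prob, threshold = 0.5) {
  y_true <- as.integer(y_true)
  stopifnot(length(y_true) == length(y_prob),
            all(y_prob >= 0 & y_prob <= 1))
  n_pos <- sum(y_true == 1); n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) {
    stopf("AUC undefined: y_true contains a single class")
  }
  pred <- as.integer(y_prob >= threshold)
  acc <- mean(pred == y_true)
  r <- rank(y_prob)  # midranks handle ties with 0.5 credit
  auc <- (sum(r[y_true == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  list(error_rate = 1 - acc, accuracy = acc, auc = auc)
}

#' k-fold cross-validation of the DBN classifier
#'
#' For each fold: fits the min-max scaler on the training rows only,
#' transforms both partitions, trains a fresh classifier from a
#' fold-derived seed, and evaluates on the held-out fold. Mean error rate
#' is the average over folds; ROC/AUC is computed on the pooled held-out
#' probabilities.
#'
#' @param fm a raw \code{feature_matrix} with 0/1 labels.
#' @param feature_columns column names (or indices) to use; default all.
#' @param config a \code{\link{dbn_model_config}}.
#' @param fold_plan a \code{\link{make_folds}} plan for \code{nrow(fm$X)}
#'   samples.
#' @param combination_label free-text tag stored in the report.
#' @return object of class \code{eval_report}: \code{per_fold} data.frame
#'   (fold, n_test, error_rate, accuracy), \code{mean_error_rate},
#'   \code{mean_accuracy}, \code{auc}, pooled \code{roc} points and
#'   \code{combination}.
#' @export
cross_validate <- function(fm, feature_columns = NULL,
                           config = dbn_model_config(),
                           fold_plan = NULL,
                           combination_label = "all features") {
  stopifnot(inherits(fm, "feature_matrix"))
  if (fm$scaling != "raw") stopf("cross_validate expects raw features; scaling is fitted per fold")
  y <- as.integer(fm$labels)
  if (any(is.na(y))) stopf("all samples need 0/1 labels for cross-validation")
  if (is.null(fold_plan)) fold_plan <- make_folds(y, seed = config$seed)
  stopifnot(inherits(fold_plan, "fold_plan"),
            fold_plan$n_samples == nrow(fm$X))
  if (is.null(feature_columns)) feature_columns <- colnames(fm$X)

  probs <- rep(NA_real_, nrow(fm$X))
  per_fold <- data.frame(fold = seq_len(fold_plan$n_folds), n_test = 0L,
                         error_rate = NA_real_, accuracy = NA_real_)
  for (f in seq_len(fold_plan$n_folds)) {
    test_idx <- which(fold_plan$assignments == f)
    train_idx <- setdiff(seq_len(nrow(fm$X)), test_idx)
    sub <- fm
    sub$X <- fm$X[, feature_columns, drop = FALSE]
    sub$families <- fm$families[match(colnames(sub$X), colnames(fm$X))]
    sc <- scale_features(sub, fit_rows = train_idx)
    Xs <- sc$fm$X
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 100L + f)
    net <- train_enhancer_model(Xs[train_idx, , drop = FALSE], y[train_idx], cfg)
    p <- dbn_forward(net, Xs[test_idx, , drop = FALSE])
    probs[test_idx] <- p
    m <- classification_metrics(y[test_idx], p)
    per_fold$n_test[f] <- length(test_idx)
    per_fold$error_rate[f] <- m$error_rate
    per_fold$accuracy[f] <- m$accuracy
  }
  pooled <- classification_metrics(y, probs)
  structure(list(per_fold = per_fold,
                 mean_error_rate = mean(per_fold$error_rate),
                 mean_accuracy = mean(per_fold$accuracy),
                 auc = pooled$auc,
                 roc = roc_points(y, probs),
                 probabilities = probs,
                 combination = combination_label,
                 fold_plan = fold_plan),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %s | %d folds | mean error %.4f | AUC %.4f>\n",
              x$combination, nrow(x$per_fold), x$mean_error_rate, x$auc))
  invisible(x)
}

# ROC curve points (FPR, TPR) over all probability cut-offs.
roc_points <- function(y_true, y_prob) {
  ord <- order(y_prob, decreasing = TRUE)
  y <- y_true[ord]
  tpr <- cumsum(y == 1) / sum(y == 1)
  fpr <- cumsum(y == 0) / sum(y == 0)
  keep <- !duplicated(y_prob[ord], fromLast = TRUE)
  data.frame(fpr = c(0, fpr[keep]), tpr = c(0, tpr[keep]))
}

#' Feature-family ablation protocol
#'
#' Runs cross-validation on the four standard feature combinations —
#' histone + k-mer sequence; plus GC; plus methylation; plus both — with
#' identical folds, so differences in error rate reflect the feature
#' families alone.
#'
#' @inheritParams cross_validate
#' @return named list of four \code{eval_report}s:
#'   \code{histone_sequence}, \code{histone_sequence_gc},
#'   \code{histone_sequence_methylation},
#'   \code{histone_sequence_methylation_gc}.
#' @export
ablation_suite <- function(fm, config = dbn_model_config(), fold_plan = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  fam <- fm$families
  need <- c("kmer", "GC", "methylation", "histone")
  missing <- setdiff(need, unique(fam))
  if (length(missing) > 0) {
    stopf("feature matrix lacks column family(ies): %s",
          paste(missing, collapse = ", "))
  }
  if (is.null(fold_plan)) fold_plan <- make_folds(fm$labels, seed = config$seed)
  cols <- colnames(fm$X)
  combos <- list(
    histone_sequence = cols[fam %in% c("histone", "kmer")],
    histone_sequence_gc = cols[fam %in% c("histone", "kmer", "GC")],
    histone_sequence_methylation = cols[fam %in% c("histone", "kmer", "methylation")],
    histone_sequence_methylation_gc = cols
  )
  labels <- c("Histone + Sequence", "Histone + Sequence + GC",
              "Histone + Sequence + Methylation",
              "Histone + Sequence + Methylation + GC")
  out <- vector("list", length(combos))
  names(out) <- names(combos)
  for (i in seq_along(combos)) {
    out[[i]] <- cross_validate(fm, feature_columns = combos[[i]],
                               config = config, fold_plan = fold_plan,
                               combination_label = labels[i])
  }
  out
}
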