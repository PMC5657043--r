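#' Extract region sequences from chromosome sequences
#'
#' @param regions region data.frame (0-based half-open).
#' @param sequences a named \code{DNAStringSet} (or named character vector)
#'   of chromosome sequences.
#' @return \code{DNAStringSet} of region sequences, named by region id.
#' @export
region_sequences <- function(regions, sequences) {
  regions <- as_region_df(regions)
  sequences <- as_dna_set(sequences)
  missing <- setdiff(unique(regions$chrom), names(sequences))
  if (length(missing) > 0) {
    stopf("no sequence for chromosome(s): %s", paste(missing, collapse = ", "))
  }
  too_long <- regions$end > Biostrings::width(sequences)[match(regions$chrom, names(sequences))]
  if (any(too_long)) {
    stopf("region(s) extend past chromosome end: %s",
          paste(head(regions$id[too_long], 5), collapse = ", "))
  }
  out <- Biostrings::DNAStringSet(lapply(seq_len(nrow(regions)), function(i) {
    Biostrings::subseq(sequences[[regions$chrom[i]]],
                       start = regions$start[i] + 1L, end = regions$end[i])
  }))
  names(out) <- regions$id
  out
}

#' Build the region-by-feature matrix
#'
#' Assembles, for each labeled region, the feature vector used by the deep
#' belief network classifier, with columns in a fixed order: the 8 + 32 +
#' 128 = 168 strand-collapsed k-mer frequency groups (k = 2, 3, 4), then
#' \code{GC}, then \code{methylation} (per-region signal sum), then one
#' column per histone mark (per-region signal sums, in the order given).
#' With 106 histone tracks this is the classical 276-dimensional
#' representation.
#'
#' @param regions region data.frame (\code{\link{region_samples}}).
#' @param sequences named \code{DNAStringSet}/character of chromosome
#'   sequences.
#' @param methylation_track a \code{\link{signal_track}}, or \code{NULL} to
#'   omit the methylation column.
#' @param histone_tracks named list of \code{\link{signal_track}}s (possibly
#'   empty).
#' @return an object of class \code{feature_matrix}: list with \code{X}
#'   (numeric matrix, rownames = region ids), \code{labels} (integer 0/1 or
#'   NA), \code{families} (per-column family: \code{kmer}, \code{GC},
#'   \code{methylation}, \code{histone}) and \code{scaling} (\code{"raw"}).
#' @export
build_feature_matrix <- function(regions, sequences, methylation_track = NULL,
                                 histone_tracks = list()) {
  regions <- as_region_df(regions)
  seqs <- region_sequences(regions, sequences)
  stopifnot(is.list(histone_tracks))
  if (length(histone_tracks) > 0 && is.null(names(histone_tracks))) {
    names(histone_tracks) <- sprintf("histone_%03d", seq_along(histone_tracks))
  }

  blocks <- list()
  families <- character(0)
  for (k in 2:4) {
    sch <- kmer_scheme(k)
    freqs <- kmer_freq_from_counts(kmer_count_matrix(seqs, sch), sch)
    blocks[[length(blocks) + 1]] <- freqs
    families <- c(families, rep("kmer", ncol(freqs)))
  }
  gc <- as.numeric(Biostrings::letterFrequency(seqs, "GC")) /
    pmax(as.numeric(Biostrings::letterFrequency(seqs, "ACGT")), 1)
  blocks[[length(blocks) + 1]] <- matrix(gc, ncol = 1, dimnames = list(NULL, "GC"))
  families <- c(families, "GC")

  if (!is.null(methylation_track)) {
    meth <- aggregate_signal(methylation_track, regions)
    blocks[[length(blocks) + 1]] <- matrix(meth, ncol = 1,
                                           dimnames = list(NULL, "methylation"))
    families <- c(families, "methylation")
  }
  if (length(histone_tracks) > 0) {
    hist_block <- vapply(histone_tracks, aggregate_signal, numeric(nrow(regions)),
                         regions = regions)
    if (nrow(regions) == 1) hist_block <- matrix(hist_block, nrow = 1)
    colnames(hist_block) <- names(histone_tracks)
    blocks[[length(blocks) + 1]] <- hist_block
    families <- c(families, rep("histone", length(histone_tracks)))
  }

  X <- do.call(cbind, blocks)
  rownames(X) <- regions$id
  structure(
    list(X = X, labels = regions$label, families = families, scaling = "raw"),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d samples x %d features (%s)>\n",
              nrow(x$X), ncol(x$X), x$scaling))
  fam <- table(factor(x$families, levels = c("kmer", "GC", "methylation", "histone")))
  cat("  families:", paste(sprintf("%s=%d", names(fam), fam), collapse = ", "), "\n")
  invisible(x)
}

#' Min-max scale features to [0, 1]
#'
#' Fits per-column minimum and maximum on \code{fit_rows} only (the training
#' fold), then transforms all rows, clipping to \code{[0, 1]} so held-out
#' values outside the fitted range stay in the unit interval. Constant
#' columns map to 0. Required before feeding the matrix to an RBM, whose
#' visible units model values in \code{[0, 1]}.
#'
#' @param fm a raw \code{feature_matrix}.
#' @param fit_rows integer indices of rows to fit the scaler on (default:
#'   all rows).
#' @return list with \code{fm} (the scaled \code{feature_matrix},
#'   \code{scaling = "scaled01"}) and \code{scaler} (reusable via
#'   \code{\link{apply_scaler}}).
#' @export
scale_features <- function(fm, fit_rows = seq_len(nrow(fm$X))) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (fm$scaling != "raw") stopf("feature matrix is already scaled")
  if (length(fit_rows) == 0) stopf("fit_rows must be non-empty")
  sub <- fm$X[fit_rows, , drop = FALSE]
  mins <- apply(sub, 2, min)
  maxs <- apply(sub, 2, max)
  scaler <- structure(list(min = mins, max = maxs,
                           feature_names = colnames(fm$X)),
                      class = "minmax_scaler")
  fm$X <- apply_scaler(scaler, fm$X)
  fm$scaling <- "scaled01"
  list(fm = fm, scaler = scaler)
}

#' Apply a fitted min-max scaler
#'
#' @param scaler a \code{minmax_scaler} from \code{\link{scale_features}}.
#' @param X numeric matrix (or \code{feature_matrix}) with the same columns
#'   the scaler was fitted on.
#' @return matrix of values in \code{[0, 1]} (or scaled
#'   \code{feature_matrix}).
#' @export
apply_scaler <- function(scaler, X) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  if (inherits(X, "feature_matrix")) {
    X$X <- apply_scaler(scaler, X$X)
    X$scaling <- "scaled01"
    return(X)
  }
  if (!identical(colnames(X), scaler$feature_names)) {
    stopf("feature columns do not match the fitted scaler")
  }
  rng <- scaler$max - scaler$min
  out <- sweep(X, 2, scaler$min, "-")
  nonconst <- rng > 0
  out[, nonconst] <- sweep(out[, nonconst, drop = FALSE], 2, rng[nonconst], "/")
  out[, !nonconst] <- 0
  pmin(pmax(out, 0), 1)
}
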