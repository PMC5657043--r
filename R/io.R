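#' Read chromosome sequences from FASTA
#'
#' @param path FASTA file.
#' @return named \code{DNAStringSet}; names truncated at first whitespace.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write chromosome sequences to FASTA
#'
#' @param sequences named \code{DNAStringSet} or character vector.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(as_dna_set(sequences), path, width = 80)
  invisible(path)
}

#' Read regions from a BED file
#'
#' BED coordinates are 0-based half-open and kept that way. Column 4, when
#' present, becomes the region id; columns 5-6 are ignored.
#'
#' @param path BED file (3+ columns, tab- or space-separated).
#' @param label label to assign every region (0, 1 or NA).
#' @return region data.frame (see \code{\link{region_samples}}).
#' @export
read_bed_regions <- function(path, label = NA) {
  gr <- rtracklayer::import(path, format = "BED")
  ids <- if (!is.null(gr$name) && !all(is.na(gr$name))) as.character(gr$name) else NULL
  region_samples(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1L,
                 end = GenomicRanges::end(gr),
                 id = ids, label = label)
}

#' Write regions to a BED file
#'
#' @param regions region data.frame.
#' @param path output file.
#' @export
write_regions_bed <- function(regions, path) {
  regions <- as_region_df(regions)
  gr <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    name = regions$id
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a signal track from bedGraph
#'
#' Intervals are validated non-overlapping (sorted on load). Malformed
#' content is rejected by the parser with file context.
#'
#' @param path bedGraph file (chrom, start, end, value).
#' @return a \code{\link{signal_track}}.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  signal_track(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = gr$score,
    stringsAsFactors = FALSE
  ))
}

#' Write a signal track to bedGraph
#'
#' @param track a \code{\link{signal_track}}.
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  df <- track_to_df(track)
  lines <- sprintf("%s\t%d\t%d\t%s", df$chrom, df$start, df$end,
                   format(df$value, digits = 10, trim = TRUE, scientific = FALSE))
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated dataset to standard files
#'
#' Emits \code{genome.fa}, \code{positives.bed}, \code{negatives.bed},
#' \code{methylation.bedGraph} and one \code{<mark>.bedGraph} per histone
#' mark, so the synthetic data exercises the same readers as real data.
#'
#' @param ds a \code{sim_dataset}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_sim_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(ds$sequences, file.path(dir, "genome.fa"))
  write_regions_bed(ds$regions[ds$regions$label == 1, ], file.path(dir, "positives.bed"))
  write_regions_bed(ds$regions[ds$regions$label == 0, ], file.path(dir, "negatives.bed"))
  write_bedgraph(ds$methylation, file.path(dir, "methylation.bedGraph"))
  for (nm in names(ds$histones)) {
    write_bedgraph(ds$histones[[nm]], file.path(dir, paste0(nm, ".bedGraph")))
  }
  invisible(dir)
}

#' Write a feature matrix to CSV
#'
#' One row per sample: an \code{id} index column, a \code{label} column,
#' then the feature columns in their frozen order.
#'
#' @param fm a \code{feature_matrix}.
#' @param path output CSV.
#' @export
write_feature_csv <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(id = rownames(fm$X), label = fm$labels,
                   fm$X, check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' @param path CSV written by \code{\link{write_feature_csv}}.
#' @param families optional per-feature family vector; inferred from the
#'   column names when omitted (k-mer group names contain \code{"_"};
#'   \code{GC} and \code{methylation} are fixed; the rest are histone).
#' @return a raw \code{feature_matrix}.
#' @export
read_feature_csv <- function(path, families = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "label") %in% names(df)))
  X <- as.matrix(df[, setdiff(names(df), c("id", "label")), drop = FALSE])
  rownames(X) <- df$id
  if (is.null(families)) {
    cn <- colnames(X)
    families <- ifelse(cn == "GC", "GC",
                ifelse(cn == "methylation", "methylation",
                ifelse(grepl("^[ACGT]+_[ACGT]+$", cn), "kmer", "histone")))
  }
  structure(list(X = X, labels = as.integer(df$label), families = families,
                 scaling = "raw"),
            class = "feature_matrix")
}

# serialization format version for classifier containers
MODEL_FORMAT_VERSION <- "1.0"

#' Save a classifier (or RBM) to a versioned JSON container
#'
#' Stores all weight matrices, biases, layer sizes, state, training history
#' and optional feature names with full double precision; round-trips
#' exactly through \code{\link{load_model}}.
#'
#' @param model a \code{dbn_classifier} or \code{rbm}.
#' @param path output JSON file.
#' @param feature_names optional character vector recorded alongside the
#'   weights (models are position-bound to their feature columns).
#' @param scaler optional \code{minmax_scaler} fitted on the training data,
#'   stored so held-out data can be scaled identically at prediction time.
#' @export
save_model <- function(model, path, feature_names = NULL, scaler = NULL) {
  scl <- if (!is.null(scaler)) list(min = scaler$min, max = scaler$max,
                                    feature_names = scaler$feature_names)
  if (inherits(model, "rbm")) {
    payload <- list(format_version = MODEL_FORMAT_VERSION, type = "rbm",
                    W = model$W, b = model$b, a = model$a,
                    feature_names = feature_names, scaler = scl)
  } else if (inherits(model, "dbn_classifier")) {
    payload <- list(format_version = MODEL_FORMAT_VERSION, type = "dbn_classifier",
                    layer_sizes = model$layer_sizes,
                    W = model$W, bias = model$bias,
                    pretrained = model$pretrained, state = model$state,
                    history = model$history, feature_names = feature_names,
                    scaler = scl)
  } else {
    stopf("unsupported model class: %s", paste(class(model), collapse = "/"))
  }
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a model saved by \code{\link{save_model}}
#'
#' @param path JSON container.
#' @return the reconstructed \code{dbn_classifier} or \code{rbm}; feature
#'   names, if stored, are attached as attribute \code{"feature_names"}.
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format_version, MODEL_FORMAT_VERSION)) {
    stopf("unsupported model format version: %s", p$format_version)
  }
  if (identical(p$type, "rbm")) {
    out <- rbm_params(p$W, p$b, p$a)
  } else if (identical(p$type, "dbn_classifier")) {
    W <- lapply(p$W, as.matrix)
    bias <- lapply(p$bias, as.numeric)
    out <- structure(list(W = W, bias = bias,
                          layer_sizes = as.integer(p$layer_sizes),
                          pretrained = isTRUE(p$pretrained),
                          state = p$state,
                          history = as.numeric(p$history)),
                     class = "dbn_classifier")
  } else {
    stopf("unknown model type: %s", p$type)
  }
  if (!is.null(p$feature_names)) attr(out, "feature_names") <- p$feature_names
  if (!is.null(p$scaler)) {
    attr(out, "scaler") <- structure(
      list(min = setNames(as.numeric(p$scaler$min), p$scaler$feature_names),
           max = setNames(as.numeric(p$scaler$max), p$scaler$feature_names),
           feature_names = p$scaler$feature_names),
      class = "minmax_scaler")
  }
  out
}
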