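#' Piecewise-constant genomic signal track
#'
#' Holds one non-negative value per interval, non-overlapping within each
#' chromosome, in BED/bedGraph 0-based half-open coordinates. Intervals are
#' sorted on construction and indexed per chromosome with cumulative sums,
#' so region aggregation is a pair of binary searches rather than a scan.
#'
#' @param chrom character vector of chromosome names, or a data.frame with
#'   columns \code{chrom}, \code{start}, \code{end}, \code{value}.
#' @param start,end 0-based half-open interval bounds.
#' @param value non-negative finite signal per interval.
#' @return an object of class \code{signal_track}.
#' @export
signal_track <- function(chrom, start = NULL, end = NULL, value = NULL) {
  if (is.data.frame(chrom)) {
    df <- chrom
    stopifnot(all(c("chrom", "start", "end", "value") %in% names(df)))
  } else {
    df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                     value = value, stringsAsFactors = FALSE)
  }
  df$chrom <- as.character(df$chrom)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  df$value <- as.numeric(df$value)
  if (nrow(df) > 0) {
    if (any(df$start < 0) || any(df$end <= df$start)) {
      stopf("signal_track intervals must satisfy 0 <= start < end")
    }
    if (any(!is.finite(df$value)) || any(df$value < 0)) {
      stopf("signal_track values must be finite and non-negative")
    }
  }
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  by_chrom <- lapply(split(df[, c("start", "end", "value")], df$chrom), function(d) {
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
      stopf("signal_track intervals overlap within a chromosome")
    }
    list(start = d$start, end = d$end, value = d$value,
         cum = cumsum(d$value * (d$end - d$start)))
  })
  structure(list(data = df, by_chrom = by_chrom), class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track: %d intervals on %d chromosome(s)>\n",
              nrow(x$data), length(x$by_chrom)))
  invisible(x)
}

# signal_track -> 0-based data.frame (bedGraph layout)
track_to_df <- function(track) track$data

#' Sum a signal track over genomic regions
#'
#' For each region, returns the per-base sum of the piecewise-constant track
#' over \code{[start, end)}: \eqn{\sum value \times overlap}. Regions on
#' chromosomes absent from the track contribute 0 (with one warning).
#'
#' @param track a \code{\link{signal_track}}.
#' @param regions a region data.frame as returned by
#'   \code{\link{region_samples}} (columns \code{chrom}, \code{start},
#'   \code{end}; 0-based half-open).
#' @return numeric vector of length \code{nrow(regions)}.
#' @export
aggregate_signal <- function(track, regions) {
  stopifnot(inherits(track, "signal_track"))
  regions <- as_region_df(regions)
  missing_chrom <- setdiff(unique(regions$chrom), names(track$by_chrom))
  if (length(missing_chrom) > 0) {
    warnf("chromosome(s) absent from track (signal taken as 0): %s",
          paste(missing_chrom, collapse = ", "))
  }
  out <- numeric(nrow(regions))
  for (chrom in intersect(unique(regions$chrom), names(track$by_chrom))) {
    idx <- which(regions$chrom == chrom)
    d <- track$by_chrom[[chrom]]
    s <- regions$start[idx]; e <- regions$end[idx]
    # first interval ending after s; last interval starting before e
    i1 <- findInterval(s, d$end) + 1L
    i2 <- findInterval(e - 0.5, d$start)
    tot <- numeric(length(idx))
    hit <- i2 >= i1
    if (any(hit)) {
      lo <- i1[hit]; hi <- i2[hit]
      cum0 <- c(0, d$cum)
      tot[hit] <- cum0[hi + 1L] - cum0[lo] -
        pmax(s[hit] - d$start[lo], 0) * d$value[lo] -
        pmax(d$end[hi] - e[hit], 0) * d$value[hi]
    }
    out[idx] <- tot
  }
  out
}

#' Labeled genomic regions
#'
#' Builds the canonical region table used throughout the package: one row
#' per candidate region with 0-based half-open coordinates, a unique id and
#' a binary label (1 = enhancer/positive, 0 = background/negative).
#'
#' @param chrom,start,end coordinates (0-based half-open).
#' @param id unique sample identifiers; generated if missing.
#' @param label 0/1 vector (or logical).
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{id}, \code{label}.
#' @export
region_samples <- function(chrom, start, end, id = NULL, label = NA) {
  n <- length(chrom)
  if (is.null(id)) id <- sprintf("region_%05d", seq_len(n))
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   id = as.character(id),
                   label = as.integer(label),
                   stringsAsFactors = FALSE)
  as_region_df(df)
}

as_region_df <- function(df) {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  if (!"id" %in% names(df)) df$id <- sprintf("region_%05d", seq_len(nrow(df)))
  if (!"label" %in% names(df)) df$label <- NA_integer_
  if (nrow(df) > 0) {
    if (any(df$start < 0) || any(df$end <= df$start)) {
      stopf("regions must satisfy 0 <= start < end")
    }
    if (anyDuplicated(df$id)) stopf("region ids must be unique")
  }
  df[, c("chrom", "start", "end", "id", "label")]
}
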