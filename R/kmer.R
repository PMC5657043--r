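#' Strand-collapsed k-mer feature scheme
#'
#' Partitions all \eqn{4^k} DNA words of length \code{k} into exactly
#' \eqn{4^k/2} feature groups. A word and its reverse complement describe the
#' same double-stranded fragment, so non-palindromic words are grouped with
#' their reverse complement. Palindromic words (their own reverse complement)
#' are paired with each other in lexicographic order so that the group count
#' is exactly \eqn{4^k/2}: 8 groups for k = 2, 32 for k = 3, 128 for k = 4,
#' 168 in total. Groups are ordered lexicographically by their smallest
#' member and named by joining members with \code{"_"}.
#'
#' @param k word length, one of 2, 3 or 4.
#' @return An object of class \code{kmer_scheme}: a list with elements
#'   \code{k}, \code{groups} (list of character vectors of 1 or 2 words) and
#'   \code{group_names}.
#' @examples
#' sch <- kmer_scheme(2)
#' length(sch$groups)  # 8
#' @export
kmer_scheme <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || !(k %in% c(2, 3, 4))) {
    stopf("k must be 2, 3 or 4 (got %s)", paste(k, collapse = ","))
  }
  k <- as.integer(k)
  cached <- kmer_scheme_cache[[as.character(k)]]
  if (!is.null(cached)) return(cached)
  bases <- c("A", "C", "G", "T")
  words <- sort(apply(expand.grid(rep(list(bases), k)), 1, paste, collapse = ""))
  rc <- revcomp(words)
  pal <- words[words == rc]
  nonpal <- words[words != rc]

  rc_of <- setNames(rc, words)
  groups <- list()
  seen <- character(0)
  for (w in nonpal) {
    if (w %in% seen) next
    partner <- rc_of[[w]]
    groups[[length(groups) + 1]] <- c(w, partner)
    seen <- c(seen, w, partner)
  }
  # palindromes paired with each other in lexicographic order
  if (length(pal) > 0) {
    pal <- sort(pal)
    for (i in seq(1, length(pal), by = 2)) {
      groups[[length(groups) + 1]] <- pal[c(i, i + 1)]
    }
  }
  groups <- lapply(groups, sort)
  ord <- order(vapply(groups, `[`, character(1), 1))
  groups <- groups[ord]
  out <- structure(
    list(k = k, groups = groups,
         group_names = vapply(groups, paste, character(1), collapse = "_")),
    class = "kmer_scheme"
  )
  kmer_scheme_cache[[as.character(k)]] <- out
  out
}

# schemes are pure functions of k; memoized for repeated featurization calls
kmer_scheme_cache <- new.env(parent = emptyenv())

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA strings over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Grouped k-mer frequencies of a sequence
#'
#' Slides a window of width \code{k} over the sequence and reports, for each
#' group in \code{scheme}, the fraction of unambiguous windows matching any
#' of the group's members. Windows containing a base outside A/C/G/T are
#' excluded from both numerator and denominator, so the values sum to 1 over
#' the scheme whenever at least one clean window exists.
#'
#' @param sequence a single DNA string (character or \code{DNAString}),
#'   case-insensitive.
#' @param scheme a \code{\link{kmer_scheme}}.
#' @return named numeric vector, one value per group. All zero (with a
#'   warning) if the sequence is shorter than \code{k} or has no clean
#'   window.
#' @export
kmer_frequencies <- function(sequence, scheme) {
  stopifnot(inherits(scheme, "kmer_scheme"))
  counts <- kmer_count_matrix(as_dna_set(sequence), scheme)
  freqs <- kmer_freq_from_counts(counts, scheme)
  drop(freqs)
}

# Coerce a single sequence or a set to an uppercase DNAStringSet.
as_dna_set <- function(sequence) {
  if (inherits(sequence, "DNAStringSet")) return(sequence)
  if (inherits(sequence, "DNAString")) return(Biostrings::DNAStringSet(sequence))
  Biostrings::DNAStringSet(toupper(as.character(sequence)))
}

# Per-sequence window counts for every group of the scheme (rows = sequences).
# oligonucleotideFrequency counts only A/C/G/T words, so windows containing
# ambiguous bases drop out of both the group counts and the totals.
kmer_count_matrix <- function(dna, scheme) {
  counts <- Biostrings::oligonucleotideFrequency(dna, width = scheme$k)
  grp <- matrix(0, nrow = nrow(counts), ncol = length(scheme$groups),
                dimnames = list(NULL, scheme$group_names))
  for (g in seq_along(scheme$groups)) {
    members <- unique(scheme$groups[[g]])
    grp[, g] <- rowSums(counts[, members, drop = FALSE])
  }
  grp
}

kmer_freq_from_counts <- function(grp_counts, scheme) {
  totals <- rowSums(grp_counts)
  empty <- totals == 0
  if (any(empty)) {
    warnf("%d sequence(s) had no unambiguous %d-mer window; frequencies set to 0",
          sum(empty), scheme$k)
    totals[empty] <- 1
  }
  grp_counts / totals
}

#' GC content of a sequence
#'
#' Fraction of unambiguous (A/C/G/T) bases that are G or C.
#'
#' @param sequence a single DNA string, case-insensitive.
#' @return a number in \code{[0, 1]}; 0 with a warning when every base is
#'   ambiguous.
#' @export
gc_content <- function(sequence) {
  dna <- as_dna_set(sequence)
  if (length(dna) != 1 || Biostrings::width(dna)[1] == 0) {
    stopf("gc_content expects one non-empty sequence")
  }
  gc <- as.numeric(Biostrings::letterFrequency(dna, "GC"))
  acgt <- as.numeric(Biostrings::letterFrequency(dna, "ACGT"))
  if (acgt == 0) {
    warnf("sequence contains no unambiguous base; GC content set to 0")
    return(0)
  }
  gc / acgt
}
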