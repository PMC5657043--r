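#' Simulation configuration
#'
#' Describes a fully synthetic study: random chromosomes, planted enhancer
#' regions with shifted GC content, binned histone tracks enriched over
#' positives, a methylation track depleted over positives, and
#' length/chromosome-matched background negatives. Defaults emulate a
#' validated-enhancer study at reduced scale: ~500 enhancers of mean length
#' 1.5 kb on two 2-Mb chromosomes, background GC 0.41 with a +0.10 shift in
#' enhancers, 10 histone marks with 4-fold enrichment and 4-fold
#' methylation depletion (factor 0.25) over log-normal background noise in
#' 25-bp bins.
#'
#' @param n_chromosomes number of synthetic chromosomes.
#' @param chromosome_length bases per chromosome.
#' @param n_positives number of planted enhancer regions.
#' @param region_length_mean,region_length_sd,region_length_min Gaussian
#'   region-length distribution (bases), truncated at the minimum.
#' @param background_gc genome-wide GC fraction.
#' @param positive_gc_shift GC increase inside planted enhancers.
#' @param n_histone_marks number of histone signal tracks.
#' @param histone_enrichment_fold multiplicative histone enrichment over
#'   positives (1 = null).
#' @param methylation_depletion_factor multiplier on methylation over
#'   positives (1 = null; < 1 = depleted).
#' @param noise_sdlog log-normal noise scale of the signal background.
#' @param bin_width signal-track bin width (bases).
#' @param seed integer fixing all randomness.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_chromosomes = 2, chromosome_length = 2e6,
                       n_positives = 500, region_length_mean = 1500,
                       region_length_sd = 300, region_length_min = 500,
                       background_gc = 0.41, positive_gc_shift = 0.10,
                       n_histone_marks = 10, histone_enrichment_fold = 4,
                       methylation_depletion_factor = 0.25,
                       noise_sdlog = 0.5, bin_width = 25, seed = 1L) {
  stopifnot(n_chromosomes >= 1, chromosome_length > 0, n_positives >= 1,
            region_length_min > 0, region_length_mean >= region_length_min,
            background_gc > 0, background_gc < 1,
            background_gc + positive_gc_shift <= 1,
            n_histone_marks >= 0, histone_enrichment_fold > 0,
            methylation_depletion_factor > 0, noise_sdlog >= 0, bin_width >= 1)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length = as.integer(chromosome_length),
                 n_positives = as.integer(n_positives),
                 region_length_mean = region_length_mean,
                 region_length_sd = region_length_sd,
                 region_length_min = as.integer(region_length_min),
                 background_gc = background_gc,
                 positive_gc_shift = positive_gc_shift,
                 n_histone_marks = as.integer(n_histone_marks),
                 histone_enrichment_fold = histone_enrichment_fold,
                 methylation_depletion_factor = methylation_depletion_factor,
                 noise_sdlog = noise_sdlog, bin_width = as.integer(bin_width),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Sample one base sequence with the given GC fraction.
random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a synthetic genome
#'
#' i.i.d. bases at the configured GC fraction, one sequence per
#' chromosome, named \code{chr1 ... chrN}. Deterministic under
#' \code{config$seed}.
#'
#' @param config a \code{\link{sim_config}}.
#' @return named \code{DNAStringSet}.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 11L), {
    seqs <- vapply(seq_len(config$n_chromosomes), function(i) {
      random_dna(config$chromosome_length, config$background_gc)
    }, character(1))
    names(seqs) <- paste0("chr", seq_len(config$n_chromosomes))
    Biostrings::DNAStringSet(seqs)
  })
}

# Draw region lengths: truncated Gaussian, rounded.
draw_lengths <- function(n, config) {
  len <- round(rnorm(n, config$region_length_mean, config$region_length_sd))
  pmax(len, config$region_length_min)
}

# Place n non-overlapping regions of given lengths uniformly on the genome.
place_regions <- function(lengths, chrom_names, chrom_len, occupied = NULL,
                          max_tries = 1000L, id_prefix = "region") {
  placed <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), stringsAsFactors = FALSE)
  taken <- occupied
  for (i in seq_along(lengths)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      chrom <- sample(chrom_names, 1)
      start <- sample.int(chrom_len - lengths[i], 1) - 1L
      cand <- c(start, start + lengths[i])
      clash <- FALSE
      if (!is.null(taken) && nrow(taken) > 0) {
        same <- taken$chrom == chrom
        clash <- any(same & taken$start < cand[2] & taken$end > cand[1])
      }
      if (!clash) {
        taken <- rbind(taken, data.frame(chrom = chrom, start = cand[1],
                                         end = cand[2], stringsAsFactors = FALSE))
        placed <- rbind(placed, data.frame(chrom = chrom, start = cand[1],
                                           end = cand[2], stringsAsFactors = FALSE))
        ok <- TRUE
        break
      }
    }
    if (!ok) stopf("could not place region %d without overlap after %d tries; genome too crowded",
                   i, max_tries)
  }
  placed$id <- sprintf("%s_%05d", id_prefix, seq_along(lengths))
  placed
}

#' Sample background negatives matched to the positives
#'
#' Each negative inherits the exact length and chromosome of one positive
#' and is placed uniformly at random on that chromosome, rejecting overlaps
#' with positives and previously accepted negatives — background regions of
#' matching length and chromosome distribution.
#'
#' @param positives region data.frame of positives.
#' @param chrom_len chromosome length (bases, same for all chromosomes).
#' @param seed integer.
#' @param max_tries rejection budget per region.
#' @return region data.frame of negatives (\code{label = 0}).
#' @export
sample_matched_negatives <- function(positives, chrom_len, seed = 1L,
                                     max_tries = 1000L) {
  positives <- as_region_df(positives)
  with_seed(seed, {
    taken <- positives[, c("chrom", "start", "end")]
    out <- data.frame()
    for (i in seq_len(nrow(positives))) {
      len <- positives$end[i] - positives$start[i]
      chrom <- positives$chrom[i]
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        start <- sample.int(chrom_len - len, 1) - 1L
        same <- taken$chrom == chrom
        if (!any(same & taken$start < start + len & taken$end > start)) {
          row <- data.frame(chrom = chrom, start = start, end = start + len,
                            stringsAsFactors = FALSE)
          taken <- rbind(taken, row)
          out <- rbind(out, row)
          ok <- TRUE
          break
        }
      }
      if (!ok) stopf("rejection budget exhausted while matching negative %d", i)
    }
    out$id <- sprintf("negative_%05d", seq_len(nrow(out)))
    out$label <- 0L
    as_region_df(out)
  })
}

# Binned log-normal background track over the whole genome, multiplied by
# `fold` inside the given regions. Bins are regular, so boosted bins are
# located by index arithmetic rather than interval scans.
simulate_track <- function(config, regions_boost, fold) {
  w <- config$bin_width
  dfs <- lapply(seq_len(config$n_chromosomes), function(ci) {
    chrom <- paste0("chr", ci)
    starts <- seq(0L, config$chromosome_length - 1L, by = w)
    ends <- pmin(starts + w, config$chromosome_length)
    value <- rlnorm(length(starts), meanlog = 0, sdlog = config$noise_sdlog)
    if (fold != 1 && nrow(regions_boost) > 0) {
      reg <- regions_boost[regions_boost$chrom == chrom, , drop = FALSE]
      if (nrow(reg) > 0) {
        hit_idx <- unlist(lapply(seq_len(nrow(reg)), function(i) {
          seq.int(reg$start[i] %/% w, (reg$end[i] - 1L) %/% w) + 1L
        }))
        hit_idx <- unique(hit_idx[hit_idx <= length(value)])
        value[hit_idx] <- value[hit_idx] * fold
      }
    }
    data.frame(chrom = chrom, start = starts, end = ends, value = value,
               stringsAsFactors = FALSE)
  })
  signal_track(do.call(rbind, dfs))
}

#' Plant enhancer regions and simulate signal tracks
#'
#' Places the positives, rewrites their sequence at the shifted GC
#' fraction, simulates the binned histone tracks (multiplicatively enriched
#' over positives) and the methylation track (multiplicatively depleted
#' over positives), then samples matched negatives.
#'
#' @param sequences genome from \code{\link{generate_genome}}.
#' @param config a \code{\link{sim_config}}.
#' @return object of class \code{sim_dataset}: \code{sequences},
#'   \code{regions} (positives then negatives, labeled), \code{methylation}
#'   (\code{signal_track}), \code{histones} (named list of
#'   \code{signal_track}s) and \code{truth} (the planted effect sizes).
#' @export
plant_regions_and_tracks <- function(sequences, config) {
  stopifnot(inherits(config, "sim_config"))
  sequences <- as_dna_set(sequences)
  chrom_names <- names(sequences)
  chrom_len <- config$chromosome_length

  positives <- with_seed(derive_seed(config$seed, 21L), {
    lens <- draw_lengths(config$n_positives, config)
    if (sum(as.numeric(lens)) * 2 > 0.6 * as.numeric(chrom_len) * length(chrom_names)) {
      stopf("requested regions would occupy most of the genome; enlarge it")
    }
    place_regions(lens, chrom_names, chrom_len, id_prefix = "enhancer")
  })
  positives$label <- 1L
  positives <- as_region_df(positives)

  # shifted GC inside positives, by re-sampling those bases
  if (config$positive_gc_shift != 0) {
    sequences <- with_seed(derive_seed(config$seed, 22L), {
      chars <- lapply(as.character(sequences), function(s) s)
      for (i in seq_len(nrow(positives))) {
        len <- positives$end[i] - positives$start[i]
        repl <- random_dna(len, config$background_gc + config$positive_gc_shift)
        s <- chars[[positives$chrom[i]]]
        substr(s, positives$start[i] + 1L, positives$end[i]) <- repl
        chars[[positives$chrom[i]]] <- s
      }
      Biostrings::DNAStringSet(unlist(chars))
    })
  }

  negatives <- sample_matched_negatives(positives, chrom_len,
                                        seed = derive_seed(config$seed, 23L))

  methylation <- with_seed(derive_seed(config$seed, 24L), {
    simulate_track(config, positives, config$methylation_depletion_factor)
  })
  histones <- list()
  if (config$n_histone_marks > 0) {
    histones <- lapply(seq_len(config$n_histone_marks), function(m) {
      with_seed(derive_seed(config$seed, 30L + m), {
        simulate_track(config, positives, config$histone_enrichment_fold)
      })
    })
    names(histones) <- sprintf("mark_%02d", seq_len(config$n_histone_marks))
  }

  structure(list(
    sequences = sequences,
    regions = rbind(positives, negatives),
    methylation = methylation,
    histones = histones,
    truth = list(gc_shift = config$positive_gc_shift,
                 histone_fold = config$histone_enrichment_fold,
                 methylation_factor = config$methylation_depletion_factor),
    config = config
  ), class = "sim_dataset")
}

#' Simulate a complete labeled dataset
#'
#' Convenience wrapper: \code{\link{generate_genome}} then
#' \code{\link{plant_regions_and_tracks}}.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{sim_dataset}.
#' @export
simulate_dataset <- function(config = sim_config()) {
  plant_regions_and_tracks(generate_genome(config), config)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset: %d chrom x %d bp | %d+/%d- regions | %d histone marks>\n",
              length(x$sequences), x$config$chromosome_length,
              sum(x$regions$label == 1), sum(x$regions$label == 0),
              length(x$histones)))
  invisible(x)
}

#' Featurize a simulated dataset
#'
#' @param ds a \code{sim_dataset}.
#' @return a raw \code{feature_matrix} (see
#'   \code{\link{build_feature_matrix}}).
#' @export
featurize_sim <- function(ds) {
  stopifnot(inherits(ds, "sim_dataset"))
  build_feature_matrix(ds$regions, ds$sequences, ds$methylation, ds$histones)
}
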