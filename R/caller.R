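#' Estimate the per-copy depth level
#'
#' The depth contributed by a single chromosome copy, the scaling constant
#' that converts window depths into copy numbers. With a flow-cytometry
#' genome size available the estimate is mass conservation: total covered
#' mass `sum(mean_depth * window_length)` divided by the genome size. With
#' no cytometry calibration, the fallback is the lowest substantial mode
#' of the positive window means under a kernel density fit, interpreted as
#' the 1-copy level.
#'
#' @param coverage a [windowed_coverage] (nuclear windows are used).
#' @param reference a [combined_reference].
#' @param genome_size_fcm flow-cytometry genome size in bp, or `NULL` for
#'   the density-mode fallback.
#' @param peak_frac a density mode must reach this fraction of the highest
#'   mode to count as substantial.
#' @param bw kernel bandwidth passed to [stats::density()].
#' @return Depth per copy (positive scalar).
#' @export
estimate_depth_per_copy <- function(coverage, reference,
                                    genome_size_fcm = NULL,
                                    peak_frac = 0.1, bw = "nrd0") {
  mtkey <- with(reference$chrom[reference$chrom$mt, , drop = FALSE],
                paste(species, chromosome, sep = "-"))
  nucrows <- !(paste(coverage$species, coverage$chromosome, sep = "-") %in%
               mtkey)
  d <- coverage$mean_depth[nucrows]
  if (length(d) == 0L || all(d == 0)) stop("all-zero coverage")
  if (!is.null(genome_size_fcm)) {
    if (genome_size_fcm <= 0) stop("genome_size_fcm must be positive")
    return(sum(d * (coverage$end[nucrows] - coverage$start[nucrows])) /
             genome_size_fcm)
  }
  pos <- d[d > 0]
  if (length(unique(pos)) == 1L) return(pos[1L])
  dens <- stats::density(pos, bw = bw)
  y <- dens$y
  is_max <- c(FALSE, diff(sign(diff(y))) < 0, FALSE)
  peaks <- which(is_max & y >= peak_frac * max(y))
  if (length(peaks) == 0L) peaks <- which.max(y)
  dens$x[min(peaks)]
}

# Round half away from zero (copy 6.5 -> 7).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Call integer copy numbers per chromosome
#'
#' For each nuclear chromosome the copy number is the median of its window
#' means divided by the per-copy depth, rounded half away from zero and
#' capped at `max_copies`. Zero-depth windows are excluded from the median
#' (they are mappability holes in an otherwise covered chromosome) but
#' counted toward the absence test: a chromosome with at least
#' `absent_frac` of its windows at zero is called absent (0 copies).
#'
#' @param coverage a [windowed_coverage].
#' @param reference a [combined_reference].
#' @param depth_per_copy per-copy depth level (> 0).
#' @param max_copies cap on called copies.
#' @param absent_frac zero-window fraction at or above which a chromosome
#'   is called absent.
#' @return A [karyotype] without segment calls (see [call_karyotype()] for
#'   the full caller including translocation detection).
#' @export
call_copy_numbers <- function(coverage, reference, depth_per_copy,
                              max_copies = 12L, absent_frac = 0.9) {
  if (depth_per_copy <= 0) stop("depth_per_copy must be > 0")
  nuc <- reference$chrom[!reference$chrom$mt, , drop = FALSE]
  copies <- integer(nrow(nuc))
  flags <- character(nrow(nuc))
  for (i in seq_len(nrow(nuc))) {
    win <- coverage_chrom(coverage, nuc$species[i], nuc$chromosome[i])
    if (nrow(win) == 0L)
      stop("no windows for ", nuc$species[i], "-", nuc$chromosome[i])
    zero_frac <- mean(win$mean_depth == 0)
    if (zero_frac >= absent_frac) {
      copies[i] <- 0L
      flags[i] <- "absent"
      next
    }
    med <- stats::median(win$mean_depth[win$mean_depth > 0])
    cc <- min(max_copies, round_half_away(med / depth_per_copy))
    copies[i] <- as.integer(cc)
    flags[i] <- if (cc == 0L) "absent" else "whole"
  }
  karyotype(data.frame(species = nuc$species, chromosome = nuc$chromosome,
                       copies = copies, flag = flags,
                       stringsAsFactors = FALSE), reference)
}

#' Detect an arm-level unbalanced translocation on one chromosome
#'
#' Exhaustive single-changepoint search on the per-window copy estimates
#' (`mean_depth / depth_per_copy`): every split between consecutive
#' windows is scored by two-segment squared error. A call is emitted only
#' when the best split's rounded segment copies differ, both segments span
#' at least `min_arm_frac` of the chromosome (a one-window quantization
#' tolerance is allowed), and the split reduces squared error by at least
#' a factor `min_gain` relative to the single-segment fit. Otherwise, or
#' on degenerate input (all-zero chromosome, fewer than `min_windows`
#' windows), no call is made.
#'
#' Segment copy numbers are the rounded medians of the non-zero windows on
#' each side (all-zero side: 0), so scattered dropout windows do not drag
#' the call.
#'
#' @param coverage a [windowed_coverage].
#' @param reference a [combined_reference].
#' @param species,chromosome chromosome to scan.
#' @param depth_per_copy per-copy depth level.
#' @param min_arm_frac minimum fraction of the chromosome per segment.
#' @param min_gain required SSE reduction factor over the one-segment fit.
#' @param min_windows minimum number of windows to attempt a call.
#' @param max_copies cap on segment copies.
#' @return A one-row data.frame (`species`, `chromosome`, `breakpoint`,
#'   `left_copies`, `right_copies`), or `NULL` when no call is made.
#' @export
detect_unbalanced_translocations <- function(coverage, reference, species,
                                             chromosome, depth_per_copy,
                                             min_arm_frac = 0.2,
                                             min_gain = 1.5,
                                             min_windows = 10L,
                                             max_copies = 12L) {
  win <- coverage_chrom(coverage, species, chromosome)
  n <- nrow(win)
  if (n < min_windows) return(NULL)
  if (all(win$mean_depth == 0)) return(NULL) # whole-chromosome loss
  len <- ref_chrom_row(reference, species, chromosome)$length
  y <- win$mean_depth / depth_per_copy

  csum <- cumsum(y)
  csq <- cumsum(y^2)
  total <- csum[n]
  total2 <- csq[n]
  sse1 <- total2 - total^2 / n
  tol <- reference$window_size / len # one-window quantization allowance
  best_k <- NA_integer_
  best_sse <- Inf
  for (k in seq_len(n - 1L)) {
    lfrac <- win$end[k] / len
    if (lfrac < min_arm_frac - tol || 1 - lfrac < min_arm_frac - tol) next
    sl <- csum[k]
    sr <- total - sl
    sse <- (csq[k] - sl^2 / k) +
      ((total2 - csq[k]) - sr^2 / (n - k))
    if (sse < best_sse) {
      best_sse <- sse
      best_k <- k
    }
  }
  if (is.na(best_k)) return(NULL)
  if (sse1 == 0) return(NULL) # perfectly uniform
  if (best_sse > 0 && sse1 / best_sse < min_gain) return(NULL)

  side_copies <- function(v) {
    nz <- v[v > 0]
    if (length(nz) == 0L) return(0L)
    as.integer(min(max_copies, round_half_away(stats::median(nz))))
  }
  left <- side_copies(y[seq_len(best_k)])
  right <- side_copies(y[(best_k + 1L):n])
  if (left == right) return(NULL)
  data.frame(species = species, chromosome = chromosome,
             breakpoint = win$end[best_k], left_copies = left,
             right_copies = right, stringsAsFactors = FALSE)
}

#' Full karyotype call: copy numbers plus translocation scan
#'
#' Runs [call_copy_numbers()] and then
#' [detect_unbalanced_translocations()] on every non-absent chromosome,
#' flagging segmented chromosomes as `recombinant-candidate`.
#'
#' @inheritParams call_copy_numbers
#' @inheritParams detect_unbalanced_translocations
#' @return A [karyotype].
#' @examples
#' ref <- saccharomyces_reference(c("Scer", "Suva"))
#' par <- sim_params(noise_sigma = 0, mappability_dropout = 0)
#' kar <- founder_karyotype(ref, "Scer")
#' cov <- simulate_coverage(kar, ref, par)
#' called <- call_karyotype(cov, ref, depth_per_copy = 30)
#' all(called$copies$copies == kar$copies$copies)
#' @export
call_karyotype <- function(coverage, reference, depth_per_copy,
                           max_copies = 12L, absent_frac = 0.9,
                           min_arm_frac = 0.2, min_gain = 1.5,
                           min_windows = 10L) {
  base <- call_copy_numbers(coverage, reference, depth_per_copy,
                            max_copies = max_copies,
                            absent_frac = absent_frac)
  segs <- list()
  cp <- base$copies
  for (i in seq_len(nrow(cp))) {
    if (cp$flag[i] == "absent") next
    s <- detect_unbalanced_translocations(
      coverage, reference, cp$species[i], cp$chromosome[i], depth_per_copy,
      min_arm_frac = min_arm_frac, min_gain = min_gain,
      min_windows = min_windows, max_copies = max_copies)
    if (!is.null(s)) segs[[length(segs) + 1L]] <- s
  }
  cp$flag <- NA_character_
  karyotype(cp, reference,
            if (length(segs) > 0L) do.call(rbind, segs) else NULL)
}

# Kernel-density G1 peak: the mode below 1.5x the first major peak.
g1_peak <- function(values, major_frac = 0.25, bw = "nrd0") {
  if (length(values) == 0L) stop("empty fluorescence sample")
  if (diff(range(values)) < .Machine$double.eps * max(abs(values), 1))
    return(values[1L])
  dens <- stats::density(values, bw = bw)
  y <- dens$y
  is_max <- c(FALSE, diff(sign(diff(y))) < 0, FALSE)
  peaks <- which(is_max & y >= major_frac * max(y))
  if (length(peaks) == 0L) stop("no detectable fluorescence peak")
  first <- dens$x[min(peaks)]
  keep <- dens$x <= 1.5 * first
  dens$x[keep][which.max(y[keep])]
}

#' Flow-cytometry ploidy estimate
#'
#' Locates the G1 fluorescence peak of the sample and of a haploid
#' laboratory reference by kernel density (the mode below 1.5 times the
#' first major peak, so a G2 peak at twice the G1 position is ignored).
#' The peak ratio is the mean number of copies per chromosome slot, and
#' times the haploid reference genome size it gives the cytometry genome
#' size used to calibrate depth per copy.
#'
#' @param sample_g1_values fluorescence values of the sample.
#' @param reference_g1_values fluorescence values of the haploid reference.
#' @param haploid_genome_size haploid reference genome size in bp.
#' @param major_frac fraction of the highest density mode a peak must
#'   reach to count as major.
#' @return A list of class `ploidy_estimate`: `fluorescence_ratio`,
#'   `mean_copies`, `genome_size_fcm`, `sample_peak`, `reference_peak`.
#' @export
estimate_ploidy_fcm <- function(sample_g1_values, reference_g1_values,
                                haploid_genome_size, major_frac = 0.25) {
  if (length(sample_g1_values) == 0L || length(reference_g1_values) == 0L)
    stop("both fluorescence samples must be non-empty")
  sp <- g1_peak(sample_g1_values, major_frac)
  rp <- g1_peak(reference_g1_values, major_frac)
  if (rp <= 0) stop("non-positive reference peak")
  ratio <- sp / rp
  structure(list(fluorescence_ratio = ratio, mean_copies = ratio,
                 genome_size_fcm = ratio * haploid_genome_size,
                 sample_peak = sp, reference_peak = rp),
            class = "ploidy_estimate")
}

#' @export
print.ploidy_estimate <- function(x, ...) {
  cat(sprintf(
    "ploidy estimate: ratio %.3f, mean copies %.2f, genome size %.2f Mb\n",
    x$fluorescence_ratio, x$mean_copies, x$genome_size_fcm / 1e6))
  invisible(x)
}
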