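#' Percent of a parent genome retained in a hybrid
#'
#' The retention statistic for one parent species:
#' `Pspp = 100 * Ct * Ws / Gs`, where `Ct` is the number of that species'
#' nuclear windows with mean depth strictly above `threshold`, `Ws` the
#' window size and `Gs` the species' nuclear reference genome size. The
#' percentage is clamped to 100 (edge-window overshoot cannot exceed the
#' genome). Presence, not copy number: a chromosome present in many copies
#' counts the same as a single-copy one.
#'
#' @param coverage a [windowed_coverage].
#' @param species parent species tag.
#' @param reference a [combined_reference].
#' @param threshold depth cutoff; a window counts when its mean is
#'   strictly greater than this.
#' @return A list of class `retention_record`: `species`, `Pspp` (percent),
#'   `Ct`, `threshold`, `retained_bp`, `Gs`.
#' @examples
#' ref <- saccharomyces_reference(c("Scer", "Suva"))
#' par <- sim_params(noise_sigma = 0, mappability_dropout = 0)
#' cov <- simulate_coverage(founder_karyotype(ref, "Scer"), ref, par)
#' percent_retention(cov, "Scer", ref)$Pspp # 100
#' @export
percent_retention <- function(coverage, species, reference, threshold = 2) {
  stopifnot(inherits(reference, "combined_reference"))
  nuc <- reference$chrom[!reference$chrom$mt, , drop = FALSE]
  if (!species %in% nuc$species) stop("unknown species: ", species)
  gs <- sum(nuc$length[nuc$species == species])
  nuckey <- paste(nuc$species[nuc$species == species],
                  nuc$chromosome[nuc$species == species], sep = "-")
  rows <- coverage[coverage$species == species &
                   paste(coverage$species, coverage$chromosome, sep = "-")
                   %in% nuckey, , drop = FALSE]
  ct <- sum(rows$mean_depth > threshold)
  pspp <- min(100, 100 * ct * reference$window_size / gs)
  structure(list(species = species, Pspp = pspp, Ct = ct,
                 threshold = threshold, retained_bp = pspp / 100 * gs,
                 Gs = gs),
            class = "retention_record")
}

#' @export
print.retention_record <- function(x, ...) {
  cat(sprintf("%s: %.1f%% retained (%.2f of %.2f Mb, %d windows > %g)\n",
              x$species, x$Pspp, x$retained_bp / 1e6, x$Gs / 1e6, x$Ct,
              x$threshold))
  invisible(x)
}

#' Cassette copy-number ratio test
#'
#' Compares the coverage of an inserted cassette with its host
#' chromosome. The ratio is the cassette mean depth over the median of
#' the host chromosome's window means at the cassette window size (median,
#' so aneuploid segments on the host do not drag the 1-copy level). A
#' one-sided rank-sum test asks whether the cassette windows deviate from
#' the 1:1 copy expectation, in the direction indicated by the ratio. The
#' exact null distribution is used whenever there are no ties;
#' otherwise a normal approximation with continuity and tie correction.
#'
#' @param cassette_depths numeric vector: mean depth of each cassette
#'   window (or per-base depths when `per_base = TRUE`).
#' @param chromosome_depths numeric vector: host-chromosome window mean
#'   depths at `cassette_window` bp (or per-base depths when
#'   `per_base = TRUE`, re-windowed internally).
#' @param cassette_window window size in bp used when re-windowing
#'   per-base input.
#' @param per_base treat both inputs as per-base depth vectors.
#' @param min_chrom_windows minimum number of host windows required.
#' @return A list of class `cassette_report`: `ratio`, `p_value`,
#'   `cassette_mean`, `chromosome_median`, `n_cassette`, `n_windows`,
#'   `alternative`, `undefined` (TRUE with no p-value when the host
#'   chromosome is absent).
#' @export
cassette_copy_ratio <- function(cassette_depths, chromosome_depths,
                                cassette_window = 3900, per_base = FALSE,
                                min_chrom_windows = 5L) {
  rewindow <- function(d) {
    n <- length(d)
    idx <- floor((seq_len(n) - 1) / cassette_window)
    as.numeric(tapply(d, idx, mean))
  }
  cas <- if (per_base) rewindow(cassette_depths) else
    as.numeric(cassette_depths)
  chr <- if (per_base) rewindow(chromosome_depths) else
    as.numeric(chromosome_depths)
  if (length(cas) < 1L) stop("cassette needs at least one value")
  if (length(chr) < min_chrom_windows)
    stop("host chromosome needs at least ", min_chrom_windows, " windows")
  if (all(chr == 0)) {
    return(structure(list(ratio = NA_real_, p_value = NA_real_,
                          cassette_mean = mean(cas),
                          chromosome_median = 0,
                          n_cassette = length(cas), n_windows = length(chr),
                          alternative = NA_character_, undefined = TRUE),
                     class = "cassette_report"))
  }
  med <- stats::median(chr)
  ratio <- mean(cas) / med
  alt <- if (ratio >= 1) "greater" else "less"
  ties <- anyDuplicated(c(cas, chr)) > 0L
  wt <- suppressWarnings(stats::wilcox.test(
    cas, chr, alternative = alt, exact = !ties, correct = TRUE))
  structure(list(ratio = ratio, p_value = wt$p.value,
                 cassette_mean = mean(cas), chromosome_median = med,
                 n_cassette = length(cas), n_windows = length(chr),
                 alternative = alt, undefined = FALSE),
            class = "cassette_report")
}

#' @export
print.cassette_report <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat("cassette report: host chromosome absent, ratio undefined\n")
  } else {
    cat(sprintf(
      "cassette/chromosome ratio %.2f (one-sided p = %.3g, %d vs %d windows)\n",
      x$ratio, x$p_value, x$n_cassette, x$n_windows))
  }
  invisible(x)
}

#' Cell volume from projected area
#'
#' Spherical-cell geometry: radius `r = sqrt(A / pi)` and volume
#' `V = (4/3) pi r^3` from a projected area `A`.
#'
#' @param area cell area(s), um^2 (non-negative).
#' @return A data.frame of class `cell_measure` with columns `area`,
#'   `radius`, `volume`.
#' @examples
#' cell_volume_from_area(pi)$volume # 4 * pi / 3
#' @export
cell_volume_from_area <- function(area) {
  if (any(area < 0)) stop("negative area")
  r <- sqrt(area / pi)
  structure(data.frame(area = area, radius = r,
                       volume = 4 / 3 * pi * r^3),
            class = c("cell_measure", "data.frame"))
}
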