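#' Expected karyotype from parental karyotypes
#'
#' The expectation for a hybrid is the elementwise sum of both parents'
#' copy numbers (whole-genome fusion: the crossing scheme mates diploids
#' without meiosis); for an evolved isolate it is the single ancestor's
#' karyotype unchanged. Segment calls carried by a parent propagate with
#' the other parent's whole-chromosome copies added to both sides; if the
#' summed per-chromosome profile ends up with more than one internal copy
#' change, it is collapsed to the best single-breakpoint approximation
#' (length-weighted least squares), matching the one-changepoint
#' convention used throughout.
#'
#' @param parent_karyotypes list of 1 or 2 [karyotype] objects.
#' @param reference a [combined_reference].
#' @return A [karyotype].
#' @export
expected_karyotype <- function(parent_karyotypes, reference) {
  if (length(parent_karyotypes) < 1L || length(parent_karyotypes) > 2L)
    stop("expected 1 or 2 parent karyotypes")
  for (k in parent_karyotypes) stopifnot(inherits(k, "karyotype"))
  base <- parent_karyotypes[[1L]]
  if (length(parent_karyotypes) == 1L)
    return(karyotype(base$copies[, c("species", "chromosome", "copies")],
                     reference, base$segments))

  k1 <- parent_karyotypes[[1L]]
  k2 <- parent_karyotypes[[2L]]
  cp <- k1$copies[, c("species", "chromosome")]
  cp$copies <- k1$copies$copies + k2$copies$copies
  seg_chroms <- unique(rbind(k1$segments[, c("species", "chromosome")],
                             k2$segments[, c("species", "chromosome")]))
  segs <- list()
  for (i in seq_len(nrow(seg_chroms))) {
    sp <- seg_chroms$species[i]
    ch <- seg_chroms$chromosome[i]
    prof <- sum_profiles(
      karyotype_profile(k1, reference, sp, ch),
      karyotype_profile(k2, reference, sp, ch))
    j <- which(cp$species == sp & cp$chromosome == ch)
    cp$copies[j] <- majority_copies(prof)
    seg <- collapse_profile(prof, sp, ch)
    if (!is.null(seg)) segs[[length(segs) + 1L]] <- seg
  }
  karyotype(cp, reference,
            if (length(segs) > 0L) do.call(rbind, segs) else NULL)
}

# Sum two piecewise-constant copy profiles over the same chromosome.
sum_profiles <- function(p1, p2) {
  cuts <- sort(unique(c(p1$start, p1$end, p2$start, p2$end)))
  starts <- cuts[-length(cuts)]
  ends <- cuts[-1L]
  mid <- (starts + ends) / 2
  copies <- p1$copies[findInterval(mid, p1$start)] +
    p2$copies[findInterval(mid, p2$start)]
  keep <- c(TRUE, diff(copies) != 0)
  idx <- cumsum(keep)
  data.frame(start = as.numeric(tapply(starts, idx, min)),
             end = as.numeric(tapply(ends, idx, max)),
             copies = as.numeric(copies[keep]))
}

# Reduce a profile to at most one internal breakpoint; NULL if uniform.
collapse_profile <- function(prof, species, chromosome) {
  if (nrow(prof) == 1L) return(NULL)
  if (nrow(prof) == 2L) {
    if (prof$copies[1L] == prof$copies[2L]) return(NULL)
    return(data.frame(species = species, chromosome = chromosome,
                      breakpoint = prof$end[1L],
                      left_copies = as.integer(prof$copies[1L]),
                      right_copies = as.integer(prof$copies[2L]),
                      stringsAsFactors = FALSE))
  }
  w <- prof$end - prof$start
  best <- NULL
  best_sse <- Inf
  for (cut in seq_len(nrow(prof) - 1L)) {
    li <- seq_len(cut)
    ri <- (cut + 1L):nrow(prof)
    lm_ <- sum(w[li] * prof$copies[li]) / sum(w[li])
    rm_ <- sum(w[ri] * prof$copies[ri]) / sum(w[ri])
    sse <- sum(w[li] * (prof$copies[li] - lm_)^2) +
      sum(w[ri] * (prof$copies[ri] - rm_)^2)
    if (sse < best_sse) {
      best_sse <- sse
      best <- list(bp = prof$end[cut], left = round(lm_), right = round(rm_))
    }
  }
  if (best$left == best$right) return(NULL)
  data.frame(species = species, chromosome = chromosome,
             breakpoint = best$bp, left_copies = as.integer(best$left),
             right_copies = as.integer(best$right), stringsAsFactors = FALSE)
}

#' Count new chromosomal aberrations at a pedigree node
#'
#' Compares an observed karyotype with the expectation formed from its
#' parents ([expected_karyotype]): aberrations inherited from a parent are
#' thereby never counted twice. Per slot, each missing copy counts as one
#' loss and each extra copy as one gain (`per_chromosome = TRUE` switches
#' to counting affected chromosomes instead of copies). A segment call on
#' a chromosome whose expectation carries none counts as one new
#' unbalanced translocation.
#'
#' @param observed observed [karyotype].
#' @param expected expected [karyotype] (same reference).
#' @param node optional node id carried into the report.
#' @param per_chromosome count affected chromosomes rather than copies.
#' @return A list of class `aberration_report` with `node`, `gains`,
#'   `losses`, `unbalanced_translocations`, `total_new`.
#' @export
count_new_aberrations <- function(observed, expected, node = NA_character_,
                                  per_chromosome = FALSE) {
  stopifnot(inherits(observed, "karyotype"), inherits(expected, "karyotype"))
  ok <- paste(observed$copies$species, observed$copies$chromosome, sep = "-")
  ek <- paste(expected$copies$species, expected$copies$chromosome, sep = "-")
  if (!identical(ok, ek))
    stop("observed and expected karyotypes cover different references")
  d <- observed$copies$copies - expected$copies$copies
  if (per_chromosome) {
    gains <- sum(d > 0)
    losses <- sum(d < 0)
  } else {
    gains <- sum(pmax(0L, d))
    losses <- sum(pmax(0L, -d))
  }
  oseg <- paste(observed$segments$species, observed$segments$chromosome,
                sep = "-")
  eseg <- paste(expected$segments$species, expected$segments$chromosome,
                sep = "-")
  tr <- sum(!(oseg %in% eseg))
  structure(list(node = node, gains = gains, losses = losses,
                 unbalanced_translocations = tr,
                 total_new = gains + losses + tr),
            class = "aberration_report")
}

#' @export
print.aberration_report <- function(x, ...) {
  cat(sprintf(
    "aberrations at %s: %d gains, %d losses, %d unbalanced translocations (total %d)\n",
    x$node, x$gains, x$losses, x$unbalanced_translocations, x$total_new))
  invisible(x)
}

#' Classify mitochondrial inheritance from mt coverage
#'
#' Computes, for each species with a mitochondrial genome in the
#' reference, the fraction of its mt windows with mean depth above the
#' detection cutoff. Classification:
#' exactly one species at or above `full_thr` with all others at or below
#' `absent_thr` is homoplasmic; two or more species at or above `full_thr`
#' is heteroplasmic; a species strictly between the thresholds whose
#' covered windows form one contiguous block, complemented by another
#' species covering the opposite end of its genome with the fractions
#' summing to about one, is recombinant; other partial patterns are
#' incomplete; everything at or below `absent_thr` is none.
#'
#' @param mt_coverage [windowed_coverage] over the mt chromosomes.
#' @param reference a [combined_reference] with mt chromosomes.
#' @param full_thr covered fraction at or above which a mitotype counts as
#'   fully present.
#' @param absent_thr covered fraction at or below which it counts absent.
#' @param depth_threshold depth cutoff defining a covered window (same
#'   cutoff as percent retention).
#' @param max_gap contiguity tolerance: up to this many uncovered windows
#'   inside a block are bridged (mappability holes).
#' @return A list of class `mitotype_call` with `class`, `donors` and
#'   `covered_fraction` (named vector).
#' @export
classify_mitotype <- function(mt_coverage, reference, full_thr = 0.9,
                              absent_thr = 0.1, depth_threshold = 2,
                              max_gap = 2) {
  mt <- reference$chrom[reference$chrom$mt, , drop = FALSE]
  if (nrow(mt) == 0L) stop("reference has no mt chromosomes")
  species <- unique(mt$species)
  frac <- numeric(length(species))
  names(frac) <- species
  blocks <- list()
  for (s in species) {
    row <- mt[mt$species == s, ][1L, ]
    win <- coverage_chrom(mt_coverage, s, row$chromosome)
    if (nrow(win) == 0L) {
      frac[s] <- 0
      blocks[[s]] <- list(contiguous = TRUE, at_start = FALSE,
                          at_end = FALSE)
      next
    }
    cov <- win$mean_depth > depth_threshold
    frac[s] <- mean(cov)
    idx <- which(cov)
    if (length(idx) == 0L) {
      blocks[[s]] <- list(contiguous = TRUE, at_start = FALSE,
                          at_end = FALSE)
    } else {
      gaps <- diff(idx) - 1L
      blocks[[s]] <- list(contiguous = all(gaps <= max_gap),
                          at_start = idx[1L] <= 1L + max_gap,
                          at_end = idx[length(idx)] >= nrow(win) - max_gap)
    }
  }

  full <- names(frac)[frac >= full_thr]
  partial <- names(frac)[frac > absent_thr & frac < full_thr]
  if (length(full) >= 2L) {
    cls <- "heteroplasmic"; donors <- full
  } else if (length(full) == 1L && length(partial) == 0L) {
    cls <- "homoplasmic"; donors <- full
  } else if (length(full) == 0L && length(partial) == 0L) {
    cls <- "none"; donors <- character()
  } else {
    # at least one partial mitotype: recombinant or incomplete
    cls <- "incomplete"
    donors <- c(full, partial)
    cand <- c(full, partial)
    if (length(partial) >= 1L) {
      found <- FALSE
      for (a in partial) {
        for (b in setdiff(cand, a)) {
          ba <- blocks[[a]]; bb <- blocks[[b]]
          complementary <- (ba$at_start && bb$at_end) ||
            (ba$at_end && bb$at_start)
          if (ba$contiguous && bb$contiguous && complementary &&
              abs(frac[a] + frac[b] - 1) <= 0.2) {
            cls <- "recombinant"; donors <- c(a, b); found <- TRUE
            break
          }
        }
        if (found) break
      }
    }
  }
  structure(list(class = cls, donors = donors, covered_fraction = frac),
            class = "mitotype_call")
}

#' @export
print.mitotype_call <- function(x, ...) {
  cat(sprintf("mitotype: %s (%s)\n", x$class,
              paste(x$donors, collapse = ", ")))
  invisible(x)
}
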