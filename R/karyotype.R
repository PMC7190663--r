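#' Karyotype: integer copy numbers per (species, chromosome)
#'
#' The inferred (or simulated ground-truth) state of a strain: one
#' non-negative integer copy number per reference chromosome slot, plus
#' arm-level segment calls for chromosomes whose copy number changes across
#' a single internal breakpoint (unbalanced translocations). For a
#' segmented chromosome the slot-level `copies` value is the copy number of
#' the length-majority side of the breakpoint.
#'
#' Flags per chromosome: `whole` (uniform copy number), `absent` (copy 0),
#' `recombinant-candidate` (carries a segment call).
#'
#' @param copies data.frame with columns `species`, `chromosome`, `copies`
#'   and optionally `flag`; must cover every reference chromosome slot
#'   (nuclear chromosomes).
#' @param reference a [combined_reference].
#' @param segments optional data.frame with columns `species`,
#'   `chromosome`, `breakpoint` (bp), `left_copies`, `right_copies`.
#' @return An object of class `karyotype`: list with elements `copies` and
#'   `segments`, rows ordered as the reference.
#' @export
karyotype <- function(copies, reference, segments = NULL) {
  stopifnot(is.data.frame(copies), inherits(reference, "combined_reference"))
  nuc <- reference$chrom[!reference$chrom$mt, , drop = FALSE]
  rkey <- paste(nuc$species, nuc$chromosome, sep = "-")
  key <- paste(copies$species, copies$chromosome, sep = "-")
  if (!setequal(key, rkey) || anyDuplicated(key))
    stop("karyotype must cover every nuclear reference chromosome exactly once")
  cp <- copies[match(rkey, key), , drop = FALSE]
  cp$copies <- as.numeric(cp$copies)
  if (any(cp$copies < 0) || any(cp$copies != round(cp$copies)))
    stop("copy numbers must be non-negative integers")
  cp$copies <- as.integer(cp$copies)
  if (is.null(segments) || nrow(segments) == 0L) {
    segments <- data.frame(species = character(), chromosome = character(),
                           breakpoint = numeric(), left_copies = integer(),
                           right_copies = integer(), stringsAsFactors = FALSE)
  } else {
    segments <- segments[, c("species", "chromosome", "breakpoint",
                             "left_copies", "right_copies")]
    skey <- paste(segments$species, segments$chromosome, sep = "-")
    if (anyDuplicated(skey))
      stop("at most one segment call per chromosome")
    if (!all(skey %in% rkey)) stop("segment on unknown chromosome")
    if (any(segments$left_copies == segments$right_copies))
      stop("segment sides must have different copy numbers")
    for (i in seq_len(nrow(segments))) {
      len <- nuc$length[rkey == skey[i]]
      if (segments$breakpoint[i] <= 0 || segments$breakpoint[i] >= len)
        stop("segment breakpoint must be strictly inside the chromosome")
    }
  }
  if (!"flag" %in% names(cp) || all(is.na(cp$flag))) {
    skey <- paste(segments$species, segments$chromosome, sep = "-")
    cp$flag <- ifelse(rkey %in% skey, "recombinant-candidate",
                      ifelse(cp$copies == 0L, "absent", "whole"))
  }
  cp <- cp[, c("species", "chromosome", "copies", "flag")]
  rownames(cp) <- NULL
  rownames(segments) <- NULL
  structure(list(copies = cp, segments = segments), class = "karyotype")
}

#' @export
print.karyotype <- function(x, ...) {
  cat(sprintf("karyotype: %d slots, %d absent, %d segment call(s), %d total chromosomes\n",
              nrow(x$copies), sum(x$copies$copies == 0L),
              nrow(x$segments), sum(x$copies$copies)))
  invisible(x)
}

#' Euploid diploid founder karyotype
#'
#' Copy number 2 for every chromosome of the founder's own species, 0 for
#' every other species' chromosome.
#'
#' @param reference a [combined_reference].
#' @param species the founder's species tag.
#' @param ploidy copies of each own chromosome (default 2).
#' @return A [karyotype].
#' @export
founder_karyotype <- function(reference, species, ploidy = 2L) {
  nuc <- reference$chrom[!reference$chrom$mt, , drop = FALSE]
  if (!species %in% nuc$species) stop("unknown species: ", species)
  karyotype(data.frame(
    species = nuc$species, chromosome = nuc$chromosome,
    copies = ifelse(nuc$species == species, as.integer(ploidy), 0L),
    stringsAsFactors = FALSE), reference)
}

# Piecewise copy profile of one chromosome: data.frame(start, end, copies).
karyotype_profile <- function(kar, reference, species, chromosome) {
  len <- ref_chrom_row(reference, species, chromosome)$length
  i <- which(kar$segments$species == species &
             kar$segments$chromosome == chromosome)
  if (length(i) == 1L) {
    s <- kar$segments[i, ]
    data.frame(start = c(0, s$breakpoint), end = c(s$breakpoint, len),
               copies = c(s$left_copies, s$right_copies))
  } else {
    j <- which(kar$copies$species == species &
               kar$copies$chromosome == chromosome)
    data.frame(start = 0, end = len, copies = kar$copies$copies[j])
  }
}

#' Genome size implied by a karyotype
#'
#' Sum over all (species, chromosome) slots of copy number times
#' chromosome length; chromosomes with a segment call contribute each
#' side's length times its own copy number.
#'
#' @param kar a [karyotype].
#' @param reference a [combined_reference].
#' @return Genome size in bp.
#' @examples
#' ref <- saccharomyces_reference()
#' genome_size_from_karyotype(founder_karyotype(ref, "Scer"), ref) # 2 * Gs
#' @export
genome_size_from_karyotype <- function(kar, reference) {
  stopifnot(inherits(kar, "karyotype"))
  total <- 0
  cp <- kar$copies
  skey <- paste(kar$segments$species, kar$segments$chromosome, sep = "-")
  for (i in seq_len(nrow(cp))) {
    k <- paste(cp$species[i], cp$chromosome[i], sep = "-")
    len <- ref_chrom_row(reference, cp$species[i], cp$chromosome[i])$length
    if (k %in% skey) {
      s <- kar$segments[skey == k, ]
      total <- total + s$left_copies * s$breakpoint +
        s$right_copies * (len - s$breakpoint)
    } else {
      total <- total + cp$copies[i] * len
    }
  }
  total
}

# Majority-length copy number implied by a profile (used to fill the
# slot-level copies of segmented chromosomes).
majority_copies <- function(profile) {
  w <- tapply(profile$end - profile$start, profile$copies, sum)
  as.integer(names(w)[which.max(w)])
}
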