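# Small in-code fixtures shared across the suite.

# Two species, two nuclear chromosomes each (plus mt), Ws = 10 kb.
tiny_reference <- function(window_size = 10000) {
  combined_reference(data.frame(
    species = c("Aaa", "Aaa", "Aaa", "Bbb", "Bbb", "Bbb"),
    chromosome = c("chr1", "chr2", "chrMT", "chr1", "chr2", "chrMT"),
    length = c(1e6, 2e6, 8e4, 1.5e6, 5e5, 7e4),
    mt = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE), window_size)
}

# Uniform-depth coverage tiling the reference's nuclear chromosomes;
# depth may be a single value or a function(n_windows) returning depths.
flat_coverage <- function(reference, depth, species = NULL) {
  nuc <- reference$chrom[!reference$chrom$mt, , drop = FALSE]
  if (!is.null(species)) nuc <- nuc[nuc$species %in% species, , drop = FALSE]
  ws <- reference$window_size
  rows <- lapply(seq_len(nrow(nuc)), function(i) {
    n <- ceiling(nuc$length[i] / ws)
    starts <- (seq_len(n) - 1) * ws
    ends <- pmin(starts + ws, nuc$length[i])
    d <- if (is.function(depth)) depth(n) else rep(depth, n)
    data.frame(species = nuc$species[i], chromosome = nuc$chromosome[i],
               start = starts, end = ends, mean_depth = d,
               stringsAsFactors = FALSE)
  })
  windowed_coverage(do.call(rbind, rows), reference)
}

# Set every window of one chromosome to a given depth vector (recycled).
set_chrom_depth <- function(coverage, species, chromosome, depth) {
  i <- coverage$species == species & coverage$chromosome == chromosome
  coverage$mean_depth[i] <- rep_len(depth, sum(i))
  coverage
}

write_tsv_text <- function(text) {
  path <- tempfile(fileext = ".tsv")
  writeLines(text, path)
  path
}

# Independent brute-force single-changepoint SSE minimizer (the oracle
# for the caller's exhaustive search): plain quadratic loop, no shared
# code with the implementation.
brute_force_changepoint <- function(y, ends, len, min_arm_frac, ws) {
  n <- length(y)
  best <- list(k = NA, sse = Inf)
  tol <- ws / len
  for (k in 1:(n - 1)) {
    lf <- ends[k] / len
    if (lf < min_arm_frac - tol || 1 - lf < min_arm_frac - tol) next
    l <- y[1:k]
    r <- y[(k + 1):n]
    sse <- sum((l - mean(l))^2) + sum((r - mean(r))^2)
    if (sse < best$sse) best <- list(k = k, sse = sse)
  }
  best
}
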