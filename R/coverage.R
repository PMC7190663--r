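#' Windowed coverage table
#'
#' Mean read depth per fixed-size genomic window over a concatenated
#' multi-species reference. Windows are 0-based half-open `[start, end)`,
#' non-overlapping, and tile each chromosome in order; the final window may
#' be shorter than Ws. This is the primary observable of the pipeline (the
#' per-window averages a species-aware mapping pipeline emits).
#'
#' @param records data.frame with columns `species`, `chromosome`, `start`,
#'   `end`, `mean_depth`.
#' @param reference a [combined_reference] to validate against.
#' @return A data.frame of class `windowed_coverage` with the five columns
#'   above, ordered as the reference lists chromosomes.
#' @export
windowed_coverage <- function(records, reference) {
  stopifnot(is.data.frame(records), inherits(reference, "combined_reference"))
  need <- c("species", "chromosome", "start", "end", "mean_depth")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L)
    stop("coverage table is missing columns: ", paste(miss, collapse = ", "))
  rec <- records[, need]
  rec$species <- as.character(rec$species)
  rec$chromosome <- as.character(rec$chromosome)
  rec$start <- as.numeric(rec$start)
  rec$end <- as.numeric(rec$end)
  rec$mean_depth <- as.numeric(rec$mean_depth)
  if (any(!is.finite(rec$mean_depth)) || any(rec$mean_depth < 0))
    stop("window mean depths must be finite and non-negative")
  if (any(rec$start >= rec$end))
    stop("window with start >= end")

  key <- paste(rec$species, rec$chromosome, sep = "-")
  rkey <- paste(reference$chrom$species, reference$chrom$chromosome, sep = "-")
  unknown <- setdiff(unique(key), rkey)
  if (length(unknown) > 0L)
    stop("unknown chromosome key in coverage: ", unknown[1L])

  ws <- reference$window_size
  out <- vector("list", length(rkey))
  for (i in seq_along(rkey)) {
    rows <- rec[key == rkey[i], , drop = FALSE]
    if (nrow(rows) == 0L) next
    rows <- rows[order(rows$start), , drop = FALSE]
    len <- reference$chrom$length[i]
    if (rows$start[1L] != 0)
      stop("tiling gap on ", rkey[i], ": first window starts at ",
           rows$start[1L], ", expected 0")
    if (nrow(rows) > 1L) {
      gap <- which(rows$start[-1L] != rows$end[-nrow(rows)])
      if (length(gap) > 0L) {
        j <- gap[1L]
        if (rows$start[j + 1L] < rows$end[j])
          stop("overlapping windows on ", rkey[i], " at position ",
               rows$start[j + 1L])
        stop("tiling gap on ", rkey[i], " at position ", rows$end[j])
      }
    }
    if (any(rows$end > len))
      stop("window beyond chromosome end on ", rkey[i], " (length ", len, ")")
    if (rows$end[nrow(rows)] != len)
      stop("tiling gap on ", rkey[i], ": last window ends at ",
           rows$end[nrow(rows)], ", expected ", len)
    widths <- rows$end - rows$start
    if (any(widths[-length(widths)] != ws))
      stop("non-Ws window width on ", rkey[i],
           " (only the final window may be short)")
    out[[i]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("windowed_coverage", "data.frame")
  res
}

#' Read windowed coverage from TSV
#'
#' The coverage dialect is a header row `chrom  start  end  mean_depth`,
#' with `chrom` holding the `"tag-chrom"` key, 0-based half-open
#' coordinates, and one row per window.
#'
#' @param path path to the TSV file.
#' @param reference a [combined_reference]; windows are validated against
#'   it (tiling, chromosome lengths, known keys).
#' @return A [windowed_coverage].
#' @export
read_coverage_windows <- function(path, reference) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "mean_depth")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("coverage file is missing columns: ", paste(miss, collapse = ", "))
  sk <- split_chrom_key(df$chrom)
  windowed_coverage(
    data.frame(species = sk$species, chromosome = sk$chromosome,
               start = df$start, end = df$end, mean_depth = df$mean_depth,
               stringsAsFactors = FALSE),
    reference)
}

#' Write windowed coverage to TSV
#'
#' Depths are written with full double precision so that a write/read
#' round-trip reproduces the table bit-identically.
#'
#' @param coverage a [windowed_coverage].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coverage_windows <- function(coverage, path) {
  df <- data.frame(
    chrom = paste(coverage$species, coverage$chromosome, sep = "-"),
    start = sprintf("%.15g", coverage$start),
    end = sprintf("%.15g", coverage$end),
    mean_depth = sprintf("%.17g", coverage$mean_depth),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate per-base depth into coverage windows
#'
#' Consumes per-base depth in the three-column dialect of depth-reporting
#' tools (`chrom  pos  depth`, 1-based positions, no header): positions
#' absent from the file are taken as depth 0. Mean depth is computed per
#' Ws-sized window; the final short window is averaged over its actual
#' length, not padded.
#'
#' @param x path to a per-base depth TSV, or a data.frame with columns
#'   `chrom`, `pos`, `depth`.
#' @param reference a [combined_reference].
#' @param window_size window size in bp; defaults to the reference's Ws.
#' @return A [windowed_coverage] tiling every reference chromosome
#'   (all-zero windows included for chromosomes with no depth rows).
#' @export
windows_from_per_base_depth <- function(x, reference,
                                        window_size = reference$window_size) {
  if (is.character(x)) {
    if (file.size(x) == 0) {
      df <- data.frame(chrom = character(), pos = numeric(),
                       depth = numeric())
    } else {
      df <- utils::read.delim(x, header = FALSE, stringsAsFactors = FALSE)
      if (ncol(df) < 3L) stop("per-base depth file needs 3 columns")
      names(df)[1:3] <- c("chrom", "pos", "depth")
    }
  } else {
    df <- as.data.frame(x)
    if (nrow(df) == 0L && ncol(df) == 0L)
      df <- data.frame(chrom = character(), pos = numeric(),
                       depth = numeric())
  }
  if (any(df$depth < 0)) stop("negative depth in per-base input")
  key <- if (nrow(df) > 0L) as.character(df$chrom) else character()
  rchrom <- reference$chrom
  rkey <- paste(rchrom$species, rchrom$chromosome, sep = "-")
  unknown <- setdiff(unique(key), rkey)
  if (length(unknown) > 0L)
    stop("unknown chromosome key in per-base depth: ", unknown[1L])

  out <- vector("list", nrow(rchrom))
  for (i in seq_len(nrow(rchrom))) {
    len <- rchrom$length[i]
    nwin <- ceiling(len / window_size)
    starts <- (seq_len(nwin) - 1L) * window_size
    ends <- pmin(starts + window_size, len)
    sums <- numeric(nwin)
    rows <- df[key == rkey[i], , drop = FALSE]
    if (nrow(rows) > 0L) {
      if (any(rows$pos < 1 | rows$pos > len))
        stop("per-base position outside ", rkey[i], " (length ", len, ")")
      win <- floor((rows$pos - 1) / window_size) + 1L
      agg <- tapply(rows$depth, win, sum)
      sums[as.integer(names(agg))] <- agg
    }
    out[[i]] <- data.frame(
      species = rchrom$species[i], chromosome = rchrom$chromosome[i],
      start = starts, end = ends, mean_depth = sums / (ends - starts),
      stringsAsFactors = FALSE)
  }
  windowed_coverage(do.call(rbind, out), reference)
}

# Windows for one chromosome of a coverage table, in genomic order.
coverage_chrom <- function(coverage, species, chromosome) {
  rows <- coverage[coverage$species == species &
                   coverage$chromosome == chromosome, , drop = FALSE]
  rows[order(rows$start), , drop = FALSE]
}
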