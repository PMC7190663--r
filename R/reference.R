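#' Combined multi-species reference index
#'
#' A `combined_reference` describes the concatenated reference genome that
#' windowed coverage is computed against: one row per chromosome of each
#' parent species, with nuclear chromosomes and (optionally) the
#' mitochondrial genome of each species. Chromosomes are addressed by the
#' `"tag-chrom"` key convention (species tag, a single hyphen, chromosome
#' name); species tags therefore may not contain hyphens.
#'
#' @param chrom data.frame with columns `species`, `chromosome`, `length`
#'   (bp), and optionally `centromere` (bp, `NA` allowed) and `mt` (logical,
#'   `TRUE` marks a mitochondrial genome; default all `FALSE`).
#' @param window_size coverage window size Ws in bp (> 0).
#'
#' @return An object of class `combined_reference`: a list with elements
#'   `chrom` (validated chromosome table, order preserved) and
#'   `window_size`.
#' @seealso [read_reference_index()], [genome_sizes()]
#' @export
combined_reference <- function(chrom, window_size) {
  stopifnot(is.data.frame(chrom))
  need <- c("species", "chromosome", "length")
  miss <- setdiff(need, names(chrom))
  if (length(miss) > 0L)
    stop("reference index is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(chrom) == 0L)
    stop("reference index has no chromosomes")
  if (!is.numeric(window_size) || length(window_size) != 1L ||
      !is.finite(window_size) || window_size <= 0)
    stop("window_size must be a single positive number")
  chrom$species <- as.character(chrom$species)
  chrom$chromosome <- as.character(chrom$chromosome)
  chrom$length <- as.numeric(chrom$length)
  if (!"centromere" %in% names(chrom)) chrom$centromere <- NA_real_
  if (!"mt" %in% names(chrom)) chrom$mt <- FALSE
  chrom$mt <- as.logical(chrom$mt)
  if (any(grepl("-", chrom$species, fixed = TRUE)))
    stop("species tags may not contain '-' (reserved as the key separator)")
  if (any(!is.finite(chrom$length) | chrom$length <= 0))
    stop("non-positive chromosome length in reference index")
  key <- paste(chrom$species, chrom$chromosome, sep = "-")
  if (anyDuplicated(key))
    stop("duplicate (species, chromosome) in reference index: ",
         key[duplicated(key)][1L])
  rownames(chrom) <- NULL
  structure(list(chrom = chrom, window_size = as.numeric(window_size)),
            class = "combined_reference")
}

#' @export
print.combined_reference <- function(x, ...) {
  nuc <- x$chrom[!x$chrom$mt, , drop = FALSE]
  cat(sprintf(
    "combined_reference: %d species, %d nuclear chromosomes (+%d mt), Ws = %g bp\n",
    length(unique(x$chrom$species)), nrow(nuc), sum(x$chrom$mt),
    x$window_size))
  gs <- genome_sizes(x)
  cat(sprintf("  %s: %.2f Mb\n", names(gs), gs / 1e6), sep = "")
  invisible(x)
}

#' Read a reference index TSV
#'
#' The index is a tab-separated table with a header row and columns
#' `species`, `chromosome`, `length`, plus optional `centromere` and `mt`.
#' The window size may be given either as the `window_size` argument or as a
#' comment line `# window_size=<bp>` before the header.
#'
#' @param path path to the TSV file.
#' @param window_size window size Ws in bp; overrides any header comment.
#' @return A [combined_reference].
#' @export
read_reference_index <- function(path, window_size = NULL) {
  lines <- readLines(path)
  comments <- grep("^#", lines, value = TRUE)
  if (is.null(window_size)) {
    m <- regmatches(comments,
                    regexpr("window_size\\s*=\\s*[0-9.eE+]+", comments))
    if (length(m) > 0L)
      window_size <- as.numeric(sub(".*=\\s*", "", m[[1L]]))
  }
  if (is.null(window_size))
    stop("window_size not supplied and not found in a '# window_size=' header")
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("reference index has no chromosomes")
  df <- utils::read.delim(text = body, stringsAsFactors = FALSE)
  combined_reference(df, window_size)
}

#' Write a reference index TSV
#'
#' @param reference a [combined_reference].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference_index <- function(reference, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# window_size=%.15g", reference$window_size), con)
  utils::write.table(reference$chrom, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-species nuclear genome sizes
#'
#' Gs for each parent species: the sum of its nuclear chromosome lengths,
#' the denominator of the percent-retention statistic.
#'
#' @param reference a [combined_reference].
#' @return Named numeric vector of genome sizes in bp, in species order.
#' @export
genome_sizes <- function(reference) {
  stopifnot(inherits(reference, "combined_reference"))
  nuc <- reference$chrom[!reference$chrom$mt, , drop = FALSE]
  sp <- unique(reference$chrom$species)
  gs <- vapply(sp, function(s) sum(nuc$length[nuc$species == s]), numeric(1))
  gs
}

# Split "tag-chrom" keys at the first hyphen.
split_chrom_key <- function(key) {
  pos <- regexpr("-", key, fixed = TRUE)
  if (any(pos < 0L)) stop("malformed chromosome key (no '-'): ",
                          key[pos < 0L][1L])
  data.frame(species = substr(key, 1L, pos - 1L),
             chromosome = substr(key, pos + 1L, nchar(key)),
             stringsAsFactors = FALSE)
}

# Look up one chromosome row; errors on unknown keys.
ref_chrom_row <- function(reference, species, chromosome) {
  i <- which(reference$chrom$species == species &
             reference$chrom$chromosome == chromosome)
  if (length(i) != 1L)
    stop("unknown chromosome key: ", species, "-", chromosome)
  reference$chrom[i, , drop = FALSE]
}

#' Stylized six-species Saccharomyces reference
#'
#' Builds a `combined_reference` emulating a concatenated reference of six
#' *Saccharomyces* species (Scer, Spar, Smik, Sarb, Skud, Suva), each with
#' the 16 nuclear chromosomes of the genus at S. cerevisiae-like lengths
#' (12.07 Mb nuclear genome for Scer, the other species scaled by a few
#' percent) plus a mitochondrial genome. Intended for simulation, testing
#' and worked examples; it is a synthetic stand-in, not an assembly-derived
#' index.
#'
#' @param species character vector of species tags (hyphens forbidden).
#' @param window_size window size Ws in bp.
#' @return A [combined_reference].
#' @examples
#' ref <- saccharomyces_reference()
#' genome_sizes(ref)["Scer"] / 1e6 # 12.07 Mb
#' @export
saccharomyces_reference <- function(
    species = c("Scer", "Spar", "Smik", "Sarb", "Skud", "Suva"),
    window_size = 10000) {
  # S. cerevisiae chromosome lengths (kb), I..XVI; sum = 12,070 kb
  scer_kb <- c(230, 813, 317, 1532, 577, 270, 1091, 562,
               440, 746, 667, 1078, 924, 784, 1091, 948)
  roman <- c("chrI", "chrII", "chrIII", "chrIV", "chrV", "chrVI", "chrVII",
             "chrVIII", "chrIX", "chrX", "chrXI", "chrXII", "chrXIII",
             "chrXIV", "chrXV", "chrXVI")
  scale <- c(1, 0.985, 1.012, 0.972, 1.028, 0.993, 1.005, 0.98)
  mt_kb <- c(85, 71, 76, 69, 78, 64, 74, 80)
  rows <- lapply(seq_along(species), function(i) {
    f <- scale[((i - 1L) %% length(scale)) + 1L]
    lens <- round(scer_kb * 1000 * f)
    rbind(
      data.frame(species = species[i], chromosome = roman,
                 length = lens, centromere = round(lens * 0.45),
                 mt = FALSE, stringsAsFactors = FALSE),
      data.frame(species = species[i], chromosome = "chrMT",
                 length = mt_kb[((i - 1L) %% length(mt_kb)) + 1L] * 1000,
                 centromere = NA_real_, mt = TRUE, stringsAsFactors = FALSE))
  })
  combined_reference(do.call(rbind, rows), window_size)
}
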