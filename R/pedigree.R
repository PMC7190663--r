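#' Crossing pedigree
#'
#' A pedigree is the DAG of strains along which hybrids are built: founder
#' strains (diploid parents, no parents of their own), hybrid nodes (exactly
#' two parents, whole-genome fusion) and evolved isolates (exactly one
#' ancestor). New chromosomal aberrations are counted per node against the
#' expectation formed from its parents.
#'
#' @param nodes data.frame with columns `node`, `role` (one of `founder`,
#'   `hybrid`, `evolved`), `parent1`, `parent2` (empty string or `NA` when
#'   absent) and, optionally, `species` (the founder's species tag).
#' @return A data.frame of class `pedigree` with a `topo` attribute giving
#'   node ids in a topological (founders-first) order.
#' @export
pedigree <- function(nodes) {
  stopifnot(is.data.frame(nodes))
  need <- c("node", "role", "parent1", "parent2")
  miss <- setdiff(need, names(nodes))
  if (length(miss) > 0L)
    stop("pedigree table is missing columns: ", paste(miss, collapse = ", "))
  ped <- nodes
  ped$node <- as.character(ped$node)
  ped$role <- as.character(ped$role)
  for (p in c("parent1", "parent2")) {
    ped[[p]] <- as.character(ped[[p]])
    ped[[p]][is.na(ped[[p]]) | ped[[p]] == ""] <- NA_character_
  }
  if (!"species" %in% names(ped)) ped$species <- NA_character_
  ped$species <- as.character(ped$species)
  if (anyDuplicated(ped$node))
    stop("duplicate node id: ", ped$node[duplicated(ped$node)][1L])
  bad_role <- setdiff(unique(ped$role), c("founder", "hybrid", "evolved"))
  if (length(bad_role) > 0L) stop("unknown role: ", bad_role[1L])

  npar <- rowSums(!is.na(ped[, c("parent1", "parent2")]))
  if (any(ped$role == "founder" & npar != 0L))
    stop("founder with parents: ",
         ped$node[ped$role == "founder" & npar != 0L][1L])
  if (any(ped$role == "hybrid" & npar != 2L))
    stop("hybrid without exactly 2 parents: ",
         ped$node[ped$role == "hybrid" & npar != 2L][1L])
  if (any(ped$role == "evolved" & npar != 1L))
    stop("evolved node without exactly 1 ancestor: ",
         ped$node[ped$role == "evolved" & npar != 1L][1L])

  parents <- unique(stats::na.omit(c(ped$parent1, ped$parent2)))
  unknown <- setdiff(parents, ped$node)
  if (length(unknown) > 0L) stop("unknown parent id: ", unknown[1L])

  # Kahn topological sort; failure to exhaust the nodes means a cycle.
  topo <- character(0)
  placed <- character(0)
  remaining <- ped$node
  repeat {
    ready <- remaining[vapply(remaining, function(n) {
      i <- which(ped$node == n)
      ps <- stats::na.omit(c(ped$parent1[i], ped$parent2[i]))
      all(ps %in% placed)
    }, logical(1))]
    if (length(ready) == 0L) break
    topo <- c(topo, ready)
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  if (length(remaining) > 0L)
    stop("pedigree contains a cycle involving: ",
         paste(remaining, collapse = ", "))
  rownames(ped) <- NULL
  structure(ped, class = c("pedigree", "data.frame"), topo = topo)
}

#' Read a pedigree TSV
#'
#' Tab-separated with header `node  role  parent1  parent2` and an optional
#' `species` column (founder species tags). Empty parent cells mean no
#' parent.
#'
#' @param path path to the TSV file.
#' @return A [pedigree].
#' @export
read_pedigree <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  pedigree(df)
}

#' Write a pedigree TSV
#'
#' @param ped a [pedigree].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  df <- as.data.frame(ped)
  df[is.na(df)] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Parent ids of one node (character(0) for founders).
pedigree_parents <- function(ped, node) {
  i <- which(ped$node == node)
  if (length(i) != 1L) stop("unknown node: ", node)
  as.character(stats::na.omit(c(ped$parent1[i], ped$parent2[i])))
}

#' Example six-founder crossing pedigree
#'
#' Eleven nodes mirroring an iterative crossing scheme: six diploid
#' founders (one per species of [saccharomyces_reference()]), three
#' two-species hybrids, one four-species hybrid built from two of them, and
#' a final six-species hybrid.
#'
#' @param species founder species tags (length 6).
#' @return A [pedigree].
#' @examples
#' ped <- example_pedigree()
#' attr(ped, "topo")
#' @export
example_pedigree <- function(
    species = c("Scer", "Spar", "Smik", "Sarb", "Skud", "Suva")) {
  stopifnot(length(species) == 6L)
  f <- paste0("F_", species)
  nodes <- data.frame(
    node = c(f, "H2a", "H2b", "H2c", "H4", "H6"),
    role = c(rep("founder", 6L), rep("hybrid", 5L)),
    parent1 = c(rep(NA, 6L), f[1L], f[3L], f[5L], "H2a", "H4"),
    parent2 = c(rep(NA, 6L), f[2L], f[4L], f[6L], "H2b", "H2c"),
    species = c(species, rep(NA, 5L)),
    stringsAsFactors = FALSE)
  pedigree(nodes)
}
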