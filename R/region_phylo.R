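#' Define antigen-presenting region windows
#'
#' Regions (e.g. the alpha-1/alpha-2 helices and the beta-sheets forming
#' the antigen-presenting platform of MHC-like proteins) are intervals on a
#' reference query's residue coordinates. Regions within a set must not
#' overlap.
#'
#' @param name Character vector of region names.
#' @param start,end 1-based inclusive residue coordinates.
#' @return A data frame with columns `name`, `start`, `end`.
#' @export
region_specs <- function(name, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 1L) || any(start > end)) {
    stop("region coordinates must satisfy 1 <= start <= end")
  }
  ord <- order(start)
  s <- start[ord]; e <- end[ord]
  if (length(s) > 1L && any(s[-1L] <= e[-length(e)])) {
    stop("regions overlap")
  }
  data.frame(name = name, start = start, end = end, stringsAsFactors = FALSE)
}

#' Read a region-spec TSV (columns: name, start, end)
#'
#' @param path Path to a tab-separated file with a header line.
#' @return A validated region-spec data frame.
#' @export
read_region_specs <- function(path) {
  if (!file.exists(path)) stop("region spec file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  region_specs(df$name, df$start, df$end)
}

#' Extract and concatenate region sequences from a protein
#'
#' @param protein A protein string (may contain `-` for uncovered
#'   positions, which are preserved), or a single-row record with `seq`.
#' @param regions A [region_specs()] data frame.
#' @return The concatenation of the region substrings in spec order.
#' @examples
#' extract_regions("MKTAQW", region_specs(c("r1", "r2"), c(1, 5), c(3, 6)))
#' @export
extract_regions <- function(protein, regions) {
  if (is.list(protein)) protein <- protein$seq
  if (any(regions$end > nchar(protein))) {
    bad <- regions$name[regions$end > nchar(protein)]
    stop("region beyond sequence end: ", paste(bad, collapse = ", "))
  }
  paste(substring(protein, regions$start, regions$end), collapse = "")
}

#' Pairwise percent identity of two column-aligned sequences
#'
#' Sequences must be equal length (pre-aligned or reference-coordinate
#' extracts). Columns where either sequence has `-` are excluded from the
#' denominator.
#'
#' @param seq_a,seq_b Equal-length strings.
#' @return Percent identity in `[0, 100]`; `NA` when no column is
#'   comparable.
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("sequences must have equal length (", nchar(seq_a), " vs ",
         nchar(seq_b), "); align or pad first")
  }
  a <- strsplit(seq_a, "", fixed = TRUE)[[1]]
  b <- strsplit(seq_b, "", fixed = TRUE)[[1]]
  comp <- a != "-" & b != "-"
  if (!any(comp)) return(NA_real_)
  100 * sum(a[comp] == b[comp]) / sum(comp)
}

#' All-vs-all percent identity matrix
#'
#' @param seqs Named character vector of equal-length sequences.
#' @return A symmetric matrix of pairwise identities with 100 on the
#'   diagonal.
#' @export
identity_matrix <- function(seqs) {
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        m[i, j] <- m[j, i] <- pairwise_identity(seqs[[i]], seqs[[j]])
      }
    }
  }
  m
}

#' Convert percent identity to a p-distance-scale distance
#'
#' `d = 100 - identity`; no evolutionary-model correction is applied, since
#' the trees built from it are descriptive.
#'
#' @param identity_percent Identity value(s) in `[0, 100]`.
#' @return `100 - identity_percent`.
#' @export
identity_to_distance <- function(identity_percent) {
  stopifnot(all(identity_percent >= 0 & identity_percent <= 100, na.rm = TRUE))
  100 - identity_percent
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via [ape::nj()]). Negative branch
#' lengths, which NJ can produce on non-additive matrices, are clamped to
#' zero with the deficit shifted to the sister branch so path lengths are
#' approximately preserved.
#'
#' @param d A symmetric distance matrix (or `dist`) over at least 3 taxa.
#' @return An [ape::phylo] tree.
#' @export
neighbor_joining <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 3L) stop("neighbor joining requires at least 3 taxa")
  if (max(abs(m - t(m))) > 1e-8 || any(diag(m) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }
  tree <- ape::nj(m)
  clamp_negative_branches(tree)
}

# Set negative branch lengths to 0, moving the deficit onto the sister
# branch (Kuhner & Felsenstein convention) so pairwise path lengths change
# as little as possible.
clamp_negative_branches <- function(tree) {
  for (it in seq_len(length(tree$edge.length) + 1L)) {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0L) break
    e <- neg[1L]
    parent <- tree$edge[e, 1L]
    sibs <- setdiff(which(tree$edge[, 1L] == parent), e)
    if (length(sibs) > 0L) {
      tree$edge.length[sibs[1L]] <- tree$edge.length[sibs[1L]] +
        tree$edge.length[e]
    }
    tree$edge.length[e] <- 0
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Build an identity-distance NJ tree from region extracts
#'
#' Convenience wrapper: extract regions from each protein, compute the
#' pairwise identity matrix, convert to distances and run neighbor joining.
#'
#' @param proteins Named character vector of equal-length (aligned or
#'   reference-coordinate) protein sequences.
#' @param regions A [region_specs()] data frame, or `NULL` to use the full
#'   sequences.
#' @return A list with `identity` (matrix), `distance` (matrix) and `tree`
#'   (phylo).
#' @export
region_identity_tree <- function(proteins, regions = NULL) {
  extracts <- if (is.null(regions)) proteins else {
    vapply(proteins, extract_regions, character(1), regions = regions)
  }
  idm <- identity_matrix(extracts)
  dm <- identity_to_distance(idm)
  diag(dm) <- 0
  list(identity = idm, distance = dm, tree = neighbor_joining(dm))
}
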