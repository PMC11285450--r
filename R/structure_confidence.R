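#' Parse per-residue pLDDT from an AlphaFold-style PDB file
#'
#' AlphaFold stores the per-residue pLDDT confidence (0-100) in the
#' B-factor column of every atom. One value per residue is returned: the CA
#' atom's B-factor, falling back to the mean over the residue's atoms (with
#' a warning) when no CA is present.
#'
#' @param pdb_path Path to a PDB file with ATOM records.
#' @return A data frame with columns `chain`, `resno` (author numbering),
#'   `residue_index` (1-based, contiguous per chain) and `plddt`.
#' @export
parse_plddt <- function(pdb_path) {
  if (!file.exists(pdb_path)) stop("PDB file not found: ", pdb_path)
  pdb <- bio3d::read.pdb(pdb_path)
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no ATOM records in ", pdb_path)
  key <- paste(atoms$chain, atoms$resno, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(chain = atoms$chain[first], resno = atoms$resno[first],
                    stringsAsFactors = FALSE)
  out$plddt <- vapply(which(first), function(i) {
    rows <- atoms[key == key[i], , drop = FALSE]
    ca <- rows$b[rows$elety == "CA"]
    if (length(ca) >= 1L) {
      ca[1L]
    } else {
      warning("no CA atom for residue ", rows$resno[1L], " chain ",
              rows$chain[1L], "; using residue mean B-factor")
      mean(rows$b)
    }
  }, numeric(1))
  out$residue_index <- stats::ave(seq_len(nrow(out)), out$chain,
                                  FUN = seq_along)
  out[, c("chain", "resno", "residue_index", "plddt")]
}

#' Parse an AlphaFold PAE matrix from JSON
#'
#' Accepts the published AlphaFold JSON layouts: an object (or
#' single-element array of objects) with a `predicted_aligned_error` (or
#' `pae`) field holding an n-by-n array of expected positional errors in
#' Angstroms, or the legacy flat `residue1`/`residue2`/`distance` triplet
#' layout. The matrix need not be symmetric: `pae[x, y]` is the expected
#' error at residue x when aligned on residue y.
#'
#' @param json_path Path to the PAE JSON file.
#' @return An n-by-n numeric matrix.
#' @export
parse_pae <- function(json_path) {
  if (!file.exists(json_path)) stop("PAE JSON not found: ", json_path)
  obj <- jsonlite::fromJSON(json_path, simplifyVector = TRUE)
  if (is.data.frame(obj) && nrow(obj) == 1L) obj <- as.list(obj[1L, ])
  if (is.list(obj) && is.null(names(obj)) && length(obj) == 1L) {
    obj <- obj[[1L]]
  }
  pae <- obj$predicted_aligned_error %||% obj$pae
  if (!is.null(pae)) {
    if (is.list(pae) && length(pae) == 1L) pae <- pae[[1L]]
    if (is.list(pae)) {
      lens <- lengths(pae)
      if (length(unique(lens)) != 1L) stop("ragged PAE rows in ", json_path)
      pae <- do.call(rbind, pae)
    }
    m <- as.matrix(pae)
  } else if (!is.null(obj$residue1)) {
    n <- max(obj$residue1)
    if (length(obj$distance) != n * max(obj$residue2)) {
      stop("incomplete legacy PAE triplets in ", json_path)
    }
    m <- matrix(NA_real_, n, n)
    m[cbind(obj$residue1, obj$residue2)] <- obj$distance
  } else {
    stop("unrecognized PAE JSON layout in ", json_path)
  }
  if (nrow(m) != ncol(m)) stop("PAE matrix is not square in ", json_path)
  if (any(is.na(m))) stop("PAE matrix has missing entries in ", json_path)
  if (any(m < 0)) stop("PAE values must be non-negative in ", json_path)
  unname(m)
}

#' Classify fold reliability from per-residue pLDDT
#'
#' A region (typically an annotated alpha-helix or beta-sheet window) is
#' unreliable when its aggregated pLDDT falls strictly below the threshold
#' (the AlphaFold low-confidence band starts below 70, so a region at
#' exactly 70.0 is reliable). The protein-level verdict is unreliable as
#' soon as any designated secondary-structure region is.
#'
#' @param residue_conf A [parse_plddt()] data frame (or any data frame with
#'   `residue_index` and `plddt`).
#' @param regions A [region_specs()] data frame on residue indices.
#' @param plddt_threshold Confidence threshold; default 70.
#' @param aggregate Region aggregator: `"mean"` (default) or `"min"`.
#' @return A list with `regions` (data frame: `name`, `start`, `end`,
#'   `plddt`, `reliable`) and `protein_reliable` (logical).
#' @export
classify_fold <- function(residue_conf, regions, plddt_threshold = 70,
                          aggregate = c("mean", "min")) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "mean") mean else min
  vals <- vapply(seq_len(nrow(regions)), function(i) {
    idx <- residue_conf$residue_index >= regions$start[i] &
      residue_conf$residue_index <= regions$end[i]
    if (!any(idx)) {
      stop("region ", regions$name[i], " contains no residues")
    }
    agg(residue_conf$plddt[idx])
  }, numeric(1))
  out <- data.frame(name = regions$name, start = regions$start,
                    end = regions$end, plddt = vals,
                    reliable = !(vals < plddt_threshold),
                    stringsAsFactors = FALSE)
  list(regions = out, protein_reliable = all(out$reliable))
}

#' Mean predicted aligned error per region pair
#'
#' For two regions A and B the summary is the mean PAE over both
#' orientations (x in A aligned on y in B, and x in B aligned on y in A);
#' for a region against itself it is the mean over its own block. Low
#' intra-region and high inter-region error indicates independently
#' well-packed but mutually unreliable domains.
#'
#' @param pae A PAE matrix from [parse_pae()].
#' @param regions A [region_specs()] data frame on residue indices.
#' @return A data frame with columns `region_a`, `region_b`, `mean_pae`
#'   for every unordered region pair (including self-pairs).
#' @export
summarize_pae <- function(pae, regions) {
  n <- nrow(pae)
  if (any(regions$end > n)) stop("region beyond PAE matrix size ", n)
  idx <- lapply(seq_len(nrow(regions)), function(i) {
    regions$start[i]:regions$end[i]
  })
  pairs <- which(upper.tri(diag(nrow(regions)), diag = TRUE), arr.ind = TRUE)
  out <- data.frame(region_a = regions$name[pairs[, 1L]],
                    region_b = regions$name[pairs[, 2L]],
                    mean_pae = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(pairs))) {
    a <- idx[[pairs[k, 1L]]]; b <- idx[[pairs[k, 2L]]]
    vals <- if (identical(a, b)) pae[a, b] else c(pae[a, b], pae[b, a])
    out$mean_pae[k] <- mean(vals)
  }
  out
}
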