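#' Tier thresholds for hit filtering
#'
#' Two tiers of homologous reads are kept: "tolerable" similarity
#' (E-value < `evalue_max` and percent identity > `identity_min_tolerable`)
#' and "low" similarity (`identity_min_low` < identity <=
#' `identity_min_tolerable`, with no E-value condition). Everything else is
#' rejected. Note the asymmetry: the boundaries are strict at 40 and 30 and
#' inclusive at the top of the low band, so identity exactly 40 is "low"
#' and exactly 30 is rejected.
#'
#' @param evalue_max Maximum E-value for the tolerable tier (exclusive).
#' @param identity_min_tolerable Identity cutoff between tiers.
#' @param identity_min_low Lower identity bound of the low tier (exclusive).
#' @return An object of class `tier_thresholds`.
#' @export
tier_thresholds <- function(evalue_max = 1e-4, identity_min_tolerable = 40,
                            identity_min_low = 30) {
  stopifnot(identity_min_low < identity_min_tolerable)
  structure(list(evalue_max = evalue_max,
                 identity_min_tolerable = identity_min_tolerable,
                 identity_min_low = identity_min_low),
            class = "tier_thresholds")
}

#' Assign hits to similarity tiers
#'
#' @param hits A hit data frame (columns `pident`, `evalue`), or omit and
#'   pass `pident`/`evalue` directly.
#' @param thresholds A [tier_thresholds()] object.
#' @param pident,evalue Numeric vectors used when `hits` is `NULL`.
#' @return Character vector over `{"tolerable", "low", "rejected"}`, one
#'   per hit.
#' @export
assign_tier <- function(hits = NULL, thresholds = tier_thresholds(),
                        pident = hits$pident, evalue = hits$evalue) {
  ifelse(evalue < thresholds$evalue_max &
           pident > thresholds$identity_min_tolerable, "tolerable",
         ifelse(pident > thresholds$identity_min_low &
                  pident <= thresholds$identity_min_tolerable, "low",
                "rejected"))
}

#' Extract and translate the matched region of a read
#'
#' Takes the nucleotides spanned by the hit on the original read
#' (reverse-complementing when the hit is on the minus strand, i.e. when
#' `sstart > send`) and translates them in the hit's reading frame. Stop
#' codons are kept as `*`.
#'
#' @param read A single-row data frame or list with `id` and `bases`.
#' @param hit A one-row hit data frame for this read.
#' @return The peptide string of the matched region.
#' @export
extract_and_translate <- function(read, hit) {
  if (hit$sseqid != read$id) {
    stop("hit read id ", hit$sseqid, " does not match read ", read$id)
  }
  L <- nchar(read$bases)
  lo <- min(hit$sstart, hit$send)
  hi <- max(hit$sstart, hit$send)
  if (lo < 1L || hi > L) {
    stop("hit coordinates [", lo, ", ", hi, "] outside read ", read$id,
         " of length ", L)
  }
  region <- substr(read$bases, lo, hi)
  if (hit$sstart > hit$send) region <- reverse_complement(region)
  translate_dna(region, "+", 1L)
}

#' Longest stop-free peptide segment
#'
#' @param peptide Peptide string(s), possibly containing `*`.
#' @return Integer vector: length of the longest `*`-free run in each.
#' @examples
#' max_orf_len("MK*LLTQ")  # 4
#' @export
max_orf_len <- function(peptide) {
  vapply(peptide, function(p) {
    if (!nzchar(p)) return(0L)
    parts <- strsplit(p, "*", fixed = TRUE)[[1]]
    if (length(parts) == 0L) 0L else max(nchar(parts))
  }, integer(1), USE.NAMES = FALSE)
}

#' Normalized stop-free peptide length
#'
#' The longest stop-free peptide length from a matched read, multiplied by
#' the read's identity fraction to the query. This is the statistic
#' compared between gene sets to detect pseudogenization: premature stop
#' codons shorten the stop-free segment, divergence shrinks the identity
#' fraction.
#'
#' @param max_orf_len Longest stop-free segment length(s).
#' @param identity_fraction Read identity fraction(s) in `[0, 1]`.
#' @return `max_orf_len * identity_fraction`.
#' @export
normalized_length <- function(max_orf_len, identity_fraction) {
  stopifnot(all(identity_fraction >= 0 & identity_fraction <= 1))
  max_orf_len * identity_fraction
}

#' Recover, tier and translate homologous read regions
#'
#' Applies the tier filter to a hit table, extracts and translates each
#' retained hit's matched region, and computes the stop-free and normalized
#' peptide-length statistics.
#'
#' @param reads Data frame of reads (columns `id`, `bases`).
#' @param hits Hit data frame for one query.
#' @param thresholds A [tier_thresholds()] object.
#' @return A data frame with columns `read_id`, `tier`, `peptide`,
#'   `max_orf_len`, `identity_fraction`, `normalized_len` (rejected hits are
#'   dropped).
#' @export
recover_peptides <- function(reads, hits, thresholds = tier_thresholds()) {
  if (is.null(hits) || nrow(hits) == 0L) {
    return(data.frame(read_id = character(), tier = character(),
                      peptide = character(), max_orf_len = integer(),
                      identity_fraction = numeric(),
                      normalized_len = numeric(), stringsAsFactors = FALSE))
  }
  tier <- assign_tier(hits, thresholds)
  keep <- tier != "rejected"
  hits <- hits[keep, , drop = FALSE]
  tier <- tier[keep]
  idx <- match(hits$sseqid, reads$id)
  if (anyNA(idx)) {
    stop("hits reference reads absent from the read set: ",
         paste(unique(hits$sseqid[is.na(idx)]), collapse = ", "))
  }
  pep <- vapply(seq_len(nrow(hits)), function(i) {
    extract_and_translate(list(id = reads$id[idx[i]], bases = reads$bases[idx[i]]),
                          hits[i, , drop = FALSE])
  }, character(1))
  orf <- max_orf_len(pep)
  idf <- hits$pident / 100
  data.frame(read_id = hits$sseqid, tier = tier, peptide = pep,
             max_orf_len = orf, identity_fraction = idf,
             normalized_len = normalized_length(orf, idf),
             stringsAsFactors = FALSE)
}

#' Write recovered peptides as FASTA (statistics in the description line)
#'
#' @param peptides A [recover_peptides()] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptides_fasta <- function(peptides, path) {
  rec <- data.frame(
    id = peptides$read_id,
    desc = sprintf("tier=%s max_orf=%d identity=%.4f normalized_len=%.3f",
                   peptides$tier, peptides$max_orf_len,
                   peptides$identity_fraction, peptides$normalized_len),
    seq = peptides$peptide, stringsAsFactors = FALSE)
  write_fasta(rec, path)
}
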