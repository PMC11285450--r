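#' Scoring parameters for the translated search
#'
#' Bundles the substitution matrix, affine gap penalties, Karlin-Altschul
#' statistical parameters and the search-space dimensions used for E-values.
#' The defaults (BLOSUM62, gap open 11, gap extend 1, K = 0.041,
#' lambda = 0.267) mimic the BLASTX family of translated searches. A gap of
#' length k costs `gap_open + k * gap_extend`.
#'
#' @param substitution_matrix Either the name `"BLOSUM62"` or a named square
#'   integer matrix over the amino-acid alphabet (including `X` and `*`).
#' @param gap_open,gap_extend Positive integer gap penalties.
#' @param karlin_K,karlin_lambda Positive Karlin-Altschul parameters.
#' @param search_space_m Total query residues (set automatically by the
#'   search functions when `NULL`).
#' @param search_space_n Total translated target residues (set automatically
#'   when `NULL`).
#' @param evalue_ceiling Hits with E-value above this are not reported.
#' @return An object of class `scoring_params`.
#' @export
scoring_params <- function(substitution_matrix = "BLOSUM62",
                           gap_open = 11L, gap_extend = 1L,
                           karlin_K = 0.041, karlin_lambda = 0.267,
                           search_space_m = NULL, search_space_n = NULL,
                           evalue_ceiling = 10) {
  if (is.character(substitution_matrix)) {
    e <- new.env()
    utils::data(list = substitution_matrix, package = "Biostrings", envir = e)
    substitution_matrix <- get(substitution_matrix, envir = e)
  }
  stopifnot(is.matrix(substitution_matrix),
            nrow(substitution_matrix) == ncol(substitution_matrix),
            gap_open > 0, gap_extend > 0, karlin_K > 0, karlin_lambda > 0)
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 karlin_K = karlin_K, karlin_lambda = karlin_lambda,
                 search_space_m = search_space_m,
                 search_space_n = search_space_n,
                 evalue_ceiling = evalue_ceiling),
            class = "scoring_params")
}

# Map a peptide to 0-based row indices of the substitution matrix; residues
# absent from the matrix alphabet fall back to 'X'.
aa_indices <- function(peptide, alphabet) {
  ch <- strsplit(peptide, "", fixed = TRUE)[[1]]
  idx <- match(ch, alphabet)
  idx[is.na(idx)] <- match("X", alphabet)
  idx - 1L
}

#' Optimal local alignment of two peptides (Smith-Waterman, affine gaps)
#'
#' Deterministic traceback: ties are broken diagonal > up > left, and among
#' equal-scoring end cells the first in row-major order is used.
#'
#' @param query_pep,target_pep Non-empty peptide strings.
#' @param scoring A [scoring_params()] object.
#' @return A list with elements `score`, `qstart`, `qend`, `tstart`, `tend`
#'   (1-based inclusive coordinates), `aligned_query`, `aligned_target`
#'   (gap character `-`), `identical`, `mismatches`, `gap_opens` and
#'   `alignment_length`. A score of 0 denotes the empty alignment.
#' @examples
#' smith_waterman("MKT", "MKT", scoring_params())$score  # 15 under BLOSUM62
#' @export
smith_waterman <- function(query_pep, target_pep, scoring = scoring_params()) {
  if (!nzchar(query_pep) || !nzchar(target_pep)) {
    stop("smith_waterman: empty peptide input")
  }
  alpha <- rownames(scoring$substitution_matrix)
  res <- .sw_align_cpp(aa_indices(query_pep, alpha),
                       aa_indices(target_pep, alpha),
                       scoring$substitution_matrix,
                       scoring$gap_open, scoring$gap_extend)
  qch <- strsplit(query_pep, "", fixed = TRUE)[[1]]
  tch <- strsplit(target_pep, "", fixed = TRUE)[[1]]
  aq <- rep("-", length(res$qa))
  aq[res$qa >= 0] <- qch[res$qa[res$qa >= 0] + 1L]
  at <- rep("-", length(res$ta))
  at[res$ta >= 0] <- tch[res$ta[res$ta >= 0] + 1L]
  list(score = res$score,
       qstart = res$qstart, qend = res$qend,
       tstart = res$tstart, tend = res$tend,
       aligned_query = paste(aq, collapse = ""),
       aligned_target = paste(at, collapse = ""),
       identical = res$identical, mismatches = res$mismatches,
       gap_opens = res$gapopens, alignment_length = res$length)
}

#' Exhaustive reference score for a local alignment
#'
#' Enumerates every local alignment path under the same affine gap model as
#' [smith_waterman()] and returns the optimal score. Exponential-time
#' reference implementation used to validate the dynamic-programming kernel;
#' restricted to peptides of length at most 12.
#'
#' @inheritParams smith_waterman
#' @return The optimal local alignment score (0 for the empty alignment).
#' @export
local_align_score_naive <- function(query_pep, target_pep,
                                    scoring = scoring_params()) {
  alpha <- rownames(scoring$substitution_matrix)
  .sw_naive_cpp(aa_indices(query_pep, alpha), aa_indices(target_pep, alpha),
                scoring$substitution_matrix, scoring$gap_open,
                scoring$gap_extend)
}

#' Karlin-Altschul E-value of a raw alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with the raw (uncorrected) search
#' space `m * n`.
#'
#' @param raw_score Non-negative raw alignment score(s).
#' @param scoring A [scoring_params()] object with `search_space_m` and
#'   `search_space_n` set.
#' @return E-value(s); strictly decreasing in `raw_score`, linear in m and n.
#' @export
evalue_of <- function(raw_score, scoring) {
  m <- scoring$search_space_m
  n <- scoring$search_space_n
  if (is.null(m) || is.null(n)) {
    stop("search_space_m and search_space_n must be set to compute E-values")
  }
  scoring$karlin_K * m * n * exp(-scoring$karlin_lambda * raw_score)
}

#' Bit score of a raw alignment score
#'
#' `S' = (lambda * S - ln K) / ln 2`.
#'
#' @inheritParams evalue_of
#' @export
bitscore_of <- function(raw_score, scoring) {
  (scoring$karlin_lambda * raw_score - log(scoring$karlin_K)) / log(2)
}

# Total residues produced by six-frame translation of a read of length L.
translated_residues <- function(read_lengths) {
  sum(vapply(read_lengths, function(L) {
    2L * sum((L - 0:2) %/% 3L)
  }, integer(1)))
}

# Map aligned positions on a frame's peptide back to 1-based nucleotide
# coordinates on the original read. Returns c(sstart, send) in the BLAST
# convention: sstart > send on the minus strand.
frame_to_read_coords <- function(tstart, tend, strand, frame, read_length) {
  nt1 <- frame + 3L * (tstart - 1L)
  nt2 <- frame + 3L * tend - 1L
  if (strand == "+") c(nt1, nt2) else c(read_length - nt1 + 1L, read_length - nt2 + 1L)
}

#' Search one read against one protein query over all six frames
#'
#' The read is translated in all three frames on both strands and each
#' peptide is locally aligned to the query. The best frame's alignment is
#' returned as a single hit (frame ties broken by lower E-value, then plus
#' strand before minus, then lower frame number). Hits with E-value above
#' `scoring$evalue_ceiling` are suppressed.
#'
#' @param query A single-row data frame with columns `id` and `seq` (as from
#'   [read_fasta()]), or a named list with those elements.
#' @param read A single-row data frame with columns `id` and `bases` (as
#'   from [read_fastq()]), or a named list.
#' @param scoring A [scoring_params()] object. When its search-space fields
#'   are `NULL`, `m` is the query length and `n` the read's six-frame
#'   translated residue count.
#' @return A one-row hit data frame (see [search_all()] for columns), or
#'   `NULL` when no reportable alignment exists.
#' @export
search_read <- function(query, read, scoring = scoring_params()) {
  qseq <- query$seq
  qid <- query$id
  bases <- read$bases
  rid <- read$id
  if (is.null(scoring$search_space_m)) scoring$search_space_m <- nchar(qseq)
  if (is.null(scoring$search_space_n)) {
    scoring$search_space_n <- translated_residues(nchar(bases))
  }
  frames <- six_frame_translations(bases)
  best <- NULL
  for (i in seq_len(6L)) {
    pep <- frames$peptide[i]
    if (!nzchar(pep)) next
    aln <- smith_waterman(qseq, pep, scoring)
    if (aln$score <= 0) next
    if (is.null(best) || aln$score > best$aln$score) {
      best <- list(aln = aln, strand = frames$strand[i], frame = frames$frame[i])
    }
  }
  if (is.null(best)) return(NULL)
  ev <- evalue_of(best$aln$score, scoring)
  if (ev > scoring$evalue_ceiling) return(NULL)
  aln <- best$aln
  sc <- frame_to_read_coords(aln$tstart, aln$tend, best$strand, best$frame,
                             nchar(bases))
  data.frame(
    qseqid = qid, sseqid = rid,
    pident = round(100 * aln$identical / aln$alignment_length, 2),
    length = aln$alignment_length, mismatch = aln$mismatches,
    gapopen = aln$gap_opens, qstart = aln$qstart, qend = aln$qend,
    sstart = sc[1], send = sc[2], evalue = ev,
    bitscore = round(bitscore_of(aln$score, scoring), 1),
    strand = best$strand, frame = best$frame, score = aln$score,
    qaln = aln$aligned_query, taln = aln$aligned_target,
    stringsAsFactors = FALSE)
}

#' Search all reads against all protein queries
#'
#' Concatenates per-(query, read) best hits in stable (query, then read
#' input) order. The E-value search space is shared across the whole read
#' set: `m` is the query length and `n` the total six-frame translated
#' residue count of all reads, so per-hit E-values do not depend on how the
#' read set is split.
#'
#' @param queries Data frame of protein queries (columns `id`, `seq`).
#' @param reads Data frame of reads (columns `id`, `bases`).
#' @param scoring A [scoring_params()] object.
#' @param threads Number of worker processes (forked; results are identical
#'   to the serial order).
#' @return A hit data frame with the 12 BLAST/DIAMOND outfmt-6 columns
#'   (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#'   evalue bitscore`) plus `strand`, `frame`, `score`, `qaln`, `taln`.
#' @export
search_all <- function(queries, reads, scoring = scoring_params(), threads = 1L) {
  if (is.null(scoring$search_space_n)) {
    scoring$search_space_n <- translated_residues(nchar(reads$bases))
  }
  out <- list()
  for (qi in seq_len(nrow(queries))) {
    sc <- scoring
    sc$search_space_m <- nchar(queries$seq[qi])
    query <- list(id = queries$id[qi], seq = queries$seq[qi])
    one <- function(ri) {
      search_read(query, list(id = reads$id[ri], bases = reads$bases[ri]), sc)
    }
    hits <- if (threads > 1L) {
      parallel::mclapply(seq_len(nrow(reads)), one, mc.cores = threads)
    } else {
      lapply(seq_len(nrow(reads)), one)
    }
    out[[qi]] <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(empty_hits())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_hits <- function() {
  data.frame(qseqid = character(), sseqid = character(), pident = numeric(),
             length = integer(), mismatch = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), evalue = numeric(), bitscore = numeric(),
             strand = character(), frame = integer(), score = integer(),
             qaln = character(), taln = character(), stringsAsFactors = FALSE)
}

outfmt6_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                  "bitscore")

#' Write hits as a BLAST/DIAMOND outfmt-6 compatible TSV
#'
#' Only the 12 standard columns are written (no header), so the file is
#' interchangeable with DIAMOND `--outfmt 6` output.
#'
#' @param hits A hit data frame from [search_all()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits[, outfmt6_cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BLAST/DIAMOND outfmt-6 TSV of hits
#'
#' Accepts any 12-column outfmt-6 file (e.g. real DIAMOND output). Strand is
#' recovered from the subject coordinate orientation; the frame and the
#' alignment strings, which outfmt 6 does not carry, are `NA`.
#'
#' @param path Path to a tab-separated outfmt-6 file without header.
#' @return A hit data frame in the layout of [search_all()].
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  raw <- tryCatch(utils::read.table(path, sep = "\t", stringsAsFactors = FALSE),
                  error = function(e) NULL)
  if (is.null(raw)) return(empty_hits())
  if (ncol(raw) < 12L) stop("expected 12 outfmt-6 columns in ", path)
  names(raw)[1:12] <- outfmt6_cols
  raw <- raw[, 1:12]
  raw$strand <- ifelse(raw$sstart <= raw$send, "+", "-")
  raw$frame <- NA_integer_
  raw$score <- NA_integer_
  raw$qaln <- NA_character_
  raw$taln <- NA_character_
  raw
}
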