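#' Read protein (or nucleotide) sequences from a FASTA file
#'
#' Sequences are returned in file order with whitespace stripped. The record
#' id is the first whitespace-delimited token of the header; the remainder of
#' the header becomes the description.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `desc` and `seq` (one row per
#'   record).
#' @examples
#' fp <- tempfile(fileext = ".fa")
#' writeLines(c(">q1 demo", "MKT"), fp)
#' read_fasta(fp)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- gsub("\\s", "", as.character(set))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("FASTA record with empty sequence: ", paste(ids[empty], collapse = ", "))
  }
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  data.frame(id = ids, desc = desc, seq = toupper(seqs),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param records A data frame as returned by [read_fasta()], or a named
#'   character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), desc = "", seq = unname(records),
                          stringsAsFactors = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(records$desc[i] %||% "")) {
      paste(records$id[i], records$desc[i])
    } else records$id[i]
    writeLines(paste0(">", hdr), con)
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read raw sequencing reads from a FASTQ file
#'
#' Bases are uppercased; qualities are decoded as Phred+33 integer scores.
#'
#' @param path Path to a 4-line-per-record FASTQ file.
#' @param min_mean_quality Optional minimum mean Phred quality; reads below
#'   it are dropped. Default `NULL` (no filtering).
#' @return A data frame with columns `id`, `bases` and a list column
#'   `qualities` of integer vectors.
#' @export
read_fastq <- function(path, min_mean_quality = NULL) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  set <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  ids <- sub("\\s.*$", "", names(set))
  bases <- toupper(as.character(set))
  quals <- as.character(S4Vectors::mcols(set)$qualities)
  qlist <- lapply(quals, function(q) utf8ToInt(q) - 33L)
  bad <- nchar(bases) != lengths(qlist)
  if (any(bad)) {
    stop("FASTQ base/quality length mismatch for read: ",
         paste(ids[bad], collapse = ", "))
  }
  reads <- data.frame(id = ids, bases = unname(bases),
                      row.names = NULL, stringsAsFactors = FALSE)
  reads$qualities <- unname(qlist)
  if (!is.null(min_mean_quality)) {
    keep <- vapply(reads$qualities, mean, numeric(1)) >= min_mean_quality
    reads <- reads[keep, , drop = FALSE]
    rownames(reads) <- NULL
  }
  reads
}

#' Write reads to a FASTQ file (Phred+33)
#'
#' Reads lacking qualities are written with a constant quality of 40 (`'I'`).
#'
#' @param reads A data frame as returned by [read_fastq()] (the `qualities`
#'   column is optional).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if (!is.null(reads$qualities)) {
    vapply(reads$qualities, function(q) intToUtf8(q + 33L), character(1))
  } else {
    vapply(nchar(reads$bases), function(n) strrep("I", n), character(1))
  }
  lines <- rbind(paste0("@", reads$id), reads$bases, "+", qual)
  writeLines(as.vector(lines), path)
  invisible(path)
}

#' Reverse-complement DNA sequences
#'
#' @param bases Character vector of sequences over the alphabet A, C, G, T, N.
#' @return Character vector of reverse complements (`N` maps to `N`).
#' @examples
#' reverse_complement("ATGC")
#' @export
reverse_complement <- function(bases) {
  bad <- regexpr("[^ACGTN]", bases)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("illegal character '", substr(bases[i], bad[i], bad[i]),
         "' at position ", bad[i], " of sequence ", i)
  }
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(bases)))
  unname(out)
}

# Codon -> amino-acid lookup (standard genetic code, NCBI table 1). Codons
# containing N (or any non-ACGT base) translate to 'X' so that coordinates
# stay aligned; stops are rendered '*'.
codon_table <- function() Biostrings::GENETIC_CODE

#' Translate a DNA sequence in a given frame
#'
#' Uses the standard genetic code (translation table 1). On the minus strand
#' the sequence is reverse-complemented first and the frame offset is counted
#' from the 5' end of the reverse complement (transeq convention). Trailing
#' 1-2 bases that do not fill a codon are dropped; codons containing `N`
#' yield `X`; stop codons yield `*`.
#'
#' @param bases A single DNA sequence.
#' @param strand `"+"` or `"-"`.
#' @param frame Frame offset on the chosen strand: 1, 2 or 3.
#' @return The peptide string (possibly empty).
#' @examples
#' translate_dna("ATGAAATAA")          # "MK*"
#' translate_dna("ATGAAATAA", "-", 1)  # "LFH"
#' @export
translate_dna <- function(bases, strand = "+", frame = 1L) {
  stopifnot(length(bases) == 1L, strand %in% c("+", "-"), frame %in% 1:3)
  if (strand == "-") bases <- reverse_complement(bases)
  n <- nchar(bases) - (frame - 1L)
  if (n < 3L) return("")
  n_codons <- n %/% 3L
  starts <- frame + 3L * (seq_len(n_codons) - 1L)
  codons <- substring(bases, starts, starts + 2L)
  aa <- codon_table()[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' All six frame specifications
#'
#' @return A data frame with columns `strand` and `frame` listing the six
#'   (strand, frame) combinations in canonical order: plus strand frames
#'   1-3, then minus strand frames 1-3.
#' @export
six_frames <- function() {
  data.frame(strand = rep(c("+", "-"), each = 3L), frame = rep(1:3, 2L),
             stringsAsFactors = FALSE)
}

#' Six-frame translation of a DNA sequence
#'
#' @param bases A single DNA sequence.
#' @return A data frame with columns `strand`, `frame`, `peptide`; exactly
#'   six rows, one per frame specification.
#' @export
six_frame_translations <- function(bases) {
  fr <- six_frames()
  fr$peptide <- vapply(seq_len(6L), function(i) {
    translate_dna(bases, fr$strand[i], fr$frame[i])
  }, character(1))
  fr
}
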