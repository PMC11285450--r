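# Independent oracles and fixture builders shared across the suite.

AAS <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

random_peptide <- function(len) paste(sample(AAS, len, replace = TRUE), collapse = "")

# Deterministic back-translation: always the alphabetically first codon.
back_translate <- function(peptide) {
  gc <- Biostrings::GENETIC_CODE
  first_codon <- vapply(split(names(gc), gc), function(x) sort(x)[1], character(1))
  ch <- strsplit(peptide, "", fixed = TRUE)[[1]]
  paste(first_codon[ch], collapse = "")
}

random_bases <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# Exhaustive per-position best-hit scan: the brute-force counterpart of
# build_profile for small inputs.
profile_by_scan <- function(query_len, hits) {
  out <- data.frame(position = seq_len(query_len), covered = FALSE,
                    best_identity = NA_real_, min_evalue = NA_real_)
  for (p in seq_len(query_len)) {
    cov <- which(hits$qstart <= p & hits$qend >= p)
    if (length(cov) == 0) next
    out$covered[p] <- TRUE
    h <- hits[cov, ]
    h <- h[order(-h$pident, h$evalue, -h$length, h$sseqid), ]
    out$best_identity[p] <- h$pident[1]
    out$min_evalue[p] <- min(hits$evalue[cov])
  }
  out
}

# Exact Mann-Whitney p-value by full enumeration of group labelings
# (tie-free samples only). W is the number of (a, b) pairs with a > b,
# matching wilcox.test's statistic for x = a.
utest_p_enumeration <- function(a, b, alternative = "less") {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  w_of <- function(x, y) sum(outer(x, y, ">"))
  w_obs <- w_of(a, b)
  idx <- utils::combn(length(pooled), length(a))
  ws <- apply(idx, 2, function(i) w_of(pooled[i], pooled[-i]))
  switch(alternative,
         less = mean(ws <= w_obs),
         greater = mean(ws >= w_obs),
         two_sided = min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs))))
}

# Minimal hit-table row with sensible defaults; only what profiling and
# tiering read.
make_hit <- function(qseqid = "q", sseqid = "r1", pident = 100, qstart = 1,
                     qend = 10, evalue = 1e-10, length = qend - qstart + 1,
                     mismatch = 0, gapopen = 0, sstart = 1,
                     send = 3 * length, qaln = NA_character_,
                     taln = NA_character_, strand = "+", frame = 1L,
                     score = 50L, bitscore = 50) {
  data.frame(qseqid = qseqid, sseqid = sseqid, pident = pident,
             length = length, mismatch = mismatch, gapopen = gapopen,
             qstart = qstart, qend = qend, sstart = sstart, send = send,
             evalue = evalue, bitscore = bitscore, strand = strand,
             frame = frame, score = score, qaln = qaln, taln = taln,
             stringsAsFactors = FALSE)
}

# Synthetic AlphaFold-style PDB: one N + CA + O per residue, pLDDT in the
# B-factor column.
write_synthetic_pdb <- function(path, plddt, chain = "A", skip_ca = integer()) {
  lines <- character()
  serial <- 0L
  aa3 <- c("ALA", "GLY", "SER", "THR", "VAL")
  for (r in seq_along(plddt)) {
    elety <- if (r %in% skip_ca) c("N", "O") else c("N", "CA", "O")
    for (e in elety) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
        serial, e, aa3[(r - 1) %% 5 + 1], chain, r,
        r * 1.5, 0, 0, 1.00, plddt[r], substr(e, 1, 1)))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

write_pae_json <- function(path, mat) {
  jsonlite::write_json(list(predicted_aligned_error = mat), path,
                       matrix = "rowmajor", digits = NA)
  path
}

# End-to-end run on an in-memory scenario: search, tolerable-tier profile,
# call, reconstruction. Returns the per-stage results.
run_scenario <- function(scenario, query_id = "q") {
  gene <- make_gene(scenario)
  reads <- make_reads(gene$genomic, scenario)
  query <- data.frame(id = query_id, seq = scenario$query_protein,
                      stringsAsFactors = FALSE)
  hits <- search_all(query, reads)
  tol <- hits[assign_tier(hits) == "tolerable", , drop = FALSE]
  q <- list(id = query_id, seq = scenario$query_protein)
  prof <- build_profile(q, tol)
  summ <- summarize_profile(prof)
  call <- call_presence(summ$median_best_identity, summ$position_loss_percent)
  list(gene = gene, reads = reads, hits = hits, tolerable = tol,
       profile = prof, summary = summ, call = call, query = q)
}
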