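sp <- scoring_params()

test_that("identical tripeptide scores the sum of BLOSUM62 diagonal entries", {
  aln <- smith_waterman("MKT", "MKT", sp)
  expect_equal(aln$score, 15)  # M=5, K=5, T=5
  expect_equal(aln$identical, 3)
  expect_equal(aln$alignment_length, 3)
  expect_equal(aln$mismatches, 0)
  expect_equal(c(aln$qstart, aln$qend, aln$tstart, aln$tend), c(1, 3, 1, 3))
})

test_that("all-negative substitution pairs yield the empty alignment", {
  aln <- smith_waterman("A", "W", sp)
  expect_equal(aln$score, 0)
  expect_equal(aln$alignment_length, 0)
  expect_error(smith_waterman("", "MK", sp), "empty")
})

test_that("DP kernel matches the exhaustive enumerator on random peptides", {
  set.seed(101)
  for (i in 1:50) {
    a <- random_peptide(sample(3:8, 1))
    b <- random_peptide(sample(3:8, 1))
    expect_equal(smith_waterman(a, b, sp)$score,
                 local_align_score_naive(a, b, sp),
                 info = paste(a, b))
  }
})

test_that("gap accounting is consistent with the alignment strings", {
  # force a gapped alignment: same flanks, extra residues in the middle
  aln <- smith_waterman("MKTWWWAAACDE", "MKTWWWCDE", sp)
  expect_gt(aln$gap_opens, 0)
  cols_q <- strsplit(aln$aligned_query, "")[[1]]
  cols_t <- strsplit(aln$aligned_target, "")[[1]]
  expect_equal(length(cols_q), aln$alignment_length)
  both <- cols_q != "-" & cols_t != "-"
  expect_equal(sum(cols_q[both] == cols_t[both]), aln$identical)
  expect_equal(sum(cols_q[both] != cols_t[both]), aln$mismatches)
  expect_equal(aln$identical + aln$mismatches + sum(!both),
               aln$alignment_length)
})

test_that("E-values follow the Karlin-Altschul form", {
  s <- scoring_params(search_space_m = 300, search_space_n = 10000)
  expect_equal(evalue_of(0, s), 0.041 * 300 * 10000)
  s2 <- s; s2$search_space_n <- 20000
  expect_equal(evalue_of(40, s2), 2 * evalue_of(40, s))
  expect_equal(evalue_of(40, s), 0.041 * 3e6 * exp(-10.68))
  scores <- 0:100
  expect_true(all(diff(evalue_of(scores, s)) < 0))
  expect_error(evalue_of(10, scoring_params()), "search_space")
})

test_that("bit score is an affine transform of the raw score", {
  s <- scoring_params()
  expect_equal(bitscore_of(40, s), (0.267 * 40 - log(0.041)) / log(2))
})

test_that("planted reads are found with exact coordinates and identity", {
  set.seed(5)
  qseq <- random_peptide(60)
  query <- list(id = "q", seq = qseq)
  cds <- back_translate(substr(qseq, 10, 29))
  read <- list(id = "r", bases = cds)
  hit <- search_read(query, read, sp)
  expect_equal(hit$qstart, 10)
  expect_equal(hit$qend, 29)
  expect_equal(hit$pident, 100)
  expect_equal(hit$mismatch, 0)
  expect_equal(hit$strand, "+")

  rc <- list(id = "r", bases = reverse_complement(cds))
  hit2 <- search_read(query, rc, sp)
  expect_equal(hit2$strand, "-")
  expect_gt(hit2$sstart, hit2$send)
  # strand symmetry: only strand/frame/read coordinates may differ
  same <- c("qseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "evalue", "bitscore", "score")
  expect_equal(hit2[, same], hit[, same])
})

test_that("random reads never breach the ceiling nor look significant", {
  set.seed(6)
  query <- list(id = "q", seq = random_peptide(80))
  n_strong <- 0
  for (i in 1:200) {
    h <- search_read(query, list(id = "r", bases = random_bases(100)), sp)
    if (!is.null(h)) {
      expect_lte(h$evalue, sp$evalue_ceiling)
      if (h$evalue < 1e-4) n_strong <- n_strong + 1
    }
  }
  # the default ceiling (10) admits chance alignments, but E < 1e-4 ones
  # should essentially never arise from random sequence
  expect_lte(n_strong, 2)
})

test_that("search_all is stable, order-preserving and thread-invariant", {
  queries <- data.frame(id = "q", seq = random_protein(50, 21))
  expect_equal(nrow(search_all(queries, data.frame(id = character(),
                                                   bases = character()))), 0)
  sc <- synthetic_scenario(queries$seq, seed = 21, coverage = 10,
                           read_length = 90, flank_length = 60,
                           base_error_rate = 0, id = "t")
  reads <- make_reads(make_gene(sc)$genomic, sc)
  h1 <- search_all(queries, reads)
  h2 <- search_all(queries, reads, threads = 2L)
  expect_identical(h1, h2)
  expect_equal(h1$sseqid, h1$sseqid[order(match(h1$sseqid, reads$id))])
})

test_that("outfmt-6 files round-trip and feed identical profiles", {
  queries <- data.frame(id = "q", seq = random_protein(50, 22))
  sc <- synthetic_scenario(queries$seq, seed = 22, coverage = 10,
                           read_length = 90, flank_length = 60,
                           base_error_rate = 0, id = "t")
  reads <- make_reads(make_gene(sc)$genomic, sc)
  hits <- search_all(queries, reads)
  fp <- withr::local_tempfile(fileext = ".tsv")
  write_hits(hits, fp)
  external <- read_hits(fp)
  expect_equal(external$strand, hits$strand)
  q <- list(id = "q", seq = queries$seq)
  p1 <- summarize_profile(build_profile(q, hits))
  p2 <- summarize_profile(build_profile(q, external))
  expect_equal(p1, p2)
})
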