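test_that("alignment columns project onto query coordinates correctly", {
  gapless <- make_hit(qstart = 5, qend = 14, qaln = "MKTWAQCDEF",
                      taln = "MKTWAQCDEF")
  p <- project_hit_to_query(gapless)
  expect_equal(p$position, 5:14)
  expect_equal(p$residue, strsplit("MKTWAQCDEF", "")[[1]])

  # read deletion: query position 7 receives '-' evidence
  del <- make_hit(qstart = 5, qend = 10, qaln = "MKTWAQ", taln = "MK-WAQ")
  pd <- project_hit_to_query(del)
  expect_equal(pd$residue[pd$position == 7], "-")

  # read insertion: one column consumes no query position
  ins <- make_hit(qstart = 5, qend = 10, qaln = "MKT-WAQ", taln = "MKTXWAQ")
  pi <- project_hit_to_query(ins)
  expect_equal(nrow(pi), 6)
  expect_equal(pi$position, 5:10)

  bad <- make_hit(qstart = 5, qend = 20, qaln = "MKT", taln = "MKT")
  expect_error(project_hit_to_query(bad), "inconsistent")
  expect_error(project_hit_to_query(make_hit()), "alignment strings")
})

test_that("conflicting evidence resolves to the higher-identity hit", {
  q <- list(id = "q", seq = "MKTWA")
  hits <- rbind(
    make_hit(sseqid = "strong", pident = 90, evalue = 1e-9, qstart = 1,
             qend = 5, qaln = "MKTWA", taln = "MQTWA"),
    make_hit(sseqid = "weak", pident = 70, evalue = 1e-9, qstart = 1,
             qend = 5, qaln = "MKTWA", taln = "MRTWA"))
  rec <- reconstruct(q, hits)
  expect_equal(substr(rec$residues, 2, 2), "Q")
  expect_equal(rec$table$depth, rep(2L, 5))
  # equal identity and E-value: majority vote, then alphabetical
  hits$pident <- 80
  rec2 <- reconstruct(q, rbind(hits, make_hit(sseqid = "third", pident = 80,
                                              evalue = 1e-9, qstart = 1,
                                              qend = 5, qaln = "MKTWA",
                                              taln = "MQTWA")))
  expect_equal(substr(rec2$residues, 2, 2), "Q")  # Q outvotes R 2:1
})

test_that("error-free tiling reconstructs the query exactly", {
  sc <- synthetic_scenario(random_protein(60, 61), seed = 61, coverage = 20,
                           read_length = 90, flank_length = 90,
                           base_error_rate = 0, id = "perfect")
  res <- run_scenario(sc)
  rec <- reconstruct(res$query, res$tolerable)
  expect_equal(rec$residues, sc$query_protein)
  rep <- reconstruction_report(rec)
  expect_equal(rep$identity_to_query, 100)
  expect_equal(rep$loss_percent, 0)
})

test_that("coverage gaps appear as '-' and match the profile's loss", {
  q <- list(id = "q", seq = strrep("MKTWA", 4))  # 20 residues
  hits <- rbind(
    make_hit(sseqid = "left", pident = 100, qstart = 1, qend = 10,
             qaln = "MKTWAMKTWA", taln = "MKTWAMKTWA"),
    make_hit(sseqid = "right", pident = 100, qstart = 16, qend = 20,
             qaln = "MKTWA", taln = "MKTWA"))
  rec <- reconstruct(q, hits)
  expect_equal(substr(rec$residues, 11, 15), "-----")
  rep <- reconstruction_report(rec)
  expect_equal(rep$loss_percent, 25)
  prof_loss <- summarize_profile(build_profile(q, hits))$position_loss_percent
  expect_equal(rep$loss_percent, prof_loss)
})

test_that("reconstruction is invariant to hit order", {
  set.seed(62)
  sc <- synthetic_scenario(random_protein(40, 63), seed = 63, coverage = 15,
                           read_length = 75, flank_length = 60,
                           base_error_rate = 0.01, id = "order")
  res <- run_scenario(sc)
  r1 <- reconstruct(res$query, res$tolerable)
  r2 <- reconstruct(res$query, res$tolerable[sample(nrow(res$tolerable)), ])
  expect_equal(r1$residues, r2$residues)
  expect_equal(r1$table, r2$table)
})

test_that("an additional perfect read never corrupts a correct residue", {
  q <- list(id = "q", seq = "MKTWAQCDEF")
  base <- make_hit(sseqid = "a", pident = 100, qstart = 1, qend = 10,
                   qaln = q$seq, taln = q$seq)
  rec1 <- reconstruct(q, base)
  extra <- make_hit(sseqid = "b", pident = 100, qstart = 3, qend = 8,
                    qaln = "TWAQCD", taln = "TWAQCD")
  rec2 <- reconstruct(q, rbind(base, extra))
  expect_equal(rec2$residues, rec1$residues)
})

test_that("hydrated outfmt-6 hits reconstruct like native hits", {
  queries <- data.frame(id = "q", seq = random_protein(50, 64))
  sc <- synthetic_scenario(queries$seq, seed = 64, coverage = 12,
                           read_length = 90, flank_length = 60,
                           base_error_rate = 0, id = "hyd")
  reads <- make_reads(make_gene(sc)$genomic, sc)
  hits <- search_all(queries, reads)
  fp <- withr::local_tempfile(fileext = ".tsv")
  write_hits(hits, fp)
  bare <- read_hits(fp)
  hydrated <- hydrate_alignments(bare, queries, reads)
  q <- list(id = "q", seq = queries$seq)
  tol_n <- hits[assign_tier(hits) == "tolerable", ]
  tol_h <- hydrated[assign_tier(hydrated) == "tolerable", ]
  expect_equal(reconstruct(q, tol_h)$residues, reconstruct(q, tol_n)$residues)
})
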