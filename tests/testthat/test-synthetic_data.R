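qprot <- random_protein(60, 900)

test_that("divergence 0 with no events encodes the query exactly", {
  sc <- synthetic_scenario(qprot, seed = 1, id = "t")
  g <- make_gene(sc)
  expect_equal(translate_dna(g$truth$cds), qprot)
  expect_equal(g$truth$true_state, "intact")
  expect_equal(g$truth$deleted_fraction, 0)
  expect_equal(nchar(g$genomic), 2 * sc$flank_length + 3 * nchar(qprot))
  expect_equal(substr(g$genomic, g$truth$cds_start, g$truth$cds_end),
               g$truth$cds)
})

test_that("amino-acid divergence hits the requested rate on average", {
  idents <- vapply(1:20, function(i) {
    sc <- synthetic_scenario(random_protein(200, i), aa_divergence = 0.2,
                             seed = i, id = "d")
    g <- make_gene(sc)
    p <- translate_dna(g$truth$cds)
    mean(strsplit(p, "")[[1]] == strsplit(sc$query_protein, "")[[1]])
  }, numeric(1))
  expect_equal(mean(idents), 0.8, tolerance = 0.02)
})

test_that("pseudogenization events edit the gene as specified", {
  sc <- synthetic_scenario(qprot, events = list(stop_gain(50)), seed = 2,
                           id = "t")
  p <- translate_dna(make_gene(sc)$truth$cds)
  expect_equal(substr(p, 50, 50), "*")
  expect_equal(substr(p, 1, 49), substr(qprot, 1, 49))

  del <- synthetic_scenario(qprot, events = list(segment_deletion(19, 42)),
                            seed = 2, id = "t")
  gd <- make_gene(del)
  expect_equal(gd$truth$deleted_fraction, 24 / 60)  # 40% of codons
  expect_equal(gd$truth$true_state, "degraded")
  expect_equal(nchar(gd$truth$cds), 3 * (60 - 24))

  fs <- synthetic_scenario(qprot, events = list(frameshift(90, -1L)),
                           seed = 2, id = "t")
  gf <- make_gene(fs)
  pf <- translate_dna(gf$truth$cds)
  expect_equal(substr(pf, 1, 29), substr(qprot, 1, 29))
  expect_false(substr(pf, 31, 55) == substr(qprot, 31, 55))
})

test_that("invalid event sets are rejected", {
  expect_error(synthetic_scenario(qprot, events = list(stop_gain(99)), id = "t"),
               "bounds")
  expect_error(synthetic_scenario(qprot, events = list(segment_deletion(10, 20),
                                                       stop_gain(15)), id = "t"),
               "overlap")
  expect_error(synthetic_scenario("MK*T", id = "t"), "stop")
})

test_that("reads are exact (reverse-complemented) substrings when error-free", {
  sc <- synthetic_scenario(qprot, seed = 3, coverage = 10, read_length = 50,
                           flank_length = 50, base_error_rate = 0, id = "t")
  g <- make_gene(sc)
  reads <- make_reads(g$genomic, sc)
  expect_gt(nrow(reads), 0)
  for (b in reads$bases) {
    expect_true(grepl(b, g$genomic, fixed = TRUE) ||
                  grepl(reverse_complement(b), g$genomic, fixed = TRUE))
  }
  zero <- synthetic_scenario(qprot, seed = 3, coverage = 0, id = "t")
  expect_equal(nrow(make_reads(g$genomic, zero)), 0)
  tiny <- synthetic_scenario(qprot, seed = 3, read_length = 10000, id = "t")
  expect_error(make_reads(g$genomic, tiny), "read_length")
})

test_that("realized depth tracks the requested coverage", {
  depths <- vapply(1:20, function(i) {
    sc <- synthetic_scenario(qprot, seed = 100 + i, coverage = 25,
                             read_length = 60, flank_length = 50, id = "t")
    g <- make_gene(sc)
    reads <- make_reads(g$genomic, sc)
    nrow(reads) * sc$read_length / nchar(g$genomic)
  }, numeric(1))
  expect_lt(abs(mean(depths) - 25), 3 * sqrt(25 / 20))
})

test_that("generation is fully deterministic under the seed", {
  sc <- synthetic_scenario(qprot, aa_divergence = 0.05,
                           events = list(stop_gain(30)), seed = 4,
                           base_error_rate = 0.01, id = "t")
  g1 <- make_gene(sc); g2 <- make_gene(sc)
  expect_identical(g1, g2)
  r1 <- make_reads(g1$genomic, sc); r2 <- make_reads(g2$genomic, sc)
  expect_identical(r1, r2)
})

test_that("benchmark suites regenerate byte-identically and are balanced", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- make_benchmark_suite(d1, query = qprot, seed = 5)
  s2 <- make_benchmark_suite(d2, query = qprot, seed = 5)
  expect_equal(nrow(s1$truth), 20)
  expect_gte(sum(s1$truth$true_state == "intact"), 10)
  expect_gte(sum(s1$truth$true_state != "intact"), 10)
  expect_equal(nrow(s1$truth), length(s1$scenarios))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  truth <- read.table(file.path(d1, "truth.tsv"), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  expect_equal(truth$scenario_id, s1$truth$scenario_id)
})
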