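test_that("region extraction concatenates windows in spec order", {
  rs <- region_specs(c("r1", "r2"), c(1, 5), c(3, 6))
  expect_equal(extract_regions("MKTAQW", rs), "MKTQW")
  expect_equal(extract_regions("MKTAQW", region_specs("all", 1, 6)), "MKTAQW")
  expect_error(extract_regions("MKTAQW", region_specs("far", 10, 12)),
               "beyond")
  expect_error(region_specs(c("a", "b"), c(1, 3), c(5, 8)), "overlap")
  expect_error(region_specs("a", 4, 2), "start")
})

test_that("region spec TSVs round-trip", {
  rs <- region_specs(c("alpha1_helix", "beta_sheet"), c(10, 40), c(30, 60))
  fp <- withr::local_tempfile(fileext = ".tsv")
  write.table(rs, fp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_region_specs(fp), rs)
})

test_that("pairwise identity excludes gap columns and is symmetric", {
  expect_equal(pairwise_identity("AAAA", "AAAT"), 75)
  expect_equal(pairwise_identity("MKTW", "MKTW"), 100)
  expect_equal(pairwise_identity("A-AA", "AGAT"), 100 * 2 / 3)
  expect_equal(pairwise_identity("AB", "BA"), pairwise_identity("BA", "AB"))
  expect_true(is.na(pairwise_identity("--", "AA")))
  expect_error(pairwise_identity("AAA", "AA"), "equal length")
})

test_that("identity-to-distance is the complement on the percent scale", {
  expect_equal(identity_to_distance(100), 0)
  expect_equal(identity_to_distance(0), 100)
  expect_true(all(diff(identity_to_distance(seq(0, 100, 10))) < 0))
  expect_error(identity_to_distance(120))
})

test_that("neighbor joining inverts a hand-built additive matrix", {
  # tree ((A:1,B:2):1,(C:3,D:4):1); path lengths summed by hand
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tree <- neighbor_joining(d)
  expect_s3_class(tree, "phylo")
  cp <- ape::cophenetic.phylo(tree)[rownames(d), colnames(d)]
  expect_equal(cp, d, tolerance = 1e-9)
  # A and B form a cherry
  ref <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  expect_equal(ape::dist.topo(ape::unroot(tree), ape::unroot(ref)), 0,
               ignore_attr = TRUE)
})

test_that("NJ recovers random additive trees exactly", {
  set.seed(81)
  for (trial in 1:20) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    d <- ape::cophenetic.phylo(tr)
    out <- neighbor_joining(d)
    cp <- ape::cophenetic.phylo(out)[rownames(d), colnames(d)]
    expect_equal(cp, d, tolerance = 1e-9)
    expect_equal(ape::dist.topo(ape::unroot(out), ape::unroot(tr)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("three equidistant taxa resolve to equal branches", {
  d <- matrix(2, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(d) <- 0
  tree <- neighbor_joining(d)
  expect_equal(sort(tree$edge.length), rep(1, 3))
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
})

test_that("taxon order does not change the tree", {
  set.seed(82)
  tr <- ape::rtree(6)
  d <- ape::cophenetic.phylo(tr)
  perm <- sample(6)
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
})

test_that("negative NJ branches are clamped to zero", {
  # strongly non-additive matrix known to produce negative NJ branches
  d <- matrix(c(0, 2, 2, 9,
                2, 0, 1, 9,
                2, 1, 0, 2,
                9, 9, 2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  raw <- ape::nj(d)
  expect_true(any(raw$edge.length < 0))  # guards fixture relevance
  tree <- neighbor_joining(d)
  expect_true(all(tree$edge.length >= 0))
})

test_that("more substitutions lengthen a taxon's terminal branch", {
  set.seed(83)
  base <- random_peptide(60)
  mutate <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(length(ch), k)
    ch[idx] <- vapply(ch[idx], function(a) sample(setdiff(AAS, a), 1), "x")
    paste(ch, collapse = "")
  }
  seqs <- c(ref = base, near1 = mutate(base, 3), near2 = mutate(base, 4))
  terminal_len <- function(divergent_k) {
    s <- c(seqs, hot = mutate(base, divergent_k))
    res <- region_identity_tree(s)
    tr <- res$tree
    edge <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "hot")]
    edge
  }
  lens <- vapply(c(5, 15, 30, 45), terminal_len, numeric(1))
  expect_true(all(diff(lens) > 0))
})

test_that("region trees built from identity matrices are internally consistent", {
  set.seed(84)
  seqs <- c(a = random_peptide(40), b = random_peptide(40),
            c = random_peptide(40), d = random_peptide(40))
  rs <- region_specs(c("w1", "w2"), c(1, 21), c(10, 35))
  res <- region_identity_tree(seqs, rs)
  expect_equal(dim(res$identity), c(4, 4))
  expect_equal(diag(res$identity), rep(100, 4), ignore_attr = TRUE)
  expect_equal(res$distance, 100 - res$identity, ignore_attr = TRUE)
  expect_equal(sort(res$tree$tip.label), sort(names(seqs)))
})
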