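#' Run the translated search stage on files
#'
#' Reads protein queries (FASTA) and raw reads (FASTQ or FASTA), runs the
#' six-frame translated search, and writes an outfmt-6 hit TSV.
#'
#' @param queries_path FASTA of protein queries.
#' @param reads_path FASTQ (or FASTA) of reads.
#' @param output_dir Run directory (created if needed).
#' @param scoring A [scoring_params()] object.
#' @param threads Worker processes for the search.
#' @return Invisibly, the hit data frame (also written to
#'   `hits.tsv` in `output_dir`).
#' @export
run_search <- function(queries_path, reads_path, output_dir,
                       scoring = scoring_params(), threads = 1L) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  queries <- read_fasta(queries_path)
  reads <- read_any_reads(reads_path)
  message(sprintf("search: %d queries vs %d reads", nrow(queries), nrow(reads)))
  if (nrow(reads) == 0L) {
    warning("no reads in ", reads_path, "; writing empty hit table")
    hits <- empty_hits()
  } else {
    hits <- search_all(queries, reads, scoring, threads = threads)
  }
  write_hits(hits, file.path(output_dir, "hits.tsv"))
  saveRDS_hits(hits, output_dir)
  message(sprintf("search: %d hits written", nrow(hits)))
  invisible(hits)
}

# Full hit tables (with alignment strings) round-trip through a TSV mirror
# so the deliverable stays text-only.
saveRDS_hits <- function(hits, output_dir) {
  utils::write.table(hits, file.path(output_dir, "hits_full.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

read_full_hits <- function(output_dir) {
  p <- file.path(output_dir, "hits_full.tsv")
  if (!file.exists(p)) return(NULL)
  utils::read.table(p, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

read_any_reads <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    return(data.frame(id = character(), bases = character(),
                      stringsAsFactors = FALSE))
  }
  if (startsWith(first, "@")) {
    read_fastq(path)
  } else {
    fa <- read_fasta(path)
    data.frame(id = fa$id, bases = fa$seq, stringsAsFactors = FALSE)
  }
}

#' Run the profiling stage
#'
#' Builds per-query-position best-hit profiles and the summary table
#' (median best identity, position loss). By default only tolerable-tier
#' hits enter the profile, matching the hit set used for reconstruction;
#' `hit_filter = "all"` profiles every reported hit.
#'
#' @param hits_path Hit TSV (internal or any outfmt-6 file), or a hit data
#'   frame.
#' @param queries_path FASTA of protein queries (or data frame).
#' @param output_dir Run directory.
#' @param species Species label attached to the summary rows.
#' @param tier A [tier_thresholds()] object.
#' @param hit_filter `"tolerable"` (default) or `"all"`.
#' @param loss_as_zero Passed to [summarize_profile()].
#' @return Invisibly, the summary data frame (one row per query), also
#'   written to `summary.tsv`; per-query profile TSVs are written
#'   alongside.
#' @export
run_profile <- function(hits_path, queries_path, output_dir,
                        species = "sample", tier = tier_thresholds(),
                        hit_filter = c("tolerable", "all"),
                        loss_as_zero = FALSE) {
  hit_filter <- match.arg(hit_filter)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  hits <- if (is.character(hits_path)) read_hits(hits_path) else hits_path
  queries <- if (is.character(queries_path)) read_fasta(queries_path) else queries_path
  if (hit_filter == "tolerable" && nrow(hits) > 0L) {
    hits <- hits[assign_tier(hits, tier) == "tolerable", , drop = FALSE]
  }
  rows <- list()
  for (qi in seq_len(nrow(queries))) {
    q <- list(id = queries$id[qi], seq = queries$seq[qi])
    prof <- build_profile(q, hits[hits$qseqid == q$id, , drop = FALSE])
    write_profile(prof, file.path(output_dir, paste0("profile_", q$id, ".tsv")))
    s <- summarize_profile(prof, loss_as_zero = loss_as_zero)
    rows[[qi]] <- data.frame(species = species, gene = q$id,
                             median_identity = s$median_best_identity,
                             loss_percent = s$position_loss_percent,
                             n_hits = s$n_hits, stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  utils::write.table(summary, file.path(output_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(summary)
}

#' Run the recovery + reconstruction stage
#'
#' Filters hits into tiers, writes the recovered tiered peptides (FASTA +
#' TSV), and reconstructs each query protein from its tolerable-tier hits
#' with per-residue evidence descriptors.
#'
#' @param hits_path Hit TSV or hit data frame (alignment strings are
#'   recomputed if absent).
#' @param queries_path FASTA of protein queries (or data frame).
#' @param reads_path FASTQ/FASTA of reads (or data frame).
#' @param output_dir Run directory.
#' @param tier A [tier_thresholds()] object.
#' @param scoring Scoring used if alignments must be recomputed.
#' @return Invisibly, a list with `reconstructions` (named list of
#'   [reconstruct()] objects), `peptides` (data frame with `gene` column)
#'   and `report` (per-query reconstruction summaries).
#' @export
run_reconstruct <- function(hits_path, queries_path, reads_path, output_dir,
                            tier = tier_thresholds(),
                            scoring = scoring_params()) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  hits <- if (is.character(hits_path)) read_hits(hits_path) else hits_path
  queries <- if (is.character(queries_path)) read_fasta(queries_path) else queries_path
  reads <- if (is.character(reads_path)) read_any_reads(reads_path) else reads_path
  if (nrow(hits) > 0L && anyNA(hits$qaln)) {
    hits <- hydrate_alignments(hits, queries, reads, scoring)
  }
  recons <- list()
  peps <- list()
  reports <- list()
  for (qi in seq_len(nrow(queries))) {
    q <- list(id = queries$id[qi], seq = queries$seq[qi])
    qh <- hits[hits$qseqid == q$id, , drop = FALSE]
    pep <- recover_peptides(reads, qh, tier)
    if (nrow(pep) > 0L) pep$gene <- q$id
    peps[[qi]] <- pep
    tol <- qh[assign_tier(qh, tier) == "tolerable", , drop = FALSE]
    rec <- reconstruct(q, tol)
    recons[[q$id]] <- rec
    write_reconstruction(
      rec, fasta_path = file.path(output_dir, paste0("recon_", q$id, ".fa")),
      tsv_path = file.path(output_dir, paste0("recon_", q$id, ".tsv")))
    rep <- reconstruction_report(rec)
    rep$gene <- q$id
    reports[[qi]] <- rep
  }
  peptides <- do.call(rbind, peps[vapply(peps, nrow, integer(1)) > 0])
  if (is.null(peptides)) {
    peptides <- cbind(recover_peptides(NULL, NULL), gene = character())
  }
  utils::write.table(peptides, file.path(output_dir, "peptides.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(peptides) > 0L) {
    write_peptides_fasta(peptides, file.path(output_dir, "peptides.fa"))
  }
  report <- do.call(rbind, reports)
  utils::write.table(report, file.path(output_dir, "reconstruction_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(reconstructions = recons, peptides = peptides,
                 report = report))
}

#' Run the presence-calling stage
#'
#' @param summary_path Summary TSV from [run_profile()] (or a data frame
#'   with columns `species`, `gene`, `median_identity`, `loss_percent`).
#' @param output_dir Run directory.
#' @param thresholds A [call_thresholds()] object.
#' @return Invisibly, the calls data frame, also written to `calls.tsv`.
#' @export
run_call <- function(summary_path, output_dir,
                     thresholds = call_thresholds()) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- if (is.character(summary_path)) {
    utils::read.table(summary_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  } else summary_path
  calls <- call_table(summary, thresholds)
  utils::write.table(calls, file.path(output_dir, "calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(calls)
}

#' Run the region phylogeny stage
#'
#' @param proteins_path FASTA of equal-length (aligned or
#'   reference-coordinate) protein sequences.
#' @param output_dir Run directory.
#' @param regions_path Optional region-spec TSV (name, start, end); when
#'   `NULL` the full sequences are used.
#' @return Invisibly, the [region_identity_tree()] result; the identity
#'   matrix TSV and Newick tree are written to the run directory.
#' @export
run_phylo <- function(proteins_path, output_dir, regions_path = NULL) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  fa <- read_fasta(proteins_path)
  seqs <- stats::setNames(fa$seq, fa$id)
  regions <- if (!is.null(regions_path)) read_region_specs(regions_path)
  res <- region_identity_tree(seqs, regions)
  utils::write.table(res$identity, file.path(output_dir, "identity_matrix.tsv"),
                     sep = "\t", quote = FALSE)
  ape::write.tree(res$tree, file.path(output_dir, "nj_tree.nwk"))
  invisible(res)
}

#' Run the structure-confidence stage
#'
#' @param pdb_path AlphaFold-style PDB with pLDDT in the B-factor column.
#' @param pae_path AlphaFold PAE JSON.
#' @param regions_path Region-spec TSV of secondary-structure windows.
#' @param output_dir Run directory.
#' @param plddt_threshold,aggregate Passed to [classify_fold()].
#' @return Invisibly, a list with the fold classification and the PAE
#'   summary, both written as TSVs.
#' @export
run_structure <- function(pdb_path, pae_path, regions_path, output_dir,
                          plddt_threshold = 70, aggregate = "mean") {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  conf <- parse_plddt(pdb_path)
  regions <- read_region_specs(regions_path)
  fold <- classify_fold(conf, regions, plddt_threshold, aggregate)
  out <- fold$regions
  out$protein_reliable <- fold$protein_reliable
  utils::write.table(out, file.path(output_dir, "fold_confidence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pae_summary <- NULL
  if (!is.null(pae_path)) {
    pae <- parse_pae(pae_path)
    pae_summary <- summarize_pae(pae, regions)
    utils::write.table(pae_summary, file.path(output_dir, "pae_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(fold = fold, pae_summary = pae_summary))
}

#' Run the simulation stage
#'
#' @param output_dir Directory for the benchmark suite.
#' @param seed Integer seed.
#' @param ... Passed to [make_benchmark_suite()].
#' @return Invisibly, the [make_benchmark_suite()] result.
#' @export
run_simulate <- function(output_dir, seed = 1L, ...) {
  make_benchmark_suite(output_dir, seed = seed, ...)
}

#' Run the full pipeline end-to-end
#'
#' Chains search, profile, reconstruct and call on one query/read pair,
#' writing every stage artifact plus a checksum manifest under a single
#' run directory. The output equals running the stages individually on the
#' same inputs.
#'
#' @param queries_path FASTA of protein queries.
#' @param reads_path FASTQ/FASTA of reads.
#' @param output_dir Run directory.
#' @param species Species label for the call table.
#' @param scoring,tier,call A [scoring_params()], [tier_thresholds()] and
#'   [call_thresholds()] object.
#' @param threads Worker processes for the search.
#' @param hit_filter Hit set used for profiling (see [run_profile()]).
#' @return Invisibly, a list with `hits`, `summary`, `reconstruction`
#'   (the [run_reconstruct()] result) and `calls`.
#' @export
run_all <- function(queries_path, reads_path, output_dir,
                    species = "sample", scoring = scoring_params(),
                    tier = tier_thresholds(), call = call_thresholds(),
                    threads = 1L, hit_filter = "tolerable") {
  hits <- run_search(queries_path, reads_path, output_dir, scoring, threads)
  summary <- run_profile(hits, queries_path, output_dir, species = species,
                         tier = tier, hit_filter = hit_filter)
  recon <- run_reconstruct(hits, queries_path, reads_path, output_dir,
                           tier = tier, scoring = scoring)
  calls <- run_call(summary, output_dir, call)
  write_manifest(output_dir)
  invisible(list(hits = hits, summary = summary, reconstruction = recon,
                 calls = calls))
}

# MD5 manifest of every artifact in a run directory.
write_manifest <- function(output_dir) {
  files <- setdiff(list.files(output_dir, recursive = TRUE), "MANIFEST.tsv")
  sums <- tools::md5sum(file.path(output_dir, files))
  utils::write.table(
    data.frame(file = files, md5 = unname(sums), stringsAsFactors = FALSE),
    file.path(output_dir, "MANIFEST.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(file.path(output_dir, "MANIFEST.tsv"))
}
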