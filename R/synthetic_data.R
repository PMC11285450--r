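AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# residue -> synonymous codon list (standard code, stops excluded)
synonymous_codons <- function() {
  gc <- codon_table()
  split(names(gc)[gc != "*"], gc[gc != "*"])
}

#' Generate a random protein sequence
#'
#' @param length Number of residues.
#' @param seed RNG seed.
#' @return A single protein string over the 20 standard amino acids,
#'   starting with methionine.
#' @export
random_protein <- function(length, seed = 1L) {
  with_seed(seed, {
    paste(c("M", sample(AA20, length - 1L, replace = TRUE)), collapse = "")
  })
}

#' Pseudogenization event constructors
#'
#' Events are positioned on the *original* (pre-event) gene coordinates:
#' residues for stop gains and segmental deletions, coding-sequence
#' nucleotides for frameshifts. Events must not overlap.
#'
#' @param residue Residue index at which a premature stop codon replaces
#'   the original codon.
#' @return A tagged list describing the event.
#' @export
stop_gain <- function(residue) {
  list(type = "stop_gain", residue = as.integer(residue))
}

#' @rdname stop_gain
#' @param nucleotide Coding-sequence nucleotide position of the frameshift.
#' @param indel Signed indel size: -2, -1 (deletion) or 1, 2 (insertion).
#' @export
frameshift <- function(nucleotide, indel = -1L) {
  stopifnot(indel %in% c(-2L, -1L, 1L, 2L))
  list(type = "frameshift", nucleotide = as.integer(nucleotide),
       indel = as.integer(indel))
}

#' @rdname stop_gain
#' @param start,end Residue range (inclusive) removed from the gene.
#' @export
segment_deletion <- function(start, end) {
  stopifnot(start <= end)
  list(type = "segment_deletion", start = as.integer(start),
       end = as.integer(end))
}

#' Describe a synthetic gene/read scenario
#'
#' A scenario fixes everything needed to generate a ground-truthed genomic
#' sequence and a shotgun read set deterministically: the query protein the
#' gene derives from, the amino-acid divergence applied to it, a list of
#' pseudogenization events, the random flank length, and the read-sampling
#' parameters. The defaults (20x coverage, 100 nt reads, 0.1% per-base
#' error, 150 nt flanks) emulate a short-read shotgun library over a
#' single-exon gene neighbourhood.
#'
#' @param query_protein Protein string, or a single-row record with `id`
#'   and `seq`.
#' @param aa_divergence Per-residue probability of a nonsynonymous swap,
#'   in `[0, 1)`.
#' @param events List of [stop_gain()], [frameshift()] and
#'   [segment_deletion()] events.
#' @param flank_length Random flanking sequence on each side, nucleotides.
#' @param coverage Expected fold coverage of the genomic sequence.
#' @param read_length Read length, nucleotides.
#' @param base_error_rate Per-base substitution error rate in `[0, 1)`.
#' @param seed Integer seed; all generation is deterministic given it.
#' @param id Scenario identifier used in output file names.
#' @param label Optional ground-truth state override
#'   (`"intact"`/`"degraded"`/`"lost"`); by default derived from the
#'   events.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(query_protein, aa_divergence = 0,
                               events = list(), flank_length = 150L,
                               coverage = 20, read_length = 100L,
                               base_error_rate = 0.001, seed = 1L,
                               id = "scenario", label = NULL) {
  if (is.list(query_protein) || is.data.frame(query_protein)) {
    query_protein <- query_protein$seq
  }
  stopifnot(aa_divergence >= 0, aa_divergence < 1,
            base_error_rate >= 0, base_error_rate < 1,
            coverage >= 0, read_length >= 1L, flank_length >= 0L)
  if (grepl("*", query_protein, fixed = TRUE)) {
    stop("query protein must not contain stop codons")
  }
  validate_events(events, nchar(query_protein))
  structure(list(query_protein = query_protein,
                 aa_divergence = aa_divergence, events = events,
                 flank_length = as.integer(flank_length),
                 coverage = coverage, read_length = as.integer(read_length),
                 base_error_rate = base_error_rate, seed = as.integer(seed),
                 id = id, label = label),
            class = "synthetic_scenario")
}

# Events claim residue ranges; ranges must lie in the gene and not overlap.
validate_events <- function(events, n_res) {
  if (length(events) == 0L) return(invisible(TRUE))
  ranges <- lapply(events, function(ev) {
    switch(ev$type,
           stop_gain = c(ev$residue, ev$residue),
           segment_deletion = c(ev$start, ev$end),
           frameshift = rep(ceiling(ev$nucleotide / 3), 2L),
           stop("unknown event type: ", ev$type))
  })
  for (r in ranges) {
    if (r[1] < 1L || r[2] > n_res) {
      stop("event outside gene bounds [1, ", n_res, "]: residues ",
           r[1], "-", r[2])
    }
  }
  rm <- do.call(rbind, ranges)
  ord <- order(rm[, 1L])
  rm <- rm[ord, , drop = FALSE]
  if (nrow(rm) > 1L && any(rm[-1L, 1L] <= rm[-nrow(rm), 2L])) {
    stop("overlapping pseudogenization events")
  }
  invisible(TRUE)
}

#' Generate the genomic sequence and ground truth for a scenario
#'
#' The query protein is back-translated with uniform synonymous codon
#' choice, amino-acid divergence is applied as nonsynonymous codon swaps,
#' pseudogenization events are applied on original coordinates (from 3' to
#' 5', so listed coordinates stay valid), and the coding sequence is
#' embedded in random flanks. Deterministic given the scenario seed.
#'
#' @param scenario A [synthetic_scenario()] object.
#' @return A list with `genomic` (sequence string) and `truth`: a list
#'   with `true_state` (`intact`/`degraded`/`lost`), `deleted_fraction`,
#'   `protein` (the diverged protein actually encoded), `cds`
#'   (post-event coding sequence), `cds_start`/`cds_end` (1-based genomic
#'   coordinates) and the `events`.
#' @export
make_gene <- function(scenario) {
  syn <- synonymous_codons()
  n_res <- nchar(scenario$query_protein)
  with_seed(scenario$seed, {
    res <- strsplit(scenario$query_protein, "", fixed = TRUE)[[1]]
    diverge <- runif(n_res) < scenario$aa_divergence
    res[diverge] <- vapply(res[diverge], function(a) {
      sample(setdiff(AA20, a), 1L)
    }, character(1))
    codons <- vapply(res, function(a) {
      opts <- syn[[a]]
      opts[sample.int(length(opts), 1L)]
    }, character(1), USE.NAMES = FALSE)
    cds <- paste(codons, collapse = "")

    evs <- scenario$events
    deleted <- 0L
    if (length(evs) > 0L) {
      nt_pos <- vapply(evs, function(ev) {
        switch(ev$type, stop_gain = 3L * ev$residue - 2L,
               segment_deletion = 3L * ev$start - 2L,
               frameshift = ev$nucleotide)
      }, integer(1))
      for (i in order(nt_pos, decreasing = TRUE)) {
        ev <- evs[[i]]
        if (ev$type == "stop_gain") {
          s <- 3L * ev$residue - 2L
          cds <- paste0(substr(cds, 1L, s - 1L),
                        sample(STOP_CODONS, 1L),
                        substr(cds, s + 3L, nchar(cds)))
        } else if (ev$type == "segment_deletion") {
          deleted <- deleted + (ev$end - ev$start + 1L)
          cds <- paste0(substr(cds, 1L, 3L * ev$start - 3L),
                        substr(cds, 3L * ev$end + 1L, nchar(cds)))
        } else {  # frameshift
          n <- ev$nucleotide
          if (ev$indel < 0L) {
            cds <- paste0(substr(cds, 1L, n - 1L),
                          substr(cds, n - ev$indel, nchar(cds)))
          } else {
            ins <- paste(sample(c("A", "C", "G", "T"), ev$indel,
                                replace = TRUE), collapse = "")
            cds <- paste0(substr(cds, 1L, n), ins,
                          substr(cds, n + 1L, nchar(cds)))
          }
        }
      }
    }
    flank <- function() {
      if (scenario$flank_length == 0L) return("")
      paste(sample(c("A", "C", "G", "T"), scenario$flank_length,
                   replace = TRUE), collapse = "")
    }
    left <- flank(); right <- flank()
    genomic <- paste0(left, cds, right)
    deleted_fraction <- deleted / n_res
    state <- scenario$label %||%
      if (length(evs) == 0L) "intact"
      else if (deleted_fraction >= 1) "lost"
      else "degraded"
    list(genomic = genomic,
         truth = list(true_state = state,
                      deleted_fraction = deleted_fraction,
                      protein = paste(res, collapse = ""),
                      cds = cds,
                      cds_start = nchar(left) + 1L,
                      cds_end = nchar(left) + nchar(cds),
                      events = evs))
  })
}

#' Simulate shotgun reads from a genomic sequence
#'
#' Read count is Poisson with mean `coverage * length / read_length`;
#' start positions and strands are uniform; per-base substitution errors
#' occur at `base_error_rate`. Deterministic given the scenario seed (a
#' distinct stream from [make_gene()]).
#'
#' @param genomic Genomic sequence string (as from [make_gene()]).
#' @param scenario A [synthetic_scenario()] object.
#' @return A read data frame (columns `id`, `bases`) suitable for
#'   [search_all()] or [write_fastq()].
#' @export
make_reads <- function(genomic, scenario) {
  L <- nchar(genomic)
  rl <- scenario$read_length
  if (rl > L) {
    stop("read_length (", rl, ") exceeds sequence length (", L, ")")
  }
  with_seed(scenario$seed + 1L, {
    n <- rpois(1L, scenario$coverage * L / rl)
    if (n == 0L) {
      return(data.frame(id = character(), bases = character(),
                        stringsAsFactors = FALSE))
    }
    starts <- sample.int(L - rl + 1L, n, replace = TRUE)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    bases <- substring(genomic, starts, starts + rl - 1L)
    if (scenario$base_error_rate > 0) {
      bases <- vapply(bases, function(b) {
        err <- which(runif(rl) < scenario$base_error_rate)
        if (length(err) == 0L) return(b)
        ch <- strsplit(b, "", fixed = TRUE)[[1]]
        ch[err] <- vapply(ch[err], function(x) {
          sample(setdiff(c("A", "C", "G", "T"), x), 1L)
        }, character(1))
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    minus <- strands == "-"
    if (any(minus)) bases[minus] <- reverse_complement(bases[minus])
    data.frame(id = sprintf("%s_r%05d", scenario$id, seq_len(n)),
               bases = bases, stringsAsFactors = FALSE)
  })
}

# The benchmark's fixed condition grid: 10 intact scenarios spanning
# divergence 0-0.10 and 10 pseudogenized scenarios (frameshifts, large
# segmental deletions, stop-codon clusters, and compound events).
benchmark_scenarios <- function(query, seed, coverage = 20,
                                read_length = 100L, base_error_rate = 0.001,
                                flank_length = 150L) {
  n_res <- nchar(query)
  mk <- function(i, id, divergence = 0, events = list(), label = NULL) {
    synthetic_scenario(query, aa_divergence = divergence, events = events,
                       flank_length = flank_length, coverage = coverage,
                       read_length = read_length,
                       base_error_rate = base_error_rate,
                       seed = seed + i, id = id, label = label)
  }
  scen <- list()
  for (i in 1:10) {
    scen[[i]] <- mk(i, sprintf("intact_%02d", i),
                    divergence = (i - 1L) * 0.10 / 9)
  }
  if (n_res < 60L) stop("benchmark scenarios need a query of >= 60 residues")
  del_mid <- function(frac) {
    k <- floor(n_res * frac)
    s <- floor((n_res - k) / 2) + 1L
    segment_deletion(s, s + k - 1L)
  }
  scen[[11]] <- mk(11, "pseudo_del50", events = list(del_mid(0.50)))
  scen[[12]] <- mk(12, "pseudo_del55", events = list(del_mid(0.55)))
  scen[[13]] <- mk(13, "pseudo_del60", events = list(del_mid(0.60)))
  scen[[14]] <- mk(14, "pseudo_del75", events = list(del_mid(0.75)))
  scen[[15]] <- mk(15, "pseudo_lost",
                   events = list(segment_deletion(1L, n_res)))
  scen[[16]] <- mk(16, "pseudo_del_5prime",
                   events = list(segment_deletion(1L, floor(n_res * 0.55))))
  scen[[17]] <- mk(17, "pseudo_del_3prime",
                   events = list(segment_deletion(n_res - floor(n_res * 0.60) + 1L,
                                                  n_res)))
  del_start <- floor(n_res * 0.45)
  early_stops <- Filter(function(ev) ev$residue < del_start - 1L,
                        lapply(c(10L, 25L, 40L), stop_gain))
  scen[[18]] <- mk(18, "pseudo_del_stops",
                   events = c(list(segment_deletion(del_start, n_res)),
                              early_stops))
  scen[[19]] <- mk(19, "pseudo_del_div", divergence = 0.10,
                   events = list(del_mid(0.55)))
  scen[[20]] <- mk(20, "pseudo_lost_b",
                   events = list(segment_deletion(1L, n_res)))
  scen
}

#' Generate a ground-truthed benchmark suite
#'
#' Writes paired intact/pseudogenized scenarios (10 of each) over a
#' divergence grid to a directory: per scenario a genome FASTA and a read
#' FASTQ, plus a `truth.tsv` table. Regenerating with the same seed
#' produces byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param query Query protein string; default is a seeded random
#'   180-residue protein.
#' @param seed Integer seed driving every scenario.
#' @param coverage,read_length,base_error_rate,flank_length Shared
#'   read-simulation conditions (see [synthetic_scenario()]).
#' @return Invisibly, a list with `scenarios`, `truth` (data frame) and
#'   `dir`.
#' @export
make_benchmark_suite <- function(dir, query = NULL, seed = 1L,
                                 coverage = 20, read_length = 100L,
                                 base_error_rate = 0.001,
                                 flank_length = 150L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(query)) query <- random_protein(180L, seed)
  scen <- benchmark_scenarios(query, seed, coverage, read_length,
                              base_error_rate, flank_length)
  rows <- list()
  for (s in scen) {
    g <- make_gene(s)
    reads <- make_reads(g$genomic, s)
    gf <- file.path(dir, paste0(s$id, "_genome.fa"))
    rf <- file.path(dir, paste0(s$id, "_reads.fq"))
    write_fasta(stats::setNames(g$genomic, s$id), gf)
    write_fastq(reads, rf)
    rows[[length(rows) + 1L]] <- data.frame(
      scenario_id = s$id, true_state = g$truth$true_state,
      aa_divergence = s$aa_divergence,
      deleted_fraction = g$truth$deleted_fraction,
      n_events = length(s$events), coverage = s$coverage,
      read_length = s$read_length, base_error_rate = s$base_error_rate,
      seed = s$seed, n_reads = nrow(reads),
      genome = basename(gf), reads = basename(rf),
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  qf <- file.path(dir, "query.fa")
  write_fasta(stats::setNames(query, "query"), qf)
  invisible(list(scenarios = scen, truth = truth, dir = dir))
}
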