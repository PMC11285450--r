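#' Project a hit's alignment onto query coordinates
#'
#' Walks the aligned query/target strings of a hit and maps each query
#' position in the alignment to the observed read residue. Insertion
#' columns (gap in the query) contribute nothing; deletion columns (gap in
#' the read) contribute `-` evidence at that query position.
#'
#' @param hit A one-row hit data frame carrying `qstart`, `qend`, `qaln`
#'   and `taln`.
#' @return A data frame with columns `position` (query coordinate) and
#'   `residue` (observed residue, or `-` for a read deletion).
#' @export
project_hit_to_query <- function(hit) {
  if (is.na(hit$qaln) || is.na(hit$taln)) {
    stop("hit lacks alignment strings; re-run the search engine or ",
         "hydrate_alignments() before reconstruction")
  }
  qch <- strsplit(hit$qaln, "", fixed = TRUE)[[1]]
  tch <- strsplit(hit$taln, "", fixed = TRUE)[[1]]
  if (length(qch) != length(tch)) {
    stop("inconsistent alignment strings for read ", hit$sseqid)
  }
  consume <- qch != "-"
  if (sum(consume) != hit$qend - hit$qstart + 1L) {
    stop("alignment inconsistent with query coordinates for read ", hit$sseqid)
  }
  data.frame(position = hit$qstart + cumsum(consume)[consume] - 1L,
             residue = tch[consume], stringsAsFactors = FALSE)
}

#' Recompute alignment strings for hits read from a bare outfmt-6 table
#'
#' Hit tables imported with [read_hits()] carry coordinates but not the
#' alignments themselves. This re-runs the search engine for the affected
#' reads so that reconstruction can proceed.
#'
#' @param hits A hit data frame.
#' @param queries,reads The query and read sets the hits refer to.
#' @param scoring A [scoring_params()] object.
#' @return The hit data frame with `qaln`/`taln` (and `strand`, `frame`,
#'   `score`) filled in; rows whose realignment produces no hit are dropped.
#' @export
hydrate_alignments <- function(hits, queries, reads,
                               scoring = scoring_params()) {
  need <- which(is.na(hits$qaln))
  if (length(need) == 0L) return(hits)
  if (is.null(scoring$search_space_n)) {
    scoring$search_space_n <- translated_residues(nchar(reads$bases))
  }
  drop <- integer()
  for (i in need) {
    qi <- match(hits$qseqid[i], queries$id)
    ri <- match(hits$sseqid[i], reads$id)
    if (is.na(qi) || is.na(ri)) {
      stop("cannot hydrate hit ", hits$qseqid[i], " vs ", hits$sseqid[i],
           ": sequence not found")
    }
    sc <- scoring
    sc$search_space_m <- nchar(queries$seq[qi])
    h <- search_read(list(id = queries$id[qi], seq = queries$seq[qi]),
                     list(id = reads$id[ri], bases = reads$bases[ri]), sc)
    if (is.null(h)) { drop <- c(drop, i); next }
    hits[i, c("qstart", "qend", "sstart", "send")] <-
      h[, c("qstart", "qend", "sstart", "send")]
    hits$strand[i] <- h$strand
    hits$frame[i] <- h$frame
    hits$score[i] <- h$score
    hits$qaln[i] <- h$qaln
    hits$taln[i] <- h$taln
    hits$pident[i] <- h$pident
    hits$length[i] <- h$length
    hits$mismatch[i] <- h$mismatch
    hits$gapopen[i] <- h$gapopen
    hits$evalue[i] <- h$evalue
  }
  if (length(drop)) hits <- hits[-drop, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Reconstruct a query-length protein from tolerable-tier hits
#'
#' At each covered query position the consensus residue is taken from the
#' best covering hit (highest percent identity; ties broken by lowest
#' E-value, then majority vote across the tied hits' residues, then
#' alphabetically). Positions with no residue evidence are emitted as `-`
#' to distinguish absence of evidence from an unknown residue.
#'
#' @param query A single-row data frame or list with `id` and `seq`.
#' @param hits A hit data frame with alignment strings (tolerable tier;
#'   apply [assign_tier()] upstream).
#' @return An object of class `reconstructed_protein`: list with
#'   `query_id`, `query_seq`, `residues` (query-length string over amino
#'   acids and `-`) and `table`, a per-residue data frame with `position`,
#'   `residue`, `depth`, `best_identity`, `mismatches_best`,
#'   `gapopens_best`, `min_evalue`.
#' @export
reconstruct <- function(query, hits) {
  len <- nchar(query$seq)
  tab <- data.frame(position = seq_len(len), residue = "-", depth = 0L,
                    best_identity = NA_real_, mismatches_best = NA_integer_,
                    gapopens_best = NA_integer_, min_evalue = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(hits) && nrow(hits) > 0L) {
    proj <- lapply(seq_len(nrow(hits)), function(i) {
      p <- project_hit_to_query(hits[i, , drop = FALSE])
      p$hit <- i
      p
    })
    long <- do.call(rbind, proj)
    long <- long[long$residue != "-", , drop = FALSE]  # residue evidence only
    if (nrow(long) > 0L) {
      if (min(long$position) < 1L || max(long$position) > len) {
        stop("hit evidence outside query ", query$id)
      }
      for (pos in unique(long$position)) {
        rows <- long[long$position == pos, ]
        pid <- hits$pident[rows$hit]
        ev <- hits$evalue[rows$hit]
        top <- rows[pid == max(pid) & ev == min(ev[pid == max(pid)]), ,
                    drop = FALSE]
        votes <- sort(table(top$residue), decreasing = TRUE)
        winners <- names(votes)[votes == max(votes)]
        res <- sort(winners)[1L]
        best_hit <- top$hit[top$residue == res][1L]
        tab$residue[pos] <- res
        tab$depth[pos] <- nrow(rows)
        tab$best_identity[pos] <- hits$pident[best_hit]
        tab$mismatches_best[pos] <- hits$mismatch[best_hit]
        tab$gapopens_best[pos] <- hits$gapopen[best_hit]
        tab$min_evalue[pos] <- min(ev)
      }
    }
  }
  structure(list(query_id = query$id, query_seq = query$seq,
                 residues = paste(tab$residue, collapse = ""), table = tab),
            class = "reconstructed_protein")
}

#' @export
print.reconstructed_protein <- function(x, ...) {
  rep <- reconstruction_report(x)
  cat("Reconstructed protein for query", x$query_id, "\n")
  cat(sprintf("  identity to query %.1f%%, position loss %.1f%%, mean depth %.1f\n",
              rep$identity_to_query, rep$loss_percent, rep$mean_depth))
  invisible(x)
}

#' Summarize a reconstructed protein
#'
#' @param recon A [reconstruct()] object.
#' @return A one-row data frame with `identity_to_query` (percent over
#'   covered positions; NA when nothing is covered), `loss_percent`
#'   (uncovered positions) and `mean_depth`.
#' @export
reconstruction_report <- function(recon) {
  tab <- recon$table
  qch <- strsplit(recon$query_seq, "", fixed = TRUE)[[1]]
  cov <- tab$depth > 0L
  ident <- if (any(cov)) 100 * mean(tab$residue[cov] == qch[cov]) else NA_real_
  data.frame(identity_to_query = ident,
             loss_percent = 100 * mean(!cov),
             mean_depth = mean(tab$depth))
}

#' Write a reconstructed protein (FASTA + per-residue TSV)
#'
#' @param recon A [reconstruct()] object.
#' @param fasta_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, a character vector of the paths written.
#' @export
write_reconstruction <- function(recon, fasta_path = NULL, tsv_path = NULL) {
  written <- character()
  if (!is.null(fasta_path)) {
    write_fasta(stats::setNames(recon$residues, paste0(recon$query_id, "_reconstructed")),
                fasta_path)
    written <- c(written, fasta_path)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(recon$table, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, tsv_path)
  }
  invisible(written)
}
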