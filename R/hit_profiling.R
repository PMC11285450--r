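#' Per-query-position best-hit profile
#'
#' A query position is covered when at least one hit spans it. Four
#' statistics are tracked per position: the best hit's percent identity,
#' mismatches and gap opens (the "best hit" at a position is the covering
#' hit with highest percent identity, ties broken by lower E-value, longer
#' alignment, then lexicographic read id), and the minimum E-value over
#' *all* covering hits, tracked independently of the best-identity hit.
#'
#' @param query A single-row data frame or list with `id` and `seq`.
#' @param hits A hit data frame (all rows must reference this query;
#'   coordinates must lie within the query).
#' @return An object of class `position_profile`: a list with `query_id`,
#'   `length`, `n_hits` and `table`, a per-position data frame with columns
#'   `position`, `covered`, `best_identity`, `mismatches_best`,
#'   `gapopens_best`, `min_evalue`, `depth`.
#' @export
build_profile <- function(query, hits) {
  len <- nchar(query$seq)
  tab <- data.frame(position = seq_len(len), covered = FALSE,
                    best_identity = NA_real_, mismatches_best = NA_integer_,
                    gapopens_best = NA_integer_, min_evalue = NA_real_,
                    depth = 0L)
  if (!is.null(hits) && nrow(hits) > 0L) {
    if (!all(hits$qseqid == query$id)) {
      bad <- unique(hits$qseqid[hits$qseqid != query$id])
      stop("hits for foreign query in profile of ", query$id, ": ",
           paste(bad, collapse = ", "))
    }
    out_of_range <- hits$qstart < 1L | hits$qend > len | hits$qstart > hits$qend
    if (any(out_of_range)) {
      stop("hit with coordinates outside query ", query$id, ": read ",
           paste(hits$sseqid[out_of_range], collapse = ", "))
    }
    span <- hits$qend - hits$qstart + 1L
    long <- data.frame(
      pos = unlist(Map(seq.int, hits$qstart, hits$qend)),
      hit = rep.int(seq_len(nrow(hits)), span))
    ord <- order(long$pos, -hits$pident[long$hit], hits$evalue[long$hit],
                 -hits$length[long$hit], hits$sseqid[long$hit])
    long <- long[ord, ]
    best <- long[!duplicated(long$pos), ]
    tab$covered[best$pos] <- TRUE
    tab$best_identity[best$pos] <- hits$pident[best$hit]
    tab$mismatches_best[best$pos] <- hits$mismatch[best$hit]
    tab$gapopens_best[best$pos] <- hits$gapopen[best$hit]
    min_ev <- tapply(hits$evalue[long$hit], long$pos, min)
    tab$min_evalue[as.integer(names(min_ev))] <- as.numeric(min_ev)
    depth <- tapply(long$hit, long$pos, length)
    tab$depth[as.integer(names(depth))] <- as.integer(depth)
  }
  structure(list(query_id = query$id, length = len,
                 n_hits = if (is.null(hits)) 0L else nrow(hits), table = tab),
            class = "position_profile")
}

#' @export
print.position_profile <- function(x, ...) {
  cat("Position profile for query", x$query_id, "(", x$length, "residues,",
      x$n_hits, "hits )\n")
  s <- summarize_profile(x)
  cat("  median best identity:", format(s$median_best_identity),
      " position loss:", format(s$position_loss_percent), "%\n")
  invisible(x)
}

#' Summarize a position profile
#'
#' The median best identity is computed over covered positions only (the
#' default) or, with `loss_as_zero = TRUE`, over all positions with
#' uncovered positions imputed as identity 0. The position-loss percentage
#' is `100 * uncovered / length` in either case.
#'
#' @param profile A [build_profile()] object.
#' @param loss_as_zero Impute uncovered positions as identity 0 in the
#'   median.
#' @return A one-row data frame with `median_best_identity` (NA when no
#'   position is covered and `loss_as_zero` is `FALSE`),
#'   `position_loss_percent` and `n_hits`.
#' @export
summarize_profile <- function(profile, loss_as_zero = FALSE) {
  tab <- profile$table
  loss <- 100 * sum(!tab$covered) / profile$length
  ids <- if (loss_as_zero) {
    ifelse(tab$covered, tab$best_identity, 0)
  } else {
    tab$best_identity[tab$covered]
  }
  med <- if (length(ids) == 0L) NA_real_ else stats::median(ids)
  data.frame(median_best_identity = med, position_loss_percent = loss,
             n_hits = profile$n_hits)
}

#' Assemble a species-by-gene call table
#'
#' Builds the long-format table behind presence/loss heatmaps: one row per
#' (species, gene) combination with the profile summary values and the
#' three-state presence call. Combinations absent from `summaries` appear
#' as `NA` rows rather than being dropped.
#'
#' @param summaries Data frame with columns `species`, `gene`,
#'   `median_identity`, `loss_percent` and optionally `n_hits`; at most one
#'   row per (species, gene).
#' @param thresholds A [call_thresholds()] object.
#' @return A data frame with columns `species`, `gene`, `median_identity`,
#'   `loss_percent`, `n_hits`, `call`, ordered by species then gene.
#' @export
call_table <- function(summaries, thresholds = call_thresholds()) {
  key <- paste(summaries$species, summaries$gene, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- summaries[duplicated(key), c("species", "gene")]
    stop("duplicate (species, gene) combination: ",
         paste(dup$species, dup$gene, sep = "/", collapse = ", "))
  }
  if (is.null(summaries$n_hits)) summaries$n_hits <- NA_integer_
  grid <- expand.grid(species = unique(summaries$species),
                      gene = unique(summaries$gene),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- merge(grid, summaries, by = c("species", "gene"), all.x = TRUE,
               sort = FALSE)
  out$call <- ifelse(is.na(out$median_identity) & is.na(out$loss_percent),
                     NA_character_,
                     call_presence(out$median_identity, out$loss_percent,
                                   thresholds))
  out <- out[order(out$species, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Write / read a position profile table as TSV
#'
#' @param profile A [build_profile()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(profile$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
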