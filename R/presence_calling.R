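#' Thresholds for three-state presence calling
#'
#' The evidence for a gene is its median best-hit identity and its
#' position-loss percentage. A gene is called `likely_lost` when identity
#' falls below `identity_lost_max` or loss exceeds `loss_lost_min`;
#' `present` when identity is at least `identity_present_min` and loss at
#' most `loss_present_max`; anything in between is `ambiguous`. The default
#' gray bands (identity 60-70, loss 20-30) encode the working rule that
#' identity below 60-70 or position loss above 20-30 indicates potential
#' loss of a functional gene.
#'
#' @param identity_present_min,identity_lost_max Identity cutoffs (percent).
#' @param loss_present_max,loss_lost_min Position-loss cutoffs (percent).
#' @return An object of class `call_thresholds`.
#' @export
call_thresholds <- function(identity_present_min = 70, identity_lost_max = 60,
                            loss_present_max = 20, loss_lost_min = 30) {
  stopifnot(identity_lost_max <= identity_present_min,
            loss_present_max <= loss_lost_min)
  structure(list(identity_present_min = identity_present_min,
                 identity_lost_max = identity_lost_max,
                 loss_present_max = loss_present_max,
                 loss_lost_min = loss_lost_min),
            class = "call_thresholds")
}

#' Three-state gene presence call
#'
#' Vectorized over the two evidence values. An `NA` median identity (zero
#' coverage) is collapsed to `likely_lost`, consistent with the 100% loss
#' that forces it.
#'
#' @param median_identity Median best-hit identity (percent; may be NA).
#' @param loss_percent Position-loss percentage.
#' @param thresholds A [call_thresholds()] object.
#' @return Character vector over `{"present", "ambiguous", "likely_lost"}`.
#' @examples
#' call_presence(95, 2)    # "present"
#' call_presence(50, 40)   # "likely_lost"
#' call_presence(65, 25)   # "ambiguous"
#' @export
call_presence <- function(median_identity, loss_percent,
                          thresholds = call_thresholds()) {
  lost <- is.na(median_identity) |
    median_identity < thresholds$identity_lost_max |
    loss_percent > thresholds$loss_lost_min
  present <- !lost &
    median_identity >= thresholds$identity_present_min &
    loss_percent <= thresholds$loss_present_max
  ifelse(lost, "likely_lost", ifelse(present, "present", "ambiguous"))
}

#' Mann-Whitney U test
#'
#' U is computed from rank sums with midranks for ties. The p-value is
#' exact (by enumeration of rank assignments) whenever both samples have at
#' most `exact_max` observations and there are no ties; otherwise the
#' normal approximation with continuity and tie corrections is used.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @param alternative `"less"` (a stochastically smaller than b),
#'   `"greater"`, or `"two_sided"`.
#' @param exact_max Largest per-sample size for which the exact p-value is
#'   attempted.
#' @return An object of class `u_test`: list with `u_statistic` (number of
#'   (a, b) pairs with a > b, ties counted 1/2), `p_value`, `alternative`,
#'   `method` (`"exact"` or `"normal_approx"`), `n_a`, `n_b`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6), "less")$p_value  # 0.05 exactly
#' @export
mann_whitney_u <- function(sample_a, sample_b,
                           alternative = c("less", "greater", "two_sided"),
                           exact_max = 20L) {
  alternative <- match.arg(alternative)
  if (length(sample_a) == 0L || length(sample_b) == 0L) {
    stop("both samples must be non-empty")
  }
  tie_free <- !anyDuplicated(c(sample_a, sample_b))
  use_exact <- tie_free && length(sample_a) <= exact_max &&
    length(sample_b) <= exact_max
  wt <- suppressWarnings(stats::wilcox.test(
    sample_a, sample_b,
    alternative = sub("two_sided", "two.sided", alternative),
    exact = use_exact, correct = TRUE))
  structure(list(u_statistic = unname(wt$statistic),
                 p_value = wt$p.value, alternative = alternative,
                 method = if (use_exact) "exact" else "normal_approx",
                 n_a = length(sample_a), n_b = length(sample_b)),
            class = "u_test")
}

#' @export
print.u_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s, %s): U = %.1f, p = %.4g (n = %d, %d)\n",
              x$alternative, x$method, x$u_statistic, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Compare normalized peptide lengths between two gene sets
#'
#' Pools the per-read normalized stop-free peptide lengths of two gene sets
#' and tests whether set A is stochastically lower than set B (the
#' pseudogenization signature: premature stops and divergence both shrink
#' the statistic).
#'
#' @param peptide_records A data frame of recovered peptides (as from
#'   [recover_peptides()]) with an added `gene` column tagging each record.
#' @param genes_a,genes_b Character vectors of gene names defining the two
#'   sets.
#' @param alternative Test direction; default `"less"` (set A lower).
#' @return A `u_test` object (see [mann_whitney_u()]).
#' @export
compare_gene_sets <- function(peptide_records, genes_a, genes_b,
                              alternative = "less") {
  if (is.null(peptide_records$gene)) {
    stop("peptide_records must carry a 'gene' column")
  }
  a <- peptide_records$normalized_len[peptide_records$gene %in% genes_a]
  b <- peptide_records$normalized_len[peptide_records$gene %in% genes_b]
  if (length(a) == 0L) stop("no records for gene set A")
  if (length(b) == 0L) stop("no records for gene set B")
  mann_whitney_u(a, b, alternative)
}
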