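#' Expression count matrix for a targeted panel
#'
#' Gene-by-sample counts for a ~100-transcript hybridization panel with
#' designated housekeeping, positive-control and (optionally)
#' negative-control probes, and a group label per sample.
#'
#' @param counts Numeric gene x sample matrix, non-negative, with row and
#'   column names.
#' @param groups Group label per sample (length = ncol).
#' @param housekeeping Character vector of housekeeping gene ids (rows).
#' @param positive Character vector of positive-control gene ids.
#' @param negative Optional negative-control gene ids.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(counts, groups, housekeeping,
                              positive = character(0),
                              negative = character(0)) {
  counts <- as.matrix(counts)
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)),
            length(groups) == ncol(counts))
  if (any(counts < 0) || anyNA(counts))
    stop_data("counts must be non-negative and complete")
  for (set in list(housekeeping, positive, negative))
    if (!all(set %in% rownames(counts)))
      stop_data("control gene ids missing from the matrix: ",
                paste(setdiff(set, rownames(counts)), collapse = ", "))
  structure(
    list(counts = counts, groups = as.character(groups),
         housekeeping = housekeeping, positive = positive,
         negative = negative),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "Expression matrix: %d genes x %d samples (%s); %d housekeeping, %d positive controls\n",
    nrow(x$counts), ncol(x$counts),
    paste(sprintf("%s n=%d", names(table(x$groups)), table(x$groups)),
          collapse = ", "),
    length(x$housekeeping), length(x$positive)))
  invisible(x)
}

#' Positive-control (technical) normalization
#'
#' Scales each sample by `geomean(all samples' positive-control sums) /
#' (that sample's positive-control sum)`, removing lane-to-lane assay
#' efficiency differences before biological normalization.
#'
#' @param mat An [expression_matrix()] with positive controls designated.
#' @return The matrix with scaled counts and recorded `pos_factors`.
#' @export
normalize_positive <- function(mat) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (length(mat$positive) == 0)
    stop_data("no positive-control genes designated")
  pos_sum <- colSums(mat$counts[mat$positive, , drop = FALSE])
  if (any(pos_sum <= 0))
    stop_data("zero positive-control signal in sample(s): ",
              paste(colnames(mat$counts)[pos_sum <= 0], collapse = ", "))
  factors <- geomean(pos_sum) / pos_sum
  mat$counts <- sweep(mat$counts, 2, factors, `*`)
  mat$pos_factors <- factors
  mat
}

#' Housekeeping geometric-mean normalization
#'
#' Scales each sample so the geometric mean of its housekeeping genes
#' equals the cohort-wide (arithmetic) mean of per-sample housekeeping
#' geometric means. After the operation the housekeeping geometric mean is
#' identical across samples (the operation's fixed point), making
#' cross-sample comparisons reflect biology rather than assay input.
#' Multiplying any sample's raw counts by a positive constant leaves every
#' *relative* normalized profile exactly unchanged; only the cohort-wide
#' reporting scale (the common target the samples are brought to, which is
#' computed from the data) can shift by a common factor, so between-sample
#' ratios and fold changes are strictly scale-invariant.
#'
#' @param mat An [expression_matrix()].
#' @param hk_ids Housekeeping ids; defaults to those recorded in `mat`.
#' @return The matrix with scaled counts and recorded `hk_factors`.
#' @export
normalize_housekeeping <- function(mat, hk_ids = NULL) {
  stopifnot(inherits(mat, "expression_matrix"))
  hk_ids <- hk_ids %||% mat$housekeeping
  if (length(hk_ids) == 0) stop_data("no housekeeping genes designated")
  hk <- mat$counts[hk_ids, , drop = FALSE]
  zero <- which(hk <= 0, arr.ind = TRUE)
  if (nrow(zero))
    stop_data("zero housekeeping count: gene ", hk_ids[zero[1, 1]],
              ", sample ", colnames(mat$counts)[zero[1, 2]])
  gm <- apply(hk, 2, geomean)
  factors <- mean(gm) / gm
  mat$counts <- sweep(mat$counts, 2, factors, `*`)
  mat$hk_factors <- factors
  mat
}

#' Per-gene differential expression between two groups
#'
#' On a normalized matrix, computes per endogenous gene the log2 fold
#' change of group means `log2(mean_b / mean_a)` and a two-sided Welch t
#' test p-value on the normalized values, reported as `-log10(p)`. No
#' multiple-testing correction is applied by default (panel reports
#' conventionally print raw p); `fdr = TRUE` adds a Benjamini-Hochberg
#' column. Genes with a zero group mean get an undefined fold change and
#' are excluded from ranking.
#'
#' @param mat A normalized [expression_matrix()].
#' @param group_a,group_b Group labels (fold change is b vs a).
#' @param p_threshold Significance flag threshold on raw p. Default 0.05.
#' @param fdr Add BH-adjusted p column. Default FALSE.
#' @return A `de_result` data frame: `gene_id`, `mean_a`, `mean_b`,
#'   `log2_fold_change`, `neg_log10_p`, `significant`.
#' @export
differential_expression <- function(mat, group_a = "ad_lib",
                                    group_b = "TRF", p_threshold = 0.05,
                                    fdr = FALSE) {
  stopifnot(inherits(mat, "expression_matrix"))
  for (g in c(group_a, group_b))
    if (sum(mat$groups == g) < 2)
      stop_data("need at least 2 samples in group `", g, "`")
  endo <- setdiff(rownames(mat$counts),
                  c(mat$housekeeping, mat$positive, mat$negative))
  a <- mat$counts[endo, mat$groups == group_a, drop = FALSE]
  b <- mat$counts[endo, mat$groups == group_b, drop = FALSE]
  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  l2fc <- ifelse(mean_a > 0 & mean_b > 0, log2(mean_b / mean_a), NA_real_)
  pvals <- vapply(seq_along(endo), function(i) {
    xa <- a[i, ]; xb <- b[i, ]
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0)
      return(if (mean(xa) == mean(xb)) 1 else 0)
    stats::t.test(xa, xb)$p.value
  }, numeric(1))
  out <- data.frame(
    gene_id = endo, mean_a = mean_a, mean_b = mean_b,
    log2_fold_change = l2fc,
    neg_log10_p = -log10(pvals),
    significant = pvals < p_threshold & !is.na(l2fc),
    row.names = NULL
  )
  if (fdr) out$p_bh <- stats::p.adjust(pvals, method = "BH")
  class(out) <- c("de_result", "data.frame")
  out
}

#' Ranked differential-expression report
#'
#' Sorts genes by ascending p (ties broken by descending absolute fold
#' change, then gene id), adds an up/down direction column, and drops
#' genes with undefined fold change from the ranking.
#'
#' @param results A `de_result` from [differential_expression()].
#' @param top Optional number of top rows to keep.
#' @return Data frame: `gene_id`, `direction`, `neg_log10_p`,
#'   `log2_fold_change`, `significant`.
#' @export
de_table <- function(results, top = NULL) {
  stopifnot(inherits(results, "de_result"))
  r <- results[!is.na(results$log2_fold_change), , drop = FALSE]
  ord <- order(-r$neg_log10_p, -abs(r$log2_fold_change), r$gene_id)
  r <- r[ord, ]
  out <- data.frame(
    gene_id = r$gene_id,
    direction = ifelse(r$log2_fold_change >= 0, "up", "down"),
    neg_log10_p = r$neg_log10_p,
    log2_fold_change = r$log2_fold_change,
    significant = r$significant,
    row.names = NULL
  )
  if (!is.null(top)) out <- utils::head(out, top)
  out
}
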