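#' Log-transform FPKM expression values
#'
#' `log2(x + 0.01)`; the 0.01 pseudocount keeps zero-FPKM samples finite
#' on the log scale.
#'
#' @param x Nonnegative numeric vector of FPKM values.
#' @return `log2(x + 0.01)`.
#' @export
log_fpkm <- function(x) {
  stopifnot(all(x >= 0))
  log2(x + 0.01)
}

#' Quartile-intersection sample groups
#'
#' Stratifies samples by a marker panel (e.g. the EMT transcription
#' factors SLUG, ZEB1, ZEB2, TWIST2): the high group contains the
#' samples strictly above the 75th percentile of EVERY marker, the low
#' group those strictly below the 25th percentile of every marker.
#' Percentiles use linear interpolation (R quantile type 7); samples
#' exactly on a boundary fall into neither tail. The grouping is
#' rank-based, hence invariant to monotone transforms of each marker.
#'
#' @param mat Numeric matrix, genes in rows (rownames required),
#'   samples in columns.
#' @param marker_genes Character vector of marker row names.
#' @return List with character vectors `high` and `low` (column names);
#'   empty groups are valid and produce a warning.
#' @export
quartile_groups <- function(mat, marker_genes) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  missing_m <- setdiff(marker_genes, rownames(mat))
  if (length(missing_m))
    stop("markers absent from matrix: ", paste(missing_m, collapse = ", "),
         call. = FALSE)
  if (ncol(mat) < 8L)
    stop("need at least 8 samples for quartile grouping", call. = FALSE)
  high <- rep(TRUE, ncol(mat)); low <- rep(TRUE, ncol(mat))
  for (g in marker_genes) {
    x <- mat[g, ]
    q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    high <- high & x > q[2]
    low <- low & x < q[1]
  }
  if (!any(high) || !any(low))
    warning("empty quartile-intersection group", call. = FALSE)
  list(high = colnames(mat)[high], low = colnames(mat)[low])
}

#' Welch's two-sample t-test
#'
#' Two-tailed unpaired t-test with Welch's correction (unequal
#' variances, Satterthwaite degrees of freedom).
#'
#' @param a,b Numeric vectors.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
welch_t <- function(a, b) {
  tt <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Relative qPCR quantification (2^-ddCt)
#'
#' Per sample, dCt = Ct(target) - Ct(reference); per condition,
#' ddCt = mean dCt(condition) - mean dCt(control); fold change =
#' 2^(-ddCt). The control condition maps to fold change 1 exactly, and
#' any reference-gene shift common to all samples cancels.
#'
#' @param ct_table Data.frame with columns `sample`, `condition`,
#'   `ct_target`, `ct_reference`.
#' @param control_condition Name of the control condition (must be
#'   present).
#' @return Data.frame with `condition`, `n`, `delta_ct_mean`,
#'   `delta_delta_ct`, `fold_change`.
#' @export
ddct_fold_change <- function(ct_table, control_condition) {
  stopifnot(all(c("sample", "condition", "ct_target", "ct_reference") %in%
                names(ct_table)))
  if (!control_condition %in% ct_table$condition)
    stop("control condition '", control_condition,
         "' absent from table", call. = FALSE)
  dct <- ct_table$ct_target - ct_table$ct_reference
  m <- tapply(dct, ct_table$condition, mean)
  ddct <- m - m[[control_condition]]
  data.frame(condition = names(m),
             n = as.vector(table(ct_table$condition)[names(m)]),
             delta_ct_mean = as.vector(m),
             delta_delta_ct = as.vector(ddct),
             fold_change = 2^(-as.vector(ddct)),
             row.names = NULL)
}
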