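# Targeted immune-oncology expression panel: reads-per-million and
# housekeeping-ratio normalization, differential expression between HED
# groups, and hypergeometric over-representation on user-supplied gene sets.

#' Reads-per-million normalization
#'
#' `RPM[g, s] = counts[g, s] * 1e6 / sum(counts[, s])`, so each sample
#' column sums to one million over the panel genes.
#'
#' @param counts Non-negative gene x sample count matrix.
#' @return RPM matrix of the same shape.
#' @export
rpm_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  totals <- colSums(counts)
  if (any(totals <= 0)) {
    stop("zero-total sample(s): ",
         paste(colnames(counts)[totals <= 0], collapse = ", "))
  }
  sweep(counts, 2, totals, "/") * 1e6
}

#' Housekeeping-ratio normalization to an internal control
#'
#' For each sample, the normalization ratio is the geometric mean of the
#' control profile's housekeeping-gene RPM divided by the geometric mean
#' of the sample's housekeeping-gene RPM; all genes in the sample are
#' scaled by that ratio. After normalization the sample's housekeeping
#' geometric mean equals the control's. Housekeeping genes with zero RPM
#' in a sample are excluded from that sample's geometric mean with a
#' warning.
#'
#' @param rpm RPM matrix from [rpm_normalize()].
#' @param hk_genes Character vector of housekeeping gene names (default
#'   panel uses 10); all must be rows of `rpm` and of `control_profile`.
#' @param control_profile Named RPM vector of the internal control sample.
#' @return nRPM matrix; per-sample ratios in the `"ratio"` attribute.
#' @export
hk_normalize <- function(rpm, hk_genes, control_profile) {
  missing_s <- setdiff(hk_genes, rownames(rpm))
  missing_c <- setdiff(hk_genes, names(control_profile))
  if (length(missing_s) > 0 || length(missing_c) > 0) {
    stop("housekeeping gene(s) absent: ",
         paste(unique(c(missing_s, missing_c)), collapse = ", "))
  }
  gm <- function(x) exp(mean(log(x)))
  ctrl <- control_profile[hk_genes]
  if (any(ctrl <= 0)) stop("control housekeeping RPM must be positive")
  ratio <- apply(rpm[hk_genes, , drop = FALSE], 2, function(x) {
    pos <- x > 0
    if (!any(pos)) stop("all housekeeping genes are zero in a sample")
    if (!all(pos)) warning("zero housekeeping RPM excluded from geometric mean")
    gm(ctrl[pos]) / gm(x[pos])
  })
  out <- sweep(rpm, 2, ratio, "*")
  attr(out, "ratio") <- ratio
  out
}

#' Log-transform a normalized expression matrix
#'
#' `log2(nRPM + 1)`; the unit pseudocount keeps zeros at zero.
#'
#' @param nrpm Matrix from [hk_normalize()].
#' @return Log-scale matrix.
#' @export
log_nrpm <- function(nrpm) log2(nrpm + 1)

#' Log2 fold-change threshold for differential-expression calls
#'
#' log2 of a 1.5-fold change, 0.5849625...
#' @return A single number.
#' @export
deg_lfc_threshold <- function() log2(1.5)

#' Differential expression between biomarker groups
#'
#' Per-gene two-sample comparison on the `log2(nRPM + 1)` matrix.
#' `method = "moderated"` (default) uses an empirical-Bayes moderated
#' t-statistic with gene variances shrunk toward a panel-wide prior
#' (limma); `method = "welch"` is a plain Welch t-test. The fold change is
#' `mean(high) - mean(low)` on the log2 scale; a gene passes iff
#' `|log2FC|` strictly exceeds `lfc` and `p < alpha` (raw p, unadjusted).
#'
#' @param log_matrix Gene x sample log2-scale matrix.
#' @param group Labels per sample with levels `low` and `high` (or any two
#'   levels, the second taken as "high").
#' @param method `"moderated"` or `"welch"`.
#' @param lfc Fold-change threshold, default [deg_lfc_threshold()].
#' @param alpha P-value threshold, default 0.05.
#' @return Data.frame: `gene`, `log2fc`, `statistic`, `p`, `pass`.
#' @export
differential_expression <- function(log_matrix, group,
                                    method = c("moderated", "welch"),
                                    lfc = deg_lfc_threshold(), alpha = 0.05) {
  method <- match.arg(method)
  group <- droplevels(factor(group))
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  if ("high" %in% levels(group)) {
    group <- stats::relevel(group, setdiff(levels(group), "high"))
  }
  if (any(table(group) < 3)) stop("need at least 3 samples per group")
  log_matrix <- as.matrix(log_matrix)
  hi <- group == levels(group)[2]
  log2fc <- rowMeans(log_matrix[, hi, drop = FALSE]) -
    rowMeans(log_matrix[, !hi, drop = FALSE])
  if (method == "moderated") {
    design <- stats::model.matrix(~group)
    fit <- limma::eBayes(limma::lmFit(log_matrix, design))
    stat <- fit$t[, 2]
    p <- fit$p.value[, 2]
  } else {
    res <- apply(log_matrix, 1, function(x) {
      ht <- stats::t.test(x[hi], x[!hi])
      c(ht$statistic, ht$p.value)
    })
    stat <- res[1, ]
    p <- res[2, ]
  }
  data.frame(gene = rownames(log_matrix), log2fc = unname(log2fc),
             statistic = unname(stat), p = unname(p),
             pass = unname(abs(log2fc) > lfc & p < alpha),
             stringsAsFactors = FALSE)
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1)
  sets
}

#' Over-representation analysis on user-supplied gene sets
#'
#' For each set, the upper-tail hypergeometric probability of observing at
#' least the actual overlap between the differentially expressed genes and
#' the set, within the panel universe; Benjamini-Hochberg adjustment
#' across sets.
#'
#' @param deg_genes Character vector of significant genes (subset of
#'   `universe`; trimmed to it otherwise).
#' @param universe Character vector of all panel genes.
#' @param gene_sets Named list of gene vectors (intersected with the
#'   universe; sets with no overlap with the universe are skipped).
#' @return Data.frame sorted by p: `set`, `set_size`, `overlap`, `p`,
#'   `p_adj`; skipped sets in the `skipped` attribute.
#' @export
ora_test <- function(deg_genes, universe, gene_sets) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  deg_genes <- intersect(unique(deg_genes), universe)
  rows <- list(); skipped <- character(0)
  for (nm in names(gene_sets)) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    if (length(set) == 0) {
      skipped <- c(skipped, nm)
      next
    }
    k <- length(intersect(deg_genes, set))
    p <- stats::phyper(k - 1, length(set), length(universe) - length(set),
                       length(deg_genes), lower.tail = FALSE)
    rows[[nm]] <- data.frame(set = nm, set_size = length(set), overlap = k,
                             p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(set = character(0), set_size = integer(0),
                      overlap = integer(0), p = numeric(0),
                      p_adj = numeric(0))
  } else {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out <- out[order(out$p), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
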