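# Biomarker stratification: optimal cutpoints (maximally selected rank
# statistics for survival endpoints, Youden index for binary response),
# joint HED x TMB groups, and the cohort-level association tests.

#' Standardized two-sample log-rank statistic
#'
#' The observed-minus-expected log-rank statistic for `group == TRUE`
#' versus `group == FALSE`, standardized by its hypergeometric variance.
#' This is the score that the maxstat cutpoint scan maximizes; its square
#' is the usual log-rank chi-square.
#'
#' @param time Follow-up times (> 0).
#' @param event Event indicator (1 = event, 0 = censored).
#' @param group Logical (or two-level) group membership.
#' @return List with `o` (observed events in group), `e` (expected), `v`
#'   (variance), `z` (standardized statistic, `(o - e)/sqrt(v)`).
#' @export
logrank_z <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (!is.logical(group)) {
    f <- factor(group)
    if (nlevels(f) != 2) stop("group must be logical or two-level")
    group <- f == levels(f)[2]
  }
  o <- e <- v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(o = o, e = e, v = v, z = if (v > 0) (o - e) / sqrt(v) else NA_real_)
}

#' Optimal survival cutpoint by maximally selected rank statistics
#'
#' Scans every distinct observed value of the biomarker whose induced split
#' (`value > c` vs `value <= c`) leaves at least `ceil(minprop * n)`
#' patients on each side, computes the standardized two-sample log-rank
#' statistic at each candidate, and returns the candidate maximizing |Z|
#' (the smallest such candidate on ties).
#'
#' @param values Biomarker values.
#' @param time,event Survival endpoint as in [logrank_z()].
#' @param minprop Minimum proportion of patients per side, in (0, 0.5).
#' @return List with `cutpoint`, `statistic` (max |Z|), `n_candidates`,
#'   `n_high`, `n_low`, and a `scan` data.frame (`cutpoint`, `z`).
#' @export
maxstat_cutpoint <- function(values, time, event, minprop = 0.1) {
  stopifnot(minprop > 0, minprop < 0.5)
  keep <- !is.na(values) & !is.na(time) & !is.na(event)
  if (any(!keep)) {
    warning(sum(!keep), " record(s) with missing values excluded")
    values <- values[keep]; time <- time[keep]; event <- event[keep]
  }
  n <- length(values)
  if (n < 10) stop("need at least 10 observations")
  if (sum(event) < 1) stop("need at least one event")
  minsize <- ceiling(minprop * n)
  cand <- sort(unique(values))
  n_high <- vapply(cand, function(c) sum(values > c), integer(1))
  cand <- cand[n_high >= minsize & (n - n_high) >= minsize]
  if (length(cand) == 0) {
    stop("no valid candidate cutpoint (constant biomarker or extreme minprop)")
  }
  z <- vapply(cand, function(c) logrank_z(time, event, values > c)$z,
              numeric(1))
  best <- which.max(abs(z))  # which.max returns the first (smallest) on ties
  list(cutpoint = cand[best], statistic = abs(z[best]),
       n_candidates = length(cand),
       n_high = sum(values > cand[best]), n_low = sum(values <= cand[best]),
       scan = data.frame(cutpoint = cand, z = z))
}

#' Optimal classification threshold by the Youden index
#'
#' Scans the distinct observed scores; a case is called positive iff its
#' score is strictly greater than the threshold. Returns the threshold
#' maximizing J = sensitivity + specificity - 1 (smallest on ties).
#' With `direction = "auto"` the scan direction is flipped, with a
#' warning, when the AUC for "higher score = positive" is below 0.5.
#'
#' @param scores Numeric classifier scores.
#' @param outcome Binary outcome (logical, or 0/1); both classes required.
#' @param direction `"greater"` (default: higher score predicts positive)
#'   or `"auto"`.
#' @return List with `threshold`, `sensitivity`, `specificity`, `youden_j`,
#'   `direction`, `auc`, and the full `scan` data.frame.
#' @export
youden_cutpoint <- function(scores, outcome, direction = c("greater", "auto")) {
  direction <- match.arg(direction)
  outcome <- as.logical(outcome)
  stopifnot(length(scores) == length(outcome), !anyNA(scores), !anyNA(outcome))
  if (length(unique(outcome)) < 2) {
    stop("both outcome classes must be present")
  }
  r <- rank(scores)
  auc <- (sum(r[outcome]) - sum(outcome) * (sum(outcome) + 1) / 2) /
    (sum(outcome) * sum(!outcome))
  flip <- FALSE
  if (direction == "auto" && auc < 0.5) {
    warning("AUC < 0.5 for higher-score-positive; flipping scan direction")
    flip <- TRUE
    scores <- -scores
  }
  cand <- sort(unique(scores))
  sens <- vapply(cand, function(t) mean(scores[outcome] > t), numeric(1))
  spec <- vapply(cand, function(t) mean(scores[!outcome] <= t), numeric(1))
  j <- sens + spec - 1
  best <- which.max(j)
  list(threshold = if (flip) -cand[best] else cand[best],
       sensitivity = sens[best], specificity = spec[best],
       youden_j = j[best],
       direction = if (flip) "lesser" else "greater", auc = auc,
       scan = data.frame(threshold = if (flip) -cand else cand,
                         sensitivity = sens, specificity = spec, j = j))
}

#' Joint HED x TMB biomarker group
#'
#' `both_high` iff HED and TMB both strictly exceed their cutpoints;
#' `both_low` iff neither does; `single_high` otherwise. Default cutpoints
#' are HLA-B HED > 8.61 and TMB > 5.22 mut/Mb.
#'
#' @param hed,tmb Numeric vectors.
#' @param hed_cut,tmb_cut Finite cutpoints.
#' @return Factor with levels `both_low`, `single_high`, `both_high`;
#'   records with a missing value become `NA` with a warning.
#' @export
assign_joint_group <- function(hed, tmb, hed_cut = 8.61, tmb_cut = 5.22) {
  stopifnot(is.finite(hed_cut), is.finite(tmb_cut))
  if (anyNA(hed) || anyNA(tmb)) {
    warning(sum(is.na(hed) | is.na(tmb)),
            " record(s) with missing HED/TMB set to NA")
  }
  n_high <- (hed > hed_cut) + (tmb > tmb_cut)
  factor(c("both_low", "single_high", "both_high")[n_high + 1],
         levels = c("both_low", "single_high", "both_high"))
}

#' Compare DCB rates between two groups
#'
#' Builds the 2x2 contingency table of group versus durable clinical
#' benefit and tests it with Fisher's exact test or the Pearson chi-square
#' without continuity correction. `method = "auto"` uses Fisher whenever
#' any expected cell count is below 5.
#'
#' @param group Two-level group labels.
#' @param dcb DCB labels (`"DCB"` / `"NDB"`, or logical benefit flag).
#' @param method `"auto"`, `"fisher"`, or `"chi2"`.
#' @return List with `table`, `proportions` (DCB rate per group), `method`,
#'   `p`, and `statistic` (chi-square only).
#' @export
dcb_contingency_test <- function(group, dcb, method = c("auto", "fisher",
                                                        "chi2")) {
  method <- match.arg(method)
  if (is.character(dcb)) dcb <- dcb == "DCB"
  group <- droplevels(factor(group))
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  tab <- table(group, factor(dcb, levels = c(TRUE, FALSE),
                             labels = c("DCB", "NDB")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate 2x2 table (empty margin)")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (method == "auto") {
    method <- if (any(expected < 5)) "fisher" else "chi2"
  }
  if (method == "fisher") {
    ht <- stats::fisher.test(tab)
    res <- list(p = ht$p.value, statistic = NA_real_)
  } else {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    res <- list(p = ht$p.value, statistic = unname(ht$statistic))
  }
  c(list(table = tab,
         proportions = tab[, "DCB"] / rowSums(tab),
         method = method), res)
}

#' Spearman rank correlation with two-sided p-value
#'
#' Midrank ties; p-value from the t-approximation (`cor.test` with
#' `exact = FALSE`).
#'
#' @param x,y Numeric vectors, length >= 4, finite.
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_assoc <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4) stop("need at least 4 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("correlation undefined for a constant vector")
  }
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ht$estimate), p = ht$p.value, n = length(x))
}

#' Per-gene mutation-frequency comparison between biomarker groups
#'
#' For each gene, the 2x2 table of mutated/wild-type by high/low group is
#' tested with a two-sided Fisher exact test; the odds ratio is the
#' conditional maximum-likelihood estimate. Genes with no contrast
#' (mutated in everyone or no one) are skipped with a note. P-values are
#' reported unadjusted.
#'
#' @param mutation_flags Logical gene x patient matrix (rownames = genes).
#' @param group Two-level labels per patient, `high`/`low`.
#' @return Data.frame (one row per tested gene) sorted by p:
#'   `gene`, `mut_high`, `n_high`, `mut_low`, `n_low`, `odds_ratio`, `p`;
#'   skipped genes listed in the `skipped` attribute.
#' @export
compare_driver_genes <- function(mutation_flags, group) {
  group <- droplevels(factor(group))
  stopifnot(nlevels(group) == 2, ncol(mutation_flags) == length(group))
  ref <- if ("high" %in% levels(group)) "high" else levels(group)[2]
  hi <- group == ref
  rows <- list(); skipped <- character(0)
  for (g in rownames(mutation_flags)) {
    mut <- as.logical(mutation_flags[g, ])
    if (all(mut) || !any(mut)) {
      skipped <- c(skipped, g)
      next
    }
    tab <- matrix(c(sum(mut & hi), sum(!mut & hi),
                    sum(mut & !hi), sum(!mut & !hi)), 2, 2)
    ht <- stats::fisher.test(tab)
    rows[[g]] <- data.frame(gene = g,
                            mut_high = sum(mut & hi), n_high = sum(hi),
                            mut_low = sum(mut & !hi), n_low = sum(!hi),
                            odds_ratio = unname(ht$estimate), p = ht$p.value,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(gene = character(0))
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Kruskal-Wallis rank test across biomarker groups
#'
#' Midrank tie correction; chi-square reference with k - 1 degrees of
#' freedom. When every value is identical the tie correction degenerates
#' and H is reported as 0 with p = 1.
#'
#' @param values Numeric vector.
#' @param group Group labels (>= 2 non-empty groups).
#' @return List with `h`, `df`, `p`.
#' @export
kruskal_test <- function(values, group) {
  group <- droplevels(factor(group))
  if (nlevels(group) < 2) stop("need at least two groups")
  if (any(table(group) == 0)) stop("empty group")
  if (length(unique(values)) == 1) {
    return(list(h = 0, df = nlevels(group) - 1L, p = 1))
  }
  ht <- stats::kruskal.test(values, group)
  list(h = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}
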