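# Tumor genomic features: somatic SNV filter cascade, TMB (mutations per
# megabase of callable exonic sequence), CNA burden, five-locus PCR MSI
# call, and the durable-clinical-benefit (DCB) rule.

#' Filter somatic SNVs for TMB calculation
#'
#' A record passes iff all five predicates hold:
#' exonic region; nonsynonymous SNV or stopgain effect; depth >= 40;
#' sample variant allele fraction >= 0.03; and every available population
#' allele frequency (ExAC, gnomAD, 1000 Genomes) <= 0.002. All boundaries
#' are inclusive. A missing population frequency means "not observed" and
#' passes that sub-filter. The rejection tally attributes each rejected
#' record to its first failing filter in the documented order
#' (region, effect, depth, vaf, pop_af).
#'
#' @param variants Data.frame with columns `region_class`, `effect`,
#'   `depth`, `vaf`, and optionally `pop_af_exac`, `pop_af_gnomad`,
#'   `pop_af_1kg`.
#' @param min_depth Minimum read depth (default 40).
#' @param min_vaf Minimum sample variant allele fraction (default 0.03).
#' @param max_pop_af Maximum population allele frequency (default 0.002).
#' @return List with `passed` (the passing rows), `tally` (named integer
#'   vector of per-filter rejections), and `n_missing_pop_af` (records
#'   with no population frequency at all).
#' @export
filter_somatic_snvs <- function(variants, min_depth = 40, min_vaf = 0.03,
                                max_pop_af = 0.002) {
  req <- c("region_class", "effect", "depth", "vaf")
  if (!all(req %in% names(variants))) {
    stop("variant table must have columns: ", paste(req, collapse = ", "))
  }
  if (any(variants$depth < 0, na.rm = TRUE) ||
      any(variants$vaf < 0 | variants$vaf > 1, na.rm = TRUE)) {
    stop("depth must be >= 0 and vaf within [0, 1]")
  }
  pop_cols <- intersect(c("pop_af_exac", "pop_af_gnomad", "pop_af_1kg"),
                        names(variants))
  ok_region <- variants$region_class == "exonic"
  ok_effect <- variants$effect %in% c("nonsynonymous SNV", "stopgain")
  ok_depth  <- variants$depth >= min_depth
  ok_vaf    <- variants$vaf >= min_vaf
  if (length(pop_cols) > 0) {
    pop <- as.matrix(variants[, pop_cols, drop = FALSE])
    ok_pop <- apply(pop, 1, function(x) all(x[!is.na(x)] <= max_pop_af))
    n_missing <- sum(rowSums(!is.na(pop)) == 0)
  } else {
    ok_pop <- rep(TRUE, nrow(variants))
    n_missing <- nrow(variants)
  }
  checks <- cbind(region = ok_region, effect = ok_effect, depth = ok_depth,
                  vaf = ok_vaf, pop_af = ok_pop)
  pass <- rowSums(checks) == ncol(checks)
  first_fail <- apply(!checks[!pass, , drop = FALSE], 1,
                      function(x) colnames(checks)[which(x)[1]])
  tally <- table(factor(first_fail, levels = colnames(checks)))
  list(passed = variants[pass, , drop = FALSE],
       tally = stats::setNames(as.integer(tally), names(tally)),
       n_missing_pop_af = n_missing)
}

#' Tumor mutational burden
#'
#' TMB = mutation count * 1e6 / callable bases, in mutations per megabase,
#' where callable bases is the number of exonic bases covered at depth
#' >= 40 in the sample.
#'
#' @param mutation_count Number of filtered somatic SNVs (vectorized).
#' @param callable_bases Positive callable-base totals (vectorized).
#' @return Numeric TMB in mut/Mb.
#' @examples
#' compute_tmb(10, 2e6)   # 5.0
#' @export
compute_tmb <- function(mutation_count, callable_bases) {
  if (any(callable_bases <= 0)) stop("callable_bases must be positive")
  if (any(mutation_count < 0)) stop("mutation_count must be non-negative")
  mutation_count * 1e6 / callable_bases
}

#' Copy-number-alteration burden
#'
#' Number of genes with a copy-number gain or loss in one sample.
#'
#' @param cna_records Data.frame with columns `gene` and `state`
#'   (`gain`, `loss`, or `neutral`) for one sample.
#' @return Integer burden.
#' @export
compute_cna_burden <- function(cna_records) {
  stopifnot(all(c("gene", "state") %in% names(cna_records)))
  if (anyDuplicated(cna_records$gene)) {
    dup <- unique(cna_records$gene[duplicated(cna_records$gene)])
    stop("duplicate CNA state for gene(s): ", paste(dup, collapse = ", "))
  }
  if (!all(cna_records$state %in% c("gain", "loss", "neutral"))) {
    stop("CNA state must be gain, loss or neutral")
  }
  sum(cna_records$state != "neutral")
}

#' Microsatellite-instability call from the five-locus PCR panel
#'
#' Instability at two or more of BAT-25, BAT-26, D2S123, D5S346 and
#' D17S250 is MSI-H; instability at one locus or none is MSS.
#'
#' @param flags Named logical vector of per-locus instability; all five
#'   loci must be present.
#' @return List with `n_unstable` and `call` (`"MSI-H"` or `"MSS"`).
#' @export
call_msi <- function(flags) {
  loci <- c("BAT-25", "BAT-26", "D2S123", "D5S346", "D17S250")
  missing <- setdiff(loci, names(flags))
  if (length(missing) > 0) {
    stop("missing MSI locus flag(s): ", paste(missing, collapse = ", "))
  }
  n <- sum(as.logical(flags[loci]))
  list(n_unstable = n, call = if (n >= 2) "MSI-H" else "MSS")
}

#' Durable clinical benefit from RECIST response
#'
#' DCB is complete response, partial response, or stable disease lasting
#' at least 24 weeks; progressive disease or shorter stable disease is NDB.
#'
#' @param response Character vector with values in `CR`, `PR`, `SD`, `PD`.
#' @param sd_duration_weeks Numeric vector; required where `response == "SD"`.
#' @return Character vector of `"DCB"` / `"NDB"`.
#' @export
derive_dcb <- function(response, sd_duration_weeks = NA_real_) {
  if (!all(response %in% c("CR", "PR", "SD", "PD"))) {
    stop("response must be one of CR, PR, SD, PD")
  }
  sd_duration_weeks <- rep_len(sd_duration_weeks, length(response))
  if (any(response == "SD" & is.na(sd_duration_weeks))) {
    stop("SD response requires sd_duration_weeks")
  }
  ifelse(response %in% c("CR", "PR"), "DCB",
         ifelse(response == "SD" & sd_duration_weeks >= 24, "DCB", "NDB"))
}
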