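# End-to-end orchestration: HED profiles -> tumor features -> cutpoints and
# joint groups -> survival and contingency analyses -> expression analyses,
# with a machine-readable JSON run report.

#' Analysis configuration
#'
#' Central registry of the workflow's constants. The reference cutpoints
#' carried here are HLA-A HED 6.06, HLA-B HED 8.61 (alternate validation
#' cohort value 10.19), HLA-C HED 2.55 and TMB 5.22 mut/Mb; the variant
#' filter constants are depth 40, VAF 0.03, population frequency 0.002;
#' the stable-disease window for durable clinical benefit is 24 weeks; the
#' differential-expression thresholds are |log2FC| > log2(1.5) = 0.5849
#' and p < 0.05. By default `hed_cut`/`tmb_cut` are `NULL`, meaning the
#' pipeline determines them from the cohort (maxstat on OS for HED, Youden
#' on DCB for TMB); set them to fixed values to reuse reference cutpoints.
#'
#' @param matrix_mode Grantham matrix mode.
#' @param minprop Minimum group proportion for the maxstat scan.
#' @param hed_cut,tmb_cut Optional fixed cutpoints overriding the scans.
#' @param ref_cutpoints Reference cutpoint set (named).
#' @param min_depth,min_vaf,max_pop_af Variant filter constants.
#' @param dcb_weeks Stable-disease duration defining DCB.
#' @param deg_lfc,deg_alpha Differential-expression thresholds.
#' @param deg_method `"moderated"` or `"welch"`.
#' @param seed Seed echoed into the run report.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(matrix_mode = "published-integer",
                            minprop = 0.1,
                            hed_cut = NULL, tmb_cut = NULL,
                            ref_cutpoints = c(hed_a = 6.06, hed_b = 8.61,
                                              hed_b_msk = 10.19,
                                              hed_c = 2.55, tmb = 5.22),
                            min_depth = 40, min_vaf = 0.03,
                            max_pop_af = 0.002,
                            dcb_weeks = 24,
                            deg_lfc = deg_lfc_threshold(), deg_alpha = 0.05,
                            deg_method = "moderated",
                            seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "analysis_config"
  cfg
}

#' Per-sample tumor feature table
#'
#' Applies the somatic SNV filter cascade per sample, computes TMB against
#' the sample's callable-base total, the CNA burden, and the five-locus
#' MSI call.
#'
#' @param variants Variant table (all samples).
#' @param callable Callable-base table (`sample_id`, `callable_bases`).
#' @param cna CNA table (`sample_id`, `gene`, `state`).
#' @param msi MSI panel table (`sample_id` plus the five locus columns).
#' @param config An [analysis_config()].
#' @return Data.frame per sample: `sample_id`, `mutation_count`,
#'   `callable_bases`, `tmb`, `cna_burden`, `msi_call`; filter tallies
#'   summed over samples in the `filter_tally` attribute.
#' @export
tumor_features <- function(variants, callable, cna, msi,
                           config = analysis_config()) {
  tally <- NULL
  rows <- lapply(seq_len(nrow(callable)), function(i) {
    s <- callable$sample_id[i]
    fs <- filter_somatic_snvs(variants[variants$sample_id == s, ,
                                       drop = FALSE],
                              config$min_depth, config$min_vaf,
                              config$max_pop_af)
    msi_row <- msi[msi$sample_id == s, , drop = FALSE]
    flags <- as.logical(msi_row[1, c("BAT-25", "BAT-26", "D2S123",
                                     "D5S346", "D17S250")])
    names(flags) <- c("BAT-25", "BAT-26", "D2S123", "D5S346", "D17S250")
    data.frame(
      sample_id = s,
      mutation_count = nrow(fs$passed),
      callable_bases = callable$callable_bases[i],
      tmb = compute_tmb(nrow(fs$passed), callable$callable_bases[i]),
      cna_burden = compute_cna_burden(
        cna[cna$sample_id == s, c("gene", "state"), drop = FALSE]),
      msi_call = if (nrow(msi_row) > 0) call_msi(flags)$call else NA,
      stringsAsFactors = FALSE)
  })
  tallies <- lapply(seq_len(nrow(callable)), function(i) {
    s <- callable$sample_id[i]
    filter_somatic_snvs(variants[variants$sample_id == s, , drop = FALSE],
                        config$min_depth, config$min_vaf,
                        config$max_pop_af)$tally
  })
  out <- do.call(rbind, rows)
  attr(out, "filter_tally") <- Reduce(`+`, tallies)
  out
}

#' Run the full biomarker analysis workflow
#'
#' Orchestrates every stage over an input bundle: HED profiles from the
#' allele library and genotypes; tumor features (TMB / CNA / MSI); DCB
#' derivation; cutpoint determination (maxstat on OS for HLA-B HED,
#' Youden on DCB for TMB, unless fixed in the config); joint group
#' assignment; Kaplan-Meier, log-rank and multivariable Cox analyses; the
#' DCB contingency test; Spearman associations of HED with TMB, TNB and
#' CNA burden among HLA-B heterozygotes; expression normalization,
#' differential expression between HED groups and over-representation on
#' the bundled gene sets.
#'
#' @param cohort A cohort list ([simulate_cohort()] /
#'   [read_cohort_bundle()]) or a bundle directory path.
#' @param config An [analysis_config()].
#' @param out_dir Optional directory; when given, result tables are
#'   written as TSV and the run report as `report.json`.
#' @return List with elements `hed`, `features`, `cohort_table`,
#'   `cutpoints`, `survival`, `dcb_tests`, `associations`, `driver_genes`,
#'   `expression`, `report`.
#' @export
run_hed_pipeline <- function(cohort, config = analysis_config(),
                             out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort_bundle(cohort)
  m <- build_grantham_matrix(mode = config$matrix_mode)
  report <- list(config = config[setdiff(names(config), "ref_cutpoints")],
                 ref_cutpoints = as.list(config$ref_cutpoints),
                 stages = list())

  ## HED profiles
  lib <- cohort$library
  hed <- hed_profiles(cohort$genotypes, lib, m)
  report$stages$hed <- list(status = "ok", n = nrow(hed))

  ## tumor features
  features <- tumor_features(cohort$variants, cohort$callable, cohort$cna,
                             cohort$msi, config)
  report$stages$features <-
    list(status = "ok", n = nrow(features),
         filter_tally = as.list(attr(features, "filter_tally")))

  ## cohort table
  clin <- cohort$clinical
  dcb <- derive_dcb(clin$response, clin$sd_duration_weeks)
  tab <- merge(merge(clin, hed, by = "patient_id"),
               features, by.x = "patient_id", by.y = "sample_id",
               all.x = TRUE)
  tab$dcb <- dcb[match(tab$patient_id, clin$patient_id)]
  report$stages$cohort_table <- list(status = "ok", n = nrow(tab))

  ## cutpoints
  ms <- maxstat_cutpoint(tab$hed_b, tab$os_months, tab$os_event,
                         config$minprop)
  hed_cut <- if (is.null(config$hed_cut)) ms$cutpoint else config$hed_cut
  yd <- youden_cutpoint(tab$tmb[!is.na(tab$tmb)],
                        (tab$dcb == "DCB")[!is.na(tab$tmb)])
  tmb_cut <- if (is.null(config$tmb_cut)) yd$threshold else config$tmb_cut
  cutpoints <- list(maxstat_hed_b = ms, youden_tmb = yd,
                    hed_cut = hed_cut, tmb_cut = tmb_cut)
  report$stages$cutpoints <- list(status = "ok", hed_cut = hed_cut,
                                  tmb_cut = tmb_cut)

  ## stratification
  tab$hed_b_group <- dichotomize(tab$hed_b, hed_cut)
  tab$tmb_group <- suppressWarnings(dichotomize(tab$tmb, tmb_cut))
  tab$joint_group <- suppressWarnings(
    assign_joint_group(tab$hed_b, tab$tmb, hed_cut, tmb_cut))

  ## survival analyses
  km_by_group <- lapply(split(tab, tab$hed_b_group), function(d) {
    km_fit(d$os_months, d$os_event)
  })
  lr_os <- logrank_test(tab$os_months, tab$os_event, tab$hed_b_group)
  lr_pfs <- logrank_test(tab$pfs_months, tab$pfs_event, tab$hed_b_group)
  with_tumor <- !is.na(tab$tmb)
  cox_cov <- data.frame(
    hed_b_high = tab$hed_b_group[with_tumor] == "high",
    tmb_high = tab$tmb_group[with_tumor] == "high",
    msi_h = tab$msi_call[with_tumor] == "MSI-H")
  cox <- cox_fit(tab$os_months[with_tumor], tab$os_event[with_tumor],
                 cox_cov)
  surv <- list(km_os_by_hed_b = km_by_group, logrank_os_hed_b = lr_os,
               logrank_pfs_hed_b = lr_pfs, cox_os = cox,
               forest = forest_table(multivariable_os = cox))
  report$stages$survival <- list(status = "ok",
                                 logrank_os_p = lr_os$p,
                                 cox_n = sum(with_tumor))

  ## DCB contingency
  dcb_hed <- dcb_contingency_test(tab$hed_b_group, tab$dcb)
  jt <- tab[with_tumor & tab$joint_group %in% c("both_high", "both_low"), ]
  dcb_joint <- dcb_contingency_test(droplevels(jt$joint_group), jt$dcb,
                                    method = "fisher")
  report$stages$dcb <- list(status = "ok", p_hed = dcb_hed$p,
                            p_joint = dcb_joint$p)

  ## associations among HLA-B heterozygotes, by MSI status
  assoc <- list()
  for (msi_level in c("MSI-H", "MSS")) {
    sub <- tab[with_tumor & tab$het_b & !is.na(tab$msi_call) &
                 tab$msi_call == msi_level, ]
    if (nrow(sub) >= 4) {
      assoc[[msi_level]] <- list(
        tmb = spearman_assoc(sub$hed_b, sub$tmb),
        tnb = spearman_assoc(sub$hed_b, sub$tnb),
        cna = spearman_assoc(sub$hed_b, sub$cna_burden))
    }
  }
  report$stages$associations <- list(status = "ok",
                                     subsets = names(assoc))

  ## driver-gene comparison (HLA-B heterozygotes with tumor data)
  driver <- NULL
  if (!is.null(cohort$driver_flags)) {
    het_ids <- tab$patient_id[tab$het_b]
    keep <- intersect(colnames(cohort$driver_flags), het_ids)
    grp <- tab$hed_b_group[match(keep, tab$patient_id)]
    driver <- compare_driver_genes(
      cohort$driver_flags[, keep, drop = FALSE], grp)
    report$stages$driver_genes <- list(status = "ok", n_genes = nrow(driver))
  }

  ## expression
  rpm <- rpm_normalize(cohort$counts)
  nrpm <- hk_normalize(rpm, cohort$hk_genes, cohort$control_profile)
  lg <- log_nrpm(nrpm)
  expr_group <- tab$hed_b_group[match(colnames(lg), tab$patient_id)]
  deg <- differential_expression(lg, expr_group,
                                 method = config$deg_method,
                                 lfc = config$deg_lfc,
                                 alpha = config$deg_alpha)
  ora <- ora_test(deg$gene[deg$pass], rownames(lg), cohort$gene_sets)
  expression <- list(deg = deg, ora = ora,
                     hk_ratio = attr(nrpm, "ratio"))
  report$stages$expression <- list(status = "ok",
                                   n_deg = sum(deg$pass),
                                   n_sets = nrow(ora))

  out <- list(hed = hed, features = features, cohort_table = tab,
              cutpoints = cutpoints, survival = surv,
              dcb_tests = list(hed_b = dcb_hed, joint = dcb_joint),
              associations = assoc, driver_genes = driver,
              expression = expression, report = report)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' Write pipeline result tables and the JSON run report
#'
#' @param result Result of [run_hed_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_tsv(result$hed, file.path(dir, "hed_profiles.tsv"))
  .write_tsv(result$features, file.path(dir, "tumor_features.tsv"))
  .write_tsv(result$cohort_table, file.path(dir, "cohort_table.tsv"))
  .write_tsv(result$survival$forest, file.path(dir, "cox_forest.tsv"))
  .write_tsv(result$expression$deg, file.path(dir, "deg.tsv"))
  .write_tsv(result$expression$ora, file.path(dir, "ora.tsv"))
  if (!is.null(result$driver_genes)) {
    .write_tsv(result$driver_genes, file.path(dir, "driver_genes.tsv"))
  }
  jsonlite::write_json(result$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
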