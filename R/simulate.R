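# Seeded synthetic-cohort generator. Emulates the *structure* of an
# ICB-treated GI cancer cohort: per-locus HLA allele pairs with tunable
# divergence, survival times whose hazard depends on the HED and TMB
# groups, DCB outcomes from a logistic model, somatic variant records with
# depth/VAF/population-frequency fields exercising every filter branch,
# CNA and MSI tables, and a negative-binomial immune-panel count matrix
# with stable housekeeping genes and a DE fraction between HED groups.

#' Simulation configuration
#'
#' Defaults mirror the shape of the study the package analyzes: 84
#' patients with germline HLA typing, 76 with tumor profiling, biomarker
#' cutpoints HLA-B HED 8.61 and TMB 5.22 mut/Mb, a 395-gene immune panel
#' with 10 housekeeping genes. Hazard ratios, DCB log-odds, divergence
#' targets and filter-failure fractions are tunable.
#'
#' @param seed Integer RNG seed; fixed seed gives identical output.
#' @param n_patients Cohort size (germline analysis).
#' @param n_tumor Patients with tumor profiling (first `n_tumor` patients).
#' @param pool_sizes Named alleles-per-locus pool sizes.
#' @param divergence_targets Named per-locus target mean pairwise HED.
#' @param hom_rates Named per-locus homozygosity probabilities.
#' @param pbr_len Peptide-binding-region length (exon 2 + exon 3).
#' @param hed_cut,tmb_cut Cutpoints defining the high groups that the
#'   outcome models condition on.
#' @param os_h0,pfs_h0 Baseline exponential hazards (per month).
#' @param beta_hed,beta_tmb Log hazard ratios for the HED-high and
#'   TMB-high groups (negative = protective).
#' @param censor_rate Exponential censoring hazard (per month).
#' @param dcb_b0,dcb_b_hed,dcb_b_tmb DCB logistic model: intercept and
#'   log-odds increments for the high groups.
#' @param callable_mean Mean callable exonic bases per sample.
#' @param tmb_meanlog,tmb_sdlog Log-normal distribution of each sample's
#'   expected TMB (mut/Mb) before the group shift.
#' @param tmb_shift_high Multiplier on expected TMB for HED-high patients
#'   (1 = independent).
#' @param filter_fail_fracs Named fractions (relative to passing count) of
#'   deliberately failing variant records per filter.
#' @param n_cna_genes,cna_alter_prob CNA table shape.
#' @param msi_h_rate Fraction of MSI-H samples.
#' @param n_genes,n_hk Panel size and housekeeping gene count.
#' @param de_fraction,de_lfc_range Fraction of non-housekeeping genes
#'   differentially expressed between HED groups and the log2
#'   fold-change range.
#' @param nb_size Negative-binomial dispersion (size parameter).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 84L,
                       n_tumor = 76L,
                       pool_sizes = c(A = 12L, B = 14L, C = 10L),
                       divergence_targets = c(A = 6, B = 9, C = 3),
                       hom_rates = c(A = 0.15, B = 0.07, C = 0.15),
                       pbr_len = 182L,
                       hed_cut = 8.61, tmb_cut = 5.22,
                       os_h0 = log(2) / 10, pfs_h0 = log(2) / 4,
                       beta_hed = log(0.5), beta_tmb = log(0.5),
                       censor_rate = 0.03,
                       dcb_b0 = stats::qlogis(0.16),
                       dcb_b_hed = 1.1, dcb_b_tmb = 1.1,
                       callable_mean = 35e6,
                       tmb_meanlog = log(3.5), tmb_sdlog = 0.8,
                       tmb_shift_high = 1,
                       filter_fail_fracs = c(region = 0.15, effect = 0.30,
                                             depth = 0.08, vaf = 0.08,
                                             pop_af = 0.08),
                       n_cna_genes = 60L, cna_alter_prob = 0.16,
                       msi_h_rate = 0.18,
                       n_genes = 395L, n_hk = 10L,
                       de_fraction = 0.10, de_lfc_range = c(0.7, 1.6),
                       nb_size = 10,
                       de_seeded_in = "high") {
  cfg <- as.list(environment())
  stopifnot(cfg$n_tumor <= cfg$n_patients,
            all(cfg$pool_sizes >= 2),
            all(cfg$hom_rates >= 0 & cfg$hom_rates <= 1),
            cfg$censor_rate >= 0, cfg$msi_h_rate >= 0, cfg$msi_h_rate <= 1,
            cfg$de_fraction >= 0, cfg$de_fraction <= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate an aligned HLA allele library
#'
#' Per locus, draws an ancestral peptide-binding-region sequence and
#' derives each allele by random substitutions, with the substitution
#' count chosen so the expected mean pairwise divergence matches the
#' locus target (two alleles with `k` substitutions each differ at about
#' `2k` sites, each contributing roughly the matrix-average distance 100).
#'
#' @param cfg A [sim_config()]. The caller is responsible for seeding.
#' @param m Grantham matrix used to report achieved divergences.
#' @return List with `library` (data.frame `allele`, `locus`, `pbr_seq`,
#'   `source_len`) and `achieved_divergence` (named per-locus means).
#' @export
simulate_allele_library <- function(cfg = sim_config(),
                                    m = build_grantham_matrix()) {
  aa <- aa_alphabet()
  len <- cfg$pbr_len
  mean_d <- mean(m[upper.tri(m)])
  rows <- list(); achieved <- c()
  for (locus in c("A", "B", "C")) {
    target <- cfg$divergence_targets[[locus]]
    k <- max(1L, round(target * len / (2 * mean_d)))
    if (2 * k > len) {
      stop("divergence target unattainable at locus ", locus)
    }
    anc <- sample(aa, len, replace = TRUE)
    ## redraw until the realized mean pairwise divergence is within 20% of
    ## the target (small substitution counts are noisy)
    for (attempt in 1:25) {
      pool <- character(cfg$pool_sizes[[locus]])
      for (i in seq_along(pool)) {
        s <- anc
        pos <- sample(len, k)
        s[pos] <- vapply(s[pos], function(r) sample(setdiff(aa, r), 1),
                         character(1))
        pool[i] <- paste(s, collapse = "")
      }
      hed <- utils::combn(pool, 2, function(p) pairwise_hed(p[1], p[2], m))
      if (abs(mean(hed) - target) <= 0.2 * target) break
      if (attempt == 25) {
        stop("could not reach divergence target at locus ", locus)
      }
    }
    achieved[locus] <- mean(hed)
    rows[[locus]] <- data.frame(
      allele = sprintf("%s*%02d:01", locus, seq_along(pool)),
      locus = locus, pbr_seq = pool, source_len = len,
      stringsAsFactors = FALSE)
  }
  list(library = do.call(rbind, rows), achieved_divergence = achieved)
}

# Draw one genotype column pair for a locus.
.sim_genotype_locus <- function(n, alleles, hom_rate) {
  a1 <- sample(alleles, n, replace = TRUE)
  a2 <- ifelse(stats::runif(n) < hom_rate, a1,
               vapply(a1, function(a) sample(setdiff(alleles, a), 1),
                      character(1)))
  list(a1 = a1, a2 = a2)
}

#' Simulate survival records given group flags
#'
#' Exponential event times with hazard
#' `h0 * exp(beta_hed * hed_high + beta_tmb * tmb_high)` and independent
#' exponential censoring; used for both OS and PFS and for calibration
#' experiments. The caller is responsible for seeding.
#'
#' @param hed_high,tmb_high Logical vectors.
#' @param h0 Baseline hazard per month.
#' @param beta_hed,beta_tmb Log hazard ratios.
#' @param censor_rate Exponential censoring hazard per month.
#' @return Data.frame with `time` (months) and `event`.
#' @export
simulate_survival <- function(hed_high, tmb_high = rep(FALSE,
                                                       length(hed_high)),
                              h0 = log(2) / 10, beta_hed = log(0.5),
                              beta_tmb = log(0.5), censor_rate = 0.03) {
  n <- length(hed_high)
  h <- h0 * exp(beta_hed * hed_high + beta_tmb * tmb_high)
  t_event <- stats::rexp(n, h)
  t_cens <- if (censor_rate > 0) stats::rexp(n, censor_rate) else Inf
  data.frame(time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
}

# Variant records for one sample: n_pass records passing all filters plus
# deliberately failing records per filter, so every branch is exercised.
.sim_variants_sample <- function(sample_id, n_pass, fracs) {
  mk <- function(n, region = "exonic",
                 effect = c("nonsynonymous SNV", "stopgain"),
                 depth = NULL, vaf = NULL, pop = NULL) {
    if (n == 0) return(NULL)
    if (is.null(depth)) depth <- 40 + stats::rpois(n, 60)
    if (is.null(vaf)) vaf <- round(0.03 + stats::rbeta(n, 2, 5) * 0.6, 4)
    if (is.null(pop)) {
      pop <- ifelse(stats::runif(n) < 0.7, 0,
                    round(stats::runif(n, 0, 0.002), 6))
    }
    data.frame(
      sample_id = sample_id,
      chrom = paste0("chr", sample(1:22, n, replace = TRUE)),
      pos = sample.int(1e8, n),
      ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      gene = paste0("GENE", sample.int(500, n, replace = TRUE)),
      region_class = rep_len(region, n),
      effect = sample(effect, n, replace = TRUE),
      depth = depth, vaf = vaf,
      pop_af_exac = pop,
      pop_af_gnomad = ifelse(stats::runif(n) < 0.05, NA, pop),
      pop_af_1kg = pop,
      stringsAsFactors = FALSE)
  }
  nf <- function(frac) stats::rpois(1, max(n_pass, 2) * frac)
  n_region <- nf(fracs[["region"]]); n_effect <- nf(fracs[["effect"]])
  n_depth <- nf(fracs[["depth"]]); n_vaf <- nf(fracs[["vaf"]])
  n_pop <- nf(fracs[["pop_af"]])
  rbind(
    mk(n_pass),
    mk(n_region, region = sample(c("intronic", "UTR3", "UTR5"), n_region,
                                 replace = TRUE)),
    mk(n_effect, effect = "synonymous SNV"),
    mk(n_depth, depth = sample(5:39, n_depth, replace = TRUE)),
    mk(n_vaf, vaf = round(stats::runif(n_vaf, 0.001, 0.029), 4)),
    mk(n_pop, pop = round(stats::runif(n_pop, 0.0021, 0.05), 6)))
}

#' Simulate a complete cohort input bundle
#'
#' Generates every table the analysis pipeline consumes. Outcomes are
#' generated from the configured models conditioned on the realized
#' HLA-B HED and TMB groups, so downstream estimators can be checked for
#' parameter recovery and null calibration.
#'
#' @param cfg A [sim_config()].
#' @param library Optional pre-built allele library (list as returned by
#'   [simulate_allele_library()]); built from `cfg` when `NULL`.
#' @param m Grantham matrix used for HED computation.
#' @return List of class `hed_cohort` with elements `library`, `exons`,
#'   `genotypes`, `hed` (true profiles used for generation), `clinical`,
#'   `variants`, `callable`, `cna`, `msi`, `counts`, `control_profile`,
#'   `hk_genes`, `gene_sets`, `driver_flags`, `config`.
#' @export
simulate_cohort <- function(cfg = sim_config(), library = NULL,
                            m = build_grantham_matrix()) {
  set.seed(cfg$seed)
  if (is.null(library)) library <- simulate_allele_library(cfg, m)
  lib <- library$library
  n <- cfg$n_patients
  ids <- sprintf("P%03d", seq_len(n))

  ## genotypes
  g <- list()
  for (locus in c("A", "B", "C")) {
    gl <- .sim_genotype_locus(n, lib$allele[lib$locus == locus],
                              cfg$hom_rates[[locus]])
    g[[paste0(locus, "1")]] <- gl$a1
    g[[paste0(locus, "2")]] <- gl$a2
  }
  genotypes <- data.frame(patient_id = ids, g, stringsAsFactors = FALSE)
  hed <- hed_profiles(genotypes, lib, m)
  hed_high <- hed$hed_b > cfg$hed_cut

  ## tumor subset, callable bases and variant tables
  tumor_ids <- ids[seq_len(cfg$n_tumor)]
  callable <- data.frame(
    sample_id = tumor_ids,
    callable_bases = round(stats::rnorm(cfg$n_tumor, cfg$callable_mean,
                                        cfg$callable_mean * 0.05)))
  tmb_expected <- stats::rlnorm(cfg$n_tumor, cfg$tmb_meanlog, cfg$tmb_sdlog) *
    ifelse(hed_high[seq_len(cfg$n_tumor)], cfg$tmb_shift_high, 1)
  variants <- list()
  for (i in seq_len(cfg$n_tumor)) {
    n_pass <- stats::rpois(1, tmb_expected[i] *
                             callable$callable_bases[i] / 1e6)
    variants[[i]] <- .sim_variants_sample(tumor_ids[i], n_pass,
                                          cfg$filter_fail_fracs)
  }
  variants <- do.call(rbind, variants)
  rownames(variants) <- NULL

  ## realized TMB and the TMB-high flag conditioning the outcome models
  tmb <- vapply(seq_len(cfg$n_tumor), function(i) {
    v <- variants[variants$sample_id == tumor_ids[i], , drop = FALSE]
    compute_tmb(nrow(filter_somatic_snvs(v)$passed),
                callable$callable_bases[i])
  }, numeric(1))
  tmb_high <- rep(FALSE, n)
  tmb_high[seq_len(cfg$n_tumor)] <- tmb > cfg$tmb_cut

  ## survival and DCB outcomes
  os <- simulate_survival(hed_high, tmb_high, cfg$os_h0, cfg$beta_hed,
                          cfg$beta_tmb, cfg$censor_rate)
  pfs <- simulate_survival(hed_high, tmb_high, cfg$pfs_h0, cfg$beta_hed,
                           cfg$beta_tmb, cfg$censor_rate)
  p_dcb <- stats::plogis(cfg$dcb_b0 + cfg$dcb_b_hed * hed_high +
                           cfg$dcb_b_tmb * tmb_high)
  dcb <- stats::runif(n) < p_dcb
  response <- ifelse(dcb, sample(c("CR", "PR", "SD"), n, replace = TRUE,
                                 prob = c(0.1, 0.5, 0.4)),
                     sample(c("PD", "SD"), n, replace = TRUE,
                            prob = c(0.8, 0.2)))
  sd_dur <- ifelse(response == "SD",
                   ifelse(dcb, round(stats::runif(n, 24, 80), 1),
                          round(stats::runif(n, 4, 23.9), 1)), NA)

  ## MSI panel
  msi_h <- stats::runif(cfg$n_tumor) < cfg$msi_h_rate
  loci <- c("BAT-25", "BAT-26", "D2S123", "D5S346", "D17S250")
  msi <- data.frame(sample_id = tumor_ids)
  flags <- t(vapply(msi_h, function(h) {
    k <- if (h) 2 + stats::rbinom(1, 3, 0.5) else stats::rbinom(1, 1, 0.15)
    seq_along(loci) %in% sample(seq_along(loci), k)
  }, logical(5)))
  colnames(flags) <- loci
  msi <- cbind(msi, as.data.frame(flags, check.names = FALSE))

  ## CNA table
  cna_genes <- paste0("CN", sprintf("%03d", seq_len(cfg$n_cna_genes)))
  cna <- do.call(rbind, lapply(tumor_ids, function(s) {
    data.frame(sample_id = s, gene = cna_genes,
               state = sample(c("gain", "loss", "neutral"),
                              cfg$n_cna_genes, replace = TRUE,
                              prob = c(cfg$cna_alter_prob / 2,
                                       cfg$cna_alter_prob / 2,
                                       1 - cfg$cna_alter_prob)),
               stringsAsFactors = FALSE)
  }))

  ## driver-gene mutation flags (enriched in the low-HED group)
  drivers <- c("KMT2D", "TP53", "ARID1A", "NOTCH1", "PIK3CA", "KRAS",
               "APC", "SMAD4")
  base_rate <- c(0.35, 0.55, 0.30, 0.25, 0.20, 0.25, 0.30, 0.15)
  shift <- c(-1.0, -0.8, -0.8, -0.8, 0, 0, 0, 0)
  driver_flags <- t(vapply(seq_along(drivers), function(j) {
    p <- stats::plogis(stats::qlogis(base_rate[j]) +
                         shift[j] * hed_high[seq_len(cfg$n_tumor)])
    stats::runif(cfg$n_tumor) < p
  }, logical(cfg$n_tumor)))
  dimnames(driver_flags) <- list(drivers, tumor_ids)

  ## TNB (provided column): roughly proportional to mutation load
  tnb <- rep(NA_real_, n)
  tnb[seq_len(cfg$n_tumor)] <- stats::rpois(cfg$n_tumor, pmax(tmb, 0.1) * 3)

  clinical <- data.frame(
    patient_id = ids,
    os_months = pmax(round(os$time, 2), 0.01), os_event = os$event,
    pfs_months = pmax(round(pfs$time, 2), 0.01), pfs_event = pfs$event,
    response = response, sd_duration_weeks = sd_dur,
    msi_status = c(ifelse(msi_h, "MSI-H", "MSS"),
                   rep(NA, n - cfg$n_tumor)),
    tnb = tnb, stringsAsFactors = FALSE)

  ## immune panel counts
  n_io <- cfg$n_genes - cfg$n_hk
  genes <- c(paste0("IO", sprintf("%03d", seq_len(n_io))),
             paste0("HK", sprintf("%02d", seq_len(cfg$n_hk))))
  hk_genes <- genes[(n_io + 1):cfg$n_genes]
  mu <- stats::rlnorm(cfg$n_genes, log(200), 1)
  mu[(n_io + 1):cfg$n_genes] <- stats::rlnorm(cfg$n_hk, log(1500), 0.2)
  n_de <- round(cfg$de_fraction * n_io)
  de_genes <- sample(genes[seq_len(n_io)], n_de)
  lfc <- stats::runif(n_de, cfg$de_lfc_range[1], cfg$de_lfc_range[2])
  counts <- matrix(0L, cfg$n_genes, cfg$n_tumor,
                   dimnames = list(genes, tumor_ids))
  lib_size <- stats::rlnorm(cfg$n_tumor, log(1.5e6), 0.2)
  for (s in seq_len(cfg$n_tumor)) {
    mu_s <- mu
    if (hed_high[s] == (cfg$de_seeded_in == "high")) {
      mu_s[match(de_genes, genes)] <- mu[match(de_genes, genes)] * 2^lfc
    }
    mu_s <- mu_s / sum(mu_s) * lib_size[s]
    counts[, s] <- stats::rnbinom(cfg$n_genes, mu = mu_s, size = cfg$nb_size)
  }
  control_profile <- stats::setNames(mu / sum(mu) * 1e6, genes)

  ## simple gene sets over the panel for enrichment tests: one enriched in
  ## the seeded DE genes, the rest random
  gene_sets <- list(
    seeded_de_set = c(de_genes[seq_len(min(15, n_de))],
                      sample(setdiff(genes, de_genes), 5)),
    random_set_1 = sample(genes, 25),
    random_set_2 = sample(genes, 40))

  structure(list(library = lib,
                 exons = data.frame(locus = rep(c("A", "B", "C"), each = 2),
                                    exon = rep(c(2L, 3L), 3),
                                    start = rep(c(1L, 91L), 3),
                                    end = rep(c(90L, 182L), 3)),
                 genotypes = genotypes, hed = hed, clinical = clinical,
                 variants = variants, callable = callable, cna = cna,
                 msi = msi, counts = counts,
                 control_profile = control_profile, hk_genes = hk_genes,
                 gene_sets = gene_sets, driver_flags = driver_flags,
                 achieved_divergence = library$achieved_divergence,
                 config = cfg),
            class = "hed_cohort")
}
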