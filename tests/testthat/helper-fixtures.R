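# Shared fixtures, built in code at test time.

GM <- build_grantham_matrix()
GM_CONT <- build_grantham_matrix(mode = "continuous")

# A 182-residue sequence and single/double-substitution variants whose
# divergences are known in closed form (L<->I is 5, W<->C is 215).
make_pbr_pair <- function(n_diff = 1, len = 182) {
  base <- strsplit(paste(rep("A", len), collapse = ""), "")[[1]]
  base[1] <- "L"; base[2] <- "W"
  v <- base
  if (n_diff >= 1) v[1] <- "I"
  if (n_diff >= 2) v[2] <- "C"
  list(a = paste(base, collapse = ""), b = paste(v, collapse = ""))
}

# Write a tiny allele FASTA + exon sidecar; returns the two paths.
write_tiny_library <- function(headers, proteins,
                               exon2 = c(2, 4), exon3 = c(5, 7),
                               dir = tempfile("lib")) {
  dir.create(dir, showWarnings = FALSE)
  fa <- file.path(dir, "alleles.fasta")
  writeLines(paste0(">", headers, "\n", proteins), fa)
  ann <- file.path(dir, "exons.tsv")
  loci <- unique(substr(sub("^HLA-", "", headers), 1, 1))
  writeLines(c("# 1-based inclusive protein coordinates",
               "locus\texon\tstart\tend",
               unlist(lapply(loci, function(l) {
                 c(paste(l, 2, exon2[1], exon2[2], sep = "\t"),
                   paste(l, 3, exon3[1], exon3[2], sep = "\t"))
               }))), ann)
  list(fasta = fa, exons = ann)
}

# Random survival cohort for cutpoint oracle checks.
rand_survival_cohort <- function(n) {
  list(values = round(stats::rlnorm(n, 1, 0.8), 2),
       time = round(stats::rexp(n, 0.08), 2) + 0.01,
       event = stats::rbinom(n, 1, 0.7))
}

# Independent maxstat oracle: exhaustive scan using survival::survdiff.
brute_maxstat <- function(values, time, event, minprop = 0.1) {
  n <- length(values)
  minsize <- ceiling(minprop * n)
  cand <- sort(unique(values))
  cand <- cand[vapply(cand, function(c) {
    h <- sum(values > c); h >= minsize && (n - h) >= minsize
  }, logical(1))]
  z <- vapply(cand, function(c) {
    g <- factor(values > c)
    sd <- survival::survdiff(survival::Surv(time, event) ~ g)
    sqrt(sd$chisq) * sign(sd$obs[2] - sd$exp[2])
  }, numeric(1))
  best <- which.max(abs(z))
  list(cutpoint = cand[best], statistic = abs(z[best]))
}

# Independent Youden oracle: exhaustive threshold scan, direct counting.
brute_youden <- function(scores, outcome) {
  outcome <- as.logical(outcome)
  cand <- sort(unique(scores))
  j <- vapply(cand, function(t) {
    sum(scores > t & outcome) / sum(outcome) +
      sum(scores <= t & !outcome) / sum(!outcome) - 1
  }, numeric(1))
  best <- which.max(j)
  list(threshold = cand[best], j = j[best])
}
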