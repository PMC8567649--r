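# HLA-I evolutionary divergence (HED): mean per-site Grantham distance
# between the peptide-binding-region (exon 2 + exon 3) protein sequences of
# a patient's two alleles at one locus.

#' Normalize an HLA allele name to two-field resolution
#'
#' Accepts names like `"B*15:01"`, `"B*15:01:01:02N"` or `"HLA-B*15:01"`
#' and truncates higher-resolution fields and expression suffixes, so all
#' lookups happen at the two-field (protein-group) level.
#'
#' @param x Character vector of allele names.
#' @return Character vector of names of the form `"B*15:01"`.
#' @export
normalize_allele_name <- function(x) {
  x <- sub("^HLA-", "", trimws(x))
  m <- regmatches(x, regexec("^([ABC])\\*([0-9]+):([0-9]+)", x))
  bad <- vapply(m, length, integer(1)) == 0
  if (any(bad)) {
    stop("unparseable HLA allele name(s): ",
         paste(unique(x[bad]), collapse = ", "))
  }
  vapply(m, function(g) paste0(g[2], "*", g[3], ":", g[4]), character(1))
}

#' Locus letter of an allele name
#' @param x Character vector of allele names.
#' @return Character vector with values in `A`, `B`, `C`.
#' @export
allele_locus <- function(x) {
  substr(normalize_allele_name(x), 1, 1)
}

#' Load an HLA allele protein library and extract the peptide-binding region
#'
#' Reads full-protein allele sequences from FASTA (header = allele name) and
#' an exon-annotation sidecar giving, per locus, 1-based inclusive protein
#' coordinates of exons 2 and 3. The peptide-binding-region sequence of each
#' allele is the concatenation of the two exon intervals; all alleles at one
#' locus must yield the same length (an aligned library).
#'
#' @param fasta_path FASTA of allele proteins.
#' @param exon_annotation_path TSV with columns `locus`, `exon` (2 or 3),
#'   `start`, `end` (1-based inclusive protein coordinates).
#' @return A data.frame with columns `allele` (two-field name), `locus`,
#'   `pbr_seq`, `source_len`.
#' @export
load_allele_library <- function(fasta_path, exon_annotation_path) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  ann <- utils::read.delim(exon_annotation_path, comment.char = "#",
                           stringsAsFactors = FALSE)
  req <- c("locus", "exon", "start", "end")
  if (!all(req %in% names(ann))) {
    stop("exon annotation must have columns: ", paste(req, collapse = ", "))
  }
  allele <- normalize_allele_name(sub("\\s.*$", "", names(seqs)))
  locus <- substr(allele, 1, 1)
  full <- as.character(seqs)
  pbr <- character(length(full))
  for (i in seq_along(full)) {
    rows <- ann[ann$locus == locus[i] & ann$exon %in% c(2, 3), , drop = FALSE]
    if (nrow(rows) != 2) {
      stop("annotation must give exactly exons 2 and 3 for locus ", locus[i])
    }
    rows <- rows[order(rows$exon), , drop = FALSE]
    if (any(rows$end > nchar(full[i])) || any(rows$start < 1) ||
        any(rows$start > rows$end)) {
      stop("exon interval outside sequence for allele ", allele[i])
    }
    pbr[i] <- paste0(substr(full[i], rows$start[1], rows$end[1]),
                     substr(full[i], rows$start[2], rows$end[2]))
  }
  lib <- data.frame(allele = allele, locus = locus, pbr_seq = pbr,
                    source_len = nchar(full), stringsAsFactors = FALSE)
  for (lc in unique(lib$locus)) {
    len <- nchar(lib$pbr_seq[lib$locus == lc])
    if (length(unique(len)) > 1) {
      off <- lib$allele[lib$locus == lc][len != max(len)]
      stop("unequal peptide-binding-region lengths at locus ", lc, ": ",
           paste(off, collapse = ", "))
    }
  }
  bad <- grepl(paste0("[^", paste(aa_alphabet(), collapse = ""), "-]"),
               lib$pbr_seq)
  if (any(bad)) {
    stop("non-canonical residues in: ", paste(lib$allele[bad], collapse = ", "))
  }
  lib
}

#' Pairwise HED between two aligned peptide-binding-region sequences
#'
#' Sum of per-site Grantham distances divided by the number of compared
#' sites. Sites where either sequence carries the gap character `-` are
#' excluded from both numerator and denominator; if more than 5% of sites
#' are excluded a warning is emitted.
#'
#' @param seq1,seq2 Aligned protein sequences of equal length (characters).
#' @param m Grantham matrix from [build_grantham_matrix()].
#' @return Mean per-site divergence (non-negative number).
#' @export
pairwise_hed <- function(seq1, seq2, m = build_grantham_matrix()) {
  if (nchar(seq1) != nchar(seq2)) {
    stop("sequences differ in length (", nchar(seq1), " vs ", nchar(seq2), ")")
  }
  a <- strsplit(seq1, "")[[1]]
  b <- strsplit(seq2, "")[[1]]
  keep <- a != "-" & b != "-"
  if (!any(keep)) stop("no comparable sites (all gapped)")
  if (mean(!keep) > 0.05) {
    warning(sprintf("%.1f%% of sites excluded as gaps", 100 * mean(!keep)))
  }
  a <- a[keep]; b <- b[keep]
  bad <- setdiff(c(a, b), aa_alphabet())
  if (length(bad) > 0) {
    stop("non-canonical residue(s): ", paste(bad, collapse = ", "))
  }
  sum(m[cbind(a, b)]) / length(a)
}

#' Per-locus zygosity from a genotype table
#'
#' A locus is homozygous iff its two two-field allele names are identical.
#'
#' @param genotypes Data.frame with columns `patient_id`, `A1`, `A2`, `B1`,
#'   `B2`, `C1`, `C2`.
#' @return Data.frame with `patient_id` and logical `het_a`, `het_b`, `het_c`.
#' @export
classify_zygosity <- function(genotypes) {
  req <- c("patient_id", "A1", "A2", "B1", "B2", "C1", "C2")
  if (!all(req %in% names(genotypes))) {
    stop("genotype table must have columns: ", paste(req, collapse = ", "))
  }
  data.frame(
    patient_id = genotypes$patient_id,
    het_a = normalize_allele_name(genotypes$A1) !=
            normalize_allele_name(genotypes$A2),
    het_b = normalize_allele_name(genotypes$B1) !=
            normalize_allele_name(genotypes$B2),
    het_c = normalize_allele_name(genotypes$C1) !=
            normalize_allele_name(genotypes$C2),
    stringsAsFactors = FALSE
  )
}

.lookup_pbr <- function(allele, lib) {
  i <- match(allele, lib$allele)
  if (is.na(i)) stop("allele not found in library: ", allele)
  lib$pbr_seq[i]
}

#' HED profile of one patient
#'
#' Per-locus HED is the pairwise divergence of the patient's two alleles;
#' a homozygous locus (identical two-field names) has HED 0 by definition
#' and needs no sequence lookup. `mean_hed` is the arithmetic mean over the
#' three loci, homozygous zeros included.
#'
#' @param genotype One-row data.frame (or list) with `patient_id`, `A1`,
#'   `A2`, `B1`, `B2`, `C1`, `C2`.
#' @param lib Allele library from [load_allele_library()].
#' @param m Grantham matrix.
#' @return One-row data.frame: `patient_id`, `hed_a`, `hed_b`, `hed_c`,
#'   `mean_hed`, `het_a`, `het_b`, `het_c`.
#' @export
profile_patient <- function(genotype, lib, m = build_grantham_matrix()) {
  loci <- list(a = c("A1", "A2"), b = c("B1", "B2"), c = c("C1", "C2"))
  hed <- vapply(loci, function(cols) {
    a1 <- normalize_allele_name(genotype[[cols[1]]])
    a2 <- normalize_allele_name(genotype[[cols[2]]])
    if (a1 == a2) return(0)
    pairwise_hed(.lookup_pbr(a1, lib), .lookup_pbr(a2, lib), m)
  }, numeric(1))
  out <- data.frame(patient_id = genotype[["patient_id"]],
                    hed_a = hed[["a"]], hed_b = hed[["b"]], hed_c = hed[["c"]],
                    mean_hed = (hed[["a"]] + hed[["b"]] + hed[["c"]]) / 3,
                    stringsAsFactors = FALSE)
  zyg <- classify_zygosity(cbind(genotype, stringsAsFactors = FALSE))
  cbind(out, zyg[, c("het_a", "het_b", "het_c")])
}

#' HED profiles for a whole genotype table
#'
#' @param genotypes Data.frame as in [classify_zygosity()].
#' @inheritParams profile_patient
#' @return Data.frame with one row per patient, columns as in
#'   [profile_patient()].
#' @export
hed_profiles <- function(genotypes, lib, m = build_grantham_matrix()) {
  rows <- lapply(seq_len(nrow(genotypes)), function(i) {
    profile_patient(genotypes[i, , drop = FALSE], lib, m)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dichotomize a biomarker at a cutpoint
#'
#' Label is `"high"` iff the value is strictly greater than the cutpoint,
#' `"low"` otherwise (boundary values are low, matching the convention
#' "high > cut, low <= cut"). Missing values propagate as `NA` with a
#' warning rather than being silently dropped.
#'
#' @param values Numeric vector.
#' @param cutpoint Finite number.
#' @return Factor with levels `low`, `high`.
#' @export
dichotomize <- function(values, cutpoint) {
  stopifnot(is.finite(cutpoint))
  if (anyNA(values)) {
    warning(sum(is.na(values)), " missing value(s) left NA in dichotomization")
  }
  factor(ifelse(values > cutpoint, "high", "low"), levels = c("low", "high"))
}
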