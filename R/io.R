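# Plain-text bundle I/O. All tables are TSV with documented headers; the
# allele library travels as FASTA plus an exon-annotation sidecar.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "#")
}

# Required columns per input table, used for schema validation messages.
.bundle_schema <- list(
  genotypes = c("patient_id", "A1", "A2", "B1", "B2", "C1", "C2"),
  clinical = c("patient_id", "os_months", "os_event", "pfs_months",
               "pfs_event", "response", "sd_duration_weeks", "msi_status",
               "tnb"),
  variants = c("sample_id", "gene", "region_class", "effect", "depth",
               "vaf"),
  callable = c("sample_id", "callable_bases"),
  cna = c("sample_id", "gene", "state"),
  msi = c("sample_id", "BAT-25", "BAT-26", "D2S123", "D5S346", "D17S250")
)

#' Write a cohort bundle to a directory
#'
#' Emits the complete plain-text input bundle for [run_hed_pipeline()]:
#' `alleles.fasta`, `exons.tsv`, `genotypes.tsv`, `clinical.tsv`,
#' `variants.tsv`, `callable.tsv`, `cna.tsv`, `msi.tsv`, `counts.tsv`,
#' `control_profile.tsv`, `hk_genes.txt`, `gene_sets.gmt`.
#'
#' @param cohort A cohort list as produced by [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_bundle <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "alleles.fasta")
  writeLines(paste0(">", cohort$library$allele, "\n", cohort$library$pbr_seq),
             fa)
  con <- file.path(dir, "exons.tsv")
  writeLines("# 1-based inclusive protein coordinates of exons 2 and 3",
             con)
  suppressWarnings(utils::write.table(cohort$exons, con, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  .write_tsv(cohort$genotypes, file.path(dir, "genotypes.tsv"))
  .write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"))
  .write_tsv(cohort$variants, file.path(dir, "variants.tsv"))
  .write_tsv(cohort$callable, file.path(dir, "callable.tsv"))
  .write_tsv(cohort$cna, file.path(dir, "cna.tsv"))
  .write_tsv(cohort$msi, file.path(dir, "msi.tsv"))
  counts <- data.frame(gene = rownames(cohort$counts), cohort$counts,
                       check.names = FALSE)
  .write_tsv(counts, file.path(dir, "counts.tsv"))
  .write_tsv(data.frame(gene = names(cohort$control_profile),
                        rpm = unname(cohort$control_profile)),
             file.path(dir, "control_profile.tsv"))
  writeLines(cohort$hk_genes, file.path(dir, "hk_genes.txt"))
  writeLines(vapply(names(cohort$gene_sets), function(nm) {
    paste(c(nm, "na", cohort$gene_sets[[nm]]), collapse = "\t")
  }, character(1)), file.path(dir, "gene_sets.gmt"))
  invisible(dir)
}

#' Read a cohort bundle from a directory
#'
#' Inverse of [write_cohort_bundle()]. Each table is schema-checked; a
#' missing or malformed file raises an error naming the table and its
#' required columns. Note the allele FASTA in a bundle stores the
#' already-extracted peptide-binding-region sequences, so the exon sidecar
#' read back spans them fully.
#'
#' @param dir Bundle directory.
#' @return A cohort list with the same table elements as
#'   [simulate_cohort()] (the generative metadata — true HED profiles,
#'   driver flags, config — is not part of the on-disk exchange format).
#' @export
read_cohort_bundle <- function(dir) {
  need <- function(file, table) {
    path <- file.path(dir, file)
    if (!file.exists(path)) {
      cols <- .bundle_schema[[table]]
      stop("missing input '", table, "' (", file, ")",
           if (!is.null(cols)) paste0("; required columns: ",
                                      paste(cols, collapse = ", ")))
    }
    path
  }
  check <- function(df, table) {
    cols <- .bundle_schema[[table]]
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      stop("input '", table, "' lacks column(s): ",
           paste(miss, collapse = ", "),
           "; required columns: ", paste(cols, collapse = ", "))
    }
    df
  }
  lib <- load_allele_library(need("alleles.fasta", "alleles"),
                             need("exons.tsv", "exons"))
  counts_df <- .read_tsv(need("counts.tsv", "counts"))
  counts <- as.matrix(counts_df[, -1, drop = FALSE])
  rownames(counts) <- counts_df$gene
  ctrl <- .read_tsv(need("control_profile.tsv", "control_profile"))
  list(library = lib,
       exons = .read_tsv(need("exons.tsv", "exons")),
       genotypes = check(.read_tsv(need("genotypes.tsv", "genotypes")),
                         "genotypes"),
       clinical = check(.read_tsv(need("clinical.tsv", "clinical")),
                        "clinical"),
       variants = check(.read_tsv(need("variants.tsv", "variants")),
                        "variants"),
       callable = check(.read_tsv(need("callable.tsv", "callable")),
                        "callable"),
       cna = check(.read_tsv(need("cna.tsv", "cna")), "cna"),
       msi = check(.read_tsv(need("msi.tsv", "msi")), "msi"),
       counts = counts,
       control_profile = stats::setNames(ctrl$rpm, ctrl$gene),
       hk_genes = readLines(need("hk_genes.txt", "hk_genes")),
       gene_sets = read_gmt(need("gene_sets.gmt", "gene_sets")))
}
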