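make_counts <- function(n_genes = 50, n_samples = 8, seed = 1) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * n_samples, mu = 300, size = 5) + 1L,
              n_genes, n_samples,
              dimnames = list(paste0("G", seq_len(n_genes)),
                              paste0("S", seq_len(n_samples))))
  m
}

test_that("RPM columns sum to one million over the panel", {
  counts <- make_counts()
  counts["G1", "S1"] <- 200
  counts2 <- counts
  counts2[, "S1"] <- 0
  counts2["G1", "S1"] <- 2e6 - 200
  counts2["G2", "S1"] <- 200
  rpm <- rpm_normalize(counts2)
  expect_equal(rpm["G2", "S1"], 100)  # 200 reads of a 2M-read sample
  expect_equal(unname(colSums(rpm)), rep(1e6, ncol(rpm)))
  counts3 <- counts
  counts3["G5", ] <- 0
  expect_equal(unname(rpm_normalize(counts3)["G5", ]),
               rep(0, ncol(counts3)))
  counts4 <- counts
  counts4[, 2] <- 0
  expect_error(rpm_normalize(counts4), "zero-total")
})

test_that("housekeeping normalization equalizes the HK geometric mean with the control", {
  counts <- make_counts()
  rpm <- rpm_normalize(counts)
  hk <- paste0("G", 1:10)
  gm <- function(x) exp(mean(log(x)))
  # control with HK geometric mean exactly twice the sample's
  ctrl <- stats::setNames(rep(100, nrow(rpm)), rownames(rpm))
  rpm_fixed <- rpm
  rpm_fixed[hk, ] <- 50
  nrpm <- hk_normalize(rpm_fixed, hk, ctrl)
  expect_equal(unname(attr(nrpm, "ratio")), rep(2, ncol(rpm)))
  expect_equal(nrpm, 2 * rpm_fixed, ignore_attr = TRUE)

  # identity when the sample equals the control profile
  nrpm2 <- hk_normalize(rpm, hk, apply(rpm, 1, mean)[rownames(rpm)])
  for (s in colnames(rpm)) {
    expect_equal(gm(nrpm2[hk, s]), gm(rowMeans(rpm)[hk]), tolerance = 1e-9)
  }

  expect_error(hk_normalize(rpm, c(hk, "NOPE"), ctrl), "NOPE")
  rpm_zero <- rpm
  rpm_zero[hk, 1] <- 0
  expect_error(hk_normalize(rpm_zero, hk, ctrl), "all housekeeping")
  rpm_one <- rpm
  rpm_one[hk[1], 1] <- 0
  expect_warning(hk_normalize(rpm_one, hk, ctrl), "zero housekeeping")
})

test_that("the RPM -> HK chain is equivariant to sample-level count scaling", {
  counts <- make_counts()
  hk <- paste0("G", 1:10)
  ctrl <- stats::setNames(rep(120, nrow(counts)), rownames(counts))
  n1 <- hk_normalize(rpm_normalize(counts), hk, ctrl)
  counts_scaled <- counts
  counts_scaled[, 3] <- counts[, 3] * 7L
  n2 <- hk_normalize(rpm_normalize(counts_scaled), hk, ctrl)
  expect_equal(n1[, 3], n2[, 3], tolerance = 1e-12)
})

test_that("DEG thresholds are strict on fold change and raw p", {
  # group means engineered to differ by exactly log2(1.5): must NOT pass
  lo <- c(5 - 0.01, 5 + 0.01, 5 - 0.01, 5 + 0.01)
  hi <- lo + deg_lfc_threshold()
  hi2 <- lo + deg_lfc_threshold() + 0.01
  mat <- rbind(at_threshold = c(lo, hi), above_threshold = c(lo, hi2))
  colnames(mat) <- paste0("S", 1:8)
  grp <- rep(c("low", "high"), each = 4)
  deg <- differential_expression(mat, grp, method = "welch")
  expect_equal(deg$log2fc[1], deg_lfc_threshold(), tolerance = 1e-12)
  expect_false(deg$pass[deg$gene == "at_threshold"])
  expect_true(deg$pass[deg$gene == "above_threshold"])
  # pass flag is exactly the conjunction of the two thresholds
  expect_identical(deg$pass,
                   abs(deg$log2fc) > deg_lfc_threshold() & deg$p < 0.05)
})

test_that("swapping group labels flips the fold-change sign and keeps p", {
  set.seed(8)
  mat <- matrix(rnorm(30 * 12, 6), 30, 12,
                dimnames = list(paste0("G", 1:30), paste0("S", 1:12)))
  grp <- rep(c("low", "high"), each = 6)
  d1 <- differential_expression(mat, grp)
  d2 <- differential_expression(mat, rev(grp))
  expect_equal(d1$log2fc, -d2$log2fc, tolerance = 1e-12)
  expect_equal(d1$p, d2$p, tolerance = 1e-12)
  # and invariance to gene order
  ord <- sample(30)
  d3 <- differential_expression(mat[ord, ], grp)
  expect_equal(d3$p[match(d1$gene, d3$gene)], d1$p, tolerance = 1e-12)
})

test_that("moderated and Welch tests agree on strongly separated genes", {
  set.seed(19)
  mat <- matrix(rnorm(20 * 20, 5, 0.3), 20, 20,
                dimnames = list(paste0("G", 1:20), paste0("S", 1:20)))
  mat[1:3, 11:20] <- mat[1:3, 11:20] + 2
  grp <- rep(c("low", "high"), each = 10)
  dm <- differential_expression(mat, grp, method = "moderated")
  dw <- differential_expression(mat, grp, method = "welch")
  expect_identical(dm$pass[1:3], rep(TRUE, 3))
  expect_identical(dw$pass[1:3], rep(TRUE, 3))
  expect_equal(dm$log2fc, dw$log2fc, tolerance = 1e-12)
})

test_that("over-representation p-values match the hypergeometric tail sum", {
  universe <- paste0("G", 1:395)
  deg <- paste0("G", 1:40)
  sets <- list(hit = c(paste0("G", 31:40), paste0("G", 200:209)),
               miss = paste0("G", 300:320),
               outside = paste0("X", 1:5))
  res <- ora_test(deg, universe, sets)
  expect_identical(attr(res, "skipped"), "outside")
  # overlap 10 of a 20-gene set: independent dhyper tail sum
  p_direct <- sum(stats::dhyper(10:20, 20, 375, 40))
  expect_equal(res$p[res$set == "hit"], p_direct, tolerance = 1e-12)
  expect_equal(res$overlap[res$set == "hit"], 10L)
  expect_gt(res$p[res$set == "miss"], 0.5)
  # saturation: DEG = universe makes every overlap deterministic, p = 1
  res2 <- ora_test(universe, universe, sets[1:2])
  expect_equal(res2$p, c(1, 1))
  # BH adjustment is monotone in raw p
  expect_true(all(diff(res$p_adj[order(res$p)]) >= -1e-15))
  expect_true(all(res$p_adj >= res$p))
  expect_error(ora_test(deg, character(0), sets), "empty universe")
})

test_that("GMT files round-trip", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tG1\tG2\tG3", "setB\tdesc\tG9"), path)
  sets <- read_gmt(path)
  expect_identical(sets, list(setA = c("G1", "G2", "G3"), setB = "G9"))
})
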