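make_variant <- function(region_class = "exonic",
                         effect = "nonsynonymous SNV",
                         depth = 100, vaf = 0.25,
                         pop_af_exac = 0, pop_af_gnomad = 0,
                         pop_af_1kg = 0) {
  data.frame(region_class = region_class, effect = effect, depth = depth,
             vaf = vaf, pop_af_exac = pop_af_exac,
             pop_af_gnomad = pop_af_gnomad, pop_af_1kg = pop_af_1kg,
             stringsAsFactors = FALSE)
}

test_that("all filter boundaries are inclusive", {
  boundary <- make_variant(depth = 40, vaf = 0.03, pop_af_exac = 0.002,
                           pop_af_gnomad = 0.002, pop_af_1kg = 0.002)
  expect_equal(nrow(filter_somatic_snvs(boundary)$passed), 1L)
  expect_equal(nrow(filter_somatic_snvs(make_variant(depth = 39))$passed), 0L)
  expect_equal(nrow(filter_somatic_snvs(make_variant(vaf = 0.029))$passed), 0L)
  expect_equal(nrow(filter_somatic_snvs(
    make_variant(pop_af_gnomad = 0.0021))$passed), 0L)
  expect_equal(nrow(filter_somatic_snvs(
    make_variant(effect = "synonymous SNV", depth = 100,
                 vaf = 0.5))$passed), 0L)
  expect_equal(nrow(filter_somatic_snvs(
    make_variant(region_class = "intronic"))$passed), 0L)
  expect_equal(nrow(filter_somatic_snvs(make_variant(effect = "stopgain"))
                    $passed), 1L)
})

test_that("missing population frequencies pass that sub-filter", {
  v <- make_variant(pop_af_exac = NA, pop_af_gnomad = NA, pop_af_1kg = NA)
  fs <- filter_somatic_snvs(v)
  expect_equal(nrow(fs$passed), 1L)
  expect_equal(fs$n_missing_pop_af, 1L)
  # one high value among the three rejects conjunctively
  v2 <- make_variant(pop_af_exac = NA, pop_af_gnomad = 0.01)
  expect_equal(nrow(filter_somatic_snvs(v2)$passed), 0L)
})

test_that("rejection tally attributes the first failing filter and sums to the rejected count", {
  vs <- rbind(make_variant(),
              make_variant(region_class = "intronic", depth = 10),
              make_variant(effect = "synonymous SNV"),
              make_variant(depth = 5),
              make_variant(vaf = 0.01),
              make_variant(pop_af_1kg = 0.5))
  fs <- filter_somatic_snvs(vs)
  expect_equal(nrow(fs$passed), 1L)
  expect_equal(sum(fs$tally), nrow(vs) - nrow(fs$passed))
  expect_equal(unname(fs$tally[c("region", "effect", "depth", "vaf",
                                 "pop_af")]),
               c(1L, 1L, 1L, 1L, 1L))
})

test_that("the filter cascade is order-independent", {
  set.seed(5)
  vs <- do.call(rbind, replicate(200, make_variant(
    region_class = sample(c("exonic", "intronic"), 1),
    effect = sample(c("nonsynonymous SNV", "stopgain",
                      "synonymous SNV"), 1),
    depth = sample(10:200, 1), vaf = round(runif(1, 0, 0.5), 3),
    pop_af_exac = sample(c(0, 0.001, 0.01), 1)), simplify = FALSE))
  pass_joint <- filter_somatic_snvs(vs)$passed
  # apply the five predicates one at a time, in a shuffled order
  preds <- list(
    function(d) d[d$region_class == "exonic", ],
    function(d) d[d$effect %in% c("nonsynonymous SNV", "stopgain"), ],
    function(d) d[d$depth >= 40, ],
    function(d) d[d$vaf >= 0.03, ],
    function(d) d[is.na(d$pop_af_exac) | d$pop_af_exac <= 0.002, ])
  for (perm in list(5:1, c(3, 1, 5, 2, 4), c(2, 4, 1, 5, 3))) {
    d <- vs
    for (k in perm) d <- preds[[k]](d)
    expect_equal(sort(rownames(d)), sort(rownames(pass_joint)))
  }
})

test_that("TMB is mutations per callable megabase", {
  expect_equal(compute_tmb(10, 2e6), 5.0)
  expect_equal(compute_tmb(0, 2e6), 0.0)
  expect_equal(compute_tmb(209, 4e7), 5.225)
  # linear in the mutation count at fixed callable bases
  expect_equal(compute_tmb(3 * 7, 1e7), 3 * compute_tmb(7, 1e7))
  expect_error(compute_tmb(10, 0), "positive")
})

test_that("CNA burden counts genes with non-neutral state", {
  cna <- data.frame(gene = paste0("G", 1:10),
                    state = c(rep("gain", 3), rep("loss", 2),
                              rep("neutral", 5)))
  expect_equal(compute_cna_burden(cna), 5L)
  expect_equal(compute_cna_burden(data.frame(gene = "G1",
                                             state = "neutral")), 0L)
  dup <- data.frame(gene = c("G1", "G1"), state = c("gain", "gain"))
  expect_error(compute_cna_burden(dup), "duplicate")
})

test_that("MSI-H requires instability at two or more panel loci", {
  loci <- c("BAT-25", "BAT-26", "D2S123", "D5S346", "D17S250")
  flags <- stats::setNames(c(TRUE, TRUE, FALSE, FALSE, FALSE), loci)
  expect_equal(call_msi(flags)$call, "MSI-H")
  flags[2] <- FALSE
  expect_equal(call_msi(flags)$call, "MSS")
  expect_equal(call_msi(stats::setNames(rep(FALSE, 5), loci))$call, "MSS")
  expect_error(call_msi(flags[-1]), "BAT-25")
})

test_that("durable clinical benefit follows the response rule with a 24-week SD boundary", {
  expect_equal(derive_dcb("CR"), "DCB")
  expect_equal(derive_dcb("PR"), "DCB")
  expect_equal(derive_dcb("SD", 24), "DCB")
  expect_equal(derive_dcb("SD", 23), "NDB")
  expect_equal(derive_dcb("PD"), "NDB")
  expect_error(derive_dcb("SD", NA), "duration")
  expect_error(derive_dcb("XX"), "response")
})
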