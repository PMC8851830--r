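small_cfg <- function(...) {
  defaults <- list(chrom_bins = c(chr1 = 120L), n_tads = 4, n_loops = 5,
                   n_high_risk = 8, n_snps = 40, n_enhancers = 50,
                   n_tfbs = 30, loop_dist_bins = c(8L, 25L))
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("simulation is fully deterministic under (config, seed)", {
  cfg <- small_cfg()
  a <- simulate_matrix(cfg, 5)
  b <- simulate_matrix(cfg, 5)
  expect_identical(a$contacts, b$contacts)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_matrix(cfg, 6)
  expect_false(identical(a$contacts$count, c2$contacts$count))
  expect_identical(names(a$truth), names(c2$truth))
  ann_a <- simulate_annotations(cfg, a$truth, 9)
  ann_b <- simulate_annotations(cfg, a$truth, 9)
  expect_identical(ann_a, ann_b)
})

test_that("loop-free configurations record no loops", {
  cfg <- small_cfg(n_loops = 0, n_high_risk = 0)
  sim <- simulate_matrix(cfg, 1)
  expect_equal(nrow(sim$truth$loops), 0)
  ann <- simulate_annotations(cfg, sim$truth, 2)
  expect_equal(nrow(select_high_risk(ann$snps)), 0)
})

test_that("distance decay follows the configured exponent", {
  # at |i - j| = 10 the expected count under alpha = 2 is 10x smaller
  # than under alpha = 1
  mean_at_d10 <- function(alpha, seed) {
    cfg <- sim_config(chrom_bins = c(chr1 = 1200L), A = 1000, alpha = alpha,
                      tau = 0, n_loops = 0, n_high_risk = 0, n_snps = 0,
                      n_enhancers = 1, n_tfbs = 1)
    sim <- simulate_matrix(cfg, seed)
    ct <- prepare_contacts(sim$contacts, cfg$resolution)
    mean(ct[abs(bin2 - bin1) == 10, count])
  }
  r <- mean_at_d10(1, 3) / mean_at_d10(2, 4)
  expect_gt(r, 8.5)
  expect_lt(r, 11.5)
})

test_that("planted DA effects match the configured means", {
  cfg <- small_cfg(n_enhancers = 200)
  sim <- simulate_matrix(cfg, 11)
  ann <- simulate_annotations(cfg, sim$truth, 12)
  cls <- ann$truth$element_class
  enh <- ann$elements[ann$elements$kind == "enhancer"]
  assoc <- enh$da_score[enh$id %in% cls$id[cls$class == "associated"]]
  bg <- enh$da_score[enh$id %in% cls$id[cls$class == "background"]]
  expect_lt(abs(mean(assoc) - cfg$mu_assoc), 3 * cfg$sigma / sqrt(length(assoc)))
  expect_lt(abs(mean(bg) - cfg$mu_bg), 3 * cfg$sigma / sqrt(length(bg)))
  expect_true(all(ann$elements$da_score >= 0, na.rm = TRUE))
})

test_that("high-risk SNPs cannot outnumber loop-anchor bins", {
  cfg <- small_cfg(n_loops = 3, n_high_risk = 7, n_snps = 10)
  sim <- simulate_matrix(cfg, 1)
  expect_error(simulate_annotations(cfg, sim$truth, 2), "anchor bins")
  # at capacity (2 per loop end) placement succeeds
  cfg2 <- small_cfg(n_loops = 3, n_high_risk = 6, n_snps = 10)
  sim2 <- simulate_matrix(cfg2, 1)
  ann2 <- simulate_annotations(cfg2, sim2$truth, 2)
  expect_equal(nrow(select_high_risk(ann2$snps)), 6)
})

test_that("high-risk SNPs sit in anchor bins and are genome-wide significant", {
  cfg <- small_cfg()
  sim <- simulate_matrix(cfg, 21)
  ann <- simulate_annotations(cfg, sim$truth, 22)
  tr <- ann$truth$snp_assignments
  hr <- ann$snps[grepl("^rs_hr", ann$snps$snp_id)]
  expect_true(all(hr$pvalue <= 5e-8))
  expect_true(all(ann$snps[grepl("^rs_bg", snp_id), pvalue] > 5e-8))
  bins <- bin_index(hr$pos, cfg$resolution)
  expect_equal(bins, tr$snp_bin[match(hr$snp_id, tr$snp_id)])
  loop_ends <- c(sim$truth$loops$bin_a, sim$truth$loops$bin_b)
  expect_true(all(tr$snp_bin %in% loop_ends))
  expect_true(all(tr$partner_bin %in% loop_ends))
})

test_that("study bundles round-trip through the file formats", {
  cfg <- small_cfg()
  dir <- withr::local_tempdir()
  b <- simulate_study(cfg, 31, dir)
  ct <- read_contacts(file.path(dir, "contacts.tsv"))
  expect_equal(as.data.frame(ct), as.data.frame(b$contacts[count > 0]),
               tolerance = 1e-12)
  snps <- read_gwas(file.path(dir, "gwas.tsv"))
  expect_equal(snps$snp_id, b$snps$snp_id)
  expect_equal(snps$pvalue, b$snps$pvalue, tolerance = 1e-12)
  el <- read_elements(file.path(dir, "elements.bed"))
  expect_equal(el$id, b$elements$id)
  expect_equal(el$da_score, b$elements$da_score, tolerance = 1e-9)
  expect_equal(el$disease_associated, b$elements$disease_associated)
  expect_equal(el$target_genes, b$elements$target_genes)
  g <- read_genes(file.path(dir, "genes.tsv"))
  expect_equal(g$symbol, b$genes$symbol)
  # two seeds differ in values but share the schema
  dir2 <- withr::local_tempdir()
  b2 <- simulate_study(cfg, 32, dir2)
  expect_false(identical(b2$snps$pos, b$snps$pos))
  expect_identical(names(b2$snps), names(b$snps))
  expect_identical(names(b2$elements), names(b$elements))
})
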