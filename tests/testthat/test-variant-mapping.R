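snp_row <- function(id, chrom, pos, p) {
  data.table::data.table(snp_id = id, chrom = chrom, pos = pos, pvalue = p)
}

test_that("high-risk selection keeps the genome-wide bound inclusive", {
  snps <- rbind(snp_row("a", "chr1", 100, 5e-8),
                snp_row("b", "chr1", 200, 5.5e-9),
                snp_row("c", "chr1", 300, 1e-7))
  hr <- select_high_risk(snps)
  expect_equal(hr$snp_id, c("a", "b"))
  expect_error(select_high_risk(snp_row("z", "chr1", 1, 0)), "\\(0, 1\\]")
})

test_that("1D mapping respects half-open windows and tolerates emptiness", {
  res <- 10000
  genes <- make_genes(c("GA", "GB"), c(2, 4))
  el <- data.table::data.table(
    chrom = c("chr1", "chr1", "chr1"),
    start = c(100000, 104999, 90000),
    end = c(100500, 105100, 94999),
    id = c("in_window", "abuts_end", "abuts_start"),
    kind = "enhancer", da_score = c(5, 6, 7),
    disease_associated = NA, tf_name = NA_character_,
    target_genes = c("GA", "GB", "GB"))
  # window for pos 100000 is [94999, 104999)
  m <- map_1d(snp_row("s1", "chr1", 100000, 1e-9), el, genes, res)
  expect_equal(m$n_enhancers, 1L)
  expect_equal(m$enhancer_ids, "in_window")
  expect_equal(m$median_da_enh, 5)
  expect_equal(m$median_da_enh_targets, 2)
  # no elements at all: empty mapping, not an error
  m0 <- map_1d(snp_row("s2", "chr2", 5000, 1e-9), el, genes, res)
  expect_equal(m0$n_enhancers, 0L)
  expect_true(is.na(m0$median_da_enh))
})

test_that("1D mapping equals the brute-force all-element scan", {
  set.seed(101)
  res <- 10000
  for (rep in 1:5) {
    el <- make_random_elements(1000)
    genes <- make_genes()
    snps <- data.table::data.table(
      snp_id = sprintf("s%02d", 1:20),
      chrom = sample(c("chr1", "chr2"), 20, replace = TRUE),
      pos = sample.int(9e5, 20), pvalue = 1e-9)
    m <- map_1d(snps, el, genes, res)
    for (i in seq_len(nrow(snps))) {
      got <- sort(c(split_ids(m$enhancer_ids[i]), split_ids(m$tf_ids[i])))
      want <- oracle_map1d_ids(snps$chrom[i], snps$pos[i], el, res)
      expect_identical(got, want)
    }
  }
})

test_that("candidate fragments keep only element-bearing partners", {
  res <- 10000
  genes <- make_genes(c("GA"), 3)
  el <- data.table::data.table(
    chrom = "chr1", start = c(100 * res + 10, 300 * res + 10),
    end = c(100 * res + 500, 300 * res + 40),
    id = c("enhA", "tfA"), kind = c("enhancer", "tfbs"),
    da_score = c(5, NA), disease_associated = c(NA, TRUE),
    tf_name = c(NA, "TFX"), target_genes = "GA")
  sig <- make_sig_contacts("chr1", c(10, 10, 10), "chr1", c(100, 200, 300),
                           c(0.01, 0.001, 0.04), res)
  snp_pos <- 10 * res + 5
  cand <- candidate_fragments("chr1", snp_pos, sig, el, res)
  expect_setequal(cand$bin, c(100L, 300L))     # empty partner 200 excluded
  cand_e <- candidate_fragments("chr1", snp_pos, sig, el, res, "enhancer")
  expect_equal(cand_e$bin, 100L)
  none <- candidate_fragments("chr2", snp_pos, sig, el, res)
  expect_equal(nrow(none), 0)
})

test_that("fragment selection is a total order: min q, then longest range", {
  cand <- data.table::data.table(
    chrom = "chr1", bin = c(20L, 80L),
    qvalue = c(0.01, 0.02), distance = c(2e5, 8e5))
  expect_equal(select_fragment(cand)$bin, 20L)        # q dominates distance
  cand$qvalue <- c(0.01, 0.01)
  expect_equal(select_fragment(cand)$bin, 80L)        # tie -> longest range
  inter <- rbind(cand,
                 data.table::data.table(chrom = "chr2", bin = 5L,
                                        qvalue = 0.01, distance = NA_real_))
  expect_equal(select_fragment(inter)$chrom, "chr2")  # inter beats any intra
  expect_null(select_fragment(cand[0]))
})

test_that("selected fragment is the argmin under exhaustive comparison", {
  set.seed(55)
  for (rep in 1:30) {
    k <- sample(2:12, 1)
    cand <- data.table::data.table(
      chrom = sample(c("chr1", "chr2"), k, replace = TRUE),
      bin = sample.int(500, k),
      qvalue = sample(c(0.01, 0.02, 0.03), k, replace = TRUE),
      distance = ifelse(runif(k) < 0.2, NA_real_,
                        sample.int(100, k) * 1e4))
    sel <- select_fragment(cand)
    for (i in seq_len(k)) {
      expect_false(oracle_better_fragment(as.list(cand[i]), as.list(sel)))
    }
    perm <- sample(k)
    expect_equal(select_fragment(cand[perm]), sel)
  }
})

test_that("3D mapping reports the selected fragment's elements and genes", {
  res <- 10000
  # worked-example-like fixture: the SNP's only significant partner holds
  # one enhancer targeting one gene with DA score 5.3
  genes <- make_genes(c("MAP3K1", "OTHER"), c(5.3, 1.0))
  el <- data.table::data.table(
    chrom = "chr1", start = 500 * res + 100, end = 500 * res + 900,
    id = "enh_119861", kind = "enhancer", da_score = 4.2,
    disease_associated = NA, tf_name = NA_character_,
    target_genes = "MAP3K1")
  sig <- make_sig_contacts("chr1", 480, "chr1", 500, 0.001, res)
  snp <- snp_row("rs_x", "chr1", 480 * res + 7, 1e-10)
  m <- map_3d(snp, sig, el, genes, res)
  expect_equal(m$n_enhancers, 1L)
  expect_equal(m$enhancer_ids, "enh_119861")
  expect_equal(m$enh_target_genes, "MAP3K1")
  expect_equal(m$median_da_enh_targets, 5.3)
  expect_equal(m$frag_start, 500 * res)
  # a SNP with no significant contacts yields an empty mapping, not an error
  m0 <- map_3d(snp_row("rs_y", "chr9", 100, 1e-10), sig, el, genes, res)
  expect_equal(m0$n_enhancers, 0L)
  expect_true(is.na(m0$frag_start))
  # every reported element overlaps the selected fragment
  expect_true(el$start < m$frag_end && el$end > m$frag_start)
})

test_that("per-class and joint selection scopes differ as designed", {
  res <- 10000
  genes <- make_genes(c("GA", "GB"), c(2, 6))
  # min-q fragment (bin 100) holds only a tfbs; an enhancer sits at bin 200
  el <- data.table::data.table(
    chrom = "chr1", start = c(100 * res + 10, 200 * res + 10),
    end = c(100 * res + 30, 200 * res + 800),
    id = c("tfA", "enhA"), kind = c("tfbs", "enhancer"),
    da_score = c(NA, 7), disease_associated = c(TRUE, NA),
    tf_name = c("TFX", NA), target_genes = c("GA", "GB"))
  sig <- make_sig_contacts("chr1", c(10, 10), "chr1", c(100, 200),
                           c(0.001, 0.01), res)
  snp <- snp_row("s", "chr1", 10 * res + 1, 1e-10)
  joint <- map_3d(snp, sig, el, genes, res, scope = "joint")
  expect_equal(joint$n_enhancers, 0L)
  expect_equal(joint$n_tfs, 1L)
  per <- map_3d(snp, sig, el, genes, res, scope = "per_class")
  expect_equal(per$n_enhancers, 1L)
  expect_equal(per$n_tfs, 1L)
  expect_equal(per$median_da_enh, 7)
  expect_equal(per$tf_fraction, 1)
})

test_that("3D mapping recovers planted partners when loops dominate", {
  # tau = 0: planted loops are the unique minimal-q contacts
  hits <- 0; tot <- 0
  for (s in 1:3) {
    cfg <- sim_config(chrom_bins = c(chr1 = 800L), tau = 0, n_loops = 20,
                      n_high_risk = 30, n_snps = 100, n_enhancers = 120,
                      n_tfbs = 80)
    sim <- simulate_matrix(cfg, s)
    sc <- score_contacts(sim$contacts, cfg$resolution, min_dist_bins = 5)
    sig <- significant_contacts(sc)
    ann <- simulate_annotations(cfg, sim$truth, s + 100)
    hr <- select_high_risk(ann$snps)
    m3 <- map_3d(hr, sig, ann$elements, ann$genes, cfg$resolution)
    tr <- ann$truth$snp_assignments
    sel_bin <- ifelse(is.na(m3$frag_start), -1L,
                      as.integer(m3$frag_start / cfg$resolution))
    hits <- hits + sum(sel_bin == tr$partner_bin[match(m3$snp_id, tr$snp_id)])
    tot <- tot + nrow(m3)
  }
  expect_gte(hits / tot, 0.95)
})
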