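sym_mat <- function(n, fill = 0) matrix(fill, n, n)

set_pair <- function(m, i, j, v) { m[i, j] <- v; m[j, i] <- v; m }

two_block <- function(n = 20, high = 10, low = 0) {
  m <- matrix(low, n, n)
  half <- n / 2
  m[1:half, 1:half] <- high
  m[(half + 1):n, (half + 1):n] <- high
  m
}

test_that("binSignal is the truncated cross-boundary submatrix mean", {
  m <- sym_mat(6, fill = 3)
  expect_equal(binsignal(m, 2), rep(3, 5))   # uniform matrix -> constant c
  m4 <- sym_mat(4)
  m4 <- set_pair(m4, 1, 3, 1)
  m4 <- set_pair(m4, 1, 4, 2)
  m4 <- set_pair(m4, 2, 3, 3)
  m4 <- set_pair(m4, 2, 4, 4)
  sig <- binsignal(m4, 2)
  expect_equal(sig[2], 2.5)                  # mean(1, 2, 3, 4)
  # edge truncation: boundary 1 with w = 2 uses the 1 x 2 available cells
  expect_equal(sig[1], mean(c(m4[1, 2], m4[1, 3])))
})

test_that("boundary candidates are leftmost window minima", {
  expect_equal(candidate_boundaries(1:10, 2), 1L)   # monotone: end minimum only
  v <- c(5, 4, 3, 2, 1, 2, 3, 4, 5)
  expect_equal(candidate_boundaries(v, 3), 5L)      # V shape
  plateau <- c(5, 4, 3, 1, 1, 3, 4, 5)
  expect_equal(candidate_boundaries(plateau, 2), 4L) # tie -> leftmost
})

test_that("boundary p-value matches the exact rank-sum tail", {
  # complete separation at w = 3: all cross-boundary counts zero
  n <- 8
  m <- matrix(0, n, n)
  for (side in list(1:4, 5:8))
    m[side, side] <- matrix(10 + seq_len(16), 4, 4)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  p <- boundary_pvalue(m, 4, 3)
  left <- 2:4; right <- 5:7
  cross <- as.vector(m[left, right])
  within <- c(m[left, left][upper.tri(m[left, left])],
              m[right, right][upper.tri(m[right, right])])
  expect_equal(p, oracle_ranksum_exact(cross, within), tolerance = 1e-12)
  expect_lt(p, 0.01)
  # identical distributions carry no depletion signal
  set.seed(2)
  u <- matrix(rpois(14 * 14, 20), 14, 14)
  u <- u + t(u)
  expect_gte(boundary_pvalue(u, 7, 3), 0.05)
  # degenerate cases return 1
  expect_equal(boundary_pvalue(sym_mat(6, fill = 2), 3, 2), 1)
  expect_equal(boundary_pvalue(sym_mat(4, fill = 1), 2, 1), 1)
})

test_that("hand-rolled rank-sum agrees with wilcox.test when ties are absent", {
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(7, 1)
    ours <- varcontact:::ranksum_less(x, y)
    ref <- stats::wilcox.test(x, y, alternative = "less", exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("TAD calling recovers block structure and degenerate inputs", {
  res <- 10000
  expect_equal(nrow(call_tads(sym_mat(30, fill = 4), "chr1", res)), 1)
  tads <- call_tads(two_block(20, high = 10), "chr1", res, w = 5)
  expect_equal(nrow(tads), 2)
  expect_equal(tads$end[1], 10 * res)        # boundary at the block junction
  expect_warning(t1 <- call_tads(sym_mat(6, fill = 2), "chr1", res, w = 5),
                 "single TAD")
  expect_equal(nrow(t1), 1)
  # determinism
  m <- two_block(24, high = 8)
  expect_identical(call_tads(m, "chr1", res), call_tads(m, "chr1", res))
  # boundary calls are invariant under global scaling; binSignal scales by c
  expect_identical(call_tads(m * 7, "chr1", res), call_tads(m, "chr1", res))
  expect_equal(binsignal(m * 7, 3), 7 * binsignal(m, 3))
})

test_that("called TADs partition the covered span", {
  for (s in 1:3) {
    cfg <- sim_config(chrom_bins = c(chr1 = 150L), n_tads = 6, n_loops = 4,
                      n_high_risk = 6, n_snps = 30, n_enhancers = 50,
                      n_tfbs = 25, loop_dist_bins = c(8L, 25L))
    sim <- simulate_matrix(cfg, s)
    m <- contacts_to_matrix(sim$contacts, "chr1", 150, cfg$resolution)
    tads <- call_tads(m, "chr1", cfg$resolution)
    expect_equal(tads$start[1], 0)
    expect_equal(tads$end[nrow(tads)], 150 * cfg$resolution)
    expect_true(all(tads$start[-1] == tads$end[-nrow(tads)]))
    # every high-risk SNP lies in exactly one TAD
    ann <- simulate_annotations(cfg, sim$truth, s + 40)
    hr <- select_high_risk(ann$snps)
    for (p0 in hr$pos - 1) {
      expect_equal(sum(tads$start <= p0 & p0 < tads$end), 1)
    }
  }
})

test_that("zero-coverage runs are emitted as gaps", {
  m <- two_block(30, high = 6)
  m[11:18, ] <- 0
  m[, 11:18] <- 0
  tads <- call_tads(m, "chr1", 10000, w = 5)
  covered <- unlist(lapply(seq_len(nrow(tads)), function(k)
    (tads$start[k] / 10000 + 1):(tads$end[k] / 10000)))
  expect_false(any(11:18 %in% covered))
})

test_that("SNP-rich labels follow half-open containment", {
  res <- 10000
  tads <- data.table::data.table(tad_id = c("t1", "t2"), chrom = "chr1",
                                 start = c(0, 50 * res),
                                 end = c(50 * res, 100 * res))
  snps <- data.table::data.table(
    snp_id = c("in_t1", "at_shared_boundary"), chrom = "chr1",
    pos = c(10 * res, 50 * res + 1),  # 0-based positions 10*res-1, 50*res
    pvalue = 1e-9)
  lab <- classify_tads(tads, snps)
  expect_equal(lab$label, c("snp_rich", "snp_rich"))
  expect_equal(lab$n_snps, c(1, 1))  # boundary SNP belongs to exactly one TAD
  far <- classify_tads(tads, data.table::data.table(
    snp_id = "x", chrom = "chr1", pos = 200 * res, pvalue = 1e-9))
  expect_equal(far$label, c("control", "control"))
})

test_that("TAD group summaries aggregate per-TAD medians", {
  res <- 10000
  tads <- data.table::data.table(
    tad_id = sprintf("t%d", 1:4), chrom = "chr1",
    start = c(0, 50, 100, 150) * res, end = c(50, 100, 150, 200) * res,
    label = c("snp_rich", "control", "control", "control"))
  el <- data.table::data.table(
    chrom = "chr1",
    start = c(10, 20, 60, 110, 160) * res,
    end = c(10, 20, 60, 110, 160) * res + 500,
    id = sprintf("e%d", 1:5), kind = "enhancer",
    da_score = c(5, 6, 4.55, 4.75, 4.90),
    disease_associated = NA, tf_name = NA_character_, target_genes = "")
  ts <- tad_group_summary(tads, el)
  expect_equal(ts$per_tad$median_da_enh[1], 5.5)
  ctrl <- ts$summary[ts$summary$group == "control" &
                       ts$summary$measure == "enhancer_da"]
  expect_equal(ctrl$q2, 4.75)
  expect_equal(ctrl$n, 3)
  # no TF rows at all: class absent from the report, not an error
  expect_false("tf_da" %in% ts$summary$measure)
})
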