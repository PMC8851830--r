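# Independent oracles used to check the package's statistical primitives.
# Each is written from the definition, on a different code path from the
# implementation it checks.

# Upper-tail binomial probability as an explicit PMF sum.
oracle_binom_upper <- function(k, n, p) {
  if (k == 0) return(1)
  if (p == 0) return(0)
  if (p == 1) return(1)
  j <- k:n
  sum(exp(lchoose(n, j) + j * log(p) + (n - j) * log1p(-p)))
}

# Benjamini-Hochberg step-up from the definition: sort ascending,
# raw_i = p_(i) * m / i, q_(i) = min_{j >= i} raw_j capped at 1, mapped back.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  raw <- p[o] * m / seq_len(m)
  q <- numeric(m)
  run <- Inf
  for (i in m:1) {
    run <- min(run, raw[i])
    q[i] <- min(run, 1)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Brute-force 1D mapping: element ids overlapping the SNP window, one
# element at a time.
oracle_map1d_ids <- function(snp_chrom, snp_pos, elements, resolution) {
  w <- window_around(snp_pos, resolution)
  ids <- character(0)
  for (i in seq_len(nrow(elements))) {
    same <- normalize_chrom(elements$chrom[i]) == normalize_chrom(snp_chrom)
    if (same && elements$start[i] < w$end && elements$end[i] > w$start)
      ids <- c(ids, elements$id[i])
  }
  sort(ids)
}

# TRUE iff candidate row a is strictly better than b under the declared
# fragment order (min q; then max distance with inter-chromosomal = +Inf;
# then chrom, bin ascending).
oracle_better_fragment <- function(a, b) {
  if (a$qvalue != b$qvalue) return(a$qvalue < b$qvalue)
  da <- if (is.na(a$distance)) Inf else a$distance
  db <- if (is.na(b$distance)) Inf else b$distance
  if (da != db) return(da > db)
  if (a$chrom != b$chrom) return(a$chrom < b$chrom)
  a$bin < b$bin
}

# Exact one-sided rank-sum tail P(W_x <= w_obs) by bitmask enumeration over
# all assignments of the midranks to the x-sample (feasible for m + n <= 20).
oracle_ranksum_exact <- function(x, y) {
  m <- length(x); n <- length(y)
  N <- m + n
  stopifnot(N <= 20)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(m)])
  hits <- 0; total <- 0
  for (mask in 0:(2^N - 1)) {
    bits <- as.integer(intToBits(mask))[1:N]
    if (sum(bits) != m) next
    total <- total + 1
    if (sum(r[bits == 1L]) <= w_obs) hits <- hits + 1
  }
  hits / total
}

# Random element fixture on a handful of chromosomes.
make_random_elements <- function(n, chrom_span = c(chr1 = 2e6, chr2 = 1e6),
                                 genes = sprintf("G%03d", 1:50)) {
  ch <- sample(names(chrom_span), n, replace = TRUE)
  len <- sample(50:3000, n, replace = TRUE)
  start <- floor(runif(n, 0, chrom_span[ch] - len))
  kind <- sample(c("enhancer", "tfbs"), n, replace = TRUE)
  data.table::data.table(
    chrom = ch, start = start, end = start + len,
    id = sprintf("el_%05d", seq_len(n)), kind = kind,
    da_score = ifelse(kind == "enhancer", round(runif(n, 0, 10), 3), NA_real_),
    disease_associated = ifelse(kind == "tfbs", runif(n) < 0.5, NA),
    tf_name = ifelse(kind == "tfbs", "TFX", NA_character_),
    target_genes = vapply(seq_len(n), function(i)
      paste(sample(genes, sample(1:3, 1)), collapse = ","), character(1)))
}

make_genes <- function(symbols = sprintf("G%03d", 1:50), scores = NULL) {
  if (is.null(scores)) scores <- round(runif(length(symbols), 0, 8), 3)
  data.table::data.table(symbol = symbols, da_score = scores)
}

# Minimal scored-contact table builder (bins given, q-values assigned).
make_sig_contacts <- function(chrom1, bin1, chrom2, bin2, qvalue,
                              resolution = 10000) {
  data.table::data.table(
    chrom1 = chrom1, mid1 = bin1 * resolution + resolution / 2,
    chrom2 = chrom2, mid2 = bin2 * resolution + resolution / 2,
    count = 10L, bin1 = as.integer(bin1), bin2 = as.integer(bin2),
    distance = ifelse(chrom1 == chrom2,
                      abs(bin2 - bin1) * resolution, NA_real_),
    qvalue = qvalue)
}

split_ids <- function(x) {
  if (length(x) != 1L || is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, ",", fixed = TRUE)[[1]]
}
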