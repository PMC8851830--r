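# TopDom-style TAD detection and SNP-rich versus control stratification.
#
# For every inter-bin boundary the mean contact count over the w x w
# cross-boundary submatrix ("binSignal") is computed; local minima of that
# signal are boundary candidates; a candidate is accepted when a one-sided
# rank-sum test shows the cross-boundary counts to be stochastically smaller
# than the pooled within-side counts. TADs are the inter-boundary segments.
# Raw intra-chromosomal counts are used (no balancing), mirroring the
# significance stage.

#' Dense intra-chromosomal contact matrix from a contact table
#'
#' @param contacts Contact table with `chrom1`, `mid1`, `chrom2`, `mid2`,
#'   `count`.
#' @param chrom Chromosome to extract.
#' @param n_bins Number of bins on the chromosome.
#' @param resolution Bin size in bp.
#' @return Symmetric `n_bins x n_bins` numeric matrix.
#' @export
contacts_to_matrix <- function(contacts, chrom, n_bins, resolution) {
  dt <- data.table::as.data.table(contacts)
  chrom <- normalize_chrom(chrom)
  dt <- dt[normalize_chrom(chrom1) == chrom & normalize_chrom(chrom2) == chrom]
  m <- matrix(0, n_bins, n_bins)
  if (nrow(dt) > 0L) {
    i <- as.integer(floor(dt$mid1 / resolution)) + 1L
    j <- as.integer(floor(dt$mid2 / resolution)) + 1L
    keep <- i >= 1L & i <= n_bins & j >= 1L & j <= n_bins
    i <- i[keep]; j <- j[keep]; v <- as.numeric(dt$count[keep])
    m[cbind(i, j)] <- m[cbind(i, j)] + v
    off <- i != j
    m[cbind(j[off], i[off])] <- m[cbind(j[off], i[off])] + v[off]
  }
  m
}

#' Cross-boundary mean contact signal
#'
#' For the boundary between bins `i` and `i + 1` (1-based `i`), the mean of
#' counts over the `w x w` submatrix `{rows i-w+1..i} x {cols i+1..i+w}`,
#' truncated at chromosome edges (mean over the available cells).
#'
#' @param mat Symmetric contact matrix.
#' @param w Window size in bins (`>= 1`).
#' @return Numeric vector of length `nrow(mat) - 1`, one value per boundary.
#' @export
binsignal <- function(mat, w) {
  if (w < 1) stop("'w' must be >= 1", call. = FALSE)
  n <- nrow(mat)
  if (n < 2L) return(numeric(0))
  vapply(seq_len(n - 1L), function(i) {
    rows <- max(1L, i - w + 1L):i
    cols <- (i + 1L):min(n, i + w)
    mean(mat[rows, cols, drop = FALSE])
  }, numeric(1))
}

#' Boundary candidates from the binSignal profile
#'
#' Positions `i` whose signal attains the minimum within the window
#' `i - w .. i + w`, keeping the leftmost position on plateaus of equal
#' minima.
#'
#' @param signal Output of [binsignal()].
#' @param w Window size in bins.
#' @return Integer vector of candidate boundary positions (1-based, boundary
#'   `i` lies between bins `i` and `i + 1`).
#' @export
candidate_boundaries <- function(signal, w) {
  L <- length(signal)
  if (L == 0L) return(integer(0))
  keep <- vapply(seq_len(L), function(i) {
    lo <- max(1L, i - w)
    hi <- min(L, i + w)
    win <- signal[lo:hi]
    m <- min(win)
    signal[i] == m && (lo - 1L + which(win == m)[1L]) == i
  }, logical(1))
  which(keep)
}

# Internal: one-sided rank-sum p-value for H1 "x stochastically smaller
# than y". Exact midrank permutation when choose(m+n, m) is small enough,
# tie-corrected normal approximation with continuity correction otherwise.
# Empty or fully degenerate samples return 1.
ranksum_less <- function(x, y, exact_limit = 2e4) {
  m <- length(x); n <- length(y)
  if (m == 0L || n == 0L) return(1)
  comb <- c(x, y)
  if (length(unique(comb)) == 1L) return(1)
  r <- rank(comb)
  w_obs <- sum(r[seq_len(m)])
  if (choose(m + n, m) <= exact_limit) {
    sets <- utils::combn(m + n, m)
    ws <- colSums(matrix(r[sets], nrow = m))
    return(mean(ws <= w_obs))
  }
  N <- m + n
  ties <- table(comb)
  mu <- m * (N + 1) / 2
  sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  stats::pnorm((w_obs - mu + 0.5) / sqrt(sigma2))
}

#' Statistical filter for a boundary candidate
#'
#' One-sided rank-sum p-value testing whether the `w x w` cross-boundary
#' counts at boundary `i` are stochastically smaller than the pooled
#' within-side counts (strict upper-triangle cells within bins
#' `i-w+1..i` and within `i+1..i+w`). Returns 1 when either sample is empty
#' or all counts are tied.
#'
#' @param mat Symmetric contact matrix.
#' @param i Boundary position (1-based, between bins `i` and `i + 1`).
#' @param w Window size in bins.
#' @return p-value.
#' @export
boundary_pvalue <- function(mat, i, w) {
  if (w < 1) stop("'w' must be >= 1", call. = FALSE)
  n <- nrow(mat)
  left <- max(1L, i - w + 1L):i
  right <- (i + 1L):min(n, i + w)
  cross <- as.vector(mat[left, right, drop = FALSE])
  within_side <- function(idx) {
    if (length(idx) < 2L) return(numeric(0))
    sub <- mat[idx, idx, drop = FALSE]
    sub[upper.tri(sub)]
  }
  within <- c(within_side(left), within_side(right))
  ranksum_less(cross, within)
}

#' Call topologically associating domains
#'
#' Boundary candidates from [candidate_boundaries()] are filtered at
#' `boundary_pvalue < alpha`; chromosome ends are implicit boundaries; TADs
#' are the inter-boundary segments, with segments shorter than
#' `min_tad_size` bins merged into the preceding segment (the first into the
#' following one). Runs of `>= w` consecutive zero-coverage bins are treated
#' as gaps and excluded. A chromosome shorter than `2 w` bins yields a
#' single whole-chromosome TAD with a warning.
#'
#' @param mat Symmetric intra-chromosomal contact matrix of raw counts.
#' @param chrom Chromosome name (for the output table).
#' @param resolution Bin size in bp.
#' @param w TopDom-style window size in bins (default 5).
#' @param alpha Boundary p-value threshold (default 0.05, strict).
#' @param min_tad_size Minimum TAD length in bins (default 2).
#' @return `data.table` with columns `tad_id`, `chrom`, `start`, `end`
#'   (bp, bin-aligned, half-open).
#' @export
call_tads <- function(mat, chrom, resolution, w = 5L, alpha = 0.05,
                      min_tad_size = 2L) {
  n <- nrow(mat)
  chrom <- normalize_chrom(chrom)
  mk <- function(starts, ends) {
    data.table::data.table(
      tad_id = sprintf("%s_tad_%04d", chrom, seq_along(starts)),
      chrom = chrom,
      start = bin_start(starts - 1L, resolution),
      end = bin_start(ends, resolution))
  }
  if (n < 2L * w) {
    warning("chromosome shorter than 2*w bins; returning a single TAD")
    return(mk(1L, n))
  }
  sig <- binsignal(mat, w)
  cand <- candidate_boundaries(sig, w)
  pv <- vapply(cand, function(i) boundary_pvalue(mat, i, w), numeric(1))
  bounds <- cand[pv < alpha]
  edges <- c(0L, bounds, n)                       # segment k: bins e[k]+1..e[k+1]
  starts <- utils::head(edges, -1L) + 1L
  ends <- edges[-1L]
  # merge short segments into the preceding one (first into the following)
  k <- 2L
  while (k <= length(starts)) {
    if (ends[k] - starts[k] + 1L < min_tad_size) {
      ends[k - 1L] <- ends[k]
      starts <- starts[-k]; ends <- ends[-k]
    } else k <- k + 1L
  }
  if (length(starts) > 1L && ends[1L] - starts[1L] + 1L < min_tad_size) {
    starts <- starts[-1L]
    starts[1L] <- 1L
  }
  # gaps: runs of >= w zero-coverage bins are excluded from TADs
  cov <- rowSums(mat)
  gap_runs <- rle(cov == 0)
  if (any(gap_runs$values & gap_runs$lengths >= w)) {
    gend <- cumsum(gap_runs$lengths)
    gstart <- gend - gap_runs$lengths + 1L
    gaps <- cbind(gstart, gend)[gap_runs$values & gap_runs$lengths >= w, ,
                                drop = FALSE]
    pieces_s <- integer(0); pieces_e <- integer(0)
    for (k in seq_along(starts)) {
      cur <- starts[k]:ends[k]
      in_gap <- vapply(cur, function(b)
        any(b >= gaps[, 1L] & b <= gaps[, 2L]), logical(1))
      runs <- rle(!in_gap)
      pe <- cumsum(runs$lengths); ps <- pe - runs$lengths + 1L
      ok <- runs$values & runs$lengths >= min_tad_size
      pieces_s <- c(pieces_s, cur[ps[ok]])
      pieces_e <- c(pieces_e, cur[pe[ok]])
    }
    starts <- pieces_s; ends <- pieces_e
  }
  mk(starts, ends)
}

#' Label TADs as SNP-rich or control
#'
#' A TAD is `snp_rich` iff at least one high-risk SNP position (1-based,
#' converted to 0-based) falls in its half-open `[start, end)` interval;
#' otherwise `control`. Because TADs partition the chromosome, every SNP
#' belongs to exactly one TAD.
#'
#' @param tads Output of [call_tads()].
#' @param high_risk_snps SNP table already filtered at the genome-wide
#'   significance threshold.
#' @return Input `data.table` with added `label` and `n_snps` columns.
#' @export
classify_tads <- function(tads, high_risk_snps) {
  td <- data.table::as.data.table(tads)
  sn <- data.table::as.data.table(high_risk_snps)
  if (nrow(sn) > 0L) {
    sch <- normalize_chrom(sn$chrom)
    sp0 <- as.numeric(sn$pos) - 1
    td[, n_snps := vapply(seq_len(.N), function(k)
      sum(sch == chrom[k] & sp0 >= start[k] & sp0 < end[k]), numeric(1))]
  } else td[, n_snps := 0]
  td[, label := ifelse(n_snps > 0, "snp_rich", "control")]
  td[]
}

#' Per-group DA summaries over TADs
#'
#' For each TAD, the median enhancer DA score and the median TF DA score
#' (or, when TF scores are absent, the disease-associated-TF fraction) over
#' the contained elements (>= 1 bp overlap); per-TAD values are then
#' summarized within each label group, separately per element class. TADs
#' holding no element of a class contribute nothing to that class's
#' distribution; empty groups are absent from the result, not an error.
#'
#' @param tads Labeled TADs from [classify_tads()].
#' @param elements Element table.
#' @param type Quantile estimator type.
#' @return List with `per_tad` (one row per TAD: per-class medians/fraction)
#'   and `summary` (long `data.table`: `measure`, `group`, `n`, `q1`, `q2`,
#'   `q3`, `iqr`; `n` counts TADs).
#' @export
tad_group_summary <- function(tads, elements, type = 7) {
  td <- data.table::as.data.table(tads)
  edt <- data.table::as.data.table(elements)
  ech <- normalize_chrom(edt$chrom)
  per <- lapply(seq_len(nrow(td)), function(k) {
    inside <- ech == td$chrom[k] & edt$start < td$end[k] & edt$end > td$start[k]
    enh <- edt[inside & edt$kind == "enhancer"]
    tfb <- edt[inside & edt$kind == "tfbs"]
    tf_med <- NA_real_; tf_frac <- NA_real_
    if (nrow(tfb) > 0L) {
      if (all(!is.na(tfb$da_score))) tf_med <- median_da(tfb$da_score)
      else tf_frac <- fraction_da(tfb$disease_associated)
    }
    data.table::data.table(
      tad_id = td$tad_id[k], label = td$label[k],
      n_enhancers = nrow(enh), n_tfs = nrow(tfb),
      median_da_enh = if (nrow(enh)) median_da(enh$da_score) else NA_real_,
      median_da_tf = tf_med, tf_fraction = tf_frac)
  })
  per <- data.table::rbindlist(per)
  measures <- c(enhancer_da = "median_da_enh", tf_da = "median_da_tf",
                tf_fraction_da = "tf_fraction")
  rows <- list()
  for (g in unique(per$label)) {
    for (m in names(measures)) {
      v <- per[which(per[["label"]] == g)][[measures[[m]]]]
      v <- v[!is.na(v)]
      if (length(v) == 0L) next
      s <- summarize_da(v, type = type)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        measure = m, group = g, n = as.numeric(s$n), q1 = s$q1, q2 = s$q2,
        q3 = s$q3, iqr = s$iqr)
    }
  }
  summary <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(measure = character(0), group = character(0),
                           n = integer(0), q1 = numeric(0), q2 = numeric(0),
                           q3 = numeric(0), iqr = numeric(0))
  list(per_tad = per, summary = summary)
}
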