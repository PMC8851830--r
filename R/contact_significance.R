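# Statistical confidence for binned Hi-C contacts.
#
# The expected contact probability is estimated from equal-occupancy
# genomic-distance strata (a deliberate simplification of spline-based
# distance models): intra-chromosomal bin pairs are sorted by midpoint
# distance and split into `n_strata` contiguous groups of near-equal pair
# counts; all inter-chromosomal pairs form one extra stratum. Within a
# stratum the per-read-pair probability of hitting one member pair is
# total stratum count / (N * stratum pair count), with N the total observed
# count over all analyzed pairs. Each pair's count is then tested against
# Binomial(N, p_expected) (upper tail) and q-values are obtained by
# Benjamini-Hochberg correction applied jointly across intra- and
# inter-chromosomal records. Raw counts are used throughout; no matrix
# balancing is applied.

#' Canonicalize a contact table
#'
#' Normalizes chromosome names, enforces canonical pair order (lexicographic
#' chromosome, then midpoint), derives bin ordinals and midpoint distances
#' (`NA` for inter-chromosomal pairs), and drops intra-chromosomal pairs
#' closer than `min_dist_bins` bins (self-pairs by default, as the diagonal
#' carries no interaction signal).
#'
#' @param contacts `data.frame`/`data.table` with columns `chrom1`, `mid1`,
#'   `chrom2`, `mid2`, `count` (fragment midpoints in bp).
#' @param resolution Bin size in bp.
#' @param min_dist_bins Minimum intra-chromosomal separation in bins
#'   (default 1 excludes the diagonal).
#' @return `data.table` with added columns `bin1`, `bin2`, `distance`.
#' @export
prepare_contacts <- function(contacts, resolution, min_dist_bins = 1L) {
  req <- c("chrom1", "mid1", "chrom2", "mid2", "count")
  miss <- setdiff(req, names(contacts))
  if (length(miss))
    stop("contact table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  dt <- data.table::as.data.table(contacts)[, req, with = FALSE]
  if (any(dt$count < 0) || any(is.na(dt$count)))
    stop("contact counts must be non-negative", call. = FALSE)
  dt[, `:=`(chrom1 = normalize_chrom(chrom1), chrom2 = normalize_chrom(chrom2))]
  swap <- dt$chrom2 < dt$chrom1 | (dt$chrom1 == dt$chrom2 & dt$mid2 < dt$mid1)
  if (any(swap)) {
    dt[swap, `:=`(chrom1 = chrom2, chrom2 = chrom1, mid1 = mid2, mid2 = mid1)]
  }
  dt[, `:=`(bin1 = as.integer(floor(mid1 / resolution)),
            bin2 = as.integer(floor(mid2 / resolution)))]
  dt[, distance := ifelse(chrom1 == chrom2, abs(mid2 - mid1), NA_real_)]
  dt[is.na(distance) | abs(bin2 - bin1) >= min_dist_bins]
}

#' Build equal-occupancy distance strata
#'
#' Intra-chromosomal pairs are sorted by genomic distance and split into
#' `n_strata` contiguous distance groups of as-nearly-as-possible equal pair
#' counts (fewer distinct distances than strata collapse adjacent groups);
#' all inter-chromosomal pairs form one extra stratum.
#'
#' @param contacts Output of [prepare_contacts()] (needs a `distance` column).
#' @param n_strata Target number of intra-chromosomal strata (`>= 1`).
#' @return List with `contacts` (input plus integer `stratum` column) and
#'   `strata` (`data.table`: `stratum`, `inter`, `d_min`, `d_max`, `n_pairs`,
#'   `total_count`).
#' @export
build_strata <- function(contacts, n_strata = 100L) {
  if (n_strata < 1) stop("'n_strata' must be >= 1", call. = FALSE)
  dt <- data.table::as.data.table(contacts)
  if (!"distance" %in% names(dt))
    stop("contacts lack a 'distance' column; run prepare_contacts() first",
         call. = FALSE)
  if (nrow(dt) == 0L) stop("contact table is empty", call. = FALSE)
  intra <- !is.na(dt$distance)
  dt[, stratum := NA_integer_]
  if (any(intra)) {
    d <- dt$distance[intra]
    breaks <- numeric(0)
    if (n_strata > 1L) {
      breaks <- unique(stats::quantile(d, probs = seq_len(n_strata - 1L) / n_strata,
                                       type = 1, names = FALSE))
      breaks <- breaks[breaks < max(d)]
    }
    dt[intra == TRUE, stratum := findInterval(distance, breaks, left.open = TRUE) + 1L]
    # guard against empty leading groups after collapse
    dt[intra == TRUE, stratum := as.integer(factor(stratum))]
  }
  n_intra_strata <- if (any(intra)) max(dt$stratum, na.rm = TRUE) else 0L
  if (any(!intra)) dt[is.na(distance), stratum := n_intra_strata + 1L]
  strata <- dt[, .(inter = anyNA(distance),
                   d_min = suppressWarnings(min(distance, na.rm = TRUE)),
                   d_max = suppressWarnings(max(distance, na.rm = TRUE)),
                   n_pairs = .N,
                   total_count = sum(as.numeric(count))),
               by = stratum][order(stratum)]
  strata[inter == TRUE, `:=`(d_min = NA_real_, d_max = NA_real_)]
  list(contacts = dt, strata = strata)
}

#' Expected per-pair contact probability of a stratum
#'
#' Under the null, each of the `n_total` read pairs falls on one member pair
#' of a stratum with probability
#' `total_count / (n_total * n_pairs)`.
#'
#' @param total_count Total observed count in the stratum.
#' @param n_pairs Number of member pairs (`> 0`).
#' @param n_total Total read pairs in the analysis (`> 0`).
#' @return Probability (vectorized over strata).
#' @export
stratum_expected_p <- function(total_count, n_pairs, n_total) {
  if (any(n_pairs <= 0)) stop("stratum pair count must be positive", call. = FALSE)
  if (length(n_total) != 1L || n_total <= 0)
    stop("'n_total' must be a single positive count", call. = FALSE)
  as.numeric(total_count) / (as.numeric(n_total) * as.numeric(n_pairs))
}

#' Upper-tail binomial p-value
#'
#' Probability of observing a contact count at least as large as `k` under
#' `X ~ Binomial(n, p)`: `P(X >= k)`; equal to 1 when `k = 0`.
#'
#' @param k Observed count(s), `0 <= k <= n`.
#' @param n Number of trials (total read pairs).
#' @param p Expected per-trial probability.
#' @return Numeric vector of p-values.
#' @export
binomial_pvalue <- function(k, n, p) {
  if (any(k < 0) || any(k > n)) stop("'k' must satisfy 0 <= k <= n", call. = FALSE)
  if (any(p < 0) || any(p > 1)) stop("'p' must lie in [0, 1]", call. = FALSE)
  stats::pbinom(k - 1, size = n, prob = p, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment, returned in input order.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Numeric vector of q-values (same order as input).
#' @export
bh_qvalues <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Score a contact table
#'
#' Full significance stage: canonicalization, equal-occupancy strata,
#' per-pair expected probabilities, upper-tail binomial p-values against
#' `Binomial(N, p_expected)` with `N` the total observed count, and joint
#' BH correction across all records.
#'
#' @inheritParams prepare_contacts
#' @inheritParams build_strata
#' @return `data.table` with added columns `expected_p`, `pvalue`, `qvalue`.
#' @export
score_contacts <- function(contacts, resolution, n_strata = 100L,
                           min_dist_bins = 1L) {
  dt <- prepare_contacts(contacts, resolution, min_dist_bins)
  if (nrow(dt) == 0L) stop("no contacts left to analyze", call. = FALSE)
  st <- build_strata(dt, n_strata)
  dt <- st$contacts
  n_total <- sum(as.numeric(dt$count))
  if (n_total <= 0) stop("total contact count is zero", call. = FALSE)
  strata <- st$strata
  strata[, expected_p := stratum_expected_p(total_count, n_pairs, n_total)]
  dt[strata, expected_p := i.expected_p, on = "stratum"]
  dt[, pvalue := binomial_pvalue(count, n_total, expected_p)]
  dt[, qvalue := bh_qvalues(pvalue)]
  dt[]
}

#' Filter to significant contacts
#'
#' Keeps exactly the records with `qvalue <= q_max` (inclusive threshold),
#' preserving input order.
#'
#' @param scored Output of [score_contacts()] (must carry `qvalue`).
#' @param q_max Inclusive q-value threshold (default 0.05).
#' @return Filtered `data.table`.
#' @export
significant_contacts <- function(scored, q_max = 0.05) {
  if (!"qvalue" %in% names(scored))
    stop("records lack q-values; run score_contacts() first", call. = FALSE)
  data.table::as.data.table(scored)[qvalue <= q_max]
}
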