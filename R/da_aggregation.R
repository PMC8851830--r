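# Disease-association (DA) score aggregation: per-SNP medians,
# disease-associated-TF fractions, and quantile/IQR distribution summaries.

#' Median disease-association score
#'
#' Median of the supplied scores with linear interpolation between the two
#' central order statistics for even sample sizes. An empty input yields
#' `NA` (no value); a missing score is an error, because score-less TFs must
#' be routed to [fraction_da()] instead.
#'
#' @param scores Numeric DA scores.
#' @return Median, or `NA_real_` for empty input.
#' @export
median_da <- function(scores) {
  if (length(scores) == 0L) return(NA_real_)
  if (any(is.na(scores)))
    stop("missing DA score; use fraction_da() for flag-only elements",
         call. = FALSE)
  stats::median(scores)
}

#' Fraction of disease-associated elements
#'
#' Share of elements whose binary disease-associated flag is set; used where
#' no numeric DA score exists (e.g. TF sets annotated only with a flag).
#'
#' @param flags Logical vector.
#' @return Fraction in `[0, 1]`, or `NA_real_` for empty input.
#' @export
fraction_da <- function(flags) {
  if (length(flags) == 0L) return(NA_real_)
  if (any(is.na(flags))) stop("missing disease-associated flag", call. = FALSE)
  mean(flags)
}

#' Quantile/IQR distribution summary
#'
#' First, second and third quartiles by linear interpolation between order
#' statistics (`stats::quantile` type 7 by default), the inter-quantile
#' range `IQR = Q3 - Q1`, outliers outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`,
#' and whisker minima/maxima computed after outlier exclusion (the
#' violin-style reporting convention).
#'
#' @param values Numeric vector, `length >= 1`.
#' @param type Quantile estimator type passed to [stats::quantile()].
#' @return List with `n`, `q1`, `q2`, `q3`, `iqr`, `whisker_min`,
#'   `whisker_max`, `outliers`.
#' @export
summarize_da <- function(values, type = 7) {
  if (length(values) == 0L) stop("cannot summarize an empty vector", call. = FALSE)
  if (any(is.na(values))) stop("missing values in summary input", call. = FALSE)
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = type))
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  out <- values[values < lo | values > hi]
  kept <- values[values >= lo & values <= hi]
  list(n = length(values), q1 = q[1], q2 = q[2], q3 = q[3], iqr = iqr,
       whisker_min = min(kept), whisker_max = max(kept), outliers = out)
}

#' Distribution summaries of per-SNP mapping results
#'
#' Summarizes the per-SNP aggregation columns of [map_1d()]/[map_3d()]
#' output into the statistic-by-condition layout used for 1D-versus-3D
#' comparisons: for each mapping mode and measure (enhancer DA, enhancer
#' target-gene DA, TF DA or disease-associated-TF fraction, TF target-gene
#' DA), the number of contributing SNPs and the quartiles/IQR over per-SNP
#' values. SNPs without a value for a measure contribute nothing (they are
#' not zero-filled).
#'
#' @param mappings `data.table` of per-SNP mapping rows (possibly several
#'   modes combined).
#' @param type Quantile estimator type.
#' @return Long-format `data.table`: `measure`, `mode`, `n`, `q1`, `q2`,
#'   `q3`, `iqr`.
#' @export
mapping_summary <- function(mappings, type = 7) {
  dt <- data.table::as.data.table(mappings)
  measures <- c(enhancer_da = "median_da_enh",
                enhancer_target_da = "median_da_enh_targets",
                tf_da = "median_da_tf",
                tf_fraction_da = "tf_fraction",
                tf_target_da = "median_da_tf_targets")
  rows <- list()
  for (md in unique(dt$mode)) {
    sub <- dt[which(dt[["mode"]] == md)]
    for (m in names(measures)) {
      v <- sub[[measures[[m]]]]
      v <- v[!is.na(v)]
      if (length(v) == 0L) next
      s <- summarize_da(v, type = type)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        measure = m, mode = md, n = as.numeric(s$n), q1 = s$q1, q2 = s$q2,
        q3 = s$q3, iqr = s$iqr)
    }
  }
  if (length(rows) == 0L)
    return(data.table::data.table(measure = character(0), mode = character(0),
                                  n = integer(0), q1 = numeric(0),
                                  q2 = numeric(0), q3 = numeric(0),
                                  iqr = numeric(0)))
  data.table::rbindlist(rows)
}
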