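# Coordinate conventions used throughout the package:
#   * internal intervals are 0-based, half-open [start, end)
#   * GWAS positions are 1-based as published and converted where needed
#   * chromosome names are normalized to a "chr" prefix at ingest
# Strand is ignored everywhere; an element overlapping an interval by
# >= 1 bp counts as contained.

#' Map a 1-based genomic position to its bin ordinal
#'
#' Chromosomes are tiled with fixed-size bins; bin `i` covers the half-open
#' interval `[i * resolution, (i + 1) * resolution)` in 0-based coordinates.
#' A 1-based position `pos` therefore falls into bin
#' `floor((pos - 1) / resolution)`.
#'
#' @param pos 1-based base-pair position(s), `>= 1`.
#' @param resolution Bin size in bp, `> 0`.
#' @return Integer vector of 0-based bin ordinals.
#' @examples
#' bin_index(1, 10000)        # 0
#' bin_index(56011357, 10000) # bin starting at 56,010,000
#' @export
bin_index <- function(pos, resolution) {
  if (length(resolution) != 1L || !is.finite(resolution) || resolution <= 0)
    stop("'resolution' must be a single positive number", call. = FALSE)
  if (length(pos) == 0L) return(integer(0))
  if (any(!is.finite(pos)) || any(pos < 1))
    stop("'pos' must be 1-based positions >= 1", call. = FALSE)
  as.integer(floor((as.numeric(pos) - 1) / resolution))
}

#' Start coordinate (0-based) of a bin
#'
#' @param index 0-based bin ordinal(s).
#' @param resolution Bin size in bp.
#' @return Numeric vector of 0-based start coordinates.
#' @export
bin_start <- function(index, resolution) {
  as.numeric(index) * resolution
}

#' Normalize chromosome names to a "chr" prefix
#'
#' Mixed dialects ("5", "chr5", "Chr5") compare equal after normalization.
#'
#' @param x Character vector of chromosome names.
#' @return Character vector with a lowercase "chr" prefix.
#' @export
normalize_chrom <- function(x) {
  x <- as.character(x)
  if (any(!nzchar(x) | is.na(x)))
    stop("chromosome names must be non-empty", call. = FALSE)
  paste0("chr", sub("^[Cc][Hh][Rr]", "", x))
}

#' Half-open interval overlap
#'
#' Two intervals overlap iff they are on the same chromosome and
#' `a.start < b.end && b.start < a.end` (0-based, half-open semantics, so
#' abutting intervals do not overlap).
#'
#' @param chrom_a,start_a,end_a First interval (vectors recycle).
#' @param chrom_b,start_b,end_b Second interval.
#' @return Logical vector.
#' @export
interval_overlaps <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  if (any(start_a < 0) || any(start_b < 0) ||
      any(end_a <= start_a) || any(end_b <= start_b))
    stop("intervals must satisfy 0 <= start < end", call. = FALSE)
  normalize_chrom(chrom_a) == normalize_chrom(chrom_b) &
    start_a < end_b & start_b < end_a
}

#' Resolution-sized window centered on a variant
#'
#' Builds the 0-based half-open window of total width `window` centered on a
#' 1-based SNP position: `[pos0 - window/2, pos0 + window/2)` with
#' `pos0 = pos - 1`, clipped at the chromosome start. With the default usage
#' `window` equals the Hi-C resolution, i.e. `window/2` bp up- and downstream
#' of the variant.
#'
#' @param pos 1-based SNP position(s).
#' @param window Total window width in bp; must be positive and even.
#' @return `data.frame` with columns `start`, `end` (0-based half-open).
#' @export
window_around <- function(pos, window) {
  if (length(window) != 1L || !is.finite(window) || window <= 0 || window %% 2 != 0)
    stop("'window' must be a single positive even number of bp", call. = FALSE)
  if (any(pos < 1)) stop("'pos' must be 1-based positions >= 1", call. = FALSE)
  pos0 <- as.numeric(pos) - 1
  data.frame(start = pmax(0, pos0 - window / 2), end = pos0 + window / 2)
}

# Internal: split "a,b,c" target-gene strings into a character vector.
split_targets <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- unlist(strsplit(x[!is.na(x) & nzchar(x)], ",", fixed = TRUE))
  unique(trimws(out[nzchar(out)]))
}
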