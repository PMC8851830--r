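# Mapping high-risk variants to regulatory elements.
#
# 1D: elements overlapping a resolution-sized window centered on the SNP.
# 3D: among the SNP bin's significant contact partners that contain at least
# one regulatory element, select the single most confident fragment (lowest
# contact q-value; ties broken by the longest range, with inter-chromosomal
# partners outranking every intra-chromosomal one; residual ties broken by
# chromosome name and bin index). Elements on the selected fragment and the
# union of their target genes make up the mapping.

#' Select variants highly associated with disease
#'
#' Retains exactly the SNPs with `pvalue <= p_max`; the genome-wide
#' significance bound is inclusive.
#'
#' @param snps `data.frame` with columns `snp_id`, `chrom`, `pos`, `pvalue`.
#' @param p_max Inclusive p-value threshold (default `5e-8`).
#' @return Filtered `data.table`.
#' @export
select_high_risk <- function(snps, p_max = 5e-8) {
  dt <- data.table::as.data.table(snps)
  if (any(is.na(dt$pvalue)) || any(dt$pvalue <= 0) || any(dt$pvalue > 1))
    stop("SNP p-values must lie in (0, 1]", call. = FALSE)
  dt[pvalue <= p_max]
}

# Internal: per-SNP aggregation over a set of mapped elements.
# Returns a one-row data.table with element ids, target genes and the
# median/fraction disease-association summaries.
aggregate_mapping <- function(snp_id, chrom, pos, mode, elems, genes,
                              frag = NULL) {
  gdt <- data.table::as.data.table(genes)
  enh <- elems[elems$kind == "enhancer", , drop = FALSE]
  tfb <- elems[elems$kind == "tfbs", , drop = FALSE]
  gene_median <- function(e) {
    syms <- split_targets(e$target_genes)
    if (length(syms) == 0L) return(NA_real_)
    sc <- gdt$da_score[match(syms, gdt$symbol)]
    sc <- sc[!is.na(sc)]
    if (length(sc) == 0L) NA_real_ else median_da(sc)
  }
  tf_median <- NA_real_
  tf_frac <- NA_real_
  if (nrow(tfb) > 0L) {
    if (all(!is.na(tfb$da_score))) {
      tf_median <- median_da(tfb$da_score)
    } else {
      tf_frac <- fraction_da(tfb$disease_associated)
    }
  }
  out <- data.table::data.table(
    snp_id = snp_id, chrom = chrom, pos = pos, mode = mode,
    frag_chrom = NA_character_, frag_start = NA_real_, frag_end = NA_real_,
    frag_qvalue = NA_real_, frag_distance = NA_real_,
    n_enhancers = nrow(enh), n_tfs = nrow(tfb),
    enhancer_ids = paste(enh$id, collapse = ","),
    tf_ids = paste(tfb$id, collapse = ","),
    enh_target_genes = paste(split_targets(enh$target_genes), collapse = ","),
    tf_target_genes = paste(split_targets(tfb$target_genes), collapse = ","),
    median_da_enh = if (nrow(enh)) median_da(enh$da_score) else NA_real_,
    median_da_enh_targets = gene_median(enh),
    median_da_tf = tf_median,
    tf_fraction = tf_frac,
    median_da_tf_targets = gene_median(tfb))
  if (!is.null(frag)) {
    out[, `:=`(frag_chrom = frag$chrom,
               frag_start = bin_start(frag$bin, frag$resolution),
               frag_end = bin_start(frag$bin + 1, frag$resolution),
               frag_qvalue = frag$qvalue, frag_distance = frag$distance)]
  }
  out
}

#' Map variants to elements by linear (1D) proximity
#'
#' Each SNP is mapped to every element overlapping (by at least 1 bp) the
#' resolution-sized window centered on it; target genes are the union over
#' mapped elements. SNPs whose window holds no element yield an empty
#' mapping row, never an error.
#'
#' @param snps High-risk SNP table (`snp_id`, `chrom`, `pos`, `pvalue`).
#' @param elements Element table (see [read_elements()]).
#' @param genes Gene score table (`symbol`, `da_score`).
#' @param resolution Window width in bp (matched to the Hi-C resolution).
#' @return `data.table`, one row per SNP, with element ids, gene symbols and
#'   the per-SNP disease-association summaries.
#' @export
map_1d <- function(snps, elements, genes, resolution) {
  sdt <- data.table::as.data.table(snps)
  edt <- data.table::as.data.table(elements)
  if (nrow(sdt) == 0L) return(empty_mapping())
  win <- window_around(sdt$pos, resolution)
  sdt[, `:=`(w_chrom = normalize_chrom(chrom),
             w_start = win$start, w_end = win$end - 1)]  # closed for foverlaps
  hits <- vector("list", nrow(sdt))
  if (nrow(edt) > 0L) {
    e <- edt[, .(w_chrom = normalize_chrom(chrom), w_start = start,
                 w_end = end - 1, row = .I)]
    data.table::setkey(e, w_chrom, w_start, w_end)
    ov <- data.table::foverlaps(
      sdt[, .(w_chrom, w_start, w_end, snp = .I)], e, type = "any")
    ov <- ov[!is.na(row)]
    hits <- split(ov$row, factor(ov$snp, levels = seq_len(nrow(sdt))))
  }
  out <- lapply(seq_len(nrow(sdt)), function(i) {
    idx <- if (nrow(edt) > 0L) hits[[i]] else integer(0)
    aggregate_mapping(sdt$snp_id[i], sdt$w_chrom[i], sdt$pos[i], "1D",
                      edt[idx], genes)
  })
  data.table::rbindlist(out)
}

empty_mapping <- function() {
  aggregate_mapping(character(0), character(0), numeric(0), character(0),
                    data.table::data.table(kind = character(0), id = character(0),
                                           da_score = numeric(0),
                                           disease_associated = logical(0),
                                           target_genes = character(0)),
                    data.table::data.table(symbol = character(0),
                                           da_score = numeric(0)))[0]
}

# Internal: elements overlapping a set of bins; returns indices into `edt`
# for each (chrom, bin) key.
elements_in_bin <- function(edt, chrom, bin, resolution, kind = NULL) {
  bs <- bin_start(bin, resolution)
  keep <- normalize_chrom(edt$chrom) == chrom &
    edt$start < bs + resolution & edt$end > bs
  if (!is.null(kind)) keep <- keep & edt$kind == kind
  which(keep)
}

#' Candidate partner fragments of a variant
#'
#' Every partner bin of the SNP's containing bin among the significant
#' contacts (either side of the pair) that contains at least one regulatory
#' element (of `kind` when given), with the contact's q-value and genomic
#' distance (`NA` for inter-chromosomal partners).
#'
#' @param snp_chrom,snp_pos Chromosome and 1-based position of the SNP.
#' @param sig_contacts Significant contact table (output of
#'   [significant_contacts()]).
#' @param elements Element table.
#' @param resolution Bin size in bp.
#' @param kind Optional element kind filter (`"enhancer"` or `"tfbs"`).
#' @return `data.table` with columns `chrom`, `bin`, `qvalue`, `distance`,
#'   `n_elements` (possibly zero rows).
#' @export
candidate_fragments <- function(snp_chrom, snp_pos, sig_contacts, elements,
                                resolution, kind = NULL) {
  sc <- data.table::as.data.table(sig_contacts)
  edt <- data.table::as.data.table(elements)
  chrom <- normalize_chrom(snp_chrom)
  b <- bin_index(snp_pos, resolution)
  empty <- data.table::data.table(chrom = character(0), bin = integer(0),
                                  qvalue = numeric(0), distance = numeric(0),
                                  n_elements = integer(0))
  if (nrow(sc) == 0L) return(empty)
  if (!all(c("bin1", "bin2") %in% names(sc))) {
    sc[, `:=`(bin1 = as.integer(floor(mid1 / resolution)),
              bin2 = as.integer(floor(mid2 / resolution)))]
  }
  left <- sc[chrom1 == chrom & bin1 == b,
             .(chrom = chrom2, bin = bin2, qvalue, distance)]
  right <- sc[chrom2 == chrom & bin2 == b,
              .(chrom = chrom1, bin = bin1, qvalue, distance)]
  part <- unique(rbind(left, right))
  if (nrow(part) == 0L) return(empty)
  part[, n_elements := vapply(seq_len(.N), function(i)
    length(elements_in_bin(edt, chrom[i], bin[i], resolution, kind)), integer(1))]
  part[n_elements > 0L]
}

#' Select the single most confident fragment
#'
#' Total order over candidates: lowest contact q-value first; among equal
#' minimal q-values, the longest-range candidate, where inter-chromosomal
#' candidates (distance `NA`) outrank every intra-chromosomal one; residual
#' ties break deterministically by chromosome name, then bin index.
#'
#' @param candidates Output of [candidate_fragments()].
#' @return One-row `data.table`, or `NULL` when `candidates` is empty (the
#'   SNP is unmapped in 3D).
#' @export
select_fragment <- function(candidates) {
  cd <- data.table::as.data.table(candidates)
  if (nrow(cd) == 0L) return(NULL)
  dist_key <- ifelse(is.na(cd$distance), Inf, cd$distance)
  ord <- order(cd$qvalue, -dist_key, cd$chrom, cd$bin)
  cd[ord[1L]]
}

#' Map variants to elements through significant chromatin contacts (3D)
#'
#' For each SNP, one fragment is selected by [select_fragment()] among the
#' element-bearing significant contact partners of the SNP's bin. With
#' `scope = "per_class"` (default) the selection runs independently for
#' enhancers and for TF binding sites and the results are merged, so each
#' element class is represented whenever any significant element-bearing
#' contact exists; with `scope = "joint"` one fragment is selected over all
#' element-bearing candidates.
#'
#' @inheritParams map_1d
#' @param sig_contacts Significant contact table (already filtered at
#'   `q <= 0.05`).
#' @param scope `"per_class"` or `"joint"`.
#' @return `data.table`, one row per SNP. For `per_class` the reported
#'   fragment coordinates are those of the enhancer-selected fragment when
#'   present, otherwise the TF-selected one; per-class summaries are always
#'   computed from the class's own fragment.
#' @export
map_3d <- function(snps, sig_contacts, elements, genes, resolution,
                   scope = c("per_class", "joint")) {
  scope <- match.arg(scope)
  sdt <- data.table::as.data.table(snps)
  edt <- data.table::as.data.table(elements)
  if (nrow(sdt) == 0L) return(empty_mapping())
  sc <- data.table::as.data.table(sig_contacts)
  if (nrow(sc) > 0L && !all(c("bin1", "bin2") %in% names(sc))) {
    sc[, `:=`(bin1 = as.integer(floor(mid1 / resolution)),
              bin2 = as.integer(floor(mid2 / resolution)))]
  }
  out <- lapply(seq_len(nrow(sdt)), function(i) {
    chrom <- normalize_chrom(sdt$chrom[i])
    pick <- function(kind) {
      cand <- candidate_fragments(chrom, sdt$pos[i], sc, edt, resolution, kind)
      select_fragment(cand)
    }
    frags <- if (scope == "per_class") {
      list(enhancer = pick("enhancer"), tfbs = pick("tfbs"))
    } else {
      f <- pick(NULL)
      list(enhancer = f, tfbs = f)
    }
    idx <- integer(0)
    for (kind in names(frags)) {
      f <- frags[[kind]]
      if (!is.null(f))
        idx <- c(idx, elements_in_bin(edt, f$chrom, f$bin, resolution, kind))
    }
    frag <- frags$enhancer
    if (is.null(frag)) frag <- frags$tfbs
    row <- aggregate_mapping(
      sdt$snp_id[i], chrom, sdt$pos[i], "3D", edt[unique(idx)], genes,
      frag = if (is.null(frag)) NULL else
        list(chrom = frag$chrom, bin = frag$bin, qvalue = frag$qvalue,
             distance = frag$distance, resolution = resolution))
    row
  })
  data.table::rbindlist(out)
}
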