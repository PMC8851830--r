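# End-to-end orchestration: contact significance -> high-risk selection ->
# 1D and 3D mapping -> DA aggregation -> TAD calling -> SNP-rich/control
# stratification -> report tables, plus a run manifest making reruns
# byte-reproducible.

#' Pipeline run configuration
#'
#' Collects input paths and every tunable threshold of the workflow.
#'
#' @param contacts,gwas,elements,genes Input file paths.
#' @param resolution Hi-C bin size in bp.
#' @param q_max Inclusive contact q-value threshold (default 0.05).
#' @param p_max Inclusive GWAS p-value threshold (default `5e-8`).
#' @param n_strata Distance strata for the expected model (default 100).
#' @param min_dist_bins Minimum intra-chromosomal separation in bins for the
#'   significance analysis (workflow default 5, i.e. 50 kbp at 10 kbp
#'   resolution: below that the steep distance decay dominates the flat
#'   within-stratum expectation and short-range pairs would be called
#'   significant on decay curvature alone).
#' @param selection_scope `"per_class"` or `"joint"` fragment selection.
#' @param tad_w,tad_alpha,tad_min_size TAD-calling window (bins), boundary
#'   p threshold and minimum TAD size (bins).
#' @param quantile_type Quantile estimator for summaries (default 7).
#' @param element_coords Coordinate convention of the element table.
#' @return List of class `run_config`.
#' @export
run_config <- function(contacts, gwas, elements, genes, resolution,
                       q_max = 0.05, p_max = 5e-8, n_strata = 100L,
                       min_dist_bins = 5L,
                       selection_scope = c("per_class", "joint"),
                       tad_w = 5L, tad_alpha = 0.05, tad_min_size = 2L,
                       quantile_type = 7, element_coords = c("bed", "one_based")) {
  selection_scope <- match.arg(selection_scope)
  element_coords <- match.arg(element_coords)
  if (resolution <= 0) stop("'resolution' must be positive", call. = FALSE)
  for (v in c(q_max = q_max, p_max = p_max))
    if (v <= 0 || v > 1) stop("thresholds must lie in (0, 1]", call. = FALSE)
  structure(list(contacts = contacts, gwas = gwas, elements = elements,
                 genes = genes, resolution = resolution, q_max = q_max,
                 p_max = p_max, n_strata = as.integer(n_strata),
                 min_dist_bins = as.integer(min_dist_bins),
                 selection_scope = selection_scope, tad_w = as.integer(tad_w),
                 tad_alpha = tad_alpha, tad_min_size = as.integer(tad_min_size),
                 quantile_type = quantile_type,
                 element_coords = element_coords),
            class = "run_config")
}

#' Run the full variant-to-element workflow
#'
#' Executes contact significance calling, high-risk SNP selection, 1D and 3D
#' mapping, per-SNP DA aggregation, TAD calling with SNP-rich/control
#' stratification, and report rendering. All declared outputs plus a YAML
#' manifest (config echo, input checksums, package version) are written to
#' `out_dir`; reruns from the same manifest produce byte-identical files.
#'
#' @param config A [run_config()] object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all intermediate objects (`scored`,
#'   `significant`, `high_risk`, `mappings`, `mapping_summary`, `tads`,
#'   `tad_summary`, `outputs`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  contacts <- stage("read_contacts", read_contacts(config$contacts))
  snps <- stage("read_gwas", read_gwas(config$gwas))
  elements <- stage("read_elements",
                    read_elements(config$elements, config$element_coords))
  genes <- stage("read_genes", read_genes(config$genes))
  message(sprintf("inputs: %d contacts, %d SNPs, %d elements, %d genes",
                  nrow(contacts), nrow(snps), nrow(elements), nrow(genes)))

  scored <- stage("score_contacts",
                  score_contacts(contacts, config$resolution,
                                 config$n_strata, config$min_dist_bins))
  sig <- stage("significant_contacts", significant_contacts(scored, config$q_max))
  high_risk <- stage("select_high_risk", select_high_risk(snps, config$p_max))
  message(sprintf("%d significant contacts (q <= %g); %d high-risk SNPs (p <= %g)",
                  nrow(sig), config$q_max, nrow(high_risk), config$p_max))

  m1 <- stage("map_1d", map_1d(high_risk, elements, genes, config$resolution))
  m3 <- stage("map_3d", map_3d(high_risk, sig, elements, genes,
                               config$resolution, config$selection_scope))
  mappings <- rbind(m1, m3)
  msum <- stage("mapping_summary",
                mapping_summary(mappings, config$quantile_type))

  # TADs per chromosome present in the (intra-chromosomal) contacts
  tads <- stage("call_tads", {
    cdt <- prepare_contacts(contacts, config$resolution, min_dist_bins = 0L)
    intra <- cdt[!is.na(distance)]
    out <- list()
    for (ch in sort(unique(intra$chrom1))) {
      n_bins <- max(intra[chrom1 == ch, pmax(bin1, bin2)]) + 1L
      m <- contacts_to_matrix(intra[chrom1 == ch], ch, n_bins, config$resolution)
      out[[ch]] <- call_tads(m, ch, config$resolution, config$tad_w,
                             config$tad_alpha, config$tad_min_size)
    }
    data.table::rbindlist(out)
  })
  tads <- stage("classify_tads", classify_tads(tads, high_risk))
  tsum <- stage("tad_group_summary",
                tad_group_summary(tads, elements, config$quantile_type))

  outputs <- list(
    scored_contacts = file.path(out_dir, "contacts_scored.tsv"),
    significant_contacts = file.path(out_dir, "contacts_significant.tsv"),
    snp_mappings = file.path(out_dir, "snp_mappings.tsv"),
    mapping_summary = file.path(out_dir, "mapping_summary.tsv"),
    tads = file.path(out_dir, "tads.bed"),
    tad_summary = file.path(out_dir, "tad_summary.tsv"),
    manifest = file.path(out_dir, "manifest.yaml"))
  write_tsv_file(scored, outputs$scored_contacts)
  write_tsv_file(sig, outputs$significant_contacts)
  write_tsv_file(fmt_mappings(mappings), outputs$snp_mappings)
  write_tsv_file(msum, outputs$mapping_summary)
  write_tads_bed(tads, outputs$tads)
  write_tsv_file(tsum$summary, outputs$tad_summary)
  manifest <- list(
    package = "varcontact",
    version = as.character(utils::packageVersion("varcontact")),
    config = unclass(config),
    input_md5 = as.list(tools::md5sum(c(config$contacts, config$gwas,
                                        config$elements, config$genes))))
  yaml::write_yaml(manifest, outputs$manifest)
  invisible(list(scored = scored, significant = sig, high_risk = high_risk,
                 mappings = mappings, mapping_summary = msum, tads = tads,
                 tad_summary = tsum, outputs = outputs))
}

# Internal: serialize mapping rows (distance NA means inter-chromosomal).
fmt_mappings <- function(mappings) {
  dt <- data.table::copy(data.table::as.data.table(mappings))
  dt[, frag_distance := ifelse(mode == "3D" & !is.na(frag_chrom) &
                                 is.na(frag_distance), "inter",
                               as.character(frag_distance))]
  dt
}

#' Render the report tables
#'
#' Wide statistic-by-condition tables from the long summaries: one row per
#' statistic (`n`, `q1`, `q2`, `q3`, `iqr`), one column per
#' measure-condition pair. Conditions with no contributing values are
#' omitted. Where TF sets carry no numeric scores, the
#' disease-associated-TF fraction rows stand in for the TF DA rows.
#'
#' @param summary Long summary from [mapping_summary()] (`mode` column) or
#'   [tad_group_summary()] (`group` column).
#' @return `data.table` with a `statistic` column and one column per
#'   condition.
#' @export
render_report <- function(summary) {
  dt <- data.table::as.data.table(summary)
  cond <- if ("mode" %in% names(dt)) "mode" else "group"
  if (nrow(dt) == 0L)
    return(data.table::data.table(statistic = c("n", "q1", "q2", "q3", "iqr")))
  long <- data.table::melt(dt, id.vars = c("measure", cond),
                           measure.vars = c("n", "q1", "q2", "q3", "iqr"),
                           variable.name = "statistic")
  wide <- data.table::dcast(long, statistic ~ measure + get(cond),
                            value.var = "value")
  wide
}

#' Violin-style plot of per-SNP or per-TAD DA distributions
#'
#' Cosmetic companion to the report tables; requires `ggplot2`.
#'
#' @param values Numeric vector of DA values.
#' @param group Grouping factor (e.g. mapping mode or TAD label).
#' @return A `ggplot` object.
#' @export
plot_da_distribution <- function(values, group) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_da_distribution() requires the 'ggplot2' package", call. = FALSE)
  df <- data.frame(value = values, group = group)
  ggplot2::ggplot(df, ggplot2::aes(x = group, y = value, fill = group)) +
    ggplot2::geom_violin(trim = FALSE, alpha = 0.7) +
    ggplot2::geom_boxplot(width = 0.12, fill = "grey85", outlier.shape = 18) +
    ggplot2::labs(x = NULL, y = "disease-association score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
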