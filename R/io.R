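# Readers and writers for the pipeline's plain-text formats. All readers
# are gzip-transparent (a ".gz" suffix is read through a gzfile
# connection); writers emit tab-separated text, gzip-compressed when the
# target path ends in ".gz".

read_tsv_file <- function(path, header = TRUE, col.names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  args <- list(con, header = header, sep = "\t", quote = "",
               stringsAsFactors = FALSE, comment.char = "",
               blank.lines.skip = TRUE)
  if (!is.null(col.names)) args$col.names <- col.names
  df <- tryCatch(do.call(utils::read.table, args),
                 error = function(e) {
                   if (grepl("no lines available", conditionMessage(e)))
                     return(NULL)
                   stop("failed to parse ", path, ": ", conditionMessage(e),
                        call. = FALSE)
                 })
  df
}

write_tsv_file <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE, na = ".",
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Read a FitHiC-style contact table
#'
#' Expects a header line and five columns: `chrom1`, `mid1`, `chrom2`,
#' `mid2`, `count` (FitHiC's `chr1/fragmentMid1/chr2/fragmentMid2/
#' contactCount` names are accepted too).
#'
#' @param path TSV path (optionally gzipped).
#' @return `data.table` with canonical column names.
#' @export
read_contacts <- function(path) {
  df <- read_tsv_file(path)
  if (is.null(df))
    stop("contact file is empty (no header): ", path, call. = FALSE)
  fithic <- c(chr1 = "chrom1", fragmentMid1 = "mid1", chr2 = "chrom2",
              fragmentMid2 = "mid2", contactCount = "count")
  names(df)[names(df) %in% names(fithic)] <- fithic[names(df)[names(df) %in% names(fithic)]]
  req <- c("chrom1", "mid1", "chrom2", "mid2", "count")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("contact file lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  dt <- data.table::as.data.table(df[req])
  if (nrow(dt) == 0L) warning("contact file has a header but no rows: ", path)
  bad <- which(!is.finite(dt$count) | dt$count < 0 | !is.finite(dt$mid1) |
                 !is.finite(dt$mid2))
  if (length(bad))
    stop("malformed contact rows (line ", paste(bad + 1L, collapse = ", "),
         "): counts/midpoints must be non-negative numbers", call. = FALSE)
  dt
}

#' Write a contact table
#' @param contacts Contact `data.table`.
#' @param path Output path.
#' @export
write_contacts <- function(contacts, path) {
  write_tsv_file(data.table::as.data.table(contacts), path)
}

#' Read a GWAS summary table
#'
#' TSV with header `snp_id`, `chrom`, `pos`, `pvalue` (`pos_1based` is
#' accepted for `pos`). Positions are 1-based as published; rows with
#' p-values outside `(0, 1]` or positions `< 1` are rejected with their
#' line numbers.
#'
#' @param path TSV path (optionally gzipped).
#' @return `data.table` with columns `snp_id`, `chrom`, `pos`, `pvalue`.
#' @export
read_gwas <- function(path) {
  df <- read_tsv_file(path)
  if (is.null(df)) stop("GWAS file is empty (no header): ", path, call. = FALSE)
  names(df)[names(df) == "pos_1based"] <- "pos"
  req <- c("snp_id", "chrom", "pos", "pvalue")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("GWAS file lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  dt <- data.table::as.data.table(df[req])
  if (nrow(dt) == 0L) {
    warning("GWAS file has a header but no rows: ", path)
    return(dt)
  }
  suppressWarnings({
    dt[, pos := as.numeric(pos)]
    dt[, pvalue := as.numeric(pvalue)]
  })
  bad <- which(is.na(dt$pvalue) | dt$pvalue <= 0 | dt$pvalue > 1 |
                 is.na(dt$pos) | dt$pos < 1)
  if (length(bad))
    stop("malformed GWAS rows (line ", paste(bad + 1L, collapse = ", "),
         "): p-values must lie in (0, 1] and positions must be >= 1",
         call. = FALSE)
  dt[, chrom := normalize_chrom(chrom)]
  dt[]
}

#' Write a GWAS summary table
#' @param snps SNP `data.table`.
#' @param path Output path.
#' @export
write_gwas <- function(snps, path) {
  dt <- data.table::as.data.table(snps)[, .(snp_id, chrom, pos, pvalue)]
  write_tsv_file(dt, path)
}

#' Read a BED-plus regulatory-element table
#'
#' Nine tab-separated columns without a header (lines starting with `#` or
#' a `chrom` header line are skipped): `chrom`, `start`, `end`, `id`,
#' `kind` (`enhancer`/`tfbs`), `da_score` or `.`, `disease_associated`
#' (`1`/`0`/`TRUE`/`FALSE`) or `.`, `tf_name` or `.`, comma-separated
#' target genes or `.`. Coordinates are BED (0-based half-open) by default;
#' `coords = "one_based"` converts 1-based inclusive tables at ingest.
#'
#' @param path BED-plus path (optionally gzipped).
#' @param coords `"bed"` (default) or `"one_based"`.
#' @return `data.table` with typed columns.
#' @export
read_elements <- function(path, coords = c("bed", "one_based")) {
  coords <- match.arg(coords)
  cols <- c("chrom", "start", "end", "id", "kind", "da_score",
            "disease_associated", "tf_name", "target_genes")
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  lines <- readLines(con); close(con)
  keep <- !grepl("^#", lines) & nzchar(lines) & !grepl("^chrom\t", lines)
  if (!any(keep)) {
    warning("element file has no data rows: ", path)
    return(data.table::data.table(chrom = character(0), start = numeric(0),
                                  end = numeric(0), id = character(0),
                                  kind = character(0), da_score = numeric(0),
                                  disease_associated = logical(0),
                                  tf_name = character(0),
                                  target_genes = character(0)))
  }
  df <- utils::read.table(text = lines[keep], sep = "\t", quote = "",
                          stringsAsFactors = FALSE, col.names = cols,
                          na.strings = ".")
  dt <- data.table::as.data.table(df)
  dt[, `:=`(start = as.numeric(start), end = as.numeric(end),
            da_score = as.numeric(da_score))]
  dt[, disease_associated := as.logical(disease_associated)]
  dt[, target_genes := ifelse(is.na(target_genes), "", target_genes)]
  if (coords == "one_based") dt[, start := start - 1]
  line_no <- which(keep)
  bad <- which(is.na(dt$start) | is.na(dt$end) | dt$start < 0 |
                 dt$end <= dt$start | !dt$kind %in% c("enhancer", "tfbs") |
                 (is.na(dt$da_score) & is.na(dt$disease_associated)) |
                 (dt$kind == "tfbs" & is.na(dt$tf_name)))
  if (length(bad))
    stop("malformed element rows (line ", paste(line_no[bad], collapse = ", "),
         "): need 0 <= start < end, kind in {enhancer, tfbs}, a DA score or ",
         "flag, and a tf_name for tfbs rows", call. = FALSE)
  if (anyDuplicated(dt$id))
    stop("duplicate element ids: ",
         paste(unique(dt$id[duplicated(dt$id)]), collapse = ", "), call. = FALSE)
  dt[, chrom := normalize_chrom(chrom)]
  dt[]
}

#' Write a BED-plus regulatory-element table
#' @param elements Element `data.table`.
#' @param path Output path.
#' @export
write_elements <- function(elements, path) {
  dt <- data.table::as.data.table(elements)[
    , .(chrom, start, end, id, kind, da_score,
        disease_associated = ifelse(is.na(disease_associated), NA_integer_,
                                    as.integer(disease_associated)),
        tf_name,
        target_genes = ifelse(nzchar(target_genes), target_genes, NA_character_))]
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE, na = ".",
                     col.names = FALSE,
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Read a gene disease-association score table
#'
#' TSV with header `symbol`, `da_score`.
#'
#' @param path TSV path (optionally gzipped).
#' @return `data.table`.
#' @export
read_genes <- function(path) {
  df <- read_tsv_file(path)
  if (is.null(df)) stop("gene file is empty (no header): ", path, call. = FALSE)
  miss <- setdiff(c("symbol", "da_score"), names(df))
  if (length(miss))
    stop("gene file lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  dt <- data.table::as.data.table(df[c("symbol", "da_score")])
  if (nrow(dt) == 0L) {
    warning("gene file has a header but no rows: ", path)
    return(dt)
  }
  suppressWarnings(dt[, da_score := as.numeric(da_score)])
  bad <- which(is.na(dt$da_score) | dt$da_score < 0)
  if (length(bad))
    stop("malformed gene rows (line ", paste(bad + 1L, collapse = ", "),
         "): DA scores must be non-negative numbers", call. = FALSE)
  dt[]
}

#' Write a gene score table
#' @param genes Gene `data.table`.
#' @param path Output path.
#' @export
write_genes <- function(genes, path) {
  write_tsv_file(data.table::as.data.table(genes)[, .(symbol, da_score)], path)
}

#' Write labeled TADs as BED
#'
#' Columns: chrom, start, end, id, label.
#'
#' @param tads Labeled TAD table.
#' @param path Output path.
#' @export
write_tads_bed <- function(tads, path) {
  dt <- data.table::as.data.table(tads)[, .(chrom, start, end, tad_id, label)]
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE, col.names = FALSE,
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}
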