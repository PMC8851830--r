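# Seeded synthetic-data generator with recorded ground truth.
#
# Contact model: the expected count of an intra-chromosomal bin pair at
# separation d bins is
#   mu_ij = A * max(1, d)^(-alpha) * (1 + tau * [same planted TAD])
#                                  * (1 + lambda * [planted loop]),
# with Poisson (default) or negative-binomial noise. Planted TADs partition
# each chromosome, as real domains tile chromosomes, so the within-domain
# enrichment is absorbed into the distance expectation and only planted
# loops stand out genome-wide. High-risk SNPs are placed in loop-anchor
# bins; regulatory elements at the opposite loop end receive
# "associated" DA draws while all other elements receive "background"
# draws, emulating the situation where spatial (3D) partners of risk
# variants are more disease-relevant than their linear neighborhoods.

#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by
#' [simulate_matrix()], [simulate_annotations()] and [simulate_study()].
#'
#' @param chrom_bins Named integer vector: bins per chromosome
#'   (default one 2,000-bin chromosome).
#' @param resolution Bin size in bp (default 10,000).
#' @param A Base contact intensity: expected count of an unenriched pair at
#'   1-bin separation (default 200, the near-diagonal depth of a deeply
#'   sequenced 5-10 kbp map, and deep enough that a `lambda = 5` loop at the
#'   longest planted range stays detectable genome-wide).
#' @param alpha Power-law distance-decay exponent (default 1.0).
#' @param n_tads Planted TADs per chromosome; `"auto"` plants roughly one
#'   per 100 bins (1 Mbp domains at 10 kbp resolution).
#' @param tau Within-TAD contact enrichment (default 2.0).
#' @param min_tad_bins Minimum planted TAD width in bins (default 10).
#' @param n_loops Number of planted loops (default 40).
#' @param lambda Loop contact enrichment (default 5.0).
#' @param loop_dist_bins Range of loop separations in bins (default 10-50,
#'   i.e. 100-500 kbp at the default resolution).
#' @param noise `"poisson"` (default) or `"nb"` (negative binomial).
#' @param nb_dispersion NB dispersion (`size = 1/nb_dispersion`).
#' @param inter_mu Expected count per inter-chromosomal pair (used only with
#'   more than one chromosome; default 0.01).
#' @param n_snps Total SNPs (default 300).
#' @param n_high_risk SNPs placed at loop anchors with p-values below the
#'   genome-wide threshold (default 60).
#' @param n_enhancers,n_tfbs Background elements scattered over the genome
#'   (defaults 300 and 200).
#' @param enh_len,tf_len Element length ranges in bp.
#' @param mu_bg,mu_assoc,sigma DA-score model: background draws from
#'   `N(mu_bg, sigma)` and associated draws from `N(mu_assoc, sigma)`, both
#'   truncated at 0 (defaults 2.5, 5.0, 0.5).
#' @param p_tf_bg,p_tf_assoc Bernoulli rates of the TF disease-associated
#'   flag for background and associated TF binding sites (0.33 / 0.67).
#' @param tf_score_mode `"flag"` (TFs carry only the binary flag, as for
#'   prostate TF sets) or `"score"` (TFs carry numeric DA scores).
#' @param targets_range Targets per element, uniform integer range
#'   (default 1-3).
#' @param n_genes Gene pool size (default 200).
#' @param frac_assoc_genes Fraction of the gene pool reserved for targets of
#'   associated elements (default 0.25).
#' @param tad_da_shift Additive DA shift for elements inside SNP-rich
#'   planted TADs (default 0: the loop-mapping effect and the
#'   TAD-stratification effect are orthogonal toggles).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(chrom_bins = c(chr1 = 2000L), resolution = 10000,
                       A = 200, alpha = 1.0,
                       n_tads = "auto", tau = 2.0, min_tad_bins = 10L,
                       n_loops = 40L, lambda = 5.0,
                       loop_dist_bins = c(10L, 50L),
                       noise = c("poisson", "nb"), nb_dispersion = 0.2,
                       inter_mu = 0.01,
                       n_snps = 300L, n_high_risk = 60L,
                       n_enhancers = 300L, n_tfbs = 200L,
                       enh_len = c(200L, 2000L), tf_len = c(10L, 20L),
                       mu_bg = 2.5, mu_assoc = 5.0, sigma = 0.5,
                       p_tf_bg = 0.33, p_tf_assoc = 0.67,
                       tf_score_mode = c("flag", "score"),
                       targets_range = c(1L, 3L),
                       n_genes = 200L, frac_assoc_genes = 0.25,
                       tad_da_shift = 0) {
  noise <- match.arg(noise)
  tf_score_mode <- match.arg(tf_score_mode)
  if (is.null(names(chrom_bins)) || any(!nzchar(names(chrom_bins))))
    stop("'chrom_bins' must be a named vector", call. = FALSE)
  if (any(chrom_bins < 2)) stop("each chromosome needs >= 2 bins", call. = FALSE)
  if (resolution <= 0) stop("'resolution' must be positive", call. = FALSE)
  if (A <= 0 || alpha < 0) stop("'A' must be > 0 and 'alpha' >= 0", call. = FALSE)
  if (tau < 0 || lambda < 0) stop("'tau' and 'lambda' must be >= 0", call. = FALSE)
  if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  if (n_loops < 0 || n_snps < 0 || n_high_risk < 0)
    stop("counts must be non-negative", call. = FALSE)
  if (n_high_risk > n_snps) stop("'n_high_risk' cannot exceed 'n_snps'", call. = FALSE)
  if (any(loop_dist_bins < 1) || loop_dist_bins[1] > loop_dist_bins[2])
    stop("'loop_dist_bins' must be an increasing range of >= 1", call. = FALSE)
  if (p_tf_bg < 0 || p_tf_bg > 1 || p_tf_assoc < 0 || p_tf_assoc > 1)
    stop("TF flag rates must lie in [0, 1]", call. = FALSE)
  if (identical(n_tads, "auto"))
    n_tads <- pmax(1L, as.integer(round(chrom_bins / 100)))
  n_tads <- rep_len(as.integer(n_tads), length(chrom_bins))
  if (any(n_tads < 1)) stop("'n_tads' must be >= 1", call. = FALSE)
  structure(list(
    chrom_bins = chrom_bins, resolution = resolution, A = A, alpha = alpha,
    n_tads = n_tads, tau = tau, min_tad_bins = as.integer(min_tad_bins),
    n_loops = as.integer(n_loops), lambda = lambda,
    loop_dist_bins = as.integer(loop_dist_bins), noise = noise,
    nb_dispersion = nb_dispersion, inter_mu = inter_mu,
    n_snps = as.integer(n_snps), n_high_risk = as.integer(n_high_risk),
    n_enhancers = as.integer(n_enhancers), n_tfbs = as.integer(n_tfbs),
    enh_len = as.integer(enh_len), tf_len = as.integer(tf_len),
    mu_bg = mu_bg, mu_assoc = mu_assoc, sigma = sigma,
    p_tf_bg = p_tf_bg, p_tf_assoc = p_tf_assoc,
    tf_score_mode = tf_score_mode, targets_range = as.integer(targets_range),
    n_genes = as.integer(n_genes), frac_assoc_genes = frac_assoc_genes,
    tad_da_shift = tad_da_shift), class = "sim_config")
}

# Internal: planted TAD boundaries (bin ordinals after which a boundary
# falls, 1-based) for one chromosome.
plant_boundaries <- function(n_bins, n_tads, min_width) {
  if (n_tads <= 1L) return(integer(0))
  # boundaries on a grid guaranteeing the minimum width
  slots <- seq(min_width, n_bins - min_width, by = min_width)
  if (length(slots) < n_tads - 1L)
    stop("chromosome too short for the requested TAD count", call. = FALSE)
  sort(sample(slots, n_tads - 1L))
}

#' Simulate a binned Hi-C contact map with planted TADs and loops
#'
#' Draws the full intra-chromosomal pair grid (zero counts included, so the
#' records define a calibrated analysis universe for [score_contacts()]) and,
#' with more than one chromosome, a flat inter-chromosomal background.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; identical `(config, seed)` reproduce the
#'   simulation exactly.
#' @return List with `contacts` (`chrom1`, `mid1`, `chrom2`, `mid2`,
#'   `count`) and `truth` (per-chromosome boundary bins, TAD table, loop
#'   table).
#' @export
simulate_matrix <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  res <- config$resolution
  chroms <- names(config$chrom_bins)
  truth_bound <- list()
  tad_tabs <- list()
  parts <- list()
  tad_of <- list()
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    n <- as.integer(config$chrom_bins[[ci]])
    b <- plant_boundaries(n, config$n_tads[ci], config$min_tad_bins)
    truth_bound[[ch]] <- b
    edges <- c(0L, b, n)
    ids <- rep(seq_len(length(edges) - 1L), diff(edges))
    tad_of[[ch]] <- ids
    tad_tabs[[ch]] <- data.table::data.table(
      chrom = ch, tad = seq_len(length(edges) - 1L),
      start_bin = utils::head(edges, -1L), end_bin = edges[-1L])
    d <- sequence((n - 1L):1L)                       # 1,2,..,n-1, 1,2,..,n-2, ...
    i <- rep(seq_len(n - 1L), (n - 1L):1L)
    j <- i + d
    mu <- config$A * d^(-config$alpha) *
      (1 + config$tau * (ids[i] == ids[j]))
    parts[[ch]] <- data.table::data.table(
      chrom1 = ch, bin1 = i - 1L, chrom2 = ch, bin2 = j - 1L, mu = mu)
  }
  dt <- data.table::rbindlist(parts)
  # planted loops: distinct anchor bins across all loop ends
  loops <- data.table::data.table(chrom = character(0), bin_a = integer(0),
                                  bin_b = integer(0))
  if (config$n_loops > 0L) {
    probs <- config$chrom_bins / sum(config$chrom_bins)
    got <- 0L; used <- character(0); tries <- 0L
    la <- integer(0); lb <- integer(0); lc <- character(0)
    while (got < config$n_loops && tries < 50L * config$n_loops) {
      tries <- tries + 1L
      ch <- sample(chroms, 1L, prob = probs)
      n <- config$chrom_bins[[ch]]
      dmax <- min(config$loop_dist_bins[2L], n - 1L)
      dmin <- min(config$loop_dist_bins[1L], dmax)
      dd <- sample(dmin:dmax, 1L)
      a <- sample.int(n - dd, 1L) - 1L
      bnd <- a + dd
      k1 <- paste(ch, a); k2 <- paste(ch, bnd)
      if (k1 %in% used || k2 %in% used) next
      used <- c(used, k1, k2)
      la <- c(la, a); lb <- c(lb, bnd); lc <- c(lc, ch)
      got <- got + 1L
    }
    if (got < config$n_loops)
      stop("could not place the requested number of loops", call. = FALSE)
    loops <- data.table::data.table(chrom = lc, bin_a = la, bin_b = lb)
    dt[loops, mu := mu * (1 + config$lambda),
       on = c(chrom1 = "chrom", bin1 = "bin_a", bin2 = "bin_b")]
  }
  # inter-chromosomal background
  if (length(chroms) > 1L && config$inter_mu > 0) {
    inter <- list()
    for (a in seq_len(length(chroms) - 1L)) for (b in (a + 1L):length(chroms)) {
      na <- config$chrom_bins[[a]]; nb <- config$chrom_bins[[b]]
      inter[[length(inter) + 1L]] <- data.table::data.table(
        chrom1 = chroms[a], bin1 = rep(seq_len(na) - 1L, each = nb),
        chrom2 = chroms[b], bin2 = rep(seq_len(nb) - 1L, times = na),
        mu = config$inter_mu)
    }
    dt <- data.table::rbindlist(c(list(dt), inter))
  }
  dt[, count := if (config$noise == "poisson") stats::rpois(.N, mu) else
    stats::rnbinom(.N, mu = mu, size = 1 / config$nb_dispersion)]
  dt[, `:=`(mid1 = bin_start(bin1, res) + res / 2,
            mid2 = bin_start(bin2, res) + res / 2)]
  contacts <- dt[, .(chrom1, mid1, chrom2, mid2, count)]
  truth <- list(boundaries = truth_bound,
                tads = data.table::rbindlist(tad_tabs),
                loops = loops)
  list(contacts = contacts, truth = truth)
}

# Internal: truncated-at-zero normal draws.
rnorm_trunc0 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < 0]
  }
  x
}

#' Simulate GWAS variants, regulatory elements and gene scores
#'
#' High-risk SNPs are placed inside loop-anchor bins (one designated end per
#' loop, reused round-robin when there are more high-risk SNPs than loops;
#' an error is raised when they outnumber the anchor bins, i.e.
#' `2 * n_loops`) with p-values drawn log-uniformly in `[1e-30, 5e-8]`;
#' remaining SNPs land anywhere with p-values in `(5e-8, 1]`. Each
#' SNP-designated anchor bin receives one background enhancer and one
#' background TF binding site (the variant's linear regulatory
#' neighborhood); each opposite loop end receives one associated enhancer
#' and one associated TF binding site; further background elements are
#' scattered uniformly. Elements inside planted TADs that carry a high-risk
#' SNP additionally receive the `tad_da_shift` on their numeric scores.
#' Target genes are drawn from class-matched pools whose DA scores follow
#' the element's class.
#'
#' @param config A [sim_config()] object.
#' @param truth Truth record from [simulate_matrix()].
#' @param seed Integer seed.
#' @return List with `snps`, `elements`, `genes` tables and an extended
#'   `truth` (adds SNP-to-partner-bin assignments and element classes).
#' @export
simulate_annotations <- function(config, truth, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  res <- config$resolution
  chroms <- names(config$chrom_bins)
  loops <- truth$loops
  if (config$n_high_risk > 0L) {
    if (nrow(loops) == 0L)
      stop("cannot place high-risk SNPs without planted loop anchors",
           call. = FALSE)
    if (config$n_high_risk > 2L * nrow(loops))
      stop("more high-risk SNPs than loop-anchor bins", call. = FALSE)
  }
  # designated SNP end per loop (the other end carries associated elements)
  snp_end <- if (nrow(loops)) sample(c("a", "b"), nrow(loops), replace = TRUE)
             else character(0)
  loops2 <- data.table::copy(loops)
  loops2[, `:=`(snp_bin = ifelse(snp_end == "a", bin_a, bin_b),
                partner_bin = ifelse(snp_end == "a", bin_b, bin_a))]
  # --- SNPs ---
  snps <- data.table::data.table(snp_id = character(0), chrom = character(0),
                                 pos = numeric(0), pvalue = numeric(0))
  assign <- data.table::data.table(snp_id = character(0), chrom = character(0),
                                   snp_bin = integer(0), partner_bin = integer(0))
  if (config$n_high_risk > 0L) {
    li <- rep(seq_len(nrow(loops2)), length.out = config$n_high_risk)
    pos <- bin_start(loops2$snp_bin[li], res) + sample.int(res, config$n_high_risk,
                                                           replace = TRUE)
    hr <- data.table::data.table(
      snp_id = sprintf("rs_hr_%03d", seq_len(config$n_high_risk)),
      chrom = loops2$chrom[li], pos = pos,
      pvalue = 10^stats::runif(config$n_high_risk, -30, log10(5e-8)))
    snps <- rbind(snps, hr)
    assign <- data.table::data.table(snp_id = hr$snp_id, chrom = hr$chrom,
                                     snp_bin = loops2$snp_bin[li],
                                     partner_bin = loops2$partner_bin[li])
  }
  n_bg <- config$n_snps - config$n_high_risk
  if (n_bg > 0L) {
    ch <- sample(chroms, n_bg, replace = TRUE,
                 prob = config$chrom_bins / sum(config$chrom_bins))
    span <- config$chrom_bins[ch] * res
    bg <- data.table::data.table(
      snp_id = sprintf("rs_bg_%04d", seq_len(n_bg)), chrom = ch,
      pos = floor(stats::runif(n_bg, 0, span)) + 1,
      pvalue = stats::runif(n_bg, 5e-8, 1))
    bg[pvalue <= 5e-8, pvalue := 1e-7]
    snps <- rbind(snps, bg)
  }
  # --- SNP-rich planted TADs (for the optional DA shift) ---
  tads <- truth$tads
  snp_rich_tad <- rep(FALSE, nrow(tads))
  if (nrow(assign)) {
    for (k in seq_len(nrow(tads))) {
      snp_rich_tad[k] <- any(assign$chrom == tads$chrom[k] &
                               assign$snp_bin >= tads$start_bin[k] &
                               assign$snp_bin < tads$end_bin[k])
    }
  }
  in_snp_rich_tad <- function(chrom, bin) {
    if (!any(snp_rich_tad)) return(rep(FALSE, length(bin)))
    vapply(seq_along(bin), function(k)
      any(snp_rich_tad & tads$chrom == chrom[k] & tads$start_bin <= bin[k] &
            tads$end_bin > bin[k]), logical(1))
  }
  # --- elements ---
  place_in_bin <- function(chrom, bin, len_range, n_each = 1L) {
    len <- sample(len_range[1L]:len_range[2L], length(bin) * n_each,
                  replace = TRUE)
    start <- bin_start(rep(bin, n_each), res) +
      sample.int(res, length(bin) * n_each, replace = TRUE) - 1L
    data.table::data.table(chrom = rep(chrom, n_each), start = start,
                           end = start + len)
  }
  els <- list()
  add_elements <- function(df, kind, class) {
    if (nrow(df) == 0L) return()
    df[, `:=`(kind = kind, class = class)]
    els[[length(els) + 1L]] <<- df
  }
  anchor <- unique(assign[, .(chrom, bin = snp_bin)])
  partner <- unique(assign[, .(chrom, bin = partner_bin)])
  if (nrow(anchor)) {
    add_elements(place_in_bin(anchor$chrom, anchor$bin, config$enh_len),
                 "enhancer", "background")
    add_elements(place_in_bin(anchor$chrom, anchor$bin, config$tf_len),
                 "tfbs", "background")
  }
  if (nrow(partner)) {
    add_elements(place_in_bin(partner$chrom, partner$bin, config$enh_len),
                 "enhancer", "associated")
    add_elements(place_in_bin(partner$chrom, partner$bin, config$tf_len),
                 "tfbs", "associated")
  }
  scatter <- function(n, len_range) {
    ch <- sample(chroms, n, replace = TRUE,
                 prob = config$chrom_bins / sum(config$chrom_bins))
    len <- sample(len_range[1L]:len_range[2L], n, replace = TRUE)
    start <- floor(stats::runif(n, 0, config$chrom_bins[ch] * res - len))
    data.table::data.table(chrom = ch, start = start, end = start + len)
  }
  if (config$n_enhancers > 0L)
    add_elements(scatter(config$n_enhancers, config$enh_len),
                 "enhancer", "background")
  if (config$n_tfbs > 0L)
    add_elements(scatter(config$n_tfbs, config$tf_len), "tfbs", "background")
  edt <- data.table::rbindlist(els)
  if (nrow(edt) == 0L)
    stop("configuration produced no regulatory elements", call. = FALSE)
  edt[, id := sprintf("%s_%05d", ifelse(kind == "enhancer", "enh", "tfbs"),
                      seq_len(.N))]
  # DA scores / flags
  assoc <- edt$class == "associated"
  edt[, da_score := NA_real_]
  edt[, disease_associated := NA]
  is_enh <- edt$kind == "enhancer"
  edt[is_enh & assoc, da_score := rnorm_trunc0(sum(is_enh & assoc),
                                               config$mu_assoc, config$sigma)]
  edt[is_enh & !assoc, da_score := rnorm_trunc0(sum(is_enh & !assoc),
                                                config$mu_bg, config$sigma)]
  if (config$tf_score_mode == "score") {
    edt[!is_enh & assoc, da_score := rnorm_trunc0(sum(!is_enh & assoc),
                                                  config$mu_assoc, config$sigma)]
    edt[!is_enh & !assoc, da_score := rnorm_trunc0(sum(!is_enh & !assoc),
                                                   config$mu_bg, config$sigma)]
  } else {
    edt[!is_enh, disease_associated := as.logical(
      stats::rbinom(sum(!is_enh), 1,
                    ifelse(assoc[!is_enh], config$p_tf_assoc, config$p_tf_bg)))]
  }
  # optional TAD-level shift on numeric scores
  if (config$tad_da_shift != 0) {
    ebin <- bin_index(edt$start + 1, res)
    shift <- in_snp_rich_tad(edt$chrom, ebin)
    edt[shift & !is.na(da_score), da_score := da_score + config$tad_da_shift]
  }
  edt[, tf_name := ifelse(kind == "tfbs",
                          sprintf("TF%02d", (seq_len(.N) %% 25L) + 1L),
                          NA_character_)]
  # --- genes ---
  n_assoc_genes <- max(1L, round(config$n_genes * config$frac_assoc_genes))
  gclass <- rep(c("associated", "background"),
                c(n_assoc_genes, config$n_genes - n_assoc_genes))
  genes <- data.table::data.table(
    symbol = sprintf("G%04d", seq_len(config$n_genes)), class = gclass)
  genes[, da_score := ifelse(class == "associated",
                             rnorm_trunc0(.N, config$mu_assoc, config$sigma),
                             rnorm_trunc0(.N, config$mu_bg, config$sigma))]
  pool_assoc <- genes$symbol[genes$class == "associated"]
  pool_bg <- genes$symbol[genes$class == "background"]
  k <- sample(config$targets_range[1L]:config$targets_range[2L], nrow(edt),
              replace = TRUE)
  edt[, target_genes := vapply(seq_len(.N), function(i) {
    pool <- if (assoc[i]) pool_assoc else pool_bg
    paste(sample(pool, min(k[i], length(pool))), collapse = ",")
  }, character(1))]
  truth$element_class <- edt[, .(id, class)]
  truth$snp_assignments <- assign
  truth$snp_rich_tads <- tads[snp_rich_tad]
  truth$da_means <- c(background = config$mu_bg, associated = config$mu_assoc)
  elements <- edt[, .(chrom, start, end, id, kind, da_score,
                      disease_associated, tf_name, target_genes)]
  list(snps = snps, elements = elements,
       genes = genes[, .(symbol, da_score)], truth = truth)
}

#' Write a complete synthetic study bundle to disk
#'
#' Runs [simulate_matrix()] (seed) and [simulate_annotations()] (seed + 1)
#' and writes the bundle in the pipeline's input formats: a FitHiC-style
#' contact TSV (non-zero pairs), a GWAS TSV, a BED-plus element table, a
#' gene score TSV and a YAML ground-truth record.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of written file paths plus the in-memory
#'   objects.
#' @export
simulate_study <- function(config, seed, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_matrix(config, seed)
  ann <- simulate_annotations(config, sim$truth, seed + 1L)
  paths <- list(contacts = file.path(dir, "contacts.tsv"),
                gwas = file.path(dir, "gwas.tsv"),
                elements = file.path(dir, "elements.bed"),
                genes = file.path(dir, "genes.tsv"),
                truth = file.path(dir, "truth.yaml"))
  write_contacts(sim$contacts[count > 0], paths$contacts)
  write_gwas(ann$snps, paths$gwas)
  write_elements(ann$elements, paths$elements)
  write_genes(ann$genes, paths$genes)
  tr <- ann$truth
  yaml::write_yaml(list(
    seed = seed,
    boundaries = lapply(tr$boundaries, as.integer),
    loops = as.list(tr$loops),
    snp_assignments = as.list(tr$snp_assignments),
    element_class = as.list(tr$element_class),
    da_means = as.list(tr$da_means)), paths$truth)
  invisible(list(paths = paths, contacts = sim$contacts, snps = ann$snps,
                 elements = ann$elements, genes = ann$genes, truth = tr))
}
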