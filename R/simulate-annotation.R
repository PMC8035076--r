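# Synthetic regulatory annotations matched to a simulated genome: gene
# models, per-window differential-enrichment tables (the output a windowed
# differential ChIP analysis would hand over), and gene x genotype
# expression tables with planted tissue-specific enhancer effects.

#' Generate synthetic regulatory annotations
#'
#' Emits a gene model, a 150-bp differential-window table with planted
#' enriched regions for each genotype, and a TPM expression table in which
#' genes targeted by a genotype's planted enhancers are up in that genotype.
#' Planted enhancers are placed so that they are consistent with the
#' enhancer-to-gene assignment rules: they avoid promoter windows, their
#' target is the nearest eligible promoter, and (when the simulation spec
#' carries domains) enhancer and target share a domain. Decoy regions that
#' are enriched in only one pairwise contrast, and enriched regions that
#' overlap promoters, are planted as negative controls for the
#' tissue-specificity filters.
#'
#' @param spec A [sim_spec()] (supplies chromosome sizes and, optionally,
#'   domains used to co-place enhancers and targets).
#' @param genotypes Three genotype labels.
#' @param n_enhancers Planted enhancers per genotype.
#' @param gene_spacing Approximate distance between consecutive genes (bp).
#' @param hk_fraction Fraction of genes flagged as housekeeping.
#' @param effect_meanlog,effect_sdlog Log-normal expression effect of an
#'   active enhancer on its target in the matching genotype.
#' @param window_size Differential-window width (bp).
#' @param n_background Background (null) windows per contrast.
#' @param promoter_flank Promoter half-window used for placement exclusion.
#' @param seed Integer seed.
#' @return List with `genes` (a `gene_model`), `windows` (data.frame:
#'   chrom, start, end, contrast, logFC, FDR; contrasts labelled `"A>B"`),
#'   `expression` (gene x genotype TPM matrix) and `truth` (planted enhancer
#'   `GRanges` per genotype with `target_gene`).
#' @export
generate_regulatory_annotation <- function(spec,
                                           genotypes = c("A", "B", "C"),
                                           n_enhancers = 20,
                                           gene_spacing = 25000,
                                           hk_fraction = 0.3,
                                           effect_meanlog = log(6),
                                           effect_sdlog = 0.3,
                                           window_size = 150,
                                           n_background = 300,
                                           promoter_flank = 500,
                                           seed = 1L) {
  stopifnot(length(genotypes) == 3)
  set.seed(seed)
  sizes <- spec$chrom_sizes

  ## gene model: jittered gene grid along each chromosome
  tss <- list(); chrom <- list(); strand <- list(); glen <- list()
  for (ch in names(sizes)) {
    grid <- seq(gene_spacing, sizes[[ch]] - gene_spacing, by = gene_spacing)
    pos <- grid + round(stats::runif(length(grid), -0.2, 0.2) * gene_spacing)
    chrom[[ch]] <- rep(ch, length(pos))
    tss[[ch]] <- pos
    strand[[ch]] <- sample(c("+", "-"), length(pos), replace = TRUE)
    glen[[ch]] <- round(stats::runif(length(pos), 1000, 4000))
  }
  chrom <- unlist(chrom, use.names = FALSE)
  tss <- unlist(tss, use.names = FALSE)
  strand <- unlist(strand, use.names = FALSE)
  glen <- unlist(glen, use.names = FALSE)
  n_genes <- length(tss)
  gene_id <- sprintf("gene%04d", seq_len(n_genes))
  tx_start <- ifelse(strand == "+", tss, tss - glen + 1)
  tx_end <- ifelse(strand == "+", tss + glen - 1, tss)
  tx <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(pmax(1, tx_start),
                                                pmin(sizes[chrom], tx_end)),
                               strand = strand)
  tx$transcript_id <- paste0(gene_id, ".t1")
  tx$gene_id <- gene_id
  housekeeping <- stats::runif(n_genes) < hk_fraction
  genes <- data.frame(gene_id = gene_id, symbol = gene_id,
                      housekeeping = housekeeping)
  gm <- gene_model(genes, tx)

  ## baseline expression
  tpm <- matrix(0, n_genes, 3, dimnames = list(gene_id, genotypes))
  base <- ifelse(housekeeping,
                 stats::rlnorm(n_genes, log(50), 0.5),
                 stats::rlnorm(n_genes, log(3), 1.2))
  for (g in 1:3) tpm[, g] <- base * stats::rlnorm(n_genes, 0, 0.3)

  ## enhancer placement
  prom <- promoter_windows(gm, flank = promoter_flank)
  tss_gr <- tss_sites(gm)
  candidate <- !housekeeping & rowMeans(tpm) >= 1
  placeable <- which(!housekeeping & rowMeans(tpm) >= 2)
  used <- logical(n_genes)
  enh_truth <- list()
  for (g in genotypes) {
    got <- GenomicRanges::GRanges()
    targets <- character()
    pool <- sample(setdiff(placeable, which(used)))
    for (gi in pool) {
      if (length(targets) >= n_enhancers) break
      e <- try_place_enhancer(gi, gm, tss_gr, prom, candidate, spec, sizes)
      if (is.null(e)) next
      used[gi] <- TRUE
      got <- suppressWarnings(c(got, e))
      targets <- c(targets, gene_id[gi])
    }
    got$target_gene <- targets
    enh_truth[[g]] <- got
    ## expression effect in the matching genotype
    m <- match(targets, gene_id)
    tpm[m, g] <- tpm[m, g] * stats::rlnorm(length(m), effect_meanlog,
                                           effect_sdlog)
  }

  ## differential-window table; null/decoy windows represent constitutive
  ## acetylated regions elsewhere and are kept clear of planted enhancers so
  ## the planted truth is internally consistent with the merging rules
  planted <- suppressWarnings(do.call(c, unname(lapply(enh_truth,
                                                       GenomicRanges::granges))))
  keep_clear <- GenomicRanges::resize(planted,
                                      width = GenomicRanges::width(planted) +
                                        2000, fix = "center")
  others <- function(g) setdiff(genotypes, g)
  rows <- list()
  add_windows <- function(region, contrast, lfc_mean, sig) {
    w <- tile_windows(region, window_size)
    k <- length(w)
    data.frame(chrom = as.character(GenomicRanges::seqnames(w)),
               start = GenomicRanges::start(w) - 1L,
               end = GenomicRanges::end(w),
               contrast = contrast,
               logFC = stats::rnorm(k, lfc_mean, 0.3),
               FDR = if (sig) 10^-stats::runif(k, 3, 8)
                     else stats::runif(k, 0.1, 1))
  }
  for (g in genotypes) {
    oth <- others(g)
    for (e in seq_along(enh_truth[[g]])) {
      reg <- enh_truth[[g]][e]
      for (h in oth)
        rows[[length(rows) + 1]] <-
          add_windows(reg, paste0(g, ">", h), 2, TRUE)
    }
    ## decoys enriched vs one genotype only
    for (k in seq_len(3)) {
      reg <- random_region(sizes, 400, avoid = keep_clear)
      rows[[length(rows) + 1]] <-
        add_windows(reg, paste0(g, ">", oth[1]), 2, TRUE)
    }
    ## enriched regions overlapping a promoter (excluded downstream)
    pg <- sample(which(!used & !housekeeping), 2)
    for (gi in pg) {
      reg <- GenomicRanges::resize(tss_gr[gi], width = 600, fix = "center")
      for (h in oth)
        rows[[length(rows) + 1]] <-
          add_windows(GenomicRanges::granges(reg), paste0(g, ">", h), 2, TRUE)
    }
    ## null background windows
    for (h in oth) {
      reg <- random_region(sizes, window_size * 2, n = n_background,
                           avoid = keep_clear)
      rows[[length(rows) + 1]] <- add_windows(reg, paste0(g, ">", h), 0, FALSE)
    }
  }
  windows <- do.call(rbind, rows)
  windows <- windows[order(windows$contrast, windows$chrom, windows$start), ]
  rownames(windows) <- NULL

  list(genes = gm, windows = windows, expression = tpm,
       truth = list(enhancers = enh_truth))
}

# Place one enhancer near the TSS of gene gi; NULL if constraints cannot be
# met after a bounded number of draws.
try_place_enhancer <- function(gi, gm, tss_gr, prom, candidate, spec, sizes,
                               tries = 50) {
  t_tss <- tss_gr[gm$transcripts$gene_id == gm$genes$gene_id[gi]][1]
  ch <- as.character(GenomicRanges::seqnames(t_tss))
  t_pos <- GenomicRanges::start(t_tss)
  dom <- spec$domains
  my_dom <- if (!is.null(dom))
    GenomicRanges::findOverlaps(t_tss, dom, select = "first") else NA
  other_tss <- tss_gr[candidate[match(gm$transcripts$gene_id,
                                      gm$genes$gene_id)] &
                        gm$transcripts$gene_id != gm$genes$gene_id[gi]]
  for (k in seq_len(tries)) {
    w <- round(stats::runif(1, 300, 1500))
    d <- round(stats::runif(1, 2500, 10000))
    side <- sample(c(-1, 1), 1)
    start <- t_pos + side * d - round(w / 2)
    if (start < 1 || start + w - 1 > sizes[[ch]]) next
    e <- GenomicRanges::GRanges(ch, IRanges::IRanges(start, width = w))
    if (length(GenomicRanges::findOverlaps(e, prom))) next
    d_target <- GenomicRanges::distance(e, t_tss)
    d_other <- suppressWarnings(
      min(GenomicRanges::distance(e, other_tss), na.rm = TRUE))
    if (is.finite(d_other) && d_other <= d_target) next
    if (!is.null(dom)) {
      e_dom <- GenomicRanges::findOverlaps(e, dom, select = "first")
      if (is.na(my_dom) || is.na(e_dom) || e_dom != my_dom) next
    }
    return(e)
  }
  NULL
}

random_region <- function(sizes, width, n = 1, avoid = NULL, tries = 20) {
  draw <- function(k) {
    ch <- sample(names(sizes), k, replace = TRUE)
    start <- floor(stats::runif(k, 1, sizes[ch] - width))
    GenomicRanges::GRanges(ch, IRanges::IRanges(start, width = width))
  }
  gr <- draw(n)
  if (!is.null(avoid) && length(avoid)) {
    for (t in seq_len(tries)) {
      bad <- which(IRanges::overlapsAny(gr, avoid))
      if (!length(bad)) break
      gr[bad] <- draw(length(bad))
    }
  }
  gr
}

# Fixed-grid windows overlapping each region (grid anchored at coordinate 0).
tile_windows <- function(regions, window_size) {
  pieces <- lapply(seq_along(regions), function(i) {
    s <- GenomicRanges::start(regions)[i] - 1L  # 0-based
    e <- GenomicRanges::end(regions)[i]
    starts <- seq(floor(s / window_size) * window_size, e - 1,
                  by = window_size)
    GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(regions))[i],
      IRanges::IRanges(starts + 1, width = window_size))
  })
  suppressWarnings(do.call(c, pieces))
}
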