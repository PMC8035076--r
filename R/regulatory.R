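# From per-window differential-enrichment statistics to tissue-specific
# candidate enhancers, their target genes, and expression validation.

#' Merge differential windows into signed regions
#'
#' Windows of one contrast are merged when their gaps are at most `tol_bp`;
#' merged runs longer than `max_width_bp` are split left-to-right into
#' near-equal-count chunks no wider than `max_width_bp`. The region-level
#' FDR is the Simes combination of member-window FDRs; regions are kept when
#' that FDR is below `fdr_max` and all member log-fold-changes share one
#' sign, which becomes the region sign.
#'
#' @param table data.frame with columns `chrom`, `start` (0-based), `end`,
#'   `contrast`, `logFC`, `FDR`.
#' @param contrast Contrast label to extract (e.g. `"A>B"`).
#' @param tol_bp,max_width_bp,fdr_max Merge tolerance, maximum region width
#'   and FDR threshold.
#' @return `GRanges` with `fdr`, `sign` and `n_windows` columns.
#' @export
merge_windows <- function(table, contrast, tol_bp = 100, max_width_bp = 5000,
                          fdr_max = 0.05) {
  t <- table[table$contrast == contrast, , drop = FALSE]
  if (!nrow(t)) return(empty_regions())
  t <- unique(t[order(t$chrom, t$start), ])
  out <- list()
  for (ch in unique(t$chrom)) {
    d <- t[t$chrom == ch, , drop = FALSE]
    cl <- cumsum(c(1, d$start[-1] - cummax(d$end)[-nrow(d)] > tol_bp))
    for (g in unique(cl)) {
      dd <- d[cl == g, , drop = FALSE]
      for (chunk in split_chunks(dd, max_width_bp)) {
        fdr <- simes(chunk$FDR)
        sgn <- sign(chunk$logFC)
        if (is.na(fdr) || fdr >= fdr_max) next
        if (length(unique(sgn[sgn != 0])) != 1) next
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = min(chunk$start), end = max(chunk$end),
          fdr = fdr, sign = unique(sgn[sgn != 0]),
          n_windows = nrow(chunk))
      }
    }
  }
  if (!length(out)) return(empty_regions())
  o <- do.call(rbind, out)
  gr <- GenomicRanges::GRanges(o$chrom,
                               IRanges::IRanges(o$start + 1, o$end))
  gr$fdr <- o$fdr; gr$sign <- o$sign; gr$n_windows <- o$n_windows
  sort(gr)
}

empty_regions <- function() {
  gr <- GenomicRanges::GRanges()
  gr$fdr <- numeric(); gr$sign <- numeric(); gr$n_windows <- integer()
  gr
}

# Split a merged window run into consecutive near-equal-count chunks, using
# the smallest chunk count for which every chunk span is <= max_width_bp.
split_chunks <- function(dd, max_width_bp) {
  span <- max(dd$end) - min(dd$start)
  if (span <= max_width_bp) return(list(dd))
  for (k in seq(ceiling(span / max_width_bp), nrow(dd))) {
    grp <- ceiling(seq_len(nrow(dd)) / (nrow(dd) / k))
    chunks <- split(dd, grp)
    if (all(vapply(chunks, function(c) max(c$end) - min(c$start), 0) <=
              max_width_bp))
      return(chunks)
  }
  split(dd, seq_len(nrow(dd)))  # one window per chunk always satisfies
}

#' Tissue-specific candidate enhancer sets
#'
#' The set for genotype A is the span intersection of the positive regions of
#' the A-vs-B and A-vs-C contrasts, minus any region overlapping a promoter
#' window.
#'
#' @param regions Named list of signed region `GRanges` keyed `"A>B"`,
#'   `"A>C"`, ... (six contrasts for three genotypes); only positive-sign
#'   regions are used.
#' @param genotypes Three genotype labels.
#' @param promoters `GRanges` of promoter windows (see [promoter_windows()]).
#' @return Named list (genotype -> `GRanges`).
#' @export
tissue_specific_regions <- function(regions, genotypes, promoters) {
  stopifnot(length(genotypes) == 3)
  out <- list()
  for (g in genotypes) {
    oth <- setdiff(genotypes, g)
    keys <- paste0(g, ">", oth)
    missing <- setdiff(keys, names(regions))
    if (length(missing))
      stop("missing contrast region list: ", paste(missing, collapse = ", "))
    pos <- lapply(keys, function(k) {
      r <- regions[[k]]
      GenomicRanges::granges(r[r$sign > 0])
    })
    inter <- suppressWarnings(GenomicRanges::intersect(pos[[1]], pos[[2]]))
    if (length(promoters))
      inter <- inter[!IRanges::overlapsAny(inter, promoters)]
    out[[g]] <- inter
  }
  out
}

#' Filter candidate target genes
#'
#' Housekeeping-flagged genes and genes whose mean TPM across genotypes is
#' below `min_tpm` are removed. Genes missing from the expression table are
#' treated as TPM 0 with a warning.
#'
#' @param gm A `gene_model`.
#' @param expression Gene x genotype TPM matrix (rownames = gene ids).
#' @param min_tpm Mean-TPM threshold.
#' @return Character vector of candidate gene ids.
#' @export
filter_expressed_genes <- function(gm, expression, min_tpm = 1) {
  ids <- gm$genes$gene_id
  m <- match(ids, rownames(expression))
  if (anyNA(m))
    warning(sum(is.na(m)), " gene(s) missing from the expression table; ",
            "treated as TPM 0")
  mean_tpm <- ifelse(is.na(m), 0, rowMeans(expression)[m])
  ids[!gm$genes$housekeeping & mean_tpm >= min_tpm]
}

#' Assign candidate enhancers to target genes
#'
#' Rules are applied in order and the first applicable rule wins:
#' 1. `overlap_single_transcript`: the enhancer intersects transcripts of
#'    exactly one candidate gene.
#' 2. `closest_no_boundary`: the closest candidate promoter not separated
#'    from the enhancer by a domain boundary.
#' 3. `closest_in_domain`: the closest candidate promoter within the
#'    enhancer's domain.
#' 4. `closest_any`: the unconstrained closest candidate promoter.
#'
#' @param enhancers `GRanges` of candidate enhancers.
#' @param candidates Candidate gene ids from [filter_expressed_genes()].
#' @param gm A `gene_model`.
#' @param boundaries `GRanges` of domain boundaries (blockers for rule 2).
#' @param domains `GRanges` of domains (rule 3).
#' @return data.frame with `chrom`, `start` (0-based), `end`, `gene_id`,
#'   `rule`, `distance`; unassignable enhancers get NA with a warning.
#' @export
assign_enhancers <- function(enhancers, candidates, gm, boundaries,
                             domains) {
  tx <- gm$transcripts[gm$transcripts$gene_id %in% candidates]
  proms <- tss_sites(gm)
  proms <- proms[proms$gene_id %in% candidates]
  gene_id <- rep(NA_character_, length(enhancers))
  rule <- rep(NA_character_, length(enhancers))
  dist <- rep(NA_real_, length(enhancers))
  for (k in seq_along(enhancers)) {
    e <- enhancers[k]
    ov_genes <- unique(tx$gene_id[IRanges::overlapsAny(
      tx, e, ignore.strand = TRUE)])
    if (length(ov_genes) == 1) {
      gene_id[k] <- ov_genes
      rule[k] <- "overlap_single_transcript"
      dist[k] <- 0
      next
    }
    hit <- closest_feature(e, proms, blockers = boundaries)
    if (!is.na(hit)) {
      gene_id[k] <- proms$gene_id[hit]
      rule[k] <- "closest_no_boundary"
      dist[k] <- GenomicRanges::distance(e, proms[hit])
      next
    }
    dom <- GenomicRanges::findOverlaps(e, domains, select = "first")
    if (!is.na(dom)) {
      inside <- which(IRanges::overlapsAny(proms, domains[dom]))
      hit <- closest_feature(e, proms[inside])
      if (!is.na(hit)) {
        gene_id[k] <- proms$gene_id[inside[hit]]
        rule[k] <- "closest_in_domain"
        dist[k] <- GenomicRanges::distance(e, proms[inside[hit]])
        next
      }
    }
    hit <- closest_feature(e, proms)
    if (!is.na(hit)) {
      gene_id[k] <- proms$gene_id[hit]
      rule[k] <- "closest_any"
      dist[k] <- GenomicRanges::distance(e, proms[hit])
    } else {
      warning("no candidate promoter on the chromosome of enhancer ", k)
    }
  }
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(enhancers)),
    start = GenomicRanges::start(enhancers) - 1L,
    end = GenomicRanges::end(enhancers),
    gene_id = gene_id, rule = rule, distance = dist)
}

#' Validate assignments against expression
#'
#' For each genotype's enhancer set, the TPM of the assigned target genes in
#' the matching genotype is compared to the same genes' TPM in each other
#' genotype with a two-sided rank-sum test.
#'
#' @param assignments Named list (genotype -> [assign_enhancers()] output).
#' @param expression Gene x genotype TPM matrix.
#' @return data.frame with `set`, `other`, `n`, `median_ratio`, `p`.
#' @export
validate_assignment_expression <- function(assignments, expression) {
  out <- list()
  for (g in names(assignments)) {
    ids <- assignments[[g]]$gene_id
    ids <- ids[!is.na(ids) & ids %in% rownames(expression)]
    if (length(ids) < 3) {
      warning("fewer than 3 assigned genes for set ", g)
      next
    }
    x <- expression[ids, g]
    for (h in setdiff(colnames(expression), g)) {
      y <- expression[ids, h]
      out[[length(out) + 1]] <- data.frame(
        set = g, other = h, n = length(ids),
        median_ratio = stats::median(x) / stats::median(y),
        p = rank_sum_test(x, y))
    }
  }
  do.call(rbind, out)
}

#' Compare sizes of feature-containing and feature-free domains
#'
#' Domains are classified by >= 1 bp overlap with the features; group mean
#' sizes and a two-sided rank-sum p-value are reported.
#'
#' @param domains `GRanges` of domains.
#' @param features `GRanges` of features (enhancers or DE genes).
#' @return List with `mean_with`, `mean_without`, `n_with`, `n_without`,
#'   `p` (NA with a warning when a group is empty or too small).
#' @export
domain_size_comparison <- function(domains, features) {
  with_f <- IRanges::overlapsAny(domains, features)
  w <- GenomicRanges::width(domains)
  x <- w[with_f]; y <- w[!with_f]
  p <- if (length(x) < 3 || length(y) < 3) {
    warning("a domain group is empty or too small; no test")
    NA_real_
  } else rank_sum_test(x, y)
  list(mean_with = mean(x), mean_without = mean(y),
       n_with = length(x), n_without = length(y), p = p)
}
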