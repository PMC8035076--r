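# Insulation score, boundary calling with scores, multi-parameter consensus
# boundaries, and domain construction.

#' Insulation score
#'
#' For each bin i, the raw score is the mean normalized contact over the
#' square window a in \[i-w, i-1\], b in \[i+1, i+w\]; the reported value is
#' log2(raw / chromosome mean of raw). Values are missing within `window_size`
#' bins of a chromosome edge and where more than half of the flanking bins
#' are masked.
#'
#' @param cm A balanced `contact_matrix`.
#' @param window_size Window size w in bins.
#' @return Bin `GRanges` with a `score` column (NA where undefined);
#'   `metadata()` records `window_size` and `resolution`.
#' @export
insulation_score <- function(cm, window_size) {
  if (window_size < 1) stop("window_size must be >= 1")
  w <- as.integer(window_size)
  norm <- need_normalized(cm)
  idx <- chrom_bin_index(cm$bins)
  values <- rep(NA_real_, length(cm$bins))
  for (ch in names(idx)) {
    ix <- idx[[ch]]
    sub <- norm[ix, ix, drop = FALSE]
    v <- cm$valid[ix]
    n <- length(ix)
    raw <- rep(NA_real_, n)
    if (n >= 2 * w + 1) {
      for (i in (w + 1):(n - w)) {
        flank <- c((i - w):(i - 1), (i + 1):(i + w))
        if (!v[i] || sum(!v[flank]) > w) next  # > 50% of window masked
        block <- sub[(i - w):(i - 1), (i + 1):(i + w), drop = FALSE]
        raw[i] <- mean(block, na.rm = TRUE)
      }
    }
    mu <- mean(raw, na.rm = TRUE)
    if (is.finite(mu) && mu > 0)
      values[ix] <- log2(raw / mu)
  }
  out <- GenomicRanges::granges(cm$bins)
  out$score <- values
  S4Vectors::metadata(out)$window_size <- w
  S4Vectors::metadata(out)$resolution <- bin_size(cm$bins)
  out
}

# delta vector: mean of the next delta_bins values minus mean of the
# previous delta_bins values.
insulation_delta <- function(values, delta_bins) {
  n <- length(values)
  delta <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    after <- (i + 1):(i + delta_bins)
    before <- (i - delta_bins):(i - 1)
    if (min(before) < 1 || max(after) > n) next
    a <- mean(values[after], na.rm = TRUE)
    b <- mean(values[before], na.rm = TRUE)
    delta[i] <- a - b
  }
  delta
}

#' Call insulation boundaries
#'
#' Candidate boundaries sit at insulation minima where the delta vector
#' crosses zero from negative to positive. The boundary score is
#' max(delta over \[i, i+delta_bins\]) - min(delta over \[i-delta_bins, i\]),
#' a measure of the depth of the insulation minimum; boundaries below
#' `min_score` are discarded.
#'
#' @param track Output of [insulation_score()].
#' @param delta_bins Delta parameter in bins.
#' @param min_score Minimum boundary score.
#' @return `GRanges` of one-bin boundaries with a `score` column; metadata is
#'   carried over from the track.
#' @export
call_boundaries <- function(track, delta_bins = 3L, min_score = 0.7) {
  values <- track$score
  chr <- as.character(GenomicRanges::seqnames(track))
  out <- list()
  for (ch in unique(chr)) {
    ix <- which(chr == ch)
    v <- values[ix]
    n <- length(v)
    if (all(is.na(v))) next
    delta <- insulation_delta(v, delta_bins)
    cand <- integer()
    for (i in seq_len(n - 1)) {
      if (is.na(delta[i]) || is.na(delta[i + 1])) next
      if (delta[i] < 0 && delta[i + 1] >= 0) {
        pair <- c(i, i + 1)
        pair <- pair[!is.na(v[pair])]
        if (!length(pair)) next
        cand <- c(cand, pair[which.min(v[pair])])
      }
    }
    if (!length(cand)) next
    score <- vapply(cand, function(i) {
      lo <- max(1, i - delta_bins); hi <- min(n, i + delta_bins)
      after <- delta[i:hi]; before <- delta[lo:i]
      if (all(is.na(after)) || all(is.na(before))) return(NA_real_)
      max(after, na.rm = TRUE) - min(before, na.rm = TRUE)
    }, 0)
    keep <- !is.na(score) & score >= min_score
    if (!any(keep)) next
    b <- track[ix[cand[keep]]]
    b$score <- score[keep]
    out[[ch]] <- b
  }
  if (!length(out)) {
    res <- GenomicRanges::GRanges()
    res$score <- numeric()
  } else {
    res <- suppressWarnings(do.call(c, unname(out)))
  }
  S4Vectors::metadata(res) <- S4Vectors::metadata(track)
  res
}

#' Consensus boundaries over a parameter grid
#'
#' Boundaries called with different (resolution, window size) combinations
#' are clustered by single linkage at `merge_dist`; clusters supported by at
#' least `min_support` distinct combinations are emitted at the median
#' position, snapped to the finest participating resolution.
#'
#' @param boundary_sets List of [call_boundaries()] outputs, each carrying
#'   `resolution` and `window_size` metadata.
#' @param min_support Minimum number of distinct parameter combinations.
#' @param merge_dist Single-linkage distance in bp (default: the coarsest
#'   participating resolution).
#' @return `GRanges` of consensus boundaries (width = finest resolution) with
#'   `support` and `score` (mean member score) columns.
#' @export
consensus_boundaries <- function(boundary_sets, min_support = 4L,
                                 merge_dist = NULL) {
  info <- lapply(boundary_sets, function(b) S4Vectors::metadata(b))
  res <- vapply(info, function(m) as.numeric(m$resolution), 0)
  if (anyNA(res)) stop("boundary sets must carry resolution metadata")
  if (is.null(merge_dist)) merge_dist <- max(res)
  fine <- min(res)
  combo <- paste0(res, "w", vapply(info, function(m)
    as.numeric(m$window_size), 0))
  df <- do.call(rbind, lapply(seq_along(boundary_sets), function(k) {
    b <- boundary_sets[[k]]
    if (!length(b)) return(NULL)
    data.frame(chrom = as.character(GenomicRanges::seqnames(b)),
               mid = (GenomicRanges::start(b) + GenomicRanges::end(b)) / 2,
               score = b$score, combo = combo[k])
  }))
  if (is.null(df) || !nrow(df)) return(GenomicRanges::GRanges())
  out <- list()
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, ]
    d <- d[order(d$mid), ]
    cl <- cumsum(c(1, diff(d$mid) > merge_dist))
    for (g in unique(cl)) {
      dd <- d[cl == g, ]
      support <- length(unique(dd$combo))
      if (support < min_support) next
      pos <- stats::median(dd$mid)
      start <- floor((pos - 1) / fine) * fine + 1
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = start, support = support,
        score = mean(dd$score))
    }
  }
  if (!length(out)) return(GenomicRanges::GRanges())
  o <- do.call(rbind, out)
  gr <- GenomicRanges::GRanges(o$chrom,
                               IRanges::IRanges(o$start, width = fine))
  gr$support <- o$support
  gr$score <- o$score
  sort(gr)
}

#' Pair consecutive boundaries into domains
#'
#' One domain per consecutive boundary pair on the same chromosome; domains
#' outside \[`min_size`, `max_size`\] are removed.
#'
#' @param boundaries Sorted consensus boundary `GRanges`.
#' @param min_size,max_size Size filter in bp.
#' @return `GRanges` of domains.
#' @export
pair_domains <- function(boundaries, min_size = 10000, max_size = 500000) {
  chr <- as.character(GenomicRanges::seqnames(boundaries))
  out <- list()
  for (ch in unique(chr)) {
    b <- sort(boundaries[chr == ch])
    if (length(b) < 2) next
    mids <- floor((GenomicRanges::start(b) + GenomicRanges::end(b)) / 2)
    starts <- mids[-length(mids)]
    ends <- mids[-1]
    gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(starts + 1, ends))
    w <- GenomicRanges::width(gr)
    out[[ch]] <- gr[w >= min_size & w <= max_size]
  }
  if (!length(out)) return(GenomicRanges::GRanges())
  suppressWarnings(do.call(c, unname(out)))
}
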