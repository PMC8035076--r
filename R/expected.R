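# Expected contacts, observed/expected matrices, distance-decay (P(s))
# curves and virtual 4C tracks.

#' Expected contacts by genomic separation
#'
#' Per chromosome, the mean normalized contact value at each distance (in
#' bins), over valid pixels only; pixels touching a masked bin are excluded
#' from both numerator and denominator. Trans expected is the mean of all
#' valid trans pixels per chromosome pair.
#'
#' @param cm A balanced `contact_matrix`.
#' @return An object of class `expected_profile`: a list with `cis` (named
#'   list of per-distance mean vectors, distance 0 ... n-1 bins) and `trans`
#'   (matrix of per-chromosome-pair means).
#' @export
expected_profile <- function(cm) {
  norm <- need_normalized(cm)
  idx <- chrom_bin_index(cm$bins)
  chroms <- names(idx)
  cis <- lapply(chroms, function(ch) {
    i <- idx[[ch]]
    sub <- norm[i, i, drop = FALSE]
    v <- cm$valid[i]
    sub[!v, ] <- NA
    sub[, !v] <- NA
    d <- abs(row(sub) - col(sub))
    num <- rowsum(as.vector(ifelse(is.na(sub), 0, sub)), as.vector(d))
    den <- rowsum(as.vector(!is.na(sub)) + 0, as.vector(d))
    out <- rep(NA_real_, length(i))
    dd <- as.integer(rownames(num))
    out[dd + 1L] <- ifelse(den > 0, num / den, NA_real_)
    out
  })
  names(cis) <- chroms
  trans <- matrix(NA_real_, length(chroms), length(chroms),
                  dimnames = list(chroms, chroms))
  if (length(chroms) > 1) {
    for (a in seq_along(chroms)) for (b in seq_along(chroms)) {
      if (a == b) next
      sub <- norm[idx[[a]], idx[[b]], drop = FALSE]
      sub <- sub[cm$valid[idx[[a]]], cm$valid[idx[[b]]], drop = FALSE]
      trans[a, b] <- mean(sub, na.rm = TRUE)
    }
  }
  structure(list(cis = cis, trans = trans,
                 bin_size = bin_size(cm$bins)),
            class = "expected_profile")
}

need_normalized <- function(cm) {
  if (is.null(cm$normalized))
    stop("contact matrix must be balanced first (kr_balance / ice_balance)")
  cm$normalized
}

#' Observed/expected matrix
#'
#' Each normalized pixel is divided by the expected value at its genomic
#' separation (cis) or by the chromosome-pair mean (trans). Masked-bin pixels
#' are `NA`.
#'
#' @param cm A balanced `contact_matrix`.
#' @param expected Optional precomputed [expected_profile()].
#' @return An object of class `oe_matrix`: list with `bins`, `values`
#'   (dense matrix with `NA` at masked/undefined pixels) and `valid`.
#' @export
observed_expected <- function(cm, expected = NULL) {
  norm <- need_normalized(cm)
  if (is.null(expected)) expected <- expected_profile(cm)
  idx <- chrom_bin_index(cm$bins)
  n <- length(cm$bins)
  oe <- matrix(NA_real_, n, n)
  for (ch in names(idx)) {
    i <- idx[[ch]]
    sub <- norm[i, i, drop = FALSE]
    e <- expected$cis[[ch]]
    d <- abs(row(sub) - col(sub))
    ev <- matrix(e[d + 1L], nrow(sub), ncol(sub))
    oe[i, i] <- ifelse(is.na(ev) | ev == 0, NA_real_, sub / ev)
  }
  chroms <- names(idx)
  if (length(chroms) > 1) {
    for (a in chroms) for (b in chroms) {
      if (a == b) next
      ev <- expected$trans[a, b]
      if (is.na(ev) || ev == 0) next
      oe[idx[[a]], idx[[b]]] <- norm[idx[[a]], idx[[b]]] / ev
    }
  }
  oe[!cm$valid, ] <- NA
  oe[, !cm$valid] <- NA
  structure(list(bins = cm$bins, values = oe, valid = cm$valid),
            class = "oe_matrix")
}

#' @export
print.oe_matrix <- function(x, ...) {
  cat("oe_matrix:", length(x$bins), "bins, bin size",
      bin_size(x$bins), "bp\n")
  invisible(x)
}

#' Contact-probability decay curve P(s)
#'
#' Cis pixel values are pooled across chromosomes into log-spaced distance
#' bins; P(s) is the mean normalized contact per bin, optionally total-sum
#' normalized so curves are comparable across samples. The derivative
#' d log P / d log s is computed by central differences.
#'
#' @param cm A balanced `contact_matrix`.
#' @param log_bin_factor Ratio between successive distance-bin edges.
#' @param normalize Divide P(s) by its sum (default TRUE).
#' @return data.frame with columns `s` (geometric mid-distance, bp), `p`,
#'   and `deriv`.
#' @export
contact_decay <- function(cm, log_bin_factor = 1.15, normalize = TRUE) {
  norm <- need_normalized(cm)
  bs <- bin_size(cm$bins)
  idx <- chrom_bin_index(cm$bins)
  dists <- vals <- list()
  for (ch in names(idx)) {
    i <- idx[[ch]]
    sub <- norm[i, i, drop = FALSE]
    v <- cm$valid[i]
    sub[!v, ] <- NA
    sub[, !v] <- NA
    d <- (col(sub) - row(sub))
    keep <- d > 0 & !is.na(sub)
    dists[[ch]] <- d[keep] * bs
    vals[[ch]] <- sub[keep]
  }
  d_all <- unlist(dists, use.names = FALSE)
  v_all <- unlist(vals, use.names = FALSE)
  if (!length(d_all)) stop("no valid cis pixels")
  max_d <- max(d_all)
  edges <- bs * log_bin_factor^(0:ceiling(log(max_d / bs) /
                                            log(log_bin_factor)))
  edges <- unique(c(edges, max_d + 1))
  grp <- cut(d_all, breaks = c(0, edges), right = FALSE, labels = FALSE)
  p <- tapply(v_all, grp, mean)
  mids <- sqrt(c(0, edges)[as.integer(names(p))] *
                 c(0, edges)[as.integer(names(p)) + 1L])
  mids[mids == 0] <- edges[1] / 2  # guard the bin whose lower edge is 0
  keep <- is.finite(p) & p > 0
  p <- as.vector(p[keep]); mids <- mids[keep]
  if (normalize) p <- p / sum(p)
  lp <- log(p); ls <- log(mids)
  deriv <- rep(NA_real_, length(p))
  if (length(p) > 2)
    deriv[2:(length(p) - 1)] <-
      (lp[3:length(p)] - lp[1:(length(p) - 2)]) /
      (ls[3:length(p)] - ls[1:(length(p) - 2)])
  data.frame(s = mids, p = p, deriv = deriv)
}

#' Virtual 4C track from an anchor region
#'
#' The per-bin mean of the normalized contact rows of all valid anchor bins.
#'
#' @param cm A balanced `contact_matrix`.
#' @param anchor A `GRanges` of length 1.
#' @return The bin `GRanges` with a `score` column (`NA` at masked bins).
#' @export
virtual_4c <- function(cm, anchor) {
  norm <- need_normalized(cm)
  stopifnot(length(anchor) == 1)
  ab <- bins_overlapping(cm$bins, anchor)
  ab <- ab[cm$valid[ab]]
  if (!length(ab)) stop("anchor region contains no valid bins")
  track <- colMeans(norm[ab, , drop = FALSE])
  out <- GenomicRanges::granges(cm$bins)
  out$score <- track
  out
}
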