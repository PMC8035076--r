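# Synthetic contact maps with planted structure.
#
# The generative model for the expected intensity of a cis pixel (i, j) at
# genomic separation d bp is
#
#   e(i,j) = (d + s0)^(-alpha)
#            * (1 + tau)           if i and j lie in the same planted domain
#            * (1 + lambda * exp(-(di^2 + dj^2) / (2 sigma^2)))  near a loop
#            * exp(kappa * v_i * v_j)                            compartments
#
# Intensities are normalized to sum 1 over the upper triangle and counts are
# drawn Poisson(depth * b_i * b_j * e), with log-normal per-bin biases b.
# Balancer-like rearrangements are modelled by recomputing the decay term
# with bin distances measured in the rearranged genome, mixing the mutant
# and reference intensities by the carrier fraction, and re-sampling.

#' Specify a synthetic contact-map simulation
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param bin_size Bin width in bp.
#' @param decay_exponent Power-law exponent alpha > 0 of the distance decay.
#' @param decay_offset Offset s0 in bp (regularizes the diagonal); default one
#'   bin.
#' @param domains `GRanges` of self-interacting domains, optionally with a
#'   numeric `boost` column (contact boost tau >= 0; default 1).
#' @param compartments `GRanges` with a `sign` column (+1 = A, -1 = B) giving
#'   the planted compartment profile; bins outside are neutral (0).
#' @param compartment_strength Compartment strength kappa >= 0.
#' @param loops A `Pairs` of anchor `GRanges`, or data.frame with columns
#'   chrom1, start1, end1, chrom2, start2, end2; optional `boost` column
#'   (lambda >= 0, default 1).
#' @param loop_sigma Gaussian loop width in bins.
#' @param bias_sigma Log-sd of the per-bin log-normal biases.
#' @param depth Expected total pair count (sequencing depth scale).
#' @param trans_level Flat trans intensity relative to the cis decay scale
#'   (default 0: no trans contacts).
#' @param rearrangements List of [rearrangement()] objects.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(chrom_sizes, bin_size,
                     decay_exponent = 0.8,
                     decay_offset = bin_size,
                     domains = NULL,
                     compartments = NULL,
                     compartment_strength = 0,
                     loops = NULL,
                     loop_sigma = 1,
                     bias_sigma = 0.2,
                     depth = 1e6,
                     trans_level = 0,
                     rearrangements = list()) {
  validate_chrom_sizes(chrom_sizes)
  stopifnot(decay_exponent > 0, decay_offset >= 0, compartment_strength >= 0,
            bias_sigma >= 0, depth > 0, trans_level >= 0, loop_sigma > 0)
  if (!is.null(domains)) {
    if (is.null(domains$boost)) domains$boost <- 1
    if (any(domains$boost < 0)) stop("domain boosts must be >= 0")
    ends_ok <- GenomicRanges::end(domains) <=
      chrom_sizes[as.character(GenomicRanges::seqnames(domains))]
    if (!all(ends_ok)) stop("domains must lie within chromosome bounds")
  }
  if (!is.null(loops) && is.data.frame(loops)) {
    loops <- S4Vectors::Pairs(
      GenomicRanges::GRanges(loops$chrom1,
                             IRanges::IRanges(loops$start1 + 1, loops$end1)),
      GenomicRanges::GRanges(loops$chrom2,
                             IRanges::IRanges(loops$start2 + 1, loops$end2)),
      boost = if (is.null(loops$boost)) rep(1, nrow(loops)) else loops$boost)
  }
  if (!is.null(loops) && is.null(S4Vectors::mcols(loops)$boost))
    S4Vectors::mcols(loops)$boost <- 1
  structure(list(chrom_sizes = chrom_sizes, bin_size = bin_size,
                 decay_exponent = decay_exponent, decay_offset = decay_offset,
                 domains = domains, compartments = compartments,
                 compartment_strength = compartment_strength,
                 loops = loops, loop_sigma = loop_sigma,
                 bias_sigma = bias_sigma, depth = depth,
                 trans_level = trans_level,
                 rearrangements = rearrangements),
            class = "sim_spec")
}

#' Describe a balancer-like rearrangement
#'
#' @param type `"inversion"` or `"translocation"`.
#' @param chrom,start,end Inversion segment (bp; must fall on bin edges).
#' @param chrom2,pos,pos2 For translocations: breakpoints `pos` on `chrom`
#'   and `pos2` on `chrom2` (reciprocal exchange of the distal segments).
#' @param fraction Carrier fraction f in \[0, 1\] of the pooled embryos.
#' @return A `rearrangement` list.
#' @export
rearrangement <- function(type = c("inversion", "translocation"),
                          chrom, start = NULL, end = NULL,
                          chrom2 = NULL, pos = NULL, pos2 = NULL,
                          fraction = 1) {
  type <- match.arg(type)
  if (fraction < 0 || fraction > 1) stop("carrier fraction must be in [0, 1]")
  structure(list(type = type, chrom = chrom, start = start, end = end,
                 chrom2 = chrom2, pos = pos, pos2 = pos2,
                 fraction = fraction),
            class = "rearrangement")
}

# Layout: for every bin, which derivative chromosome it sits on and at which
# position index. The identity layout is the reference genome.
identity_layout <- function(bins) {
  chr <- as.character(GenomicRanges::seqnames(bins))
  pos <- stats::ave(seq_along(bins), chr, FUN = seq_along)
  list(chrom = chr, pos = pos)
}

apply_layout_rearrangement <- function(layout, bins, r, bin_size) {
  on_edge <- function(p) p %% bin_size == 0
  if (r$type == "inversion") {
    if (!on_edge(r$start) || !on_edge(r$end))
      stop("inversion breakpoints must fall on bin edges")
    idx <- which(layout$chrom == r$chrom &
                   GenomicRanges::start(bins) > r$start &
                   GenomicRanges::start(bins) <= r$end)
    if (!length(idx)) stop("inversion segment contains no bins")
    layout$pos[idx] <- rev(layout$pos[idx])
  } else {
    if (!on_edge(r$pos) || !on_edge(r$pos2))
      stop("translocation breakpoints must fall on bin edges")
    a_head <- which(layout$chrom == r$chrom &
                      GenomicRanges::start(bins) <= r$pos)
    a_tail <- which(layout$chrom == r$chrom &
                      GenomicRanges::start(bins) > r$pos)
    b_head <- which(layout$chrom == r$chrom2 &
                      GenomicRanges::start(bins) <= r$pos2)
    b_tail <- which(layout$chrom == r$chrom2 &
                      GenomicRanges::start(bins) > r$pos2)
    der1 <- c(a_head, b_tail)
    der2 <- c(b_head, a_tail)
    layout$chrom[der1] <- paste0("der_", r$chrom)
    layout$chrom[der2] <- paste0("der_", r$chrom2)
    layout$pos[der1] <- seq_along(der1)
    layout$pos[der2] <- seq_along(der2)
  }
  layout
}

# Dense expected-intensity matrix for a given genome layout.
sim_intensity <- function(spec, bins, layout = identity_layout(bins)) {
  n <- length(bins)
  bs <- spec$bin_size
  same <- outer(layout$chrom, layout$chrom, "==")
  dbin <- abs(outer(layout$pos, layout$pos, "-"))
  e <- matrix(spec$trans_level * (spec$decay_offset + bs)^(-spec$decay_exponent),
              n, n)
  e[same] <- (dbin[same] * bs + spec$decay_offset)^(-spec$decay_exponent)
  if (!is.null(spec$domains) && length(spec$domains)) {
    mids <- GenomicRanges::resize(bins, width = 1L, fix = "center")
    dom <- GenomicRanges::findOverlaps(mids, spec$domains, select = "first")
    for (d in unique(dom[!is.na(dom)])) {
      idx <- which(!is.na(dom) & dom == d)
      e[idx, idx] <- e[idx, idx] * (1 + spec$domains$boost[d])
    }
  }
  if (!is.null(spec$compartments) && spec$compartment_strength > 0) {
    v <- compartment_profile(spec, bins)
    e <- e * exp(spec$compartment_strength * tcrossprod(v))
  }
  if (!is.null(spec$loops) && length(spec$loops)) {
    sg <- spec$loop_sigma
    half <- ceiling(4 * sg)
    a1 <- anchor_bin(bins, S4Vectors::first(spec$loops))
    a2 <- anchor_bin(bins, S4Vectors::second(spec$loops))
    lam <- S4Vectors::mcols(spec$loops)$boost
    for (k in seq_along(a1)) {
      i0 <- a1[k]; j0 <- a2[k]
      ri <- max(1, i0 - half):min(n, i0 + half)
      rj <- max(1, j0 - half):min(n, j0 + half)
      bump <- 1 + lam[k] *
        exp(-(outer((ri - i0)^2, (rj - j0)^2, "+")) / (2 * sg^2))
      e[ri, rj] <- e[ri, rj] * bump
      e[rj, ri] <- e[rj, ri] * t(bump)
    }
  }
  e
}

compartment_profile <- function(spec, bins) {
  v <- rep(0, length(bins))
  if (is.null(spec$compartments)) return(v)
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::resize(bins, width = 1L, fix = "center"),
    spec$compartments, select = "first")
  sgn <- spec$compartments$sign
  if (is.null(sgn)) stop("compartment profile needs a 'sign' column")
  ok <- !is.na(hits)
  v[ok] <- sgn[hits[ok]]
  v
}

anchor_bin <- function(bins, gr) {
  mids <- floor((GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2)
  pts <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                IRanges::IRanges(mids, width = 1L))
  hit <- GenomicRanges::findOverlaps(pts, bins, select = "first")
  if (anyNA(hit)) stop("loop anchor outside the binned genome")
  hit
}

sample_counts <- function(p, biases, depth) {
  n <- nrow(p)
  mu <- depth * p * tcrossprod(biases)
  up <- upper.tri(mu, diag = TRUE)
  counts <- matrix(0, n, n)
  counts[up] <- stats::rpois(sum(up), mu[up])
  counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
  counts
}

#' Generate a synthetic contact map
#'
#' @param spec A [sim_spec()].
#' @param seed Integer seed; fixed seeds give bit-identical output.
#' @return List with elements `matrix` (a raw-count `contact_matrix`) and
#'   `truth` (planted boundaries, domains, compartment labels, loop anchors
#'   and the per-bin biases used).
#' @export
generate_contact_map <- function(spec, seed = 1L) {
  bins <- bin_table(spec$chrom_sizes, spec$bin_size)
  set.seed(seed)
  biases <- stats::rlnorm(length(bins), meanlog = -spec$bias_sigma^2 / 2,
                          sdlog = spec$bias_sigma)
  e <- sim_intensity(spec, bins)
  p <- e / sum(e[upper.tri(e, diag = TRUE)])
  counts <- sample_counts(p, biases, spec$depth)
  cm <- contact_matrix(bins, counts)
  truth <- sim_truth(spec, bins, biases)
  list(matrix = cm, truth = truth)
}

sim_truth <- function(spec, bins, biases) {
  boundaries <- GenomicRanges::GRanges()
  if (!is.null(spec$domains) && length(spec$domains)) {
    d <- spec$domains
    pos <- sort(unique(c(GenomicRanges::start(d) - 1L,
                         GenomicRanges::end(d))))
    chr <- as.character(GenomicRanges::seqnames(d))
    bnd <- suppressWarnings(do.call(c, lapply(unique(chr), function(ch) {
      p <- sort(unique(c(GenomicRanges::start(d[chr == ch]) - 1L,
                         GenomicRanges::end(d[chr == ch]))))
      p <- p[p > 0 & p < spec$chrom_sizes[ch]]  # chromosome ends excluded
      GenomicRanges::GRanges(ch, IRanges::IRanges(p, width = 1L))
    })))
    boundaries <- bnd
  }
  list(boundaries = boundaries,
       domains = spec$domains,
       compartments = compartment_profile(spec, bins),
       loops = spec$loops,
       breakpoints = rearrangement_breakpoints(spec),
       biases = biases)
}

rearrangement_breakpoints <- function(spec) {
  if (!length(spec$rearrangements)) return(GenomicRanges::GRanges())
  suppressWarnings(do.call(c, lapply(spec$rearrangements, function(r) {
    if (r$type == "inversion")
      GenomicRanges::GRanges(r$chrom, IRanges::IRanges(c(r$start, r$end),
                                                       width = 1L))
    else
      GenomicRanges::GRanges(c(r$chrom, r$chrom2),
                             IRanges::IRanges(c(r$pos, r$pos2), width = 1L))
  })))
}

#' Sample a rearranged (mutant) contact map
#'
#' The expected intensity of the rearranged genome is computed in reference
#' coordinates (an inversion reverses bin order within its segment before the
#' decay term is evaluated), mixed with the reference intensity as
#' `f * mutant + (1 - f) * reference` to emulate a pooled sample in which a
#' fraction f of embryos carry the rearrangement, and Poisson-sampled.
#'
#' @param spec A [sim_spec()] whose `rearrangements` list is non-empty.
#' @param map Output of [generate_contact_map()] for the reference genome;
#'   supplies the bin table and per-bin biases so mutant and reference share
#'   bias structure.
#' @param seed Integer seed for the Poisson draw.
#' @return List with `matrix` (mutant `contact_matrix`) and `truth`
#'   (including rearrangement breakpoints).
#' @export
apply_rearrangement <- function(spec, map, seed = 1L) {
  if (!length(spec$rearrangements))
    stop("spec carries no rearrangements")
  bins <- map$matrix$bins
  biases <- map$truth$biases
  layout <- identity_layout(bins)
  for (r in spec$rearrangements)
    layout <- apply_layout_rearrangement(layout, bins, r, spec$bin_size)
  fractions <- vapply(spec$rearrangements, `[[`, 0, "fraction")
  f <- fractions[1]
  if (length(unique(fractions)) > 1)
    stop("all rearrangements must share one carrier fraction")
  e_ref <- sim_intensity(spec, bins)
  e_mut <- sim_intensity(spec, bins, layout)
  e <- f * e_mut + (1 - f) * e_ref
  # keep the reference normalization so carrier mixing does not change depth
  p <- e / sum(e_ref[upper.tri(e_ref, diag = TRUE)])
  set.seed(seed)
  counts <- sample_counts(p, biases, spec$depth)
  truth <- sim_truth(spec, bins, biases)
  list(matrix = contact_matrix(bins, counts), truth = truth)
}
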