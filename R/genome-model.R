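# Genomic coordinate system: chromosome sizes, bin tables, interval I/O.
#
# Intervals are held as GRanges (1-based, closed) throughout the package;
# 0-based half-open conventions (BED, bedGraph, COO bin tables) are converted
# at the format boundary, as is 1-based-inclusive GFF3.

#' Read a two-column chrom.sizes file
#'
#' @param path Path to a tab-separated file with columns chromosome name and
#'   length in bp.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  sizes <- stats::setNames(df$length, df$chrom)
  validate_chrom_sizes(sizes)
  sizes
}

#' Write chromosome sizes
#'
#' @param sizes Named numeric vector of chromosome lengths.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_chrom_sizes <- function(sizes, path) {
  validate_chrom_sizes(sizes)
  writeLines(paste(names(sizes), format(sizes, scientific = FALSE,
                                        trim = TRUE), sep = "\t"), path)
  invisible(path)
}

validate_chrom_sizes <- function(sizes) {
  if (is.null(names(sizes)) || any(!nzchar(names(sizes))))
    stop("chromosome sizes must be named")
  if (anyDuplicated(names(sizes)))
    stop("duplicated chromosome name: ",
         names(sizes)[duplicated(names(sizes))][1])
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stop("chromosome lengths must be positive and finite")
  invisible(sizes)
}

#' Tile a genome into fixed-size bins
#'
#' Bins tile each chromosome left to right; the last bin of a chromosome may
#' be short. Bin ids are dense, 1-based and ordered by chromosome then start.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param bin_size Bin width in bp.
#' @return A `GRanges` of bins with metadata column `bin_id` and seqlengths
#'   set from `chrom_sizes`.
#' @export
bin_table <- function(chrom_sizes, bin_size) {
  validate_chrom_sizes(chrom_sizes)
  stopifnot(bin_size >= 1)
  sl <- stats::setNames(as.integer(chrom_sizes), names(chrom_sizes))
  bins <- GenomicRanges::tileGenome(sl, tilewidth = as.integer(bin_size),
                                    cut.last.tile.in.chrom = TRUE)
  bins$bin_id <- seq_along(bins)
  S4Vectors::metadata(bins)$bin_size <- as.integer(bin_size)
  bins
}

#' Bin size of a bin table
#' @param bins A bin table from [bin_table()].
#' @return Bin width in bp.
#' @export
bin_size <- function(bins) {
  bs <- S4Vectors::metadata(bins)$bin_size
  if (is.null(bs)) bs <- max(GenomicRanges::width(bins))
  bs
}

# Indices of bins overlapped by a set of ranges.
bins_overlapping <- function(bins, x) {
  unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(bins, x)))
}

check_known_chroms <- function(gr, chrom_sizes) {
  if (is.null(chrom_sizes)) return(invisible(gr))
  bad <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))),
                 names(chrom_sizes))
  if (length(bad))
    stop("unknown chromosome: ", paste(bad, collapse = ", "))
  invisible(gr)
}

#' Read genomic intervals from standard formats
#'
#' BED and bedGraph are 0-based half-open on disk, GFF3 is 1-based inclusive;
#' all are returned in the internal `GRanges` convention. BEDPE yields a
#' [S4Vectors::Pairs] of intervals.
#'
#' @param path Input file.
#' @param format One of `"bed"`, `"bedpe"`, `"gff3"`, `"bedgraph"`.
#' @param chrom_sizes Optional named vector; when given, chromosome names are
#'   validated against it.
#' @return A `GRanges`, or a `Pairs` of `GRanges` for BEDPE.
#' @export
read_intervals <- function(path, format = c("bed", "bedpe", "gff3", "bedgraph"),
                           chrom_sizes = NULL) {
  format <- match.arg(format)
  x <- switch(format,
    bed      = rtracklayer::import(path, format = "BED"),
    bedgraph = rtracklayer::import(path, format = "bedGraph"),
    gff3     = rtracklayer::import(path, format = "GFF3"),
    bedpe    = read_bedpe(path))
  if (format == "bedpe") {
    check_known_chroms(S4Vectors::first(x), chrom_sizes)
    check_known_chroms(S4Vectors::second(x), chrom_sizes)
  } else {
    check_known_chroms(x, chrom_sizes)
  }
  x
}

read_bedpe <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(S4Vectors::Pairs(GenomicRanges::GRanges(), GenomicRanges::GRanges()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields < 6)
  if (length(bad))
    stop("malformed BEDPE line ", bad[1], ": fewer than 6 fields")
  coord <- function(j) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", j)))
    if (anyNA(v))
      stop("malformed BEDPE line ", which(is.na(v))[1],
           ": non-numeric coordinate in field ", j)
    v
  }
  gr <- function(chr_col, start_col, end_col) {
    GenomicRanges::GRanges(
      vapply(fields, `[[`, "", chr_col),
      IRanges::IRanges(start = coord(start_col) + 1,
                       end = coord(end_col)))
  }
  p <- S4Vectors::Pairs(gr(1, 2, 3), gr(4, 5, 6))
  if (all(n_fields >= 7))
    S4Vectors::mcols(p)$name <- vapply(fields, `[[`, "", 7)
  if (all(n_fields >= 8))
    S4Vectors::mcols(p)$score <-
      suppressWarnings(as.numeric(vapply(fields, `[[`, "", 8)))
  p
}

#' Write genomic intervals
#'
#' @param x A `GRanges` (BED, bedGraph, GFF3) or `Pairs` of `GRanges` (BEDPE).
#' @param path Output file.
#' @param format One of `"bed"`, `"bedpe"`, `"gff3"`, `"bedgraph"`.
#' @return Invisibly, `path`.
#' @export
write_intervals <- function(x, path,
                            format = c("bed", "bedpe", "gff3", "bedgraph")) {
  format <- match.arg(format)
  switch(format,
    bed      = rtracklayer::export(x, path, format = "BED"),
    bedgraph = rtracklayer::export(x, path, format = "bedGraph"),
    gff3     = rtracklayer::export(x, path, format = "GFF3"),
    bedpe    = write_bedpe(x, path))
  invisible(path)
}

write_bedpe <- function(pairs, path) {
  a <- S4Vectors::first(pairs)
  b <- S4Vectors::second(pairs)
  df <- data.frame(
    chrom1 = as.character(GenomicRanges::seqnames(a)),
    start1 = GenomicRanges::start(a) - 1L,
    end1 = GenomicRanges::end(a),
    chrom2 = as.character(GenomicRanges::seqnames(b)),
    start2 = GenomicRanges::start(b) - 1L,
    end2 = GenomicRanges::end(b))
  mc <- S4Vectors::mcols(pairs)
  if (!is.null(mc$name)) {
    df$name <- mc$name
    if (!is.null(mc$score)) df$score <- mc$score
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Closest feature, optionally respecting blocking intervals
#'
#' For each query, returns the index of the minimum-distance subject on the
#' same chromosome such that no blocker interval lies strictly within the open
#' interval between query and subject. Distance is the end-to-start gap in bp
#' (0 for overlapping or adjacent intervals); ties are broken by the smaller
#' subject start coordinate.
#'
#' @param query `GRanges` of query intervals.
#' @param subjects `GRanges` of candidate subjects.
#' @param blockers Optional `GRanges` of blocking intervals (e.g. domain
#'   boundaries separating an enhancer from a promoter).
#' @return Integer vector of subject indices (NA where no eligible subject).
#' @export
closest_feature <- function(query, subjects, blockers = NULL) {
  if (length(subjects) == 0) return(rep(NA_integer_, length(query)))
  q_chr <- as.character(GenomicRanges::seqnames(query))
  s_chr <- as.character(GenomicRanges::seqnames(subjects))
  b_chr <- if (!is.null(blockers) && length(blockers))
    as.character(GenomicRanges::seqnames(blockers)) else character()
  out <- rep(NA_integer_, length(query))
  for (i in seq_along(query)) {
    cand <- which(s_chr == q_chr[i])
    if (!length(cand)) next
    d <- GenomicRanges::distance(query[i], subjects[cand])
    if (length(b_chr)) {
      ok <- !vapply(seq_along(cand), function(k) {
        is_separated(query[i], subjects[cand[k]], blockers, b_chr, q_chr[i])
      }, logical(1))
      cand <- cand[ok]; d <- d[ok]
    }
    if (!length(cand)) next
    ord <- order(d, GenomicRanges::start(subjects[cand]))
    out[i] <- cand[ord[1]]
  }
  out
}

# TRUE if any blocker lies strictly within the open interval between q and s.
is_separated <- function(q, s, blockers, b_chr, chrom) {
  qs <- GenomicRanges::start(q); qe <- GenomicRanges::end(q)
  ss <- GenomicRanges::start(s); se <- GenomicRanges::end(s)
  if (qe >= ss && se >= qs) return(FALSE)  # overlap: nothing in between
  inner_left <- min(qe, se)   # right edge of the left interval
  inner_right <- max(qs, ss)  # left edge of the right interval
  idx <- which(b_chr == chrom)
  if (!length(idx)) return(FALSE)
  bs <- GenomicRanges::start(blockers[idx])
  be <- GenomicRanges::end(blockers[idx])
  any(bs > inner_left & be < inner_right)
}

#' Bin a scored interval track
#'
#' Each bin receives the reducer over the scores of overlapping intervals,
#' weighted by overlap length. With `reducer = "mean"` the average is over
#' covered bases only (sparse-coverage semantics); with `"sum"` each interval
#' contributes its score times the fraction of the interval inside the bin.
#' Bins with no overlapping data are `NA`.
#'
#' @param x `GRanges` with a numeric `score` column.
#' @param bins Bin table from [bin_table()].
#' @param reducer `"mean"` or `"sum"`.
#' @return Numeric vector, one value per bin.
#' @export
bin_track <- function(x, bins, reducer = c("mean", "sum")) {
  reducer <- match.arg(reducer)
  out <- rep(NA_real_, length(bins))
  if (length(x) == 0) return(out)
  score <- S4Vectors::mcols(x)$score
  if (is.null(score)) stop("'x' must carry a numeric score column")
  hits <- GenomicRanges::findOverlaps(bins, x)
  if (!length(hits)) return(out)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(bins)[qh], GenomicRanges::ranges(x)[sh]))
  if (reducer == "mean") {
    num <- rowsum(score[sh] * ov, qh)
    den <- rowsum(ov, qh)
    out[as.integer(rownames(num))] <- num / den
  } else {
    contrib <- score[sh] * ov / GenomicRanges::width(x)[sh]
    num <- rowsum(contrib, qh)
    out[as.integer(rownames(num))] <- num
  }
  out
}

# Gene models -----------------------------------------------------------------

#' Construct a gene model
#'
#' @param genes data.frame with columns `gene_id`, `symbol` and logical
#'   `housekeeping`.
#' @param transcripts `GRanges` with metadata columns `transcript_id` and
#'   `gene_id`; every transcript must have exactly one parent gene present in
#'   `genes`.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(genes, transcripts) {
  stopifnot(all(c("gene_id", "symbol") %in% names(genes)))
  if (is.null(genes$housekeeping)) genes$housekeeping <- FALSE
  mc <- S4Vectors::mcols(transcripts)
  stopifnot(!is.null(mc$transcript_id), !is.null(mc$gene_id))
  orphan <- setdiff(mc$gene_id, genes$gene_id)
  if (length(orphan))
    stop("transcript with unknown parent gene: ", orphan[1])
  structure(list(genes = genes, transcripts = transcripts),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model:", nrow(x$genes), "genes,",
      length(x$transcripts), "transcripts\n")
  invisible(x)
}

#' Transcription start sites of a gene model
#'
#' Promoters are 1-bp TSS points: the transcript start on the + strand, the
#' transcript end on the - strand.
#'
#' @param gm A `gene_model`.
#' @return `GRanges` of width-1 TSS positions with `gene_id` and
#'   `transcript_id` columns.
#' @export
tss_sites <- function(gm) {
  tx <- gm$transcripts
  GenomicRanges::resize(tx, width = 1L, fix = "start")
}

#' Promoter-proximal windows
#'
#' Symmetric window around each TSS, used for "does not overlap a promoter"
#' filters. The extent is a parameter (default +/- 500 bp).
#'
#' @param gm A `gene_model`.
#' @param flank Half-width of the window in bp.
#' @return `GRanges` of promoter windows.
#' @export
promoter_windows <- function(gm, flank = 500) {
  p <- tss_sites(gm)
  GenomicRanges::trim(suppressWarnings(
    GenomicRanges::resize(p, width = 2 * flank + 1, fix = "center")))
}

#' Read a gene model from GFF3
#'
#' Recognizes `gene` features and transcript-level features (`mRNA`,
#' `transcript`) with `Parent` attributes.
#'
#' @param path GFF3 file.
#' @return A `gene_model`.
#' @export
read_gene_model <- function(path) {
  gff <- rtracklayer::import(path, format = "GFF3")
  type <- as.character(gff$type)
  g <- gff[type == "gene"]
  tx <- gff[type %in% c("mRNA", "transcript")]
  hk <- if (!is.null(g$housekeeping))
    as.logical(g$housekeeping) else rep(FALSE, length(g))
  genes <- data.frame(
    gene_id = as.character(g$ID),
    symbol = if (!is.null(g$Name)) as.character(g$Name) else as.character(g$ID),
    housekeeping = hk)
  parent <- vapply(as.list(tx$Parent), function(p) as.character(p)[1], "")
  txg <- GenomicRanges::granges(tx)
  txg$transcript_id <- as.character(tx$ID)
  txg$gene_id <- parent
  gene_model(genes, txg)
}

#' Write a gene model to GFF3
#'
#' @param gm A `gene_model`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_gene_model <- function(gm, path) {
  tx <- gm$transcripts
  gid <- unique(tx$gene_id)
  first_of <- match(gid, tx$gene_id)
  genes <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(tx))[first_of],
    IRanges::IRanges(
      as.vector(tapply(GenomicRanges::start(tx), tx$gene_id, min)[gid]),
      as.vector(tapply(GenomicRanges::end(tx), tx$gene_id, max)[gid])),
    strand = as.character(GenomicRanges::strand(tx))[first_of])
  m <- match(gid, gm$genes$gene_id)
  genes$source <- "dvchrom"
  genes$type <- "gene"
  genes$ID <- gid
  genes$Name <- gm$genes$symbol[m]
  genes$housekeeping <- tolower(as.character(gm$genes$housekeeping[m]))
  txo <- GenomicRanges::granges(tx)
  txo$source <- "dvchrom"
  txo$type <- "mRNA"
  txo$ID <- tx$transcript_id
  txo$Parent <- as.character(tx$gene_id)
  out <- suppressWarnings(c(genes, txo))
  out <- out[order(as.character(GenomicRanges::seqnames(out)),
                   GenomicRanges::start(out))]
  rtracklayer::export(out, path, format = "GFF3")
  invisible(path)
}
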