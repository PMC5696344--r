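# Depth-normalized coverage and region quantification.
#
# The measurement model mirrors IGV-style density counting: sequenced reads
# are extended to the average sonication fragment size, per-base pileup is
# normalized to a reference sequencing depth (1e6 or 1e7 reads), and region
# densities are additionally normalized to 1 kb of region length, i.e.
#   density = raw_count * (depth_scale / library_size) / (length_bp / 1000)
# with raw_count the sum of fragment-overlap fractions.

#' Extend stranded reads to the average fragment size
#'
#' A read is replaced by the fragment it came from: on the + strand the
#' fragment starts at the read's 5' end and runs `fragment_size` bp
#' downstream; on the - strand it ends at the read's 5' end. Fragments are
#' clipped to chromosome bounds when lengths are known.
#'
#' @param reads stranded `GRanges`.
#' @param fragment_size average fragment length in bp (default 250, the
#'   sonication fragment size fixed for peak calling upstream).
#' @return `GRanges` of extended fragments.
#' @export
extend_reads <- function(reads, fragment_size = 250) {
  stopifnot(is(reads, "GRanges"), fragment_size > 0)
  if (any(strand(reads) == "*"))
    stop("unstranded reads cannot be extended: strand is required")
  fr <- suppressWarnings(resize(reads, width = fragment_size,
                                fix = "start"))
  # clip at chromosome bounds (left bound always; right when lengths known)
  sl <- seqlengths(fr)
  if (all(!is.na(sl)) && length(sl)) {
    fr <- trim(fr)
  } else {
    start(fr) <- pmax(start(fr), 1L)
  }
  fr
}

#' Build a binned, depth-normalized coverage track
#'
#' Reads are extended to `fragment_size`, piled up per base, averaged into
#' `bin_size` bins, and scaled by `depth_scale / library_size`. Bin values
#' are therefore invariant under duplication of the read multiset.
#'
#' @param reads stranded `GRanges` of raw reads (or pre-extended fragments
#'   with `extend = FALSE`).
#' @param fragment_size fragment extension length (bp).
#' @param bin_size bin width in bp; 50 bp resolves 250 bp fragments.
#' @param depth_scale reference depth: `1e7` (RP10M, used for figures and
#'   peak densities) or `1e6` (RPM).
#' @param chrom_lengths named vector of chromosome lengths; defaults to
#'   `seqlengths(reads)` or, failing that, the rightmost covered base.
#' @param extend set `FALSE` if `reads` are already fragments.
#' @return a `CoverageTrack`: list with per-chromosome bin-value vectors
#'   (`bins`), `bin_size`, `depth_scale`, `library_size`, `fragment_size`,
#'   `chrom_lengths`.
#' @export
build_coverage <- function(reads, fragment_size = 250, bin_size = 50,
                           depth_scale = 1e7, chrom_lengths = NULL,
                           extend = TRUE) {
  stopifnot(is(reads, "GRanges"))
  n <- length(reads)
  if (n == 0L) stop("empty library: no reads")
  stopifnot(bin_size >= 1, depth_scale > 0)
  frags <- if (extend) extend_reads(reads, fragment_size) else reads
  if (is.null(chrom_lengths)) {
    sl <- seqlengths(frags)
    chrom_lengths <- if (all(!is.na(sl)) && length(sl)) sl
      else vapply(split(end(frags), as.character(seqnames(frags))), max, 0)
  }
  scale <- depth_scale / n
  cov <- coverage(frags)
  bins <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    nb <- as.integer(ceiling(len / bin_size))
    v <- if (ch %in% names(cov)) cov[[ch]] else Rle(0L, 0L)
    # pad / truncate the pileup to the chromosome length
    if (length(v) < len) v <- c(v, Rle(0L, len - length(v)))
    if (length(v) > len) v <- v[seq_len(len)]
    starts <- seq.int(1L, by = bin_size, length.out = nb)
    widths <- pmin(bin_size, len - starts + 1L)
    s <- IRanges::viewSums(IRanges::Views(v, start = starts, width = widths))
    as.numeric(s) / bin_size * scale
  })
  names(bins) <- names(chrom_lengths)
  structure(list(bins = bins, bin_size = as.integer(bin_size),
                 depth_scale = depth_scale, library_size = n,
                 fragment_size = as.integer(fragment_size),
                 chrom_lengths = chrom_lengths),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat("CoverageTrack:", length(x$bins), "chromosome(s), bin", x$bin_size,
      "bp, library", x$library_size, "reads, scale", format(x$depth_scale),
      "\n")
  invisible(x)
}

#' Export a CoverageTrack as bedGraph
#'
#' Adjacent equal-valued bins are collapsed into steps; zero bins are
#' dropped.
#'
#' @param track a `CoverageTrack`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
track_to_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "CoverageTrack"))
  grs <- lapply(names(track$bins), function(ch) {
    v <- track$bins[[ch]]
    nb <- length(v)
    if (nb == 0L) return(GRanges())
    starts <- seq.int(1L, by = track$bin_size, length.out = nb)
    ends <- pmin(starts + track$bin_size - 1L, track$chrom_lengths[[ch]])
    keep <- v != 0
    GRanges(ch, IRanges(starts[keep], ends[keep]), score = v[keep])
  })
  gr <- suppressWarnings(do.call(c, grs))
  gr <- reduce_equal_steps(gr)
  export(gr, path, format = "bedGraph")
  invisible(path)
}

# Merge adjacent intervals with identical scores into single steps.
reduce_equal_steps <- function(gr) {
  if (length(gr) < 2L) return(gr)
  o <- order(as.character(seqnames(gr)), start(gr))
  gr <- gr[o]
  same <- as.character(seqnames(gr))[-1] == as.character(seqnames(gr))[-length(gr)] &
    start(gr)[-1] == end(gr)[-length(gr)] + 1L &
    gr$score[-1] == gr$score[-length(gr)]
  grp <- cumsum(c(TRUE, !same))
  st <- tapply(start(gr), grp, min)
  en <- tapply(end(gr), grp, max)
  ch <- tapply(as.character(seqnames(gr)), grp, `[`, 1L)
  sc <- tapply(gr$score, grp, `[`, 1L)
  GRanges(as.character(ch), IRanges(as.integer(st), as.integer(en)),
          score = as.numeric(sc))
}

#' Quantify normalized read density over regions
#'
#' For every region, `raw_count` is the sum over fragments of the fraction
#' of the fragment overlapping the region (pileup semantics), and
#' `density = raw_count * (depth_scale / library_size) / (length / 1000)`,
#' i.e. reads per `depth_scale` sequenced reads per kb of region.
#'
#' @param reads stranded `GRanges` of raw reads, extended internally, or
#'   pre-extended fragments with `extend = FALSE`.
#' @param regions `GRanges` of regions to quantify.
#' @param depth_scale reference depth (default `1e7`, RP10M).
#' @param fragment_size extension length when `extend = TRUE`.
#' @param library_size total mapped reads; defaults to `length(reads)`.
#' @param extend whether to extend reads first.
#' @param mode `"fraction"` (default, fractional fragment overlap) or
#'   `"midpoint"` (a fragment counts 1 iff its midpoint is in the region).
#' @return a data.frame with one row per region: `chrom`, `start`, `end`,
#'   `width`, `raw_count`, `density`.
#' @export
quantify_regions <- function(reads, regions, depth_scale = 1e7,
                             fragment_size = 250,
                             library_size = length(reads),
                             extend = TRUE,
                             mode = c("fraction", "midpoint")) {
  mode <- match.arg(mode)
  stopifnot(is(reads, "GRanges"), is(regions, "GRanges"))
  if (library_size <= 0) stop("empty library: library_size must be > 0")
  if (any(width(regions) <= 0)) stop("regions must have positive length")
  frags <- if (extend) extend_reads(reads, fragment_size) else reads
  raw <- numeric(length(regions))
  if (mode == "fraction") {
    hits <- findOverlaps(frags, regions, ignore.strand = TRUE)
    if (length(hits)) {
      ovw <- width(pintersect(frags[queryHits(hits)],
                              regions[subjectHits(hits)],
                              ignore.strand = TRUE))
      frac <- ovw / width(frags)[queryHits(hits)]
      agg <- tapply(frac, subjectHits(hits), sum)
      raw[as.integer(names(agg))] <- as.numeric(agg)
    }
  } else {
    mid <- GRanges(seqnames(frags),
                   IRanges(start(frags) + (width(frags) - 1L) %/% 2L,
                           width = 1L))
    cnt <- countOverlaps(regions, mid, ignore.strand = TRUE)
    raw <- as.numeric(cnt)
  }
  dens <- raw * (depth_scale / library_size) / (width(regions) / 1000)
  data.frame(chrom = as.character(seqnames(regions)),
             start = start(regions), end = end(regions),
             width = width(regions), raw_count = raw, density = dens,
             stringsAsFactors = FALSE)
}

#' Quantify a single region
#'
#' Convenience wrapper around [quantify_regions()] for one region.
#'
#' @inheritParams quantify_regions
#' @param region a length-1 `GRanges`.
#' @return a one-row data.frame (see [quantify_regions()]).
#' @export
quantify_region <- function(reads, region, depth_scale = 1e7,
                            fragment_size = 250,
                            library_size = length(reads), extend = TRUE) {
  stopifnot(length(region) == 1L)
  quantify_regions(reads, region, depth_scale = depth_scale,
                   fragment_size = fragment_size,
                   library_size = library_size, extend = extend)
}

#' Region density from a binned track
#'
#' Track-based counterpart of [quantify_regions()]: the mean bin value over
#' the region, converted to per-kb density via the track's fragment size.
#' Agrees with the read-based quantifier up to bin-boundary error.
#'
#' @param track a `CoverageTrack`.
#' @param regions `GRanges`.
#' @return numeric vector of densities (reads per `depth_scale` per kb).
#' @export
track_region_density <- function(track, regions) {
  stopifnot(inherits(track, "CoverageTrack"), is(regions, "GRanges"))
  vapply(seq_along(regions), function(i) {
    ch <- as.character(seqnames(regions))[i]
    v <- track$bins[[ch]]
    if (is.null(v)) stop("region chromosome ", ch, " absent from track")
    b1 <- (start(regions)[i] - 1L) %/% track$bin_size + 1L
    b2 <- min((end(regions)[i] - 1L) %/% track$bin_size + 1L, length(v))
    mean(v[b1:b2]) * 1000 / track$fragment_size
  }, 0)
}
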