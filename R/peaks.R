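# Peak-set overlap, signal matrices, metaprofiles, Mrg15-stratified
# comparison and knockdown dependency analysis.

#' Peak-set overlap (Venn semantics)
#'
#' A peak in A is overlapping iff at least one peak in B shares at least
#' `min_overlap_bp` bases; each peak counts once however many partners it
#' has, matching Venn-diagram semantics. Counts are reported symmetrically.
#'
#' @param setA,setB `GRanges` peak sets in the same chromosome namespace.
#' @param min_overlap_bp minimum shared bases (default 1).
#' @return list with `n_a`, `n_b`, `a_overlapping`, `b_overlapping`,
#'   `a_only`, `b_only`, `fraction_a`, `fraction_b`, and a `pairs`
#'   data.frame of overlapping index pairs.
#' @export
overlap_peaks <- function(setA, setB, min_overlap_bp = 1) {
  stopifnot(is(setA, "GRanges"), is(setB, "GRanges"))
  check_shared_namespace(setA, setB)
  hits <- findOverlaps(setA, setB, minoverlap = min_overlap_bp,
                       ignore.strand = TRUE)
  a_ov <- length(unique(queryHits(hits)))
  b_ov <- length(unique(subjectHits(hits)))
  list(n_a = length(setA), n_b = length(setB),
       a_overlapping = a_ov, b_overlapping = b_ov,
       a_only = length(setA) - a_ov, b_only = length(setB) - b_ov,
       fraction_a = a_ov / length(setA), fraction_b = b_ov / length(setB),
       pairs = data.frame(a = queryHits(hits), b = subjectHits(hits)))
}

#' Peak-by-sample signal matrix
#'
#' One row per peak, one column per (antibody, condition) sample; cells are
#' normalized densities from [quantify_regions()]. Rows can be re-sorted by
#' any column with [sort_signal_matrix()].
#'
#' @param peaks `GRanges`; `name` metadata used for row names if present.
#' @param samples named list; each element either a `GRanges` of reads or a
#'   list `list(reads=, library_size=)`.
#' @param depth_scale reference depth for all cells.
#' @param fragment_size fragment extension applied to every sample.
#' @return numeric matrix (peaks x samples) with attribute `"peaks"`.
#' @export
signal_matrix <- function(peaks, samples, depth_scale = 1e7,
                          fragment_size = 250) {
  stopifnot(is(peaks, "GRanges"), length(samples) > 0,
            !is.null(names(samples)))
  cols <- lapply(samples, function(s) {
    if (is(s, "GRanges")) s <- list(reads = s, library_size = length(s))
    if (s$library_size <= 0) stop("sample with empty library")
    check_shared_namespace(peaks, s$reads, c("peaks", "sample reads"))
    quantify_regions(s$reads, peaks, depth_scale = depth_scale,
                     fragment_size = fragment_size,
                     library_size = s$library_size)$density
  })
  m <- do.call(cbind, cols)
  colnames(m) <- names(samples)
  rownames(m) <- if (!is.null(peaks$name)) as.character(peaks$name)
    else paste0("peak_", seq_along(peaks))
  attr(m, "peaks") <- peaks
  m
}

#' Sort a signal matrix by one column
#'
#' @param m matrix from [signal_matrix()].
#' @param by column name to sort on (descending).
#' @return the matrix with rows (and the `"peaks"` attribute) reordered.
#' @export
sort_signal_matrix <- function(m, by) {
  stopifnot(by %in% colnames(m))
  o <- order(-m[, by], rownames(m))
  out <- m[o, , drop = FALSE]
  attr(out, "peaks") <- attr(m, "peaks")[o]
  out
}

#' Pearson correlation of transformed peak intensities
#'
#' Correlation between two aligned density vectors after a variance-
#' stabilizing transform (default `log2(1 + d)`, matching log-scaled
#' intensity scatter plots).
#'
#' @param x_densities,y_densities equal-length numeric vectors, n >= 3.
#' @param transform function applied to both vectors before correlating.
#' @return list with `r`, `n` and the deparsed transform.
#' @export
correlate_intensities <- function(x_densities, y_densities,
                                  transform = function(d) log2(1 + d)) {
  stopifnot(length(x_densities) == length(y_densities))
  n <- length(x_densities)
  if (n < 3L) stop("need at least 3 paired observations")
  tx <- transform(x_densities); ty <- transform(y_densities)
  if (var(tx) == 0 || var(ty) == 0)
    stop("zero variance after transform: correlation undefined")
  list(r = cor(tx, ty), n = n,
       transform = paste(deparse(body(transform)), collapse = ""))
}

#' Metaprofile of track signal around peak anchors
#'
#' Row i holds the track's bin values across `[-window, +window)` around
#' the midpoint of peak i; the mean profile is the column mean. Peaks whose
#' window runs off a chromosome contribute `NA` to the truncated columns,
#' which are excluded from the affected column means.
#'
#' @param peaks `GRanges`.
#' @param track a `CoverageTrack`.
#' @param window half-window in bp; must be a multiple of the track bin.
#' @return list with `matrix` (peaks x offset bins), `offsets` (bin-start
#'   offsets relative to the anchor), `mean_profile`.
#' @export
metaprofile <- function(peaks, track, window = 2000) {
  stopifnot(is(peaks, "GRanges"), inherits(track, "CoverageTrack"))
  bs <- track$bin_size
  if (window %% bs != 0) stop("window must be a multiple of the bin size")
  nb <- 2L * window %/% bs
  mids <- start(peaks) + (width(peaks) - 1L) %/% 2L
  chs <- as.character(seqnames(peaks))
  if (!any(chs %in% names(track$bins)))
    stop("no peaks on track chromosomes")
  m <- matrix(NA_real_, nrow = length(peaks), ncol = nb)
  for (i in seq_along(peaks)) {
    v <- track$bins[[chs[i]]]
    if (is.null(v)) next
    b0 <- (mids[i] - window - 1L) %/% bs + 1L
    idx <- b0:(b0 + nb - 1L)
    ok <- idx >= 1L & idx <= length(v)
    m[i, ok] <- v[idx[ok]]
  }
  offsets <- seq.int(-window, window - bs, by = bs)
  list(matrix = m, offsets = offsets,
       mean_profile = colMeans(m, na.rm = TRUE))
}

#' Stratified comparison of a mark by cofactor level
#'
#' Splits peaks into Mrg15 high/low at the median Mrg15 density, then into
#' `n_ash1_strata` Ash1-abundance strata (tertiles by default, balanced by
#' rank) within the whole peak set, and summarizes the response densities
#' (e.g. H3K36me2) per (stratum, cofactor group) subgroup. The paired
#' comparison is same Ash1 stratum, different Mrg15 group.
#'
#' @param response numeric response densities (e.g. H3K36me2), aligned
#'   with peaks.
#' @param cofactor numeric cofactor densities (e.g. Mrg15).
#' @param abundance numeric abundance densities (e.g. Ash1).
#' @param n_ash1_strata number of abundance strata (default 3).
#' @return list with `summary` (data.frame of n/median/q1/q3 per subgroup),
#'   `assignment` (per-peak stratum and group), `groups` (response vectors
#'   per subgroup).
#' @export
stratify_by_cofactor <- function(response, cofactor, abundance,
                                 n_ash1_strata = 3) {
  n <- length(response)
  stopifnot(length(cofactor) == n, length(abundance) == n)
  if (n < 2 * n_ash1_strata)
    stop("need at least ", 2 * n_ash1_strata, " peaks")
  med <- median(cofactor)
  hi <- cofactor > med
  if (all(hi) || !any(hi))
    stop("degenerate median split: cofactor densities are all equal")
  grp <- ifelse(hi, "high", "low")
  stratum <- ntile_strata(abundance, n_ash1_strata)
  key <- interaction(stratum, grp, drop = FALSE)
  groups <- split(response, list(stratum = stratum, group = grp))
  summ <- do.call(rbind, lapply(names(groups), function(k) {
    v <- groups[[k]]
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    data.frame(stratum = as.integer(parts[1]), group = parts[2],
               n = length(v),
               median = if (length(v)) median(v) else NA_real_,
               q1 = if (length(v)) unname(quantile(v, 0.25)) else NA_real_,
               q3 = if (length(v)) unname(quantile(v, 0.75)) else NA_real_)
  }))
  list(summary = summ[order(summ$stratum, summ$group), ],
       assignment = data.frame(stratum = stratum, group = grp),
       groups = groups)
}

#' Knockdown dependency by intensity stratum
#'
#' Peaks are stratified into `n_strata` quantile strata of wild-type
#' density; per stratum the retained fraction is the median of
#' `kd / (wt + eps)` with a small regularizer `eps` (default 1% of the
#' median wild-type density). A rising profile across strata means
#' occupancy at weak peaks is more dependent on the depleted factor than
#' at strong peaks.
#'
#' @param wt_density,kd_density aligned density vectors.
#' @param n_strata number of quantile strata (default 5).
#' @param eps ratio regularizer; default `0.01 * median(wt_density)`.
#' @return list with `retained` (per-stratum data.frame), `eps`,
#'   `monotone_increasing` flag.
#' @export
dependency_analysis <- function(wt_density, kd_density, n_strata = 5,
                                eps = NULL) {
  n <- length(wt_density)
  stopifnot(length(kd_density) == n)
  if (all(wt_density == 0)) stop("all wild-type densities are zero")
  if (is.null(eps)) eps <- 0.01 * median(wt_density)
  stratum <- ntile_strata(wt_density, n_strata)
  ret <- vapply(seq_len(n_strata), function(s) {
    i <- stratum == s
    median(kd_density[i] / (wt_density[i] + eps))
  }, 0)
  df <- data.frame(stratum = seq_len(n_strata),
                   n = as.integer(table(factor(stratum,
                                               levels = seq_len(n_strata)))),
                   wt_median = vapply(seq_len(n_strata), function(s)
                     median(wt_density[stratum == s]), 0),
                   retained = ret)
  list(retained = df, eps = eps,
       monotone_increasing = all(diff(ret) >= -1e-9))
}

#' Minimal fallback peak caller on a coverage track
#'
#' Intended only for inputs lacking an upstream peak caller's output: bins
#' above `mean + threshold_sd * sd` of the background (bins at or below the
#' 95th percentile) are chained into runs, runs closer than `merge_gap` are
#' merged, and runs shorter than `min_width` are dropped. The score is the
#' mean bin density over the call.
#'
#' @param track a `CoverageTrack`.
#' @param threshold_sd background standard deviations above the background
#'   mean (default 4).
#' @param min_width minimum call width in bp (default 200).
#' @param merge_gap maximum gap merged, in bp (default 100).
#' @return `GRanges` of calls with `name` and `score`.
#' @export
call_peaks_simple <- function(track, threshold_sd = 4, min_width = 200,
                              merge_gap = 100) {
  stopifnot(inherits(track, "CoverageTrack"))
  all_bins <- unlist(track$bins, use.names = FALSE)
  if (sd(all_bins) == 0) {
    warning("flat track: no peaks called")
    return(GRanges())
  }
  bg <- all_bins[all_bins <= quantile(all_bins, 0.95)]
  thr <- mean(bg) + threshold_sd * sd(bg)
  bs <- track$bin_size
  out <- lapply(names(track$bins), function(ch) {
    v <- track$bins[[ch]]
    above <- v > thr
    if (!any(above)) return(GRanges())
    r <- IRanges(above)           # runs of TRUE, in bin coordinates
    r <- IRanges::reduce(r, min.gapwidth = merge_gap %/% bs + 1L)
    gstart <- (start(r) - 1L) * bs + 1L
    gend <- pmin(end(r) * bs, track$chrom_lengths[[ch]])
    keep <- (gend - gstart + 1L) >= min_width
    if (!any(keep)) return(GRanges())
    score <- vapply(which(keep), function(i)
      mean(v[start(r)[i]:end(r)[i]]), 0)
    GRanges(ch, IRanges(gstart[keep], gend[keep]), score = score)
  })
  gr <- suppressWarnings(do.call(c, out))
  if (length(gr)) gr$name <- paste0("peak_", seq_along(gr))
  gr
}
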