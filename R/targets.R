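# Gene-level Ash1 scoring: target assignment, first-exon density ranking,
# super-target detection, and expression fold-change integration.

#' Flag genes overlapped by a peak set
#'
#' A gene is a target iff at least one peak overlaps its body (optionally
#' widened by `flank` bp on both sides) by at least 1 bp.
#'
#' @param models a `GeneModelSet`.
#' @param peaks `GRanges`.
#' @param flank symmetric flank in bp added to gene bodies (default 0).
#' @return data.frame: `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `has_peak`, `n_peaks`.
#' @export
assign_targets <- function(models, peaks, flank = 0) {
  stopifnot(inherits(models, "GeneModelSet"), is(peaks, "GRanges"))
  g <- models$genes
  check_shared_namespace(g, peaks, c("genes", "peaks"))
  q <- if (flank > 0) suppressWarnings(g + flank) else g
  cnt <- countOverlaps(q, peaks, ignore.strand = TRUE)
  data.frame(gene_id = as.character(g$gene_id),
             chrom = as.character(seqnames(g)),
             start = start(g), end = end(g),
             strand = as.character(strand(g)),
             has_peak = cnt > 0L, n_peaks = cnt,
             stringsAsFactors = FALSE)
}

#' First-exon scoring regions, floored at a minimum length
#'
#' The representative transcript's first exon; exons shorter than `min_len`
#' are extended to `min_len` in the transcription direction (downstream),
#' clipped at chromosome bounds when lengths are known.
#'
#' @param models a `GeneModelSet`.
#' @param min_len length floor in bp (default 200).
#' @return `GRanges` named by gene id, strand preserved.
#' @export
first_exon_regions <- function(models, min_len = 200) {
  stopifnot(inherits(models, "GeneModelSet"))
  g <- models$genes
  fwd <- as.character(strand(g)) != "-"
  # exons are stored in genomic order per gene: the first exon in
  # transcription order is the leftmost (+) or rightmost (-) stored exon
  ue <- unlist(models$exons, use.names = TRUE)
  gid_e <- names(ue)
  lo <- !duplicated(gid_e)
  hi <- !duplicated(gid_e, fromLast = TRUE)
  gid_order <- gid_e[lo]
  pick <- function(flag) {
    i <- which(flag)
    data.frame(gid = gid_e[i], s = start(ue)[i], e = end(ue)[i])
  }
  first <- pick(lo); last <- pick(hi)
  m <- match(as.character(g$gene_id), gid_order)
  st <- ifelse(fwd, first$s[m], last$s[m])
  en <- ifelse(fwd, first$e[m], last$e[m])
  len <- en - st + 1L
  short <- len < min_len
  en[short & fwd] <- st[short & fwd] + min_len - 1L
  st[short & !fwd] <- en[short & !fwd] - min_len + 1L
  st <- pmax(st, 1L)
  out <- GRanges(seqnames(g), IRanges(st, en), strand = strand(g),
                 gene_id = as.character(g$gene_id))
  sl <- seqlengths(g)
  if (all(!is.na(sl)) && length(sl)) {
    suppressWarnings(seqlengths(out) <- sl[seqlevels(out)])
    out <- trim(out)
  }
  names(out) <- as.character(g$gene_id)
  out
}

#' Score and rank target genes by first-exon read density
#'
#' Each target gene's score is the normalized read density (reads per
#' `depth_scale` per kb) of its first-exon region (floored at `min_len`
#' bp). Genes are ranked by descending score with a stable tie-break on
#' gene id; the `top` flag marks the `top_n` highest-scoring genes.
#'
#' @param models a `GeneModelSet`.
#' @param target_ids character vector of gene ids to score (typically the
#'   peak-overlapping genes from [assign_targets()]).
#' @param reads `GRanges` of ChIP reads.
#' @param top_n size of the head retained for super-target analysis
#'   (default 200); if larger than the number of targets, all are used
#'   with a warning.
#' @param depth_scale reference depth (default `1e7`).
#' @param fragment_size read extension length.
#' @param library_size total mapped reads.
#' @param min_len first-exon length floor (bp).
#' @return data.frame sorted by rank: `gene_id`, `exon_chrom`,
#'   `exon_start`, `exon_end`, `score`, `rank`, `top`.
#' @export
score_and_rank <- function(models, target_ids, reads, top_n = 200,
                           depth_scale = 1e7, fragment_size = 250,
                           library_size = length(reads), min_len = 200) {
  stopifnot(inherits(models, "GeneModelSet"))
  fe <- first_exon_regions(models, min_len = min_len)
  fe <- fe[names(fe) %in% target_ids]
  if (length(fe) == 0L) stop("no target genes to score")
  if (top_n > length(fe)) {
    warning("top_n (", top_n, ") exceeds number of targets (", length(fe),
            "); using all")
    top_n <- length(fe)
  }
  q <- quantify_regions(reads, fe, depth_scale = depth_scale,
                        fragment_size = fragment_size,
                        library_size = library_size)
  df <- data.frame(gene_id = names(fe), exon_chrom = q$chrom,
                   exon_start = q$start, exon_end = q$end,
                   score = q$density, stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$gene_id), ]
  df$rank <- seq_len(nrow(df))
  df$top <- df$rank <= top_n
  rownames(df) <- NULL
  df
}

#' Detect super-target genes by cumulative score share
#'
#' Among the descending-sorted scores, the super-target set is the minimal
#' prefix whose cumulative share of the total reaches `share_threshold`.
#' This formalizes "a small subset of top-ranked genes carries about half
#' of the normalized reads".
#'
#' @param scores numeric vector sorted descending (all >= 0, sum > 0), or
#'   a data.frame from [score_and_rank()] (its `top` head is used).
#' @param share_threshold cumulative-share cutoff (default 0.45).
#' @param ids optional ids aligned with `scores`.
#' @return list: `n_super`, `super_ids`, `share_captured`,
#'   `cumulative_share`, `top_n`.
#' @export
detect_super_targets <- function(scores, share_threshold = 0.45,
                                 ids = NULL) {
  if (is.data.frame(scores)) {
    head_df <- scores[scores$top, ]
    ids <- head_df$gene_id
    scores <- head_df$score
  }
  n <- length(scores)
  if (n == 0L) stop("no scores")
  if (any(scores < 0)) stop("scores must be nonnegative")
  if (is.unsorted(rev(scores))) stop("scores must be sorted descending")
  tot <- sum(scores)
  if (tot == 0) stop("all scores are zero")
  cs <- cumsum(scores) / tot
  # tiny relative tolerance so exact-hit shares are not pushed one past
  # the boundary by floating-point summation
  k <- which(cs >= share_threshold * (1 - 1e-9))[1]
  if (is.null(ids)) ids <- paste0("g", seq_len(n))
  list(n_super = k, super_ids = ids[seq_len(k)],
       share_captured = cs[k], cumulative_share = cs, top_n = n)
}

#' Classify expression response to knockdown by fold change
#'
#' `fc = (kd + pseudocount) / (wt + pseudocount)`; genes with
#' `fc <= 1/fold` are `down`, `fc >= fold` are `up`, the rest `unchanged`.
#'
#' @param expr_wt,expr_kd nonnegative abundance vectors (same units).
#' @param gene_id optional ids.
#' @param pseudocount added to both abundances (default 1 expression unit).
#' @param fold fold-change cutoff (default 2).
#' @return data.frame: `gene_id`, `wt`, `kd`, `fold_change`, `class`.
#' @export
fold_change_classify <- function(expr_wt, expr_kd, gene_id = NULL,
                                 pseudocount = 1.0, fold = 2.0) {
  n <- length(expr_wt)
  stopifnot(length(expr_kd) == n)
  if (any(expr_wt < 0) || any(expr_kd < 0))
    stop("abundances must be nonnegative")
  if (is.null(gene_id)) gene_id <- paste0("g", seq_len(n))
  fc <- (expr_kd + pseudocount) / (expr_wt + pseudocount)
  cls <- ifelse(fc <= 1 / fold, "down", ifelse(fc >= fold, "up",
                                               "unchanged"))
  data.frame(gene_id = as.character(gene_id), wt = expr_wt, kd = expr_kd,
             fold_change = fc,
             class = factor(cls, levels = c("down", "unchanged", "up")),
             stringsAsFactors = FALSE)
}

#' Enrichment of repression among super targets
#'
#' 2x2 association between downregulation and super-target membership:
#' odds ratio with Haldane's +0.5 correction and the exact hypergeometric
#' (Fisher) two-sided p value.
#'
#' @param classes factor/character vector of expression classes
#'   (`"down"` / other).
#' @param super_flag logical vector: is the gene a super target?
#' @return list: `table` (2x2), `odds_ratio`, `p`.
#' @export
repression_enrichment <- function(classes, super_flag) {
  stopifnot(length(classes) == length(super_flag))
  down <- as.character(classes) == "down"
  if (!any(down)) stop("no downregulated genes: enrichment undefined")
  if (!any(super_flag)) stop("no super targets: enrichment undefined")
  tab <- matrix(c(sum(down & super_flag), sum(down & !super_flag),
                  sum(!down & super_flag), sum(!down & !super_flag)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("down", "not_down"),
                                c("super", "not_super")))
  or <- ((tab[1, 1] + 0.5) * (tab[2, 2] + 0.5)) /
        ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
  p <- fisher.test(tab)$p.value
  list(table = tab, odds_ratio = or, p = p)
}
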