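# Fixture generators and independent brute-force oracles used across the
# suite. Oracles are deliberately naive (per-base pileup, all-pairs scans,
# grid searches) and never share code with the implementation they check.

# Random peak set on one or two chromosomes.
random_peaks <- function(n, chrom_len = 1e5, chroms = "chr2L",
                         max_width = 500, named = TRUE) {
  ch <- sample(chroms, n, replace = TRUE)
  st <- sample.int(chrom_len - max_width - 1L, n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(st, width = w))
  if (named) {
    gr$name <- sprintf("pk%04d", seq_len(n))
    gr$score <- round(stats::runif(n, 0, 1000), 2)
    GenomicRanges::strand(gr) <- sample(c("+", "-"), n, replace = TRUE)
  }
  gr
}

# Random stranded short reads.
random_reads <- function(n, chrom_len = 1e4, chrom = "chrT",
                         read_len = 36) {
  st <- sample.int(chrom_len - read_len, n, replace = TRUE)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(st, width = read_len),
                         strand = sample(c("+", "-"), n, replace = TRUE))
}

# All-pairs overlap scan: which elements of `a` share >= min_bp bases with
# any element of `b`.
brute_overlapping <- function(a, b, min_bp = 1) {
  ac <- as.character(GenomicRanges::seqnames(a))
  bc <- as.character(GenomicRanges::seqnames(b))
  as_ <- GenomicRanges::start(a); ae <- GenomicRanges::end(a)
  bs <- GenomicRanges::start(b); be <- GenomicRanges::end(b)
  vapply(seq_along(a), function(i) {
    j <- bc == ac[i]
    any(pmin(ae[i], be[j]) - pmax(as_[i], bs[j]) + 1L >= min_bp)
  }, TRUE)
}

# Per-base pileup of extended reads, aggregated to bins: the coverage
# oracle. Single chromosome.
brute_binned_track <- function(reads, fragment, bin, depth_scale,
                               chrom_len) {
  base <- numeric(chrom_len)
  st <- GenomicRanges::start(reads); en <- GenomicRanges::end(reads)
  neg <- as.character(GenomicRanges::strand(reads)) == "-"
  for (i in seq_along(reads)) {
    if (neg[i]) { e <- en[i]; s <- e - fragment + 1L }
    else { s <- st[i]; e <- s + fragment - 1L }
    s <- max(s, 1L); e <- min(e, chrom_len)
    base[s:e] <- base[s:e] + 1
  }
  nb <- ceiling(chrom_len / bin)
  vapply(seq_len(nb), function(b) {
    i1 <- (b - 1L) * bin + 1L
    sum(base[i1:min(b * bin, chrom_len)]) / bin
  }, 0) * depth_scale / length(reads)
}

# Fractional-overlap region count oracle for already-extended fragments.
brute_region_count <- function(frag_start, frag_end, reg_start, reg_end) {
  ov <- pmin(frag_end, reg_end) - pmax(frag_start, reg_start) + 1L
  sum(pmax(ov, 0) / (frag_end - frag_start + 1L))
}

# Exhaustive two-sided hypergeometric p for a 2x2 table.
enum_hyper_p <- function(tab) {
  m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
  supp <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(supp, m, n, k)
  obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Hand-built gene models: regular slots on one chromosome, 1-3 exons.
random_models <- function(n_genes, chrom_len = 3e5, chrom = "chrT") {
  slot <- floor(chrom_len / n_genes)
  stopifnot(slot >= 900)
  gid <- sprintf("t%03d", seq_len(n_genes))
  strands <- sample(c("+", "-"), n_genes, replace = TRUE)
  nx <- sample.int(3L, n_genes, replace = TRUE)
  gi <- rep.int(seq_len(n_genes), nx)
  w <- sample(80:300, length(gi), replace = TRUE)
  gap <- sample(60:200, length(gi), replace = TRUE)
  base <- (seq_len(n_genes) - 1L) * slot +
    sample.int(50L, n_genes, replace = TRUE)
  ss <- ee <- integer(length(gi))
  pos <- base[gi[1]]
  for (k in seq_along(gi)) {       # light cursor walk, vector alloc once
    if (k > 1L && gi[k] != gi[k - 1L]) pos <- base[gi[k]]
    ss[k] <- pos; ee[k] <- pos + w[k] - 1L
    pos <- ee[k] + gap[k]
  }
  ex <- GenomicRanges::GRanges(chrom, IRanges::IRanges(ss, ee),
                               strand = strands[gi])
  exl <- GenomicRanges::split(ex, gid[gi])
  bodies <- unlist(range(exl))
  genes <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(bodies), IRanges::ranges(bodies),
    strand = strands, gene_id = gid, tx_id = paste0(gid, ".t1"))
  gene_model_set(genes, exl)
}

# Reduced simulation: same structure as the defaults, scaled down for
# fast structural tests (the acceptance suite uses the full defaults).
small_sim_overrides <- function() {
  list(
    chrom_sizes = c(chr2L = 1e6, chr2R = 1e6),
    n_genes = 500,
    n_mrg15_peaks = 600,
    n_ash1_peaks = 120,
    n_targets = 80, top_n = 40, n_super = 8,
    n_down = 6, n_up = 3, n_down_super = 4, n_mrg15_down = 2,
    lib_sizes = c(Ash1 = 3e5, Mrg15 = 3e5, H3K36me2 = 4e5,
                  H3K27me3 = 2e5),
    n_nonspecific_sites = 250, n_h3k36_domains = 60,
    n_h3k27_domains = 30
  )
}

small_sim_config <- function(seed = 1, ...) {
  do.call(sim_config,
          c(list(seed = seed), utils::modifyList(small_sim_overrides(),
                                                 list(...))))
}
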