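# Synthetic ChIP-seq landscape generator with ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# a compact two-chromosome genome; non-overlapping gene models; a large
# Mrg15 peak set nesting a small Ash1 peak set (3678 vs 562, 41% of Ash1
# peaks co-called); bivariate-correlated log intensities (rho = 0.58) with
# sub-threshold Mrg15 arising as the lower tail of the same draw; planted
# first-exon score shares so that the 26-gene prefix of the top 200 targets
# carries ~45% of the normalized reads; knockdown conditions that scale
# factor-specific signal (Ash1 KD retains 10%, Mrg15 KD halves H3K36me2 at
# Ash1 peaks and removes Ash1 more at weak peaks than strong ones); and
# expression tables with 18 down / 8 up responders concentrated in the
# super targets. Every stochastic component draws from its own sub-seeded
# stream, so one master seed reproduces every output exactly.

#' Simulation configuration
#'
#' Defaults encode the study conditions the analysis is designed for; see
#' the package vignette for the rationale behind values the study design
#' leaves open (library sizes, signal mass fractions, noise levels).
#'
#' @param seed master seed; all sub-streams derive from it.
#' @param ... overrides for any default field (unknown fields rejected).
#' @return object of class `SimConfig`.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    chrom_sizes = c(chr2L = 5e6, chr2R = 5e6),
    n_genes = 3000,
    n_mrg15_peaks = 3678,
    n_ash1_peaks = 562,
    ash1_overlap_fraction = 0.41,
    rho = 0.58,
    n_targets = 398,
    top_n = 200,
    n_super = 26,
    super_share = 0.45,
    # knockdown effect sizes (retained signal fractions)
    ash1_kd_retained = 0.1,
    ash1_kd_mrg15_retained = 0.3,
    ash1_kd_h3k36_retained = 0,
    mrg15_kd_retained = 0.1,
    mrg15_kd_h3k36_retained = 0.5,
    mrg15_kd_ash1_retained = c(0.5, 0.6, 0.7, 0.8, 0.9),
    # expression effects
    n_down = 18, n_up = 8, fold = 2,
    n_down_super = 12, n_mrg15_down = 6, mrg15_kd_expr_factor = 0.7,
    expr_noise_cv = 0.1,
    # sequencing model
    fragment_size = 250, read_length = 36, bin_size = 50,
    lib_sizes = c(Ash1 = 1.5e6, Mrg15 = 1.5e6,
                  H3K36me2 = 2e6, H3K27me3 = 1e6),
    # signal-mass fractions per antibody (remainder after listed
    # components is thin uniform background)
    ash1_peak_mass = 0.30, ash1_nonspecific_mass = 0.65,
    mrg15_ash1_mass = 0.10, mrg15_peak_mass = 0.55,
    mrg15_nonspecific_mass = 0.30,
    h3k36_peak_mass = 0.17, h3k36_domain_mass = 0.78,
    h3k27_domain_mass = 0.85, ash1_kd_h3k27_super_mass = 0.10,
    # landscape shape
    n_nonspecific_sites = 1200, nonspecific_width = 800,
    n_h3k36_domains = 300, h3k36_domain_width = 6000,
    n_h3k27_domains = 150, h3k27_domain_width = 5000,
    mrg15_sdlog2 = 1, mrg15_only_sdlog2 = 1,
    k36_ash1_weight = 0.6, k36_mrg15_weight = 0.4, k36_noise_sdlog2 = 0.3,
    nontarget_score_range = c(2e-4, 8e-3),
    super_decay = 0.985, super_share_margin = 0.005,
    tail_score_start = 5e-4, tail_score_ratio = 0.9954,
    # expression baselines
    expr_baseline_meanlog = log(15), expr_baseline_sdlog = 1,
    expr_responder_meanlog = log(40), expr_responder_sdlog = 0.5,
    down_factor_range = c(0.2, 0.4), up_factor_range = c(2.2, 4)
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown SimConfig field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  validate_sim_config(structure(cfg, class = "SimConfig"))
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_super <= top_n, top_n <= n_targets,
              n_targets <= n_ash1_peaks,
              ash1_overlap_fraction > 0, ash1_overlap_fraction <= 1,
              super_share > 0, super_share < 1,
              all(mrg15_kd_ash1_retained > 0),
              all(mrg15_kd_ash1_retained <= 1),
              n_down + n_up <= n_targets, n_down_super <= n_down,
              n_down_super <= n_super, n_mrg15_down <= n_down_super,
              fragment_size > 0, all(chrom_sizes > 0))
    if (n_genes * 600 > sum(chrom_sizes))
      stop("genome too small for n_genes at minimum spacing")
  })
  cfg
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig: seed", x$seed, "|", length(x$chrom_sizes),
      "chromosomes,", x$n_genes, "genes,", x$n_ash1_peaks, "Ash1 /",
      x$n_mrg15_peaks, "Mrg15 peaks,", x$n_targets, "targets\n")
  invisible(x)
}

#' Planted first-exon score shares for the target genes
#'
#' Descending relative densities for ranks 1..n_targets, scaled so the top
#' `top_n` sum to 1. The first `n_super` scores decay geometrically and sum
#' to `super_share + super_share_margin`, placing the minimal prefix that
#' reaches `super_share` exactly at `n_super`; ranks `n_super+1 .. top_n`
#' continue from half the last super score; the tail decays gently so even
#' the weakest target peak keeps a measurable read count.
#'
#' @param cfg a `SimConfig`.
#' @return numeric vector of length `cfg$n_targets`, strictly decreasing.
#' @export
design_target_scores <- function(cfg) {
  ns <- cfg$n_super; nt <- cfg$top_n; q <- cfg$super_decay
  ssum <- cfg$super_share + cfg$super_share_margin
  a <- ssum * (1 - q) / (1 - q^ns)
  sup <- a * q^(seq_len(ns) - 1)
  s27 <- sup[ns] / 2
  m <- nt - ns
  f <- function(r) s27 * (1 - r^m) / (1 - r) - (1 - ssum)
  r <- stats::uniroot(f, c(0.9, 0.99999), tol = 1e-12)$root
  mid <- s27 * r^(seq_len(m) - 1)
  tail_n <- cfg$n_targets - nt
  tl <- if (tail_n > 0)
    cfg$tail_score_start * cfg$tail_score_ratio^(seq_len(tail_n) - 1)
  else numeric(0)
  s <- c(sup, mid, tl)
  cs <- cumsum(s[seq_len(nt)]) / sum(s[seq_len(nt)])
  if (!(cs[ns] >= cfg$super_share && (ns == 1 || cs[ns - 1] < cfg$super_share)))
    stop("score design failed to place the super prefix at n_super")
  if (tail_n > 0 && tl[1] >= mid[m])
    stop("tail scores must sit below the top_n floor")
  s
}

# Place n non-overlapping intervals of the given widths, avoiding a
# forbidden set (with `pad` bp of clearance) and each other. Rejection
# sampling in rounds on a linearized coordinate system (spacers between
# chromosomes prevent cross-boundary adjacency); errors if the counts are
# unplaceable.
sample_nonoverlapping <- function(n, widths, chrom_sizes,
                                  forbidden = GRanges(), pad = 0,
                                  max_rounds = 400) {
  stopifnot(length(widths) == n)
  if (n == 0L) return(GRanges())
  chn <- names(chrom_sizes)
  spacer <- pad + 1e6
  off <- cumsum(c(0, as.numeric(chrom_sizes) + spacer))[seq_along(chn)]
  fb <- reduce(granges(forbidden))
  fs <- off[match(as.character(seqnames(fb)), chn)] + start(fb)
  fe <- off[match(as.character(seqnames(fb)), chn)] + end(fb)
  o <- order(fs); fs <- fs[o]; fe <- fe[o]
  acc_s <- acc_e <- numeric(0)
  acc_ci <- acc_st <- acc_w <- integer(0)
  queue <- as.integer(widths)
  for (round in seq_len(max_rounds)) {
    need <- length(queue)
    if (need == 0L) break
    ci <- sample.int(length(chn), need, replace = TRUE, prob = chrom_sizes)
    span <- chrom_sizes[ci] - queue - 2 * pad
    if (any(span < 1)) stop("interval too wide for its chromosome")
    stl <- as.integer(floor(runif(need) * span)) + pad + 1L
    s <- off[ci] + stl
    e <- s + queue - 1
    bad <- rep(FALSE, need)
    if (length(fs)) {
      i <- pmax(findInterval(e + pad, fs), 1L)
      bad <- findInterval(e + pad, fs) >= 1L & fe[i] >= s - pad
    }
    if (length(acc_s)) {
      i <- pmax(findInterval(e + pad, acc_s), 1L)
      bad <- bad | (findInterval(e + pad, acc_s) >= 1L &
                      acc_e[i] >= s - pad)
    }
    k <- which(!bad)
    if (length(k)) {
      o2 <- k[order(s[k])]
      ee <- e[o2] + pad
      prev_max <- c(-Inf, cummax(ee)[-length(ee)])
      sel <- o2[s[o2] - pad > prev_max]
      acc_s <- c(acc_s, s[sel]); acc_e <- c(acc_e, e[sel])
      acc_ci <- c(acc_ci, ci[sel]); acc_st <- c(acc_st, stl[sel])
      acc_w <- c(acc_w, queue[sel])
      oo <- order(acc_s)
      acc_s <- acc_s[oo]; acc_e <- acc_e[oo]; acc_ci <- acc_ci[oo]
      acc_st <- acc_st[oo]; acc_w <- acc_w[oo]
      queue <- queue[-sel]
    }
  }
  if (length(queue))
    stop("counts unplaceable: could not place ", length(queue),
         " interval(s) after ", max_rounds, " rounds")
  GRanges(chn[acc_ci], IRanges(acc_st, width = acc_w))
}

#' Generate a synthetic genome annotation
#'
#' Non-overlapping genes with 1--8 exons on both strands; first-exon
#' lengths are log-uniform on 100--1500 bp so both branches of the 200 bp
#' scoring floor occur. Deterministic given the config seed.
#'
#' @param cfg a `SimConfig`.
#' @return a `GeneModelSet` with seqlengths set.
#' @export
generate_annotation <- function(cfg) {
  with_seed(sub_seed(cfg$seed, "annotation"), {
    nch <- length(cfg$chrom_sizes)
    per <- diff(round(seq(0, cfg$n_genes, length.out = nch + 1)))
    n <- cfg$n_genes
    chrom <- rep(names(cfg$chrom_sizes), per)
    slot <- rep(floor(cfg$chrom_sizes / per), per)
    if (any(slot < 600)) stop("infeasible packing: slots under 600 bp")
    slot_idx <- unlist(lapply(per, seq_len)) - 1L
    usable <- slot - 200L
    max_extra <- 7L
    # exon/intron length draws, truncated to the usable slot length
    L1 <- round(exp(runif(n, log(100), log(1500))))
    n_ex <- sample.int(8L, n, replace = TRUE)
    Lm <- matrix(round(exp(runif(n * max_extra, log(80), log(600)))), n)
    Im <- matrix(sample(60:400, n * max_extra, replace = TRUE), n)
    cum <- L1
    keep <- matrix(FALSE, n, max_extra)
    for (j in seq_len(max_extra)) {
      cum_j <- cum + Im[, j] + Lm[, j]
      keep[, j] <- (j < n_ex) & (cum_j <= usable)
      cum <- ifelse(keep[, j], cum_j, cum)
    }
    total <- cum
    strand <- sample(c("+", "-"), n, replace = TRUE)
    jitter <- floor(runif(n) * pmax(usable - total, 1))
    gstart <- slot_idx * slot + 100L + jitter     # 0-based gene start
    # within-gene 1-based exon bounds in transcription order
    A <- t(apply(cbind(0L, (Im + Lm) * keep), 1, cumsum))[, -1, drop = FALSE]
    ex_s <- cbind(1L, L1 + A - Lm + 1L)
    ex_e <- cbind(L1, L1 + A)
    keep_all <- cbind(TRUE, keep)
    # mirror for minus-strand genes (first exon = rightmost genomic)
    neg <- strand == "-"
    tmp_s <- ex_s
    ex_s[neg, ] <- total[neg] - ex_e[neg, ] + 1L
    ex_e[neg, ] <- total[neg] - tmp_s[neg, ] + 1L
    idx <- which(keep_all, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    gi <- idx[, 1]
    gene_id <- sprintf("g%04d", seq_len(n))
    ex <- GRanges(chrom[gi],
                  IRanges(as.integer(gstart[gi] + ex_s[idx]),
                          as.integer(gstart[gi] + ex_e[idx])),
                  strand = strand[gi],
                  seqinfo = GenomeInfoDb::Seqinfo(names(cfg$chrom_sizes),
                                                  cfg$chrom_sizes))
    o <- order(gi, start(ex))
    ex <- ex[o]
    exl <- split(ex, gene_id[gi[o]])
    bodies <- unlist(range(exl))
    genes <- GRanges(seqnames(bodies), ranges(bodies),
                     strand = strand(bodies),
                     gene_id = names(bodies),
                     tx_id = paste0(names(bodies), ".t1"),
                     seqinfo = GenomeInfoDb::Seqinfo(names(cfg$chrom_sizes),
                                                     cfg$chrom_sizes))
    o <- order(as.character(seqnames(genes)), start(genes))
    genes <- genes[o]
    gene_model_set(genes, exl[as.character(genes$gene_id)])
  })
}

#' Generate the peak landscape and ground truth
#'
#' Places Ash1 peaks (target peaks at first exons of randomly chosen
#' genes, carrying the planted score profile; the rest intergenic), draws
#' correlated log Mrg15 intensities at all Ash1 peaks (the highest
#' `round(overlap_fraction * n_ash1)` are co-called as Mrg15 peaks; the
#' lower tail is the sub-threshold Mrg15 the peak caller misses), places
#' the remaining Mrg15-only peaks, H3K36me2 / H3K27me3 domains and
#' non-specific background sites, and records every true parameter.
#'
#' @param cfg a `SimConfig`.
#' @param annotation a `GeneModelSet` from [generate_annotation()].
#' @return object of class `TruthSet`.
#' @export
generate_landscape <- function(cfg, annotation) {
  with_seed(sub_seed(cfg$seed, "landscape"), {
    scores <- design_target_scores(cfg)
    genes <- annotation$genes
    gid <- as.character(genes$gene_id)
    target_ids <- sample(gid, cfg$n_targets)
    fe <- first_exon_regions(annotation, min_len = 200)
    tpk <- granges(fe[target_ids])
    mcols(tpk) <- NULL
    tpk$gene_id <- target_ids
    tpk$rank <- seq_len(cfg$n_targets)
    tpk$intensity <- scores
    tpk$is_target <- TRUE

    n_nt <- cfg$n_ash1_peaks - cfg$n_targets
    forb <- c(granges(genes), granges(tpk))
    nt <- sample_nonoverlapping(
      n_nt, sample(400:700, n_nt, replace = TRUE),
      cfg$chrom_sizes, forbidden = forb, pad = 100)
    nt$gene_id <- NA_character_
    nt$rank <- NA_integer_
    nt$intensity <- exp(runif(n_nt, log(cfg$nontarget_score_range[1]),
                              log(cfg$nontarget_score_range[2])))
    nt$is_target <- FALSE
    ash1 <- sort_intervals(c(tpk, nt))
    ash1$name <- sprintf("ash1_pk_%03d", seq_along(ash1))
    ash1$is_super <- !is.na(ash1$rank) & ash1$rank <= cfg$n_super

    # correlated log intensities; co-called = top Mrg15 tail
    zA <- as.numeric(scale(log2(ash1$intensity)))
    zM <- cfg$rho * zA + sqrt(1 - cfg$rho^2) * rnorm(length(ash1))
    ash1$mrg15_intensity <- 2^(cfg$mrg15_sdlog2 * zM)
    n_ov <- round(cfg$ash1_overlap_fraction * cfg$n_ash1_peaks)
    ov_idx <- order(-ash1$mrg15_intensity)[seq_len(n_ov)]
    ash1$mrg15_overlap <- seq_along(ash1) %in% ov_idx

    # H3K36me2 truth intensity: multiplicative in Ash1 and Mrg15
    ash1$k36_intensity <- 2^(cfg$k36_ash1_weight * zA +
                             cfg$k36_mrg15_weight * cfg$mrg15_sdlog2 * zM +
                             rnorm(length(ash1), 0, cfg$k36_noise_sdlog2))
    # Mrg15-KD retained fraction for Ash1, rising with intensity stratum
    strat <- ntile_strata(ash1$intensity,
                          length(cfg$mrg15_kd_ash1_retained))
    ash1$wt_stratum <- strat
    ash1$mrg15_kd_ash1_retained <- cfg$mrg15_kd_ash1_retained[strat]

    # co-called Mrg15 peaks sit on their Ash1 peak with a small jitter pad
    co <- granges(ash1[ov_idx])
    pads <- sample(20:80, n_ov, replace = TRUE)
    co <- suppressWarnings(resize(co, width(co) + 2L * pads,
                                  fix = "center"))
    co <- trim(co)
    co$intensity <- ash1$mrg15_intensity[ov_idx]
    mo_n <- cfg$n_mrg15_peaks - n_ov
    mo <- sample_nonoverlapping(
      mo_n, sample(500:1200, mo_n, replace = TRUE), cfg$chrom_sizes,
      forbidden = granges(ash1), pad = 150)
    mo$intensity <- 2^rnorm(mo_n, 0, cfg$mrg15_only_sdlog2)
    mrg15 <- sort_intervals(c(co, mo))
    mrg15$name <- sprintf("mrg15_pk_%04d", seq_along(mrg15))

    ns <- sample_nonoverlapping(
      cfg$n_nonspecific_sites,
      rep(cfg$nonspecific_width, cfg$n_nonspecific_sites),
      cfg$chrom_sizes, forbidden = granges(ash1), pad = 300)
    ns$w_ash1 <- 2^rnorm(length(ns), 0, 0.5)
    ns$w_mrg15 <- 2^rnorm(length(ns), 0, 0.5)

    k36dom <- sample_nonoverlapping(
      cfg$n_h3k36_domains, rep(cfg$h3k36_domain_width, cfg$n_h3k36_domains),
      cfg$chrom_sizes, forbidden = granges(ash1), pad = 1000)
    k36dom$level <- 2^rnorm(length(k36dom), 0, 0.5)
    k27dom <- sample_nonoverlapping(
      cfg$n_h3k27_domains, rep(cfg$h3k27_domain_width, cfg$n_h3k27_domains),
      cfg$chrom_sizes, forbidden = granges(ash1), pad = 1000)
    k27dom$level <- 2^rnorm(length(k27dom), 0, 0.5)

    target_table <- data.frame(
      gene_id = target_ids, rank = seq_len(cfg$n_targets),
      score = scores, is_top = seq_len(cfg$n_targets) <= cfg$top_n,
      is_super = seq_len(cfg$n_targets) <= cfg$n_super,
      stringsAsFactors = FALSE)

    structure(list(config = cfg, ash1_peaks = ash1, mrg15_peaks = mrg15,
                   nonspecific_sites = ns, k36_domains = k36dom,
                   k27_domains = k27dom, target_table = target_table,
                   n_overlap = n_ov),
              class = "TruthSet")
  })
}

#' @export
print.TruthSet <- function(x, ...) {
  cat("TruthSet:", length(x$ash1_peaks), "Ash1 peaks (",
      x$n_overlap, "co-called ),", length(x$mrg15_peaks),
      "Mrg15 peaks,", nrow(x$target_table), "target genes\n")
  invisible(x)
}

# Expected fraction of a fragment overlapping its source region when the
# fragment center is uniform over the region (closed form; L >= frag/2).
expected_overlap_fraction <- function(L, fragment) {
  pmax(1 - fragment / (4 * L), fragment / (4 * L))
}

# Sample reads for one signal component: expected counts per region are
# Poisson, fragment centers uniform within the region, read = the 5' end
# of the fragment on a random strand. Returns plain columns; the caller
# assembles a single GRanges per track.
sample_component_reads <- function(regions, expected, cfg) {
  m <- rpois(length(regions), expected)
  tot <- sum(m)
  chn <- names(cfg$chrom_sizes)
  if (tot == 0L) return(list(ch = integer(0), start = integer(0),
                             end = integer(0), neg = logical(0)))
  idx <- rep.int(seq_along(regions), m)
  w <- width(regions)[idx]
  centers <- start(regions)[idx] + floor(runif(tot) * w)
  half <- cfg$fragment_size %/% 2L
  ch <- match(as.character(seqnames(regions)), chn)[idx]
  lim <- unname(cfg$chrom_sizes)[ch]
  fs <- pmax(centers - half, 1)
  fe <- pmin(fs + cfg$fragment_size - 1L, lim)
  neg <- runif(tot) < 0.5
  rs <- fs
  rs[neg] <- pmax(fe[neg] - cfg$read_length + 1L, 1)
  re <- pmin(rs + cfg$read_length - 1L, lim)
  list(ch = ch, start = as.integer(rs), end = as.integer(re), neg = neg)
}

# Density-calibrated per-region expected counts: count weight makes the
# measured per-kb density proportional to the truth intensity.
density_weights <- function(regions, intensity, cfg) {
  L <- width(regions)
  intensity * (L / 1000) / expected_overlap_fraction(L, cfg$fragment_size)
}

#' Generate a condition/antibody read track
#'
#' Fragment reads are sampled component-wise (factor-specific peaks,
#' constant non-specific sites or domains, thin uniform background) with
#' per-condition multipliers from the truth set, then emitted as stranded
#' `read_length` reads at fragment 5' ends. Deterministic per
#' (seed, condition, antibody).
#'
#' @param truth a `TruthSet`.
#' @param condition `"WT"`, `"Ash1KD"`, or `"Mrg15KD"`.
#' @param antibody `"Ash1"`, `"Mrg15"`, `"H3K36me2"`, or `"H3K27me3"`.
#' @param annotation the `GeneModelSet` (needed for H3K27me3 under
#'   Ash1 KD, whose gain is planted at super-target gene bodies).
#' @return stranded `GRanges` of reads with seqlengths set.
#' @export
generate_tracks <- function(truth, condition, antibody, annotation = NULL) {
  stopifnot(inherits(truth, "TruthSet"))
  condition <- match.arg(condition, c("WT", "Ash1KD", "Mrg15KD"))
  antibody <- match.arg(antibody,
                        c("Ash1", "Mrg15", "H3K36me2", "H3K27me3"))
  cfg <- truth$config
  lib <- cfg$lib_sizes[[antibody]]
  ash1 <- truth$ash1_peaks
  comps <- list()
  add <- function(regions, weights, mass, mult = 1) {
    e <- mass * lib * weights / sum(weights) * mult
    comps[[length(comps) + 1L]] <<- list(regions = regions, expected = e)
  }
  uni_mass <- 0.05
  if (antibody == "Ash1") {
    mult <- switch(condition, WT = 1,
                   Ash1KD = cfg$ash1_kd_retained,
                   Mrg15KD = ash1$mrg15_kd_ash1_retained)
    add(ash1, density_weights(ash1, ash1$intensity, cfg),
        cfg$ash1_peak_mass, mult)
    add(truth$nonspecific_sites,
        truth$nonspecific_sites$w_ash1 *
          width(truth$nonspecific_sites) / 1000,
        cfg$ash1_nonspecific_mass)
  } else if (antibody == "Mrg15") {
    mult_a <- switch(condition, WT = 1,
                     Ash1KD = cfg$ash1_kd_mrg15_retained,
                     Mrg15KD = cfg$mrg15_kd_retained)
    mult_m <- switch(condition, WT = 1, Ash1KD = 1,
                     Mrg15KD = cfg$mrg15_kd_retained)
    add(ash1, density_weights(ash1, ash1$mrg15_intensity, cfg),
        cfg$mrg15_ash1_mass, mult_a)
    mo <- truth$mrg15_peaks[countOverlaps(truth$mrg15_peaks, ash1) == 0]
    add(mo, density_weights(mo, mo$intensity, cfg),
        cfg$mrg15_peak_mass, mult_m)
    add(truth$nonspecific_sites,
        truth$nonspecific_sites$w_mrg15 *
          width(truth$nonspecific_sites) / 1000,
        cfg$mrg15_nonspecific_mass)
  } else if (antibody == "H3K36me2") {
    mult <- switch(condition, WT = 1,
                   Ash1KD = cfg$ash1_kd_h3k36_retained,
                   Mrg15KD = cfg$mrg15_kd_h3k36_retained)
    add(ash1, density_weights(ash1, ash1$k36_intensity, cfg),
        cfg$h3k36_peak_mass, mult)
    add(truth$k36_domains,
        truth$k36_domains$level * width(truth$k36_domains) / 1000,
        cfg$h3k36_domain_mass)
  } else {                               # H3K27me3
    uni_mass <- 1 - cfg$h3k27_domain_mass
    add(truth$k27_domains,
        truth$k27_domains$level * width(truth$k27_domains) / 1000,
        cfg$h3k27_domain_mass)
    if (condition == "Ash1KD") {
      if (is.null(annotation))
        stop("annotation required for H3K27me3 under Ash1KD")
      sup_ids <- truth$target_table$gene_id[truth$target_table$is_super]
      sup <- annotation$genes[match(sup_ids,
                                    as.character(annotation$genes$gene_id))]
      add(sup, width(sup) / 1000, cfg$ash1_kd_h3k27_super_mass)
    }
  }
  genome <- GRanges(names(cfg$chrom_sizes),
                    IRanges(1L, as.integer(cfg$chrom_sizes)))
  comps[[length(comps) + 1L]] <- list(
    regions = genome,
    expected = uni_mass * lib * cfg$chrom_sizes / sum(cfg$chrom_sizes))
  with_seed(sub_seed(cfg$seed, paste("tracks", condition, antibody)), {
    parts <- lapply(comps, function(cp)
      sample_component_reads(cp$regions, cp$expected, cfg))
    chn <- names(cfg$chrom_sizes)
    neg <- unlist(lapply(parts, `[[`, "neg"), use.names = FALSE)
    GRanges(structure(unlist(lapply(parts, `[[`, "ch"),
                             use.names = FALSE),
                      levels = chn, class = "factor"),
            IRanges(unlist(lapply(parts, `[[`, "start"),
                           use.names = FALSE),
                    unlist(lapply(parts, `[[`, "end"),
                           use.names = FALSE)),
            strand = Rle(factor(ifelse(neg, "-", "+"),
                                levels = c("+", "-", "*"))),
            seqinfo = GenomeInfoDb::Seqinfo(chn, cfg$chrom_sizes))
  })
}

#' Generate expression tables with planted knockdown responders
#'
#' Lognormal baselines for all genes; under Ash1 KD, `n_down` planted
#' genes (mostly super targets) fall below `1/fold` and `n_up` rise above
#' `fold`; under Mrg15 KD the `n_mrg15_down` most-repressed planted super
#' targets receive the milder `mrg15_kd_expr_factor`. Multiplicative
#' lognormal noise on every measured column.
#'
#' @param truth a `TruthSet`.
#' @param annotation the `GeneModelSet`.
#' @return list: `table` (data.frame gene_id / wt / ash1_kd / mrg15_kd),
#'   `truth_classes` (planted class and factors per gene).
#' @export
generate_expression <- function(truth, annotation) {
  cfg <- truth$config
  with_seed(sub_seed(cfg$seed, "expression"), {
    gid <- as.character(annotation$genes$gene_id)
    n <- length(gid)
    base <- rlnorm(n, cfg$expr_baseline_meanlog, cfg$expr_baseline_sdlog)
    tt <- truth$target_table
    sup_ids <- tt$gene_id[tt$is_super]
    nonsup_targets <- tt$gene_id[!tt$is_super]
    down_ids <- c(sample(sup_ids, cfg$n_down_super),
                  sample(nonsup_targets, cfg$n_down - cfg$n_down_super))
    up_ids <- sample(setdiff(nonsup_targets, down_ids), cfg$n_up)
    responders <- c(down_ids, up_ids)
    base[match(responders, gid)] <-
      rlnorm(length(responders), cfg$expr_responder_meanlog,
             cfg$expr_responder_sdlog)
    fac_a <- rep(1, n)
    dfac <- runif(cfg$n_down, cfg$down_factor_range[1],
                  cfg$down_factor_range[2])
    fac_a[match(down_ids, gid)] <- dfac
    fac_a[match(up_ids, gid)] <- runif(cfg$n_up, cfg$up_factor_range[1],
                                       cfg$up_factor_range[2])
    # Mrg15 KD: milder repression of the most-repressed planted supers
    sup_down <- down_ids[seq_len(cfg$n_down_super)]
    sup_down_sorted <- sup_down[order(dfac[seq_len(cfg$n_down_super)])]
    m_ids <- sup_down_sorted[seq_len(cfg$n_mrg15_down)]
    fac_m <- rep(1, n)
    fac_m[match(m_ids, gid)] <- cfg$mrg15_kd_expr_factor
    noise <- function() exp(rnorm(n, 0, cfg$expr_noise_cv))
    tab <- data.frame(gene_id = gid,
                      wt = base * noise(),
                      ash1_kd = base * fac_a * noise(),
                      mrg15_kd = base * fac_m * noise(),
                      stringsAsFactors = FALSE)
    cls <- rep("unchanged", n)
    cls[match(down_ids, gid)] <- "down"
    cls[match(up_ids, gid)] <- "up"
    list(table = tab,
         truth_classes = data.frame(gene_id = gid, planted_class = cls,
                                    ash1_kd_factor = fac_a,
                                    mrg15_kd_factor = fac_m,
                                    stringsAsFactors = FALSE))
  })
}

#' Run the full simulator
#'
#' Convenience wrapper: annotation, landscape truth, the requested read
#' tracks, and expression tables, all from one master seed.
#'
#' @param cfg a `SimConfig`.
#' @param tracks data.frame with `condition` and `antibody` columns, or
#'   `NULL` for the default set covering the whole analysis (Ash1, Mrg15
#'   and H3K36me2 in WT and both knockdowns).
#' @return list: `config`, `annotation`, `truth`, `reads` (named
#'   `condition.antibody`), `expression`.
#' @export
simulate_experiment <- function(cfg, tracks = NULL) {
  if (is.null(tracks)) {
    tracks <- expand.grid(condition = c("WT", "Ash1KD", "Mrg15KD"),
                          antibody = c("Ash1", "Mrg15", "H3K36me2"),
                          stringsAsFactors = FALSE)
  }
  ann <- generate_annotation(cfg)
  truth <- generate_landscape(cfg, ann)
  reads <- lapply(seq_len(nrow(tracks)), function(i)
    generate_tracks(truth, tracks$condition[i], tracks$antibody[i],
                    annotation = ann))
  names(reads) <- paste(tracks$condition, tracks$antibody, sep = ".")
  expr <- generate_expression(truth, ann)
  list(config = cfg, annotation = ann, truth = truth, reads = reads,
       expression = expr)
}

#' Write a simulation to plain-file outputs
#'
#' GTF annotation, BED peak sets, BED read files, TSV expression table and
#' a JSON truth summary, under `dir`.
#'
#' @param sim result of [simulate_experiment()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(annotation = file.path(dir, "annotation.gtf"),
             ash1_peaks = file.path(dir, "ash1_peaks.bed"),
             mrg15_peaks = file.path(dir, "mrg15_peaks.bed"),
             expression = file.path(dir, "expression.tsv"),
             truth = file.path(dir, "truth.json"))
  write_gtf(sim$annotation, paths["annotation"])
  a <- sim$truth$ash1_peaks
  a$score <- a$intensity * 1e4    # BED score column: scaled intensity
  write_intervals(a, paths["ash1_peaks"], "bed")
  m <- sim$truth$mrg15_peaks
  m$score <- m$intensity * 1e4
  write_intervals(m, paths["mrg15_peaks"], "bed")
  fwrite(sim$expression$table, paths["expression"], sep = "\t")
  tt <- sim$truth$target_table
  write_json(list(seed = sim$config$seed,
                  n_ash1_peaks = length(sim$truth$ash1_peaks),
                  n_mrg15_peaks = length(sim$truth$mrg15_peaks),
                  n_overlap = sim$truth$n_overlap,
                  target_table = tt,
                  planted_classes = sim$expression$truth_classes),
             paths["truth"], auto_unbox = TRUE, digits = NA)
  for (nm in names(sim$reads)) {
    p <- file.path(dir, paste0("reads_", sub("\\.", "_", nm), ".bed"))
    r <- sim$reads[[nm]]
    fwrite(data.table(chrom = as.character(seqnames(r)),
                      start = start(r) - 1L, end = end(r),
                      name = ".", score = 0L,
                      strand = as.character(strand(r))),
           p, sep = "\t", col.names = FALSE)
    paths[paste0("reads_", nm)] <- p
  }
  invisible(paths)
}
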