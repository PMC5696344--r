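# Gene-level scoring: target assignment, first-exon regions, ranking,
# super-target detection, fold-change classes, enrichment.

test_that("target assignment uses gene-body overlap with exact boundaries", {
  ex <- methods::as(list(gA = GRanges("chrT", IRanges(c(1001, 2001),
                                                      c(1200, 2400)),
                                      strand = "+")), "GRangesList")
  genes <- GRanges("chrT", IRanges(1001, 2400), strand = "+",
                   gene_id = "gA", tx_id = "gA.t1")
  mod <- gene_model_set(genes, ex)
  # peak entirely inside the intron still marks the gene
  intronic <- GRanges("chrT", IRanges(1500, 1800))
  expect_true(assign_targets(mod, intronic)$has_peak)
  # peak starting 1 bp past the gene end is not a target at flank 0
  past <- GRanges("chrT", IRanges(2401, 2600))
  expect_false(assign_targets(mod, past)$has_peak)
  expect_true(assign_targets(mod, past, flank = 1)$has_peak)
})

test_that("target assignment equals the all-pairs overlap oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    mod <- random_models(60, chrom_len = 1e5)
    pk <- random_peaks(80, chrom_len = 1e5, chroms = "chrT",
                       named = FALSE)
    got <- assign_targets(mod, pk)
    want <- brute_overlapping(mod$genes, pk)
    expect_equal(got$has_peak, unname(want))
  }
})

test_that("short first exons are extended downstream to the floor", {
  mk <- function(s, e, strand) {
    ex <- methods::as(list(g1 = GRanges("chrT", IRanges(s, e),
                                        strand = strand)), "GRangesList")
    genes <- GRanges("chrT", IRanges(min(s), max(e)), strand = strand,
                     gene_id = "g1", tx_id = "g1.t1")
    gene_model_set(genes, ex)
  }
  # + strand 150 bp exon [100,250) -> [100,300): extend the end
  fe <- first_exon_regions(mk(101, 250, "+"))
  expect_equal(c(start(fe), end(fe)), c(101L, 300L))
  # - strand: extend toward lower coordinates (downstream)
  fe <- first_exon_regions(mk(1001, 1150, "-"))
  expect_equal(c(start(fe), end(fe)), c(951L, 1150L))
  # exon at the floor or above: unchanged
  fe <- first_exon_regions(mk(101, 300, "+"))
  expect_equal(c(start(fe), end(fe)), c(101L, 300L))
  # multi-exon minus-strand gene: first exon is the rightmost one
  ex <- methods::as(list(g1 = GRanges("chrT",
                                      IRanges(c(1001, 2001), c(1500, 2600)),
                                      strand = "-")), "GRangesList")
  genes <- GRanges("chrT", IRanges(1001, 2600), strand = "-",
                   gene_id = "g1", tx_id = "g1.t1")
  fe <- first_exon_regions(gene_model_set(genes, ex))
  expect_equal(c(start(fe), end(fe)), c(2001L, 2600L))
})

test_that("first-exon scoring follows the RP10M-per-kb formula", {
  ex <- methods::as(list(g1 = GRanges("chrT", IRanges(1001, 1500),
                                      strand = "+")), "GRangesList")
  genes <- GRanges("chrT", IRanges(1001, 1500), strand = "+",
                   gene_id = "g1", tx_id = "g1.t1")
  mod <- gene_model_set(genes, ex)
  # 20 fragments fully inside a 500 bp first exon, library 1e7 -> 20/0.5
  set.seed(41)
  fr <- GRanges("chrT", IRanges(sample(1001:1251, 20, replace = TRUE),
                                width = 250), strand = "+")
  rk <- score_and_rank(mod, "g1", fr, top_n = 1, library_size = 1e7)
  expect_equal(rk$score, 40)
})

test_that("ranking is a stable descending sort with gene-id tie-break", {
  set.seed(43)
  mod <- random_models(150, chrom_len = 3e5)
  reads <- random_reads(5000, chrom_len = 3e5)
  rk <- score_and_rank(mod, as.character(mod$genes$gene_id), reads,
                       top_n = 50)
  fe <- first_exon_regions(mod)
  want <- quantify_regions(reads, fe)$density
  names(want) <- names(fe)
  o <- order(-want, names(want))
  expect_equal(rk$gene_id, names(want)[o])
  expect_equal(rk$score, unname(want[o]))
  expect_equal(rk$rank, seq_len(150))
  expect_equal(sum(rk$top), 50L)
  # input order is irrelevant
  rk2 <- score_and_rank(mod, sample(as.character(mod$genes$gene_id)),
                        reads, top_n = 50)
  expect_equal(rk2$gene_id, rk$gene_id)
  expect_warning(score_and_rank(mod, "t001", reads, top_n = 5), "top_n")
})

test_that("super-target prefix is minimal for the share threshold", {
  # constructed exact hit: 45 + 11x5 = 100, threshold 0.45 -> one gene
  st <- detect_super_targets(c(45, rep(5, 11)), 0.45)
  expect_equal(st$n_super, 1L)
  expect_equal(st$share_captured, 0.45)
  # uniform scores: ceiling arithmetic
  st <- detect_super_targets(rep(1, 200), 0.45)
  expect_equal(st$n_super, 90L)
  # invariance under rescaling
  st2 <- detect_super_targets(rep(0.037, 200), 0.45)
  expect_equal(st2$n_super, 90L)
  expect_error(detect_super_targets(c(3, 1, 2)), "descending")
  expect_error(detect_super_targets(rep(0, 5)), "zero")
})

test_that("designed score vector puts exactly 26 supers at the 45% share", {
  cfg <- sim_config(seed = 1)
  s <- design_target_scores(cfg)
  expect_equal(length(s), 398L)
  expect_true(all(diff(s) < 0))
  st <- detect_super_targets(s[1:200], 0.45)
  expect_equal(st$n_super, 26L)
  # exhaustive prefix scan: cumulative-share oracle confirms minimality
  cs <- cumsum(s[1:200]) / sum(s[1:200])
  expect_true(all(cs[1:25] < 0.45))
  expect_gte(cs[26], 0.45)
  expect_equal(st$share_captured, cs[26])
})

test_that("fold-change classes match an independently coded filter", {
  expect_equal(as.character(
    fold_change_classify(10, 4, pseudocount = 0)$class), "down")
  expect_equal(as.character(
    fold_change_classify(3, 6.01, pseudocount = 0)$class), "up")
  expect_equal(as.character(
    fold_change_classify(3, 6.01)$class), "unchanged")  # pseudocount 1
  set.seed(47)
  wt <- rlnorm(500, 2, 1.5); kd <- rlnorm(500, 2, 1.5)
  got <- fold_change_classify(wt, kd, pseudocount = 1, fold = 2)
  fc <- (kd + 1) / (wt + 1)
  expect_equal(sum(got$class == "down"), sum(fc <= 0.5))
  expect_equal(sum(got$class == "up"), sum(fc >= 2))
  expect_equal(sum(got$class == "unchanged"), sum(fc > 0.5 & fc < 2))
  expect_error(fold_change_classify(c(-1, 2), c(1, 2)), "nonnegative")
})

test_that("repression enrichment: Haldane odds ratio and exact p", {
  r <- repression_enrichment(rep(c("down", "other"), each = 10),
                             rep(c(TRUE, FALSE), each = 10))
  expect_equal(r$odds_ratio, (10.5 * 10.5) / (0.5 * 0.5))
  r2 <- repression_enrichment(rep(c("down", "other"), 10),
                              rep(c(TRUE, TRUE, FALSE, FALSE), 5))
  expect_equal(r2$odds_ratio, 1)
  expect_equal(r2$p, 1)
  # random tables: p equals exhaustive hypergeometric enumeration
  set.seed(53)
  for (i in 1:25) {
    n <- sample(20:60, 1)
    cls <- sample(c("down", "other"), n, replace = TRUE,
                  prob = c(0.3, 0.7))
    sup <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(cls == "down") || !any(sup)) next
    r <- repression_enrichment(cls, sup)
    expect_equal(r$p, enum_hyper_p(r$table), tolerance = 1e-9)
  }
  expect_error(repression_enrichment(rep("other", 5),
                                     rep(TRUE, 5)), "down")
})
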