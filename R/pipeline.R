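# End-to-end pipeline: simulate -> quantify -> analyze -> report.
#
# Stages hand data off through plain files in the output directory so each
# stage is independently inspectable and the whole run is reproducible
# from the config echo; one structured log line per stage records timing
# and input fingerprints.

#' Fast BED6 reader for large read files
#'
#' @param path BED file of reads (0-based half-open).
#' @param chrom_sizes optional named lengths to set as seqlengths.
#' @return stranded `GRanges`.
#' @export
read_reads_bed <- function(path, chrom_sizes = NULL) {
  dt <- fread(path, header = FALSE, sep = "\t", data.table = FALSE)
  names(dt)[1:3] <- c("chrom", "start", "end")
  strand <- if (ncol(dt) >= 6) dt[[6]] else "*"
  gr <- GRanges(dt$chrom, IRanges(dt$start + 1L, dt$end), strand = strand)
  if (!is.null(chrom_sizes)) {
    seqlevels(gr) <- names(chrom_sizes)
    seqlengths(gr) <- chrom_sizes
  }
  gr
}

#' Default run configuration
#'
#' @param seed master seed.
#' @param out_dir output directory.
#' @param simulate named list of [sim_config()] overrides.
#' @param analysis named list: `depth_scale`, `profile_window`,
#'   `n_dependency_strata`, `n_ash1_strata`, `flank`.
#' @param kinetics named list: `enabled`, `vmax`, `km`, `vmax_effect`,
#'   `km_effect`, `noise_cv`.
#' @return a validated run-config list.
#' @export
run_config <- function(seed = 1, out_dir = tempfile("cochip_run_"),
                       simulate = list(), analysis = list(),
                       kinetics = list()) {
  ana <- list(depth_scale = 1e7, profile_window = 2000,
              n_dependency_strata = 5, n_ash1_strata = 3, flank = 0,
              export_bedgraph = FALSE)
  bad <- setdiff(names(analysis), names(ana))
  if (length(bad)) stop("unknown analysis key(s): ",
                        paste(bad, collapse = ", "))
  ana[names(analysis)] <- analysis
  kin <- list(enabled = TRUE, vmax = 10, km = 2, vmax_effect = 2.5,
              km_effect = 1, noise_cv = 0.05)
  bad <- setdiff(names(kinetics), names(kin))
  if (length(bad)) stop("unknown kinetics key(s): ",
                        paste(bad, collapse = ", "))
  kin[names(kinetics)] <- kinetics
  list(seed = seed, out_dir = out_dir, simulate = simulate,
       analysis = ana, kinetics = kin)
}

#' Load a run configuration from YAML
#'
#' Unknown top-level keys are rejected.
#'
#' @param path YAML file.
#' @return a run-config list (see [run_config()]).
#' @export
read_run_config <- function(path) {
  y <- read_yaml(path)
  known <- c("seed", "out_dir", "simulate", "analysis", "kinetics")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config key(s): ",
                        paste(bad, collapse = ", "))
  do.call(run_config, y)
}

#' Run the full analysis pipeline
#'
#' Stages: simulate, coverage, overlap, matrix, correlation, profiles,
#' stratify, dependency, targets, expression, kinetics (optional). Outputs
#' land in `config$out_dir`; the returned bundle carries every stage's
#' in-memory result plus file paths, the config echo and a timing log.
#' Reruns with the same config and seed are numerically identical.
#'
#' @param config list from [run_config()] / [read_run_config()], or a
#'   path to a YAML config.
#' @return the results bundle, invisibly a list.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  bundle <- list(config = config)
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log[[length(log) + 1L]] <<- data.frame(
      stage = name, seconds = round(proc.time()[["elapsed"]] - t0, 2))
    res
  }
  scfg <- do.call(sim_config,
                  c(list(seed = config$seed), config$simulate))
  ana <- config$analysis

  sim <- stage("simulate", function() {
    s <- simulate_experiment(scfg)
    bundle$paths <<- write_simulation(s, config$out_dir)
    s
  })
  cs <- scfg$chrom_sizes
  need <- function(key) {
    p <- bundle$paths[[paste0("reads_", key)]]
    if (is.null(p) || !file.exists(p))
      stop("missing stage input: reads for ", key)
    read_reads_bed(p, cs)
  }

  reads <- stage("coverage", function() {
    keys <- names(sim$reads)
    rl <- lapply(keys, need)
    names(rl) <- keys
    if (isTRUE(ana$export_bedgraph)) {
      for (k in keys) {
        tr <- build_coverage(rl[[k]], fragment_size = scfg$fragment_size,
                             bin_size = scfg$bin_size,
                             depth_scale = ana$depth_scale,
                             chrom_lengths = cs)
        track_to_bedgraph(tr, file.path(config$out_dir,
                                        paste0("coverage_",
                                               sub("\\.", "_", k), ".bg")))
      }
    }
    rl
  })

  ash1_peaks <- read_intervals(bundle$paths[["ash1_peaks"]], "bed")
  mrg15_peaks <- read_intervals(bundle$paths[["mrg15_peaks"]], "bed")

  bundle$overlap <- stage("overlap", function() {
    ov <- overlap_peaks(ash1_peaks, mrg15_peaks)
    write_json(ov[setdiff(names(ov), "pairs")],
               file.path(config$out_dir, "overlap.json"),
               auto_unbox = TRUE, digits = NA)
    ov
  })

  bundle$matrix <- stage("matrix", function() {
    m <- signal_matrix(ash1_peaks, reads, depth_scale = ana$depth_scale,
                       fragment_size = scfg$fragment_size)
    out <- data.frame(peak = rownames(m), m, check.names = FALSE)
    fwrite(out, file.path(config$out_dir, "signal_matrix.tsv"), sep = "\t")
    m
  })

  bundle$correlation <- stage("correlation", function() {
    r <- correlate_intensities(bundle$matrix[, "WT.Ash1"],
                               bundle$matrix[, "WT.Mrg15"])
    write_json(r, file.path(config$out_dir, "correlation.json"),
               auto_unbox = TRUE, digits = NA)
    r
  })

  bundle$profiles <- stage("profiles", function() {
    keys <- c("WT.Ash1", "WT.Mrg15", "WT.H3K36me2", "Ash1KD.H3K36me2",
              "Mrg15KD.H3K36me2")
    prof <- lapply(keys, function(k) {
      tr <- build_coverage(reads[[k]], fragment_size = scfg$fragment_size,
                           bin_size = scfg$bin_size,
                           depth_scale = ana$depth_scale,
                           chrom_lengths = cs)
      metaprofile(ash1_peaks, tr, window = ana$profile_window)
    })
    names(prof) <- keys
    out <- data.frame(offset = prof[[1]]$offsets,
                      vapply(prof, `[[`, prof[[1]]$mean_profile,
                             "mean_profile"))
    fwrite(out, file.path(config$out_dir, "mean_profiles.tsv"), sep = "\t")
    prof
  })

  bundle$stratified <- stage("stratify", function() {
    s <- stratify_by_cofactor(bundle$matrix[, "WT.H3K36me2"],
                              bundle$matrix[, "WT.Mrg15"],
                              bundle$matrix[, "WT.Ash1"],
                              n_ash1_strata = ana$n_ash1_strata)
    fwrite(s$summary, file.path(config$out_dir, "stratified_h3k36.tsv"),
           sep = "\t")
    s
  })

  bundle$dependency <- stage("dependency", function() {
    dep <- dependency_analysis(bundle$matrix[, "WT.Ash1"],
                               bundle$matrix[, "Mrg15KD.Ash1"],
                               n_strata = ana$n_dependency_strata)
    fwrite(dep$retained, file.path(config$out_dir,
                                   "ash1_dependency_on_mrg15.tsv"),
           sep = "\t")
    k36 <- list(
      ash1_kd_retained = mean(bundle$matrix[, "Ash1KD.H3K36me2"]) /
        mean(bundle$matrix[, "WT.H3K36me2"]),
      mrg15_kd_retained = mean(bundle$matrix[, "Mrg15KD.H3K36me2"]) /
        mean(bundle$matrix[, "WT.H3K36me2"]))
    write_json(k36, file.path(config$out_dir, "h3k36_retained.json"),
               auto_unbox = TRUE, digits = NA)
    c(dep, k36)
  })

  bundle$targets <- stage("targets", function() {
    models <- read_intervals(bundle$paths[["annotation"]], "gtf")
    tg <- assign_targets(models, ash1_peaks, flank = ana$flank)
    ranked <- score_and_rank(models, tg$gene_id[tg$has_peak],
                             reads[["WT.Ash1"]], top_n = scfg$top_n,
                             depth_scale = ana$depth_scale,
                             fragment_size = scfg$fragment_size)
    st <- detect_super_targets(ranked, share_threshold = scfg$super_share)
    fwrite(ranked, file.path(config$out_dir, "target_genes.tsv"),
           sep = "\t")
    writeLines(st$super_ids, file.path(config$out_dir,
                                       "super_targets.txt"))
    write_json(st[c("n_super", "share_captured", "top_n")],
               file.path(config$out_dir, "super_targets.json"),
               auto_unbox = TRUE, digits = NA)
    list(models = models, table = tg, ranked = ranked, super = st)
  })

  bundle$expression <- stage("expression", function() {
    et <- fread(bundle$paths[["expression"]], sep = "\t",
                data.table = FALSE)
    cls <- fold_change_classify(et$wt, et$ash1_kd, et$gene_id,
                                fold = scfg$fold)
    tg <- bundle$targets$table
    target_cls <- cls[cls$gene_id %in% tg$gene_id[tg$has_peak], ]
    enr <- repression_enrichment(
      target_cls$class,
      target_cls$gene_id %in% bundle$targets$super$super_ids)
    fwrite(cls, file.path(config$out_dir, "expression_classes.tsv"),
           sep = "\t")
    write_json(list(n_down = sum(target_cls$class == "down"),
                    n_up = sum(target_cls$class == "up"),
                    odds_ratio = enr$odds_ratio, p = enr$p),
               file.path(config$out_dir, "expression_enrichment.json"),
               auto_unbox = TRUE, digits = NA)
    list(classes = cls, target_classes = target_cls, enrichment = enr)
  })

  if (isTRUE(config$kinetics$enabled)) {
    bundle$kinetics <- stage("kinetics", function() {
      kc <- config$kinetics
      dA <- simulate_kinetics(kc$vmax, kc$km, noise_cv = kc$noise_cv,
                              seed = sub_seed(config$seed, "kinetics A"))
      dB <- simulate_kinetics(kc$vmax * kc$vmax_effect,
                              kc$km * kc$km_effect,
                              noise_cv = kc$noise_cv,
                              seed = sub_seed(config$seed, "kinetics B"))
      fA <- fit_mm(dA); fB <- fit_mm(dB)
      cmp <- compare_fits(fA, fB)
      write_json(list(enzyme_a = fA[c("vmax", "km", "vmax_se", "km_se")],
                      enzyme_b = fB[c("vmax", "km", "vmax_se", "km_se")],
                      comparison = cmp),
                 file.path(config$out_dir, "kinetics.json"),
                 auto_unbox = TRUE, digits = NA)
      list(fit_a = fA, fit_b = fB, comparison = cmp)
    })
  }

  logdf <- do.call(rbind, log)
  logdf$tool_version <- as.character(packageVersion("cochip"))
  fwrite(logdf, file.path(config$out_dir, "run_log.tsv"), sep = "\t")
  cfg_echo <- config
  cfg_echo$simulate <- scfg[setdiff(names(scfg), "chrom_sizes")]
  cfg_echo$simulate$chrom_sizes <- as.list(scfg$chrom_sizes)
  write_json(cfg_echo, file.path(config$out_dir, "config.json"),
             auto_unbox = TRUE, digits = NA, force = TRUE)
  bundle$log <- logdf
  invisible(bundle)
}
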