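# Interval and annotation I/O.
#
# Internal coordinates follow the Bioconductor convention (GRanges, 1-based
# closed); BED's 0-based half-open and GTF's 1-based closed coordinates are
# converted at the I/O boundary by rtracklayer, never inside analysis code.

#' Read genomic intervals, peaks, or gene models from standard formats
#'
#' Supported formats: BED3/BED6 (returns a `GRanges`, with `name`/`score`
#' metadata when present), bedGraph (a `GRanges` with a `score` column), and
#' GTF/GFF (a [gene_model_set()] with one representative transcript chosen
#' per gene). The format is inferred from the file extension unless given.
#'
#' BED records with `start >= end` are rejected with a warning and counted;
#' lines that cannot be parsed at all raise an error naming the line number.
#' Records are returned sorted by (chrom, start, end, name).
#'
#' @param path path to the input file.
#' @param format one of `"auto"`, `"bed"`, `"bedgraph"`, `"gtf"`, `"gff"`.
#' @param strip_chr_prefix prefix stripped from chromosome names for
#'   namespace normalization; `""` disables stripping.
#' @return a `GRanges` (BED/bedGraph) or a `GeneModelSet` (GTF/GFF).
#' @export
read_intervals <- function(path, format = c("auto", "bed", "bedgraph",
                                            "gtf", "gff"),
                           strip_chr_prefix = "") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- infer_format(path)
  gr <- switch(format,
    bed      = read_bed_checked(path),
    bedgraph = read_bedgraph_checked(path),
    gtf      = ,
    gff      = return(gene_models_from_gtf(import_gtf_checked(path, format),
                                           strip_chr_prefix)),
    stop("unsupported format: ", format)
  )
  if (nzchar(strip_chr_prefix)) {
    seqlevels(gr) <- norm_chrom_names(seqlevels(gr), strip_chr_prefix)
  }
  sort_intervals(gr)
}

infer_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
         bed = "bed", bedgraph = "bedgraph", bg = "bedgraph",
         gtf = "gtf", gff = "gff", gff3 = "gff",
         stop("cannot infer format from extension: .", ext))
}

# Sort by (chrom, start, end, name): stable and total.
sort_intervals <- function(gr) {
  nm <- if (!is.null(gr$name)) as.character(gr$name) else rep("", length(gr))
  gr[order(as.character(seqnames(gr)), start(gr), end(gr), nm)]
}

# Pre-validate a BED file: malformed lines are fatal (with line number),
# empty intervals (start >= end in 0-based half-open terms) are dropped
# with a warning. Parsing proper is delegated to rtracklayer.
read_bed_checked <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)|^\\s*$", lines)
  body <- lines[keep]
  if (length(body) == 0L) {
    return(GRanges())
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad)) {
    stop("malformed BED line ", which(keep)[bad[1]], " in ", path,
         ": fewer than 3 fields")
  }
  starts <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  ends   <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(starts) | is.na(ends))
  if (length(bad)) {
    stop("malformed BED line ", which(keep)[bad[1]], " in ", path,
         ": non-numeric coordinates")
  }
  empty <- starts >= ends
  if (any(empty)) {
    warning(sum(empty), " BED record(s) with start >= end rejected")
    if (all(empty)) return(GRanges())
    tmp <- tempfile(fileext = ".bed")
    on.exit(unlink(tmp))
    writeLines(body[!empty], tmp)
    return(import(tmp, format = "BED"))
  }
  import(path, format = "BED")
}

read_bedgraph_checked <- function(path) {
  gr <- tryCatch(import(path, format = "bedGraph"),
                 error = function(e) stop("parse error in bedGraph file ",
                                          path, ": ", conditionMessage(e)))
  gr
}

import_gtf_checked <- function(path, format) {
  tryCatch(import(path, format = format),
           error = function(e) stop("parse error in ", toupper(format),
                                    " file ", path, ": ",
                                    conditionMessage(e)))
}

#' Write genomic intervals to a standard format
#'
#' Inverse of [read_intervals()]. Output is byte-deterministic for a fixed
#' input ordering. bedGraph output must be sorted and non-overlapping;
#' peak sets with duplicate names are refused.
#'
#' @param records a `GRanges` (BED/bedGraph) or `GeneModelSet` (GTF).
#' @param path output file path.
#' @param format `"bed"`, `"bedgraph"`, or `"gtf"`.
#' @return the path, invisibly.
#' @export
write_intervals <- function(records, path,
                            format = c("bed", "bedgraph", "gtf")) {
  format <- match.arg(format)
  if (format == "gtf") {
    if (!inherits(records, "GeneModelSet"))
      stop("GTF output requires a GeneModelSet")
    return(write_gtf(records, path))
  }
  stopifnot(is(records, "GRanges"))
  if (format == "bed") {
    if (!is.null(records$name)) {
      nm <- as.character(records$name)
      if (anyDuplicated(nm))
        stop("duplicate peak names in BED output: ",
             paste(head(unique(nm[duplicated(nm)]), 3), collapse = ", "))
    }
    export(records, path, format = "BED")
  } else {
    if (is.null(records$score)) stop("bedGraph output requires a score column")
    records <- sort_intervals(records)
    if (length(records) > 1L) {
      ov <- findOverlaps(records, drop.self = TRUE, drop.redundant = TRUE)
      if (length(ov) > 0L) stop("bedGraph steps must be non-overlapping")
    }
    export(records, path, format = "bedGraph")
  }
  invisible(path)
}

#' Gene models with one representative transcript per gene
#'
#' A light container pairing gene bodies (a `GRanges` with `gene_id` and
#' `tx_id`) with the representative transcript's exons (a `GRangesList`
#' named by `gene_id`, exons in genomic order).
#'
#' @param genes `GRanges` of gene bodies with `gene_id`, `tx_id` metadata.
#' @param exons `GRangesList` of exons, names matching `genes$gene_id`.
#' @return an object of class `GeneModelSet`.
#' @export
gene_model_set <- function(genes, exons) {
  stopifnot(is(genes, "GRanges"), is(exons, "GRangesList"),
            !is.null(genes$gene_id),
            identical(names(exons), as.character(genes$gene_id)))
  structure(list(genes = genes, exons = exons), class = "GeneModelSet")
}

#' @export
print.GeneModelSet <- function(x, ...) {
  cat("GeneModelSet:", length(x$genes), "genes on",
      length(seqlevelsInUse(x$genes)), "chromosome(s)\n")
  invisible(x)
}

#' @export
length.GeneModelSet <- function(x) length(x$genes)

#' Build gene models from imported GTF/GFF records
#'
#' One representative transcript is chosen per gene: the transcript whose
#' TSS is most 5' in the transcription direction; ties broken by longer
#' first exon, then by lexicographically smallest transcript id. This is a
#' package convention -- annotation formats do not designate an isoform.
#'
#' @param gr `GRanges` as returned by `rtracklayer::import` on a GTF/GFF,
#'   with `type`, `gene_id` and `transcript_id` metadata.
#' @param strip_chr_prefix chromosome-name prefix to strip (`""` = keep).
#' @return a `GeneModelSet`.
#' @export
gene_models_from_gtf <- function(gr, strip_chr_prefix = "") {
  if (is.null(gr$type) || is.null(gr$gene_id))
    stop("GTF/GFF records lack type/gene_id attributes")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) stop("no exon records in annotation")
  tx_id <- as.character(ex$transcript_id)
  if (anyNA(tx_id)) stop("exon records lack transcript_id")
  dt <- data.table(
    chrom = as.character(seqnames(ex)),
    start = start(ex), end = end(ex),
    strand = as.character(strand(ex)),
    gene_id = as.character(ex$gene_id), tx_id = tx_id)
  if (nzchar(strip_chr_prefix))
    dt$chrom <- norm_chrom_names(dt$chrom, strip_chr_prefix)
  # per-transcript summary: TSS and first-exon length in transcription order
  txs <- dt[, {
    fwd <- strand[1] != "-"
    tss <- if (fwd) min(start) else max(end)
    fe  <- if (fwd) which.min(start) else which.max(end)
    list(chrom = chrom[1], strand = strand[1], tss = tss,
         first_len = end[fe] - start[fe] + 1L,
         gene_id = gene_id[1])
  }, by = tx_id]
  # representative per gene: most 5' TSS, then longest first exon, then id
  txs[, tss_key := ifelse(strand == "-", -tss, tss)]
  data.table::setorder(txs, gene_id, tss_key, -first_len, tx_id)
  rep_tx <- txs[, .SD[1], by = gene_id]
  keep <- dt[tx_id %in% rep_tx$tx_id]
  data.table::setorder(keep, gene_id, start)
  exg <- GRanges(keep$chrom, IRanges(keep$start, keep$end),
                 strand = keep$strand)
  exl <- split(exg, keep$gene_id)
  bodies <- unlist(range(exl))
  gid <- names(bodies)
  genes <- GRanges(seqnames(bodies), ranges(bodies), strand = strand(bodies),
                   gene_id = gid,
                   tx_id = rep_tx$tx_id[match(gid, rep_tx$gene_id)])
  o <- order(as.character(seqnames(genes)), start(genes), genes$gene_id)
  genes <- genes[o]
  gene_model_set(genes, exl[as.character(genes$gene_id)])
}

#' Write a GeneModelSet as GTF
#'
#' Emits one `gene` line and per-exon `exon` lines for the representative
#' transcript of every gene. Reading the file back with [read_intervals()]
#' reproduces the models.
#'
#' @param models a `GeneModelSet`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gtf <- function(models, path) {
  stopifnot(inherits(models, "GeneModelSet"))
  g <- models$genes
  ex <- unlist(models$exons, use.names = TRUE)
  gid <- names(ex)
  out <- c(
    GRanges(seqnames(g), ranges(g), strand = strand(g),
            source = "cochip", type = "gene",
            gene_id = as.character(g$gene_id),
            transcript_id = as.character(g$tx_id)),
    GRanges(seqnames(ex), ranges(ex), strand = strand(ex),
            source = "cochip", type = "exon",
            gene_id = gid,
            transcript_id = as.character(
              g$tx_id[match(gid, as.character(g$gene_id))]))
  )
  out <- out[order(as.character(seqnames(out)), start(out),
                   match(out$type, c("gene", "exon")))]
  export(out, path, format = "gtf")
  invisible(path)
}
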