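# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a tag
#'
#' Every stochastic component of the simulator draws from its own stream,
#' seeded deterministically from the master seed and a component tag, so
#' that adding or reordering components never perturbs the others.
#'
#' @param seed master integer seed.
#' @param tag character tag naming the stream.
#' @return an integer seed in `[0, 2^31)`.
#' @keywords internal
sub_seed <- function(seed, tag) {
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes)) %% 100003
  as.integer((as.numeric(seed) %% 2147483629 * 20011 + h * 7919 + 13) %%
               2147483629)
}

#' Strip a chromosome-name prefix for dialect-tolerant comparison
#'
#' "chr2L" and "2L" refer to the same chromosome in different annotation
#' dialects; comparisons are made after stripping the configured prefix.
#'
#' @param x character vector of chromosome names.
#' @param strip prefix to remove (default `"chr"`).
#' @return character vector of normalized names.
#' @export
norm_chrom_names <- function(x, strip = "chr") {
  if (nzchar(strip)) sub(paste0("^", strip), "", as.character(x))
  else as.character(x)
}

# Shared-namespace check between two GRanges-like objects; errors rather
# than silently reporting zero overlap when dialects are mixed.
check_shared_namespace <- function(a, b, what = c("setA", "setB")) {
  ca <- unique(norm_chrom_names(as.character(seqnames(a))))
  cb <- unique(norm_chrom_names(as.character(seqnames(b))))
  if (length(intersect(ca, cb)) == 0L) {
    stop("no shared chromosomes between ", what[1], " and ", what[2],
         " (possible coordinate-dialect mismatch: ",
         paste(head(ca, 3), collapse = ","), " vs ",
         paste(head(cb, 3), collapse = ","), ")")
  }
  invisible(TRUE)
}

# Quantile-based stratum index: 1..k, balanced by rank, stable for ties.
ntile_strata <- function(x, k) {
  n <- length(x)
  if (n < k) stop("fewer observations (", n, ") than strata (", k, ")")
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r / (n / k)))
}

# Evaluate an expression under a local RNG state seeded by `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
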