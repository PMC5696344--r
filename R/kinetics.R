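# Michaelis-Menten kinetics for scintillation HMT assays.
#
# v = Vmax * S / (Km + S) is fitted per replicate series by unweighted
# nonlinear least squares on a log-parameterization (positivity without
# constraints); the point estimate is the mean of the replicate fits and
# the s.e.m. is sd/sqrt(n), matching how duplicate assays are reported.

#' Assemble a kinetics dataset
#'
#' @param substrate_conc strictly positive, distinct substrate
#'   concentrations (uM nucleosome), at least 4.
#' @param rate_replicates matrix of measured rates (d.p.m.), one row per
#'   concentration, at least 2 replicate columns.
#' @param cofactor_conc labeled methyl-donor concentration (uM), metadata.
#' @return object of class `KineticsDataset`.
#' @export
kinetics_dataset <- function(substrate_conc, rate_replicates,
                             cofactor_conc = NA_real_) {
  rate_replicates <- as.matrix(rate_replicates)
  if (length(substrate_conc) < 4)
    stop("need at least 4 substrate concentrations")
  if (any(substrate_conc <= 0)) stop("concentrations must be positive")
  if (anyDuplicated(substrate_conc)) stop("concentrations must be distinct")
  if (nrow(rate_replicates) != length(substrate_conc))
    stop("rate matrix rows must match concentrations")
  if (ncol(rate_replicates) < 2) stop("need at least 2 replicates")
  structure(list(S = as.numeric(substrate_conc),
                 rates = rate_replicates,
                 cofactor_conc = cofactor_conc),
            class = "KineticsDataset")
}

#' Read a kinetics assay table from CSV
#'
#' Expected columns: `S_uM`, then `rate_rep1`, `rate_rep2`, ...
#'
#' @param path CSV path.
#' @param cofactor_conc optional metadata.
#' @return a `KineticsDataset`.
#' @export
read_kinetics_csv <- function(path, cofactor_conc = NA_real_) {
  df <- read.table(path, sep = ",", header = TRUE)
  if (!"S_uM" %in% names(df)) stop("missing S_uM column in ", path)
  repcols <- grep("^rate_rep", names(df), value = TRUE)
  if (length(repcols) < 2) stop("need >= 2 rate_rep* columns in ", path)
  kinetics_dataset(df$S_uM, as.matrix(df[repcols]), cofactor_conc)
}

# Single-series fit: log-parameterized Levenberg-Marquardt least squares.
# Init: Vmax0 = 1.2 * max(v); Km0 = S at half-maximal v, interpolated.
fit_mm_one <- function(S, v, max_iter = 500) {
  vmax0 <- 1.2 * max(v)
  km0 <- tryCatch(
    suppressWarnings(approx(v, S, xout = max(v) / 2, ties = mean)$y),
    error = function(e) NA_real_)   # degenerate (e.g. constant) rates
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(S)
  df <- data.frame(S = S, v = v)
  fit <- tryCatch(
    nlsLM(v ~ exp(lV) * S / (exp(lK) + S), data = df,
          start = list(lV = log(vmax0), lK = log(km0)),
          control = nls.lm.control(maxiter = max_iter, ftol = 1e-12,
                                   ptol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # singular gradients (e.g. saturated/constant rates): direct search
    # on the log scale, flagged as poorly determined
    obj <- function(p) sum((v - exp(p[1]) * S / (exp(p[2]) + S))^2)
    op <- stats::optim(c(log(vmax0), log(km0)), obj,
                       control = list(maxit = 5000, reltol = 1e-14))
    return(list(vmax = exp(op$par[1]), km = exp(op$par[2]),
                rss = op$value, converged = FALSE))
  }
  p <- coef(fit)
  conv <- fit$convInfo$isConv %||% TRUE
  list(vmax = exp(p[["lV"]]), km = exp(p[["lK"]]),
       rss = sum(stats::residuals(fit)^2), converged = isTRUE(conv))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the Michaelis-Menten model to a kinetics dataset
#'
#' Each replicate series is fitted independently; the reported Vmax and Km
#' are the means of the replicate estimates with s.e.m. `sd/sqrt(n)`.
#' A pooled fit over all points is available with `pooled = TRUE`.
#'
#' @param dataset a `KineticsDataset`.
#' @param pooled fit all replicates jointly instead (no s.e.m.).
#' @return object of class `KineticsFit`: `vmax`, `km`, `vmax_se`,
#'   `km_se`, `rss`, `converged`, `replicates` (per-replicate estimates),
#'   `n_rep`.
#' @export
fit_mm <- function(dataset, pooled = FALSE) {
  stopifnot(inherits(dataset, "KineticsDataset"))
  S <- dataset$S
  if (pooled) {
    v <- as.numeric(dataset$rates)
    f <- fit_mm_one(rep(S, ncol(dataset$rates)), v)
    reps <- data.frame(vmax = f$vmax, km = f$km)
    out <- list(vmax = f$vmax, km = f$km, vmax_se = NA_real_,
                km_se = NA_real_, rss = f$rss, converged = f$converged,
                replicates = reps, n_rep = 1L)
  } else {
    fits <- lapply(seq_len(ncol(dataset$rates)), function(j)
      fit_mm_one(S, dataset$rates[, j]))
    vm <- vapply(fits, `[[`, 0, "vmax")
    km <- vapply(fits, `[[`, 0, "km")
    n <- length(fits)
    out <- list(vmax = mean(vm), km = mean(km),
                vmax_se = sd(vm) / sqrt(n), km_se = sd(km) / sqrt(n),
                rss = sum(vapply(fits, `[[`, 0, "rss")),
                converged = all(vapply(fits, `[[`, TRUE, "converged")),
                replicates = data.frame(vmax = vm, km = km), n_rep = n)
  }
  structure(out, class = "KineticsFit")
}

#' @export
print.KineticsFit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit: Vmax = %.4g +/- %.3g, Km = %.4g +/- %.3g (n = %d)\n",
              x$vmax, x$vmax_se, x$km, x$km_se, x$n_rep))
  if (!x$converged) cat("  warning: fit did not converge\n")
  invisible(x)
}

#' Compare two kinetics fits parameter-wise
#'
#' Two-sided two-sample Student's t test (pooled variance,
#' `df = n1 + n2 - 2`) on the replicate-level Vmax estimates and on the
#' replicate-level Km estimates, separately.
#'
#' @param fitA,fitB `KineticsFit` objects with replicate-level estimates.
#' @param alpha significance level for the `significant` flag (0.05).
#' @return data.frame with rows `vmax`, `km`: `t`, `df`, `p`,
#'   `significant`.
#' @export
compare_fits <- function(fitA, fitB, alpha = 0.05) {
  stopifnot(inherits(fitA, "KineticsFit"), inherits(fitB, "KineticsFit"))
  one <- function(a, b) {
    n1 <- length(a); n2 <- length(b)
    if (n1 < 2 || n2 < 2) stop("replicate-level estimates required")
    sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
    if (sp2 == 0) stop("zero pooled variance: t statistic undefined")
    tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    dfree <- n1 + n2 - 2
    c(t = tt, df = dfree, p = 2 * pt(-abs(tt), dfree))
  }
  v <- one(fitA$replicates$vmax, fitB$replicates$vmax)
  k <- one(fitA$replicates$km, fitB$replicates$km)
  out <- data.frame(parameter = c("vmax", "km"),
                    t = c(v["t"], k["t"]), df = c(v["df"], k["df"]),
                    p = c(v["p"], k["p"]))
  out$significant <- out$p < alpha
  out
}

#' Simulate a kinetics assay
#'
#' Rates follow the Michaelis-Menten curve with multiplicative lognormal
#' noise, matching the duplicate assay design.
#'
#' @param vmax,km true parameters.
#' @param S substrate concentrations (uM); the default spans 1/8x to 4x Km
#'   around `km = 2`.
#' @param n_rep replicates per concentration (default 2).
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (default 0.05).
#' @param seed optional RNG seed.
#' @return a `KineticsDataset`.
#' @export
simulate_kinetics <- function(vmax, km, S = c(0.25, 0.5, 1, 2, 4, 8),
                              n_rep = 2, noise_cv = 0.05, seed = NULL) {
  sim <- function() {
    mu <- vmax * S / (km + S)
    rates <- vapply(seq_len(n_rep), function(j)
      mu * exp(rnorm(length(S), 0, noise_cv)), numeric(length(S)))
    kinetics_dataset(S, rates)
  }
  if (is.null(seed)) sim() else with_seed(seed, sim())
}
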