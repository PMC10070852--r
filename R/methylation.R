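# Methylation module: beta/M transforms and genotype inference from the
# tripartite M-value distribution at a SNP-overlapping probe.

#' Convert methylation beta-values to M-values
#'
#' M = log2(beta / (1 - beta)). Beta-values are clipped to
#' [eps, 1 - eps] before the log-ratio so boundary values stay finite; the
#' transform is strictly increasing in beta.
#'
#' @param beta numeric vector of methylation fractions in [0, 1].
#' @param eps clipping bound applied before the log-ratio (default 1e-6).
#' @param sampleIds optional identifiers used in error messages.
#' @return numeric vector of M-values.
#' @examples
#' betaToM(c(0.2, 0.5, 0.8))  # -2, 0, 2
#' @seealso [mToBeta()]
#' @export
betaToM <- function(beta, eps = 1e-6, sampleIds = NULL) {
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1))
  if (length(bad)) {
    who <- if (is.null(sampleIds)) paste0("element ", bad[1]) else
      sampleIds[bad[1]]
    stop("beta-value outside [0, 1] for sample ", who, ": ", beta[bad[1]])
  }
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Convert M-values back to beta-values
#'
#' Inverse of [betaToM()] (up to boundary clipping):
#' beta = 2^M / (1 + 2^M).
#'
#' @param m numeric vector of finite M-values.
#' @return numeric vector of methylation fractions.
#' @examples
#' mToBeta(c(-2, 0, 2))  # 0.2, 0.5, 0.8
#' @export
mToBeta <- function(m) {
  if (any(!is.finite(m) & !is.na(m)))
    stop("non-finite M-value")
  # 1/(1+2^-m) is stable for large |m|
  1 / (1 + 2^(-m))
}

# log-density of the mixture, rows = observations, cols = components
.mixtureLogDens <- function(x, weights, means, sds) {
  k <- length(weights)
  ld <- matrix(0, length(x), k)
  for (j in seq_len(k))
    ld[, j] <- log(weights[j]) + dnorm(x, means[j], sds[j], log = TRUE)
  ld
}

.logSumExpRows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# EM for a univariate Gaussian mixture with deterministic quantile
# initialization. Returns a plain list; sorting/packaging happens above.
.emFit <- function(x, k, tol = 1e-8, maxIter = 500L, varFloor = 1e-4) {
  n <- length(x)
  probs <- seq(0.1, 0.9, length.out = max(k, 1L))
  if (k == 1L) probs <- 0.5
  means <- as.numeric(quantile(x, probs, names = FALSE, type = 7))
  # jitter-free separation of coincident quantiles via data range
  if (k > 1L && any(diff(means) <= 0)) {
    rng <- range(x)
    means <- seq(rng[1], rng[2], length.out = k)
  }
  sds <- rep(max(sd(x), sqrt(varFloor)), k)
  weights <- rep(1 / k, k)
  prevLL <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxIter)) {
    ld <- .mixtureLogDens(x, weights, means, sds)
    lse <- .logSumExpRows(ld)
    ll <- sum(lse)
    resp <- exp(ld - lse)
    nk <- colSums(resp)
    weights <- nk / n
    means <- colSums(resp * x) / nk
    for (j in seq_len(k)) {
      v <- sum(resp[, j] * (x - means[j])^2) / nk[j]
      sds[j] <- sqrt(max(v, varFloor))
    }
    if (is.finite(prevLL) && abs(ll - prevLL) < tol) {
      converged <- TRUE
      break
    }
    prevLL <- ll
  }
  ld <- .mixtureLogDens(x, weights, means, sds)
  ll <- sum(.logSumExpRows(ld))
  list(weights = weights, means = means, sds = sds,
       logLik = ll, converged = converged, nIter = iter)
}

#' Fit a Gaussian mixture to M-values at a probe
#'
#' Fits a univariate Gaussian mixture by expectation-maximization, the
#' model behind genotype inference from methylation: at a probe overlapping
#' a CpG-abolishing SNP the M-value distribution is tripartite
#' (hypomethylated, hemimethylated, hypermethylated), one mode per
#' genotype. Initialization is deterministic (component means at the
#' 10th/50th/90th data percentiles for k = 3), so the fit depends only on
#' the data; `seed` is accepted for interface uniformity with the
#' stochastic generators. Components are returned sorted by ascending mean.
#'
#' @param mValues numeric vector of finite M-values, length >= 3 * k.
#' @param k number of components, default 3 (the three genotype classes).
#' @param seed ignored by the deterministic fit; kept so callers can thread
#'   one seed through a whole pipeline.
#' @param selectK if TRUE, fit k in \{1, 2, 3\} and keep the fit with the
#'   lowest BIC; `k` is then the upper bound considered.
#' @param tol EM convergence tolerance on the log-likelihood (default 1e-8).
#' @param maxIter maximum EM iterations (default 500); non-convergence is
#'   reported via the `converged` slot, not an error.
#' @param varFloor variance floor preventing component collapse
#'   (default 1e-4).
#' @return A [MixtureFit-class] object.
#' @examples
#' set.seed(1)
#' m <- c(rnorm(50, -4.2, 0.3), rnorm(50, -0.5, 0.3), rnorm(50, 1.4, 0.3))
#' fitMethylationMixture(m)
#' @export
fitMethylationMixture <- function(mValues, k = 3L, seed = NULL,
                                  selectK = FALSE, tol = 1e-8,
                                  maxIter = 500L, varFloor = 1e-4) {
  x <- as.numeric(mValues)
  if (any(!is.finite(x)))
    stop("M-values must be finite")
  k <- as.integer(k)
  if (length(x) < 3L * k)
    stop("need at least ", 3L * k, " observations to fit ", k,
         " components; got ", length(x))
  if (var(x) == 0)
    stop("degenerate input: all M-values identical (zero variance)")
  ks <- if (selectK) seq_len(min(k, 3L)) else k
  best <- NULL
  bestBic <- Inf
  bestK <- NA_integer_
  for (kk in ks) {
    fit <- .emFit(x, kk, tol = tol, maxIter = maxIter, varFloor = varFloor)
    nPar <- 3L * kk - 1L
    bic <- -2 * fit$logLik + nPar * log(length(x))
    if (bic < bestBic) {
      best <- fit
      bestBic <- bic
      bestK <- kk
    }
  }
  ord <- order(best$means)
  new("MixtureFit",
      k = bestK,
      weights = best$weights[ord],
      means = best$means[ord],
      sds = best$sds[ord],
      logLik = best$logLik,
      bic = bestBic,
      converged = best$converged,
      nIter = as.integer(best$nIter))
}

#' Posterior genotype responsibilities under a mixture fit
#'
#' Bayes-rule posteriors P(component j | M) for each observation; rows sum
#' to 1.
#'
#' @param mValues numeric vector of M-values.
#' @param fit a [MixtureFit-class] object.
#' @return numeric matrix, observations x components.
#' @export
posteriorResponsibilities <- function(mValues, fit) {
  ld <- .mixtureLogDens(as.numeric(mValues), fit@weights, fit@means,
                        fit@sds)
  exp(ld - .logSumExpRows(ld))
}

#' Call genotypes from M-values under a three-class mixture
#'
#' Maps mixture components to diploid genotypes: the lowest-mean
#' (hypomethylated) component is the homozygote for the CpG-abolishing
#' allele (`lowAllele`, default "A", since removing the CpG removes the
#' methylation substrate), the highest-mean component the homozygote for
#' `highAllele` (default "G"), and the middle component the heterozygote.
#' Which allele abolishes the CpG is locus-specific, so the orientation is
#' a pair of arguments rather than a constant. The hard call is the argmax
#' posterior.
#'
#' @param samples data.frame with columns `sample_id` and `m_value` (or
#'   `beta`, converted via [betaToM()]).
#' @param fit a converged [MixtureFit-class] with k = 3, or any fit if
#'   `thresholds` is supplied.
#' @param lowAllele,highAllele allele letters for the hypo-/hypermethylated
#'   homozygote classes.
#' @param thresholds optional numeric length-2 cut points on the M scale
#'   forcing interval-based calls (below, between, above) instead of
#'   mixture posteriors.
#' @return data.frame with `sample_id`, `genotype` (e.g. "A/A", "A/G",
#'   "G/G"), three posterior columns and `m_value`.
#' @examples
#' fit <- new("MixtureFit", k = 3L, weights = rep(1/3, 3),
#'            means = c(-4.21, -0.51, 1.41), sds = rep(1, 3),
#'            logLik = NA_real_, bic = NA_real_, converged = TRUE,
#'            nIter = 0L)
#' callGenotypes(data.frame(sample_id = "s1", m_value = -5), fit)
#' @export
callGenotypes <- function(samples, fit, lowAllele = "A", highAllele = "G",
                          thresholds = NULL) {
  if (!"m_value" %in% names(samples)) {
    if (!"beta" %in% names(samples))
      stop("'samples' needs an 'm_value' or 'beta' column")
    samples$m_value <- betaToM(samples$beta,
                               sampleIds = samples$sample_id)
  }
  labels <- c(paste(lowAllele, lowAllele, sep = "/"),
              paste(lowAllele, highAllele, sep = "/"),
              paste(highAllele, highAllele, sep = "/"))
  m <- as.numeric(samples$m_value)
  if (is.null(thresholds)) {
    if (fit@k != 3L)
      stop("genotype calling needs a k = 3 fit (got k = ", fit@k,
           "); supply 'thresholds' to force interval calls")
    post <- posteriorResponsibilities(m, fit)
  } else {
    if (length(thresholds) != 2L || any(diff(sort(thresholds)) <= 0))
      stop("'thresholds' must be two distinct cut points")
    thresholds <- sort(thresholds)
    cls <- findInterval(m, thresholds) + 1L
    post <- matrix(0, length(m), 3L)
    post[cbind(seq_along(m), cls)] <- 1
  }
  cls <- max.col(post, ties.method = "first")
  out <- data.frame(sample_id = samples$sample_id,
                    genotype = labels[cls],
                    stringsAsFactors = FALSE)
  postNames <- paste0("posterior_", gsub("/", "", labels))
  for (j in 1:3) out[[postNames[j]]] <- post[, j]
  out$m_value <- m
  out
}

#' Per-genotype M-value summaries
#'
#' Arithmetic mean and sample standard deviation of the M-values in each
#' called genotype class. Classes with no members are absent from the
#' output (not reported as zero); a single-member class has `sd = NA`.
#'
#' @param calls data.frame from [callGenotypes()] (needs `sample_id`,
#'   `genotype`).
#' @param samples data.frame with `sample_id` and `m_value` (or `beta`).
#' @return data.frame with `genotype`, `n`, `mean_m`, `sd_m`, one row per
#'   observed class.
#' @export
summarizeClasses <- function(calls, samples) {
  if (nrow(calls) == 0L)
    stop("empty input: no genotype calls to summarize")
  if (!"m_value" %in% names(samples))
    samples$m_value <- betaToM(samples$beta,
                               sampleIds = samples$sample_id)
  m <- samples$m_value[match(calls$sample_id, samples$sample_id)]
  sp <- split(m, calls$genotype)
  data.frame(genotype = names(sp),
             n = vapply(sp, length, 0L),
             mean_m = vapply(sp, mean, 0),
             sd_m = vapply(sp, function(v)
               if (length(v) > 1L) sd(v) else NA_real_, 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Reference presets for the tripartite methylation classes
#'
#' Named class means/sds for the hypomethylated, hemimethylated and
#' hypermethylated groups: `"cohort96"` (the 96-sample genotyped cohort,
#' the default elsewhere), `"cohort45"` (the original 45-sample array
#' cohort, whose normalization evidently differed) and `"test"` (the
#' cohort96 means with tight sds, for simulations where class assignment
#' must be near-certain).
#'
#' @param name one of "cohort96", "cohort45", "test".
#' @return list with numeric `means` and `sds`, length 3, ascending means.
#' @examples
#' methylationClassPreset("cohort96")
#' @export
methylationClassPreset <- function(name = c("cohort96", "cohort45",
                                            "test")) {
  name <- match.arg(name)
  switch(name,
    cohort96 = list(means = c(-4.21, -0.51, 1.41),
                    sds = c(1.96, 2.06, 0.97)),
    cohort45 = list(means = c(-5.01, -0.11, 1.97),
                    sds = c(0.67, 0.49, 0.36)),
    test = list(means = c(-4.21, -0.51, 1.41),
                sds = c(0.3, 0.3, 0.3)))
}
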