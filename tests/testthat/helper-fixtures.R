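# Shared fixtures, built in code.

# a converged three-class fit at the published class means, unit sds,
# equal weights — used wherever a fixed reference fit is needed
referenceFit <- function(sds = c(1, 1, 1)) {
  new("MixtureFit", k = 3L, weights = rep(1 / 3, 3),
      means = c(-4.21, -0.51, 1.41), sds = sds,
      logLik = NA_real_, bic = NA_real_, converged = TRUE, nIter = 0L)
}

# brute-force pairwise-difference oracle, independent of pairwisePi()
bruteForcePi <- function(a) {
  n <- nrow(a)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(a[i, ] != a[j, ], na.rm = TRUE)
  tot / choose(n, 2)
}

# direct evaluation of the D formula from first principles (harmonic sums
# written out), independent of tajimaConstants()/tajimasD()
oracleTajimaD <- function(a) {
  n <- nrow(a)
  seg <- apply(a, 2, function(v) {
    v <- v[!is.na(v)]
    any(v == 0) && any(v == 1)
  })
  S <- sum(seg)
  if (S == 0) return(NaN)
  pi <- bruteForcePi(a[, seg, drop = FALSE])
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# random 0/1 haplotype matrix, polymorphic columns only
randomHapMatrix <- function(n, S) {
  a <- matrix(0L, n, S)
  for (j in seq_len(S)) {
    k <- sample(1:(n - 1), 1)
    a[sample(n, k), j] <- 1L
  }
  a
}

writeTempFasta <- function(lines) {
  tmp <- tempfile(fileext = ".fa")
  writeLines(lines, tmp)
  tmp
}
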