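suppressPackageStartupMessages(library(SummarizedExperiment))

# ---- small fixture builders -------------------------------------------------

toyMeta <- function(n, bf = NULL, age = NULL, genotype = NULL) {
  data.frame(
    accession_id = paste0("acc", seq_len(n)),
    genotype = if (is.null(genotype)) rep("G1", n) else genotype,
    bf_category = "unknown",
    bf_score = if (is.null(bf)) rep(1L, n) else bf,
    clonal_age_decades = if (is.null(age)) rep(1L, n) else age,
    stringsAsFactors = FALSE)
}

# Build an EpigenotypeMatrix directly from a state-code matrix (1..4) by
# inverting the call scheme and classifying, so tests exercise the real path.
epiFromStates <- function(st, meta = NULL) {
  st <- as.matrix(st)
  if (is.null(rownames(st))) rownames(st) <- paste0("a", seq_len(nrow(st)))
  if (is.null(colnames(st))) colnames(st) <- paste0("acc", seq_len(ncol(st)))
  hpa <- matrix(as.integer(st %in% c(1L, 2L)), nrow(st), dimnames = dimnames(st))
  msp <- matrix(as.integer(st %in% c(1L, 3L)), nrow(st), dimnames = dimnames(st))
  cd <- if (!is.null(meta))
    S4Vectors::DataFrame(meta[, -1, drop = FALSE], row.names = meta$accession_id)
  else NULL
  classifyMatrix(BandMatrix(hpa, msp, colData = cd))
}

writeToyCsv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# ---- independent oracles ----------------------------------------------------

# Kendall tau-b by explicit pair enumeration with tie-corrected denominator.
tauBruteForce <- function(x, y) {
  n <- length(x)
  sx <- sign(outer(x, x, `-`)); sy <- sign(outer(y, y, `-`))
  s <- sx * sy
  up <- upper.tri(s)
  C <- sum(s[up] > 0); D <- sum(s[up] < 0)
  n0 <- n * (n - 1) / 2
  n1 <- sum(choose(table(x), 2)); n2 <- sum(choose(table(y), 2))
  (C - D) / sqrt((n0 - n1) * (n0 - n2))
}

# Pearson chi-square by naive summation loops.
chi2BruteForce <- function(tab) {
  n <- sum(tab)
  out <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / n
    out <- out + (tab[i, j] - e)^2 / e
  }
  out
}

# Logistic-regression Newton iteration, independent of stats::glm.
irlsOracle <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    p <- plogis(drop(X %*% beta))
    w <- p * (1 - p)
    z <- drop(X %*% beta) + (y - p) / w
    betaNew <- drop(solve(crossprod(X, w * X), crossprod(X, w * z)))
    if (max(abs(betaNew - beta)) < tol) return(betaNew)
    beta <- betaNew
  }
  beta
}

# Rigid-motion (rotation/reflection) alignment error between configurations.
procrustesError <- function(A, B) {
  A <- scale(as.matrix(A), center = TRUE, scale = FALSE)
  B <- scale(as.matrix(B), center = TRUE, scale = FALSE)
  k <- max(ncol(A), ncol(B))
  A <- cbind(A, matrix(0, nrow(A), k - ncol(A)))
  B <- cbind(B, matrix(0, nrow(B), k - ncol(B)))
  s <- svd(crossprod(B, A))
  R <- s$v %*% t(s$u)
  max(abs(A %*% R - B))
}

# Numerically integrated marginal likelihood for one log-linear model:
# Laplace approximation over coefficients at fixed g (via optim/BFGS, an
# independent optimizer), trapezoid quadrature over log g (the integrand
# spans orders of magnitude in g, so a log grid is needed to resolve the
# strong-shrinkage region). Hyper-prior density (a = 4): p(g) = (1+g)^-2.
# Flat intercept prior as in the sampler; the improper constant is shared
# by all models and cancels in posterior model probabilities.
logMarginalOracle <- function(cells, model, step = 0.25, range = 20) {
  dat <- cells
  for (v in names(dat))
    if (is.character(dat[[v]])) dat[[v]] <- factor(dat[[v]])
  f <- if (length(model)) stats::reformulate(model) else ~1
  X <- stats::model.matrix(f, dat)
  y <- cells$y
  off <- if ("offset" %in% names(cells)) cells$offset else rep(0, length(y))
  p <- ncol(X); N <- nrow(X)
  if (p > 1) {
    Xc <- scale(X[, -1, drop = FALSE], center = TRUE, scale = FALSE)
    C <- crossprod(Xc)
    logdetC <- as.numeric(determinant(C)$modulus)
  }
  logpost <- function(beta, g) {
    eta <- drop(X %*% beta) + off
    ll <- sum(y * eta - exp(eta))
    if (p == 1) return(ll)
    bt <- beta[-1]
    ll - 0.5 * (p - 1) * log(2 * pi) -
      0.5 * ((p - 1) * log(g * N) - logdetC) -
      0.5 * sum(bt * (C %*% bt)) / (g * N)
  }
  laplace <- function(g) {
    start <- c(log(mean(y / exp(off))), rep(0, p - 1))
    opt <- stats::optim(start, function(b) -logpost(b, g), method = "BFGS",
                        hessian = TRUE,
                        control = list(maxit = 1000, reltol = 1e-14))
    -opt$value + 0.5 * p * log(2 * pi) -
      0.5 * as.numeric(determinant(opt$hessian)$modulus)
  }
  if (p == 1) return(laplace(1))
  t <- seq(-range, range, by = step)
  g <- exp(t)
  vals <- vapply(g, laplace, numeric(1)) - 2 * log1p(g) + t
  m <- max(vals)
  m + log(sum(exp(vals - m)) * step)
}

oracleModelProbs <- function(cells, models) {
  lm <- vapply(models, function(m) logMarginalOracle(cells, m), numeric(1))
  w <- exp(lm - max(lm))
  w / sum(w)
}

# Batch-means Monte-Carlo standard error of a model-indicator chain, with
# the iid binomial SE as a floor.
indicatorSE <- function(ind, nBatch = 30) {
  n <- length(ind)
  bs <- floor(n / nBatch)
  bm <- colMeans(matrix(ind[seq_len(bs * nBatch)], bs))
  p <- mean(ind)
  max(stats::sd(bm) / sqrt(nBatch), sqrt(p * (1 - p) / n), 1e-4)
}
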