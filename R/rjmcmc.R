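#' MCMC settings for the log-linear sampler
#'
#' Defaults mirror the study conditions: 12,500 iterations with the first
#' 2,500 discarded as burn-in and no thinning.
#'
#' @param nIter total iterations.
#' @param burnIn iterations discarded (must be `< nIter`).
#' @param thin keep every `thin`-th retained iteration (`>= 1`).
#' @param seed integer RNG seed; chains are exactly reproducible given
#'   (seed, settings, data). `NULL` leaves the RNG state alone.
#' @param priorA hyper-g shape: `g/(1+g) ~ Beta(1, (priorA-2)/2)`; the
#'   default `priorA = 4` makes the shrinkage weight uniform on (0,1).
#' @param proposalInflate scale inflation of the Laplace proposal
#'   covariance used for reversible-jump moves.
#' @return list of settings.
#' @export
mcmcSettings <- function(nIter = 12500L, burnIn = 2500L, thin = 1L,
                         seed = NULL, priorA = 4, proposalInflate = 1.3) {
  stopifnot(burnIn < nIter, thin >= 1L, priorA > 2)
  list(nIter = as.integer(nIter), burnIn = as.integer(burnIn),
       thin = as.integer(thin), seed = seed, priorA = priorA,
       proposalInflate = proposalInflate)
}

# --- prior ------------------------------------------------------------------
# Generalized hyper-g prior: flat (improper) prior on the intercept;
# non-intercept coefficients beta ~ N(0, g * N * C^{-1}) with C the
# cross-product of the column-centered design (unit-information scaling,
# N = number of cells); g/(1+g) ~ Beta(1, (a-2)/2).

.priorStructure <- function(X) {
  p <- ncol(X)
  if (p == 1L)
    return(list(p = 1L, ptilde = 0L, C = NULL, logdetC = 0, N = nrow(X)))
  Xc <- scale(X[, -1L, drop = FALSE], center = TRUE, scale = FALSE)
  C <- crossprod(Xc)
  R <- tryCatch(chol(C), error = function(e)
    stop("centered design is singular; model not identifiable"))
  list(p = p, ptilde = p - 1L, C = C, logdetC = 2 * sum(log(diag(R))),
       N = nrow(X))
}

.logPriorBeta <- function(beta, ps, g) {
  if (ps$ptilde == 0L) return(0)
  bt <- beta[-1L]
  scale <- g * ps$N
  -0.5 * ps$ptilde * log(2 * pi) -
    0.5 * (ps$ptilde * log(scale) - ps$logdetC) -
    0.5 * sum(bt * (ps$C %*% bt)) / scale
}

.logPriorG <- function(g, a = 4) log((a - 2) / 2) - (a / 2) * log1p(g)

# Poisson log-likelihood kernel (lgamma(y+1) constant dropped).
.logLik <- function(beta, X, y, off) {
  eta <- drop(X %*% beta) + off
  if (any(eta > 500)) return(-Inf)
  sum(y * eta - exp(eta))
}

# Prior-regularized Newton mode and curvature, used for Laplace proposals.
.loglinMode <- function(X, y, off, ps, gref) {
  p <- ncol(X)
  P <- matrix(0, p, p)
  if (ps$ptilde > 0L) P[-1L, -1L] <- ps$C / (gref * ps$N)
  beta <- c(log(mean(y / exp(off)) + 1e-8), rep(0, p - 1L))
  obj <- function(b) .logLik(b, X, y, off) - 0.5 * sum(b * (P %*% b))
  cur <- obj(beta)
  for (it in 1:50) {
    eta <- drop(X %*% beta) + off
    mu <- exp(pmin(eta, 500))
    gr <- drop(crossprod(X, y - mu)) - drop(P %*% beta)
    H <- crossprod(X * mu, X) + P
    step <- tryCatch(solve(H, gr), error = function(e) gr / max(diag(H)))
    lam <- 1
    repeat {
      cand <- beta + lam * step
      val <- obj(cand)
      if (is.finite(val) && val >= cur - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) { cand <- beta; val <- cur; break }
    }
    conv <- abs(val - cur) < 1e-10 * (abs(cur) + 1)
    beta <- cand; cur <- val
    if (conv) break
  }
  eta <- drop(X %*% beta) + off
  H <- crossprod(X * exp(pmin(eta, 500)), X) + P
  list(mode = beta, hessian = H)
}

# Multivariate normal proposal helpers (upper-triangular chol factor R of
# the covariance: cov = t(R) %*% R).
.mvnSample <- function(mean, R) mean + drop(t(R) %*% rnorm(length(mean)))
.mvnLogDensity <- function(x, mean, R) {
  z <- backsolve(R, x - mean, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

#' Reversible-jump MCMC over hierarchical log-linear models
#'
#' Bayesian analysis of a complete contingency structure: a Poisson
#' log-linear likelihood on cell counts, a generalized hyper-g prior on the
#' non-intercept coefficients (flat prior on the intercept, uniform prior
#' over candidate models), within-model Metropolis--Hastings updates of the
#' coefficient vector and of the shrinkage hyper-parameter `g`, and
#' between-model reversible-jump moves that add or delete a single term
#' while respecting the hierarchy principle. Jump proposals redraw the full
#' coefficient vector from a prior-regularized Laplace approximation to the
#' destination model's posterior, so dimension matching is exact.
#'
#' @param cells cell-level `data.frame` (see [loglinearCells()]) with a
#'   count column `y`, optional `offset`, and the model covariates.
#' @param models list of candidate models (character term vectors, as from
#'   [enumerateModels()]); every model must satisfy the hierarchy
#'   principle.
#' @param settings a [mcmcSettings()] list.
#' @return A [LoglinearPosterior-class].
#' @examples
#' set.seed(1)
#' cells <- data.frame(A = gl(2, 2), B = gl(2, 1, 4),
#'                     y = rpois(4, 50), offset = 0)
#' fit <- rjmcmc(cells, enumerateModels(c("A", "B")),
#'               mcmcSettings(nIter = 600, burnIn = 100, seed = 1))
#' modelProbabilities(fit)
#' @export
rjmcmc <- function(cells, models, settings = mcmcSettings()) {
  stopifnot(is.data.frame(cells), "y" %in% names(cells),
            length(models) >= 1L)
  if (!all(vapply(models, .isHierarchical, logical(1))))
    stop("every candidate model must satisfy the hierarchy principle")
  if (!is.null(settings$seed)) set.seed(settings$seed)
  y <- cells$y
  off <- if ("offset" %in% names(cells)) cells$offset else rep(0, length(y))
  a <- settings$priorA
  infl <- settings$proposalInflate

  nM <- length(models)
  prep <- lapply(models, function(m) {
    X <- .designMatrix(cells, m)
    ps <- .priorStructure(X)
    lap <- .loglinMode(X, y, off, ps, gref = max(ps$N, 10))
    V <- solve(lap$hessian) * infl^2
    V <- (V + t(V)) / 2
    Rp <- chol(V)
    Rrw <- chol(solve(lap$hessian))
    list(X = X, ps = ps, mode = lap$mode, Rprop = Rp, Rrw = Rrw,
         label = attr(m, "label") %||% (if (length(m))
           paste(m, collapse = " + ") else "1"))
  })
  # neighbourhood: models whose term sets differ by exactly one term
  nbrs <- lapply(seq_len(nM), function(i) {
    which(vapply(seq_len(nM), function(j) {
      di <- setdiff(models[[i]], models[[j]])
      dj <- setdiff(models[[j]], models[[i]])
      (length(di) + length(dj)) == 1L
    }, logical(1)))
  })

  allPars <- unique(unlist(lapply(prep, function(p) colnames(p$X))))
  nIter <- settings$nIter; burnIn <- settings$burnIn; thin <- settings$thin
  keepIdx <- seq(burnIn + 1L, nIter, by = thin)
  nKeep <- length(keepIdx)
  betaOut <- matrix(NA_real_, nKeep, length(allPars),
                    dimnames = list(NULL, allPars))
  gOut <- numeric(nKeep); mOut <- integer(nKeep)

  # initial state: first model, Laplace mode, g from prior median
  m <- 1L
  beta <- prep[[m]]$mode
  g <- 1
  ll <- .logLik(beta, prep[[m]]$X, y, off)
  lpb <- .logPriorBeta(beta, prep[[m]]$ps, g)
  rjAtt <- rjAcc <- mhAtt <- mhAcc <- 0L
  kpos <- 0L

  for (it in seq_len(nIter)) {
    ## reversible jump
    if (nM > 1L && length(nbrs[[m]])) {
      rjAtt <- rjAtt + 1L
      m2 <- nbrs[[m]][sample.int(length(nbrs[[m]]), 1L)]
      beta2 <- .mvnSample(prep[[m2]]$mode, prep[[m2]]$Rprop)
      ll2 <- .logLik(beta2, prep[[m2]]$X, y, off)
      lpb2 <- .logPriorBeta(beta2, prep[[m2]]$ps, g)
      lqFwd <- .mvnLogDensity(beta2, prep[[m2]]$mode, prep[[m2]]$Rprop)
      lqRev <- .mvnLogDensity(beta, prep[[m]]$mode, prep[[m]]$Rprop)
      logA <- (ll2 + lpb2) - (ll + lpb) + (lqRev - lqFwd) +
        log(length(nbrs[[m]])) - log(length(nbrs[[m2]]))
      if (is.finite(logA) && log(runif(1)) < logA) {
        rjAcc <- rjAcc + 1L
        m <- m2; beta <- beta2; ll <- ll2; lpb <- lpb2
      }
    }
    ## within-model MH on beta (full-vector random walk, Laplace metric)
    mhAtt <- mhAtt + 1L
    tau <- 2.38 / sqrt(length(beta))
    beta2 <- beta + tau * drop(t(prep[[m]]$Rrw) %*% rnorm(length(beta)))
    ll2 <- .logLik(beta2, prep[[m]]$X, y, off)
    lpb2 <- .logPriorBeta(beta2, prep[[m]]$ps, g)
    if (is.finite(ll2) && log(runif(1)) < (ll2 + lpb2) - (ll + lpb)) {
      mhAcc <- mhAcc + 1L
      beta <- beta2; ll <- ll2; lpb <- lpb2
    }
    ## hyper-parameter g
    if (prep[[m]]$ps$ptilde > 0L) {
      g2 <- g * exp(0.8 * rnorm(1))
      num <- .logPriorBeta(beta, prep[[m]]$ps, g2) + .logPriorG(g2, a) + log(g2)
      den <- lpb + .logPriorG(g, a) + log(g)
      if (log(runif(1)) < num - den) {
        g <- g2
        lpb <- .logPriorBeta(beta, prep[[m]]$ps, g)
      }
    } else {
      u <- runif(1)           # conditional posterior = prior when no
      g <- u / (1 - u)        # shrinkable coefficients are present
    }
    if (it > burnIn && ((it - burnIn - 1L) %% thin == 0L)) {
      kpos <- kpos + 1L
      betaOut[kpos, colnames(prep[[m]]$X)] <- beta
      gOut[kpos] <- g
      mOut[kpos] <- m
    }
  }

  labels <- vapply(prep, `[[`, character(1), "label")
  tabM <- tabulate(mOut, nM)
  modelProbs <- data.frame(
    model = labels,
    n_params = vapply(prep, function(p) ncol(p$X), integer(1)),
    post_prob = tabM / nKeep, stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(allPars, function(pn) {
    col <- betaOut[, pn]
    incl <- !is.na(col)
    if (any(incl)) {
      dr <- col[incl]
      hpd <- .hpd(dr, 0.95)
      data.frame(parameter = pn, post_prob = mean(incl), mean = mean(dr),
                 variance = if (length(dr) > 1) var(dr) else 0,
                 lower = hpd[1], upper = hpd[2], stringsAsFactors = FALSE)
    } else
      data.frame(parameter = pn, post_prob = 0, mean = NA_real_,
                 variance = NA_real_, lower = NA_real_, upper = NA_real_,
                 stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  acc <- c(rj_pct = if (rjAtt) 100 * rjAcc / rjAtt else 0,
           mh_pct = if (mhAtt) 100 * mhAcc / mhAtt else 0)
  new("LoglinearPosterior",
      summary = summ, modelProbs = modelProbs,
      draws = list(beta = betaOut, g = gOut, model = mOut),
      models = models, acceptance = acc, settings = settings,
      data = list(y = y, offset = off,
                  designs = lapply(prep, `[[`, "X"),
                  cells = cells))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.hpd <- function(draws, level) {
  x <- sort(draws)
  n <- length(x)
  if (n < 2L) return(c(x[1], x[1]))
  m <- ceiling(level * n)          # points the interval must contain
  if (m >= n) return(c(x[1], x[n]))
  i <- which.min(x[m:n] - x[1:(n - m + 1L)])
  c(x[i], x[i + m - 1L])
}

#' Highest posterior density interval (Chen--Shao sweep)
#'
#' The shortest interval containing `ceiling(level * n)` of the sorted
#' draws: appropriate for unimodal posteriors.
#'
#' @param draws numeric vector of at least `minDraws` posterior draws.
#' @param level interval mass in (0, 1).
#' @param minDraws minimum draws accepted (default 100; HPD estimates from
#'   fewer draws are too unstable to report).
#' @return `c(lower, upper)`.
#' @examples
#' hpdInterval(rnorm(1e4))  # about c(-1.96, 1.96)
#' @export
hpdInterval <- function(draws, level = 0.95, minDraws = 100L) {
  stopifnot(level > 0, level < 1)
  draws <- draws[!is.na(draws)]
  if (length(draws) < minDraws)
    stop("need at least ", minDraws, " draws for an HPD interval")
  .hpd(draws, level)
}

#' Posterior predictive (Bayesian) p-value via the deviance
#'
#' For each retained draw, a replicate table is simulated from the Poisson
#' means at the drawn parameters and its deviance is compared to the
#' observed-data deviance at the same parameters;
#' `p_B = Pr(D(y_rep) >= D(y))`, ties counting toward `p_B` (so a
#' saturated, zero-deviance fit yields `p_B = 1`). Values near 0 indicate
#' lack of fit; values near 0.5 are ideal.
#'
#' @param fit a [LoglinearPosterior-class].
#' @param maxDraws cap on the number of draws used (subsampled evenly).
#' @param seed optional seed for the replicate simulation.
#' @return `p_B` in `[0, 1]`.
#' @export
bayesianPValue <- function(fit, maxDraws = 2000L, seed = NULL) {
  stopifnot(is(fit, "LoglinearPosterior"))
  if (!is.null(seed)) set.seed(seed)
  dr <- fit@draws
  n <- nrow(dr$beta)
  idx <- if (n > maxDraws) round(seq(1, n, length.out = maxDraws)) else seq_len(n)
  y <- fit@data$y; off <- fit@data$offset
  ge <- 0L
  for (i in idx) {
    m <- dr$model[i]
    X <- fit@data$designs[[m]]
    beta <- dr$beta[i, colnames(X)]
    mu <- exp(pmin(drop(X %*% beta) + off, 500))
    dObs <- loglinDeviance(y, mu)
    yRep <- rpois(length(mu), mu)
    dRep <- loglinDeviance(yRep, mu)
    if (dRep >= dObs) ge <- ge + 1L
  }
  ge / length(idx)
}

#' Rank model terms by their variance contribution
#'
#' For each term of the most probable model, computes the variance across
#' cells of the term's posterior-mean linear-predictor component
#' (design columns times posterior-mean coefficients) and ranks terms in
#' decreasing order of that variance: rank 1 is the top contributor.
#'
#' @param fit a [LoglinearPosterior-class].
#' @param model model to rank terms in; default the maximum a posteriori
#'   model. Given as an index into `fit@models` or a character term
#'   vector.
#' @return `data.frame` with `term`, `variance_contribution`, `rank`.
#' @export
rankTermsByVariance <- function(fit, model = NULL) {
  stopifnot(is(fit, "LoglinearPosterior"))
  mIdx <- if (is.null(model)) which.max(fit@modelProbs$post_prob)
          else if (is.numeric(model)) as.integer(model)
          else which(vapply(fit@models, function(m)
            setequal(m, model), logical(1)))[1]
  if (is.na(mIdx) || mIdx < 1L || mIdx > length(fit@models))
    stop("model not found among candidates")
  terms <- fit@models[[mIdx]]
  if (!length(terms)) stop("intercept-only model has no terms to rank")
  X <- fit@data$designs[[mIdx]]
  assign <- attr(X, "assign")
  tl <- attr(X, "term.labels")
  postMean <- setNames(fit@summary$mean, fit@summary$parameter)
  contrib <- vapply(terms, function(tm) {
    cols <- which(assign == match(tm, tl))
    b <- postMean[colnames(X)[cols]]
    b[is.na(b)] <- 0
    var(drop(X[, cols, drop = FALSE] %*% b))
  }, numeric(1))
  out <- data.frame(term = terms, variance_contribution = contrib,
                    rank = rank(-contrib, ties.method = "first"))
  out[order(out$rank), , drop = FALSE]
}
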