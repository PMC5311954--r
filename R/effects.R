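#' Maximum-likelihood GLM fit of a selected model
#'
#' Fits the selected log-linear / logistic model by iteratively reweighted
#' least squares (tight convergence: relative deviance change below 1e-10,
#' at most 100 iterations) and records the quantities needed for
#' likelihood-ratio fit indices. Complete or quasi-complete separation of
#' a binomial fit -- the convergence pathology reported for dichotomized
#' BF responses -- is detected and signalled as a warning rather than
#' silently returning divergent coefficients.
#'
#' @param frame record-level `data.frame`.
#' @param model character vector of term labels (empty = intercept only).
#' @param response name of the response column.
#' @param family `"binomial"` (logit link) or `"poisson"` (log link).
#' @return list of class `"msapbf_glm"`: `coefficients`, `log_likelihood`,
#'   `null_log_likelihood`, `k` (non-intercept parameter count),
#'   `deviance`, `family`, `separation` flag, and the underlying
#'   [stats::glm] object (`fit`).
#' @export
fitGlm <- function(frame, model, response,
                   family = c("binomial", "poisson")) {
  family <- match.arg(family)
  stopifnot(response %in% names(frame))
  fam <- if (family == "binomial") binomial() else poisson()
  rhs <- if (length(model)) paste(model, collapse = "+") else "1"
  f <- as.formula(paste(response, "~", rhs))
  dat <- frame
  for (v in names(dat))
    if (is.character(dat[[v]])) dat[[v]] <- factor(dat[[v]])
  degenWarn <- FALSE
  quietGlm <- function(...) withCallingHandlers(
    glm(..., control = glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      # glm.fit's fitted-probability warnings are re-reported below as a
      # single separation diagnostic
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        degenWarn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  fit <- quietGlm(f, family = fam, data = dat)
  nullFit <- quietGlm(as.formula(paste(response, "~ 1")), family = fam,
                      data = dat)
  sep <- FALSE
  if (family == "binomial") {
    mu <- fit$fitted.values
    sep <- !fit$converged || any(abs(coef(fit)) > 15) || degenWarn ||
      all(mu > 1 - 1e-8 | mu < 1e-8)
    if (sep)
      warning("possible separation: binomial fit is unstable ",
              "(divergent coefficients or degenerate fitted probabilities)")
  }
  structure(list(
    coefficients = coef(fit),
    log_likelihood = as.numeric(logLik(fit)),
    null_log_likelihood = as.numeric(logLik(nullFit)),
    k = length(coef(fit)) - 1L,
    deviance = fit$deviance,
    family = family, separation = sep, fit = fit), class = "msapbf_glm")
}

#' McFadden adjusted pseudo-R-squared
#'
#' `1 - (logLik_model - k) / logLik_null`, a likelihood-ratio fit index
#' penalized by the number of non-intercept parameters `k`; adding a
#' parameter that does not improve the likelihood strictly decreases it.
#'
#' @param fit an object from [fitGlm()], or a list with elements
#'   `log_likelihood`, `null_log_likelihood`, `k`.
#' @return The adjusted pseudo-R-squared.
#' @examples
#' mcfaddenAdjustedR2(list(log_likelihood = -50,
#'                         null_log_likelihood = -100, k = 5))  # 0.45
#' @export
mcfaddenAdjustedR2 <- function(fit) {
  l1 <- fit$log_likelihood; l0 <- fit$null_log_likelihood; k <- fit$k
  if (l0 == 0) stop("null log-likelihood is zero; index undefined")
  1 - (l1 - k) / l0
}

#' Odds ratio for a coefficient contrast
#'
#' `exp(sum(contrast * coefficients))` over named contrast weights: e.g.
#' the per-age-unit odds ratio at methylation level 1 is the contrast
#' `c(ChronoAge = 1, "deMet011:ChronoAge" = 1)`.
#'
#' @param coefficients named numeric coefficients.
#' @param contrast named numeric contrast; every name must match a
#'   coefficient.
#' @return The odds ratio (1.0 for an empty/zero contrast).
#' @examples
#' oddsRatio(c(ChronoAge = -0.105934), c(ChronoAge = 1))  # 0.89948
#' @export
oddsRatio <- function(coefficients, contrast) {
  if (!length(contrast)) return(1)
  bad <- setdiff(names(contrast), names(coefficients))
  if (length(bad))
    stop("unknown coefficient(s): ", paste(bad, collapse = ", "))
  exp(sum(contrast * coefficients[names(contrast)]))
}

#' Predicted log-odds and probability curves over clonal age
#'
#' For a logistic model with intercept, methylation main effect, age slope
#' and (optionally) their interaction, returns the two predicted curves:
#' log-odds linear in age per methylation level, probabilities through the
#' logistic link. The difference between the two log-odds slopes equals
#' the interaction coefficient exactly.
#'
#' @param coefficients named vector with elements `(Intercept)`,
#'   `ChronoAge`, and optionally `deMet011` and `deMet011:ChronoAge`
#'   (absent terms are treated as zero). A [fitGlm()] object is also
#'   accepted.
#' @param ageGrid numeric grid of clonal ages (decades).
#' @return `data.frame`: `age`, `demethylated_log_odds`,
#'   `methylated_log_odds`, `demethylated_prob`, `methylated_prob`.
#' @export
effectCurves <- function(coefficients, ageGrid = seq(1, 70, by = 1)) {
  if (inherits(coefficients, "msapbf_glm"))
    coefficients <- coefficients$coefficients
  getc <- function(nm) if (nm %in% names(coefficients))
    coefficients[[nm]] else 0
  b0 <- getc("(Intercept)"); bM <- getc("deMet011")
  bA <- getc("ChronoAge"); bI <- getc("deMet011:ChronoAge")
  if (!"ChronoAge" %in% names(coefficients))
    stop("model must include a ChronoAge slope")
  lo0 <- b0 + bA * ageGrid
  lo1 <- b0 + bM + (bA + bI) * ageGrid
  data.frame(
    age = ageGrid,
    demethylated_log_odds = lo0, methylated_log_odds = lo1,
    demethylated_prob = stats::plogis(lo0),
    methylated_prob = stats::plogis(lo1))
}
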