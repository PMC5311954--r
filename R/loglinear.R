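.termLabel <- function(factors) paste(factors, collapse = ":")

.termFactors <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

.subTerms <- function(term) {
  f <- .termFactors(term)
  if (length(f) == 1L) return(character(0))
  subs <- unlist(lapply(seq_len(length(f) - 1L), function(k)
    apply(utils::combn(f, k), 2L, paste, collapse = ":")))
  subs
}

.isHierarchical <- function(terms) {
  all(vapply(terms, function(t) all(.subTerms(t) %in% terms), logical(1)))
}

#' Enumerate hierarchical log-linear models
#'
#' All downward-closed term sets (every sub-term of an included interaction
#' is included; the intercept is always implicit) over the given factors up
#' to interactions of order `maxOrder`, in deterministic order (by number
#' of terms, then lexicographically by label).
#'
#' @param factors character vector of 1--3 factor names.
#' @param maxOrder highest interaction order considered (default: all).
#' @param forceMainEffects keep only models containing every main effect.
#' @return list of models; each model is a character vector of term labels
#'   (empty for the intercept-only model), with a `label` attribute.
#' @examples
#' length(enumerateModels(c("A", "B")))                      # 5
#' length(enumerateModels(c("A", "B", "C"),
#'                        forceMainEffects = TRUE))          # 9
#' @export
enumerateModels <- function(factors, maxOrder = length(factors),
                            forceMainEffects = FALSE) {
  stopifnot(length(factors) >= 1L, length(factors) <= 3L,
            maxOrder >= 1L)
  terms <- unlist(lapply(seq_len(min(maxOrder, length(factors))), function(k)
    apply(utils::combn(factors, k), 2L, paste, collapse = ":")))
  nT <- length(terms)
  models <- list()
  for (mask in 0:(2^nT - 1L)) {
    sel <- terms[bitwAnd(mask, 2^(seq_len(nT) - 1L)) > 0]
    if (!.isHierarchical(sel)) next
    if (forceMainEffects && !all(factors %in% sel)) next
    models[[length(models) + 1L]] <- sel
  }
  ord <- order(lengths(models),
               vapply(models, function(m) paste(sort(m), collapse = "+"),
                      character(1)))
  models <- models[ord]
  lapply(models, function(m) {
    attr(m, "label") <- if (length(m)) paste(m, collapse = " + ") else "1"
    m
  })
}

#' Log-linear (Poisson / G-squared) deviance
#'
#' `2 * sum(O * log(O/E) - (O - E))` with the `0 * log(0) = 0` convention;
#' when the fitted margins match the observed ones (as for any hierarchical
#' log-linear fit containing the intercept) the second term vanishes and
#' this is the classical G-squared statistic, equal to minus twice the
#' log-likelihood ratio of the model against the saturated model.
#'
#' @param observed,expected non-negative cell counts / fitted means of
#'   equal length; `expected` strictly positive.
#' @return The deviance (non-negative).
#' @examples
#' o <- c(3, 1, 1, 3)
#' e <- rep(2, 4)               # independence fit
#' loglinDeviance(o, e)         # ~2.093
#' @export
loglinDeviance <- function(observed, expected) {
  stopifnot(length(observed) == length(expected),
            all(observed >= 0), all(expected > 0))
  term <- ifelse(observed == 0, 0, observed * log(observed / expected))
  2 * sum(term - (observed - expected))
}

#' Aggregate a record-level model frame into contingency cells
#'
#' Records sharing identical values of the model covariates are collapsed
#' into one cell with the summed response and a `log(n records)` offset,
#' which leaves the Poisson log-linear likelihood unchanged up to a
#' constant while making MCMC iterations cheap.
#'
#' @param frame record-level `data.frame`.
#' @param response name of the (count-valued) response column.
#' @param factors names of the model covariate columns.
#' @return `data.frame` with columns `y`, `offset`, `n_records` and the
#'   covariates, one row per distinct covariate combination.
#' @export
loglinearCells <- function(frame, response, factors) {
  stopifnot(all(c(response, factors) %in% names(frame)))
  key <- interaction(frame[factors], drop = TRUE, lex.order = TRUE)
  y <- tapply(frame[[response]], key, sum)
  n <- tapply(rep(1L, nrow(frame)), key, sum)
  first <- match(levels(key), key)
  cells <- frame[first, factors, drop = FALSE]
  cells$y <- as.numeric(y[levels(key)])
  cells$n_records <- as.integer(n[levels(key)])
  cells$offset <- log(cells$n_records)
  rownames(cells) <- NULL
  cells
}

# Build the design matrix of a model on cell data. Character covariates are
# coerced to factors (treatment contrasts), so parameter names nest across
# models.
.designMatrix <- function(cells, model) {
  dat <- cells
  for (v in names(dat))
    if (is.character(dat[[v]])) dat[[v]] <- factor(dat[[v]])
  f <- if (length(model)) as.formula(paste("~", paste(model, collapse = "+")))
       else ~1
  X <- model.matrix(f, dat)
  attr(X, "term.labels") <- attr(terms(f), "term.labels")
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient for model '",
         paste(model, collapse = " + "), "'")
  X
}
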