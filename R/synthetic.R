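#' Configuration for the synthetic MS-AFLP band-matrix generator
#'
#' Defaults emulate the 22-accession almond panel: the packaged accession
#' metadata, nine primer combinations (a--i) with the study's per-primer
#' band counts (120, 136, 125, 161, 114, 214, 133, 121, 124; 1248 bands in
#' total), a small fraction of non-methylation-susceptible loci, and a
#' log-odds dependence of the per-cell methylation indicator on BF score,
#' clonal age and genotype. The default effect direction makes methylation
#' more likely in high-BF accessions.
#'
#' @param accessions metadata `data.frame` (default [accessionMetadata()]).
#' @param bandsPerPrimer named integer vector of band counts per primer.
#' @param mslProb probability that a band is methylation-susceptible
#'   (non-susceptible bands are demethylated everywhere apart from call
#'   errors); default matches the study's 1238/1248 split.
#' @param baselineMean,baselineSd normal distribution of per-band baseline
#'   log-odds of methylation; the spread lets some loci sit near fixation,
#'   so a realistic minority of susceptible loci are monomorphic.
#' @param bfEffect,ageEffect log-odds of methylation per BF-score unit and
#'   per decade of clonal age.
#' @param genotypeEffects named numeric per-genotype log-odds offsets
#'   (default all zero).
#' @param stateProbs probabilities of (hemimethylated, internal-C,
#'   full methylation) conditional on a cell being methylated; must sum
#'   to 1.
#' @param callErrorRate probability, in `[0, 0.5)`, of independently
#'   flipping each HPA and MSP call (can convert states, exercising the
#'   MSL error threshold).
#' @param seed integer seed; with the seed the generator is bit-exact.
#' @return list of class `"msapbf_simconfig"`.
#' @export
simulationConfig <- function(accessions = accessionMetadata(),
                             bandsPerPrimer = c(a = 120L, b = 136L, c = 125L,
                                                d = 161L, e = 114L, f = 214L,
                                                g = 133L, h = 121L, i = 124L),
                             mslProb = 1238 / 1248,
                             baselineMean = -0.3, baselineSd = 2,
                             bfEffect = 0.12, ageEffect = 0.02,
                             genotypeEffects = NULL,
                             stateProbs = c(hemi = 0.17, internal = 0.20,
                                            full = 0.63),
                             callErrorRate = 0.01, seed = 1L) {
  stopifnot(all(bandsPerPrimer >= 1L), mslProb >= 0, mslProb <= 1,
            abs(sum(stateProbs) - 1) < 1e-8, all(stateProbs >= 0),
            callErrorRate >= 0, callErrorRate < 0.5)
  genos <- sort(unique(accessions$genotype))
  if (is.null(genotypeEffects))
    genotypeEffects <- setNames(rep(0, length(genos)), genos)
  stopifnot(all(genos %in% names(genotypeEffects)))
  structure(list(accessions = accessions, bandsPerPrimer = bandsPerPrimer,
                 mslProb = mslProb, baselineMean = baselineMean,
                 baselineSd = baselineSd, bfEffect = bfEffect,
                 ageEffect = ageEffect, genotypeEffects = genotypeEffects,
                 stateProbs = stateProbs, callErrorRate = callErrorRate,
                 seed = as.integer(seed)), class = "msapbf_simconfig")
}

#' Generate a synthetic band matrix with known statistical structure
#'
#' For each (band, accession) cell of a methylation-susceptible band, the
#' methylated indicator is drawn from a logistic model in BF score, clonal
#' age and genotype (plus a per-band baseline); methylated cells are
#' assigned one of hemimethylated / internal-C / full methylation; states
#' are inverted to (HPA, MSP) calls by the isoschizomer scheme
#' (demethylated = 1/1, hemi = 1/0, internal-C = 0/1, full = 0/0); call
#' errors are applied independently per assay. Deterministic under the
#' configured seed.
#'
#' @param config a [simulationConfig()].
#' @return list with `matrix` (a [BandMatrix-class]) and `truth` (the
#'   config, seed, per-band baselines and susceptibility mask -- enough to
#'   regenerate the matrix bit-exactly, plus the `planted` band record
#'   maintained by [plantPerfectBand()]).
#' @export
generateBandMatrix <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "msapbf_simconfig"))
  set.seed(config$seed)
  meta <- config$accessions
  bandIds <- unlist(lapply(names(config$bandsPerPrimer), function(p)
    paste0(p, seq_len(config$bandsPerPrimer[[p]]))))
  nB <- length(bandIds); nA <- nrow(meta)
  msl <- runif(nB) < config$mslProb
  alpha <- rnorm(nB, config$baselineMean, config$baselineSd)
  eff <- config$bfEffect * meta$bf_score +
    config$ageEffect * meta$clonal_age_decades +
    config$genotypeEffects[meta$genotype]
  lo <- outer(alpha, eff, `+`)            # bands x accessions log-odds
  methyl <- matrix(runif(nB * nA) < stats::plogis(lo), nB, nA)
  methyl[!msl, ] <- FALSE
  # state codes: 1 demethylated; methylated cells get 2/3/4
  st <- matrix(1L, nB, nA)
  nMeth <- sum(methyl)
  st[methyl] <- sample(2:4, nMeth, replace = TRUE, prob = config$stateProbs)
  hpa <- matrix(as.integer(st %in% c(1L, 2L)), nB, nA)
  msp <- matrix(as.integer(st %in% c(1L, 3L)), nB, nA)
  if (config$callErrorRate > 0) {
    flipH <- matrix(runif(nB * nA) < config$callErrorRate, nB, nA)
    flipM <- matrix(runif(nB * nA) < config$callErrorRate, nB, nA)
    hpa[flipH] <- 1L - hpa[flipH]
    msp[flipM] <- 1L - msp[flipM]
  }
  dimnames(hpa) <- dimnames(msp) <- list(bandIds, meta$accession_id)
  cd <- DataFrame(meta[, setdiff(names(meta), "accession_id")],
                  row.names = meta$accession_id)
  bm <- BandMatrix(hpa, msp, colData = cd)
  truth <- list(config = config, seed = config$seed, msl = msl,
                baseline = setNames(alpha, bandIds), planted = character(0))
  list(matrix = bm, truth = truth)
}

#' Plant a band in perfect correspondence with BF exhibition
#'
#' Overwrites one band so that it is fully methylated (HPA-/MSP- calls) in
#' every BF accession and demethylated (HPA+/MSP+) in every NBF accession,
#' emulating a fully diagnostic band. Planting the same band twice is a
#' no-op; the planted band id is recorded in the truth object.
#'
#' @param matrix a [BandMatrix-class].
#' @param truth the matching truth list from [generateBandMatrix()].
#' @param grouping named BF/NBF factor over the accessions.
#' @param band band id to overwrite; defaults to `"e22"` when present,
#'   else the first band.
#' @return list with updated `matrix` and `truth`.
#' @export
plantPerfectBand <- function(matrix, truth, grouping, band = NULL) {
  stopifnot(is(matrix, "BandMatrix"))
  grouping <- factor(grouping[colnames(matrix)])
  if (!all(c("BF", "NBF") %in% levels(grouping)))
    stop("grouping must contain both BF and NBF accessions")
  if (is.null(band))
    band <- if ("e22" %in% rownames(matrix)) "e22" else rownames(matrix)[1]
  if (!band %in% rownames(matrix)) stop("unknown band: ", band)
  isBF <- grouping == "BF"
  hpa <- assay(matrix, "HPA"); msp <- assay(matrix, "MSP")
  hpa[band, ] <- as.integer(!isBF)  # BF: 0/0 (full methylation)
  msp[band, ] <- as.integer(!isBF)  # NBF: 1/1 (demethylated)
  out <- BandMatrix(hpa, msp, colData = colData(matrix))
  truth$planted <- union(truth$planted, band)
  list(matrix = out, truth = truth)
}

#' Build a record-level model frame from an epigenotype matrix
#'
#' One record per (band, accession) with the binary methylation score
#' `deMet01` (factor), the accession's clonal age in decades `ChronoAge`,
#' the integer-coded genotype factor `GenotypeN` (codes 1..K by sorted
#' genotype label), and the BF score `BudFailure`.
#'
#' @param epi an [EpigenotypeMatrix-class].
#' @param meta metadata `data.frame` covering all accessions (default: the
#'   `colData` when it has the needed columns).
#' @return record-level `data.frame` with columns `accession`, `band`,
#'   `BudFailure`, `deMet01`, `ChronoAge`, `GenotypeN`.
#' @export
frameFromMatrix <- function(epi, meta = NULL) {
  stopifnot(is(epi, "EpigenotypeMatrix"))
  acc <- colnames(epi)
  if (is.null(meta)) {
    cd <- as.data.frame(colData(epi))
    need <- c("genotype", "bf_score", "clonal_age_decades")
    if (!all(need %in% names(cd)))
      stop("colData lacks metadata; supply `meta`")
    meta <- cbind(accession_id = acc, cd)
  }
  idx <- match(acc, meta$accession_id)
  if (anyNA(idx)) stop("metadata missing for: ",
                       paste(acc[is.na(idx)], collapse = ", "))
  genoLevels <- sort(unique(meta$genotype))
  me <- assay(epi, "methylated")
  nB <- nrow(epi); nA <- length(acc)
  data.frame(
    accession = rep(acc, each = nB),
    band = rep(rownames(epi), nA),
    BudFailure = rep(meta$bf_score[idx], each = nB),
    deMet01 = factor(as.vector(me), levels = c(0L, 1L)),
    ChronoAge = rep(as.numeric(meta$clonal_age_decades[idx]), each = nB),
    GenotypeN = factor(rep(match(meta$genotype[idx], genoLevels), each = nB),
                       levels = seq_along(genoLevels)),
    stringsAsFactors = FALSE)
}

#' Simulate a record-level count frame from known log-linear coefficients
#'
#' Generates records with a binary methylation factor and a clonal-age
#' covariate, and a Poisson response with log mean
#' `b0 + b1 deMet01 + b2 ChronoAge + b3 deMet01:ChronoAge`, for
#' parameter-recovery checks of the reversible-jump sampler.
#'
#' @param coefficients numeric vector
#'   `c(intercept, deMet011, ChronoAge, interaction)`.
#' @param n number of records.
#' @param ages pool of clonal ages sampled uniformly (decades).
#' @param seed optional RNG seed.
#' @return `data.frame` with columns `y`, `deMet01` (factor), `ChronoAge`.
#' @export
simulateCountFrame <- function(coefficients, n = 5000L,
                               ages = 1:14, seed = NULL) {
  stopifnot(length(coefficients) == 4L)
  if (!is.null(seed)) set.seed(seed)
  deMet <- rbinom(n, 1L, 0.5)
  age <- sample(ages, n, replace = TRUE)
  eta <- coefficients[1] + coefficients[2] * deMet +
    coefficients[3] * age + coefficients[4] * deMet * age
  data.frame(y = rpois(n, exp(eta)),
             deMet01 = factor(deMet, levels = c(0L, 1L)),
             ChronoAge = as.numeric(age))
}
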