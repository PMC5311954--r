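#' BandMatrix: paired HpaII/MspI presence/absence calls
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] subclass holding an
#' MS-AFLP band matrix: two binary assays, `"HPA"` (EcoRI+HpaII digest) and
#' `"MSP"` (EcoRI+MspI digest), with bands (fragments) as rows and
#' accessions as columns. `rowData` carries the primer-combination letter
#' (`primer`, one of a--i) and the within-primer band index (`band_index`,
#' ordered heavy to light fragment). `colData` carries accession metadata
#' (at minimum `bf_category`; typically also `genotype`, `bf_score`,
#' `clonal_age_decades`).
#'
#' @seealso [readBandMatrix()], [classifyMatrix()], [generateBandMatrix()]
#' @exportClass BandMatrix
setClass("BandMatrix", contains = "SummarizedExperiment")

.validBandMatrix <- function(object) {
  msg <- character()
  if (!identical(sort(assayNames(object)), c("HPA", "MSP")))
    msg <- c(msg, "assays must be exactly 'HPA' and 'MSP'")
  else {
    for (a in c("HPA", "MSP")) {
      v <- assay(object, a)
      if (!all(v %in% c(0L, 1L)))
        msg <- c(msg, sprintf("assay '%s' contains non-binary calls", a))
    }
  }
  rd <- rowData(object)
  if (!all(c("primer", "band_index") %in% colnames(rd)))
    msg <- c(msg, "rowData must have columns 'primer' and 'band_index'")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "accession (column) names must be present and unique")
  if (length(msg)) msg else TRUE
}
setValidity("BandMatrix", .validBandMatrix)

#' Construct a BandMatrix from two binary call matrices
#'
#' @param hpa,msp integer 0/1 matrices, bands x accessions, with identical
#'   dimnames. Row names follow the `"<primer><index>"` convention
#'   (e.g. `"a1"`, `"e22"`); `rowData` is derived from them unless
#'   `primer`/`bandIndex` are given.
#' @param colData a `data.frame` or [S4Vectors::DataFrame-class] of
#'   accession metadata (one row per column of `hpa`). A `bf_category`
#'   column is added as `"unknown"` when absent.
#' @param primer,bandIndex optional explicit row annotations.
#' @return A validated [BandMatrix-class].
#' @examples
#' h <- matrix(c(1L,0L,1L,1L), 2, 2, dimnames = list(c("a1","a2"), c("X","Y")))
#' m <- matrix(c(1L,1L,0L,1L), 2, 2, dimnames = dimnames(h))
#' BandMatrix(h, m)
#' @export
BandMatrix <- function(hpa, msp, colData = NULL, primer = NULL,
                       bandIndex = NULL) {
  hpa <- as.matrix(hpa); msp <- as.matrix(msp)
  storage.mode(hpa) <- "integer"; storage.mode(msp) <- "integer"
  if (!identical(dim(hpa), dim(msp)))
    stop("HPA and MSP matrices must have identical dimensions")
  if (!identical(dimnames(hpa), dimnames(msp)))
    stop("HPA and MSP matrices must have identical dimnames")
  if (is.null(rownames(hpa)))
    stop("band (row) names are required")
  if (is.null(primer)) {
    primer <- sub("^([a-z]+).*$", "\\1", rownames(hpa))
    bandIndex <- as.integer(sub("^[a-z]+", "", rownames(hpa)))
  }
  if (is.null(colData))
    colData <- DataFrame(row.names = colnames(hpa))
  else
    colData <- DataFrame(colData, row.names = colnames(hpa))
  if (!"bf_category" %in% colnames(colData))
    colData$bf_category <- rep("unknown", ncol(hpa))
  se <- SummarizedExperiment(
    assays = list(HPA = hpa, MSP = msp),
    rowData = DataFrame(primer = primer, band_index = bandIndex,
                        row.names = rownames(hpa)),
    colData = colData)
  new("BandMatrix", se)
}

#' EpigenotypeMatrix: four-state methylation calls per band and accession
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] subclass produced by
#' [classifyMatrix()]. Assay `"state"` holds integer codes 1--4 for the four
#' methylation states (see [methStates()]); assay `"methylated"` holds the
#' binary methylation score (`deMet01`): 0 for demethylated (HPA+/MSP+),
#' 1 otherwise. `rowData` gains `locus_class` ("MSL"/"NML", set by
#' [partitionLoci()]) and `polymorphic` (set by [polymorphicLoci()]).
#'
#' @seealso [classifyMatrix()], [partitionLoci()], [polymorphicLoci()]
#' @exportClass EpigenotypeMatrix
setClass("EpigenotypeMatrix", contains = "SummarizedExperiment")

.validEpigenotypeMatrix <- function(object) {
  msg <- character()
  if (!all(c("state", "methylated") %in% assayNames(object)))
    msg <- c(msg, "assays must include 'state' and 'methylated'")
  else {
    st <- assay(object, "state"); me <- assay(object, "methylated")
    if (!all(st %in% c(1:4, NA))) msg <- c(msg, "state codes must be in 1..4")
    if (!all(me %in% c(0L, 1L, NA))) msg <- c(msg, "methylated must be 0/1")
    if (!identical(is.na(st), is.na(me)) ||
        any((me == 0L) != (st == 1L), na.rm = TRUE))
      msg <- c(msg, "methylated must be 0 exactly where state is DEMETHYLATED")
  }
  if (length(msg)) msg else TRUE
}
setValidity("EpigenotypeMatrix", .validEpigenotypeMatrix)

#' The four MS-AFLP methylation states
#'
#' State codes follow the isoschizomer banding logic: HpaII is blocked by
#' full or internal-C methylation of CCGG, MspI by hemimethylation of the
#' external C; a band in both assays therefore indicates an unmethylated
#' (demethylated) site, and joint absence is scored as full methylation.
#'
#' @return Named integer vector mapping state names to codes 1--4:
#'   `DEMETHYLATED` (HPA+/MSP+), `HEMIMETHYLATED` (HPA+/MSP-),
#'   `INTERNAL_C_METHYLATION` (HPA-/MSP+), `FULL_METHYLATION` (HPA-/MSP-).
#' @examples
#' methStates()
#' @export
methStates <- function() {
  c(DEMETHYLATED = 1L, HEMIMETHYLATED = 2L,
    INTERNAL_C_METHYLATION = 3L, FULL_METHYLATION = 4L)
}

#' LoglinearPosterior: RJMCMC output for hierarchical log-linear models
#'
#' Returned by [rjmcmc()]. Holds the retained (post burn-in) draws, the
#' per-parameter posterior summary in the usual report schema (posterior
#' inclusion probability, mean, variance, 95% HPD limits), posterior model
#' probabilities, and sampler diagnostics.
#'
#' @slot summary `data.frame` with one row per parameter of the largest
#'   candidate model: `parameter`, `post_prob`, `mean`, `variance`,
#'   `lower`, `upper` (95% HPD, conditional on inclusion).
#' @slot modelProbs `data.frame`: model label, number of parameters,
#'   posterior probability.
#' @slot draws list with elements `beta` (iterations x parameters, `NA`
#'   when a parameter is excluded at that iteration), `g` (hyper-parameter
#'   chain), `model` (model index chain).
#' @slot models list of candidate models (character vectors of terms).
#' @slot acceptance named numeric: `rj_pct`, `mh_pct` acceptance rates (%).
#' @slot settings the [mcmcSettings()] used.
#' @slot data the cell data used (for posterior predictive checks).
#' @exportClass LoglinearPosterior
setClass("LoglinearPosterior",
  representation(summary = "data.frame", modelProbs = "data.frame",
                 draws = "list", models = "list", acceptance = "numeric",
                 settings = "list", data = "list"))

#' @describeIn LoglinearPosterior compact display of model probabilities and
#'   the parameter summary of the most probable model.
#' @param object a `LoglinearPosterior`
#' @export
setMethod("show", "LoglinearPosterior", function(object) {
  cat("LoglinearPosterior:", nrow(object@draws$beta), "retained draws,",
      length(object@models), "candidate models\n")
  cat(sprintf("RJ acceptance %.2f%%, MH acceptance %.2f%%\n",
              object@acceptance["rj_pct"], object@acceptance["mh_pct"]))
  cat("Posterior model probabilities:\n")
  print(object@modelProbs, row.names = FALSE)
  cat("Top-model parameter summary:\n")
  print(head(object@summary, 10), row.names = FALSE)
  invisible(NULL)
})

#' @describeIn LoglinearPosterior posterior model probabilities.
#' @export
modelProbabilities <- function(object) object@modelProbs

#' @describeIn LoglinearPosterior per-parameter posterior summary table.
#' @export
posteriorSummary <- function(object) object@summary
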