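#' Classify a paired HpaII/MspI call into a methylation state
#'
#' Implements the standard isoschizomer banding logic: both bands present
#' means an unmethylated CCGG site (demethylated); HPA-only indicates
#' hemimethylation of the external cytosine; MSP-only indicates internal
#' cytosine methylation; joint absence is scored as full methylation (with
#' the known caveat that it can also reflect target absence; see
#' [classifyMatrix()]'s `jointAbsence` switch).
#'
#' @param h,m binary HpaII / MspI presence calls (vectorized).
#' @return Integer state code(s) as in [methStates()].
#' @examples
#' names(methStates())[classifyPattern(c(1, 1, 0, 0), c(1, 0, 1, 0))]
#' @export
classifyPattern <- function(h, m) {
  if (!all(h %in% c(0, 1)) || !all(m %in% c(0, 1)))
    stop("calls must be binary 0/1")
  if (length(h) != length(m)) stop("h and m must have equal length")
  # (1,1)->1, (1,0)->2, (0,1)->3, (0,0)->4
  unname(ifelse(h == 1 & m == 1, 1L,
         ifelse(h == 1 & m == 0, 2L,
         ifelse(h == 0 & m == 1, 3L, 4L))))
}

#' Classify a whole band matrix into epigenotypes
#'
#' Applies [classifyPattern()] cell-wise and fills the binary methylation
#' score `deMet01` (0 = demethylated, 1 = any methylated state).
#'
#' @param bands a [BandMatrix-class].
#' @param jointAbsence how to treat HPA-/MSP- cells: `"full_methylation"`
#'   (default, the conventional four-state scoring) or `"missing"` (treat as
#'   uninformative: state `NA`, methylated `NA`), the alternative MSAP
#'   convention since joint absence can also mean the CCGG target is absent.
#' @return An [EpigenotypeMatrix-class] with assays `state` and
#'   `methylated`; `locus_class` and `polymorphic` are `NA` until
#'   [partitionLoci()] / [polymorphicLoci()] are run.
#' @export
classifyMatrix <- function(bands,
                           jointAbsence = c("full_methylation", "missing")) {
  stopifnot(is(bands, "BandMatrix"))
  jointAbsence <- match.arg(jointAbsence)
  h <- assay(bands, "HPA"); m <- assay(bands, "MSP")
  st <- matrix(classifyPattern(as.vector(h), as.vector(m)),
               nrow(h), ncol(h), dimnames = dimnames(h))
  me <- matrix(as.integer(st != 1L), nrow(h), ncol(h),
               dimnames = dimnames(h))
  if (jointAbsence == "missing") {
    st[st == 4L] <- NA_integer_
    me[is.na(st)] <- NA_integer_
  }
  rd <- rowData(bands)
  rd$locus_class <- rep(NA_character_, nrow(bands))
  rd$polymorphic <- rep(NA, nrow(bands))
  se <- SummarizedExperiment(
    assays = list(state = st, methylated = me),
    rowData = rd, colData = colData(bands))
  out <- new("EpigenotypeMatrix", se)
  if (jointAbsence == "full_methylation") validObject(out)
  out
}

#' Partition loci into methylation-susceptible (MSL) and non-methylated (NML)
#'
#' A band is a methylation-susceptible locus when the fraction of accessions
#' showing any non-demethylated state exceeds `errorThreshold`; otherwise it
#' is a non-methylated locus. The 5% default is the conventional MSAP
#' scoring-error allowance.
#'
#' @param epi an [EpigenotypeMatrix-class].
#' @param errorThreshold fraction in `[0, 1)`.
#' @return `epi` with `rowData(epi)$locus_class` filled ("MSL"/"NML") and
#'   the threshold recorded in `metadata(epi)$error_threshold`.
#' @export
partitionLoci <- function(epi, errorThreshold = 0.05) {
  stopifnot(is(epi, "EpigenotypeMatrix"))
  if (errorThreshold < 0 || errorThreshold >= 1)
    stop("errorThreshold must be in [0, 1)")
  me <- assay(epi, "methylated")
  frac <- unname(rowMeans(me == 1L, na.rm = TRUE))
  rowData(epi)$locus_class <- ifelse(frac > errorThreshold, "MSL", "NML")
  metadata(epi)$error_threshold <- errorThreshold
  epi
}

#' Flag polymorphic methylation-susceptible loci
#'
#' An MSL band is polymorphic when at least two distinct methylation states
#' occur across accessions; NML bands are scored non-polymorphic.
#'
#' @param epi an [EpigenotypeMatrix-class] after [partitionLoci()].
#' @return `epi` with `rowData(epi)$polymorphic` filled.
#' @export
polymorphicLoci <- function(epi) {
  stopifnot(is(epi, "EpigenotypeMatrix"))
  lc <- rowData(epi)$locus_class
  if (anyNA(lc)) stop("run partitionLoci() first")
  st <- assay(epi, "state")
  ndistinct <- apply(st, 1L, function(z) length(unique(z[!is.na(z)])))
  rowData(epi)$polymorphic <- unname(lc == "MSL" & ndistinct >= 2L)
  epi
}

#' Group-conditional methylation-state fraction table
#'
#' For each group (typically BF vs NBF) tallies every (band, accession)
#' cell by its four-state methylation call and reports within-group
#' fractions, the analogue of the study's banding-proportion table.
#'
#' @param epi an [EpigenotypeMatrix-class].
#' @param grouping named factor/character mapping accession to group (as
#'   from [bfGrouping()]); must cover all accessions and every group must
#'   be non-empty.
#' @return `data.frame` with columns `group`, `state`, `count`, `fraction`;
#'   fractions within each group sum to 1.
#' @export
methylationFractionTable <- function(epi, grouping) {
  stopifnot(is(epi, "EpigenotypeMatrix"))
  grouping <- grouping[colnames(epi)]
  if (anyNA(grouping)) stop("grouping must cover all accessions")
  grouping <- droplevels(factor(grouping))
  if (nlevels(grouping) < 1L || any(table(grouping) == 0L))
    stop("every group must contain at least one accession")
  st <- assay(epi, "state")
  out <- do.call(rbind, lapply(levels(grouping), function(g) {
    cells <- st[, grouping == g, drop = FALSE]
    cnt <- vapply(1:4, function(k) sum(cells == k, na.rm = TRUE), integer(1))
    data.frame(group = g, state = names(methStates()), count = cnt,
               fraction = cnt / sum(cnt), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
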