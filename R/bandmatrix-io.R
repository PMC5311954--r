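.ASSAY_SYNONYMS <- c(
  "HPA" = "HPA", "MSP" = "MSP",
  "EcoRI+HpaII" = "HPA", "EcoRI+MspI" = "MSP",
  "ECORI+HPAII" = "HPA", "ECORI+MSPI" = "MSP")

.normalizeAssay <- function(x) {
  out <- .ASSAY_SYNONYMS[x]
  nm <- is.na(out)
  out[nm] <- .ASSAY_SYNONYMS[toupper(x[nm])]
  if (anyNA(out))
    stop("unknown assay label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "),
         " (expected HPA/MSP or EcoRI+HpaII/EcoRI+MspI)")
  unname(out)
}

#' Read an MS-AFLP band matrix in the MSAP CSV convention
#'
#' The file layout is: a first column with the BF-exhibition category, a
#' second column with the accession name, a third column naming the assay
#' (the EcoRI+HpaII or EcoRI+MspI digest; `HPA`/`MSP` accepted as
#' synonyms), followed by one binary column per band, named
#' `"<primer><index>"` with primers `a`--`i` and indices ordered heavy to
#' light fragment. Every accession must have exactly one HPA and one MSP
#' row over the same band set.
#'
#' @param path CSV file path.
#' @param metadata optional `data.frame` of accession metadata (as from
#'   [accessionMetadata()]) keyed by `accession_id`, merged into `colData`.
#'   Accessions absent from the metadata are allowed and reported via a
#'   message.
#' @return A validated [BandMatrix-class] with bands as rows, accessions as
#'   columns, and band order as in the file.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeBandMatrix(generateBandMatrix(simulationConfig(seed = 1,
#'   bandsPerPrimer = c(a = 3, b = 2)))$matrix, f)
#' bm <- readBandMatrix(f)
#' dim(bm)
#' @export
readBandMatrix <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 4L)
    stop("band matrix must have bf_category, accession, assay and at least one band column")
  names(raw)[1:3] <- c("bf_category", "accession", "assay")
  raw$assay <- .normalizeAssay(raw$assay)
  bandCols <- names(raw)[-(1:3)]
  if (!all(grepl("^[a-z]+[0-9]+$", bandCols)))
    stop("band columns must be named '<primer><index>', e.g. 'a1'")
  acc <- unique(raw$accession)
  for (a in acc) {
    have <- raw$assay[raw$accession == a]
    missing <- setdiff(c("HPA", "MSP"), have)
    if (length(missing))
      stop(sprintf("accession '%s' lacks %s row(s)", a,
                   paste(missing, collapse = " and ")))
    if (anyDuplicated(have))
      stop(sprintf("accession '%s' has duplicated assay rows", a))
  }
  vals <- as.matrix(raw[, bandCols, drop = FALSE])
  bad <- which(!(vals %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(vals)) + 1
    j <- ((bad[1] - 1) %/% nrow(vals)) + 1
    stop(sprintf("non-binary call at row %d (accession '%s'), band '%s'",
                 i, raw$accession[i], bandCols[j]))
  }
  toMat <- function(lbl) {
    sub <- raw[raw$assay == lbl, , drop = FALSE]
    m <- t(as.matrix(sub[, bandCols, drop = FALSE]))
    storage.mode(m) <- "integer"
    colnames(m) <- sub$accession
    m[, acc, drop = FALSE]
  }
  cd <- DataFrame(
    bf_category = raw$bf_category[match(acc, raw$accession)],
    row.names = acc)
  if (!is.null(metadata)) {
    idx <- match(acc, metadata$accession_id)
    unknown <- acc[is.na(idx)]
    if (length(unknown))
      message("accessions without metadata: ", paste(unknown, collapse = ", "))
    for (col in setdiff(colnames(metadata), "accession_id"))
      cd[[col]] <- metadata[[col]][idx]
  }
  BandMatrix(toMat("HPA"), toMat("MSP"), colData = cd)
}

#' Write a band matrix in the same CSV dialect readBandMatrix accepts
#'
#' Rows are emitted accession by accession (HPA row then MSP row), so two
#' writes of the same object are byte-identical and
#' `readBandMatrix(writeBandMatrix(x))` is the identity on calls, band
#' order and the bf_category column.
#'
#' @param x a [BandMatrix-class] with at least one band.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeBandMatrix <- function(x, path) {
  stopifnot(is(x, "BandMatrix"))
  if (nrow(x) == 0L) stop("refusing to write a band matrix with no bands")
  acc <- colnames(x)
  bf <- as.character(colData(x)$bf_category)
  hpa <- t(assay(x, "HPA")); msp <- t(assay(x, "MSP"))
  out <- data.frame(
    bf_category = rep(bf, each = 2L),
    accession = rep(acc, each = 2L),
    assay = rep(c("HPA", "MSP"), length(acc)),
    stringsAsFactors = FALSE, check.names = FALSE)
  calls <- matrix(0L, nrow(out), nrow(x))
  calls[seq(1, nrow(out), 2), ] <- hpa
  calls[seq(2, nrow(out), 2), ] <- msp
  colnames(calls) <- rownames(x)
  write.csv(cbind(out, as.data.frame(calls, check.names = FALSE)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Accession metadata for the 22-accession almond bud-failure panel
#'
#' The packaged fixture: 22 accessions from 7 cultivars/genotypes, each with
#' its BF-exhibition category on the six-level ordinal scale (scored 6, 5,
#' 4, 3, 2, 1 for high, medium-to-high, medium, low-to-medium, low and no
#' bud-failure exhibition) and the clonal age in decades since the clone
#' was first used as a budwood propagation source.
#'
#' @return `data.frame` with columns `accession_id`, `genotype`,
#'   `bf_category`, `bf_score` (integer 1--6), `clonal_age_decades`.
#' @examples
#' meta <- accessionMetadata()
#' nrow(meta)   # 22
#' @export
accessionMetadata <- function() {
  path <- system.file("extdata", "accession_metadata.csv", package = "msapBF",
                      mustWork = TRUE)
  meta <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(meta$bf_score %in% 1:6), all(meta$clonal_age_decades >= 1))
  meta
}

#' Dichotomize BF exhibition into BF / NBF groups
#'
#' The six-level score is split at `threshold`: accessions with
#' `bf_score >= threshold` are `BF`, the rest `NBF`. The default threshold
#' of 4 ("Medium" and above) splits the packaged 22-accession panel 11/11.
#'
#' @param meta metadata `data.frame` with a `bf_score` column (or a
#'   [BandMatrix-class]/[EpigenotypeMatrix-class] whose `colData` has one).
#' @param threshold integer in 2..6.
#' @return Named factor with levels `c("NBF", "BF")`, one element per
#'   accession.
#' @examples
#' table(bfGrouping(accessionMetadata()))
#' @export
bfGrouping <- function(meta, threshold = 4L) {
  stopifnot(threshold %in% 2:6)
  if (is(meta, "SummarizedExperiment")) {
    sc <- colData(meta)$bf_score
    ids <- colnames(meta)
  } else {
    sc <- meta$bf_score
    ids <- meta$accession_id
  }
  if (is.null(sc)) stop("no bf_score available")
  setNames(factor(ifelse(sc >= threshold, "BF", "NBF"),
                  levels = c("NBF", "BF")), ids)
}
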