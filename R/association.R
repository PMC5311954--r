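#' Aggregate a 2x2 methylation-by-BF contingency table
#'
#' Counts every scored (band, accession) cell as methylated or unmethylated
#' and cross-classifies by the accession's BF/NBF group, giving the
#' genome-wide 2x2 table used for the first-pass independence test.
#'
#' @param epi an [EpigenotypeMatrix-class].
#' @param grouping named factor mapping accession to `BF`/`NBF` (as from
#'   [bfGrouping()]); both groups must be non-empty.
#' @return 2x2 integer matrix, rows `c("methylated", "unmethylated")`,
#'   columns the group levels.
#' @export
buildContingency2x2 <- function(epi, grouping) {
  stopifnot(is(epi, "EpigenotypeMatrix"))
  grouping <- droplevels(factor(grouping[colnames(epi)]))
  if (anyNA(grouping)) stop("grouping must cover all accessions")
  if (nlevels(grouping) != 2L || any(table(grouping) == 0L))
    stop("grouping must define exactly two non-empty groups")
  me <- assay(epi, "methylated")
  lev <- levels(grouping)
  if (all(c("BF", "NBF") %in% lev)) lev <- c("BF", "NBF")
  tab <- vapply(lev, function(g) {
    cells <- me[, grouping == g, drop = FALSE]
    c(methylated = sum(cells == 1L, na.rm = TRUE),
      unmethylated = sum(cells == 0L, na.rm = TRUE))
  }, integer(2))
  tab
}

#' Phi coefficient of a 2x2 table
#'
#' `(n11 n22 - n12 n21) / sqrt(n1. n2. n.1 n.2)`, the correlation
#' coefficient for a 2x2 contingency table; its square times N equals the
#' Pearson chi-square statistic.
#'
#' @param tab 2x2 numeric matrix of counts with all margins positive.
#' @return The phi coefficient, in `[-1, 1]`.
#' @examples
#' phiCoefficient(matrix(c(6598, 5798, 5799, 6597), 2))  # ~0.0645
#' @export
phiCoefficient <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  rm <- rowSums(tab); cm <- colSums(tab)
  if (any(rm == 0) || any(cm == 0))
    stop("phi coefficient undefined: zero margin")
  (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1]) /
    sqrt(prod(c(rm, cm)))
}

#' Pearson chi-square test of independence for a two-way table
#'
#' Computes the chi-square statistic, degrees of freedom, upper-tail
#' p-value, per-cell Pearson residuals `(O - E)/sqrt(E)` and expected
#' counts; for 2x2 tables also the [phiCoefficient()]. No continuity
#' correction by default, matching Pearson-residual-based mosaic displays.
#'
#' @param tab two-way matrix of counts.
#' @param correct apply the Yates continuity correction to the statistic
#'   (2x2 only); residuals and phi are always uncorrected.
#' @return list with `chi2`, `df`, `p_value`, `expected`, `residuals`,
#'   `phi` (2x2 only, else `NA`), and `observed`.
#' @export
pearsonChi2 <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0), nrow(tab) >= 2, ncol(tab) >= 2)
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  if (any(E == 0)) stop("zero expected count")
  if (correct && all(dim(tab) == 2L)) {
    adj <- pmin(abs(tab - E), 0.5)
    chi2 <- sum((abs(tab - E) - adj)^2 / E)
  } else {
    chi2 <- sum((tab - E)^2 / E)
  }
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(chi2 = chi2, df = df,
       p_value = pchisq(chi2, df, lower.tail = FALSE),
       expected = E, residuals = (tab - E) / sqrt(E),
       phi = if (all(dim(tab) == 2L)) phiCoefficient(tab) else NA_real_,
       observed = tab)
}

#' Cochran-Mantel-Haenszel conditional independence test
#'
#' Tests conditional independence of the two classifying factors of a
#' 2x2xK table given the stratifying factor, by summing hypergeometric
#' means and variances of the (1,1) cell over strata. Strata with a zero
#' margin carry no information and are skipped with a warning.
#'
#' @param tab 2x2xK array of counts.
#' @param correct apply the 0.5 continuity correction (off by default, so
#'   exact per-stratum independence gives a statistic of exactly zero;
#'   when on, the correction follows the usual convention of
#'   `stats::mantelhaen.test`).
#' @return list with `statistic`, `df` (= 1), `p_value`, and per-stratum
#'   Pearson `residuals` (for mosaic export).
#' @export
cmhTest <- function(tab, correct = FALSE) {
  tab <- as.array(tab)
  if (length(dim(tab)) == 2L) tab <- array(tab, c(dim(tab), 1L))
  stopifnot(length(dim(tab)) == 3L, all(dim(tab)[1:2] == 2L))
  K <- dim(tab)[3]
  a <- e <- v <- numeric(0)
  resid <- vector("list", K)
  for (k in seq_len(K)) {
    t2 <- tab[, , k]
    n <- sum(t2); r <- rowSums(t2); c <- colSums(t2)
    if (n == 0 || any(r == 0) || any(c == 0)) {
      warning(sprintf("stratum %d has a zero margin; skipped", k))
      next
    }
    a <- c(a, t2[1, 1])
    e <- c(e, r[1] * c[1] / n)
    v <- c(v, prod(r) * prod(c) / (n^2 * (n - 1)))
    E <- outer(r, c) / n
    resid[[k]] <- (t2 - E) / sqrt(E)
  }
  if (!length(a)) stop("no informative strata")
  d <- abs(sum(a) - sum(e))
  yates <- if (correct && d >= 0.5) 0.5 else 0  # mantelhaen.test convention
  stat <- (d - yates)^2 / sum(v)
  list(statistic = stat, df = 1L,
       p_value = pchisq(stat, 1L, lower.tail = FALSE),
       residuals = resid)
}

#' Kendall's tau-b (tie-adjusted) between two vectors
#'
#' `(C - D) / sqrt((n0 - n1)(n0 - n2))` where `C`/`D` are concordant and
#' discordant pair counts, `n0 = n(n-1)/2`, and `n1`, `n2` are the
#' within-ties pair counts of `x` and `y`. For binary vectors this reduces
#' to the phi coefficient of their 2x2 cross-table, which is used as a
#' fast closed form; general vectors fall back to pair enumeration.
#'
#' @param x,y equal-length vectors (length >= 2); undefined (error) when
#'   either vector is constant.
#' @return tau-b in `[-1, 1]`.
#' @examples
#' kendallTauB(c(0, 1, 1, 0, 1), c(0, 1, 0, 0, 1))  # 2/3
#' @export
kendallTauB <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least two observations")
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("tau-b undefined for a constant vector")
  if (all(x %in% c(0, 1)) && all(y %in% c(0, 1))) {
    t2 <- table(factor(x, c(0, 1)), factor(y, c(0, 1)))
    return(phiCoefficient(t2))
  }
  n <- length(x)
  C <- D <- 0
  for (i in seq_len(n - 1L)) {
    dx <- x[i] - x[(i + 1L):n]; dy <- y[i] - y[(i + 1L):n]
    s <- sign(dx) * sign(dy)
    C <- C + sum(s > 0); D <- D + sum(s < 0)
  }
  n0 <- n * (n - 1) / 2
  n1 <- sum(choose(table(x), 2)); n2 <- sum(choose(table(y), 2))
  (C - D) / sqrt((n0 - n1) * (n0 - n2))
}

#' Pairwise Kendall tau-b concordance of methylation profiles
#'
#' Computes tau-b between the binary methylation (`deMet01`) profiles of
#' every accession pair, tagging pairs as within- or between-genotype when
#' genotype metadata is present, with group-wise mean summaries.
#'
#' @param epi an [EpigenotypeMatrix-class] (>= 2 accessions).
#' @param meta optional metadata `data.frame` with `accession_id` and
#'   `genotype`; defaults to `colData` when it carries `genotype`.
#' @return list with `tau` (symmetric matrix, unit diagonal for
#'   non-constant profiles, `NA` where undefined), `pairs` (long-format
#'   `data.frame` with `within_genotype` flags), and `summary` (mean tau
#'   within/between genotypes).
#' @export
pairwiseConcordance <- function(epi, meta = NULL) {
  stopifnot(is(epi, "EpigenotypeMatrix"), ncol(epi) >= 2L)
  me <- assay(epi, "methylated")
  acc <- colnames(epi)
  geno <- if (!is.null(meta)) meta$genotype[match(acc, meta$accession_id)]
          else colData(epi)$genotype
  n <- length(acc)
  tau <- matrix(NA_real_, n, n, dimnames = list(acc, acc))
  rows <- list()
  for (i in seq_len(n)) {
    if (length(unique(me[, i])) >= 2L) tau[i, i] <- 1
    for (j in seq_len(n)[-seq_len(i)]) {
      tij <- tryCatch(kendallTauB(me[, i], me[, j]), error = function(e) NA_real_)
      tau[i, j] <- tau[j, i] <- tij
      rows[[length(rows) + 1L]] <- data.frame(
        a = acc[i], b = acc[j], tau = tij,
        within_genotype = if (is.null(geno)) NA else
          identical(geno[i], geno[j]),
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  summ <- if (!is.null(geno))
    data.frame(
      group = c("within_genotype", "between_genotype"),
      mean_tau = c(mean(pairs$tau[pairs$within_genotype], na.rm = TRUE),
                   mean(pairs$tau[!pairs$within_genotype], na.rm = TRUE)))
  else NULL
  list(tau = tau, pairs = pairs, summary = summ)
}

#' Bands in perfect correspondence with BF exhibition
#'
#' Finds bands whose binary methylation score is 1 for every BF accession
#' and 0 for every NBF accession (direction `"methylated_in_BF"`), or the
#' exact complement (direction `"demethylated_in_BF"`), the analogue of
#' fully BF-diagnostic MS-AFLP bands.
#'
#' @param epi an [EpigenotypeMatrix-class].
#' @param grouping named BF/NBF factor (as from [bfGrouping()]) with both
#'   groups non-empty.
#' @return `data.frame` with columns `band`, `primer`, `band_index`,
#'   `direction`; zero rows when no band separates the groups perfectly.
#' @export
perfectlyAssociatedBands <- function(epi, grouping) {
  stopifnot(is(epi, "EpigenotypeMatrix"))
  grouping <- droplevels(factor(grouping[colnames(epi)]))
  if (nlevels(grouping) != 2L || !all(c("BF", "NBF") %in% levels(grouping)))
    stop("grouping must contain both BF and NBF accessions")
  me <- assay(epi, "methylated")
  bf <- me[, grouping == "BF", drop = FALSE]
  nbf <- me[, grouping == "NBF", drop = FALSE]
  pos <- rowSums(bf == 1L) == ncol(bf) & rowSums(nbf == 0L) == ncol(nbf)
  neg <- rowSums(bf == 0L) == ncol(bf) & rowSums(nbf == 1L) == ncol(nbf)
  idx <- c(which(pos), which(neg))
  out <- data.frame(
    band = rownames(epi)[idx],
    primer = rowData(epi)$primer[idx],
    band_index = rowData(epi)$band_index[idx],
    direction = rep(c("methylated_in_BF", "demethylated_in_BF"),
                    c(sum(pos), sum(neg))),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
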