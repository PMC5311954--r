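#' Pairwise distances between binary methylation profiles
#'
#' @param epi an [EpigenotypeMatrix-class] (>= 2 accessions).
#' @param metric `"mismatch"` (simple-matching distance: proportion of
#'   bands with differing binary methylation; treats 0/0 agreement as
#'   informative, appropriate since absence of methylation is itself a
#'   state) or `"jaccard"` (1 - intersection/union over methylated bands;
#'   a pair with no methylated band in either profile is scored 0 with a
#'   warning).
#' @return A [stats::dist] object over accessions.
#' @export
binaryDistance <- function(epi, metric = c("mismatch", "jaccard")) {
  stopifnot(is(epi, "EpigenotypeMatrix"), ncol(epi) >= 2L)
  metric <- match.arg(metric)
  me <- t(assay(epi, "methylated"))  # accessions x bands
  n <- nrow(me)
  d <- matrix(0, n, n, dimnames = list(rownames(me), rownames(me)))
  warned <- FALSE
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    x <- me[i, ]; y <- me[j, ]
    if (metric == "mismatch") {
      dij <- mean(x != y)
    } else {
      u <- sum(x == 1L | y == 1L)
      if (u == 0L) { dij <- 0; warned <- TRUE }
      else dij <- 1 - sum(x == 1L & y == 1L) / u
    }
    d[i, j] <- d[j, i] <- dij
  }
  if (warned)
    warning("jaccard undefined for an all-unmethylated pair; scored 0")
  as.dist(d)
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical multidimensional scaling: Gower double-centering
#' `B = -1/2 J D^2 J`, eigendecomposition, coordinates as eigenvectors
#' scaled by the square root of the (positive) eigenvalues. Negative
#' eigenvalues, which arise for non-Euclidean distances, are retained and
#' reported rather than corrected.
#'
#' @param d a [stats::dist] or symmetric distance matrix.
#' @return list with `coordinates` (accessions x axes, positive-eigenvalue
#'   axes only, ordered by decreasing eigenvalue), `eigenvalues` (all, in
#'   decreasing order), and `trace` (of the centered matrix).
#' @export
pcoaOrdination <- function(d) {
  d <- as.dist(d)
  n <- attr(d, "Size")
  if (n < 2L) stop("need at least two points")
  # k = n-1 is requested so every eigenvalue is reported; cmdscale warns
  # when some of those are non-positive, which is expected here
  fit <- withCallingHandlers(
    cmdscale(d, k = n - 1L, eig = TRUE),
    warning = function(w) {
      if (grepl("eigenvalues", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ev <- sort(fit$eig, decreasing = TRUE)
  pos <- which(fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig), 1))
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  if (length(pos) == 0L)
    coords <- matrix(0, n, 1, dimnames = list(attr(d, "Labels"), "Axis1"))
  else
    colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = ev, trace = sum(fit$eig))
}

#' UPGMA (average-linkage) dendrogram from a distance matrix
#'
#' Agglomerative average-linkage clustering yielding an ultrametric rooted
#' tree (every root-to-leaf path has equal length, half the final merge
#' height). Labels are processed in lexicographic order so equal-distance
#' ties break deterministically.
#'
#' @param d a [stats::dist] or symmetric matrix with labels (>= 2 leaves).
#' @return An [ape::as.phylo()] tree with branch lengths; write with
#'   [ape::write.tree()] for Newick export.
#' @export
upgmaTree <- function(d) {
  dm <- as.matrix(as.dist(d))
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <-
      paste0("t", seq_len(nrow(dm)))
  ord <- order(rownames(dm))
  dm <- dm[ord, ord]
  hc <- hclust(as.dist(dm), method = "average")
  as.phylo(hc)
}

#' Export the binary methylation heatmap matrix
#'
#' Writes (or returns) the accessions x bands matrix of binary methylation
#' codes used for visual inspection, with accessions ordered by clonal age
#' (stable for ties: input order preserved) and annotated with their age.
#'
#' @param epi an [EpigenotypeMatrix-class].
#' @param meta metadata with `accession_id` and `clonal_age_decades`;
#'   defaults to `colData` when it carries `clonal_age_decades`.
#' @param path optional TSV output path.
#' @return `data.frame`: `accession`, `clonal_age_decades`, then one 0/1
#'   column per band. Written to `path` when given (tab-separated).
#' @export
heatmapExport <- function(epi, meta = NULL, path = NULL) {
  stopifnot(is(epi, "EpigenotypeMatrix"))
  acc <- colnames(epi)
  age <- if (!is.null(meta))
    meta$clonal_age_decades[match(acc, meta$accession_id)]
  else colData(epi)$clonal_age_decades
  if (is.null(age)) stop("no clonal_age_decades available")
  ord <- order(age)  # stable: ties keep input order
  me <- t(assay(epi, "methylated"))[ord, , drop = FALSE]
  out <- data.frame(accession = acc[ord], clonal_age_decades = age[ord],
                    me, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(path))
    write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  out
}
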