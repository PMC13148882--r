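#' MdsProjection: classical (Torgerson) MDS of a distance matrix
#'
#' @slot labels population labels.
#' @slot points n x k coordinate matrix; columns are ordered by decreasing
#'   eigenvalue and each axis is oriented so that the focal population's
#'   coordinate is non-negative.
#' @slot eig all eigenvalues of the double-centered matrix, descending;
#'   negative values diagnose non-Euclidean input and are never used for
#'   coordinates.
#' @slot residual Frobenius norm of (input distances - reconstructed
#'   distances), a stress-like reconstruction error.
#' @slot k number of retained dimensions.
#' @aliases MdsProjection-class
#' @exportClass MdsProjection
setClass("MdsProjection",
         representation(labels = "character", points = "matrix",
                        eig = "numeric", residual = "numeric",
                        k = "integer"))

#' @rdname nullmark-generics
#' @export
setMethod("coordinates", "MdsProjection", function(x) x@points)

#' @rdname nullmark-generics
#' @export
setMethod("eigenvalues", "MdsProjection", function(x) x@eig)

#' @rdname nullmark-generics
#' @export
setMethod("reconstructionError", "MdsProjection", function(x) x@residual)

setMethod("show", "MdsProjection", function(object) {
  cat(sprintf("MdsProjection: %d populations in %d dimensions\n",
              length(object@labels), object@k))
  negMass <- sum(abs(object@eig[object@eig < 0]))
  cat(sprintf("  reconstruction error (Frobenius): %.4g\n", object@residual))
  cat(sprintf("  negative eigenvalue mass: %.4g\n", negMass))
  invisible(NULL)
})

checkDistanceMatrix <- function(d, minLeaves = 1L) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m))
    stop("distance matrix must be square")
  if (is.null(rownames(m)))
    rownames(m) <- colnames(m) <- paste0("P", seq_len(nrow(m)))
  if (anyNA(m))
    stop("distance matrix contains NA")
  if (any(is.infinite(m))) {
    bad <- unique(rownames(m)[which(is.infinite(m), arr.ind = TRUE)[, 1]])
    stop("infinite distances involving: ", paste(bad, collapse = ", "),
         "; exclude these populations first")
  }
  if (max(abs(m - t(m))) > 1e-8)
    stop("distance matrix must be symmetric")
  if (max(abs(diag(m))) > 1e-12)
    stop("distance matrix must have a zero diagonal")
  if (nrow(m) < minLeaves)
    stop("need at least ", minLeaves, " populations")
  m
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Double-centers the squared distances (B = -1/2 J D^2 J), eigendecomposes,
#' and scales the top eigenvectors by the square roots of their (positive)
#' eigenvalues. The requested dimension is capped at the number of positive
#' eigenvalues; negative eigenvalues are reported as diagnostics. Each axis
#' is oriented so that the focal population (by default the first label) has
#' a non-negative coordinate, making plots reproducible.
#'
#' @param d symmetric finite distance matrix with zero diagonal (a
#'   \code{dist} is also accepted).
#' @param k number of dimensions to retain (default 2).
#' @param focal label or index of the population fixing axis orientation.
#' @return an \linkS4class{MdsProjection}.
#' @export
classicalMds <- function(d, k = 2L, focal = 1L) {
  m <- checkDistanceMatrix(d, minLeaves = 2L)
  if (k < 1) stop("k must be >= 1")
  labs <- rownames(m)
  f <- if (is.character(focal)) match(focal, labs) else as.integer(focal)
  if (is.na(f) || f < 1 || f > nrow(m))
    stop("focal population not found")
  fit <- suppressWarnings(
    cmdscale(m, k = max(1L, nrow(m) - 1L), eig = TRUE))
  eig <- sort(fit$eig, decreasing = TRUE)
  pts <- fit$points
  ## count eigenvalues positive beyond numerical noise (relative tolerance)
  npos <- sum(eig > max(eig, 0) * 1e-9)
  kUse <- max(1L, min(as.integer(k), ncol(pts), npos))
  pts <- pts[, seq_len(kUse), drop = FALSE]
  ## deterministic axis orientation
  for (j in seq_len(ncol(pts))) {
    ref <- pts[f, j]
    if (ref == 0) {
      nz <- which(pts[, j] != 0)
      ref <- if (length(nz)) pts[nz[1], j] else 1
    }
    if (ref < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- labs
  colnames(pts) <- paste0("dim", seq_len(ncol(pts)))
  resid <- norm(m - as.matrix(dist(pts)), type = "F")
  new("MdsProjection", labels = labs, points = pts, eig = eig,
      residual = resid, k = kUse)
}

#' UpgmaDendrogram: ultrametric average-linkage tree
#'
#' @slot merge (n-1) x 2 integer matrix in \code{hclust} convention:
#'   negative entries are leaves, positive entries earlier merges.
#' @slot height merge heights on the ultrametric scale, i.e. half the
#'   between-cluster distance at each merge, so the cophenetic distance
#'   between two leaves equals the full cluster distance at their join.
#' @slot labels leaf labels.
#' @slot order leaf ordering for plotting.
#' @slot newick Newick serialization with branch lengths (height
#'   differences).
#' @aliases UpgmaDendrogram-class
#' @exportClass UpgmaDendrogram
setClass("UpgmaDendrogram",
         representation(merge = "matrix", height = "numeric",
                        labels = "character", order = "integer",
                        newick = "character"))

setValidity("UpgmaDendrogram", function(object) {
  h <- object@height
  if (length(h) > 1 && any(diff(h) < -1e-12))
    return("merge heights must be non-decreasing (ultrametricity)")
  TRUE
})

#' @rdname nullmark-generics
#' @export
setMethod("mergeHeights", "UpgmaDendrogram", function(x) x@height)

#' @rdname nullmark-generics
#' @export
setMethod("leafLabels", "UpgmaDendrogram", function(x) x@labels)

#' @rdname nullmark-generics
#' @export
setMethod("newick", "UpgmaDendrogram", function(x) x@newick)

setMethod("show", "UpgmaDendrogram", function(object) {
  cat(sprintf("UpgmaDendrogram with %d leaves; root height %.4g\n",
              length(object@labels), max(object@height)))
  cat(" ", object@newick, "\n")
  invisible(NULL)
})

#' UPGMA (average linkage) clustering of a distance matrix
#'
#' Iteratively merges the closest pair of clusters; the distance from the
#' merged cluster to any other is the size-weighted (unweighted pair-group)
#' average of its parts. Among tied minima the pair that is first in the
#' current cluster order (clusters ordered by creation: leaves in input
#' order, then merges) is taken, so the output is deterministic. Merge
#' heights are half the between-cluster distance, which makes the tree
#' ultrametric with leaf-to-leaf path lengths equal to the cluster distance
#' at the join.
#'
#' @param d symmetric finite distance matrix (or \code{dist}) over >= 2
#'   leaves.
#' @return an \linkS4class{UpgmaDendrogram}.
#' @export
#' @examples
#' m <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
#' newick(upgma(m))  # "(A:1,B:1);"
upgma <- function(d) {
  m <- checkDistanceMatrix(d, minLeaves = 2L)
  n <- nrow(m)
  labs <- rownames(m)
  dd <- m
  diag(dd) <- NA_real_
  ids <- -seq_len(n)          # hclust convention: leaves negative
  sizes <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    idx <- which(dd == min(dd, na.rm = TRUE), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    merge[s, ] <- c(ids[i], ids[j])
    height[s] <- dd[i, j]
    newRow <- (sizes[i] * dd[i, ] + sizes[j] * dd[j, ]) / (sizes[i] + sizes[j])
    dd[i, ] <- newRow
    dd[, i] <- newRow
    dd[i, i] <- NA_real_
    dd <- dd[-j, -j, drop = FALSE]
    sizes[i] <- sizes[i] + sizes[j]
    sizes <- sizes[-j]
    ids[i] <- s
    ids <- ids[-j]
  }
  half <- height / 2
  ord <- upgmaLeafOrder(merge, n)
  nwk <- upgmaNewick(merge, half, labs)
  new("UpgmaDendrogram", merge = merge, height = half, labels = labs,
      order = ord, newick = nwk)
}

upgmaLeafOrder <- function(merge, n) {
  rec <- function(node) {
    if (node < 0) return(-node)
    c(rec(merge[node, 1]), rec(merge[node, 2]))
  }
  as.integer(rec(nrow(merge)))
}

upgmaNewick <- function(merge, half, labs) {
  fmt <- function(x) format(x, digits = 12, trim = TRUE, scientific = FALSE)
  rec <- function(node, parentHeight) {
    if (node < 0)
      return(sprintf("%s:%s", labs[-node], fmt(parentHeight)))
    h <- half[node]
    sprintf("(%s,%s):%s", rec(merge[node, 1], h), rec(merge[node, 2], h),
            fmt(parentHeight - h))
  }
  root <- nrow(merge)
  h <- half[root]
  sprintf("(%s,%s);", rec(merge[root, 1], h), rec(merge[root, 2], h))
}

#' Cophenetic distances implied by a UPGMA tree
#'
#' For each leaf pair, twice the (half-distance) height of their lowest
#' common ancestor — i.e. the between-cluster distance at which they were
#' joined.
#'
#' @param dend an \linkS4class{UpgmaDendrogram}.
#' @return symmetric matrix over the leaf labels.
#' @export
copheneticDistances <- function(dend) {
  stopifnot(is(dend, "UpgmaDendrogram"))
  labs <- dend@labels
  n <- length(labs)
  coph <- matrix(0, n, n, dimnames = list(labs, labs))
  members <- vector("list", nrow(dend@merge))
  for (s in seq_len(nrow(dend@merge))) {
    side <- lapply(dend@merge[s, ], function(node)
      if (node < 0) -node else members[[node]])
    for (a in side[[1]]) for (b in side[[2]]) {
      coph[a, b] <- coph[b, a] <- 2 * dend@height[s]
    }
    members[[s]] <- c(side[[1]], side[[2]])
  }
  coph
}

#' Write a Newick file
#'
#' @param dend an \linkS4class{UpgmaDendrogram}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeNewick <- function(dend, path) {
  writeLines(newick(dend), path)
  invisible(path)
}

#' Write MDS coordinates as TSV
#'
#' @param mds an \linkS4class{MdsProjection}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeCoordinates <- function(mds, path) {
  pts <- coordinates(mds)
  df <- data.frame(population = rownames(pts),
                   apply(pts, 2, fmtNum),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
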