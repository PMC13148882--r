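## Shared fixtures and independent oracles for the test suite.

## Cohort with the published two-locus joint counts:
## (+/+, +/null, null/+, null/null) = (104, 80, 98, 18), n = 300.
table2Cohort <- function() {
  gm <- c(rep(FALSE, 104 + 80), rep(TRUE, 98 + 18))
  gt <- c(rep(FALSE, 104), rep(TRUE, 80), rep(FALSE, 98), rep(TRUE, 18))
  m <- rbind(GSTM1 = gm, GSTT1 = gt)
  colnames(m) <- sprintf("S%03d", seq_len(300))
  GenotypeCohort(m)
}

## Textbook Pearson statistic: sum (|O-E| - c)^2 / E with E from margins.
chi2Oracle <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  adj <- if (yates) pmax(0, abs(tab - E) - 0.5) else abs(tab - E)
  sum(adj^2 / E)
}

## Brute-force Fisher two-sided p: enumerate every table with the observed
## margins, compute each point probability from factorials, and sum the
## probabilities not exceeding the observed one.
fisherOracle <- function(tab) {
  tab <- round(as.matrix(tab))
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  N <- r1 + r2
  logP <- function(a) {
    b <- r1 - a; cc <- c1 - a; d <- r2 - cc
    lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
      lfactorial(N) - lfactorial(a) - lfactorial(b) - lfactorial(cc) -
      lfactorial(d)
  }
  as <- max(0, c1 - r2):min(c1, r1)
  lp <- vapply(as, logP, numeric(1))
  lObs <- logP(tab[1, 1])
  sum(exp(lp[lp <= lObs + 1e-7]))
}

## Random 2x2 tables with all margins positive.
randomTable <- function(maxCount = 500) {
  repeat {
    tab <- matrix(sample.int(maxCount + 1, 4, replace = TRUE) - 1L, 2)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) return(tab)
  }
}

## Euclidean distance matrix from random points (exactly embeddable).
randomEuclideanMatrix <- function(n, dim = 3) {
  pts <- matrix(runif(n * dim), n)
  m <- as.matrix(dist(pts))
  dimnames(m) <- list(paste0("P", 1:n), paste0("P", 1:n))
  m
}

## Random symmetric non-negative distance-like matrix with zero diagonal.
randomSymmetricMatrix <- function(n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.1, 10)
  m <- m + t(m)
  dimnames(m) <- list(paste0("L", 1:n), paste0("L", 1:n))
  m
}

## UPGMA cophenetic oracle via stats::hclust average linkage. hclust heights
## are the full between-cluster distances, so cophenetic() already returns
## the join distance for each leaf pair.
hclustCopheneticOracle <- function(m) {
  hc <- stats::hclust(stats::as.dist(m), method = "average")
  as.matrix(stats::cophenetic(hc))[rownames(m), rownames(m)]
}
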