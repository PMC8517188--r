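# Stability feature selection: zero-variance removal, repeated univariate
# F-screening on row subsamples, frequency shortlist, MRMR.

asFeatureMatrix <- function(table) {
  m <- as.matrix(table)
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) stop("feature table must have column names")
  if (anyDuplicated(colnames(m))) stop("feature names must be unique")
  if (anyNA(m)) stop("feature table contains missing values")
  m
}

#' Remove constant (zero-variance) features
#'
#' @param table feature table (rows = plans, named columns)
#' @return the table without constant columns; removed names in attribute
#'   \code{"dropped"}
#' @export
dropZeroVariance <- function(table) {
  m <- asFeatureMatrix(table)
  rng <- apply(m, 2, function(x) max(x) - min(x))
  dropped <- colnames(m)[rng == 0]
  if (length(dropped) == ncol(m)) stop("all features are constant")
  out <- table[, !(colnames(m) %in% dropped), drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

#' Univariate F statistics of every feature against a label
#'
#' Continuous labels use the simple-regression F statistic
#' \eqn{F = r^2 (n - 2) / (1 - r^2)}; binary labels (factor or two unique
#' values) use the one-way ANOVA F. Constant features score 0.
#'
#' @param table feature table
#' @param label numeric vector (continuous) or factor/binary vector
#' @return named numeric vector of F statistics
#' @export
univariateFScores <- function(table, label) {
  m <- asFeatureMatrix(table)
  n <- nrow(m)
  if (is.factor(label) || length(unique(label)) == 2L) {
    g <- as.factor(label)
    if (nlevels(droplevels(g)) < 2L) stop("label has a single class")
    g <- droplevels(g)
    k <- nlevels(g)
    ng <- tabulate(g)
    gm <- rowsum(m, g) / ng
    grand <- colMeans(m)
    ssb <- colSums(ng * (t(t(gm) - grand))^2)
    ssw <- colSums((m - gm[as.integer(g), , drop = FALSE])^2)
    f <- (ssb / (k - 1)) / (ssw / (n - k))
  } else {
    y <- as.numeric(label)
    if (stats::sd(y) == 0) stop("label has zero variance")
    r <- suppressWarnings(as.numeric(stats::cor(m, y)))
    r[is.na(r)] <- 0
    r2 <- pmin(r^2, 1 - 1e-15)
    f <- r2 * (n - 2) / (1 - r2)
  }
  f[!is.finite(f)] <- 0
  names(f) <- colnames(m)
  f
}

#' Stability shortlist by repeated subsampled F-screening
#'
#' Each iteration draws a row subsample (without replacement), removes
#' constant features on the subsample, scores the rest by univariate F and
#' keeps the top \code{keepPerIter}; the shortlist is the
#' \code{shortlistSize} most frequently kept features over all iterations
#' (ties broken by mean F, then name order). Only training-cohort rows and
#' labels should be passed in.
#'
#' @param table feature table (training cohort)
#' @param label training label (continuous or binary)
#' @param nIter number of iterations (default 100)
#' @param keepPerIter features kept per iteration (default 100)
#' @param shortlistSize shortlist length (default 30)
#' @param subsampleFrac row fraction per iteration (default 0.8)
#' @param seed integer seed
#' @return list with \code{frequency} (named counts over screened
#'   features), \code{meanF}, \code{shortlist}, \code{dropped}
#'   (constant on the full table), \code{nIter} and \code{seed}
#' @export
stabilityShortlist <- function(table, label, nIter = 100, keepPerIter = 100,
                               shortlistSize = 30, subsampleFrac = 0.8,
                               seed = 1) {
  stopifnot(nIter >= 1)
  full <- dropZeroVariance(table)
  droppedFull <- attr(full, "dropped")
  m <- asFeatureMatrix(full)
  n <- nrow(m)
  freq <- stats::setNames(numeric(ncol(m)), colnames(m))
  fSum <- freq; fCnt <- freq
  binary <- is.factor(label) || length(unique(label)) == 2L
  for (it in seq_len(nIter)) {
    set.seed(subSeed(seed, it))
    rows <- sample.int(n, max(2L, round(subsampleFrac * n)))
    if (binary) {                 # both classes must appear in the subsample
      tries <- 0L
      while (length(unique(label[rows])) < 2L && tries < 25L) {
        rows <- sample.int(n, max(2L, round(subsampleFrac * n)))
        tries <- tries + 1L
      }
    }
    sub <- m[rows, , drop = FALSE]
    rng <- apply(sub, 2, function(x) max(x) - min(x))
    keepCols <- rng > 0
    labSub <- label[rows]
    if (is.factor(labSub)) labSub <- droplevels(labSub)
    f <- univariateFScores(sub[, keepCols, drop = FALSE], labSub)
    fSum[names(f)] <- fSum[names(f)] + f
    fCnt[names(f)] <- fCnt[names(f)] + 1
    top <- names(sort(f, decreasing = TRUE))[seq_len(min(keepPerIter, length(f)))]
    freq[top] <- freq[top] + 1
  }
  meanF <- ifelse(fCnt > 0, fSum / pmax(fCnt, 1), 0)
  ord <- order(-freq, -meanF, names(freq))
  size <- min(shortlistSize, sum(freq > 0))
  if (size < shortlistSize)
    warning("fewer screened features (", size, ") than the requested shortlist")
  list(frequency = freq, meanF = meanF,
       shortlist = names(freq)[ord][seq_len(size)],
       dropped = droppedFull, nIter = nIter, seed = seed)
}

#' Greedy minimum-redundancy maximum-relevance selection
#'
#' Relevance is the univariate F statistic normalized by its maximum over
#' the shortlist; redundancy is the mean absolute Pearson correlation with
#' the already-selected features. The first pick maximizes relevance;
#' subsequent picks maximize relevance minus redundancy.
#'
#' @param table feature table (training cohort)
#' @param label training label
#' @param shortlist candidate feature names
#' @param k number of features to select (default 10)
#' @return character vector of k names in selection order
#' @export
mrmrSelect <- function(table, label, shortlist, k = 10) {
  if (k > length(shortlist))
    stop("k (", k, ") exceeds the shortlist size (", length(shortlist), ")")
  m <- asFeatureMatrix(table[, shortlist, drop = FALSE])
  f <- univariateFScores(m, label)
  rel <- if (max(f) > 0) f / max(f) else f
  cors <- abs(suppressWarnings(stats::cor(m)))
  cors[is.na(cors)] <- 0
  selected <- character(0)
  candidates <- shortlist
  for (step in seq_len(k)) {
    score <- rel[candidates]
    if (length(selected))
      score <- score - rowMeans(cors[candidates, selected, drop = FALSE])
    best <- candidates[order(-score, candidates)][1]
    selected <- c(selected, best)
    candidates <- setdiff(candidates, best)
  }
  selected
}

#' Full feature-selection pipeline
#'
#' Zero-variance removal, stability shortlist of 30 by repeated F
#' screening, then MRMR down to k features. Deterministic given the seed.
#'
#' @inheritParams stabilityShortlist
#' @param k final number of features (default 10)
#' @return a selection report: list with \code{selected} (k names in MRMR
#'   order), \code{shortlist}, \code{frequency}, \code{meanF},
#'   \code{dropped}, \code{nIter}, \code{k}, \code{seed}
#' @export
selectFeatures <- function(table, label, k = 10, nIter = 100,
                           keepPerIter = 100, shortlistSize = 30,
                           subsampleFrac = 0.8, seed = 1) {
  rep <- stabilityShortlist(table, label, nIter = nIter,
                            keepPerIter = keepPerIter,
                            shortlistSize = shortlistSize,
                            subsampleFrac = subsampleFrac, seed = seed)
  rep$selected <- mrmrSelect(table, label, rep$shortlist,
                             k = min(k, length(rep$shortlist)))
  rep$k <- k
  class(rep) <- "SelectionReport"
  rep
}

#' @export
print.SelectionReport <- function(x, ...) {
  cat("SelectionReport:", length(x$selected), "features from a shortlist of",
      length(x$shortlist), "(", x$nIter, "iterations, seed", x$seed, ")\n")
  cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
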