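#' Simple-matching similarity between lines
#'
#' For each pair of lines, the fraction of agreeing calls over the loci at
#' which both lines are scored (pairwise-complete denominator). Pairs with
#' no shared non-missing locus get `NA`.
#'
#' @param dataset an `aligned_dataset` or [genotype_matrix()].
#' @return Symmetric lines x lines matrix with unit diagonal and attribute
#'   `kind = "simple_matching"`.
#' @export
simple_matching <- function(dataset) {
  X <- calls_of(dataset)
  if (nrow(X) < 2) stop("need >= 2 lines")
  W <- !is.na(X)
  M <- X; M[!W] <- 0L
  storage.mode(M) <- "double"; storage.mode(W) <- "double"
  n <- tcrossprod(W)                       # shared non-missing loci
  both1 <- tcrossprod(M)                   # loci where both are 1
  both0 <- tcrossprod(W - M)               # loci where both are 0
  S <- (both1 + both0) / n
  S[n == 0] <- NA_real_
  diag(S) <- ifelse(rowSums(W) > 0, 1, NA_real_)
  dimnames(S) <- list(rownames(X), rownames(X))
  attr(S, "kind") <- "simple_matching"
  S
}

#' Modified Rogers' distance between lines
#'
#' For homozygous lines scored at biallelic loci the modified Rogers'
#' distance reduces to `sqrt(H/m)` where `H` is the number of disagreeing
#' loci and `m` the number of pairwise-complete loci; equivalently
#' `MRD^2 = 1 - simple matching`. Values lie in `[0, 1]`.
#'
#' @param dataset an `aligned_dataset` or [genotype_matrix()].
#' @return Symmetric distance matrix, zero diagonal, attribute
#'   `kind = "MRD"`. Pairs without shared loci are `NA` (with a warning).
#' @export
modified_rogers <- function(dataset) {
  S <- simple_matching(dataset)
  D <- matrix(sqrt(pmax(0, 1 - S)), nrow(S), ncol(S),
              dimnames = dimnames(S))
  diag(D) <- 0
  if (anyNA(D[upper.tri(D)]))
    warning("line pair(s) with no shared non-missing loci: NA distance")
  attr(D, "kind") <- "MRD"
  D
}

calls_of <- function(dataset) {
  if (inherits(dataset, "aligned_dataset") ||
      inherits(dataset, "genotype_matrix")) return(dataset$calls)
  as.matrix(dataset)
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centres `-D^2/2`, eigendecomposes, and returns the leading axes.
#' Percent variance is taken over the sum of positive eigenvalues (Gower's
#' convention); negative eigenvalues, possible for non-Euclidean distances
#' under pairwise deletion, are reported separately. Each axis is oriented
#' so that its largest-magnitude coordinate is positive, for reproducible
#' output.
#'
#' @param dist complete symmetric distance matrix (e.g. [modified_rogers()]).
#' @param n_axes maximum number of axes to return.
#' @return List of class `pcoa_result`: `coordinates` (lines x axes, column
#'   j scaled so its sum of squares equals eigenvalue j), `eigenvalues`
#'   (positive, descending), `pct_variance`, `negative_eigenvalues`.
#' @export
pcoa <- function(dist, n_axes = 10) {
  D <- as.matrix(dist)
  if (anyNA(D))
    stop("distance matrix has missing entries; impute or switch the ",
         "missing-data policy to pairwise deletion upstream")
  n <- nrow(D)
  B <- -0.5 * D^2
  B <- sweep(B, 1, rowMeans(B))
  B <- sweep(B, 2, colMeans(B))
  B <- B + mean(-0.5 * D^2) - mean(B)      # guard tiny asymmetry
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-12 & e$values > 0
  lam <- e$values[pos]
  k <- min(n_axes, length(lam))
  V <- e$vectors[, which(pos)[seq_len(k)], drop = FALSE]
  coords <- sweep(V, 2, sqrt(lam[seq_len(k)]), `*`)
  for (j in seq_len(k)) {                  # deterministic sign
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PCo", seq_len(k))
  structure(list(coordinates = coords,
                 eigenvalues = lam[seq_len(k)],
                 pct_variance = 100 * lam[seq_len(k)] / sum(lam),
                 negative_eigenvalues = e$values[e$values < 0]),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("pcoa_result: %d lines, %d axes\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  cat("pct variance:",
      paste(sprintf("%.1f", utils::head(x$pct_variance, 5)), collapse = " "),
      if (length(x$pct_variance) > 5) "..." else "", "\n")
  invisible(x)
}

#' Kernel density summary of principal coordinates
#'
#' Gaussian-kernel density (Silverman's rule bandwidth by default) of each
#' axis, as drawn in violin plots of population structure. A bimodality
#' flag is set when the density shows more than one mode above a small
#' relative prominence, the signature of subpopulation structure on an axis.
#'
#' @param result a [pcoa()] result.
#' @param n_axes number of leading axes to summarise.
#' @param bw bandwidth specification passed to [stats::density()].
#' @param min_mode_height modes below this fraction of the global maximum
#'   are ignored when counting.
#' @return List with one element per axis: `grid` (data frame `x`,
#'   `density`), `bimodal`, `degenerate`, `bw`.
#' @export
axis_density_summary <- function(result, n_axes = 10, bw = "nrd0",
                                 min_mode_height = 0.05) {
  stopifnot(inherits(result, "pcoa_result"))
  n_axes <- min(n_axes, ncol(result$coordinates))
  out <- vector("list", n_axes)
  names(out) <- colnames(result$coordinates)[seq_len(n_axes)]
  for (j in seq_len(n_axes)) {
    x <- result$coordinates[, j]
    if (stats::sd(x) < 1e-12) {
      out[[j]] <- list(grid = data.frame(x = mean(x), density = NA_real_),
                       bimodal = FALSE, degenerate = TRUE, bw = NA_real_)
      next
    }
    d <- stats::density(x, bw = bw)
    y <- d$y
    peaks <- which(diff(sign(diff(y))) == -2) + 1
    peaks <- peaks[y[peaks] >= min_mode_height * max(y)]
    out[[j]] <- list(grid = data.frame(x = d$x, density = y),
                     bimodal = length(peaks) >= 2,
                     degenerate = FALSE, bw = d$bw)
  }
  out
}

#' Within-group relatedness from a similarity matrix
#'
#' Means (and the pair values, for histogramming) of the off-diagonal
#' simple-matching similarities within each group, plus the all-lines
#' summary. Groups with fewer than two lines are skipped with a warning.
#'
#' @param sim similarity matrix from [simple_matching()].
#' @param groups per-line group label (e.g. growth habit), matched to the
#'   matrix by names when named.
#' @return List: `means` (data frame `group`, `n_lines`, `n_pairs`,
#'   `mean_similarity`) and `pairs` (named list of pair-value vectors).
#' @export
group_similarity_summary <- function(sim, groups) {
  S <- as.matrix(sim)
  ids <- rownames(S)
  if (!is.null(names(groups))) groups <- groups[ids]
  groups <- as.character(groups)
  lv <- unique(groups[!is.na(groups)])
  take <- function(idx) {
    s <- S[idx, idx, drop = FALSE]
    s[upper.tri(s)]
  }
  pairs <- list(all = take(seq_along(ids)))
  rows <- data.frame(group = "all", n_lines = length(ids),
                     n_pairs = length(pairs$all),
                     mean_similarity = mean(pairs$all, na.rm = TRUE))
  for (g in lv) {
    idx <- which(groups == g)
    if (length(idx) < 2) {
      warning("group '", g, "' has < 2 lines: skipped")
      next
    }
    v <- take(idx)
    pairs[[g]] <- v
    rows <- rbind(rows, data.frame(group = g, n_lines = length(idx),
                                   n_pairs = length(v),
                                   mean_similarity = mean(v, na.rm = TRUE)))
  }
  list(means = rows, pairs = pairs)
}
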