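#' Squared allele-frequency correlation between two markers
#'
#' `r^2 = D^2 / (pA qA pB qB)` with `D = pAB - pA pB`, computed over the
#' lines with both calls non-missing. Inbred lines carry one allele per
#' locus, so the 0/1 calls are used directly as haplotypes and `r^2` equals
#' the squared Pearson correlation of the two binary vectors.
#'
#' @param x,y binary call vectors of equal length (NA allowed).
#' @param min_lines minimum pairwise-complete lines (default 2).
#' @return `r^2` in `[0, 1]`, or `NA` when either marker is monomorphic on
#'   the shared lines or too few lines remain.
#' @export
pairwise_r2 <- function(x, y, min_lines = 2) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < min_lines) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  px <- mean(x); py <- mean(y)
  if (px %in% c(0, 1) || py %in% c(0, 1)) return(NA_real_)
  D <- mean(x * y) - px * py
  D^2 / (px * (1 - px) * py * (1 - py))
}

#' All pairwise r-squared values of a marker panel
#'
#' Vectorised over pairwise-complete lines via cross-products; identical to
#' applying [pairwise_r2()] to every column pair.
#'
#' @param dataset an `aligned_dataset`, [genotype_matrix()] or binary
#'   matrix (lines x markers).
#' @param min_lines minimum pairwise-complete lines per pair.
#' @return Symmetric markers x markers matrix of `r^2` (NA where undefined).
#' @export
r2_matrix <- function(dataset, min_lines = 2) {
  X <- calls_of(dataset)
  W <- !is.na(X); M <- X; M[!W] <- 0L
  storage.mode(M) <- "double"; storage.mode(W) <- "double"
  n <- crossprod(W)
  Sx <- crossprod(M, W)          # sum of x over lines shared with y
  Sxy <- crossprod(M)
  num <- (n * Sxy - Sx * t(Sx))^2
  den <- (n * Sx - Sx^2) * (n * t(Sx) - t(Sx)^2)
  R2 <- num / den
  R2[den <= 0 | n < min_lines] <- NA_real_
  dimnames(R2) <- list(colnames(X), colnames(X))
  R2
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Hypergeometric enumeration: the p-value sums the probabilities of all
#' tables with the observed margins that are no more probable than the
#' observed one. Degenerate tables (a zero margin) return p = 1.
#'
#' @param a,b,c,d cell counts (vectorised), rows = marker 1 absent/present,
#'   columns = marker 2.
#' @return Numeric vector of p-values.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  key <- paste(a, b, c, d)
  u <- !duplicated(key)
  pu <- mapply(function(a, b, c, d) {
    m1 <- a + b; m2 <- c + d; k <- a + c
    if (m1 == 0 || m2 == 0 || k == 0 || k == m1 + m2) return(1)
    lo <- max(0L, k - m2); hi <- min(k, m1)
    pr <- stats::dhyper(lo:hi, m1, m2, k)
    pobs <- stats::dhyper(a, m1, m2, k)
    min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
  }, a[u], b[u], c[u], d[u])
  unname(pu[match(key, key[u])])
}

#' Fisher's exact test of association between two markers
#'
#' @param x,y binary call vectors; lines with a missing call in either are
#'   dropped.
#' @return Two-sided exact p-value from the 2x2 table of joint call counts.
#' @export
fisher_exact <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  fisher_exact_p(sum(x == 0 & y == 0), sum(x == 0 & y == 1),
                 sum(x == 1 & y == 0), sum(x == 1 & y == 1))
}

#' Partition marker pairs into linked and unlinked
#'
#' Linked = same linkage group (with map distance `|pos_i - pos_j|`,
#' co-located markers included at distance 0); unlinked = different linkage
#' groups. Split groups (2R-1 / 2R-2) count as different linkage groups.
#'
#' @param map data frame with `marker`, `chrom`, `pos_cm` (map order), e.g.
#'   the `map` of an `aligned_dataset`.
#' @return List: `linked` (data frame `i`, `j`, `marker_i`, `marker_j`,
#'   `chrom`, `dist_cm`), `n_unlinked`, `n_linked`, `n_pairs`.
#' @export
partition_pairs <- function(map) {
  if (inherits(map, "aligned_dataset")) map <- map$map
  m <- nrow(map)
  linked <- NULL
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    if (length(idx) < 2) next
    cmb <- utils::combn(idx, 2)
    linked <- rbind(linked, data.frame(
      i = cmb[1, ], j = cmb[2, ],
      marker_i = map$marker[cmb[1, ]], marker_j = map$marker[cmb[2, ]],
      chrom = ch,
      dist_cm = abs(map$pos_cm[cmb[1, ]] - map$pos_cm[cmb[2, ]])))
  }
  n_linked <- if (is.null(linked)) 0L else nrow(linked)
  n_pairs <- as.integer(m * (m - 1) / 2)
  list(linked = linked, n_linked = n_linked,
       n_unlinked = n_pairs - n_linked, n_pairs = n_pairs)
}

#' Population-specific LD significance threshold
#'
#' The `level` empirical quantile (type 7, linear interpolation) of the
#' `r^2` values of unlinked marker pairs: LD above it is unlikely to arise
#' without genetic linkage in this population.
#'
#' @param r2 vector of unlinked-pair `r^2` values (NA dropped).
#' @param level quantile level (default 0.95).
#' @param min_n minimum number of values required.
#' @return The threshold, a number in `[0, 1]`.
#' @export
ld_threshold <- function(r2, level = 0.95, min_n = 20) {
  r2 <- r2[!is.na(r2)]
  if (length(r2) < min_n)
    stop("need >= ", min_n, " unlinked r^2 values, got ", length(r2))
  unname(stats::quantile(r2, level, type = 7))
}

#' Fit an LD decay curve by local regression
#'
#' Locally weighted linear regression (tricube weights, degree 1) of `r^2`
#' against map distance, evaluated on a grid from 0 to the maximum observed
#' distance; fitted values are clipped to `[0, 1]`.
#'
#' @param dist_cm,r2 linked-pair distances and `r^2` values (NA pairs
#'   dropped).
#' @param span loess span (fraction of pairs in each local neighbourhood).
#' @param grid_n evaluation grid size.
#' @return List of class `decay_curve`: `grid_cm`, `fit`, `span`, `n_pairs`,
#'   `min_dist_cm`.
#' @export
fit_decay <- function(dist_cm, r2, span = 0.33, grid_n = 200) {
  ok <- !is.na(dist_cm) & !is.na(r2)
  dist_cm <- dist_cm[ok]; r2 <- r2[ok]
  if (length(r2) < 10) stop("need >= 10 linked pairs with defined r^2")
  if (diff(range(dist_cm)) <= 0) stop("linked pairs must span > 0 cM")
  surface <- if (length(r2) <= 1000) "direct" else "interpolate"
  fit <- tryCatch(
    stats::loess(r2 ~ dist_cm, span = span, degree = 1, family = "gaussian",
                 surface = surface),
    error = function(e)
      stop("loess failed (span = ", span, "): ", conditionMessage(e),
           "; try a larger span", call. = FALSE))
  grid <- seq(0, max(dist_cm), length.out = grid_n)
  pred <- stats::predict(fit, data.frame(dist_cm = grid))
  # outside the observed distance range loess extrapolation is undefined
  # under surface="interpolate": carry the nearest fitted value
  if (anyNA(pred)) {
    inb <- which(!is.na(pred))
    pred[seq_len(min(inb) - 1)] <- pred[min(inb)]
    if (max(inb) < length(pred)) pred[(max(inb) + 1):length(pred)] <- pred[max(inb)]
  }
  structure(list(grid_cm = grid, fit = pmin(1, pmax(0, pred)), span = span,
                 n_pairs = length(r2), min_dist_cm = min(dist_cm)),
            class = "decay_curve")
}

#' Extent of LD: first crossing of the decay curve with a threshold
#'
#' The smallest grid distance at which the fitted curve falls below the
#' threshold, linearly interpolated between the bracketing grid points.
#' A curve starting below the threshold has extent 0; one that never drops
#' below it is censored at the maximum grid distance.
#'
#' @param curve a [fit_decay()] result.
#' @param threshold the population-specific threshold from [ld_threshold()].
#' @return List: `extent_cm`, `censored`.
#' @export
ld_extent <- function(curve, threshold) {
  stopifnot(inherits(curve, "decay_curve"))
  g <- curve$grid_cm; f <- curve$fit
  below <- which(f < threshold)
  if (!length(below))
    return(list(extent_cm = max(g), censored = TRUE))
  i <- below[1]
  if (i == 1) return(list(extent_cm = 0, censored = FALSE))
  x <- g[i - 1] + (g[i] - g[i - 1]) * (f[i - 1] - threshold) /
    (f[i - 1] - f[i])
  list(extent_cm = unname(x), censored = FALSE)
}

#' LD between map-adjacent markers
#'
#' `r^2` of each marker with its successor in map order within each linkage
#' group, located at the pair midpoint — the marker-density-conditional
#' view of LD used for along-chromosome profiles.
#'
#' @param dataset an `aligned_dataset`.
#' @param r2m optional precomputed [r2_matrix()] (reuse at scale).
#' @return List: `mean_r2` (NA pairs excluded) and `pairs` (data frame
#'   `chrom`, `mid_cm`, `dist_cm`, `r2`).
#' @export
adjacent_ld <- function(dataset, r2m = NULL) {
  stopifnot(inherits(dataset, "aligned_dataset"))
  map <- dataset$map
  rows <- NULL
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    if (length(idx) < 2) next
    i <- idx[-length(idx)]; j <- idx[-1]
    r2 <- if (is.null(r2m)) {
      mapply(function(a, b) pairwise_r2(dataset$calls[, a], dataset$calls[, b]),
             i, j)
    } else r2m[cbind(i, j)]
    rows <- rbind(rows, data.frame(
      chrom = ch, mid_cm = (map$pos_cm[i] + map$pos_cm[j]) / 2,
      dist_cm = map$pos_cm[j] - map$pos_cm[i], r2 = r2))
  }
  if (is.null(rows)) stop("no linkage group with >= 2 markers")
  list(mean_r2 = mean(rows$r2, na.rm = TRUE), pairs = rows)
}

#' Sliding-window profile of adjacent-marker LD along chromosomes
#'
#' Each adjacent pair contributes its `r^2` at the pair midpoint; the
#' profile is the windowed median on the standard grid.
#'
#' @param dataset an `aligned_dataset`.
#' @param window_cm,n_positions sliding-window settings.
#' @param r2m optional precomputed [r2_matrix()].
#' @return Data frame `chrom`, `grid_cm`, `n_markers` (pairs in window),
#'   `value` (median `r^2`).
#' @export
ld_window_profile <- function(dataset, window_cm = 5, n_positions = 500,
                              r2m = NULL) {
  adj <- adjacent_ld(dataset, r2m = r2m)
  pmap <- data.frame(chrom = adj$pairs$chrom, pos_cm = adj$pairs$mid_cm)
  windowed_profile(pmap, adj$pairs$r2, window_cm, n_positions, "median")
}

#' Full LD characterisation of a marker panel
#'
#' Runs the whole LD stage for one set of lines: pairwise `r^2`, the
#' linked/unlinked partition, the population-specific threshold from
#' unlinked pairs, per-genome (and pooled) decay curves with extents and
#' close-range LD, adjacent-marker LD, and the along-chromosome profile.
#' Fisher's exact p-values are attached to linked pairs (`fisher =
#' "linked"`, the default), to none, or to every pair.
#'
#' @param dataset an `aligned_dataset`.
#' @param span loess span (reported alongside every extent).
#' @param level threshold quantile level.
#' @param window_cm,n_positions sliding-window settings for the profile.
#' @param genomes genome groupings for decay curves; `"ABR"` pools all
#'   linked pairs.
#' @param grid_n decay-curve grid size.
#' @param fisher `"linked"`, `"none"` or `"all"`.
#' @param min_lines minimum pairwise-complete lines per `r^2`.
#' @return List of class `ld_analysis`: `threshold`, `n_unlinked`,
#'   `n_linked`, `linked` (pair table with `r2` and optionally `fisher_p`,
#'   `fisher_p_bonf`), `decay` (per genome: `curve`, `extent_cm`,
#'   `censored`, `close_r2` = curve at the smallest observed linked
#'   distance, `bin01_r2` = mean `r^2` of 0-1 cM pairs, `n_pairs`),
#'   `adjacent`, `profile`, `settings`.
#' @export
ld_analysis <- function(dataset, span = 0.33, level = 0.95, window_cm = 5,
                        n_positions = 500, genomes = c("A", "B", "R", "ABR"),
                        grid_n = 200, fisher = c("linked", "none", "all"),
                        min_lines = 2) {
  stopifnot(inherits(dataset, "aligned_dataset"))
  fisher <- match.arg(fisher)
  R2 <- r2_matrix(dataset, min_lines = min_lines)
  pp <- partition_pairs(dataset$map)
  if (pp$n_unlinked == 0)
    stop("all markers on one linkage group: no unlinked pairs, the ",
         "population-specific threshold cannot be estimated")
  grp <- dataset$map$chrom
  unl_mask <- outer(grp, grp, `!=`) & upper.tri(R2)
  r2_unl <- R2[unl_mask]
  thr <- ld_threshold(r2_unl, level = level)
  linked <- pp$linked
  linked$r2 <- R2[cbind(linked$i, linked$j)]
  if (fisher != "none") {
    ii <- linked$i; jj <- linked$j
    linked$fisher_p <- fisher_pairs(dataset$calls, ii, jj)
    linked$fisher_p_bonf <- pmin(1, linked$fisher_p * pp$n_pairs)
  }
  decay <- list()
  gmap <- dataset$map$genome[match(linked$chrom, dataset$map$chrom)]
  for (g in genomes) {
    sel <- if (g == "ABR") rep(TRUE, nrow(linked)) else gmap == g
    d <- linked$dist_cm[sel]; r <- linked$r2[sel]
    ok <- !is.na(r)
    if (sum(ok) < 10) {
      warning("genome '", g, "': fewer than 10 linked pairs, no decay curve")
      next
    }
    curve <- fit_decay(d[ok], r[ok], span = span, grid_n = grid_n)
    ext <- ld_extent(curve, thr)
    close_r2 <- stats::approx(curve$grid_cm, curve$fit,
                              xout = curve$min_dist_cm, rule = 2)$y
    b01 <- r[ok][d[ok] <= 1]
    decay[[g]] <- list(curve = curve, extent_cm = ext$extent_cm,
                       censored = ext$censored, close_r2 = close_r2,
                       bin01_r2 = if (length(b01)) mean(b01) else NA_real_,
                       n_pairs = sum(ok))
  }
  adj <- adjacent_ld(dataset, r2m = R2)
  prof <- ld_window_profile(dataset, window_cm, n_positions, r2m = R2)
  structure(list(threshold = thr, n_unlinked = pp$n_unlinked,
                 n_linked = pp$n_linked, n_r2_unlinked = sum(!is.na(r2_unl)),
                 linked = linked, decay = decay, adjacent = adj,
                 profile = prof,
                 settings = list(span = span, level = level,
                                 window_cm = window_cm,
                                 n_positions = n_positions,
                                 grid_n = grid_n, fisher = fisher)),
            class = "ld_analysis")
}

# Fisher p-values for an index-pair list, with caching over identical
# 2x2 tables (marker panels repeat tables heavily).
fisher_pairs <- function(X, ii, jj) {
  W <- !is.na(X); M <- X; M[!W] <- 0L
  storage.mode(M) <- "double"; storage.mode(W) <- "double"
  n11 <- crossprod(M)[cbind(ii, jj)]
  n1. <- crossprod(M, W)[cbind(ii, jj)]
  n.1 <- crossprod(W, M)[cbind(ii, jj)]
  nn <- crossprod(W)[cbind(ii, jj)]
  a <- nn - n1. - n.1 + n11   # both 0
  b <- n.1 - n11              # x=0, y=1
  c <- n1. - n11              # x=1, y=0
  fisher_exact_p(a, b, c, n11)
}

#' @export
print.ld_analysis <- function(x, ...) {
  cat(sprintf("ld_analysis: threshold (level %.2f) = %.4f over %d unlinked pairs\n",
              x$settings$level, x$threshold, x$n_unlinked))
  for (g in names(x$decay)) {
    d <- x$decay[[g]]
    cat(sprintf("  %s: close-range r2 %.3f, extent %.1f cM%s (span %.2f, %d pairs)\n",
                g, d$close_r2, d$extent_cm,
                if (d$censored) " [censored]" else "",
                x$settings$span, d$n_pairs))
  }
  cat(sprintf("  adjacent-marker mean r2: %.3f\n", x$adjacent$mean_r2))
  invisible(x)
}
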