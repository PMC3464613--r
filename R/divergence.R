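#' Per-locus genetic distance between two subpopulations
#'
#' Default metric: the single-locus modified Rogers' distance
#' `sqrt(((p1-p2)^2 + (q1-q2)^2) / 2)`, which for a biallelic locus equals
#' `|p1 - p2|`. An FST-like alternative `(p1-p2)^2 / (2 p_bar q_bar)` is
#' available (capped at 1; 0 when the pooled locus is monomorphic).
#'
#' @param p1,p2 allele frequencies in the two groups (vectorised);
#'   `NA` propagates.
#' @param metric `"mrd"` (default) or `"fst"`.
#' @return Divergence values in `[0, 1]`.
#' @export
locus_divergence <- function(p1, p2, metric = c("mrd", "fst")) {
  metric <- match.arg(metric)
  if (metric == "mrd") return(abs(p1 - p2))
  pb <- (p1 + p2) / 2
  den <- 2 * pb * (1 - pb)
  ifelse(den > 0, pmin(1, (p1 - p2)^2 / den), ifelse(is.na(den), NA_real_, 0))
}

#' Sliding-window divergence scan between two groups
#'
#' Computes group-wise allele frequencies, the per-locus divergence, and
#' its windowed mean along every linkage group — the scan used to flag
#' chromosomal regions under divergent selection between growth habits.
#'
#' @param dataset an `aligned_dataset`.
#' @param group_a,group_b group labels (matched against `groups`).
#' @param groups per-line labels; `NULL` uses the stored habit.
#' @param window_cm,n_positions sliding-window settings (defaults 5 cM /
#'   500 positions).
#' @param metric see [locus_divergence()].
#' @return List of class `divergence_scan`: `per_marker` (data frame with
#'   `marker`, `chrom`, `pos_cm`, `p1`, `p2`, `d`), `windowed`
#'   ([windowed_profile()] output), plus the settings.
#' @export
divergence_scan <- function(dataset, group_a = "winter", group_b = "spring",
                            groups = NULL, window_cm = 5, n_positions = 500,
                            metric = c("mrd", "fst")) {
  stopifnot(inherits(dataset, "aligned_dataset"))
  metric <- match.arg(metric)
  if (is.null(groups)) groups <- dataset$habit
  if (!is.null(names(groups))) groups <- groups[rownames(dataset$calls)]
  ia <- which(groups == group_a); ib <- which(groups == group_b)
  if (!length(ia)) stop("group '", group_a, "' is empty")
  if (!length(ib)) stop("group '", group_b, "' is empty")
  p1 <- suppressWarnings(allele_frequency(dataset$calls[ia, , drop = FALSE]))
  p2 <- suppressWarnings(allele_frequency(dataset$calls[ib, , drop = FALSE]))
  d <- locus_divergence(p1, p2, metric)
  per_marker <- data.frame(marker = dataset$map$marker,
                           chrom = dataset$map$chrom,
                           pos_cm = dataset$map$pos_cm,
                           p1 = unname(p1), p2 = unname(p2), d = unname(d))
  wnd <- windowed_profile(dataset$map, d, window_cm, n_positions, "mean")
  structure(list(per_marker = per_marker, windowed = wnd,
                 group_a = group_a, group_b = group_b,
                 window_cm = window_cm, n_positions = n_positions,
                 metric = metric),
            class = "divergence_scan")
}

#' Permutation null cutoff for a divergence scan
#'
#' Permutes the two group labels over the pooled lines and recomputes the
#' windowed scan, recording the genome-wide maximum of each permuted scan.
#' The cutoff is the `level` quantile of those maxima (family-wise control:
#' under the null the observed scan exceeds it anywhere with probability
#' about `1 - level`). `null = "pointwise"` instead pools all permuted
#' windowed means.
#'
#' @param dataset,group_a,group_b,groups,window_cm,n_positions,metric as in
#'   [divergence_scan()].
#' @param n_perm number of label permutations.
#' @param level quantile of the null distribution.
#' @param null `"max"` (default) or `"pointwise"`.
#' @param seed optional integer seed for the permutations.
#' @return List: `cutoff`, `null_values`, `n_perm`, `level`, `null`.
#' @export
divergence_null_cutoff <- function(dataset, group_a = "winter",
                                   group_b = "spring", groups = NULL,
                                   window_cm = 5, n_positions = 500,
                                   metric = c("mrd", "fst"),
                                   n_perm = 200, level = 0.95,
                                   null = c("max", "pointwise"),
                                   seed = NULL) {
  stopifnot(inherits(dataset, "aligned_dataset"))
  metric <- match.arg(metric); null <- match.arg(null)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(groups)) groups <- dataset$habit
  if (!is.null(names(groups))) groups <- groups[rownames(dataset$calls)]
  pool <- which(groups %in% c(group_a, group_b))
  na <- sum(groups == group_a)
  if (na == 0 || na == length(pool)) stop("one of the groups is empty")
  X <- dataset$calls[pool, , drop = FALSE]
  W <- !is.na(X); M <- X; M[!W] <- 0L
  storage.mode(M) <- "double"; storage.mode(W) <- "double"
  wg <- window_grid(dataset$map, window_cm, n_positions)
  stat <- numeric(0)
  for (b in seq_len(n_perm)) {
    ia <- sample.int(nrow(X), na)
    sel <- rep(FALSE, nrow(X)); sel[ia] <- TRUE
    p1 <- colSums(M[sel, , drop = FALSE]) /
          pmax(1, colSums(W[sel, , drop = FALSE]))
    p2 <- colSums(M[!sel, , drop = FALSE]) /
          pmax(1, colSums(W[!sel, , drop = FALSE]))
    n1 <- colSums(W[sel, , drop = FALSE]); n2 <- colSums(W[!sel, , drop = FALSE])
    d <- locus_divergence(p1, p2, metric)
    d[n1 == 0 | n2 == 0] <- NA_real_
    obs <- as.numeric(!is.na(d)); d0 <- d; d0[is.na(d0)] <- 0
    num <- as.numeric(wg$A %*% d0); den <- as.numeric(wg$A %*% obs)
    w <- ifelse(den > 0, num / den, NA_real_)
    stat <- c(stat, if (null == "max") max(w, na.rm = TRUE) else w[!is.na(w)])
  }
  list(cutoff = unname(stats::quantile(stat, level, type = 7)),
       null_values = stat, n_perm = n_perm, level = level, null = null)
}

#' Flag contiguous regions above a divergence cutoff
#'
#' Maximal runs of grid points whose windowed mean is at or above the
#' cutoff; runs separated by a single below-cutoff grid point are merged.
#'
#' @param scan a [divergence_scan()] result (or its `windowed` data frame).
#' @param cutoff divergence threshold, e.g. from [divergence_null_cutoff()].
#' @return Data frame `chrom`, `start_cm`, `end_cm`, `peak` (empty if no
#'   grid point reaches the cutoff).
#' @export
flag_regions <- function(scan, cutoff) {
  wnd <- if (inherits(scan, "divergence_scan")) scan$windowed else scan
  out <- data.frame(chrom = character(), start_cm = numeric(),
                    end_cm = numeric(), peak = numeric())
  for (ch in unique(wnd$chrom)) {
    w <- wnd[wnd$chrom == ch, , drop = FALSE]
    above <- which(!is.na(w$value) & w$value >= cutoff)
    if (!length(above)) next
    gap <- which(diff(above) > 2)          # gap of >=2 grid points splits
    starts <- above[c(1, gap + 1)]
    ends <- above[c(gap, length(above))]
    for (r in seq_along(starts)) {
      seg <- w[starts[r]:ends[r], , drop = FALSE]
      out <- rbind(out, data.frame(chrom = ch,
                                   start_cm = min(seg$grid_cm),
                                   end_cm = max(seg$grid_cm),
                                   peak = max(seg$value, na.rm = TRUE)))
    }
  }
  out
}
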