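#' Allele frequency of dominant markers
#'
#' The frequency of the presence allele per marker: the mean of non-missing
#' binary calls. All-missing markers get `NA` with a warning.
#'
#' @param calls binary matrix (lines x markers), a single marker vector, or
#'   an `aligned_dataset`/[genotype_matrix()].
#' @return Numeric vector of frequencies in `[0, 1]` (named by marker).
#' @export
allele_frequency <- function(calls) {
  if (inherits(calls, "aligned_dataset") || inherits(calls, "genotype_matrix"))
    calls <- calls$calls
  if (is.null(dim(calls))) calls <- matrix(calls, ncol = 1)
  p <- colMeans(calls, na.rm = TRUE)
  nn <- colSums(!is.na(calls))
  if (any(nn == 0)) {
    warning(sum(nn == 0), " marker(s) with no non-missing call: NA frequency")
    p[nn == 0] <- NA_real_
  }
  p
}

#' Polymorphic information content of a biallelic locus
#'
#' `PIC = 1 - (p^2 + q^2)` with `q = 1 - p`: 0 at fixation, maximal 0.5 at
#' equal allele frequencies.
#'
#' @param p allele frequency (vectorised); `NA` propagates.
#' @return PIC values in `[0, 0.5]`.
#' @export
pic <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("allele frequency outside [0, 1]")
  1 - (p^2 + (1 - p)^2)
}

#' Mean PIC by group and linkage group
#'
#' The per-chromosome diversity table: mean PIC for every (group x linkage
#' group) cell, with per-genome and overall means. Group rows recompute
#' allele frequencies within the group's own lines — a marker fixed in one
#' subpopulation but segregating overall scores 0 there. Markers
#' monomorphic within the evaluated line set are excluded from means by
#' default (they would deflate them); `include_monomorphic = TRUE` keeps
#' them at PIC 0.
#'
#' @param dataset an `aligned_dataset`.
#' @param groups per-line labels; `NULL` uses the stored habit. Groups with
#'   no lines are skipped with a warning. The `"all"` row always uses every
#'   line.
#' @param include_monomorphic keep PIC-0 markers in the means.
#' @return List: `by_chrom` (data frame `group`, `chrom`, `genome`,
#'   `n_markers`, `mean_pic`), `by_genome`, `overall` (data frame `group`,
#'   `mean_pic`), `per_marker` (frequencies and PIC per group).
#' @export
pic_summary <- function(dataset, groups = NULL, include_monomorphic = FALSE) {
  stopifnot(inherits(dataset, "aligned_dataset"))
  if (is.null(groups)) groups <- dataset$habit
  if (!is.null(names(groups))) groups <- groups[rownames(dataset$calls)]
  groups <- as.character(groups)
  sets <- c(list(all = seq_len(nrow(dataset$calls))),
            split(seq_along(groups), groups))
  sets <- sets[!duplicated(names(sets))]
  map <- dataset$map
  per_marker <- data.frame(marker = map$marker, chrom = map$chrom,
                           genome = map$genome, pos_cm = map$pos_cm)
  by_chrom <- by_genome <- overall <- NULL
  for (g in names(sets)) {
    idx <- sets[[g]]
    if (!length(idx)) { warning("group '", g, "' empty: skipped"); next }
    p <- suppressWarnings(allele_frequency(dataset$calls[idx, , drop = FALSE]))
    v <- pic(p)
    per_marker[[paste0("p_", g)]] <- p
    per_marker[[paste0("pic_", g)]] <- v
    use <- if (include_monomorphic) !is.na(v) else !is.na(v) & v > 0
    agg <- function(f) {
      k <- tapply(use, f, sum)
      m <- tapply(ifelse(use, v, NA_real_), f, mean, na.rm = TRUE)
      data.frame(group = g, key = names(m), n_markers = as.integer(k),
                 mean_pic = ifelse(k > 0, as.numeric(m), NA_real_))
    }
    bc <- agg(map$chrom)
    names(bc)[2] <- "chrom"
    bc$genome <- map$genome[match(bc$chrom, map$chrom)]
    by_chrom <- rbind(by_chrom, bc[, c("group", "chrom", "genome",
                                       "n_markers", "mean_pic")])
    bg <- agg(map$genome); names(bg)[2] <- "genome"
    by_genome <- rbind(by_genome, bg)
    overall <- rbind(overall,
                     data.frame(group = g, n_markers = sum(use),
                                mean_pic = mean(v[use])))
  }
  list(by_chrom = by_chrom, by_genome = by_genome, overall = overall,
       per_marker = per_marker)
}

# Precompute the sliding-window grid: n_positions equally spaced points per
# linkage group spanning [min, max] marker position; each grid point covers
# markers within +/- window_cm/2.  Returns the grid and per-point marker
# index lists (and a row-stochastic sparse matrix for fast means).
window_grid <- function(map, window_cm = 5, n_positions = 500) {
  chroms <- unique(map$chrom)
  half <- window_cm / 2
  grids <- lapply(chroms, function(ch) {
    pos <- map$pos_cm[map$chrom == ch]
    data.frame(chrom = ch,
               grid_cm = seq(min(pos), max(pos), length.out = n_positions))
  })
  grid <- do.call(rbind, grids)
  idx <- vector("list", nrow(grid))
  ii <- jj <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    sel <- which(map$chrom == grid$chrom[k] &
                 abs(map$pos_cm - grid$grid_cm[k]) <= half)
    idx[[k]] <- sel
    ii[[k]] <- rep.int(k, length(sel))
    jj[[k]] <- sel
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = 1,
                            dims = c(nrow(grid), nrow(map)))
  list(grid = grid, idx = idx, A = A)
}

#' Sliding-window statistic along chromosomes
#'
#' Evaluates a windowed mean or median of per-marker values on a grid of
#' `n_positions` equally spaced points per linkage group (spanning the
#' observed marker positions). A window of total width `window_cm` centred
#' at each grid point collects the markers with `|pos - grid| <= window/2`;
#' empty windows yield `NA`.
#'
#' @param map data frame with columns `chrom`, `pos_cm` (one row per value),
#'   e.g. the `map` of an `aligned_dataset`.
#' @param values per-marker numeric values aligned with `map` rows.
#' @param window_cm total window width in cM.
#' @param n_positions grid points per linkage group.
#' @param statistic `"mean"` or `"median"` (missing values excluded).
#' @param wg optional precomputed [window_grid] (internal reuse).
#' @return Data frame `chrom`, `grid_cm`, `n_markers`, `value`.
#' @export
windowed_profile <- function(map, values, window_cm = 5, n_positions = 500,
                             statistic = c("mean", "median"), wg = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(length(values) == nrow(map))
  if (is.null(wg)) wg <- window_grid(map, window_cm, n_positions)
  nmark <- vapply(wg$idx, function(i) sum(!is.na(values[i])), integer(1))
  if (statistic == "mean") {
    v <- values; obs <- as.numeric(!is.na(v)); v[is.na(v)] <- 0
    num <- as.numeric(wg$A %*% v)
    den <- as.numeric(wg$A %*% obs)
    out <- ifelse(den > 0, num / den, NA_real_)
  } else {
    out <- vapply(wg$idx, function(i) {
      x <- values[i]; x <- x[!is.na(x)]
      if (length(x)) stats::median(x) else NA_real_
    }, numeric(1))
  }
  data.frame(chrom = wg$grid$chrom, grid_cm = wg$grid$grid_cm,
             n_markers = nmark, value = out)
}
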