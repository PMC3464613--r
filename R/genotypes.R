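#' Construct a genotype matrix of dominant marker calls
#'
#' Container for presence/absence marker scores of fully inbred lines.
#' Dominant markers (e.g. DArT) on homozygous lines admit no heterozygous
#' call, so every non-missing call is 0 or 1 and lines are treated as
#' haplotypes throughout the package.
#'
#' @param calls integer/numeric matrix, lines in rows and markers in
#'   columns, values in \{0, 1, NA\}; must carry unique row and column names.
#' @param habit optional per-line growth-habit label; one of
#'   `"winter"`, `"spring"`, `"facultative"`, `"unknown"`. Unnamed vectors
#'   are matched by position, named vectors by line id.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls` (integer matrix) and `habit` (character vector).
#' @export
genotype_matrix <- function(calls, habit = NULL) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("calls must have line ids as rownames and marker ids as colnames")
  dup_l <- unique(rownames(calls)[duplicated(rownames(calls))])
  if (length(dup_l))
    stop("duplicate line ids: ", paste(dup_l, collapse = ", "))
  dup_m <- unique(colnames(calls)[duplicated(colnames(calls))])
  if (length(dup_m))
    stop("duplicate marker ids: ", paste(dup_m, collapse = ", "))
  storage.mode(calls) <- "integer"
  bad <- which(!is.na(calls) & !(calls %in% c(0L, 1L)), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-binary call at line '%s', marker '%s'",
                 rownames(calls)[bad[1, 1]], colnames(calls)[bad[1, 2]]))
  habit <- normalize_habit(habit, rownames(calls))
  structure(list(calls = calls, habit = habit), class = "genotype_matrix")
}

habit_levels <- c("winter", "spring", "facultative", "unknown")

normalize_habit <- function(habit, line_ids) {
  n <- length(line_ids)
  if (is.null(habit)) return(stats::setNames(rep("unknown", n), line_ids))
  habit <- as.character(habit)
  if (!is.null(names(habit))) {
    miss <- setdiff(line_ids, names(habit))
    out <- stats::setNames(rep("unknown", n), line_ids)
    out[intersect(line_ids, names(habit))] <-
      habit[intersect(line_ids, names(habit))]
    habit <- out
    if (length(miss))
      warning(length(miss), " line(s) without habit label set to 'unknown'")
  } else {
    if (length(habit) != n)
      stop("habit length (", length(habit), ") != number of lines (", n, ")")
    names(habit) <- line_ids
  }
  habit <- tolower(trimws(habit))
  bad <- !(habit %in% habit_levels)
  if (any(bad)) {
    warning("unrecognised habit label(s) set to 'unknown': ",
            paste(unique(habit[bad]), collapse = ", "))
    habit[bad] <- "unknown"
  }
  habit
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d lines x %d markers, %.2f%% missing\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  tb <- table(factor(x$habit, levels = habit_levels))
  cat("habit:", paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Construct a genetic map
#'
#' @param marker character vector of unique marker ids.
#' @param chrom linkage-group name per marker (e.g. `"1A"`, `"5R"`; split
#'   groups such as `"2R-1"`/`"2R-2"` are distinct linkage groups).
#' @param pos_cm finite, non-negative map position in centimorgans.
#' @return A `genetic_map`: data frame with columns `marker`, `chrom`,
#'   `pos_cm`.
#' @export
genetic_map <- function(marker, chrom, pos_cm) {
  marker <- as.character(marker)
  chrom <- as.character(chrom)
  pos_cm <- as.numeric(pos_cm)
  if (length(chrom) == 1) chrom <- rep(chrom, length(marker))
  if (length(marker) != length(chrom) || length(marker) != length(pos_cm))
    stop("marker, chrom and pos_cm must have equal length")
  dup <- unique(marker[duplicated(marker)])
  if (length(dup))
    stop("duplicate marker ids in map: ", paste(dup, collapse = ", "))
  if (any(!nzchar(chrom) | is.na(chrom)))
    stop("empty linkage-group name")
  bad <- which(!is.finite(pos_cm) | pos_cm < 0)
  if (length(bad))
    stop("invalid map position for marker '", marker[bad[1]],
         "': positions must be finite and >= 0")
  structure(data.frame(marker = marker, chrom = chrom, pos_cm = pos_cm,
                       stringsAsFactors = FALSE),
            class = c("genetic_map", "data.frame"))
}

#' Genome label from a linkage-group name
#'
#' Strips a split-group suffix (`"2R-1"` -> `"2R"`) and takes the trailing
#' letter; labels outside A/B/R give `"unknown"` with a warning.
#'
#' @param chrom character vector of linkage-group names.
#' @return Character vector of `"A"`, `"B"`, `"R"` or `"unknown"`.
#' @export
genome_of <- function(chrom) {
  base <- sub("-[0-9]+$", "", as.character(chrom))
  g <- toupper(substring(base, nchar(base)))
  bad <- !(g %in% c("A", "B", "R"))
  if (any(bad)) {
    warning("unknown genome suffix for linkage group(s): ",
            paste(unique(chrom[bad]), collapse = ", "))
    g[bad] <- "unknown"
  }
  g
}

#' Align a genotype matrix with a genetic map
#'
#' Restricts the panel to mapped markers, orders markers by linkage group
#' and position (ties broken by marker id for reproducibility) and attaches
#' genome labels. The number of unmapped markers dropped is reported via
#' `message()`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param map a [genetic_map()].
#' @param drop_monomorphic if `TRUE`, markers monomorphic over all
#'   non-missing calls are removed; the default keeps them (downstream
#'   statistics exclude them per their own policies).
#' @return An `aligned_dataset`: list with `calls` (lines x markers matrix
#'   in map order), `map` (data frame `marker`, `chrom`, `pos_cm`, `genome`),
#'   and `habit`.
#' @export
align_markers <- function(genotypes, map, drop_monomorphic = FALSE) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(map, "genetic_map"))
  shared <- intersect(colnames(genotypes$calls), map$marker)
  if (!length(shared))
    stop("no marker shared between genotypes and map")
  n_drop <- ncol(genotypes$calls) - length(shared)
  if (n_drop > 0)
    message(n_drop, " genotyped marker(s) not in map: dropped")
  m <- map[match(shared, map$marker), , drop = FALSE]
  ord <- order(m$chrom, m$pos_cm, m$marker, method = "radix")
  m <- m[ord, , drop = FALSE]
  calls <- genotypes$calls[, m$marker, drop = FALSE]
  if (drop_monomorphic) {
    p <- colMeans(calls, na.rm = TRUE)
    keep <- !is.nan(p) & p > 0 & p < 1
    calls <- calls[, keep, drop = FALSE]
    m <- m[keep, , drop = FALSE]
    if (!ncol(calls)) stop("all shared markers are monomorphic")
  }
  m$genome <- suppressWarnings(genome_of(m$chrom))
  unk <- sum(m$genome == "unknown")
  if (unk) warning(unk, " marker(s) with unknown genome label")
  rownames(m) <- NULL
  structure(list(calls = calls, map = m, habit = genotypes$habit),
            class = "aligned_dataset")
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat(sprintf("aligned_dataset: %d lines x %d mapped markers, %d linkage groups\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$map$chrom))))
  tb <- table(x$map$genome)
  cat("genomes:", paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
  invisible(x)
}

#' Restrict an aligned dataset to a subset of lines
#'
#' @param dataset an `aligned_dataset`.
#' @param lines character vector of line ids or logical/integer index.
#' @return The restricted `aligned_dataset`.
#' @export
subset_lines <- function(dataset, lines) {
  stopifnot(inherits(dataset, "aligned_dataset"))
  calls <- dataset$calls[lines, , drop = FALSE]
  structure(list(calls = calls, map = dataset$map,
                 habit = dataset$habit[rownames(calls)]),
            class = "aligned_dataset")
}
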