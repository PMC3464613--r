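#' Read a genotype matrix from delimited text
#'
#' Expects a header row/column of ids. Orientation is configurable because
#' marker panels circulate both ways: `"lines"` (default) means lines in
#' rows and markers in columns; `"markers"` the transpose.
#'
#' @param path file path (TSV by default; `sep` configurable).
#' @param orientation `"lines"` or `"markers"`.
#' @param sep field separator; default tab, use `","` for CSV.
#' @param missing_tokens tokens parsed as missing calls.
#' @param habit optional path to a two-column delimited file (line id,
#'   habit label) or a named character vector of labels.
#' @param quiet suppress the summary message.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, orientation = c("lines", "markers"),
                           sep = "\t", missing_tokens = c("", "NA", "-"),
                           habit = NULL, quiet = FALSE) {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          na.strings = missing_tokens, check.names = FALSE,
                          colClasses = "character",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("genotype file needs an id column plus >=1 data column")
  ids <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  colnames(mat) <- colnames(df)[-1]   # data.frame subsetting de-dupes names
  rownames(mat) <- ids
  num <- suppressWarnings(matrix(as.numeric(mat), nrow(mat), ncol(mat),
                                 dimnames = dimnames(mat)))
  bad <- which(!is.na(mat) & (is.na(num) | !(num %in% c(0, 1))), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-binary call '%s' at row '%s', column '%s' in %s",
                 mat[bad[1, 1], bad[1, 2]], rownames(mat)[bad[1, 1]],
                 colnames(mat)[bad[1, 2]], path))
  if (orientation == "markers") num <- t(num)
  if (is.character(habit) && length(habit) == 1 && is.null(names(habit)) &&
      file.exists(habit))
    habit <- read_line_metadata(habit, sep = sep)
  gm <- genotype_matrix(num, habit = habit)
  if (!quiet)
    message(sprintf("read %d lines x %d markers (missing rate %.4f) from %s",
                    nrow(gm$calls), ncol(gm$calls),
                    mean(is.na(gm$calls)), path))
  gm
}

#' Read per-line growth-habit labels
#'
#' Two-column delimited file: line id, habit label (winter / spring /
#' facultative; anything else becomes "unknown" with a warning downstream).
#'
#' @param path file path.
#' @param sep field separator.
#' @return Named character vector of labels.
#' @export
read_line_metadata <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("line metadata needs columns: line, habit")
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Read a genetic map from delimited text
#'
#' Columns (header required): marker, chrom, pos_cM (names matched
#' case-insensitively by prefix; extra columns ignored).
#'
#' @param path file path.
#' @param sep field separator.
#' @return A [genetic_map()].
#' @export
read_genetic_map <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("map file needs columns: marker, chrom, pos_cM")
  pos <- suppressWarnings(as.numeric(df[[3]]))
  if (anyNA(pos) & !anyNA(df[[3]]))
    stop("non-numeric map position in ", path)
  genetic_map(df[[1]], df[[2]], pos)
}

#' Write a genotype matrix to delimited text
#'
#' Round-trips with [read_genotypes()], missing calls written as `NA`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output path.
#' @param sep field separator.
#' @export
write_genotypes <- function(genotypes, path, sep = "\t") {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  df <- data.frame(line = rownames(genotypes$calls),
                   genotypes$calls, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genetic map to delimited text
#' @param map a [genetic_map()].
#' @param path output path.
#' @param sep field separator.
#' @export
write_genetic_map <- function(map, path, sep = "\t") {
  stopifnot(inherits(map, "genetic_map"))
  df <- data.frame(marker = map$marker, chrom = map$chrom,
                   pos_cM = map$pos_cm)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-line habit labels
#' @param genotypes a [genotype_matrix()].
#' @param path output path.
#' @param sep field separator.
#' @export
write_line_metadata <- function(genotypes, path, sep = "\t") {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  df <- data.frame(line = names(genotypes$habit), habit = genotypes$habit)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
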