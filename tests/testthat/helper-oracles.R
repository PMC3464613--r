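# Independent brute-force oracles used to freeze expected values.
# They deliberately use explicit loops / enumeration, not the package's
# vectorised code paths.

# r^2 from the haplotype-frequency definition, counted with loops
oracle_r2 <- function(x, y) {
  n11 <- n1. <- n.1 <- n <- 0
  for (k in seq_along(x)) {
    if (is.na(x[k]) || is.na(y[k])) next
    n <- n + 1
    if (x[k] == 1) n1. <- n1. + 1
    if (y[k] == 1) n.1 <- n.1 + 1
    if (x[k] == 1 && y[k] == 1) n11 <- n11 + 1
  }
  if (n < 2) return(NA_real_)
  pA <- n1. / n; pB <- n.1 / n
  if (pA == 0 || pA == 1 || pB == 0 || pB == 1) return(NA_real_)
  D <- n11 / n - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# two-sided Fisher exact p by full enumeration of tables with the observed
# margins, probabilities from choose()
oracle_fisher <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; n <- m1 + m2
  if (m1 == 0 || m2 == 0 || k == 0 || k == n) return(1)
  xs <- max(0, k - m2):min(k, m1)
  pr <- choose(m1, xs) * choose(m2, k - xs) / choose(n, k)
  pobs <- choose(m1, a) * choose(m2, k - a) / choose(n, k)
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

# simple matching / MRD by loops over pairwise-complete loci
oracle_sm <- function(x, y) {
  agree <- tot <- 0
  for (k in seq_along(x)) {
    if (is.na(x[k]) || is.na(y[k])) next
    tot <- tot + 1
    if (x[k] == y[k]) agree <- agree + 1
  }
  if (tot == 0) NA_real_ else agree / tot
}

oracle_mrd <- function(x, y) {
  s <- oracle_sm(x, y)
  if (is.na(s)) NA_real_ else sqrt(1 - s)
}

# interval Jaccard of a planted region against the union of flagged
# intervals (a flagged scan may split across a marker-sparse dip)
region_jaccard <- function(start, end, flagged) {
  if (!nrow(flagged)) return(0)
  ov <- pmax(0, pmin(end, flagged$end_cm) - pmax(start, flagged$start_cm))
  inter <- sum(ov)
  outside <- sum((flagged$end_cm - flagged$start_cm)[ov > 0]) - inter
  inter / (end - start + outside)
}

random_panel <- function(n, m, p = NULL, miss = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(p)) p <- runif(m, 0.1, 0.9)
  X <- matrix(rbinom(n * m, 1, rep(p, each = n)), n, m)
  if (miss > 0) X[runif(n * m) < miss] <- NA
  dimnames(X) <- list(sprintf("l%02d", 1:n), sprintf("m%03d", 1:m))
  X
}

toy_aligned <- function(calls, chrom, pos_cm, habit = NULL) {
  gm <- genotype_matrix(calls, habit = habit)
  map <- genetic_map(colnames(calls), chrom, pos_cm)
  align_markers(gm, map)
}
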