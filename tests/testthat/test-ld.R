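test_that("pairwise r2 frozen examples", {
  expect_equal(pairwise_r2(c(0, 1, 0, 1, 1), c(0, 1, 0, 1, 1)), 1)
  expect_equal(pairwise_r2(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  # frozen from the D^2/(pq) oracle: D = 1/3 - 1/4 = 1/12, denom = 1/16
  x <- c(0, 0, 0, 1, 1, 1); y <- c(0, 0, 1, 1, 1, 0)
  expect_equal(oracle_r2(x, y), 1 / 9, tolerance = 1e-15)
  expect_equal(pairwise_r2(x, y), 1 / 9, tolerance = 1e-12)
  # monomorphic on shared lines -> NA
  expect_true(is.na(pairwise_r2(c(1, 1, 1, 0), c(0, 1, 0, NA))))
  expect_true(is.na(pairwise_r2(c(1, NA, NA), c(0, 1, 0))))
})

test_that("r2 equals the brute-force oracle on exhaustive 6-line inputs", {
  vecs <- as.matrix(expand.grid(rep(list(0:1), 6)))
  poly <- vecs[rowSums(vecs) %in% 1:5, ]   # polymorphic columns only
  set.seed(8)
  pick <- poly[sample(nrow(poly), 18), ]
  for (i in seq_len(nrow(pick)))
    for (j in seq_len(nrow(pick)))
      expect_equal(pairwise_r2(pick[i, ], pick[j, ]),
                   oracle_r2(pick[i, ], pick[j, ]), tolerance = 1e-12)
})

test_that("r2 is symmetric, coding-flip invariant, matrix path consistent", {
  X <- random_panel(15, 25, miss = 0.1, seed = 12)
  R2 <- r2_matrix(X)
  for (k in 1:40) {
    i <- sample(25, 1); j <- sample(25, 1)
    r <- pairwise_r2(X[, i], X[, j])
    expect_equal(R2[i, j], if (i == j && !is.na(r)) 1 else r,
                 tolerance = 1e-12)
    expect_equal(pairwise_r2(X[, j], X[, i]), r, tolerance = 1e-12)
    expect_equal(pairwise_r2(1 - X[, i], X[, j]), r, tolerance = 1e-12)
  }
})

test_that("fisher exact matches enumeration oracle and stats::fisher.test", {
  expect_equal(fisher_exact_p(2, 0, 0, 2), 1 / 3)
  expect_equal(fisher_exact_p(1, 1, 1, 1), 1)
  expect_equal(fisher_exact_p(0, 0, 3, 4), 1)   # degenerate margin
  set.seed(5)
  for (k in 1:60) {
    x <- rbinom(8, 1, 0.5); y <- rbinom(8, 1, 0.5)
    a <- sum(!x & !y); b <- sum(!x & y); c <- sum(x & !y); d <- sum(x & y)
    p <- fisher_exact(x, y)
    expect_equal(p, oracle_fisher(a, b, c, d), tolerance = 1e-12)
    tab <- matrix(c(a, c, b, d), 2)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("partition_pairs enumerates linked/unlinked correctly", {
  map <- genetic_map(paste0("m", 1:9),
                     rep(c("1A", "2B", "3R"), times = c(2, 3, 4)),
                     c(0, 5, 0, 2, 9, 0, 1, 1, 8))
  pp <- partition_pairs(map)
  expect_identical(pp$n_unlinked, 2L * 3L + 2L * 4L + 3L * 4L)
  expect_identical(pp$n_linked, 1L + 3L + 6L)
  expect_equal(sort(pp$linked$dist_cm[pp$linked$chrom == "2B"]), c(2, 7, 9))
  # co-located markers kept at distance 0
  expect_true(0 %in% pp$linked$dist_cm[pp$linked$chrom == "3R"])

  one <- genetic_map(paste0("m", 1:5), "1A", 0:4)
  expect_identical(partition_pairs(one)$n_unlinked, 0L)
})

test_that("ld_threshold is a type-7 quantile with guard rails", {
  expect_equal(ld_threshold(0.01 * (1:100)), 0.9505)
  expect_equal(ld_threshold(rep(0.2, 50)), 0.2)
  expect_error(ld_threshold(runif(5)), ">= 20")
  # adding values below the current threshold never increases it
  set.seed(2)
  v <- runif(200)
  t0 <- ld_threshold(v)
  for (k in 1:5) {
    v <- c(v, runif(40, max = t0 * 0.9))
    t1 <- ld_threshold(v)
    expect_lte(t1, t0 + 1e-12)
    t0 <- t1
  }
})

test_that("fit_decay reproduces constants and straight lines", {
  set.seed(6)
  d <- runif(60, 0, 30)
  cc <- fit_decay(d, rep(0.4, 60), span = 0.5)
  expect_equal(cc$fit, rep(0.4, length(cc$fit)), tolerance = 1e-9)

  r2 <- 0.8 - 0.02 * d
  cl <- fit_decay(d, r2, span = 0.5)
  inside <- cl$grid_cm >= min(d) & cl$grid_cm <= max(d)
  expect_equal(cl$fit[inside], 0.8 - 0.02 * cl$grid_cm[inside],
               tolerance = 1e-6)
  expect_true(all(cl$fit >= 0 & cl$fit <= 1))
  expect_error(fit_decay(d[1:12], r2[1:12], span = 0.01), "span")
  expect_error(fit_decay(rep(1, 20), runif(20)), "span > 0 cM")
})

test_that("ld_extent crossing, censoring and zero cases", {
  curve <- structure(list(grid_cm = c(10, 20), fit = c(0.3, 0.1),
                          span = 0.3, n_pairs = 2L, min_dist_cm = 10),
                     class = "decay_curve")
  e <- ld_extent(curve, 0.2)
  expect_equal(e$extent_cm, 15)
  expect_false(e$censored)

  curve$fit <- c(0.3, 0.3)
  e2 <- ld_extent(curve, 0.12)
  expect_true(e2$censored)
  expect_equal(e2$extent_cm, 20)

  curve$fit <- c(0.05, 0.04)
  expect_equal(ld_extent(curve, 0.12)$extent_cm, 0)
})

test_that("adjacent LD and window profile", {
  set.seed(14)
  X <- random_panel(300, 6)
  X <- cbind(X, m_dup = X[, 6])      # duplicated column adjacent to itself
  ds <- toy_aligned(X, rep("1A", 7), c(0, 2, 4, 6, 8, 10, 11))
  adj <- adjacent_ld(ds)
  expect_identical(nrow(adj$pairs), 6L)
  expect_equal(adj$pairs$r2[6], 1)   # the duplicated pair
  expect_equal(adj$pairs$mid_cm[1], 1)

  # two independent markers, n = 1000 lines: near-zero r2
  Y <- random_panel(1000, 2, p = c(0.5, 0.5), seed = 15)
  ds2 <- toy_aligned(Y, c("1A", "1A"), c(0, 50))
  expect_lt(adjacent_ld(ds2)$mean_r2, 0.01)

  # flat profile when all adjacent r2 are equal (single pair case)
  prof <- ld_window_profile(ds2, window_cm = 200, n_positions = 10)
  expect_equal(unique(round(prof$value, 12)),
               round(adjacent_ld(ds2)$mean_r2, 12))
})

test_that("ld_analysis end-to-end on a small simulated panel", {
  sim <- simulate_panel(sim_config(
    seed = 31, n_lines = c(30, 30),
    groups = data.frame(chrom = c("1A", "1R"), length_cm = 80,
                        n_markers = 60)))
  ds <- align_markers(sim$genotypes, sim$map)
  la <- suppressWarnings(ld_analysis(ds, n_positions = 40, grid_n = 80,
                                     genomes = c("A", "R", "ABR")))
  expect_identical(la$n_unlinked, 60L * 60L)
  expect_identical(la$n_linked, as.integer(2 * choose(60, 2)))
  expect_true(la$threshold > 0 && la$threshold < 1)
  # high-LD panel: curve near zero distance exceeds curve at max distance
  abr <- la$decay$ABR$curve
  expect_gt(abr$fit[1], abr$fit[length(abr$fit)])
  # fisher p attached to linked pairs, bonferroni capped at 1
  expect_true(all(la$linked$fisher_p >= 0 & la$linked$fisher_p <= 1))
  expect_true(all(la$linked$fisher_p_bonf <= 1))
  # strongly linked pairs are significant
  tight <- la$linked$r2 > 0.8 & !is.na(la$linked$r2)
  expect_true(median(la$linked$fisher_p[tight]) < 1e-4)

  one <- subset_lines(ds, 1:30)
  one$map <- one$map[one$map$chrom == "1A", ]
  one$calls <- one$calls[, one$map$marker]
  expect_error(ld_analysis(one), "unlinked")
})
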