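test_that("simple matching and MRD match hand counts", {
  calls <- rbind(l1 = c(0, 1, NA, 1), l2 = c(0, 0, 1, 1),
                 l3 = c(1, 0, 0, 0), l4 = c(0, 1, NA, 1))
  colnames(calls) <- paste0("m", 1:4)
  S <- simple_matching(genotype_matrix(calls))
  expect_equal(S["l1", "l2"], 2 / 3)      # agree at m1, m4 of 3 shared
  expect_equal(S["l1", "l4"], 1)          # identical lines
  expect_equal(S["l2", "l3"], 1 / 4)
  D <- modified_rogers(genotype_matrix(calls))
  expect_equal(D["l1", "l4"], 0)
  opp <- rbind(a = c(0, 0, 1, 1), b = c(1, 1, 0, 0))
  colnames(opp) <- paste0("m", 1:4)
  expect_equal(simple_matching(genotype_matrix(opp))["a", "b"], 0)
  expect_equal(modified_rogers(genotype_matrix(opp))["a", "b"], 1)
})

test_that("MRD^2 + simple matching = 1 and both match the loop oracle", {
  for (seed in 1:5) {
    X <- random_panel(8, 30, miss = ifelse(seed > 3, 0.2, 0), seed = seed)
    gm <- genotype_matrix(X)
    S <- simple_matching(gm)
    D <- suppressWarnings(modified_rogers(gm))
    expect_equal(D^2 + S, matrix(1, 8, 8, dimnames = dimnames(S)),
                 ignore_attr = TRUE, tolerance = 1e-12)
    for (i in 1:7) for (j in (i + 1):8) {
      expect_equal(S[i, j], oracle_sm(X[i, ], X[j, ]), tolerance = 1e-12)
      expect_equal(D[i, j], oracle_mrd(X[i, ], X[j, ]), tolerance = 1e-12)
    }
  }
})

test_that("pair with no shared loci gives NA with warning", {
  calls <- rbind(l1 = c(0, 1, NA, NA), l2 = c(NA, NA, 1, 0),
                 l3 = c(0, 1, 1, 0))
  colnames(calls) <- paste0("m", 1:4)
  S <- simple_matching(genotype_matrix(calls))
  expect_true(is.na(S["l1", "l2"]))
  expect_warning(modified_rogers(genotype_matrix(calls)), "no shared")
})

test_that("pcoa closed-form cases", {
  # three mutually equidistant points: two equal axes, 50/50 variance
  D3 <- matrix(1, 3, 3) - diag(3)
  dimnames(D3) <- list(letters[1:3], letters[1:3])
  p3 <- pcoa(D3)
  expect_equal(p3$eigenvalues[1], p3$eigenvalues[2], tolerance = 1e-10)
  expect_equal(p3$pct_variance, c(50, 50), tolerance = 1e-10)

  # two points at distance d: one axis, coordinates +/- d/2
  d <- 0.8
  D2 <- matrix(c(0, d, d, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  p2 <- pcoa(D2)
  expect_identical(ncol(p2$coordinates), 1L)
  expect_equal(sort(p2$coordinates[, 1]), c(-d / 2, d / 2),
               ignore_attr = TRUE, tolerance = 1e-12)

  # collinear Euclidean points: axis 1 carries 100% of the variance and
  # inter-point distances are recovered exactly
  x <- c(0, 1, 2.5, 7)
  Dl <- as.matrix(dist(x)); dimnames(Dl) <- list(1:4, 1:4)
  pl <- pcoa(Dl)
  expect_equal(pl$pct_variance[1], 100, tolerance = 1e-8)
  expect_equal(as.matrix(dist(pl$coordinates[, 1])), Dl,
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("pcoa agrees with classical scaling oracle on random panels", {
  X <- random_panel(12, 60, seed = 9)
  D <- modified_rogers(genotype_matrix(X))
  p <- pcoa(D, n_axes = 5)
  cs <- stats::cmdscale(D, k = 5, eig = TRUE)
  expect_equal(p$eigenvalues, cs$eig[1:5], tolerance = 1e-8)
  for (j in 1:5)  # equal up to axis sign
    expect_equal(abs(p$coordinates[, j]), abs(cs$points[, j]),
                 ignore_attr = TRUE, tolerance = 1e-8)
  expect_true(all(p$pct_variance >= 0))
  expect_lte(sum(p$pct_variance), 100 + 1e-9)
  # sign convention: largest-magnitude loading positive
  for (j in 1:5) expect_gt(p$coordinates[which.max(abs(p$coordinates[, j])), j], 0)
  expect_error(pcoa(matrix(c(0, NA, NA, 0), 2)), "missing")
})

test_that("axis density summaries integrate to 1 and flag bimodality", {
  set.seed(4)
  fake <- function(v) structure(list(coordinates = cbind(PCo1 = v)),
                                class = "pcoa_result")
  dens <- axis_density_summary(fake(rnorm(1000)), n_axes = 1)
  g <- dens[[1]]$grid
  area <- sum(diff(g$x) * (head(g$density, -1) + tail(g$density, -1)) / 2)
  expect_equal(area, 1, tolerance = 0.01)
  expect_false(dens[[1]]$bimodal)

  two <- axis_density_summary(fake(c(rnorm(200, -4), rnorm(200, 4))))
  expect_true(two[[1]]$bimodal)

  deg <- axis_density_summary(fake(rep(1.5, 50)))
  expect_true(deg[[1]]$degenerate)
})

test_that("group similarity summary enumerates pairs correctly", {
  calls <- rbind(a = c(0, 0), b = c(0, 1), c = c(1, 1),
                 d = c(1, 0), e = c(1, 0))
  colnames(calls) <- c("m1", "m2")
  S <- simple_matching(genotype_matrix(calls))
  gs <- group_similarity_summary(S, c(a = "g1", b = "g1", c = "g1",
                                      d = "g2", e = "g2"))
  m <- gs$means
  expect_equal(m$mean_similarity[m$group == "g1"], 1 / 3)   # {1/2, 0, 1/2}
  expect_equal(m$mean_similarity[m$group == "g2"], 1)       # identical pair
  expect_identical(m$n_pairs[m$group == "all"], 10L)
  expect_warning(
    group_similarity_summary(S, c("g1", "g1", "g1", "g1", "solo")),
    "solo")
})
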