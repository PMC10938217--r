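test_that("rarefaction conserves depth exactly and drops shallow samples", {
  x <- rbind(a = c(1000L, 0L, 0L), b = c(300L, 300L, 400L),
             c = c(10L, 20L, 30L))
  expect_warning(r <- rarefy(x, 100, seed = 1), "dropped.*c")
  expect_equal(attr(r, "dropped"), "c")
  expect_true(all(rowSums(r) == 100))
  expect_equal(unname(r["a", ]), c(100L, 0L, 0L))  # single-taxon sample

  # sample with total exactly at depth is returned unchanged
  y <- rbind(s = c(40L, 35L, 25L))
  expect_equal(rarefy(y, 100, seed = 1)["s", ], y["s", ])

  expect_error(rarefy(x, 0), "positive")
  # same seed -> same draw
  expect_identical(rarefy(x[1:2, ], 100, seed = 7),
                   rarefy(x[1:2, ], 100, seed = 7))
})

test_that("rarefaction is an unbiased uniform subsample", {
  x <- rbind(s = c(500L, 300L, 150L, 50L))
  draws <- sapply(1:1000, function(s) rarefy(x, 100, seed = s)[1, ])
  expect_equal(rowMeans(draws), 100 * c(0.5, 0.3, 0.15, 0.05),
               tolerance = 0.05, ignore_attr = TRUE)
})

test_that("alpha diversity matches closed forms and brute-force oracles", {
  x <- rbind(a = c(3L, 0L, 7L), b = c(1L, 1L, 1L))
  expect_equal(unname(alpha_observed(x)), c(2L, 3L))

  u <- rbind(s = rep(5L, 4))
  expect_equal(unname(alpha_shannon(u)), log(4), tolerance = 1e-12)
  expect_equal(unname(alpha_shannon(rbind(s = c(9L, 0L, 0L)))), 0)
  p <- c(1, 2, 3) / 6
  expect_equal(unname(alpha_shannon(rbind(s = c(1L, 2L, 3L)))),
               -sum(p * log(p)), tolerance = 1e-12)
  expect_error(alpha_shannon(rbind(s = c(0L, 0L))), "empty")

  # brute-force agreement on random rows
  set.seed(4)
  m <- matrix(rpois(100 * 12, 2), 100, 12,
              dimnames = list(paste0("s", 1:100), paste0("t", 1:12)))
  m[rowSums(m) == 0, 1] <- 1L
  expect_equal(unname(alpha_observed(m)),
               unname(apply(m, 1, function(r) sum(r != 0))))
  sh <- apply(m, 1, function(r) {
    pr <- r[r > 0] / sum(r); -sum(pr * log(pr))
  })
  expect_equal(alpha_shannon(m), sh, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Faith PD follows the root-inclusive path-sum convention", {
  tr <- toy_tree()
  x <- matrix(0L, 3, 4, dimnames = list(c("only_A", "all", "none"),
                                        c("A", "B", "C", "D")))
  x["only_A", "A"] <- 5L
  x["all", ] <- 1L
  pd <- alpha_faith_pd(x, tr)
  expect_equal(unname(pd["only_A"]), 2)   # tip branch + stem to root
  expect_equal(unname(pd["all"]), 6)      # total tree length
  expect_equal(unname(pd["none"]), 0)     # empty-set convention

  bad <- matrix(1L, 1, 5, dimnames = list("s", c("A", "B", "C", "D", "E")))
  expect_error(alpha_faith_pd(bad, tr), "E")
})

test_that("Faith PD is monotone under adding observed taxa", {
  set.seed(8)
  tr <- ape::rtree(20, br = stats::rexp)
  tr$tip.label <- paste0("t", 1:20)
  base <- matrix(0L, 1, 20, dimnames = list("s", tr$tip.label))
  present <- sample(20, 5)
  base[1, present] <- 1L
  pd0 <- alpha_faith_pd(base, tr)
  for (add in sample(setdiff(1:20, present), 5)) {
    grown <- base
    grown[1, add] <- 1L
    pd1 <- alpha_faith_pd(grown, tr)
    expect_gte(pd1, pd0)
    base <- grown
    pd0 <- pd1
  }
})

test_that("Bray-Curtis matches closed forms and metric-like properties", {
  x <- rbind(a = c(5, 5, 0), b = c(0, 5, 5), c = c(5, 5, 0),
             d = c(7, 0, 0), e = c(0, 0, 3))
  d <- bray_curtis(x)
  expect_equal(d["a", "b"], 0.5)   # 1 - 2*5/20
  expect_equal(d["a", "c"], 0)     # identical rows
  expect_equal(d["d", "e"], 1)     # disjoint supports
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  expect_error(bray_curtis(rbind(a = c(1, 1), z = c(0, 0))), "z")

  set.seed(5)
  m <- matrix(rpois(20 * 10, 3) + 1L, 20, 10)
  dm <- bray_curtis(m)
  expect_true(isSymmetric(dm))
  expect_true(all(dm >= 0 & dm <= 1 - 1e-12 | dm <= 1))
})

test_that("PCoA recovers known geometry", {
  # points on a line: first axis reproduces the configuration
  pts <- c(0, 1, 3, 6)
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- paste0("s", 1:4)
  ord <- pcoa(d, n_axes = 3)
  rec <- as.matrix(dist(ord$coordinates[, 1]))
  expect_equal(unname(rec), unname(d), tolerance = 1e-8)
  expect_true(all(diff(ord$eigenvalues) <= 1e-8))
  expect_lte(sum(ord$proportion_explained), 1 + 1e-12)

  # Euclidean input distances are reproduced by the embedding
  set.seed(2)
  Y <- matrix(rnorm(6 * 3), 6, 3)
  dE <- as.matrix(dist(Y))
  ordE <- pcoa(dE, n_axes = 5)
  expect_equal(unname(as.matrix(dist(ordE$coordinates))), unname(dE),
               tolerance = 1e-8)

  # zero matrix -> all-zero coordinates
  z <- matrix(0, 4, 4)
  expect_true(all(pcoa(z, 2)$coordinates == 0))

  asym <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pcoa(asym), "symmetric")
})

test_that("PERMANOVA p on 6 samples equals exhaustive enumeration", {
  set.seed(10)
  pts <- c(rnorm(3, 0), rnorm(3, 1.5))
  d <- as.matrix(dist(pts))
  lab <- factor(rep(c("g1", "g2"), each = 3))
  res <- permanova(d, lab, n_permutations = 999)
  expect_true(res$exhaustive)

  # brute-force oracle: pseudo-F over every one of the 20 label splits
  f_oracle <- function(d, idx1) {
    n <- nrow(d); d2 <- d^2
    sst <- sum(d2) / (2 * n)
    ssw <- sum(d2[idx1, idx1]) / (2 * length(idx1)) +
      sum(d2[-idx1, -idx1]) / (2 * (n - length(idx1)))
    ((sst - ssw) / 1) / (ssw / (n - 2))
  }
  fs <- combn(6, 3, function(i) f_oracle(d, i))
  expect_equal(length(fs), 20L)
  f_obs <- f_oracle(d, 1:3)
  expect_equal(res$pseudo_f, f_obs, tolerance = 1e-12)
  expect_equal(res$p, mean(fs >= f_obs - 1e-12), tolerance = 1e-12)
})

test_that("PERMANOVA agrees with vegan::adonis2 and respects its bounds", {
  set.seed(6)
  m <- matrix(rpois(24 * 15, 4) + 1L, 24, 15)
  lab <- factor(rep(c("a", "b"), each = 12))
  d <- bray_curtis(m)
  res <- permanova(d, lab, n_permutations = 999, seed = 3)
  ad <- vegan::adonis2(stats::as.dist(d) ~ lab, permutations = 99)
  expect_equal(res$pseudo_f, ad$F[1], tolerance = 1e-10)
  expect_equal(res$r2, ad$R2[1], tolerance = 1e-10)
  expect_gte(res$p, 1 / (res$n_permutations + 1))
  expect_true(res$r2 >= 0 && res$r2 <= 1)

  # two tight, fully separated clusters: p hits the permutation floor
  pts <- c(rnorm(10, 0, 0.01), rnorm(10, 10, 0.01))
  dsep <- as.matrix(dist(pts))
  lsep <- factor(rep(c("a", "b"), each = 10))
  rsep <- permanova(dsep, lsep, n_permutations = 999, seed = 4)
  expect_false(rsep$exhaustive)
  expect_equal(rsep$p, 1 / 1000)

  expect_error(permanova(d, factor(rep("a", 24))), "two groups")
})

test_that("PERMANOVA R2 is invariant to relabelling and sample reordering", {
  set.seed(7)
  m <- matrix(rpois(20 * 10, 4) + 1L, 20, 10)
  rownames(m) <- paste0("s", 1:20)
  lab <- factor(rep(c("a", "b"), each = 10))
  d <- bray_curtis(m)
  r1 <- permanova(d, lab, 99, seed = 1)$r2
  # swap the two group labels (same partition)
  r2 <- permanova(d, factor(lab, levels = c("b", "a")), 99, seed = 1)$r2
  expect_equal(r1, r2, tolerance = 1e-12)
  # reorder samples consistently
  ord <- sample(20)
  r3 <- permanova(d[ord, ord], lab[ord], 99, seed = 1)$r2
  expect_equal(r1, r3, tolerance = 1e-12)
})

test_that("PERMANOVA p-values are calibrated under a label-independent null", {
  set.seed(9)
  m <- matrix(rpois(16 * 12, 4) + 1L, 16, 12)
  d <- bray_curtis(m)
  ps <- vapply(1:500, function(s) {
    lab <- withr::with_seed(1000 + s, factor(sample(rep(c("a", "b"), each = 8))))
    permanova(d, lab, n_permutations = 199, seed = s)$p
  }, numeric(1))
  rej <- mean(ps <= 0.05)
  expect_gt(rej, 0.05 - 2.5 * sqrt(0.05 * 0.95 / 500))
  expect_lt(rej, 0.05 + 2.5 * sqrt(0.05 * 0.95 / 500))
})
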