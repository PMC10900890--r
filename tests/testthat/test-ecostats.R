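test_that("rarefaction hits the target depth exactly and reproducibly", {
  m <- matrix(c(5, 0, 3, 12, 4, 9), 2, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("a", "b", "c")))
  r <- rarefyCounts(m, depth = 8, seed = 1)
  expect_identical(unname(rowSums(r)), c(8, 8))
  expect_identical(unname(r["S1", ]), c(5, 0, 3))  # row already at depth
  r2 <- rarefyCounts(m, depth = 8, seed = 1)
  expect_identical(r, r2)
  one <- matrix(c(10, 0), 1, dimnames = list("S1", c("a", "b")))
  expect_identical(unname(rarefyCounts(one, depth = 5, seed = 1)[1, ]), c(5, 0))
  expect_error(rarefyCounts(m, depth = 20), "S1")
  expect_error(rarefyCounts(matrix(c(1.5, 2), 1)), "integers")
})

test_that("rarefied per-taxon means match the hypergeometric expectation", {
  row <- matrix(c(50, 30, 20), 1, dimnames = list("S1", c("a", "b", "c")))
  depth <- 40; K <- 100
  set.seed(2)
  reps <- t(vapply(1:1000, function(i) rarefyCounts(row, depth)[1, ], numeric(3)))
  for (j in 1:3) {
    expMean <- depth * row[1, j] / K
    v <- depth * (row[1, j] / K) * (1 - row[1, j] / K) * (K - depth) / (K - 1)
    se <- sqrt(v / 1000)
    expect_lt(abs(mean(reps[, j]) - expMean), 3 * se + 1e-9)
  }
})

test_that("Shannon and richness match closed forms and brute force", {
  expect_equal(shannonIndex(c(1, 1, 1, 1)), log(4))
  expect_equal(shannonIndex(c(0, 7, 0)), 0)
  expect_identical(richnessIndex(c(0, 7, 0)), 1L)
  set.seed(41)
  x <- rpois(20, 5)
  p <- x[x > 0] / sum(x)
  expect_equal(shannonIndex(x), -sum(p * log(p)))
  expect_identical(richnessIndex(x), sum(x > 0))
  # matrix input is per-row and taxon-order invariant
  m <- matrix(rpois(12, 8), 3)
  expect_equal(shannonIndex(m), shannonIndex(m[, sample(ncol(m))]))
})

test_that("distance matrices match the brute-force double loop", {
  m <- matrix(c(1, 0, 0, 1, 2, 2), 3, byrow = TRUE)
  d <- communityDistance(m, "bray-curtis")
  expect_equal(d[1, 2], 1)      # disjoint rows
  expect_equal(d[3, 3], 0)
  set.seed(43)
  x <- matrix(runif(24, 0, 10), 6, 4)
  de <- communityDistance(x, "euclidean")
  db <- communityDistance(x, "bray-curtis")
  for (i in 1:6) for (j in 1:6) {
    expect_equal(de[i, j], sqrt(sum((x[i, ] - x[j, ])^2)))
    expect_equal(db[i, j],
                 if (i == j) 0 else sum(abs(x[i, ] - x[j, ])) / sum(x[i, ] + x[j, ]))
  }
  expect_equal(de, t(de))
  expect_true(all(diag(db) == 0))
  # identical rows are at distance zero
  same <- rbind(x[1, ], x[1, ])
  expect_equal(communityDistance(same, "euclidean")[1, 2], 0)
})

test_that("Mantel statistic and exact permutation p match the enumeration oracle", {
  set.seed(47)
  x <- matrix(runif(20), 5, 4)
  y <- x + matrix(rnorm(20, 0, 0.3), 5, 4)
  dx <- communityDistance(x, "euclidean")
  dy <- communityDistance(y, "euclidean")
  expect_equal(mantelTest(dx, dx, permutations = 9, seed = 1)$r, 1)
  res <- mantelTest(dx, dy, exact = TRUE)
  # independent oracle: recursive enumeration of all 120 permutations
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  lt <- function(m) m[lower.tri(m)]
  robs <- cor(lt(dx), lt(dy))
  rs <- vapply(perms(1:5), function(p) cor(lt(dx), lt(dy[p, p])), numeric(1))
  expect_equal(res$r, robs)
  expect_equal(res$p, mean(rs >= robs - 1e-12))
  expect_identical(res$permutations, 120L)
  # agreement with the vegan implementation on the statistic
  expect_equal(res$r, unname(vegan::mantel(dx, dy, permutations = 0)$statistic))
  expect_error(mantelTest(dx, dy[1:4, 1:4]), "same dimension")
})

test_that("OLS regression recovers slope, intercept, fit and p-value", {
  x <- 1:20
  res <- linRegress(x, 2 * x)
  expect_equal(res$slope, 2)
  expect_equal(res$intercept, 0)
  expect_equal(res$r2, 1)
  resConst <- linRegress(x, rep(3, 20))
  expect_equal(resConst$slope, 0)
  set.seed(53)
  xs <- rnorm(200)
  ys <- 0.5 * xs + rnorm(200, 0, 0.1)
  fit <- linRegress(xs, ys)
  se <- summary(lm(ys ~ xs))$coefficients[2, 2]
  expect_lt(abs(fit$slope - 0.5), 1.96 * se * 1.5)
  expect_lt(fit$p, 1e-10)
})

test_that("Spearman screen handles ties and BH matches the step-up oracle", {
  ab <- c(1, 2, 3, 4, 5, 6)
  feats <- cbind(mono = c(10, 20, 30, 40, 50, 60),
                 anti = c(6, 5, 4, 3, 2, 1),
                 tied = c(1, 1, 2, 2, 3, 3))
  res <- spearmanFdr(ab, feats)
  expect_equal(res$rho[res$feature == "mono"], 1)
  expect_equal(res$rho[res$feature == "anti"], -1)
  expect_equal(res$rho[res$feature == "tied"],
               cor(rank(ab), rank(feats[, "tied"])))
  # hand-computed BH on p = 0.01..0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  # textbook step-up oracle on random p-vectors
  bhOracle <- function(p) {
    n <- length(p); o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    pmin(1, q)[order(o)]
  }
  set.seed(59)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    expect_equal(p.adjust(p, "BH"), bhOracle(p))
  }
})

test_that("null Spearman screen controls the false discovery rate", {
  set.seed(61)
  ab <- rnorm(40)
  feats <- matrix(rnorm(40 * 100), 40, 100)
  res <- spearmanFdr(ab, feats)
  se <- sqrt(0.05 * 0.95 / 100)
  expect_lte(mean(res$q < 0.05), 0.05 + 3 * se)
})

test_that("rank-sum test is exact for small samples including ties", {
  expect_equal(wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(wilcoxonRankSum(c(1, 2, 3), c(10, 11, 12)), 0.1)
  # tie-free small samples agree with the exact base-R implementation
  set.seed(67)
  for (i in 1:15) {
    a <- rnorm(sample(3:6, 1)); b <- rnorm(sample(3:6, 1))
    expect_equal(wilcoxonRankSum(a, b),
                 wilcox.test(a, b, exact = TRUE)$p.value)
  }
  # large samples agree with the tie-corrected normal approximation
  a <- rnorm(30); b <- rnorm(30, 0.3)
  expect_equal(wilcoxonRankSum(a, b),
               wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value)
  ta <- sample(1:4, 30, replace = TRUE); tb <- sample(1:4, 30, replace = TRUE)
  expect_equal(wilcoxonRankSum(ta, tb),
               wilcox.test(ta, tb, exact = FALSE, correct = FALSE)$p.value)
  expect_error(wilcoxonRankSum(numeric(0), 1), "non-empty")
})

test_that("volcano table computes Haldane rates, fold changes and flags enrichment", {
  set.seed(71)
  n <- 400
  producer <- rep(c(TRUE, FALSE), each = n / 2)
  presence <- cbind(
    enriched = c(runif(n / 2) < 0.8, runif(n / 2) < 0.2),
    flat1 = runif(n) < 0.5,
    flat2 = runif(n) < 0.3)
  v <- volcanoTable(presence, producer)
  expect_equal(v$rate_producer[1], (sum(presence[producer, 1]) + 0.5) / (n / 2 + 1))
  expect_equal(v$log2fc, log2(v$rate_producer / v$rate_nonproducer))
  expect_true(v$significant[v$pathway_id == "enriched"])
  expect_identical(v$direction[v$pathway_id == "enriched"], "up")
  expect_lt(abs(v$log2fc[v$pathway_id == "enriched"] - 2), 0.5)
  # identical rates give ~zero fold change
  same <- cbind(p1 = rep(c(TRUE, FALSE), n / 2))
  v2 <- volcanoTable(same, producer)
  expect_lt(abs(v2$log2fc), 0.2)
  expect_error(volcanoTable(presence, rep(TRUE, n)), "nonproducer")
})

test_that("label shuffling yields no excess significant pathways", {
  set.seed(73)
  n <- 200; nPath <- 60
  presence <- matrix(runif(n * nPath) < 0.4, n, nPath,
                     dimnames = list(NULL, paste0("P", 1:nPath)))
  flags <- sample(rep(c(TRUE, FALSE), each = n / 2))
  v <- volcanoTable(presence, flags)
  se <- sqrt(0.05 * 0.95 / nPath)
  expect_lte(mean(v$significant), 0.05 + 3 * se)
})

test_that("nutrient-cycle aggregation is a groupby sum", {
  map <- c(g1 = "procA", g2 = "procA", g3 = "procB")
  res <- cycleAggregate(c(g1 = 1, g2 = 2, g3 = 4), map)
  expect_equal(unname(res$process["procA"]), 3)
  expect_equal(res$cycle, 7)
  # one gene per process is the identity
  res1 <- cycleAggregate(c(g3 = 4), c(g3 = "procB"))
  expect_equal(unname(res1$process["procB"]), 4)
  # empty process contributes zero
  res0 <- cycleAggregate(c(g1 = 1), c(g1 = "procA", gX = "procC"))
  expect_equal(unname(res0$process["procC"]), 0)
  set.seed(79)
  genes <- paste0("g", 1:50)
  map2 <- setNames(sample(paste0("pr", 1:6), 50, replace = TRUE), genes)
  m <- matrix(runif(150), 3, 50, dimnames = list(paste0("S", 1:3), genes))
  res2 <- cycleAggregate(m, map2)
  for (p in unique(map2))
    expect_equal(unname(res2$process[, p]),
                 unname(rowSums(m[, names(map2)[map2 == p], drop = FALSE])))
  expect_equal(unname(res2$cycle), unname(rowSums(m)))
})
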