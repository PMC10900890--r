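test_that("RPKM matches its defining formula and algebraic rearrangement", {
  expect_identical(rpkm(10, 1000, 1e6), 10)
  expect_identical(rpkm(0, 500, 1e6), 0)
  expect_error(rpkm(1, 0, 1e6), "lengthBp")
  expect_error(rpkm(1, 100, 0), "totalMappedReads")
  expect_error(rpkm(-1, 100, 1e6), "readCount")
  set.seed(23)
  for (i in 1:20) {
    rc <- rpois(1, 500); l <- sample(100:5000, 1); tot <- sample(1e5:1e7, 1)
    expect_equal(rpkm(rc, l, tot), rc * 1e9 / (as.numeric(l) * tot))
  }
})

test_that("RPKM scaling invariants hold", {
  set.seed(29)
  rc <- rpois(50, 100); l <- sample(200:2000, 50); tot <- rep(2e6, 50)
  base <- rpkm(rc, l, tot)
  expect_equal(rpkm(3 * rc, l, 3 * tot), base)
  expect_equal(rpkm(rc, l, 5 * tot), base / 5)
})

test_that("log2 transform uses half the smallest nonzero value by default", {
  x <- c(0, 4, 8)
  lg <- log2Abundance(x)
  expect_identical(lg$pseudocount, 2)
  expect_equal(lg$values, log2(x + 2))
  expect_equal(log2Abundance(x, 1)$values, log2(x + 1))
})

test_that("producer abundance averages marker RPKM per genome and sums per sample", {
  counts <- data.frame(sample_id = "S1",
                       target_id = paste0("G1|sc", sprintf("%02d", 1:15)),
                       length_bp = 1000,
                       read_count = 2,
                       total_mapped_reads = 1e6)
  ab <- producerAbundance(counts)
  expect_equal(unname(abundanceValues(ab$genome)["S1", "G1"]), 2)
  expect_equal(unname(ab$sample_total["S1"]), 2)
  zero <- counts; zero$read_count <- 0
  expect_equal(unname(producerAbundance(zero)$sample_total["S1"]), 0)
  # sum mode scales with the number of markers
  expect_equal(unname(producerAbundance(counts, method = "sum")$sample_total["S1"]), 30)
  expect_error(producerAbundance(data.frame(
    sample_id = "S1", target_id = "nodelimiter", length_bp = 1,
    read_count = 1, total_mapped_reads = 1)), "genome|family")
})

test_that("taxon relative abundance aggregates by rank and sums to one", {
  m <- matrix(c(3, 1), 1, dimnames = list("S1", c("G1", "G2")))
  tax <- parseTaxonomy(c("d__B;p__X;c__;o__;f__;g__;s__",
                         "d__B;p__Y;c__;o__;f__;g__;s__"), c("G1", "G2"))
  rel <- taxonRelativeAbundance(m, tax)
  v <- abundanceValues(rel)
  expect_equal(unname(v["S1", "X"]), 0.75)
  expect_equal(unname(v["S1", "Y"]), 0.25)
  expect_identical(featureKind(rel), "taxon")
  single <- taxonRelativeAbundance(m[, 1, drop = FALSE], tax)
  expect_equal(unname(abundanceValues(single)[1, 1]), 1)

  set.seed(31)
  g <- sprintf("G%02d", 1:50)
  phyla <- sample(paste0("P", 1:6), 50, replace = TRUE)
  tax2 <- data.frame(genome_id = g, domain = "B", phylum = phyla, class = "",
                     order = "", family = "", genus = "", species = "")
  m2 <- matrix(runif(3 * 50), 3, 50, dimnames = list(paste0("S", 1:3), g))
  rel2 <- abundanceValues(taxonRelativeAbundance(m2, tax2))
  expect_equal(unname(rowSums(rel2)), rep(1, 3))
  for (p in unique(phyla)) {
    brute <- rowSums(m2[, phyla == p, drop = FALSE]) / rowSums(m2)
    expect_equal(unname(rel2[, p]), unname(brute))
  }
  # permutation invariance
  perm <- sample(50)
  rel3 <- abundanceValues(taxonRelativeAbundance(m2[, perm], tax2))
  expect_equal(rel3[, colnames(rel2)], rel2)
})

test_that("Proteobacteria can be split into classes", {
  tax <- parseTaxonomy(c("d__B;p__Proteobacteria;c__Alpha;o__;f__;g__;s__",
                         "d__B;p__Proteobacteria;c__Gamma;o__;f__;g__;s__"),
                       c("G1", "G2"))
  m <- matrix(c(1, 1), 1, dimnames = list("S1", c("G1", "G2")))
  rel <- abundanceValues(taxonRelativeAbundance(m, tax, splitProteobacteria = TRUE))
  expect_identical(sort(colnames(rel)),
                   c("Proteobacteria;Alpha", "Proteobacteria;Gamma"))
})

test_that("gene abundance sums member-sequence RPKM per family", {
  counts <- data.frame(sample_id = rep(c("S1", "S2"), each = 3),
                       target_id = rep(c("t1", "t2", "t3"), 2),
                       length_bp = c(1000, 2000, 1000),
                       read_count = c(10, 20, 5, 0, 2, 4),
                       total_mapped_reads = 1e6)
  map <- c(t1 = "cobG", t2 = "cobG", t3 = "cbiK")
  am <- geneAbundance(counts, map)
  v <- abundanceValues(am)
  expect_equal(unname(v["S1", "cobG"]), 10 + 10)   # 10/1kb + 20/2kb per million
  expect_equal(unname(v["S1", "cbiK"]), 5)
  expect_equal(unname(v["S2", "cobG"]), 0 + 1)
  expect_error(geneAbundance(counts, map[1:2]), "without a family mapping")
  # brute-force groupby oracle on random data
  set.seed(37)
  n <- 60
  counts2 <- data.frame(sample_id = sample(paste0("S", 1:4), n, replace = TRUE),
                        target_id = sample(paste0("t", 1:10), n, replace = TRUE),
                        length_bp = sample(300:3000, n, replace = TRUE),
                        read_count = rpois(n, 40),
                        total_mapped_reads = 2e6)
  counts2 <- counts2[!duplicated(counts2[, c("sample_id", "target_id")]), ]
  map2 <- setNames(sample(c("fA", "fB", "fC"), 10, replace = TRUE), paste0("t", 1:10))
  v2 <- abundanceValues(geneAbundance(counts2, map2))
  for (s in rownames(v2)) for (f in colnames(v2)) {
    sub <- counts2[counts2$sample_id == s & map2[counts2$target_id] == f, ]
    expect_equal(unname(v2[s, f]),
                 sum(sub$read_count * 1e9 / (sub$length_bp * sub$total_mapped_reads)))
  }
})

test_that("abundance matrices validate their invariants", {
  expect_error(AbundanceMatrix(matrix(-1), "marker", "raw_rpkm"), "non-negative")
  bad <- matrix(c(0.6, 0.6), 1)
  expect_error(AbundanceMatrix(bad, "taxon", "relative"), "sum to 1")
  ok <- AbundanceMatrix(matrix(c(0.5, 0.5), 1), "taxon", "relative")
  expect_s4_class(ok, "AbundanceMatrix")
})

test_that("count table TSV round-trips", {
  counts <- data.frame(sample_id = "S1", target_id = "G1|sc01",
                       length_bp = 900L, read_count = 12L,
                       total_mapped_reads = 100000L)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeCountTable(counts, f)
  expect_identical(readCountTable(f), counts)
  counts$length_bp <- 0L
  writeCountTable(counts, f)
  expect_error(readCountTable(f), "length_bp")
})
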