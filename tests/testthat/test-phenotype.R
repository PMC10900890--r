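test_that("quality score is completeness minus five times contamination", {
  expect_identical(qualityScore(100, 0), 100)
  expect_identical(qualityScore(95, 2), 85)
  expect_identical(qualityScore(60, 2.1), 49.5)
  expect_error(qualityScore(101, 0), "completeness")
  expect_error(qualityScore(90, -1), "contamination")
})

test_that("MAG quality filter is strictly greater-than and matches brute force", {
  recs <- data.frame(genome_id = c("a", "b", "c"),
                     quality_score = c(50, 50.01, 85))
  expect_identical(filterMags(recs)$genome_id, c("b", "c"))
  expect_identical(nrow(filterMags(recs[0, ])), 0L)
  set.seed(3)
  recs <- data.frame(genome_id = sprintf("G%03d", 1:500),
                     completeness = runif(500, 40, 100),
                     contamination = runif(500, 0, 8))
  kept <- filterMags(recs)
  manual <- recs$genome_id[recs$completeness - 5 * recs$contamination > 50]
  expect_identical(kept$genome_id, manual)
})

test_that("pathway completeness equals brute-force set arithmetic", {
  cat_ <- toyCatalog()
  aerAll <- familiesInSection(cat_, "ring_aerobic")
  loopAll <- familiesInSection(cat_, "loop")
  full <- c(aerAll, loopAll)
  pc <- pathwayCompleteness(full, cat_)
  expect_identical(pc$aerobic_fraction, 1)
  expect_identical(pc$best_variant, "aerobic")
  expect_identical(pc$weighted_completeness, 1)

  empty <- pathwayCompleteness(character(0), cat_)
  expect_identical(empty$aerobic_fraction, 0)
  expect_identical(empty$anaerobic_fraction, 0)
  expect_identical(empty$loop_fraction, 0)

  expect_error(pathwayCompleteness("not_a_family", cat_), "unknown families")

  anaAll <- familiesInSection(cat_, "ring_anaerobic")
  allFams <- catalogFamilies(cat_)$family_id
  set.seed(21)
  for (i in 1:50) {
    present <- sample(allFams, sample(0:length(allFams), 1))
    pc <- pathwayCompleteness(present, cat_)
    fa <- length(intersect(present, aerAll)) / length(aerAll)
    fn <- length(intersect(present, anaAll)) / length(anaAll)
    fl <- length(intersect(present, loopAll)) / length(loopAll)
    expect_equal(pc$aerobic_fraction, fa)
    expect_equal(pc$anaerobic_fraction, fn)
    expect_equal(pc$loop_fraction, fl)
    expect_identical(pc$best_variant, if (fa >= fn) "aerobic" else "anaerobic")
    nb <- if (fa >= fn) length(aerAll) else length(anaAll)
    expect_equal(pc$weighted_completeness,
                 (max(fa, fn) * nb + fl * length(loopAll)) / (nb + length(loopAll)))
  }
})

test_that("phenotype thresholds assign the four categories deterministically", {
  cat_ <- toyCatalog()
  crit <- PhenotypeCriteria()
  full <- c(familiesInSection(cat_, "ring_aerobic"), familiesInSection(cat_, "loop"))
  expect_identical(classifyPhenotype(full, cat_, crit), "very-likely-producer")
  expect_identical(classifyPhenotype(character(0), cat_, crit), "non-producer")
  # 4 of the 8 weighted families present: completeness exactly 0.5 -> possible
  half <- c("aer1", "aer2", "sh1", "loop1")
  expect_equal(pathwayCompleteness(half, cat_)$weighted_completeness, 0.5)
  expect_identical(classifyPhenotype(half, cat_, crit), "possible-producer")
  # requireLoop turns a loop-free ring profile into a non-producer
  ringOnly <- familiesInSection(cat_, "ring_aerobic")
  expect_identical(classifyPhenotype(ringOnly, cat_, PhenotypeCriteria(requireLoop = TRUE)),
                   "non-producer")
  expect_error(PhenotypeCriteria(0.5, 0.6, 0.4), "possibleMin < likelyMin")
})

test_that("every profile maps to exactly one category and growth is monotone", {
  cat_ <- toyCatalog()
  crit <- PhenotypeCriteria()
  pool <- c(familiesInSection(cat_, "ring_aerobic"),
            familiesInSection(cat_, "ring_anaerobic"),
            familiesInSection(cat_, "loop"))
  pool <- unique(pool)
  set.seed(33)
  for (i in 1:40) {
    present <- sample(pool, sample(0:(length(pool) - 1), 1))
    ph <- classifyPhenotype(present, cat_, crit)
    expect_true(ph %in% phenotypeLevels())
    add <- sample(setdiff(pool, present), 1)
    ph2 <- classifyPhenotype(c(present, add), cat_, crit)
    expect_gte(phenotypeRank(ph2), phenotypeRank(ph))
  }
})

test_that("criteria degeneracy behaves at the limits", {
  cat_ <- toyCatalog()
  loose <- PhenotypeCriteria(possibleMin = 1e-9, likelyMin = 0.6, veryLikelyMin = 0.8)
  expect_identical(classifyPhenotype("loop1", cat_, loose) == "non-producer", FALSE)
  strict <- PhenotypeCriteria(veryLikelyMin = 1, likelyMin = 0.6, possibleMin = 0.4)
  full <- c(familiesInSection(cat_, "ring_aerobic"), familiesInSection(cat_, "loop"))
  expect_identical(classifyPhenotype(full, cat_, strict), "very-likely-producer")
  expect_false(classifyPhenotype(full[-1], cat_, strict) == "very-likely-producer")
})

test_that("user flagging requires at least one cobamide-dependent family", {
  cat_ <- toyCatalog()
  expect_true(classifyUser("use1", cat_))
  expect_false(classifyUser(c("aer1", "loop1"), cat_))
  allUsers <- familiesInSection(cat_, "user_dependent")
  expect_true(classifyUser(allUsers, cat_))
  expect_identical(length(allUsers), 3L)
  expect_identical(length(familiesInSection(defaultCatalog(), "user_dependent")), 13L)
})

test_that("producer bookkeeping sums categories and reports proportions", {
  s <- producerSummary(c("very-likely-producer" = 10, "likely-producer" = 5,
                         "possible-producer" = 5, "non-producer" = 80))
  expect_identical(s$producer_count, 20)
  expect_identical(s$total, 100)
  expect_equal(s$producer_percent, 20)
  expect_error(producerSummary(c("weird-category" = 3)), "unknown phenotype")
  expect_error(producerSummary(c("likely-producer" = 10), total = 5), "exceeds")
  df <- data.frame(phenotype = c("non-producer", "likely-producer", "likely-producer"))
  s2 <- producerSummary(df)
  expect_identical(s2$producer_count, 2L)
  expect_equal(s2$producer_fraction, 2 / 3)
})

test_that("habitat overlap counts shared taxa by set intersection", {
  recs <- data.frame(habitat = c("marine", "marine", "soil", "soil"),
                     phylum = c("A", "B", "C", "D"),
                     genus = c("a", "b", "c", "d"))
  ov <- habitatOverlap(recs)
  expect_identical(ov$shared_phyla_count, 0L)
  recs2 <- data.frame(habitat = c("marine", "soil"), phylum = "A", genus = "a")
  ov2 <- habitatOverlap(recs2)
  expect_identical(ov2$shared_phyla_count, 1L)
  expect_identical(ov2$shared_genera_count, 1L)
  set.seed(5)
  recs3 <- data.frame(habitat = sample(c("marine", "soil"), 200, replace = TRUE),
                      phylum = sample(paste0("P", 1:12), 200, replace = TRUE),
                      genus = sample(paste0("g", 1:40), 200, replace = TRUE))
  ov3 <- habitatOverlap(recs3)
  brute <- length(intersect(unique(recs3$phylum[recs3$habitat == "marine"]),
                            unique(recs3$phylum[recs3$habitat == "soil"])))
  expect_identical(ov3$shared_phyla_count, brute)
  bruteG <- length(intersect(unique(recs3$genus[recs3$habitat == "marine"]),
                             unique(recs3$genus[recs3$habitat == "soil"])))
  expect_identical(ov3$shared_genera_count, bruteG)
  # empty rank labels never count as shared
  recs4 <- data.frame(habitat = c("marine", "soil"), phylum = "", genus = "")
  expect_identical(habitatOverlap(recs4)$shared_phyla_count, 0L)
})

test_that("classifyMags integrates filters, phenotype, user flag and taxonomy", {
  cat_ <- toyCatalog()
  crit <- PhenotypeCriteria()
  full <- c(familiesInSection(cat_, "ring_aerobic"), familiesInSection(cat_, "loop"))
  hits <- data.frame(
    genome_id = c(rep("G1", length(full)), "G1", "G2", "G3"),
    protein_id = paste0("G", c(rep(1, length(full)), 1, 2, 3), "_", 1:(length(full) + 3)),
    family_id = c(full, "use1", "use2", "aer1"),
    e_value = c(rep(1e-10, length(full) + 2), 1e-3),  # G3 hit fails the cutoff
    bit_score = 100)
  quality <- data.frame(genome_id = c("G1", "G2", "G3", "G4"),
                        completeness = c(95, 90, 90, 60),
                        contamination = c(1, 1, 1, 5))  # G4 fails quality
  tax <- parseTaxonomy(rep("d__Bacteria;p__Px;c__;o__;f__;g__Gx;s__", 3),
                       c("G1", "G2", "G3"))
  mags <- classifyMags(hits, quality, tax, habitat = "marine",
                       catalog = cat_, criteria = crit)
  expect_identical(sort(mags$genome_id), c("G1", "G2", "G3"))
  expect_identical(mags$phenotype[mags$genome_id == "G1"], "very-likely-producer")
  expect_true(mags$is_user[mags$genome_id == "G1"])
  expect_true(mags$is_user[mags$genome_id == "G2"])
  expect_identical(mags$phenotype[mags$genome_id == "G3"], "non-producer")
  expect_false(mags$is_producer[mags$genome_id == "G3"])
  expect_identical(mags$phylum[mags$genome_id == "G1"], "Px")
  # is_producer <=> phenotype != non-producer
  expect_identical(mags$is_producer, mags$phenotype != "non-producer")
})
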