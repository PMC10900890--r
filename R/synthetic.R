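#' @include AllClasses.R AllGenerics.R
NULL

# Completeness bands per designed phenotype, kept 0.03 clear of the criteria
# thresholds so integer rounding of family counts cannot move a genome across
# a category boundary.
.phenotypeBands <- function(criteria, margin = 0.03) {
  v <- criteria@veryLikelyMin; l <- criteria@likelyMin; p <- criteria@possibleMin
  list("very-likely-producer" = c(v + margin, 1),
       "likely-producer" = c(l + margin, v - margin),
       "possible-producer" = c(p + margin, l - margin),
       "non-producer" = c(0, p - margin))
}

#' Generate synthetic genomes with known phenotype labels
#'
#' For each genome: draws a designed phenotype from the design mix, picks a
#' corrin-ring branch at random, draws a target pathway completeness inside
#' the phenotype's band under the active criteria, and selects that many
#' families uniformly from the branch (plus shared) and loop sections.
#' Per-family hit multiplicities follow `1 + Poisson(multiplicity - 1)` with
#' the design default mean of 2.74 hits per detected gene. Real hits get
#' E-values below the 1e-6 cutoff; a configurable fraction of decoy hits is
#' drawn log-uniform in (1e-6, 1e-2] to exercise the cutoff boundary.
#' Producer genomes also carry universal single-copy families (family-specific
#' detection probability in \[0.7, 1\]) with random nucleotide gene sequences,
#' so marker selection and database construction can run end to end.
#'
#' @param design a [SyntheticDesign-class].
#' @param catalog a [GeneCatalog-class].
#' @param criteria the [PhenotypeCriteria-class] the labels are designed
#'   against.
#' @return List: `truth` (genome_id, habitat, phenotype, variant,
#'   is_user, completeness, contamination, taxonomy ranks), `hits` (tblout
#'   rows incl. decoys), `quality`, `taxonomy`, `sequences` (named DNA
#'   strings for single-copy genes).
#' @export
generateGenomes <- function(design, catalog = defaultCatalog(),
                            criteria = PhenotypeCriteria()) {
  set.seed(design@seed)
  n <- design@nGenomes
  bands <- .phenotypeBands(criteria)
  phen <- sample(names(design@phenotypeMix), n, replace = TRUE,
                 prob = design@phenotypeMix)
  habitat <- sample(names(design@habitatSplit), n, replace = TRUE,
                    prob = design@habitatSplit)
  loopFams <- familiesInSection(catalog, "loop")
  userFams <- familiesInSection(catalog, "user_dependent")
  scFams <- familiesInSection(catalog, "single_copy")
  scProb <- stats::setNames(stats::runif(length(scFams), 0.7, 1), scFams)
  scLen <- stats::setNames(sample(300:1500, length(scFams), replace = TRUE), scFams)

  phylaPool <- paste0("Phylum", sprintf("%02d", 1:12))
  genusPool <- paste0("Genus", sprintf("%02d", 1:30))

  hits <- list(); truth <- list(); seqs <- character(0)
  for (i in seq_len(n)) {
    g <- sprintf("G%03d", i)
    variant <- sample(c("aerobic", "anaerobic"), 1)
    ringFams <- familiesInSection(
      catalog, if (variant == "aerobic") "ring_aerobic" else "ring_anaerobic")
    pool <- c(ringFams, loopFams)
    N <- length(pool)
    band <- bands[[phen[i]]]
    kmin <- ceiling(band[1] * N); kmax <- floor(band[2] * N)
    if (kmin > kmax) stop("criteria band too narrow for catalog size")
    k <- if (kmin == kmax) kmin else sample(kmin:kmax, 1)
    present <- if (k > 0) sample(pool, k) else character(0)
    isUser <- stats::runif(1) < design@userFraction
    if (isUser) present <- c(present, sample(userFams, sample(1:4, 1)))
    scPresent <- scFams[stats::runif(length(scFams)) < scProb]
    genomeHits <- .familyHits(g, c(present, scPresent), design@meanHitMultiplicity)
    # decoy hits: above-cutoff E-values on random families
    nDecoy <- stats::rpois(1, design@decoyFraction * nrow(genomeHits))
    if (nDecoy > 0) {
      decoyFam <- sample(catalogFamilies(catalog)$family_id, nDecoy, replace = TRUE)
      genomeHits <- rbind(genomeHits, data.frame(
        genome_id = g,
        protein_id = sprintf("%s_%d", g, nrow(genomeHits) + seq_len(nDecoy)),
        family_id = decoyFam,
        e_value = 10^stats::runif(nDecoy, -5.9, -2),
        bit_score = stats::runif(nDecoy, 10, 25),
        stringsAsFactors = FALSE))
    }
    hits[[i]] <- genomeHits
    # one nucleotide sequence per single-copy hit (best-score selection
    # downstream needs one per protein)
    scHits <- genomeHits[genomeHits$family_id %in% scFams &
                           genomeHits$e_value <= 1e-6, , drop = FALSE]
    if (nrow(scHits)) {
      len <- scLen[scHits$family_id] + sample(-30:30, nrow(scHits), replace = TRUE)
      newSeqs <- vapply(len, function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""), "")
      names(newSeqs) <- scHits$protein_id
      seqs <- c(seqs, newSeqs)
    }
    truth[[i]] <- data.frame(
      genome_id = g, habitat = habitat[i], phenotype = phen[i],
      variant = variant, designed_completeness = k / N, is_user = isUser,
      completeness = stats::runif(1, 80, 100),
      contamination = stats::runif(1, 0, 3),
      phylum = sample(phylaPool, 1), genus = sample(genusPool, 1),
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  hits <- do.call(rbind, hits)
  rownames(hits) <- rownames(truth) <- NULL
  quality <- truth[, c("genome_id", "completeness", "contamination")]
  taxonomy <- data.frame(
    genome_id = truth$genome_id, domain = "Bacteria", phylum = truth$phylum,
    class = "", order = "", family = "", genus = truth$genus, species = "",
    stringsAsFactors = FALSE)
  list(truth = truth, hits = hits, quality = quality, taxonomy = taxonomy,
       sequences = seqs)
}

.familyHits <- function(genome, families, multiplicity) {
  if (!length(families))
    return(data.frame(genome_id = character(), protein_id = character(),
                      family_id = character(), e_value = numeric(),
                      bit_score = numeric(), stringsAsFactors = FALSE))
  nh <- 1L + stats::rpois(length(families), multiplicity - 1)
  fam <- rep(families, nh)
  m <- sum(nh)
  data.frame(genome_id = genome,
             protein_id = sprintf("%s_%d", genome, seq_len(m)),
             family_id = fam,
             e_value = 10^-stats::runif(m, 7, 50),
             bit_score = stats::runif(m, 50, 400),
             stringsAsFactors = FALSE)
}

#' Write a generated genome fixture to disk
#'
#' Emits the tblout hit table, quality and taxonomy TSVs, single-copy gene
#' FASTA, and the ground truth as JSON, so the file-based entry points can be
#' exercised end to end.
#'
#' @param gen result of [generateGenomes()].
#' @param dir output directory (created if needed).
#' @return Named vector of the file paths written.
#' @export
writeGenomeFixture <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(hits = file.path(dir, "hits.tblout"),
             quality = file.path(dir, "quality.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             fasta = file.path(dir, "single_copy_genes.fasta"),
             truth = file.path(dir, "truth.json"))
  writeTblout(gen$hits, paths["hits"])
  utils::write.table(gen$quality, paths["quality"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tax <- data.frame(genome_id = gen$taxonomy$genome_id,
                    taxonomy = apply(gen$taxonomy, 1, function(r)
                      paste0(.RANK_PREFIXES, r[.RANKS], collapse = ";")),
                    stringsAsFactors = FALSE)
  utils::write.table(tax, paths["taxonomy"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(gen$sequences)) writeFastaEntries(gen$sequences, paths["fasta"])
  jsonlite::write_json(gen$truth, paths["truth"], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  paths
}

#' Simulate marker read counts from a known genome mixture
#'
#' Reads on target (genome, marker) are Poisson with expectation
#' `depth * p_g * length_gm / sum(p * length)`: proportional to the genome's
#' mixture proportion and the marker length, summing to the sample depth in
#' expectation. The per-sample library size is the depth, and the truth
#' (mixture proportions) is returned alongside.
#'
#' @param design a [SyntheticDesign-class]; `readDepths`/`nSamples` set the
#'   samples.
#' @param db a [MarkerDatabase-class] defining targets and lengths.
#' @param proportions optional nSamples x nGenomes matrix of mixture
#'   proportions (rows sum to 1); default log-normal draws per sample.
#' @return List: `counts` (count-table data.frame over `genome|family`
#'   targets), `truth` (proportion matrix, samples x genomes).
#' @export
generateMarkerCounts <- function(design, db, proportions = NULL) {
  set.seed(design@seed + 1L)
  e <- markerEntries(db)
  if (!nrow(e)) stop("marker database is empty")
  genomes <- sort(unique(e$genome_id))
  depths <- rep_len(design@readDepths, design@nSamples)
  if (is.null(proportions)) {
    proportions <- t(vapply(seq_len(design@nSamples), function(i) {
      w <- stats::rlnorm(length(genomes), 0, 1)
      w / sum(w)
    }, numeric(length(genomes))))
    colnames(proportions) <- genomes
  }
  stopifnot(ncol(proportions) == length(genomes))
  rownames(proportions) <- sprintf("S%03d", seq_len(nrow(proportions)))
  counts <- list()
  for (s in seq_len(nrow(proportions))) {
    w <- proportions[s, e$genome_id] * e$length_bp
    lambda <- if (sum(w) > 0) depths[s] * w / sum(w) else w * 0
    counts[[s]] <- data.frame(
      sample_id = rownames(proportions)[s],
      target_id = paste(e$genome_id, e$family_id, sep = "|"),
      length_bp = e$length_bp,
      read_count = stats::rpois(nrow(e), lambda),
      total_mapped_reads = max(1, depths[s]),
      stringsAsFactors = FALSE)
  }
  list(counts = do.call(rbind, counts), truth = proportions)
}

#' Simulate a community count table
#'
#' Taxon base abundances are log-normal; each sample draws multinomial counts
#' at its design depth around a mildly perturbed composition.
#'
#' @param design a [SyntheticDesign-class].
#' @param nTaxa number of taxa.
#' @param equalAbundance force a uniform composition (useful for closed-form
#'   diversity checks).
#' @return samples x taxa integer matrix.
#' @export
generateCommunity <- function(design, nTaxa = 30, equalAbundance = FALSE) {
  set.seed(design@seed + 2L)
  depths <- rep_len(design@readDepths, design@nSamples)
  base <- if (equalAbundance) rep(1, nTaxa) else stats::rlnorm(nTaxa, 0, 1.5)
  m <- t(vapply(seq_len(design@nSamples), function(i) {
    p <- base * stats::rlnorm(nTaxa, 0, if (equalAbundance) 0 else 0.3)
    as.integer(stats::rmultinom(1, depths[i], p / sum(p)))
  }, integer(nTaxa)))
  dimnames(m) <- list(sprintf("S%03d", seq_len(design@nSamples)),
                      sprintf("T%03d", seq_len(nTaxa)))
  m
}

#' Simulate a MAG x pathway presence matrix with planted enrichments
#'
#' Pathway presence is Bernoulli; enriched pathways have different rates in
#' producers (`enrichedRates[1]`) and nonproducers (`enrichedRates[2]`), all
#' other pathways share `baseRate` in both groups.
#'
#' @param design a [SyntheticDesign-class]; producers/nonproducers are split
#'   by `phenotypeMix` (non-producer fraction).
#' @param nPathways total pathways.
#' @param nEnriched number of planted enriched pathways.
#' @param enrichedRates `c(rate_producer, rate_nonproducer)` for planted
#'   pathways.
#' @param baseRate shared rate for the rest.
#' @return List: `presence` (logical matrix), `producer` (logical vector),
#'   `enriched` (planted pathway ids).
#' @export
generatePathwayMatrix <- function(design, nPathways = 40, nEnriched = 1,
                                  enrichedRates = c(0.8, 0.2), baseRate = 0.5) {
  set.seed(design@seed + 3L)
  nProd <- round(design@nGenomes * (1 - design@phenotypeMix[["non-producer"]]))
  nNon <- design@nGenomes - nProd
  producer <- c(rep(TRUE, nProd), rep(FALSE, nNon))
  rates <- matrix(baseRate, design@nGenomes, nPathways)
  enriched <- paste0("P", sprintf("%03d", seq_len(nEnriched)))
  rates[producer, seq_len(nEnriched)] <- enrichedRates[1]
  rates[!producer, seq_len(nEnriched)] <- enrichedRates[2]
  presence <- matrix(stats::runif(length(rates)) < rates,
                     design@nGenomes, nPathways,
                     dimnames = list(sprintf("G%03d", seq_len(design@nGenomes)),
                                     paste0("P", sprintf("%03d", seq_len(nPathways)))))
  list(presence = presence, producer = producer, enriched = enriched)
}

# Deterministic smooth covariate fields over (lat, lon): the same functions
# feed samples and the prediction raster, so grid recovery can be checked
# against truth.
.covariateFields <- function(lat, lon) {
  data.frame(
    temp = 25 * cos(pi * lat / 180) + 2 * sin(pi * lon / 120),
    rad = 180 + 60 * cos(pi * lat / 90) + 10 * cos(pi * lon / 150),
    ph = 7 + 0.8 * sin(pi * lat / 60) + 0.2 * cos(pi * lon / 80))
}

.responseSurface <- function(lat, fields, peakLatitude) {
  2 * exp(-((abs(lat) - abs(peakLatitude)) / 10)^2) +
    0.05 * fields$temp + 0.002 * fields$rad
}

#' Simulate geolocated samples and a covariate raster with known response
#'
#' Samples get coordinates, deterministic smooth covariate fields (a
#' temperature-, radiation- and pH-like variable), two pure-noise covariates
#' to exercise feature elimination, and a response with a designed Gaussian
#' latitudinal peak (at `design@peakLatitude`) plus covariate effects and
#' `N(0, noiseSd)` noise. A matching raster carries the same fields and the
#' noise-free true response.
#'
#' @param design a [SyntheticDesign-class]; `nSamples` controls sample count.
#' @param latRange sampled latitude range.
#' @param rasterResolution raster cell size in degrees.
#' @return List: `samples` (lat, lon, depth, covariates, response),
#'   `raster` (grid with covariates and `true_response`),
#'   `covariates` (predictor column names), `peakLatitude`.
#' @export
generateCovariates <- function(design, latRange = c(-65, 65),
                               rasterResolution = 2) {
  set.seed(design@seed + 4L)
  n <- design@nSamples
  lat <- stats::runif(n, latRange[1], latRange[2])
  lon <- stats::runif(n, -180, 180)
  fields <- .covariateFields(lat, lon)
  samples <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                        lat = lat, lon = lon,
                        depth = sample(c(NA, stats::runif(n, 0, 50)), n, replace = TRUE),
                        fields,
                        noise1 = stats::rnorm(n), noise2 = stats::rnorm(n))
  samples$response <- .responseSurface(lat, fields, design@peakLatitude) +
    stats::rnorm(n, 0, design@noiseSd)
  grid <- predictionGrid(latRange, c(-180, 180), rasterResolution)
  gfields <- .covariateFields(grid$lat, grid$lon)
  raster <- cbind(grid, gfields,
                  noise1 = stats::rnorm(nrow(grid)),
                  noise2 = stats::rnorm(nrow(grid)))
  raster$true_response <- .responseSurface(grid$lat, gfields, design@peakLatitude)
  list(samples = samples, raster = raster,
       covariates = c("lat", "temp", "rad", "ph", "noise1", "noise2"),
       peakLatitude = design@peakLatitude)
}
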