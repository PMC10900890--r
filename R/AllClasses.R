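#' @import methods
NULL

#' Pathway sections recognised by a gene catalog
#'
#' The cobamide de novo pathway is organised into tetrapyrrole precursor
#' synthesis, the corrin-ring branch (aerobic or anaerobic, plus families whose
#' profile HMM is shared between the two branches), nucleotide-loop assembly,
#' and transport/salvage. Two further sections carry the auxiliary gene sets:
#' cobamide-dependent enzyme families used to flag users, and universal
#' single-copy families used for read recruitment.
#'
#' @return Character vector of the closed set of section labels.
#' @export
pathwaySections <- function() {
  c("precursor", "ring_aerobic", "ring_anaerobic", "ring_shared",
    "loop", "transport_salvage", "user_dependent", "single_copy")
}

#' GeneCatalog: controlled vocabulary of gene families
#'
#' A catalog maps short family identifiers to profile accessions and pathway
#' sections. Families with section `ring_shared` are counted toward both the
#' aerobic and the anaerobic corrin-ring branch, mirroring the use of a single
#' profile HMM for orthologs shared between the branches.
#'
#' @slot families data.frame with columns `family_id`, `profile_accession`,
#'   `pathway_section`, `display_name`.
#' @slot version character scalar.
#' @export
setClass("GeneCatalog",
  representation(families = "data.frame", version = "character"))

setValidity("GeneCatalog", function(object) {
  fam <- object@families
  need <- c("family_id", "profile_accession", "pathway_section", "display_name")
  if (!all(need %in% names(fam)))
    return(paste("families must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(fam$family_id))
    return(paste("duplicate family_id:",
                 paste(unique(fam$family_id[duplicated(fam$family_id)]), collapse = ", ")))
  bad <- setdiff(unique(fam$pathway_section), pathwaySections())
  if (length(bad))
    return(paste("unknown pathway_section:", paste(bad, collapse = ", ")))
  for (sec in c("ring_aerobic", "ring_anaerobic", "loop")) {
    if (!any(fam$pathway_section == sec))
      return(paste0("catalog must contain at least one '", sec, "' family"))
  }
  TRUE
})

#' Construct a GeneCatalog
#'
#' @param families data.frame of family definitions (see [GeneCatalog-class]).
#' @param version version string recorded in outputs.
#' @return A validated [GeneCatalog-class] object.
#' @export
GeneCatalog <- function(families, version = "custom") {
  families <- as.data.frame(families, stringsAsFactors = FALSE)
  if (is.null(families$display_name)) families$display_name <- families$family_id
  if (is.null(families$profile_accession)) families$profile_accession <- NA_character_
  rownames(families) <- NULL
  new("GeneCatalog", families = families, version = as.character(version))
}

#' PhenotypeCriteria: thresholds for producer phenotype calls
#'
#' Thresholds are fractions of weighted pathway completeness (best corrin-ring
#' branch combined with the nucleotide-loop section, weighted by family
#' counts). The shipped defaults (0.8 / 0.6 / 0.4) are a documented
#' reconstruction of commonly used category criteria and are fully configurable.
#'
#' @slot veryLikelyMin,likelyMin,possibleMin numeric fractions in (0, 1],
#'   strictly decreasing.
#' @slot requireLoop logical; if `TRUE`, a genome with no nucleotide-loop
#'   family detected is called non-producer regardless of ring completeness.
#' @export
setClass("PhenotypeCriteria",
  representation(veryLikelyMin = "numeric", likelyMin = "numeric",
                 possibleMin = "numeric", requireLoop = "logical"))

setValidity("PhenotypeCriteria", function(object) {
  v <- c(object@veryLikelyMin, object@likelyMin, object@possibleMin)
  if (length(v) != 3L || any(!is.finite(v)))
    return("thresholds must be three finite numbers")
  if (!(v[1] > v[2] && v[2] > v[3] && v[3] > 0 && v[1] <= 1))
    return("need 0 < possibleMin < likelyMin < veryLikelyMin <= 1")
  TRUE
})

#' Construct PhenotypeCriteria
#'
#' @param veryLikelyMin,likelyMin,possibleMin completeness thresholds.
#' @param requireLoop require at least one nucleotide-loop family for any
#'   producer call.
#' @return A [PhenotypeCriteria-class] object.
#' @export
PhenotypeCriteria <- function(veryLikelyMin = 0.8, likelyMin = 0.6,
                              possibleMin = 0.4, requireLoop = FALSE) {
  new("PhenotypeCriteria", veryLikelyMin = veryLikelyMin, likelyMin = likelyMin,
      possibleMin = possibleMin, requireLoop = requireLoop)
}

#' MarkerDatabase: single-copy marker sequences from producer genomes
#'
#' Holds, for one habitat, the selected universal single-copy families
#' (ordered by coverage among producer genomes) and one best-scoring sequence
#' per (genome, family) pair.
#'
#' @slot habitat character scalar, e.g. "marine" or "soil".
#' @slot selectedFamilies ordered character vector of family ids.
#' @slot entries data.frame with columns `family_id`, `genome_id`,
#'   `protein_id`, `sequence`, `bit_score`, `length_bp`.
#' @slot coverage named numeric: fraction of producer genomes carrying each
#'   candidate family.
#' @export
setClass("MarkerDatabase",
  representation(habitat = "character", selectedFamilies = "character",
                 entries = "data.frame", coverage = "numeric"))

setValidity("MarkerDatabase", function(object) {
  e <- object@entries
  need <- c("family_id", "genome_id", "protein_id", "sequence", "bit_score", "length_bp")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (nrow(e)) {
    if (!all(e$family_id %in% object@selectedFamilies))
      return("entry family_id outside selectedFamilies")
    if (anyDuplicated(paste(e$family_id, e$genome_id)))
      return("more than one entry per (family, genome)")
    if (any(e$length_bp <= 0)) return("length_bp must be positive")
  }
  if (length(object@coverage) && any(object@coverage < 0 | object@coverage > 1))
    return("coverage values must lie in [0, 1]")
  TRUE
})

#' AbundanceMatrix: samples-by-features abundance values
#'
#' A light container for RPKM / relative-abundance matrices with an explicit
#' record of what the features are and which transform the values carry.
#' When `featureKind = "taxon"` and `transform = "relative"` every row sums to
#' one (within 1e-9).
#'
#' @slot values numeric matrix, samples in rows, features in columns.
#' @slot featureKind one of "marker", "gene", "taxon", "genome".
#' @slot transform one of "raw_rpkm", "relative", "log2".
#' @export
setClass("AbundanceMatrix",
  representation(values = "matrix", featureKind = "character",
                 transform = "character"))

setValidity("AbundanceMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (!object@featureKind %in% c("marker", "gene", "taxon", "genome"))
    return("featureKind must be marker, gene, taxon or genome")
  if (!object@transform %in% c("raw_rpkm", "relative", "log2"))
    return("transform must be raw_rpkm, relative or log2")
  if (object@transform != "log2" && any(v < 0, na.rm = TRUE))
    return("untransformed abundances must be non-negative")
  if (object@featureKind == "taxon" && object@transform == "relative" && nrow(v)) {
    s <- rowSums(v)
    if (any(abs(s[s != 0] - 1) > 1e-9))
      return("relative taxon abundances must sum to 1 per sample")
  }
  TRUE
})

#' Construct an AbundanceMatrix
#'
#' @param values numeric matrix (samples x features).
#' @param featureKind,transform labels, see [AbundanceMatrix-class].
#' @return An [AbundanceMatrix-class] object.
#' @export
AbundanceMatrix <- function(values, featureKind = "marker", transform = "raw_rpkm") {
  new("AbundanceMatrix", values = as.matrix(values),
      featureKind = featureKind, transform = transform)
}

#' SyntheticDesign: ground-truth design for generated fixtures
#'
#' Every generator in the package is a pure function of a design plus its
#' seed, so fixtures are reproducible and every recovery test can read the
#' truth it was generated from.
#'
#' @slot nGenomes integer number of genomes to simulate.
#' @slot phenotypeMix named fractions over the four phenotype categories,
#'   summing to one.
#' @slot habitatSplit named fractions over habitats, summing to one.
#' @slot meanHitMultiplicity mean profile-HMM hits per detected family
#'   (default 2.74, the multiplicity observed in real MAG annotation).
#' @slot decoyFraction fraction of extra hits with E-value above the cutoff.
#' @slot userFraction probability that a genome carries at least one
#'   cobamide-dependent enzyme family.
#' @slot readDepths per-sample sequencing depths for marker count simulation.
#' @slot nSamples number of samples for community/count simulations.
#' @slot noiseSd Gaussian noise sd for the covariate response surface.
#' @slot peakLatitude latitude (degrees) of the designed abundance peak.
#' @slot seed integer seed; mandatory.
#' @export
setClass("SyntheticDesign",
  representation(nGenomes = "integer", phenotypeMix = "numeric",
                 habitatSplit = "numeric", meanHitMultiplicity = "numeric",
                 decoyFraction = "numeric", userFraction = "numeric",
                 readDepths = "numeric",
                 nSamples = "integer", noiseSd = "numeric",
                 peakLatitude = "numeric", seed = "integer"))

setValidity("SyntheticDesign", function(object) {
  if (length(object@seed) != 1L || is.na(object@seed))
    return("a scalar integer seed is mandatory")
  if (abs(sum(object@phenotypeMix) - 1) > 1e-8)
    return("phenotypeMix fractions must sum to 1")
  if (abs(sum(object@habitatSplit) - 1) > 1e-8)
    return("habitatSplit fractions must sum to 1")
  bad <- setdiff(names(object@phenotypeMix), phenotypeLevels())
  if (length(bad)) return(paste("unknown phenotype category:", paste(bad, collapse = ", ")))
  if (object@meanHitMultiplicity < 1)
    return("meanHitMultiplicity must be >= 1 (each detected family has >= 1 hit)")
  TRUE
})

#' Construct a SyntheticDesign
#'
#' @param nGenomes number of genomes.
#' @param phenotypeMix named fractions over
#'   `c("very-likely-producer","likely-producer","possible-producer","non-producer")`.
#' @param habitatSplit named fractions over habitats.
#' @param meanHitMultiplicity mean hits per detected family (>= 1).
#' @param decoyFraction fraction of decoy hits above the E-value cutoff.
#' @param userFraction probability a genome carries a user family.
#' @param readDepths per-sample read depths.
#' @param nSamples number of samples.
#' @param noiseSd response noise sd.
#' @param peakLatitude designed latitudinal peak (degrees).
#' @param seed integer seed (mandatory).
#' @return A [SyntheticDesign-class] object.
#' @export
syntheticDesign <- function(nGenomes = 50,
                            phenotypeMix = c("very-likely-producer" = 0.25,
                                             "likely-producer" = 0.25,
                                             "possible-producer" = 0.25,
                                             "non-producer" = 0.25),
                            habitatSplit = c(marine = 0.5, soil = 0.5),
                            meanHitMultiplicity = 2.74,
                            decoyFraction = 0.1,
                            userFraction = 0.7,
                            readDepths = rep(1e5, 10),
                            nSamples = 10,
                            noiseSd = 0,
                            peakLatitude = 0,
                            seed) {
  if (missing(seed)) stop("syntheticDesign() requires an explicit seed")
  new("SyntheticDesign", nGenomes = as.integer(nGenomes),
      phenotypeMix = phenotypeMix, habitatSplit = habitatSplit,
      meanHitMultiplicity = meanHitMultiplicity,
      decoyFraction = decoyFraction, userFraction = userFraction,
      readDepths = readDepths,
      nSamples = as.integer(nSamples), noiseSd = noiseSd,
      peakLatitude = peakLatitude, seed = as.integer(seed))
}

#' Ordered phenotype categories
#'
#' @return Character vector from strongest to weakest producer call.
#' @export
phenotypeLevels <- function() {
  c("very-likely-producer", "likely-producer", "possible-producer", "non-producer")
}
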