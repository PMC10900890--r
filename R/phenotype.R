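#' @include AllClasses.R AllGenerics.R
NULL

#' MAG quality score
#'
#' `completeness - 5 * contamination`, the standard bin-quality score; bins
#' scoring above 50 are treated as usable MAGs.
#'
#' @param completeness percent in \[0, 100\].
#' @param contamination percent >= 0.
#' @return Numeric score(s).
#' @export
qualityScore <- function(completeness, contamination) {
  validateQuality(completeness, contamination)
  completeness - 5 * contamination
}

#' Filter MAG records on quality score
#'
#' Keeps records whose score is strictly greater than the threshold ("higher
#' than 50").
#'
#' @param records data.frame with either a `quality_score` column or
#'   `completeness` + `contamination` columns.
#' @param threshold quality-score threshold (default 50).
#' @return The retained rows, with a `quality_score` column filled in.
#' @export
filterMags <- function(records, threshold = 50) {
  if (is.null(records$quality_score))
    records$quality_score <- qualityScore(records$completeness, records$contamination)
  records[records$quality_score > threshold, , drop = FALSE]
}

#' Per-genome gene presence profiles from filtered hits
#'
#' Collapses a hit table (already E-value filtered with [filterHits()]) into
#' per-genome family hit counts. Hit multiplicity is retained but presence is
#' what downstream classification uses.
#'
#' @param hits data.frame from [readTblout()].
#' @param catalog a [GeneCatalog-class]; hits to families outside the catalog
#'   are an error.
#' @return data.frame with `genome_id`, `family_id`, `n_hits` (>= 1).
#' @export
profilesFromHits <- function(hits, catalog) {
  known <- catalogFamilies(catalog)$family_id
  bad <- setdiff(unique(hits$family_id), known)
  if (length(bad))
    stop("hit families absent from catalog: ", paste(bad, collapse = ", "))
  if (!nrow(hits))
    return(data.frame(genome_id = character(), family_id = character(),
                      n_hits = integer(), stringsAsFactors = FALSE))
  agg <- stats::aggregate(list(n_hits = hits$e_value),
                          by = list(genome_id = hits$genome_id,
                                    family_id = hits$family_id),
                          FUN = length)
  agg <- agg[order(agg$genome_id, agg$family_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

presentFamilies <- function(profile) {
  if (is.data.frame(profile)) unique(profile$family_id)
  else if (!is.null(names(profile))) names(profile)[profile >= 1]
  else unique(as.character(profile))
}

#' Pathway completeness of a genome's gene presence profile
#'
#' Computes the detected fraction of the aerobic and anaerobic corrin-ring
#' branches (each branch includes the `ring_shared` families, which carry one
#' profile for orthologs shared between branches) and of the nucleotide-loop
#' section, picks the better ring branch (ties break to aerobic), and combines
#' it with the loop fraction into a weighted overall completeness with the
#' section family counts as weights.
#'
#' @param profile present families: a character vector of family ids, a named
#'   count vector, or a per-genome slice of [profilesFromHits()] output.
#' @param catalog a [GeneCatalog-class].
#' @return List with `aerobic_fraction`, `anaerobic_fraction`,
#'   `loop_fraction`, `best_variant` ("aerobic"/"anaerobic") and
#'   `weighted_completeness`.
#' @export
pathwayCompleteness <- function(profile, catalog) {
  present <- presentFamilies(profile)
  known <- catalogFamilies(catalog)$family_id
  bad <- setdiff(present, known)
  if (length(bad))
    stop("unknown families in profile: ", paste(bad, collapse = ", "))
  aer <- familiesInSection(catalog, "ring_aerobic")
  ana <- familiesInSection(catalog, "ring_anaerobic")
  loop <- familiesInSection(catalog, "loop")
  fa <- length(intersect(present, aer)) / length(aer)
  fn <- length(intersect(present, ana)) / length(ana)
  fl <- length(intersect(present, loop)) / length(loop)
  best <- if (fa >= fn) "aerobic" else "anaerobic"
  nBest <- if (best == "aerobic") length(aer) else length(ana)
  fBest <- max(fa, fn)
  list(aerobic_fraction = fa, anaerobic_fraction = fn, loop_fraction = fl,
       best_variant = best,
       weighted_completeness =
         (fBest * nBest + fl * length(loop)) / (nBest + length(loop)))
}

#' Classify a genome's producer phenotype
#'
#' Assigns one of the four phenotype categories from the weighted pathway
#' completeness of the best corrin-ring branch plus the nucleotide loop:
#' very-likely-producer, likely-producer, possible-producer or non-producer.
#' Deterministic: every profile maps to exactly one category.
#'
#' @param profile as in [pathwayCompleteness()].
#' @param catalog a [GeneCatalog-class].
#' @param criteria a [PhenotypeCriteria-class].
#' @return A phenotype label (see [phenotypeLevels()]).
#' @export
classifyPhenotype <- function(profile, catalog, criteria = PhenotypeCriteria()) {
  stopifnot(is(criteria, "PhenotypeCriteria"))
  pc <- pathwayCompleteness(profile, catalog)
  if (criteria@requireLoop && pc$loop_fraction == 0) return("non-producer")
  f <- pc$weighted_completeness
  if (f >= criteria@veryLikelyMin) "very-likely-producer"
  else if (f >= criteria@likelyMin) "likely-producer"
  else if (f >= criteria@possibleMin) "possible-producer"
  else "non-producer"
}

#' Flag a genome as a potential cobamide user
#'
#' `TRUE` iff the profile contains at least one cobamide-dependent enzyme
#' family (`user_dependent` section).
#'
#' @inheritParams classifyPhenotype
#' @return Logical scalar.
#' @export
classifyUser <- function(profile, catalog) {
  userFams <- familiesInSection(catalog, "user_dependent")
  length(intersect(presentFamilies(profile), userFams)) >= 1L
}

#' Classify all MAGs from hit, quality and taxonomy tables
#'
#' Runs the full per-genome workflow: E-value filter, quality filter,
#' phenotype classification and user flagging, and joins taxonomy.
#'
#' @param hits hit data.frame ([readTblout()]).
#' @param quality quality data.frame ([readQualityTable()]).
#' @param taxonomy optional taxonomy data.frame ([readTaxonomy()]).
#' @param habitat habitat label(s) for the genomes: scalar, or named vector by
#'   genome_id.
#' @param catalog a [GeneCatalog-class].
#' @param criteria a [PhenotypeCriteria-class].
#' @param eCutoff E-value cutoff passed to [filterHits()].
#' @param qualityThreshold quality-score threshold passed to [filterMags()].
#' @return data.frame of MAG records: `genome_id`, `habitat`, quality fields,
#'   `phenotype`, `is_producer`, `is_user`, and taxonomy ranks when supplied.
#' @export
classifyMags <- function(hits, quality, taxonomy = NULL, habitat = NA_character_,
                         catalog = defaultCatalog(),
                         criteria = PhenotypeCriteria(),
                         eCutoff = 1e-6, qualityThreshold = 50) {
  kept <- filterMags(quality, qualityThreshold)
  hits <- filterHits(hits, eCutoff)
  profiles <- profilesFromHits(hits, catalog)
  recs <- lapply(seq_len(nrow(kept)), function(i) {
    g <- kept$genome_id[i]
    prof <- profiles[profiles$genome_id == g, , drop = FALSE]
    counts <- stats::setNames(prof$n_hits, prof$family_id)
    phen <- classifyPhenotype(counts, catalog, criteria)
    data.frame(genome_id = g,
               habitat = if (length(habitat) > 1) habitat[[g]] else habitat,
               completeness = kept$completeness[i],
               contamination = kept$contamination[i],
               quality_score = kept$quality_score[i],
               phenotype = phen,
               is_producer = phen != "non-producer",
               is_user = classifyUser(counts, catalog),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  if (!is.null(taxonomy)) out <- merge(out, taxonomy, by = "genome_id",
                                       all.x = TRUE, sort = TRUE)
  out
}

#' Producer bookkeeping from category counts
#'
#' Sums the three producer categories and reports the producer fraction of
#' all recovered MAGs — the arithmetic behind statements like "2992 of 8358
#' marine MAGs (35.8%) are potential producers".
#'
#' @param x either a MAG record data.frame (with a `phenotype` column) or a
#'   named vector/list of per-category counts.
#' @param total total number of MAGs; defaults to the sum of the category
#'   counts (required when non-producers are not included in `x`).
#' @return List with `category_counts`, `total`, `producer_count`,
#'   `producer_fraction` and `producer_percent`.
#' @export
producerSummary <- function(x, total = NULL) {
  if (is.data.frame(x)) {
    counts <- table(factor(x$phenotype, levels = phenotypeLevels()))
    counts <- stats::setNames(as.integer(counts), names(counts))
  } else {
    counts <- unlist(x)
    bad <- setdiff(names(counts), phenotypeLevels())
    if (length(bad)) stop("unknown phenotype category: ", paste(bad, collapse = ", "))
  }
  if (is.null(total)) total <- sum(counts)
  producers <- sum(counts[setdiff(names(counts), "non-producer")])
  if (producers > total) stop("producer count exceeds total MAG count")
  list(category_counts = counts, total = total, producer_count = producers,
       producer_fraction = producers / total,
       producer_percent = 100 * producers / total)
}

#' Habitat overlap of producer taxa
#'
#' Counts the phyla and genera found in both habitats (marine and soil in the
#' default design) and per-habitat totals, ignoring empty rank labels.
#'
#' @param records MAG record data.frame with `habitat`, `phylum`, `genus`
#'   columns (e.g. [classifyMags()] output joined to taxonomy).
#' @param habitats the two habitat labels to intersect.
#' @return List with `shared_phyla_count`, `shared_genera_count` and
#'   `per_habitat_counts` (a data.frame).
#' @export
habitatOverlap <- function(records, habitats = c("marine", "soil")) {
  stopifnot(all(c("habitat", "phylum", "genus") %in% names(records)))
  labs <- function(h, col) {
    v <- records[[col]][records$habitat == h]
    unique(v[!is.na(v) & nzchar(v)])
  }
  p1 <- labs(habitats[1], "phylum"); p2 <- labs(habitats[2], "phylum")
  g1 <- labs(habitats[1], "genus");  g2 <- labs(habitats[2], "genus")
  list(shared_phyla_count = length(intersect(p1, p2)),
       shared_genera_count = length(intersect(g1, g2)),
       per_habitat_counts = data.frame(
         habitat = habitats,
         n_phyla = c(length(p1), length(p2)),
         n_genera = c(length(g1), length(g2)),
         stringsAsFactors = FALSE))
}
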