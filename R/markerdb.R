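#' @include AllClasses.R AllGenerics.R
NULL

#' Coverage of candidate single-copy families among producer genomes
#'
#' Coverage of a family is the fraction of producer genomes with at least one
#' hit to it. The genome universe defaults to the genomes present in
#' `profiles`; pass `genomes` explicitly when some producers have no
#' single-copy hit at all.
#'
#' @param profiles data.frame from [profilesFromHits()] (producer genomes).
#' @param catalog a [GeneCatalog-class]; candidate families are its
#'   `single_copy` section.
#' @param genomes character vector of producer genome ids.
#' @return Named numeric vector of coverages in \[0, 1\], one per candidate
#'   family.
#' @export
familyCoverage <- function(profiles, catalog, genomes = unique(profiles$genome_id)) {
  fams <- familiesInSection(catalog, "single_copy")
  if (!length(genomes))
    return(stats::setNames(numeric(length(fams)), fams))
  sub <- profiles[profiles$family_id %in% fams &
                    profiles$genome_id %in% genomes, , drop = FALSE]
  n <- vapply(fams, function(f)
    length(unique(sub$genome_id[sub$family_id == f])), integer(1))
  stats::setNames(n / length(genomes), fams)
}

#' Select the top-coverage marker families
#'
#' Orders families by coverage (descending, ties broken lexicographically by
#' family id) and returns the top `k` among those with coverage > 0. The
#' default workflow keeps the 15 best-covered of 40 universal single-copy
#' families. If fewer than `k` families have positive coverage, all of them
#' are returned with a warning.
#'
#' @param coverage named numeric vector from [familyCoverage()].
#' @param k number of families to keep (default 15).
#' @return Ordered character vector of selected family ids.
#' @export
selectMarkers <- function(coverage, k = 15) {
  stopifnot(k >= 0)
  pos <- coverage[coverage > 0]
  ord <- order(-pos, names(pos))
  sel <- names(pos)[ord]
  if (length(sel) < k) {
    warning("only ", length(sel), " families with coverage > 0 (asked for ", k, ")")
    return(sel)
  }
  sel[seq_len(k)]
}

.looksNucleotide <- function(s) {
  chars <- unique(strsplit(toupper(paste(s, collapse = "")), "")[[1]])
  all(chars %in% c("A", "C", "G", "T", "U", "N", "-"))
}

#' Build a single-copy marker database from producer genomes
#'
#' For every (genome, selected family) pair, keeps the hit with the highest
#' bit score (ties break to the lexicographically smallest protein id) and
#' attaches its sequence. Lengths are normalised to base pairs: protein
#' sequences count 3 bp per residue, so RPKM downstream is on a common scale.
#'
#' @param hits data.frame of hits against the single-copy profiles.
#' @param sequences named character vector of gene/protein sequences keyed by
#'   `protein_id` (e.g. [readFastaEntries()]).
#' @param selected ordered family ids from [selectMarkers()].
#' @param habitat habitat label for the database.
#' @param coverage optional named coverage vector to record.
#' @param sequenceType "auto" (default), "nucleotide" or "protein".
#' @return A [MarkerDatabase-class].
#' @export
buildMarkerDatabase <- function(hits, sequences, selected, habitat = "unknown",
                                coverage = numeric(),
                                sequenceType = c("auto", "nucleotide", "protein")) {
  sequenceType <- match.arg(sequenceType)
  h <- hits[hits$family_id %in% selected, , drop = FALSE]
  if (nrow(h)) {
    # argmax bit score per (genome, family); stable tie-break on protein_id
    h <- h[order(h$genome_id, h$family_id, -h$bit_score, h$protein_id), , drop = FALSE]
    h <- h[!duplicated(paste(h$genome_id, h$family_id, sep = "\r")), , drop = FALSE]
    missing <- setdiff(h$protein_id, names(sequences))
    if (length(missing))
      stop("no sequence for chosen hit(s): ", paste(missing, collapse = ", "))
    seqs <- unname(sequences[h$protein_id])
    nt <- switch(sequenceType,
                 nucleotide = TRUE, protein = FALSE,
                 auto = .looksNucleotide(seqs))
    entries <- data.frame(family_id = h$family_id, genome_id = h$genome_id,
                          protein_id = h$protein_id, sequence = seqs,
                          bit_score = h$bit_score,
                          length_bp = nchar(seqs) * if (nt) 1L else 3L,
                          stringsAsFactors = FALSE)
    rownames(entries) <- NULL
  } else {
    entries <- data.frame(family_id = character(), genome_id = character(),
                          protein_id = character(), sequence = character(),
                          bit_score = numeric(), length_bp = integer(),
                          stringsAsFactors = FALSE)
  }
  new("MarkerDatabase", habitat = habitat, selectedFamilies = selected,
      entries = entries, coverage = coverage)
}

#' Write the marker database as FASTA
#'
#' Headers follow the `genome_id|family_id` convention used throughout the
#' package; count tables index targets by the same key.
#'
#' @param db a [MarkerDatabase-class].
#' @param path output FASTA.
#' @return `path`, invisibly.
#' @export
writeMarkerFasta <- function(db, path) {
  e <- markerEntries(db)
  writeFastaEntries(stats::setNames(e$sequence,
                                    paste(e$genome_id, e$family_id, sep = "|")),
                    path)
}

#' Manifest table of a marker database
#'
#' @param db a [MarkerDatabase-class].
#' @return data.frame: `family_id`, `genome_id`, `length_bp`, `bit_score`,
#'   `coverage` (of the family, when recorded).
#' @export
markerManifest <- function(db) {
  e <- markerEntries(db)
  cov <- markerCoverage(db)
  data.frame(family_id = e$family_id, genome_id = e$genome_id,
             length_bp = e$length_bp, bit_score = e$bit_score,
             coverage = if (length(cov)) unname(cov[e$family_id]) else NA_real_,
             stringsAsFactors = FALSE)
}
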