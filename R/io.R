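#' @include AllClasses.R
NULL

#' Load a gene catalog from YAML or TSV
#'
#' A YAML catalog has a top-level `version` and a `families` list of records;
#' a TSV catalog has columns `family_id`, `profile_accession`,
#' `pathway_section`, `display_name` (version taken from an optional
#' `#version:` first line). Validation enforces unique ids, the closed section
#' vocabulary, and presence of at least one family in each of the
#' `ring_aerobic`, `ring_anaerobic` and `loop` sections.
#'
#' @param path catalog file.
#' @return A [GeneCatalog-class].
#' @export
loadCatalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  if (file.size(path) == 0) stop("catalog file is empty: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    doc <- yaml::read_yaml(path)
    if (is.null(doc$families) || !length(doc$families))
      stop("catalog file has no families: ", path)
    fam <- do.call(rbind, lapply(doc$families, function(f)
      data.frame(family_id = f$family_id,
                 profile_accession = f$profile_accession %||% NA_character_,
                 pathway_section = f$pathway_section,
                 display_name = f$display_name %||% f$family_id,
                 stringsAsFactors = FALSE)))
    version <- doc$version %||% "custom"
  } else {
    first <- readLines(path, n = 1L)
    version <- if (startsWith(first, "#version:"))
      trimws(sub("^#version:", "", first)) else "custom"
    fam <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    if (!nrow(fam)) stop("catalog file has no families: ", path)
  }
  GeneCatalog(fam, version = version)
}

#' Write a gene catalog to TSV
#'
#' @param catalog a [GeneCatalog-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
saveCatalog <- function(catalog, path) {
  stopifnot(is(catalog, "GeneCatalog"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#version: ", catalogVersion(catalog)), con)
  utils::write.table(catalogFamilies(catalog), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The bundled default gene catalog
#'
#' Ships the full controlled vocabulary: corrin-ring families for both pathway
#' branches (with shared orthologs stored once under `ring_shared`),
#' tetrapyrrole precursor and nucleotide-loop assembly families, transport and
#' salvage genes, the 13 cobamide-dependent enzyme families used to flag
#' users, and the 40 universal single-copy families used for read recruitment.
#' The user-family and biosynthesis memberships are curated reconstructions
#' shipped as editable data; edit the TSV or load your own catalog to change
#' them.
#'
#' @return A [GeneCatalog-class].
#' @export
defaultCatalog <- function() {
  loadCatalog(system.file("extdata", "catalog_default.tsv",
                          package = "cobatlas", mustWork = TRUE))
}

#' Load phenotype criteria from YAML
#'
#' @param path YAML file with `very_likely_min`, `likely_min`, `possible_min`,
#'   optional `require_loop`. `NULL` loads the bundled default
#'   (0.8 / 0.6 / 0.4, no loop requirement).
#' @return A [PhenotypeCriteria-class].
#' @export
loadCriteria <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "criteria_default.yaml",
                        package = "cobatlas", mustWork = TRUE)
  doc <- yaml::read_yaml(path)
  PhenotypeCriteria(veryLikelyMin = doc$very_likely_min,
                    likelyMin = doc$likely_min,
                    possibleMin = doc$possible_min,
                    requireLoop = isTRUE(doc$require_loop))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a HMMER tblout-style hit table
#'
#' Parses the whitespace-delimited per-target table written by `hmmsearch
#' --tblout`: column 1 is the target (protein) name, column 3 the query
#' (family) name, columns 5 and 6 the full-sequence E-value and bit score.
#' Lines starting with `#` are comments. The genome id is recovered from the
#' protein id, by default by dropping the last `_`-delimited token (the
#' Prodigal `<genome>_<gene#>` convention); supply `genomeIdPattern` (a regex
#' with one capture group) to override.
#'
#' @param path tblout file.
#' @param genomeIdPattern optional regex; capture group 1 is the genome id.
#' @return data.frame of hits: `genome_id`, `protein_id`, `family_id`,
#'   `e_value`, `bit_score`.
#' @export
readTblout <- function(path, genomeIdPattern = NULL) {
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(data.frame(genome_id = character(), protein_id = character(),
                      family_id = character(), e_value = numeric(),
                      bit_score = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  short <- lengths(fields) < 6L
  if (any(short))
    stop("malformed tblout row(s) at line ", paste(idx[short], collapse = ", "),
         ": fewer than 6 columns")
  protein_id <- vapply(fields, `[[`, "", 1L)
  family_id <- vapply(fields, `[[`, "", 3L)
  e_value <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  bit_score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 6L)))
  bad <- is.na(e_value) | is.na(bit_score)
  if (any(bad))
    stop("non-numeric E-value/score in tblout at line ",
         paste(idx[bad], collapse = ", "))
  if (any(e_value < 0))
    stop("negative E-value in tblout at line ",
         paste(idx[e_value < 0], collapse = ", "))
  genome_id <- if (is.null(genomeIdPattern)) {
    sub("_[^_]+$", "", protein_id)
  } else {
    m <- regmatches(protein_id, regexec(genomeIdPattern, protein_id))
    vapply(m, function(x) if (length(x) >= 2) x[[2]] else NA_character_, "")
  }
  if (anyNA(genome_id))
    stop("genomeIdPattern failed to match some protein ids")
  data.frame(genome_id = genome_id, protein_id = protein_id,
             family_id = family_id, e_value = e_value,
             bit_score = bit_score, stringsAsFactors = FALSE)
}

#' Write hits as a HMMER tblout-style table
#'
#' Inverse of [readTblout()] on the columns the pipeline uses; remaining
#' tblout columns are written as `-`.
#'
#' @param hits data.frame with `protein_id`, `family_id`, `e_value`,
#'   `bit_score`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTblout <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# target name        accession  query name           accession    E-value  score  bias", con)
  if (nrow(hits)) {
    rows <- sprintf("%s - %s - %s %s 0.0 %s %s 0.0 1 1 0 0 1 1 1 1 -",
                    hits$protein_id, hits$family_id,
                    format(hits$e_value, scientific = TRUE, trim = TRUE, digits = 8),
                    format(hits$bit_score, trim = TRUE, digits = 8),
                    format(hits$e_value, scientific = TRUE, trim = TRUE, digits = 8),
                    format(hits$bit_score, trim = TRUE, digits = 8))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Filter hits at an E-value cutoff
#'
#' Retains hits with `e_value <= eCutoff` (the cutoff itself is kept), in
#' input order. The default 1e-6 is the standard cutoff for profile-HMM
#' annotation of MAG proteins.
#'
#' @param hits data.frame as returned by [readTblout()].
#' @param eCutoff positive E-value cutoff.
#' @return The retained rows of `hits`.
#' @export
filterHits <- function(hits, eCutoff = 1e-6) {
  stopifnot(is.numeric(eCutoff), length(eCutoff) == 1L, eCutoff >= 0)
  hits[hits$e_value <= eCutoff, , drop = FALSE]
}

#' Read a genome quality table
#'
#' TSV with columns `genome_id`, `completeness`, `contamination` (percent).
#' Validates completeness in \[0, 100\] and contamination >= 0.
#'
#' @param path TSV file.
#' @return data.frame of quality records.
#' @export
readQualityTable <- function(path) {
  q <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "completeness", "contamination")
  if (!all(need %in% names(q)))
    stop("quality table must have columns: ", paste(need, collapse = ", "))
  validateQuality(q$completeness, q$contamination)
  q
}

validateQuality <- function(completeness, contamination) {
  if (any(!is.finite(completeness)) || any(completeness < 0 | completeness > 100))
    stop("completeness must lie in [0, 100]")
  if (any(!is.finite(contamination)) || any(contamination < 0))
    stop("contamination must be >= 0")
  invisible(TRUE)
}

.RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")
.RANK_PREFIXES <- c("d__", "p__", "c__", "o__", "f__", "g__", "s__")

#' Parse GTDB-style taxonomy strings
#'
#' Splits `d__...;p__...;...;s__...` strings into the 7 canonical ranks.
#' Missing ranks stay as empty strings and are never dropped; prefixes out of
#' order or missing are an error.
#'
#' @param strings character vector of 7-rank taxonomy strings.
#' @param genome_ids optional ids for the rows.
#' @return data.frame with `genome_id` and one column per rank.
#' @export
parseTaxonomy <- function(strings, genome_ids = NULL) {
  parts <- strsplit(strings, ";")
  bad <- which(lengths(parts) != 7L)
  if (length(bad))
    stop("taxonomy string does not have 7 ranks at position ",
         paste(bad, collapse = ", "))
  mat <- t(vapply(parts, function(p) {
    p <- trimws(p)
    pref <- substr(p, 1, 3)
    if (!identical(pref, .RANK_PREFIXES))
      stop("rank prefixes out of order: ", paste(p, collapse = ";"))
    substring(p, 4)
  }, character(7)))
  colnames(mat) <- .RANKS
  out <- data.frame(genome_id = genome_ids %||% as.character(seq_along(strings)),
                    mat, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a taxonomy table
#'
#' TSV with columns `genome_id` and `taxonomy` (a GTDB 7-rank string).
#'
#' @param path TSV file.
#' @return data.frame with `genome_id` and one column per rank.
#' @export
readTaxonomy <- function(path) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("genome_id", "taxonomy") %in% names(t)))
    stop("taxonomy table must have columns genome_id, taxonomy")
  parseTaxonomy(t$taxonomy, t$genome_id)
}

#' Format a parsed taxonomy back into a GTDB string
#'
#' @param taxRow one row of the data.frame returned by [parseTaxonomy()].
#' @return The 7-rank string.
#' @export
formatTaxonomy <- function(taxRow) {
  paste0(.RANK_PREFIXES, unlist(taxRow[.RANKS]), collapse = ";")
}

#' Write named sequences to FASTA
#'
#' Headers are the element names (the package convention is
#' `genome_id|family_id` for marker databases); duplicate headers are an
#' error.
#'
#' @param seqs named character vector of sequences.
#' @param path output FASTA.
#' @return `path`, invisibly.
#' @export
writeFastaEntries <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA headers: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
readFastaEntries <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(out)))
    stop("duplicate FASTA headers in ", path)
  out
}

#' Read / write a per-sample read-count table
#'
#' Long TSV with columns `sample_id`, `target_id`, `length_bp`, `read_count`,
#' `total_mapped_reads`. Targets are a subset of the mapped library, so the
#' per-sample total may exceed the column sum of `read_count`.
#'
#' @param path TSV file.
#' @return data.frame count table.
#' @export
readCountTable <- function(path) {
  ct <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "target_id", "length_bp", "read_count", "total_mapped_reads")
  if (!all(need %in% names(ct)))
    stop("count table must have columns: ", paste(need, collapse = ", "))
  if (any(ct$read_count < 0)) stop("read_count must be >= 0")
  if (any(ct$length_bp <= 0)) stop("length_bp must be > 0")
  if (any(ct$total_mapped_reads <= 0)) stop("total_mapped_reads must be > 0")
  ct
}

#' @rdname readCountTable
#' @param counts data.frame count table.
#' @export
writeCountTable <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
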