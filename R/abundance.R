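#' @include AllClasses.R AllGenerics.R
NULL

#' Reads per kilobase per million mapped reads
#'
#' `read_count / (length_bp/1000) / (total_mapped_reads/1e6)`. Invariant under
#' joint scaling of counts and library size; scaling the library size alone by
#' c scales RPKM by 1/c.
#'
#' @param readCount mapped reads on the target (>= 0).
#' @param lengthBp target length in bp (> 0).
#' @param totalMappedReads library size (> 0).
#' @return Numeric RPKM value(s); vectorized.
#' @export
rpkm <- function(readCount, lengthBp, totalMappedReads) {
  if (any(lengthBp <= 0)) stop("lengthBp must be > 0")
  if (any(totalMappedReads <= 0)) stop("totalMappedReads must be > 0")
  if (any(readCount < 0)) stop("readCount must be >= 0")
  readCount / (lengthBp / 1000) / (totalMappedReads / 1e6)
}

#' Log2 transform with a data-driven pseudocount
#'
#' `log2(x + pseudocount)`; the default pseudocount is half the smallest
#' nonzero value in `x`, a scale-free choice that avoids -Inf without
#' dominating small abundances.
#'
#' @param x non-negative numeric values.
#' @param pseudocount override the default.
#' @return List with `values` and the `pseudocount` used.
#' @export
log2Abundance <- function(x, pseudocount = NULL) {
  if (is.null(pseudocount)) {
    nz <- x[x > 0 & is.finite(x)]
    pseudocount <- if (length(nz)) min(nz) / 2 else 1
  }
  list(values = log2(x + pseudocount), pseudocount = pseudocount)
}

.sampleFeatureMatrix <- function(sample_id, feature, value) {
  samples <- sort(unique(sample_id))
  feats <- sort(unique(feature))
  m <- matrix(0, length(samples), length(feats),
              dimnames = list(samples, feats))
  idx <- cbind(match(sample_id, samples), match(feature, feats))
  for (i in seq_along(value)) m[idx[i, 1], idx[i, 2]] <- m[idx[i, 1], idx[i, 2]] + value[i]
  m
}

#' Producer abundance per sample from marker read counts
#'
#' Converts a count table over marker targets (`genome_id|family_id`) into
#' per-genome RPKM abundances and a per-sample producer total. The genome
#' abundance is the mean RPKM over its markers present in the count table
#' (configurable to `sum` for a strict additive reading); the sample producer
#' abundance is the sum over producer genomes, reported raw and
#' log2-transformed.
#'
#' @param counts count table ([readCountTable()] columns); `target_id` is
#'   `genome|family`.
#' @param db optional [MarkerDatabase-class]: restricts targets to its
#'   entries.
#' @param method "mean" (default) or "sum" across a genome's markers.
#' @param pseudocount for the log2 transform; default data-driven
#'   ([log2Abundance()]).
#' @return List: `genome` ([AbundanceMatrix-class], samples x genomes,
#'   raw RPKM), `sample_total` (named numeric), `sample_total_log2`,
#'   `pseudocount`.
#' @export
producerAbundance <- function(counts, db = NULL, method = c("mean", "sum"),
                              pseudocount = NULL) {
  method <- match.arg(method)
  parts <- strsplit(counts$target_id, "|", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("target_id must follow the genome|family convention")
  counts$genome_id <- vapply(parts, `[[`, "", 1L)
  counts$family_id <- vapply(parts, `[[`, "", 2L)
  if (!is.null(db)) {
    e <- markerEntries(db)
    keep <- paste(counts$genome_id, counts$family_id) %in%
      paste(e$genome_id, e$family_id)
    counts <- counts[keep, , drop = FALSE]
  }
  counts$rpkm <- rpkm(counts$read_count, counts$length_bp, counts$total_mapped_reads)
  agg <- stats::aggregate(list(v = counts$rpkm),
                          by = list(sample_id = counts$sample_id,
                                    genome_id = counts$genome_id),
                          FUN = if (method == "mean") mean else sum)
  m <- .sampleFeatureMatrix(agg$sample_id, agg$genome_id, agg$v)
  total <- rowSums(m)
  lg <- log2Abundance(total, pseudocount)
  list(genome = AbundanceMatrix(m, featureKind = "genome", transform = "raw_rpkm"),
       sample_total = total, sample_total_log2 = lg$values,
       pseudocount = lg$pseudocount)
}

#' Taxon relative abundance of producers per sample
#'
#' Sums genome abundances by a taxonomy rank label and divides by the sample
#' total, so rows sum to one. Optionally splits Proteobacteria into its
#' classes, the convention used when that phylum dominates.
#'
#' @param genomeAbundance samples x genomes [AbundanceMatrix-class] (or plain
#'   matrix) of raw abundances.
#' @param taxonomy data.frame from [parseTaxonomy()]/[readTaxonomy()].
#' @param rank taxonomy rank to aggregate at (default "phylum").
#' @param splitProteobacteria replace the Proteobacteria label with its
#'   class-level labels.
#' @return A samples x taxa [AbundanceMatrix-class] with
#'   `featureKind = "taxon"`, `transform = "relative"`.
#' @export
taxonRelativeAbundance <- function(genomeAbundance, taxonomy, rank = "phylum",
                                   splitProteobacteria = FALSE) {
  m <- if (is(genomeAbundance, "AbundanceMatrix"))
    abundanceValues(genomeAbundance) else as.matrix(genomeAbundance)
  stopifnot(rank %in% .RANKS)
  lab <- taxonomy[[rank]][match(colnames(m), taxonomy$genome_id)]
  if (splitProteobacteria && rank == "phylum") {
    cls <- taxonomy[["class"]][match(colnames(m), taxonomy$genome_id)]
    proteo <- !is.na(lab) & lab == "Proteobacteria" & !is.na(cls) & nzchar(cls)
    lab[proteo] <- paste0("Proteobacteria;", cls[proteo])
  }
  lab[is.na(lab) | !nzchar(lab)] <- "unclassified"
  taxa <- sort(unique(lab))
  agg <- sapply(taxa, function(t) rowSums(m[, lab == t, drop = FALSE]))
  agg <- matrix(agg, nrow = nrow(m), dimnames = list(rownames(m), taxa))
  tot <- rowSums(agg)
  rel <- agg / ifelse(tot == 0, 1, tot)
  AbundanceMatrix(rel, featureKind = "taxon", transform = "relative")
}

#' Biosynthesis-gene abundance per sample
#'
#' Per-sample RPKM per gene family, summed over the member gene sequences
#' detected on the assembled contigs of that sample.
#'
#' @param counts count table over gene sequences ([readCountTable()]).
#' @param targetToFamily named character vector mapping `target_id` to
#'   `family_id`; targets without a mapping are an error.
#' @return A samples x families [AbundanceMatrix-class]
#'   (`featureKind = "gene"`, raw RPKM).
#' @export
geneAbundance <- function(counts, targetToFamily) {
  fam <- targetToFamily[counts$target_id]
  if (anyNA(fam))
    stop("targets without a family mapping: ",
         paste(unique(counts$target_id[is.na(fam)]), collapse = ", "))
  v <- rpkm(counts$read_count, counts$length_bp, counts$total_mapped_reads)
  m <- .sampleFeatureMatrix(counts$sample_id, unname(fam), v)
  AbundanceMatrix(m, featureKind = "gene", transform = "raw_rpkm")
}

#' Write an AbundanceMatrix as TSV
#'
#' @param x an [AbundanceMatrix-class].
#' @param path output file; samples in rows, feature header row.
#' @return `path`, invisibly.
#' @export
writeAbundanceMatrix <- function(x, path) {
  df <- data.frame(sample_id = rownames(abundanceValues(x)),
                   abundanceValues(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
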