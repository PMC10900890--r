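#' @include AllClasses.R
NULL

#' Validate a pipeline run configuration
#'
#' A configuration is a YAML file (or equivalent list) with a mandatory
#' `seed` and `output_dir`, optional `catalog` / `criteria` file paths
#' (defaults used when absent), a `habitat` label, and per-stage sections.
#' All referenced files must exist at validation time; validation happens
#' before any stage runs.
#'
#' @param config path to a YAML config, or a list.
#' @return The validated config list, invisibly annotated with `config_md5`
#'   when read from a file.
#' @export
validateConfig <- function(config) {
  md5 <- NA_character_
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    md5 <- unname(tools::md5sum(config))
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed)) stop("config must set a seed")
  config$seed <- as.integer(config$seed)
  if (is.null(config$output_dir)) stop("config must set output_dir")
  for (key in c("catalog", "criteria", "hits", "quality", "taxonomy", "sequences")) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p))
      stop("config references missing file for '", key, "': ", p)
  }
  config$config_md5 <- md5
  config
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full pipeline from a single configuration
#'
#' Stages execute in dependency order: synthetic fixture generation (when
#' `synthetic: true`; otherwise hit/quality/taxonomy/sequence files are
#' read), phenotype classification, marker selection and database
#' construction, marker count quantification to producer abundance, and the
#' ecological statistics (diversity, Mantel, volcano). Every run directory
#' gets per-stage TSV/JSON outputs plus `run_info.json` recording the package
#' version, config checksum and seeds. Identical config + seed reproduces
#' identical outputs.
#'
#' @param config path to YAML config or list (see [validateConfig()]).
#' @return Invisibly, a list of the main in-memory results.
#' @export
runPipeline <- function(config) {
  cfg <- validateConfig(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  catalog <- if (is.null(cfg$catalog)) defaultCatalog() else loadCatalog(cfg$catalog)
  criteria <- loadCriteria(cfg$criteria)
  logLines <- character(0)
  note <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    logLines <<- c(logLines, msg)
  }

  # --- inputs -----------------------------------------------------------
  if (isTRUE(cfg$synthetic)) {
    design <- syntheticDesign(
      nGenomes = cfg$n_genomes %||% 30,
      nSamples = cfg$n_samples %||% 8,
      readDepths = rep(cfg$read_depth %||% 1e5, cfg$n_samples %||% 8),
      seed = seed)
    gen <- .stage("synth", generateGenomes(design, catalog, criteria))
    hits <- gen$hits; quality <- gen$quality
    taxonomy <- gen$taxonomy; sequences <- gen$sequences
    note("synth: ", nrow(gen$truth), " genomes generated")
  } else {
    hits <- .stage("inputs", readTblout(cfg$hits))
    quality <- .stage("inputs", readQualityTable(cfg$quality))
    taxonomy <- if (is.null(cfg$taxonomy)) NULL else .stage("inputs", readTaxonomy(cfg$taxonomy))
    sequences <- if (is.null(cfg$sequences)) character(0) else .stage("inputs", readFastaEntries(cfg$sequences))
    design <- NULL
  }

  # --- phenotype --------------------------------------------------------
  mags <- .stage("phenotype", classifyMags(
    hits, quality, taxonomy, habitat = cfg$habitat %||% "marine",
    catalog = catalog, criteria = criteria,
    eCutoff = cfg$e_cutoff %||% 1e-6,
    qualityThreshold = cfg$quality_threshold %||% 50))
  utils::write.table(mags, file.path(cfg$output_dir, "mag_records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- producerSummary(mags)
  note("phenotype: ", summ$producer_count, "/", summ$total, " producers")

  # --- marker database --------------------------------------------------
  producers <- mags$genome_id[mags$is_producer]
  filtered <- filterHits(hits, cfg$e_cutoff %||% 1e-6)
  profiles <- profilesFromHits(filtered[filtered$genome_id %in% producers, , drop = FALSE],
                               catalog)
  db <- .stage("markers", {
    cov <- familyCoverage(profiles, catalog, genomes = producers)
    sel <- selectMarkers(cov, k = cfg$n_markers %||% 15)
    buildMarkerDatabase(filtered[filtered$genome_id %in% producers, , drop = FALSE],
                        sequences, sel, habitat = cfg$habitat %||% "marine",
                        coverage = cov)
  })
  writeMarkerFasta(db, file.path(cfg$output_dir, "marker_db.fasta"))
  utils::write.table(markerManifest(db),
                     file.path(cfg$output_dir, "marker_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("markers: ", nrow(markerEntries(db)), " sequences, ",
       length(selectedFamilies(db)), " families")

  # --- quantification ---------------------------------------------------
  counts <- if (!is.null(cfg$counts)) {
    .stage("quantify", readCountTable(cfg$counts))
  } else if (!is.null(design)) {
    .stage("quantify", generateMarkerCounts(design, db))$counts
  } else NULL
  abundance <- NULL
  if (!is.null(counts)) {
    abundance <- .stage("quantify", producerAbundance(counts, db))
    writeAbundanceMatrix(abundance$genome,
                         file.path(cfg$output_dir, "genome_abundance.tsv"))
    if (!is.null(taxonomy)) {
      rel <- taxonRelativeAbundance(abundance$genome, taxonomy)
      writeAbundanceMatrix(rel, file.path(cfg$output_dir, "taxon_abundance.tsv"))
    }
    note("quantify: ", length(abundance$sample_total), " samples quantified")
  }

  # --- statistics -------------------------------------------------------
  stats_out <- NULL
  if (!is.null(design) && !is.null(abundance)) {
    stats_out <- .stage("stats", {
      comm <- generateCommunity(design)
      rar <- rarefyCounts(comm, seed = seed)
      ab <- abundance$sample_total_log2[rownames(rar)]
      reg <- linRegress(ab, shannonIndex(rar))
      dx <- communityDistance(matrix(ab, dimnames = list(names(ab), "abund")),
                              "euclidean")
      dy <- communityDistance(sweep(rar, 1, rowSums(rar), "/"), "bray-curtis")
      mt <- mantelTest(dx, dy, permutations = cfg$mantel_permutations %||% 999,
                       seed = seed)
      pw <- generatePathwayMatrix(design)
      vol <- volcanoTable(pw$presence, pw$producer)
      list(shannon = shannonIndex(rar), richness = richnessIndex(rar),
           regression = reg, mantel = mt, volcano = vol)
    })
    jsonlite::write_json(
      list(regression = stats_out$regression, mantel = stats_out$mantel,
           seed = seed),
      file.path(cfg$output_dir, "stats.json"), auto_unbox = TRUE, digits = NA)
    utils::write.table(stats_out$volcano,
                       file.path(cfg$output_dir, "volcano.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("stats: mantel r=", signif(stats_out$mantel$r, 3))
  }

  info <- list(package = "cobatlas",
               version = as.character(utils::packageVersion("cobatlas")),
               seed = seed, config_md5 = cfg$config_md5,
               catalog_version = catalogVersion(catalog))
  jsonlite::write_json(info, file.path(cfg$output_dir, "run_info.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(logLines, file.path(cfg$output_dir, "run.log"))
  invisible(list(mags = mags, summary = summ, db = db, abundance = abundance,
                 stats = stats_out, config = cfg))
}
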