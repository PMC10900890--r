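#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' `catalogFamilies()` returns the family table of a [GeneCatalog-class];
#' `catalogVersion()` its version string; `familiesInSection()` the family ids
#' belonging to one pathway section (for the two corrin-ring branches,
#' `ring_shared` families are included when `expandShared = TRUE`).
#' `selectedFamilies()`, `markerEntries()` and `markerCoverage()` access a
#' [MarkerDatabase-class]; `abundanceValues()`, `featureKind()` and
#' `abundanceTransform()` an [AbundanceMatrix-class].
#'
#' @param x object.
#' @param section a pathway section label.
#' @param expandShared include `ring_shared` families in a ring branch.
#' @return The corresponding slot content (see above).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("catalogFamilies", function(x) standardGeneric("catalogFamilies"))
#' @rdname accessors
#' @export
setGeneric("catalogVersion", function(x) standardGeneric("catalogVersion"))
#' @rdname accessors
#' @export
setGeneric("familiesInSection",
           function(x, section, expandShared = TRUE) standardGeneric("familiesInSection"))
#' @rdname accessors
#' @export
setGeneric("selectedFamilies", function(x) standardGeneric("selectedFamilies"))
#' @rdname accessors
#' @export
setGeneric("markerEntries", function(x) standardGeneric("markerEntries"))
#' @rdname accessors
#' @export
setGeneric("markerCoverage", function(x) standardGeneric("markerCoverage"))
#' @rdname accessors
#' @export
setGeneric("abundanceValues", function(x) standardGeneric("abundanceValues"))
#' @rdname accessors
#' @export
setGeneric("featureKind", function(x) standardGeneric("featureKind"))
#' @rdname accessors
#' @export
setGeneric("abundanceTransform", function(x) standardGeneric("abundanceTransform"))

#' @rdname accessors
#' @export
setMethod("catalogFamilies", "GeneCatalog", function(x) x@families)

#' @rdname accessors
#' @export
setMethod("catalogVersion", "GeneCatalog", function(x) x@version)

#' @rdname accessors
#' @export
setMethod("familiesInSection", "GeneCatalog", function(x, section, expandShared = TRUE) {
  stopifnot(section %in% pathwaySections())
  fam <- x@families
  ids <- fam$family_id[fam$pathway_section == section]
  if (expandShared && section %in% c("ring_aerobic", "ring_anaerobic")) {
    ids <- c(ids, fam$family_id[fam$pathway_section == "ring_shared"])
  }
  ids
})

#' @rdname accessors
#' @export
setMethod("selectedFamilies", "MarkerDatabase", function(x) x@selectedFamilies)

#' @rdname accessors
#' @export
setMethod("markerEntries", "MarkerDatabase", function(x) x@entries)

#' @rdname accessors
#' @export
setMethod("markerCoverage", "MarkerDatabase", function(x) x@coverage)

#' @rdname accessors
#' @export
setMethod("abundanceValues", "AbundanceMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("featureKind", "AbundanceMatrix", function(x) x@featureKind)

#' @rdname accessors
#' @export
setMethod("abundanceTransform", "AbundanceMatrix", function(x) x@transform)

setMethod("show", "GeneCatalog", function(object) {
  fam <- object@families
  cat("GeneCatalog (version ", object@version, "): ",
      nrow(fam), " families\n", sep = "")
  tab <- table(factor(fam$pathway_section, levels = pathwaySections()))
  for (s in names(tab)) cat("  ", format(s, width = 16), tab[[s]], "\n")
})

setMethod("show", "PhenotypeCriteria", function(object) {
  cat("PhenotypeCriteria: very-likely >= ", object@veryLikelyMin,
      ", likely >= ", object@likelyMin,
      ", possible >= ", object@possibleMin,
      if (object@requireLoop) ", loop family required" else "", "\n", sep = "")
})

setMethod("show", "MarkerDatabase", function(object) {
  cat("MarkerDatabase [", object@habitat, "]: ",
      length(object@selectedFamilies), " families, ",
      nrow(object@entries), " sequences from ",
      length(unique(object@entries$genome_id)), " genomes\n", sep = "")
})

setMethod("show", "AbundanceMatrix", function(object) {
  cat("AbundanceMatrix: ", nrow(object@values), " samples x ",
      ncol(object@values), " ", object@featureKind, " features (",
      object@transform, ")\n", sep = "")
})

setMethod("show", "SyntheticDesign", function(object) {
  cat("SyntheticDesign: ", object@nGenomes, " genomes, ",
      object@nSamples, " samples, seed ", object@seed, "\n", sep = "")
})
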