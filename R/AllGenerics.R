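#' @include AllClasses.R
NULL

#' Accessors for PolymerStructure, MotifQuery and MotifIndex
#'
#' \code{structureId} returns the entry identifier; \code{assemblyId} the
#' expanded assembly; \code{residueTable} the per-residue table (locator
#' fields, residue code, representative points); \code{nResidues} the
#' residue count; \code{loadReport} the per-load counters;
#' \code{indexManifest} and \code{indexPath} the manifest and directory of
#' an opened index.
#'
#' @param x A PolymerStructure, MotifQuery or MotifIndex.
#' @return See the individual descriptions.
#' @name accessors
#' @aliases structureId assemblyId residueTable nResidues loadReport
#'   indexManifest indexPath
NULL

#' @rdname accessors
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))
#' @rdname accessors
#' @export
setGeneric("assemblyId", function(x) standardGeneric("assemblyId"))
#' @rdname accessors
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))
#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))
#' @rdname accessors
#' @export
setGeneric("loadReport", function(x) standardGeneric("loadReport"))
#' @rdname accessors
#' @export
setGeneric("indexManifest", function(x) standardGeneric("indexManifest"))
#' @rdname accessors
#' @export
setGeneric("indexPath", function(x) standardGeneric("indexPath"))

#' @rdname accessors
setMethod("structureId", "PolymerStructure", function(x) x@structureId)
#' @rdname accessors
setMethod("assemblyId", "PolymerStructure", function(x) x@assemblyId)
#' @rdname accessors
setMethod("residueTable", "PolymerStructure", function(x) x@residues)
#' @rdname accessors
setMethod("nResidues", "PolymerStructure", function(x) nrow(x@residues))
#' @rdname accessors
setMethod("loadReport", "PolymerStructure", function(x) x@report)
#' @rdname accessors
setMethod("structureId", "MotifQuery", function(x) x@referenceId)
#' @rdname accessors
setMethod("residueTable", "MotifQuery", function(x) x@residues)
#' @rdname accessors
setMethod("nResidues", "MotifQuery", function(x) nrow(x@residues))
#' @rdname accessors
setMethod("indexManifest", "MotifIndex", function(x) x@manifest)
#' @rdname accessors
setMethod("indexPath", "MotifIndex", function(x) x@path)

setMethod("show", "PolymerStructure", function(object) {
  res <- object@residues
  cat("PolymerStructure", object@structureId,
      sprintf("(assembly %s)\n", object@assemblyId))
  cat(sprintf("  %d residues in %d chain copies, %d atoms\n",
              nrow(res), length(unique(paste(res$chain, res$operator))),
              nrow(object@atoms)))
  if (nrow(res)) {
    head <- renderLocator(res$chain[1L], res$operator[1L], res$seq[1L])
    tail <- renderLocator(res$chain[nrow(res)], res$operator[nrow(res)],
                          res$seq[nrow(res)])
    cat(sprintf("  locators %s ... %s\n", head, tail))
  }
  invisible(object)
})

setMethod("show", "MotifQuery", function(object) {
  cat("MotifQuery on", object@referenceId, "\n")
  tok <- vapply(object@allowed, paste, "", collapse = "/")
  loc <- renderLocator(object@residues$chain, object@residues$operator,
                       object@residues$seq)
  cat(sprintf("  role %d: %s [%s]\n", object@residues$role, loc, tok), sep = "")
  cat(sprintf("  %d admissible pair(s) under the 20 A backbone cutoff\n",
              nrow(object@pairs)))
  invisible(object)
})

setMethod("show", "MotifIndex", function(object) {
  m <- object@manifest
  cat("MotifIndex at", object@path, "\n")
  cat(sprintf("  %d structures, %d bins, %d residue-pair occurrences\n",
              length(m$indexed), m$bin_count, m$total_pairs))
  invisible(object)
})
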