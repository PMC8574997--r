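#' Accessors for fpbench S4 classes
#'
#' Small accessor family used instead of direct slot access:
#' `fpValues()` returns the compounds-by-bits matrix, `compoundIds()` its
#' row identifiers, `nBits()`/`fpType()`/`fpSubtype()`/`dataFormat()` the
#' taxonomy tags; `adjacency()`, `adjacencyNorm()`, `nodeFeatures()` and
#' `nodeCount()` expose the molecular-graph slots; `ckaValue()` the scalar
#' alignment of a [SimilarityResult-class].
#'
#' @param object an fpbench S4 object.
#' @return The corresponding slot value.
#' @name fpbench-accessors
NULL

#' @rdname fpbench-accessors
#' @export
setGeneric("fpValues", function(object) standardGeneric("fpValues"))
#' @rdname fpbench-accessors
#' @export
setGeneric("compoundIds", function(object) standardGeneric("compoundIds"))
#' @rdname fpbench-accessors
#' @export
setGeneric("nBits", function(object) standardGeneric("nBits"))
#' @rdname fpbench-accessors
#' @export
setGeneric("fpType", function(object) standardGeneric("fpType"))
#' @rdname fpbench-accessors
#' @export
setGeneric("fpSubtype", function(object) standardGeneric("fpSubtype"))
#' @rdname fpbench-accessors
#' @export
setGeneric("dataFormat", function(object) standardGeneric("dataFormat"))
#' @rdname fpbench-accessors
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))
#' @rdname fpbench-accessors
#' @export
setGeneric("adjacencyNorm", function(object) standardGeneric("adjacencyNorm"))
#' @rdname fpbench-accessors
#' @export
setGeneric("nodeFeatures", function(object) standardGeneric("nodeFeatures"))
#' @rdname fpbench-accessors
#' @export
setGeneric("nodeCount", function(object) standardGeneric("nodeCount"))
#' @rdname fpbench-accessors
#' @export
setGeneric("ckaValue", function(object) standardGeneric("ckaValue"))

#' @rdname fpbench-accessors
setMethod("fpValues", "FingerprintMatrix", function(object) object@values)
#' @rdname fpbench-accessors
setMethod("compoundIds", "FingerprintMatrix", function(object) rownames(object@values))
#' @rdname fpbench-accessors
setMethod("nBits", "FingerprintMatrix", function(object) object@nBits)
#' @rdname fpbench-accessors
setMethod("fpType", "FingerprintMatrix", function(object) object@fpType)
#' @rdname fpbench-accessors
setMethod("fpSubtype", "FingerprintMatrix", function(object) object@fpSubtype)
#' @rdname fpbench-accessors
setMethod("dataFormat", "FingerprintMatrix", function(object) object@dataFormat)

#' @rdname fpbench-accessors
setMethod("adjacency", "MolecularGraph", function(object) object@adjacency)
#' @rdname fpbench-accessors
setMethod("adjacencyNorm", "MolecularGraph", function(object) object@adjNorm)
#' @rdname fpbench-accessors
setMethod("nodeFeatures", "MolecularGraph", function(object) object@nodeFeatures)
#' @rdname fpbench-accessors
setMethod("nodeCount", "MolecularGraph", function(object) nrow(object@adjacency))

#' @rdname fpbench-accessors
setMethod("ckaValue", "SimilarityResult", function(object) object@cka)

setMethod("show", "FingerprintMatrix", function(object) {
  cat(sprintf("FingerprintMatrix: %d compounds x %d bits [%s/%s, %s]\n",
              nrow(object@values), object@nBits, object@fpType,
              object@fpSubtype, object@dataFormat))
  ids <- head(rownames(object@values), 3)
  cat("  compounds: ", paste(ids, collapse = ", "),
      if (nrow(object@values) > 3) ", ..." else "", "\n", sep = "")
})

setMethod("show", "MolecularGraph", function(object) {
  cat(sprintf("MolecularGraph: %d atoms, %d bonds | %s\n",
              nrow(object@adjacency), sum(object@adjacency) / 2, object@smiles))
})

setMethod("show", "SimilarityResult", function(object) {
  cat(sprintf("SimilarityResult: CKA = %.4f (%s estimator, %s mode)\n",
              object@cka, object@estimator, object@mode))
})
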