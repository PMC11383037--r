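#' Accessors for caspevo classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @name caspevo-accessors
NULL

#' @rdname caspevo-accessors
#' @export
setGeneric("speciesName", function(x) standardGeneric("speciesName"))
#' @rdname caspevo-accessors
#' @export
setGeneric("locusSeq", function(x) standardGeneric("locusSeq"))
#' @rdname caspevo-accessors
#' @export
setGeneric("originOffset", function(x) standardGeneric("originOffset"))
#' @rdname caspevo-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname caspevo-accessors
#' @export
setGeneric("refExons", function(x, gene) standardGeneric("refExons"))
#' @rdname caspevo-accessors
#' @export
setGeneric("simLoci", function(x) standardGeneric("simLoci"))
#' @rdname caspevo-accessors
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))
#' @rdname caspevo-accessors
#' @export
setGeneric("simTree", function(x) standardGeneric("simTree"))
#' @rdname caspevo-accessors
#' @export
setGeneric("minExonIdentity", function(x) standardGeneric("minExonIdentity"))

#' @rdname caspevo-accessors
setMethod("speciesName", "GenomicLocus", function(x) x@speciesName)
#' @rdname caspevo-accessors
setMethod("locusSeq", "GenomicLocus", function(x) x@seq)
#' @rdname caspevo-accessors
setMethod("originOffset", "GenomicLocus", function(x) x@originOffset)
#' @rdname caspevo-accessors
setMethod("geneIds", "ReferenceGeneSet", function(x) x@geneIds)
#' @rdname caspevo-accessors
setMethod("refExons", "ReferenceGeneSet", function(x, gene) {
    i <- match(gene, x@geneIds)
    if (is.na(i)) stop("unknown gene: ", gene)
    x@exons[[i]]
})
#' @rdname caspevo-accessors
setMethod("simLoci", "SimulationResult", function(x) x@loci)
#' @rdname caspevo-accessors
setMethod("simTruth", "SimulationResult", function(x) x@truth)
#' @rdname caspevo-accessors
setMethod("simTree", "SimulationResult", function(x) x@tree)
#' @rdname caspevo-accessors
setMethod("minExonIdentity", "PipelineConfig", function(x) x@minExonIdentity)

#' Extract a config value by name
#'
#' @param x a \linkS4class{PipelineConfig}.
#' @param name slot name.
#' @return the slot value.
#' @export
configValue <- function(x, name) {
    stopifnot(is(x, "PipelineConfig"))
    slot(x, name)
}
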