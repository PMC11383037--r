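#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet
NULL

#' Pipeline configuration
#'
#' Holds every threshold applied by the locus analysis stages. Defaults are
#' the working values used throughout: exon hits must reach 60% nucleotide
#' identity and a bit score above 100; a homolog with fewer than 70% of the
#' reference exons is called absent; self-similarity blocks must be at least
#' 1 kb long at 50% identity; species beyond pairwise dS 0.3 from the
#' reference are treated as outgroups; site-level tests run at alpha 0.05
#' with a gene-level Bonferroni level of 3.33e-3; alternate cleavage-site
#' aspartates are searched within +/- 5 residues.
#'
#' @slot minExonIdentity fraction, minimum exon hit identity.
#' @slot minHitScore minimum alignment bit score for an exon hit.
#' @slot minExonFraction fraction of reference exons below which a homolog is
#'   called absent.
#' @slot blockMinLen minimum self-similarity block length (bp).
#' @slot blockMinIdentity minimum self-similarity block identity (fraction).
#' @slot maxPairwiseDs maximum pairwise dS to the reference species for
#'   inclusion in selection analyses.
#' @slot siteAlpha per-site significance level.
#' @slot geneAlphaBonferroni gene/segment-level Bonferroni-corrected level.
#' @slot altCleavageWindow residues searched either side of a cleavage site
#'   for an alternate aspartate.
#' @slot locusFlank bp of flank kept either side of the anchor gene when
#'   extracting a locus.
#' @slot rngSeed integer seed used by seeded stages.
#' @exportClass PipelineConfig
setClass("PipelineConfig", representation(
    minExonIdentity = "numeric",
    minHitScore = "numeric",
    minExonFraction = "numeric",
    blockMinLen = "integer",
    blockMinIdentity = "numeric",
    maxPairwiseDs = "numeric",
    siteAlpha = "numeric",
    geneAlphaBonferroni = "numeric",
    altCleavageWindow = "integer",
    locusFlank = "integer",
    rngSeed = "integer"
))

setValidity("PipelineConfig", function(object) {
    msgs <- character()
    fr <- c(minExonIdentity = object@minExonIdentity,
            minExonFraction = object@minExonFraction,
            blockMinIdentity = object@blockMinIdentity)
    bad <- fr < 0 | fr > 1
    if (any(bad))
        msgs <- c(msgs, paste0(names(fr)[bad], " must lie in [0, 1]"))
    if (object@blockMinLen < 1L)
        msgs <- c(msgs, "blockMinLen must be >= 1")
    if (object@geneAlphaBonferroni > object@siteAlpha)
        msgs <- c(msgs, "geneAlphaBonferroni must not exceed siteAlpha")
    if (object@minHitScore < 0)
        msgs <- c(msgs, "minHitScore must be >= 0")
    if (length(msgs)) msgs else TRUE
})

#' Construct a PipelineConfig
#'
#' @param minExonIdentity,minHitScore,minExonFraction,blockMinLen,blockMinIdentity,maxPairwiseDs,siteAlpha,geneAlphaBonferroni,altCleavageWindow,locusFlank,rngSeed
#'   see the class documentation; all have working defaults.
#' @return A \linkS4class{PipelineConfig}.
#' @examples
#' cfg <- pipelineConfig()
#' minExonIdentity(cfg)
#' @export
pipelineConfig <- function(minExonIdentity = 0.60, minHitScore = 100,
                           minExonFraction = 0.70, blockMinLen = 1000L,
                           blockMinIdentity = 0.50, maxPairwiseDs = 0.3,
                           siteAlpha = 0.05, geneAlphaBonferroni = 3.33e-3,
                           altCleavageWindow = 5L, locusFlank = 175000L,
                           rngSeed = 1L) {
    new("PipelineConfig",
        minExonIdentity = minExonIdentity,
        minHitScore = minHitScore,
        minExonFraction = minExonFraction,
        blockMinLen = as.integer(blockMinLen),
        blockMinIdentity = blockMinIdentity,
        maxPairwiseDs = maxPairwiseDs,
        siteAlpha = siteAlpha,
        geneAlphaBonferroni = geneAlphaBonferroni,
        altCleavageWindow = as.integer(altCleavageWindow),
        locusFlank = as.integer(locusFlank),
        rngSeed = as.integer(rngSeed))
}

#' One species' contiguous locus sequence
#'
#' Coordinates used throughout the package are 0-based half-open on the plus
#' strand of the stored sequence; \code{originOffset} records where the
#' stored slice begins in the source assembly.
#'
#' @slot speciesName species label.
#' @slot seq a \link[Biostrings]{DNAString} over A, C, G, T, N.
#' @slot originOffset 0-based offset of the slice start in the assembly.
#' @exportClass GenomicLocus
setClass("GenomicLocus", representation(
    speciesName = "character",
    seq = "DNAString",
    originOffset = "integer"
))

setValidity("GenomicLocus", function(object) {
    msgs <- character()
    if (length(object@speciesName) != 1L || !nzchar(object@speciesName))
        msgs <- c(msgs, "speciesName must be a single non-empty string")
    if (length(object@seq) == 0L)
        msgs <- c(msgs, "locus sequence must be non-empty")
    if (object@originOffset < 0L)
        msgs <- c(msgs, "originOffset must be >= 0")
    if (length(msgs)) msgs else TRUE
})

#' Construct a GenomicLocus
#'
#' @param speciesName species label.
#' @param seq a \link[Biostrings]{DNAString}, character string, or anything
#'   coercible to \code{DNAString}.
#' @param originOffset 0-based bp offset of the slice in its source assembly.
#' @return A \linkS4class{GenomicLocus}.
#' @export
genomicLocus <- function(speciesName, seq, originOffset = 0L) {
    if (!is(seq, "DNAString")) seq <- DNAString(as.character(seq))
    new("GenomicLocus", speciesName = speciesName, seq = seq,
        originOffset = as.integer(originOffset))
}

#' Reference gene layout for exon annotation
#'
#' Ordered gene records: per gene an identifier, its exon sequences in
#' transcription order, the strand it lies on, and its syntenic slot index
#' along the locus (1 = most upstream on the plus strand).
#'
#' @slot geneIds character vector of unique gene identifiers.
#' @slot exons list of \link[Biostrings]{DNAStringSet}, one per gene, exons
#'   in transcription order.
#' @slot strand character vector of "+" or "-" per gene.
#' @slot slotIndex integer syntenic slot per gene.
#' @exportClass ReferenceGeneSet
setClass("ReferenceGeneSet", representation(
    geneIds = "character",
    exons = "list",
    strand = "character",
    slotIndex = "integer"
))

setValidity("ReferenceGeneSet", function(object) {
    msgs <- character()
    n <- length(object@geneIds)
    if (anyDuplicated(object@geneIds))
        msgs <- c(msgs, "gene ids must be unique")
    if (length(object@exons) != n || length(object@strand) != n ||
        length(object@slotIndex) != n)
        msgs <- c(msgs, "slot lengths must agree")
    if (any(!vapply(object@exons, function(e)
        is(e, "DNAStringSet") && length(e) >= 1L, logical(1))))
        msgs <- c(msgs, "each gene needs at least one exon (DNAStringSet)")
    if (!all(object@strand %in% c("+", "-")))
        msgs <- c(msgs, "strand must be '+' or '-'")
    if (length(msgs)) msgs else TRUE
})

#' Construct a ReferenceGeneSet
#'
#' @param geneIds unique gene identifiers, in syntenic order.
#' @param exons list of \link[Biostrings]{DNAStringSet} (or character
#'   vectors), one per gene, exons in transcription order.
#' @param strand "+" or "-" per gene (recycled).
#' @param slotIndex syntenic slot per gene; defaults to the input order.
#' @return A \linkS4class{ReferenceGeneSet}.
#' @export
referenceGeneSet <- function(geneIds, exons, strand = "+",
                             slotIndex = seq_along(geneIds)) {
    exons <- lapply(exons, function(e)
        if (is(e, "DNAStringSet")) e else DNAStringSet(as.character(e)))
    strand <- rep_len(strand, length(geneIds))
    new("ReferenceGeneSet", geneIds = as.character(geneIds), exons = exons,
        strand = strand, slotIndex = as.integer(slotIndex))
}

#' Result of a locus evolution simulation
#'
#' Bundles the per-species loci emitted by \code{\link{simulateDataset}} with
#' the generating truth: the structural event log, true gene statuses, true
#' exon coordinates, true coding sequences and the per-site omega profiles.
#'
#' @slot loci named list of \linkS4class{GenomicLocus}, one per species.
#' @slot tree the species tree (\code{ape} \code{phylo}).
#' @slot truth list with elements \code{events}, \code{status},
#'   \code{exons}, \code{cds}, \code{omega}.
#' @slot config the \code{simConfig} list used.
#' @exportClass SimulationResult
setClass("SimulationResult", representation(
    loci = "list",
    tree = "ANY",
    truth = "list",
    config = "list"
))

setMethod("show", "PipelineConfig", function(object) {
    cat("PipelineConfig\n")
    cat("  exon hits  : identity >=", object@minExonIdentity,
        ", bit score >=", object@minHitScore, "\n")
    cat("  absence    : exon fraction <", object@minExonFraction, "\n")
    cat("  blocks     : >=", object@blockMinLen, "bp at identity >=",
        object@blockMinIdentity, "\n")
    cat("  selection  : dS <=", object@maxPairwiseDs, ", site alpha",
        object@siteAlpha, ", gene alpha", object@geneAlphaBonferroni, "\n")
    cat("  cleavage   : alternate-D window +/-", object@altCleavageWindow,
        "residues\n")
    cat("  locusFlank :", object@locusFlank, "bp; seed", object@rngSeed, "\n")
})

setMethod("show", "GenomicLocus", function(object) {
    cat("GenomicLocus for", object@speciesName, "--", length(object@seq),
        "bp (assembly offset", object@originOffset, ")\n")
})

setMethod("show", "ReferenceGeneSet", function(object) {
    cat("ReferenceGeneSet with", length(object@geneIds), "genes:\n")
    for (i in seq_along(object@geneIds))
        cat(sprintf("  slot %d  %s (%s)  %d exon(s), %d bp CDS\n",
                    object@slotIndex[i], object@geneIds[i], object@strand[i],
                    length(object@exons[[i]]),
                    sum(Biostrings::width(object@exons[[i]]))))
})

setMethod("show", "SimulationResult", function(object) {
    cat("SimulationResult:", length(object@loci), "species,",
        nrow(object@truth$events), "scripted events,",
        length(unique(object@truth$status$gene)), "genes\n")
})
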