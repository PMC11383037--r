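# Four-way homolog classification (present / partial in-frame / pseudogene /
# absent) with pseudogene lesion evidence and cross-species corroboration.

.globalAlign <- function(a, b) {
    Biostrings::pairwiseAlignment(
        pattern = a, subject = b, type = "global",
        substitutionMatrix = .swSubMat(),
        gapOpening = 6, gapExtension = 1)
}

#' Detect pseudogenizing lesions in a CDS against a reference CDS
#'
#' The query is globally aligned to the reference. Indels whose length is
#' not a multiple of 3 are frameshifts; in-frame stop codons upstream of the
#' reference stop are premature stops; a missing start codon is a lost
#' start. Internal reference exons absent from the gene model are exon-loss
#' lesions (terminal missing exons are truncation evidence handled by the
#' classifier, not lesions).
#'
#' @param cds query coding sequence (character or \code{DNAString}).
#' @param referenceCds reference coding sequence.
#' @param exonPresence optional logical vector: which reference exons the
#'   gene model recovered (in transcription order).
#' @return data.frame of lesions: \code{kind}, \code{cdsPos} (0-based
#'   query-CDS bp for indels, codon index for stops), \code{length}.
#' @export
detectLesions <- function(cds, referenceCds, exonPresence = NULL) {
    cds <- as.character(cds)
    referenceCds <- as.character(referenceCds)
    out <- list()
    if (nchar(cds) > 0) {
        pa <- .globalAlign(cds, referenceCds)
        pat <- strsplit(as.character(Biostrings::alignedPattern(pa)),
                        "")[[1]]
        sub <- strsplit(as.character(Biostrings::alignedSubject(pa)),
                        "")[[1]]
        # indels: runs of gaps in either row
        gapRow <- ifelse(pat == "-", 1L, ifelse(sub == "-", 2L, 0L))
        r <- rle(gapRow)
        qpos <- cumsum(c(0L, as.integer(pat != "-")))  # query bp consumed
        colStart <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
        for (k in seq_along(r$lengths)) {
            if (r$values[k] == 0L) next
            len <- r$lengths[k]
            # terminal gaps reflect length differences, not internal indels
            if (colStart[k] == 1L ||
                colStart[k] + len - 1L == length(pat)) next
            if (len %% 3L == 0L) next
            out[[length(out) + 1L]] <- data.frame(
                kind = "frameshift_indel",
                cdsPos = qpos[colStart[k]],
                length = if (r$values[k] == 1L) len else -len,
                stringsAsFactors = FALSE)
        }
        # premature stops: translate the query in frame 0 and compare to the
        # reference stop position
        aa <- .translateCodons(.splitCodons(cds))
        refAA <- .translateCodons(.splitCodons(referenceCds))
        refStop <- which(refAA == "*")
        refStop <- if (length(refStop)) refStop[length(refStop)] else
            length(refAA) + 1L
        qStops <- which(aa == "*")
        qStops <- qStops[qStops < refStop]
        for (s in qStops)
            out[[length(out) + 1L]] <- data.frame(
                kind = "premature_stop", cdsPos = s, length = 0L,
                stringsAsFactors = FALSE)
        if (substr(referenceCds, 1L, 3L) == "ATG" &&
            substr(cds, 1L, 3L) != "ATG")
            out[[length(out) + 1L]] <- data.frame(
                kind = "lost_start", cdsPos = 1L, length = 0L,
                stringsAsFactors = FALSE)
    }
    if (!is.null(exonPresence)) {
        miss <- which(!exonPresence)
        lastPresent <- if (any(exonPresence)) max(which(exonPresence)) else 0L
        for (e in miss) {
            if (e > lastPresent) next  # terminal truncation, not a lesion
            if (e == 1L && !exonPresence[1L]) next  # leading truncation
            out[[length(out) + 1L]] <- data.frame(
                kind = "exon_loss", cdsPos = e, length = 0L,
                stringsAsFactors = FALSE)
        }
    }
    if (!length(out))
        return(data.frame(kind = character(0), cdsPos = integer(0),
                          length = integer(0)))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Classify a homolog into the four-way status
#'
#' Decision order: (1) fewer than \code{minExonFraction} of the reference
#' exons recovered (or no hits) gives \code{absent}; (2) lesion-free and
#' aligned over (at least 95% of) the full reference length gives
#' \code{present}; (3) lesion-free but shorter in-frame span, or partial
#' in-frame transcript evidence, gives \code{partial_in_frame}; (4)
#' otherwise \code{pseudogene}.
#'
#' @param completeness fraction of reference exons recovered.
#' @param cds assembled CDS (character), may be \code{NULL} when absent.
#' @param referenceCds reference CDS.
#' @param lesions data.frame from \code{\link{detectLesions}}.
#' @param transcriptSupport one of \code{"full"}, \code{"partial"},
#'   \code{"none"}, \code{"not_checked"}.
#' @param config a \linkS4class{PipelineConfig}.
#' @param fullLengthFraction aligned-span fraction counting as full length.
#' @return list with \code{call}, \code{completeness}, \code{lesions},
#'   \code{transcriptSupport}, \code{spanFraction}.
#' @export
classifyGeneStatus <- function(completeness, cds, referenceCds, lesions,
                               transcriptSupport = "not_checked",
                               config = pipelineConfig(),
                               fullLengthFraction = 0.95) {
    spanFraction <- if (is.null(cds) || nchar(as.character(cds)) == 0L) 0
        else min(1, nchar(as.character(cds)) /
                     nchar(as.character(referenceCds)))
    call <- if (is.na(completeness) || completeness < config@minExonFraction)
        "absent"
    else if (nrow(lesions) == 0L && spanFraction >= fullLengthFraction)
        "present"
    else if (nrow(lesions) == 0L ||
             (transcriptSupport == "partial" && nrow(lesions) == 0L))
        "partial_in_frame"
    else "pseudogene"
    list(call = call, completeness = completeness, lesions = lesions,
         transcriptSupport = transcriptSupport,
         spanFraction = spanFraction)
}

#' Corroborate lesions across species
#'
#' A lesion found at the homologous position (same kind, position within
#' \code{posTol}) in at least one other species is marked shared, supporting
#' a real event; a lesion unique to one assembly is flagged low-confidence
#' (candidate assembly error).
#'
#' @param lesionsBySpecies named list of lesion data.frames (per species),
#'   positions in homologous (reference-aligned) coordinates.
#' @param posTol coordinate tolerance in bp/codons.
#' @return one data.frame with \code{species}, the lesion columns,
#'   \code{sharedWith} (comma-joined species, "" if none) and
#'   \code{lowConfidence}.
#' @export
corroborateLesions <- function(lesionsBySpecies, posTol = 3L) {
    rows <- list()
    for (sp in names(lesionsBySpecies)) {
        les <- lesionsBySpecies[[sp]]
        if (is.null(les) || nrow(les) == 0L) next
        for (i in seq_len(nrow(les))) {
            shared <- character(0)
            for (other in setdiff(names(lesionsBySpecies), sp)) {
                lo <- lesionsBySpecies[[other]]
                if (is.null(lo) || nrow(lo) == 0L) next
                hit <- lo$kind == les$kind[i] &
                    abs(lo$cdsPos - les$cdsPos[i]) <= posTol
                if (any(hit)) shared <- c(shared, other)
            }
            rows[[length(rows) + 1L]] <- data.frame(
                species = sp, kind = les$kind[i], cdsPos = les$cdsPos[i],
                length = les$length[i],
                sharedWith = paste(shared, collapse = ","),
                lowConfidence = length(shared) == 0L,
                stringsAsFactors = FALSE)
        }
    }
    if (!length(rows))
        return(data.frame(species = character(0), kind = character(0),
                          cdsPos = integer(0), length = integer(0),
                          sharedWith = character(0),
                          lowConfidence = logical(0)))
    do.call(rbind, rows)
}

#' Check transcript evidence for a CDS
#'
#' @param cds assembled CDS (character).
#' @param transcripts optional \link[Biostrings]{DNAStringSet} (or character
#'   vector) of transcript sequences; \code{NULL} means not checked.
#' @param partialFraction minimum in-frame fraction of the CDS counting as
#'   partial support.
#' @return \code{"full"}, \code{"partial"}, \code{"none"} or
#'   \code{"not_checked"}.
#' @export
checkTranscriptSupport <- function(cds, transcripts = NULL,
                                   partialFraction = 0.5) {
    if (is.null(transcripts)) return("not_checked")
    cds <- as.character(cds)
    trs <- as.character(transcripts)
    if (any(vapply(trs, function(t) grepl(cds, t, fixed = TRUE),
                   logical(1))))
        return("full")
    bestFrac <- 0
    for (t in trs) {
        pa <- Biostrings::pairwiseAlignment(
            pattern = cds, subject = t, type = "local",
            substitutionMatrix = .swSubMat(), gapOpening = 6,
            gapExtension = 1)
        if (Biostrings::score(pa) <= 0) next
        alnLen <- Biostrings::nchar(pa)
        if (Biostrings::nmatch(pa) / alnLen < 0.95) next
        ps <- Biostrings::start(Biostrings::pattern(pa))
        ss <- Biostrings::start(Biostrings::subject(pa))
        frac <- Biostrings::width(Biostrings::pattern(pa)) / nchar(cds)
        bestFrac <- max(bestFrac, frac)
    }
    if (bestFrac >= partialFraction) "partial" else "none"
}

#' Per-species, per-gene status matrix
#'
#' Runs annotation, CDS assembly, lesion detection and classification for
#' every locus against the reference gene set, then writes (optionally) a
#' status TSV in the 1 / 0 / -1 / '*' encoding (present / pseudogene /
#' absent / partial in-frame).
#'
#' @param loci named list of \linkS4class{GenomicLocus} (or sequences).
#' @param reference a \linkS4class{ReferenceGeneSet}.
#' @param referenceCds named character vector of reference CDS per gene; by
#'   default assembled by concatenating the reference exons.
#' @param config a \linkS4class{PipelineConfig}.
#' @param transcripts optional named list (per species) of named transcript
#'   sets (per gene).
#' @param path optional TSV output path.
#' @param clusterGap passed to \code{\link{assignHitsToGenes}}.
#' @return data.frame: \code{species}, \code{gene}, \code{status},
#'   \code{completeness}, \code{nLesions}, \code{transcriptSupport}.
#' @export
geneStatusMatrix <- function(loci, reference, referenceCds = NULL,
                             config = pipelineConfig(), transcripts = NULL,
                             path = NULL, clusterGap = 2500L) {
    stopifnot(is(reference, "ReferenceGeneSet"))
    if (is.null(referenceCds)) {
        referenceCds <- vapply(reference@exons, function(e)
            paste(as.character(e), collapse = ""), character(1))
        names(referenceCds) <- reference@geneIds
    }
    nExonsRef <- stats::setNames(vapply(reference@exons, length,
                                        integer(1)), reference@geneIds)
    rows <- list()
    for (sp in names(loci)) {
        hits <- findExonHits(loci[[sp]], reference, config)
        asg <- assignHitsToGenes(hits, reference, clusterGap = clusterGap)
        for (g in reference@geneIds) {
            mrow <- asg$models[asg$models$refGene == g &
                               asg$models$gene == g, , drop = FALSE]
            if (nrow(mrow) == 0L) {
                rows[[length(rows) + 1L]] <- data.frame(
                    species = sp, gene = g, status = "absent",
                    completeness = 0, nLesions = NA_integer_,
                    transcriptSupport = "not_checked",
                    stringsAsFactors = FALSE)
                next
            }
            ex <- asg$exons[asg$exons$model == g, , drop = FALSE]
            cdsObj <- assembleCds(ex, loci[[sp]])
            present <- seq_len(nExonsRef[[g]]) %in% ex$exon
            lesions <- detectLesions(cdsObj$seq, referenceCds[[g]],
                                     exonPresence = present)
            trSup <- if (!is.null(transcripts) &&
                         !is.null(transcripts[[sp]][[g]]))
                checkTranscriptSupport(cdsObj$seq, transcripts[[sp]][[g]])
                else "not_checked"
            cls <- classifyGeneStatus(mrow$completeness[1L], cdsObj$seq,
                                      referenceCds[[g]], lesions, trSup,
                                      config)
            rows[[length(rows) + 1L]] <- data.frame(
                species = sp, gene = g, status = cls$call,
                completeness = cls$completeness, nLesions = nrow(lesions),
                transcriptSupport = trSup, stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    if (!is.null(path)) writeStatusTsv(out, path)
    out
}

#' Write / read a status matrix TSV
#'
#' Encoding mirrors the conventional presence table: 1 = present, 0 =
#' pseudogene, -1 = absent, '*' = partial in-frame.
#'
#' @param status data.frame with \code{species}, \code{gene}, \code{status}.
#' @param path TSV path.
#' @return \code{readStatusTsv} returns the long-format data.frame.
#' @export
writeStatusTsv <- function(status, path) {
    code <- c(present = "1", pseudogene = "0", absent = "-1",
              partial_in_frame = "*")
    wide <- stats::reshape(
        data.frame(species = status$species, gene = status$gene,
                   code = code[status$status], stringsAsFactors = FALSE),
        idvar = "species", timevar = "gene", direction = "wide")
    names(wide) <- sub("^code\\.", "", names(wide))
    utils::write.table(wide, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeStatusTsv
#' @export
readStatusTsv <- function(path) {
    wide <- utils::read.delim(path, check.names = FALSE,
                              stringsAsFactors = FALSE,
                              colClasses = "character", comment.char = "#")
    genes <- setdiff(names(wide), "species")
    decode <- c("1" = "present", "0" = "pseudogene", "-1" = "absent",
                "*" = "partial_in_frame")
    out <- do.call(rbind, lapply(genes, function(g)
        data.frame(species = wide$species, gene = g,
                   status = unname(decode[as.character(wide[[g]])]),
                   stringsAsFactors = FALSE)))
    rownames(out) <- NULL
    out
}
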