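# Classification of inbred-strain missense variants by cross-species
# conservation, strain recommendations, and detection of variants that
# restore the reading frame of a frameshifted reference gene model.

#' Read a strain variant table (TSV)
#'
#' Expected columns: \code{strain}, \code{gene}, \code{variant} (HGVS-like
#' protein change, e.g. "V60A", or an indel descriptor such as "5bp_del" /
#' "1bp_ins"); optional \code{class} (pre-computed classification:
#' \code{potential_impact} / \code{unlikely} / \code{unknown}).
#'
#' @param path TSV path; lines starting with '#' are comments.
#' @return data.frame with the columns above plus parsed \code{refResidue},
#'   \code{position}, \code{altResidue}, \code{type}
#'   (\code{missense}/\code{indel}).
#' @export
readVariantTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            comment.char = "#")
    need <- c("strain", "gene", "variant")
    if (!all(need %in% names(df)))
        stop("variant table needs columns: ", paste(need, collapse = ", "))
    mis <- regmatches(df$variant,
                      regexec("^([A-Y])([0-9]+)([A-Y])$", df$variant))
    df$type <- ifelse(vapply(mis, length, integer(1)) == 4L, "missense",
                      "indel")
    df$refResidue <- vapply(mis, function(m)
        if (length(m) == 4L) m[2L] else NA_character_, character(1))
    df$position <- vapply(mis, function(m)
        if (length(m) == 4L) as.integer(m[3L]) else NA_integer_, integer(1))
    df$altResidue <- vapply(mis, function(m)
        if (length(m) == 4L) m[4L] else NA_character_, character(1))
    bad <- df$type == "missense" & df$refResidue == df$altResidue
    if (any(bad)) stop("missense variants must change the residue: ",
                       paste(df$variant[bad], collapse = ", "))
    df
}

#' Classify a missense variant by cross-species conservation
#'
#' Rule order: (1) if the alternate residue occurs in any comparison
#' species at the homologous column, the variant is \code{unlikely} to
#' affect function; (2) otherwise, if the column is invariant across the
#' comparison set (optionally near-invariant), the variant has
#' \code{potential_impact}; (3) otherwise \code{unknown}. A column with no
#' residues (all gaps) yields \code{unknown}.
#'
#' @param altResidue the variant residue (single letter).
#' @param column character vector of residues at the homologous alignment
#'   column across the comparison species (gaps as "-").
#' @param nearInvariantFraction if non-NULL (e.g. 0.9), the column counts
#'   as conserved when the majority residue reaches this frequency;
#'   default NULL = strict invariance.
#' @return list with \code{class} and \code{rationale}.
#' @export
classifyVariant <- function(altResidue, column,
                            nearInvariantFraction = NULL) {
    res <- column[!is.na(column) & column != "-"]
    if (!length(res))
        return(list(class = "unknown",
                    rationale = "column gapped in all comparison species"))
    if (altResidue %in% res)
        return(list(class = "unlikely",
                    rationale = "alternate residue present in other species"))
    tab <- table(res)
    conserved <- if (is.null(nearInvariantFraction)) length(tab) == 1L
        else max(tab) / length(res) >= nearInvariantFraction
    if (conserved)
        return(list(class = "potential_impact",
                    rationale = sprintf(
                        "column conserved (%s) across %d species",
                        names(tab)[which.max(tab)], length(res))))
    list(class = "unknown",
         rationale = "column variable and alternate residue unobserved")
}

#' Flag strains to avoid / use for a set of genes of interest
#'
#' A strain is flagged \code{avoid} when it carries at least one variant in
#' a gene of interest classified \code{potential_impact} or \code{unknown};
#' \code{clean} when it carries no variant in any listed gene; otherwise
#' \code{caution} (only \code{unlikely} variants).
#'
#' @param variants data.frame from \code{\link{readVariantTable}} with a
#'   \code{class} column (from the table or
#'   \code{\link{classifyVariant}}).
#' @param genesOfInterest character vector of gene labels.
#' @param allStrains optional character vector of all strains surveyed
#'   (strains without variants are inferred from it).
#' @return data.frame: \code{strain}, \code{flag}, \code{nVariants},
#'   \code{nImpactOrUnknown}.
#' @export
recommendStrains <- function(variants, genesOfInterest,
                             allStrains = NULL) {
    if (is.null(allStrains)) allStrains <- unique(variants$strain)
    v <- variants[variants$gene %in% genesOfInterest, , drop = FALSE]
    rows <- lapply(allStrains, function(s) {
        vs <- v[v$strain == s, , drop = FALSE]
        nBad <- sum(vs$class %in% c("potential_impact", "unknown"))
        flag <- if (nrow(vs) == 0L) "clean"
            else if (nBad > 0L) "avoid" else "caution"
        data.frame(strain = s, flag = flag, nVariants = nrow(vs),
                   nImpactOrUnknown = nBad, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Detect a frame-restoring indel variant
#'
#' Tests whether applying an indel variant to a reference CDS that is
#' frameshifted relative to its homologs yields a full-length, stop-free
#' translation aligning across the homolog length. When the variant is
#' carried by every strain surveyed, an assembly-error note is emitted:
#' the reference assembly, not the strains, likely carries the error.
#'
#' @param indelLen signed indel length in bp (+ insertion, - deletion).
#' @param cdsPos 0-based CDS position of the indel.
#' @param insertSeq bases to insert (for insertions; defaults to "A"s).
#' @param referenceCds the (frameshifted) reference CDS.
#' @param homologCds named character vector of intact homolog CDSs.
#' @param carriedByAllStrains logical; TRUE when every surveyed strain has
#'   the variant.
#' @return list with \code{restoresFrame} (logical) and \code{note}
#'   (character, "" unless an assembly error is suspected).
#' @export
detectFrameRestoration <- function(indelLen, cdsPos, referenceCds,
                                   homologCds, insertSeq = NULL,
                                   carriedByAllStrains = FALSE) {
    ref <- as.character(referenceCds)
    if (indelLen > 0) {
        ins <- if (!is.null(insertSeq)) insertSeq else
            strrep("A", indelLen)
        mut <- paste0(substr(ref, 1L, cdsPos), ins,
                      substr(ref, cdsPos + 1L, nchar(ref)))
    } else {
        mut <- paste0(substr(ref, 1L, cdsPos),
                      substr(ref, cdsPos - indelLen + 1L, nchar(ref)))
    }
    aa <- .translateCodons(.splitCodons(mut))
    internalStops <- sum(aa[-length(aa)] == "*")
    fullLen <- length(aa) - sum(aa == "*")
    restores <- FALSE
    if (internalStops == 0L) {
        homLens <- nchar(as.character(homologCds)) / 3 - 1  # minus stop
        restores <- all(fullLen >= 0.95 * homLens)
        if (restores) {
            # the unmodified reference must itself be broken for the
            # variant to "restore" anything
            aaRef <- .translateCodons(.splitCodons(ref))
            refBroken <- sum(aaRef[-length(aaRef)] == "*") > 0L ||
                (nchar(ref) %% 3L) != 0L ||
                any(nchar(ref) / 3 < 0.95 * homLens)
            restores <- refBroken
        }
    }
    note <- if (restores && carriedByAllStrains)
        paste("variant carried by all strains and restores the reading",
              "frame: probable reference assembly error") else ""
    list(restoresFrame = restores, note = note)
}
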