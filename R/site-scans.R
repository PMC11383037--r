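# Conservation scan of the aspartate self-cleavage sites (CARD-p20,
# p20-linker, linker-p10 boundaries) across a protein alignment.

#' Scan aspartate cleavage sites across a protein alignment
#'
#' Site positions are given in reference-sequence residue coordinates and
#' lifted through the alignment. For every species and site the aligned
#' residue is reported, whether it is an aspartate, and whether an
#' alternate D lies within \code{altCleavageWindow} residues (gap columns
#' skipped).
#'
#' @param aln named \link[Biostrings]{AAStringSet} or character vector of
#'   aligned protein sequences (equal widths).
#' @param referenceSpecies name of the reference sequence.
#' @param siteResidues named integer vector: site label -> 1-based residue
#'   position in the ungapped reference sequence.
#' @param config a \linkS4class{PipelineConfig}.
#' @return data.frame: \code{species}, \code{site}, \code{column},
#'   \code{residue}, \code{aspartateAtSite}, \code{alternateD},
#'   \code{alternateOffset} (signed residue offset, NA if none).
#' @export
scanCleavageSites <- function(aln, referenceSpecies, siteResidues,
                              config = pipelineConfig()) {
    seqs <- .seqVector(aln)
    if (!referenceSpecies %in% names(seqs))
        stop("reference species not in alignment")
    w <- unique(nchar(seqs))
    if (length(w) != 1L) stop("alignment widths differ")
    refChars <- strsplit(seqs[[referenceSpecies]], "")[[1]]
    refResAt <- cumsum(refChars != "-")
    cols <- vapply(siteResidues, function(r) {
        i <- which(refResAt == r & refChars != "-")
        if (!length(i)) stop("site residue ", r,
                             " is gapped out of the reference")
        i[1L]
    }, integer(1))
    win <- config@altCleavageWindow
    rows <- list()
    for (sp in names(seqs)) {
        chars <- strsplit(seqs[[sp]], "")[[1]]
        for (k in seq_along(cols)) {
            col <- cols[k]
            res <- chars[col]
            isD <- !is.na(res) && res == "D"
            altOff <- NA_integer_
            if (!isD) {
                # walk outward, counting non-gap residues of this species
                for (offset in seq_len(win)) {
                    for (dir in c(1L, -1L)) {
                        cnt <- 0L; j <- col
                        while (cnt < offset) {
                            j <- j + dir
                            if (j < 1L || j > w) break
                            if (chars[j] != "-") cnt <- cnt + 1L
                        }
                        if (cnt == offset && j >= 1L && j <= w &&
                            chars[j] == "D") {
                            altOff <- offset * dir
                            break
                        }
                    }
                    if (!is.na(altOff)) break
                }
            }
            rows[[length(rows) + 1L]] <- data.frame(
                species = sp, site = names(cols)[k], column = col,
                residue = res, aspartateAtSite = isD,
                alternateD = !is.na(altOff), alternateOffset = altOff,
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
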