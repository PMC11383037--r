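# Exon annotation: locate reference exons in a locus by seeded local
# alignment, assign hits to genes by synteny, assemble in-frame CDSs.

.KMER <- 12L

# integer k-mer codes for every position of a sequence (NA across Ns)
.kmerCodes <- function(s, k = .KMER) {
    ints <- match(strsplit(as.character(s), "")[[1]], .INT2NT)
    n <- length(ints)
    if (n < k) return(integer(0))
    m <- stats::embed(ints - 1L, k)      # row i: x[i+k-1] ... x[i]
    as.numeric(m %*% 4^(seq_len(k) - 1L))
}

.kmerTable <- function(s, k = .KMER) {
    codes <- .kmerCodes(s, k)
    data.table::data.table(code = codes,
                           pos = seq_along(codes))[!is.na(code)]
}

# raw Smith-Waterman score -> bit score (BLASTN-like parameters)
.bitScore <- function(raw, lambda = 0.625, K = 0.41) {
    (lambda * raw - log(K)) / log(2)
}

.swSubMat <- function() {
    .cached("submat", function()
        Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                 baseOnly = TRUE))
}

# local alignment of query against a subject window; returns NULL or a hit
.alignWindow <- function(query, subject) {
    pa <- Biostrings::pairwiseAlignment(
        pattern = query, subject = subject, type = "local",
        substitutionMatrix = .swSubMat(), gapOpening = 1, gapExtension = 1)
    raw <- Biostrings::score(pa)
    if (raw <= 0) return(NULL)
    cols <- Biostrings::nchar(pa)
    list(raw = raw,
         identity = Biostrings::nmatch(pa) / cols,
         sStart = Biostrings::start(Biostrings::subject(pa)),
         sEnd = Biostrings::end(Biostrings::subject(pa)),
         pStart = Biostrings::start(Biostrings::pattern(pa)),
         pEnd = Biostrings::end(Biostrings::pattern(pa)))
}

# cluster seed pairs into candidate windows
.seedClusters <- function(qpos, spos, qlen, diagTol = 40L, gapTol = 400L) {
    dt <- data.table::data.table(qpos = qpos, spos = spos,
                                 diag = spos - qpos)
    data.table::setorder(dt, diag, spos)
    grp <- integer(nrow(dt))
    g <- 0L
    lastDiag <- -Inf; lastPos <- -Inf
    for (i in seq_len(nrow(dt))) {
        if (dt$diag[i] - lastDiag > diagTol) {
            g <- g + 1L
        } else if (dt$spos[i] - lastPos > gapTol) {
            g <- g + 1L
        }
        grp[i] <- g
        lastDiag <- dt$diag[i]; lastPos <- dt$spos[i]
    }
    dt$grp <- grp
    # merge clusters whose subject extents overlap (same region, shifted
    # diagonals)
    ext <- dt[, list(s1 = min(spos), s2 = max(spos)), by = "grp"]
    ext <- ext[order(ext$s1)]
    merged <- integer(nrow(ext))
    mg <- 0L; lastEnd <- -Inf
    for (i in seq_len(nrow(ext))) {
        if (ext$s1[i] > lastEnd + qlen) mg <- mg + 1L
        merged[i] <- mg
        lastEnd <- max(lastEnd, ext$s2[i])
    }
    ext$mgrp <- merged
    ext[, list(s1 = min(s1), s2 = max(s2)), by = "mgrp"]
}

#' Find reference exons in a locus
#'
#' Each reference exon is searched on both strands by exact k-mer seeding
#' followed by local (Smith-Waterman) alignment of candidate windows, with
#' match +1, mismatch -2, gap open -2/extend -1 scoring and BLASTN-style bit
#' scores. Hits must reach \code{minExonIdentity} (identity counts gap
#' columns as mismatches) and \code{minHitScore} bits.
#'
#' @param locus a \linkS4class{GenomicLocus}, \code{DNAString} or character.
#' @param referenceExons a \linkS4class{ReferenceGeneSet}, or a named list of
#'   \link[Biostrings]{DNAStringSet} (one per gene).
#' @param config a \linkS4class{PipelineConfig}.
#' @return data.frame of hits sorted by locus coordinate: \code{gene},
#'   \code{exon}, \code{start0}, \code{end0} (0-based half-open),
#'   \code{strand}, \code{identity}, \code{score} (bits).
#' @export
findExonHits <- function(locus, referenceExons, config = pipelineConfig()) {
    locSeq <- if (is(locus, "GenomicLocus"))
        as.character(locusSeq(locus)) else as.character(locus)
    if (is(referenceExons, "ReferenceGeneSet")) {
        exonList <- referenceExons@exons
        names(exonList) <- referenceExons@geneIds
    } else exonList <- referenceExons
    locDT <- .kmerTable(locSeq)
    data.table::setkey(locDT, code)
    out <- list()
    for (g in names(exonList)) {
        exs <- exonList[[g]]
        for (e in seq_along(exs)) {
            for (strand in c("+", "-")) {
                q <- as.character(exs[[e]])
                if (strand == "-")
                    q <- as.character(Biostrings::reverseComplement(
                        Biostrings::DNAString(q)))
                qlen <- nchar(q)
                if (qlen < .KMER || nchar(locSeq) < .KMER) next
                qDT <- .kmerTable(q)
                if (nrow(qDT) == 0L) next
                hits <- locDT[qDT, on = "code", nomatch = NULL,
                              allow.cartesian = TRUE]
                if (nrow(hits) == 0L) next
                wins <- .seedClusters(hits$i.pos, hits$pos, qlen)
                for (w in seq_len(nrow(wins))) {
                    ws <- max(1L, wins$s1[w] - qlen)
                    we <- min(nchar(locSeq), wins$s2[w] + .KMER + qlen)
                    al <- .alignWindow(q, substr(locSeq, ws, we))
                    if (is.null(al)) next
                    bits <- .bitScore(al$raw)
                    if (al$identity < config@minExonIdentity ||
                        bits < config@minHitScore) next
                    # extend the hit across unaligned exon ends (terminal
                    # mismatches must not truncate the exon interval); the
                    # searched query is already strand-oriented, so its
                    # prefix/suffix extend left/right on the locus
                    s0 <- max(0L, ws + al$sStart - 2L - (al$pStart - 1L))
                    e0 <- min(nchar(locSeq),
                              ws + al$sEnd - 1L + (qlen - al$pEnd))
                    out[[length(out) + 1L]] <- data.frame(
                        gene = g, exon = e,
                        start0 = s0, end0 = e0,
                        strand = strand, identity = al$identity,
                        score = bits, stringsAsFactors = FALSE)
                }
            }
        }
    }
    if (!length(out))
        return(data.frame(gene = character(0), exon = integer(0),
                          start0 = integer(0), end0 = integer(0),
                          strand = character(0), identity = numeric(0),
                          score = numeric(0)))
    hits <- do.call(rbind, out)
    # overlapping hits for the same (gene, exon): keep highest score, then
    # highest identity, then leftmost
    hits <- hits[order(hits$gene, hits$exon, -hits$score, -hits$identity,
                       hits$start0), ]
    keep <- rep(TRUE, nrow(hits))
    for (i in seq_len(nrow(hits))) {
        if (!keep[i]) next
        j <- which(keep & seq_len(nrow(hits)) > i &
                   hits$gene == hits$gene[i] & hits$exon == hits$exon[i] &
                   hits$start0 < hits$end0[i] & hits$end0 > hits$start0[i])
        keep[j] <- FALSE
    }
    hits <- hits[keep, ]
    hits <- hits[order(hits$start0, hits$end0, hits$gene, hits$exon), ]
    rownames(hits) <- NULL
    hits
}

#' Assign exon hits to gene models by synteny
#'
#' Hits are clustered along the locus into candidate gene regions; clusters
#' are then matched to the reference syntenic slot order by an
#' order-preserving dynamic program that maximizes total bit score (ties
#' broken toward the upstream slot). A slot matched by more than one cluster
#' yields duplicate models (suffix \code{"_dup"}). Within a cluster, each
#' reference exon index is filled by the best available hit, preferring hits
#' labeled with the assigned gene (synteny rescue of cross-paralog matches).
#'
#' @param hits data.frame from \code{\link{findExonHits}}.
#' @param referenceLayout a \linkS4class{ReferenceGeneSet}.
#' @param clusterGap bp gap above which consecutive hits start a new
#'   cluster; must exceed the largest intron and stay below the smallest
#'   intergenic distance.
#' @return list with \code{models} (one row per gene model: \code{gene},
#'   \code{refGene}, \code{slot}, \code{start0}, \code{end0}, \code{strand},
#'   \code{nExonsFound}, \code{completeness}), \code{exons} (assigned exon
#'   hits with a \code{model} column) and \code{unassigned} (leftover hits).
#' @export
assignHitsToGenes <- function(hits, referenceLayout, clusterGap = 2500L) {
    stopifnot(is(referenceLayout, "ReferenceGeneSet"))
    refIds <- referenceLayout@geneIds[order(referenceLayout@slotIndex)]
    nExonsRef <- vapply(referenceLayout@exons, length,
                        integer(1))[order(referenceLayout@slotIndex)]
    names(nExonsRef) <- refIds
    emptyModels <- data.frame(gene = character(0), refGene = character(0),
                              slot = integer(0), start0 = integer(0),
                              end0 = integer(0), strand = character(0),
                              nExonsFound = integer(0),
                              completeness = numeric(0))
    if (nrow(hits) == 0L)
        return(list(models = emptyModels, exons = cbind(hits,
                    model = character(0)), unassigned = hits))
    hits <- hits[order(hits$start0), ]
    cl <- cumsum(c(1L, as.integer(
        hits$start0[-1L] > cummax(hits$end0)[-nrow(hits)] + clusterGap)))
    hits$cluster <- cl
    m <- max(cl)
    n <- length(refIds)
    sc <- matrix(0, m, n)   # cluster x slot total score
    for (i in seq_len(m)) {
        h <- hits[hits$cluster == i, ]
        for (j in seq_len(n)) {
            hj <- h[h$gene == refIds[j], ]
            if (nrow(hj)) {
                best <- tapply(hj$score, hj$exon, max)
                sc[i, j] <- sum(best)
            }
        }
    }
    # DP over ordered clusters x ordered slots: g[i+1, j+1] = best total
    # score for clusters 1..i when the last assigned slot is j (0 = none).
    # The assigned-slot sequence must be non-decreasing; reusing a slot
    # (tandem duplicates) carries a tiny penalty so distinct slots are
    # preferred on ties, and a yet smaller bias prefers the upstream slot.
    epsReuse <- 1e-6
    epsSlot <- 1e-9
    g <- matrix(-Inf, m + 1L, n + 1L)
    g[1L, 1L] <- 0
    from <- array(0L, dim = c(m + 1L, n + 1L, 2L))  # (prev j, assigned)
    for (i in seq_len(m)) {
        for (j in 0:n) {
            if (!is.finite(g[i, j + 1L])) next
            # cluster i unassigned
            if (g[i, j + 1L] > g[i + 1L, j + 1L]) {
                g[i + 1L, j + 1L] <- g[i, j + 1L]
                from[i + 1L, j + 1L, ] <- c(j, 0L)
            }
            # assign cluster i to a slot jp >= max(j, 1)
            for (jp in max(j, 1L):n) {
                v <- g[i, j + 1L] + sc[i, jp] -
                    (if (jp == j) epsReuse else 0) - epsSlot * jp
                if (v > g[i + 1L, jp + 1L]) {
                    g[i + 1L, jp + 1L] <- v
                    from[i + 1L, jp + 1L, ] <- c(j, 1L)
                }
            }
        }
    }
    assignSlot <- integer(m)
    j <- which.max(g[m + 1L, ]) - 1L
    for (i in rev(seq_len(m))) {
        prev <- from[i + 1L, j + 1L, ]
        assignSlot[i] <- if (prev[2L] == 1L) j else 0L
        j <- prev[1L]
    }
    usedCount <- integer(n)
    models <- list(); exonRows <- list(); unassigned <- list()
    for (i in seq_len(m)) {
        h <- hits[hits$cluster == i, ]
        j <- assignSlot[i]
        if (j == 0L || sc[i, j] <= 0) {
            unassigned[[length(unassigned) + 1L]] <- h
            next
        }
        refGene <- refIds[j]
        usedCount[j] <- usedCount[j] + 1L
        modelGene <- if (usedCount[j] == 1L) refGene else
            paste0(refGene, "_dup",
                   if (usedCount[j] > 2L) usedCount[j] - 1L else "")
        chosen <- list()
        for (e in seq_len(nExonsRef[[refGene]])) {
            he <- h[h$exon == e, ]
            if (nrow(he) == 0L) next
            pref <- he[he$gene == refGene, ]
            if (nrow(pref)) he <- pref
            he <- he[order(-he$score, -he$identity, he$start0), ]
            chosen[[length(chosen) + 1L]] <- he[1L, ]
        }
        if (!length(chosen)) {
            unassigned[[length(unassigned) + 1L]] <- h
            next
        }
        ex <- do.call(rbind, chosen)
        chosenKey <- paste(ex$gene, ex$exon, ex$start0)
        rest <- h[!paste(h$gene, h$exon, h$start0) %in% chosenKey, ]
        if (nrow(rest))
            unassigned[[length(unassigned) + 1L]] <- rest
        ex$model <- modelGene
        ex$gene <- modelGene
        strand <- names(sort(table(ex$strand), decreasing = TRUE))[1L]
        models[[length(models) + 1L]] <- data.frame(
            gene = modelGene, refGene = refGene, slot = j,
            start0 = min(ex$start0), end0 = max(ex$end0), strand = strand,
            nExonsFound = nrow(ex),
            completeness = nrow(ex) / nExonsRef[[refGene]],
            stringsAsFactors = FALSE)
        exonRows[[length(exonRows) + 1L]] <- ex
    }
    list(models = if (length(models)) do.call(rbind, models) else
             emptyModels,
         exons = if (length(exonRows)) do.call(rbind, exonRows) else
             cbind(hits[0, ], model = character(0)),
         unassigned = if (length(unassigned)) do.call(rbind, unassigned)
             else hits[0, ])
}

#' Assemble a coding sequence from a gene model
#'
#' Exon hit sequences are concatenated in transcription order
#' (reverse-complemented for minus-strand models). The reading frame is the
#' one maximizing the stop-free span from the CDS start, preferring frame 0
#' (the reference frame) on ties.
#'
#' @param modelExons data.frame of one model's exon hits (columns
#'   \code{exon}, \code{start0}, \code{end0}, \code{strand}).
#' @param locus the \linkS4class{GenomicLocus} (or character sequence) the
#'   hits refer to.
#' @return list with \code{seq} (CDS nucleotides), \code{frame},
#'   \code{translation}, \code{exons} (the input intervals).
#' @export
assembleCds <- function(modelExons, locus) {
    locSeq <- if (is(locus, "GenomicLocus"))
        as.character(locusSeq(locus)) else as.character(locus)
    if (nrow(modelExons) < 1L) stop("gene model has no exon hits")
    ex <- modelExons[order(modelExons$exon), , drop = FALSE]
    o <- ex[order(ex$start0), ]
    if (any(o$start0[-1L] < o$end0[-nrow(o)]))
        stop("gene model has overlapping exon hits")
    strand <- ex$strand[1L]
    parts <- vapply(seq_len(nrow(ex)), function(i) {
        s <- substr(locSeq, ex$start0[i] + 1L, ex$end0[i])
        if (strand == "-")
            s <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(s)))
        s
    }, character(1))
    cds <- paste(parts, collapse = "")
    stopFree <- function(s) {
        cods <- .splitCodons(s)
        aa <- .translateCodons(cods)
        stops <- which(aa == "*")
        if (!length(stops)) length(cods) else stops[1L] - 1L
    }
    spans <- vapply(0:2, function(f) stopFree(substr(cds, f + 1L,
                                                     nchar(cds))),
                    numeric(1))
    frame <- which.max(spans + c(0.5, 0, 0)) - 1L  # prefer frame 0 on ties
    inFrame <- substr(cds, frame + 1L, nchar(cds))
    list(seq = cds, frame = frame,
         translation = .translateCDS(inFrame),
         exons = ex[, c("exon", "start0", "end0", "strand")])
}
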