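# Locus evolution simulator: evolves a multi-gene locus along a species tree
# with scripted structural events (duplication, loss, pseudogenizing lesions,
# gene conversion, segmental insertion) and nucleotide/codon substitution.
# Coding regions of intact genes evolve under a codon jump process whose
# nonsynonymous rate is multiplied by a per-site omega; everything else
# evolves neutrally under HKY. The full generating truth is logged.

.INT2NT <- c("A", "C", "G", "T")
.NT2INT <- stats::setNames(1:4, .INT2NT)

.seqToInt <- function(s) unname(.NT2INT[strsplit(as.character(s), "")[[1]]])
.intToSeq <- function(v) paste(.INT2NT[v], collapse = "")

# --- HKY machinery -----------------------------------------------------------

.hkyQ <- function(kappa) {
    Q <- matrix(1, 4, 4)
    # transitions: A<->G (1,3), C<->T (2,4)
    Q[1, 3] <- Q[3, 1] <- kappa
    Q[2, 4] <- Q[4, 2] <- kappa
    diag(Q) <- 0
    diag(Q) <- -rowSums(Q)
    Q / (kappa + 2)  # mean rate 1 under uniform frequencies
}

.hkyP <- function(t, kappa) {
    e <- eigen(.hkyQ(kappa), symmetric = TRUE)
    P <- e$vectors %*% diag(exp(e$values * t)) %*% t(e$vectors)
    P[P < 0] <- 0
    P / rowSums(P)
}

.evolveNeutral <- function(ints, t, kappa) {
    if (t <= 0 || length(ints) == 0L) return(ints)
    P <- .hkyP(t, kappa)
    out <- ints
    for (s in 1:4) {
        idx <- which(ints == s)
        if (length(idx))
            out[idx] <- sample.int(4L, length(idx), replace = TRUE,
                                   prob = P[s, ])
    }
    out
}

# --- codon jump process ------------------------------------------------------

# Neighbor structure for the codon model at a given kappa; changes creating a
# stop codon are disallowed (intact genes stay open by construction).
.codonModel <- function(kappa) {
    key <- paste0("codmod_", kappa)
    .cached(key, function() {
        nb <- .neighborTable()
        nb <- nb[!nb$isStop, ]
        w <- ifelse(nb$isTransition, kappa, 1)
        idxFrom <- match(nb$from, allCodons())
        idxTo <- match(nb$to, allCodons())
        nbIdx <- nbW <- nbSyn <- vector("list", 64L)
        Ssum <- Nsum <- numeric(64L)
        for (c in seq_len(64L)) {
            sel <- idxFrom == c
            nbIdx[[c]] <- idxTo[sel]
            nbW[[c]] <- w[sel]
            nbSyn[[c]] <- nb$isSyn[sel]
            Ssum[c] <- sum(w[sel][nb$isSyn[sel]])
            Nsum[c] <- sum(w[sel][!nb$isSyn[sel]])
        }
        sense <- .codonAA() != "*"
        # scale so a neutral (omega = 1) codon accrues on average 3 nt
        # substitutions per unit branch length
        base <- 3 / mean(Ssum[sense] + Nsum[sense])
        list(nbIdx = nbIdx, nbW = nbW, nbSyn = nbSyn,
             Ssum = Ssum, Nsum = Nsum, base = base)
    })
}

# Evolve codon states (indices into allCodons()) for time t; omega is per
# codon site. Sites with omega = 0 are frozen.
.evolveCodons <- function(cod, omega, t, kappa) {
    if (t <= 0 || length(cod) == 0L) return(cod)
    m <- .codonModel(kappa)
    trem <- rep(t, length(cod))
    repeat {
        rates <- m$base * (m$Ssum[cod] + omega * m$Nsum[cod])
        act <- which(trem > 0 & rates > 0)
        if (!length(act)) break
        dt <- stats::rexp(length(act), rates[act])
        fin <- dt >= trem[act]
        hit <- act[!fin]
        trem[act[fin]] <- 0
        trem[hit] <- trem[hit] - dt[!fin]
        for (i in hit) {
            c <- cod[i]
            wts <- m$nbW[[c]] * ifelse(m$nbSyn[[c]], 1, omega[i])
            if (sum(wts) <= 0) { trem[i] <- 0; next }
            cod[i] <- m$nbIdx[[c]][sample.int(length(wts), 1L, prob = wts)]
        }
    }
    cod
}

# --- lesions (exported CDS-level operation) ----------------------------------

#' Apply a pseudogenizing lesion to a coding sequence
#'
#' @param cds coding sequence (character or \code{DNAString}).
#' @param kind one of \code{"frameshift_indel"}, \code{"premature_stop"},
#'   \code{"exon_truncation"}, \code{"exon_loss"}.
#' @param position for \code{frameshift_indel} a 0-based CDS bp position; for
#'   \code{premature_stop} a 1-based codon index; for exon kinds a 1-based
#'   exon index (requires \code{exonLens}).
#' @param indelLen indel length in bp (frameshift: must not be a multiple of
#'   3; negative means insertion of random bases is replaced by deletion --
#'   use \code{insert} to insert).
#' @param insert optional string to insert at \code{position} instead of
#'   deleting (frameshift_indel only).
#' @param exonLens integer vector of exon lengths making up the CDS
#'   (required for exon kinds).
#' @return list with \code{cds} (mutated sequence, character) and
#'   \code{lesion} (a one-row data.frame record).
#' @examples
#' out <- applyLesion(paste(rep("ATG", 100), collapse = ""),
#'                    "premature_stop", 50)
#' out$lesion$kind
#' @export
applyLesion <- function(cds, kind, position, indelLen = 1L, insert = NULL,
                        exonLens = NULL) {
    cds <- as.character(cds)
    L <- nchar(cds)
    kind <- match.arg(kind, c("frameshift_indel", "premature_stop",
                              "exon_truncation", "exon_loss"))
    if (kind == "frameshift_indel") {
        if (!is.null(insert)) {
            if (nchar(insert) %% 3L == 0L)
                stop("frameshift insertion length must not be a multiple of 3")
            out <- paste0(substr(cds, 1L, position),
                          insert, substr(cds, position + 1L, L))
            len <- nchar(insert)
        } else {
            if (indelLen %% 3L == 0L)
                stop("frameshift deletion length must not be a multiple of 3")
            if (position + indelLen > L) stop("indel outside CDS")
            out <- paste0(substr(cds, 1L, position),
                          substr(cds, position + indelLen + 1L, L))
            len <- -indelLen
        }
        rec <- data.frame(kind = kind, cdsPos = position, length = len,
                          stringsAsFactors = FALSE)
    } else if (kind == "premature_stop") {
        nCod <- L %/% 3L
        if (position >= nCod)
            stop("premature stop must lie upstream of the native stop codon")
        if (position < 1L) stop("codon index must be >= 1")
        s <- (position - 1L) * 3L
        out <- paste0(substr(cds, 1L, s), "TAA", substr(cds, s + 4L, L))
        rec <- data.frame(kind = kind, cdsPos = s, length = 0L,
                          stringsAsFactors = FALSE)
    } else {
        if (is.null(exonLens)) stop("exon kinds require exonLens")
        if (position < 1L || position > length(exonLens))
            stop("exon index out of range")
        starts <- cumsum(c(0L, exonLens))[seq_along(exonLens)]
        s <- starts[position]
        if (kind == "exon_loss") {
            e <- s + exonLens[position]
        } else {
            e <- s + exonLens[position]
            s <- e - min(indelLen, exonLens[position])
        }
        out <- paste0(substr(cds, 1L, s), substr(cds, e + 1L, L))
        rec <- data.frame(kind = kind, cdsPos = s, length = -(e - s),
                          stringsAsFactors = FALSE)
    }
    list(cds = out, lesion = rec)
}

#' Overwrite an acceptor interval with a donor interval (gene conversion)
#'
#' Both intervals are 0-based half-open on the same locus, must have equal
#' length and must not overlap.
#'
#' @param locus a \linkS4class{GenomicLocus} or character sequence.
#' @param donorStart,donorEnd donor interval.
#' @param acceptorStart,acceptorEnd acceptor interval.
#' @return object of the same type as \code{locus} with the acceptor bases
#'   replaced by the donor bases.
#' @export
applyGeneConversion <- function(locus, donorStart, donorEnd,
                                acceptorStart, acceptorEnd) {
    isLoc <- is(locus, "GenomicLocus")
    s <- if (isLoc) as.character(locusSeq(locus)) else as.character(locus)
    if ((donorEnd - donorStart) != (acceptorEnd - acceptorStart))
        stop("donor and acceptor intervals must have equal length")
    if (max(donorStart, acceptorStart) < min(donorEnd, acceptorEnd))
        stop("donor and acceptor intervals must not overlap")
    tract <- substr(s, donorStart + 1L, donorEnd)
    out <- paste0(substr(s, 1L, acceptorStart), tract,
                  substr(s, acceptorEnd + 1L, nchar(s)))
    if (isLoc) genomicLocus(speciesName(locus), out, originOffset(locus))
    else out
}

# --- simulation config -------------------------------------------------------

#' Build a simulation configuration
#'
#' The configuration fixes the species tree (branch lengths in expected
#' neutral substitutions per nucleotide site), the ancestral gene layout,
#' the substitution model and the scripted structural events. Events are
#' scripted (never drawn from rates) so the generating truth is exact.
#'
#' @param tree a \code{phylo} with branch lengths.
#' @param layout ancestral layout as produced by \code{\link{defaultLayout}}:
#'   a list with \code{genes} (list of \code{list(id, exonLens, intronLen,
#'   strand)}) and \code{intergenicLen}.
#' @param kappa HKY transition/transversion rate ratio.
#' @param omegaProfiles named list: per gene a numeric vector of per-codon
#'   dN/dS values (recycled to CDS length); default 0.2 everywhere.
#' @param events list of scripted events; each a list with \code{kind}
#'   (\code{"loss"}, \code{"pseudogenize"}, \code{"partial_loss"},
#'   \code{"duplication"}, \code{"conversion"}, \code{"segmental_insertion"}),
#'   \code{branch} (a leaf label or comma-joined leaf labels: the event
#'   applies on the branch above their MRCA) and kind-specific fields
#'   (\code{gene}; conversion: \code{donor}, \code{offset}, \code{len};
#'   partial_loss: \code{nDrop}; pseudogenize: \code{lesion} optional).
#' @param seed integer RNG seed; identical config + seed gives
#'   byte-identical output.
#' @return a \code{simConfig} list.
#' @export
simConfig <- function(tree, layout = defaultLayout(), kappa = 4,
                      omegaProfiles = NULL, events = list(), seed = 1L) {
    stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
    ids <- vapply(layout$genes, `[[`, character(1), "id")
    if (anyDuplicated(ids)) stop("duplicate gene ids in layout")
    if (is.null(omegaProfiles)) omegaProfiles <- list()
    for (g in layout$genes) {
        nCod <- sum(g$exonLens) %/% 3L
        prof <- omegaProfiles[[g$id]]
        if (is.null(prof)) prof <- 0.2
        if (any(prof <= 0)) stop("omega values must be > 0")
        omegaProfiles[[g$id]] <- rep_len(prof, nCod)
    }
    for (ev in events) {
        if (!ev$kind %in% c("loss", "pseudogenize", "partial_loss",
                            "duplication", "conversion",
                            "segmental_insertion"))
            stop("unknown event kind: ", ev$kind)
        sp <- strsplit(ev$branch, ",")[[1]]
        if (!all(sp %in% tree$tip.label))
            stop("event branch references unknown species: ", ev$branch)
    }
    structure(list(tree = tree, layout = layout, kappa = kappa,
                   omegaProfiles = omegaProfiles, events = events,
                   seed = as.integer(seed)),
              class = "simConfig")
}

#' Default ancestral locus layout
#'
#' Eight genes in syntenic order, mirroring the architecture of an
#' inflammatory caspase locus: a central protease gene flanked by CARD-only
#' genes and tandem paralogs. Exon counts/lengths are caspase-like (CDS 270
#' bp for CARD-only genes, ~1.2 kb for proteases).
#'
#' @param intergenicLen bp of intergenic sequence between genes (and at both
#'   ends). The default reproduces a locus of roughly 350 kb; compact test
#'   configurations pass a smaller value.
#' @param intronLen bp per intron.
#' @return layout list for \code{\link{simConfig}}.
#' @export
defaultLayout <- function(intergenicLen = 36000L, intronLen = 1200L) {
    casp <- c(300L, 201L, 150L, 150L, 150L, 249L)   # 1200 bp = 400 codons
    card <- c(201L, 168L)                           # 369 bp = 123 codons
    genes <- list(
        list(id = "card16", exonLens = card, intronLen = intronLen,
             strand = "+"),
        list(id = "casp1", exonLens = casp, intronLen = intronLen,
             strand = "+"),
        list(id = "card17", exonLens = card, intronLen = intronLen,
             strand = "-"),
        list(id = "card18", exonLens = card, intronLen = intronLen,
             strand = "+"),
        list(id = "casp5", exonLens = casp, intronLen = intronLen,
             strand = "+"),
        list(id = "casp4", exonLens = casp, intronLen = intronLen,
             strand = "+"),
        list(id = "casp12", exonLens = casp, intronLen = intronLen,
             strand = "+"))
    list(genes = genes, intergenicLen = as.integer(intergenicLen))
}

# Build ancestral locus: returns list(ints, anno, cds) where anno has one row
# per exon with 0-based half-open coordinates.
.buildAncestralLocus <- function(layout) {
    genes <- layout$genes
    ig <- layout$intergenicLen
    pieces <- list()
    anno <- list()
    pos <- 0L
    emitRandom <- function(n) sample.int(4L, n, replace = TRUE)
    sense <- .senseCodons()
    nonStopStart <- sense[!sense %in% c("TAA", "TAG", "TGA")]
    for (gi in seq_along(genes)) {
        pieces[[length(pieces) + 1L]] <- emitRandom(ig)
        pos <- pos + ig
        g <- genes[[gi]]
        nCod <- sum(g$exonLens) %/% 3L
        cods <- c("ATG",
                  sample(setdiff(nonStopStart, "ATG"), nCod - 2L,
                         replace = TRUE),
                  sample(c("TAA", "TAG", "TGA"), 1L))
        cds <- paste(cods, collapse = "")
        exSeqs <- character(length(g$exonLens))
        off <- 0L
        for (k in seq_along(g$exonLens)) {
            exSeqs[k] <- substr(cds, off + 1L, off + g$exonLens[k])
            off <- off + g$exonLens[k]
        }
        # genomic gene body in transcription order, then strand-flip
        body <- character(0)
        for (k in seq_along(exSeqs)) {
            body <- c(body, exSeqs[k])
            if (k < length(exSeqs))
                body <- c(body, paste0("GT", .intToSeq(
                    emitRandom(g$intronLen - 4L)), "AG"))
        }
        bodyStr <- paste(body, collapse = "")
        if (g$strand == "-")
            bodyStr <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(bodyStr)))
        # exon coordinates within the body (genomic orientation)
        exLenGen <- g$exonLens
        starts <- integer(length(exLenGen))
        cur <- 0L
        for (k in seq_along(exLenGen)) {
            starts[k] <- cur
            cur <- cur + exLenGen[k] + if (k < length(exLenGen))
                g$intronLen else 0L
        }
        if (g$strand == "-") {
            bl <- nchar(bodyStr)
            starts <- rev(bl - (starts + exLenGen))
            exLenGen <- rev(exLenGen)
            exIdx <- rev(seq_along(g$exonLens))
        } else exIdx <- seq_along(g$exonLens)
        anno[[length(anno) + 1L]] <- data.frame(
            gene = g$id, exon = exIdx,
            start0 = pos + starts, end0 = pos + starts + exLenGen,
            strand = g$strand, stringsAsFactors = FALSE)
        pieces[[length(pieces) + 1L]] <- .seqToInt(bodyStr)
        pos <- pos + nchar(bodyStr)
    }
    pieces[[length(pieces) + 1L]] <- emitRandom(ig)
    list(ints = unlist(pieces), anno = do.call(rbind, anno))
}

# genomic positions of a gene's CDS, in CDS (transcription) order
.cdsMap <- function(anno, gene) {
    a <- anno[anno$gene == gene, , drop = FALSE]
    if (nrow(a) == 0L) return(integer(0))
    a <- a[order(a$exon), , drop = FALSE]
    strand <- a$strand[1L]
    posList <- lapply(seq_len(nrow(a)), function(i) {
        p <- seq.int(a$start0[i] + 1L, a$end0[i])  # 1-based genomic
        if (strand == "-") rev(p) else p
    })
    unlist(posList)
}

.geneSpan <- function(anno, gene) {
    a <- anno[anno$gene == gene, , drop = FALSE]
    if (nrow(a) == 0L) return(NULL)
    c(min(a$start0), max(a$end0))
}

# shift annotation coordinates for an indel: deletion of [a,b) (delta<0) or
# insertion of delta bp at position a
.shiftAnno <- function(anno, a, b, delta) {
    if (nrow(anno) == 0L) return(anno)
    if (delta < 0) {
        keep <- !(anno$start0 >= a & anno$end0 <= b)
        anno <- anno[keep, , drop = FALSE]
        # truncate partial overlaps
        anno$end0 <- ifelse(anno$start0 < a & anno$end0 > a & anno$end0 <= b,
                            a, anno$end0)
        anno$start0 <- ifelse(anno$start0 >= a & anno$start0 < b &
                              anno$end0 > b, b, anno$start0)
        len <- b - a
        anno$start0 <- ifelse(anno$start0 >= b, anno$start0 - len,
                              anno$start0)
        anno$end0 <- ifelse(anno$end0 > b, anno$end0 - len, anno$end0)
    } else {
        anno$start0 <- ifelse(anno$start0 >= a, anno$start0 + delta,
                              anno$start0)
        anno$end0 <- ifelse(anno$end0 > a, anno$end0 + delta, anno$end0)
    }
    anno
}

# --- event application -------------------------------------------------------

.applyEvent <- function(st, ev, branchLabel) {
    log1 <- function(detail)
        data.frame(kind = ev$kind, branch = branchLabel,
                   gene = if (!is.null(ev$gene)) ev$gene else NA_character_,
                   detail = detail, stringsAsFactors = FALSE)
    if (ev$kind %in% c("loss", "pseudogenize", "partial_loss",
                       "duplication")) {
        if (!ev$gene %in% names(st$status) ||
            st$status[[ev$gene]] == "absent")
            stop("event references a gene not present on this branch: ",
                 ev$gene)
    }
    if (ev$kind == "loss") {
        sp <- .geneSpan(st$anno, ev$gene)
        st$ints <- st$ints[-seq.int(sp[1] + 1L, sp[2])]
        st$anno <- .shiftAnno(st$anno, sp[1], sp[2], -(sp[2] - sp[1]))
        st$status[[ev$gene]] <- "absent"
        st$log <- rbind(st$log, log1(sprintf("deleted [%d,%d)", sp[1], sp[2])))
    } else if (ev$kind == "pseudogenize") {
        map <- .cdsMap(st$anno, ev$gene)
        nCod <- length(map) %/% 3L
        lesion <- if (!is.null(ev$lesion)) ev$lesion else
            sample(c("frameshift_indel", "premature_stop"), 1L)
        strand <- st$anno$strand[st$anno$gene == ev$gene][1L]
        if (lesion == "premature_stop") {
            j <- if (!is.null(ev$pos)) ev$pos else
                sample(seq.int(max(2L, nCod %/% 4L), nCod - 2L), 1L)
            gpos <- map[(3L * (j - 1L) + 1L):(3L * j)]
            stopInts <- .seqToInt("TAA")
            # map is in transcription order; minus-strand genomic bases are
            # the complement of the transcribed bases
            st$ints[gpos] <- if (strand == "-")
                .complementInt(stopInts) else stopInts
            st$log <- rbind(st$log, log1(sprintf(
                "premature_stop codon %d", j)))
        } else {
            k <- if (!is.null(ev$len)) ev$len else sample(c(1L, 2L), 1L)
            cstart <- if (!is.null(ev$pos)) ev$pos else
                sample.int(length(map) - 3L * 6L, 1L) + 9L
            gpos <- sort(map[cstart:(cstart + k - 1L)])
            a <- gpos[1L] - 1L
            b <- gpos[length(gpos)]
            st$ints <- st$ints[-seq.int(a + 1L, b)]
            st$anno <- .shiftAnno(st$anno, a, b, -(b - a))
            st$log <- rbind(st$log, log1(sprintf(
                "frameshift_indel -%dbp at CDS %d", k, cstart)))
        }
        st$status[[ev$gene]] <- "pseudogene"
    } else if (ev$kind == "partial_loss") {
        a <- st$anno[st$anno$gene == ev$gene, , drop = FALSE]
        nEx <- max(a$exon)
        nDrop <- if (!is.null(ev$nDrop)) ev$nDrop else 2L
        drop <- a[a$exon > nEx - nDrop, , drop = FALSE]
        s <- min(drop$start0); e <- max(drop$end0)
        st$ints <- st$ints[-seq.int(s + 1L, e)]
        st$anno <- .shiftAnno(st$anno, s, e, -(e - s))
        st$status[[ev$gene]] <- "partial_in_frame"
        st$log <- rbind(st$log, log1(sprintf("dropped %d terminal exon(s)",
                                             nDrop)))
    } else if (ev$kind == "duplication") {
        sp <- .geneSpan(st$anno, ev$gene)
        fl <- if (!is.null(ev$flank)) ev$flank else 1500L
        s <- max(0L, sp[1] - fl)
        e <- min(length(st$ints), sp[2] + fl)
        tract <- st$ints[seq.int(s + 1L, e)]
        ins <- e  # insert immediately after the source span
        newId <- ev$newId
        if (is.null(newId)) newId <- paste0(ev$gene, "_dup")
        st$ints <- append(st$ints, tract, after = ins)
        st$anno <- .shiftAnno(st$anno, ins, ins, length(tract))
        src <- st$anno[st$anno$gene == ev$gene, , drop = FALSE]
        dup <- src
        dup$gene <- newId
        dup$start0 <- ins + (src$start0 - s)
        dup$end0 <- ins + (src$end0 - s)
        st$anno <- rbind(st$anno, dup)
        st$anno <- st$anno[order(st$anno$start0), , drop = FALSE]
        st$status[[newId]] <- "present"
        st$omega[[newId]] <- st$omega[[ev$gene]]
        st$log <- rbind(st$log, log1(sprintf("duplicated as %s at %d",
                                             newId, ins)))
    } else if (ev$kind == "conversion") {
        spD <- .geneSpan(st$anno, ev$donor)
        spA <- .geneSpan(st$anno, ev$gene)
        off <- if (!is.null(ev$offset)) ev$offset else 0L
        len <- ev$len
        dS <- spD[1] + off; dE <- min(dS + len, spD[2])
        aS <- spA[1] + off; aE <- min(aS + len, spA[2])
        len <- min(dE - dS, aE - aS)
        dE <- dS + len; aE <- aS + len
        st$ints[seq.int(aS + 1L, aE)] <- st$ints[seq.int(dS + 1L, dE)]
        st$conv <- c(st$conv, list(list(donor = ev$donor, gene = ev$gene,
                                        offset = off, len = len)))
        st$log <- rbind(st$log, log1(sprintf(
            "conversion %s->%s tract %d bp at offset %d", ev$donor, ev$gene,
            len, off)))
    } else if (ev$kind == "segmental_insertion") {
        src <- ev$srcStart
        len <- ev$len
        tract <- st$ints[seq.int(src + 1L, src + len)]
        ins <- ev$insertAt
        st$ints <- append(st$ints, tract, after = ins)
        st$anno <- .shiftAnno(st$anno, ins, ins, len)
        st$log <- rbind(st$log, log1(sprintf(
            "segmental insertion %d bp from %d at %d", len, src, ins)))
    }
    st
}

.complementInt <- function(v) 5L - v

# re-apply active concerted-evolution tracts using current coordinates
.reapplyConversions <- function(st) {
    for (cv in st$conv) {
        spD <- .geneSpan(st$anno, cv$donor)
        spA <- .geneSpan(st$anno, cv$gene)
        if (is.null(spD) || is.null(spA)) next
        dS <- spD[1] + cv$offset; aS <- spA[1] + cv$offset
        len <- min(cv$len, spD[2] - dS, spA[2] - aS)
        if (len <= 0) next
        st$ints[seq.int(aS + 1L, aS + len)] <-
            st$ints[seq.int(dS + 1L, dS + len)]
    }
    st
}

# substitutions along a branch of length t
.evolveState <- function(st, t, kappa) {
    if (t <= 0) return(st)
    codingMask <- rep(FALSE, length(st$ints))
    codingGenes <- names(st$status)[st$status %in%
                                    c("present", "partial_in_frame")]
    maps <- list()
    for (g in codingGenes) {
        map <- .cdsMap(st$anno, g)
        nCod <- length(map) %/% 3L
        if (nCod < 3L) next
        maps[[g]] <- map
        codingMask[map[seq_len(3L * nCod)]] <- TRUE
    }
    nc <- which(!codingMask)
    st$ints[nc] <- .evolveNeutral(st$ints[nc], t, kappa)
    for (g in names(maps)) {
        map <- maps[[g]]
        strand <- st$anno$strand[st$anno$gene == g][1L]
        cdsInts <- st$ints[map]
        if (strand == "-") cdsInts <- .complementInt(cdsInts)
        nCod <- length(cdsInts) %/% 3L
        codStr <- substring(.intToSeq(cdsInts[seq_len(3L * nCod)]),
                            3L * seq_len(nCod) - 2L, 3L * seq_len(nCod))
        cod <- match(codStr, allCodons())
        omega <- rep_len(st$omega[[g]], nCod)
        # hold start and terminal stop codons fixed
        evolveIdx <- seq.int(2L, nCod - 1L)
        aaNow <- .codonAA()[cod]
        evolveIdx <- evolveIdx[aaNow[evolveIdx] != "*"]
        cod[evolveIdx] <- .evolveCodons(cod[evolveIdx], omega[evolveIdx], t,
                                        kappa)
        newInts <- unlist(lapply(cod, function(ci) .seqToInt(
            allCodons()[ci])))
        tailIdx <- seq_len(length(cdsInts))[seq_len(3L * nCod)]
        cdsInts[tailIdx] <- newInts
        leftover <- setdiff(seq_along(cdsInts), tailIdx)
        if (length(leftover))
            cdsInts[leftover] <- .evolveNeutral(cdsInts[leftover], t, kappa)
        if (strand == "-") cdsInts <- .complementInt(cdsInts)
        st$ints[map] <- cdsInts
    }
    st
}

# --- main driver -------------------------------------------------------------

#' Simulate a locus dataset along a species tree
#'
#' Starting from a random ancestral locus built from the configured layout,
#' the locus evolves down the tree: scripted structural events are applied
#' at the start of their branch, intact coding regions evolve under the
#' codon model with their per-site omega profile, everything else evolves
#' neutrally under HKY. Scripted gene-conversion tracts model concerted
#' evolution: after initiation they are re-copied midway along every
#' descendant branch. Deterministic given the config seed.
#'
#' @param config a \code{\link{simConfig}}.
#' @return A \linkS4class{SimulationResult}. The truth list contains
#'   \code{events} (structural event log), \code{status} (species x gene
#'   truth calls), \code{exons} (true exon coordinates, 0-based half-open),
#'   \code{cds} (true coding sequences of intact/partial genes),
#'   \code{ancestralExons} (reference exon sequences for annotation) and
#'   \code{omega} (per-gene per-codon dN/dS used).
#' @export
simulateDataset <- function(config) {
    stopifnot(inherits(config, "simConfig"))
    set.seed(config$seed)
    tree <- config$tree
    anc <- .buildAncestralLocus(config$layout)
    geneIds <- vapply(config$layout$genes, `[[`, character(1), "id")
    status0 <- stats::setNames(rep("present", length(geneIds)), geneIds)
    st0 <- list(ints = anc$ints, anno = anc$anno,
                status = as.list(status0), omega = config$omegaProfiles,
                conv = list(),
                log = data.frame(kind = character(0), branch = character(0),
                                 gene = character(0), detail = character(0),
                                 stringsAsFactors = FALSE))
    # reference exon sequences from the ancestral locus
    refExonList <- lapply(geneIds, function(g) {
        a <- anc$anno[anc$anno$gene == g, , drop = FALSE]
        a <- a[order(a$exon), , drop = FALSE]
        seqs <- vapply(seq_len(nrow(a)), function(i) {
            s <- .intToSeq(anc$ints[(a$start0[i] + 1L):a$end0[i]])
            if (a$strand[i] == "-")
                s <- as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(s)))
            s
        }, character(1))
        Biostrings::DNAStringSet(seqs)
    })
    names(refExonList) <- geneIds
    ntip <- length(tree$tip.label)
    # events keyed by the child node of their branch
    evByNode <- vector("list", ntip + tree$Nnode)
    for (ev in config$events) {
        sp <- strsplit(ev$branch, ",")[[1]]
        node <- if (length(sp) == 1L) match(sp, tree$tip.label) else
            ape::getMRCA(tree, sp)
        evByNode[[node]] <- c(evByNode[[node]], list(ev))
    }
    children <- split(tree$edge[, 2L], tree$edge[, 1L])
    edgeLen <- stats::setNames(tree$edge.length, tree$edge[, 2L])
    loci <- list(); truthStatus <- list(); truthExons <- list()
    truthCds <- list()
    logAcc <- st0$log
    recordLeaf <- function(st, species) {
        loci[[species]] <<- genomicLocus(species, .intToSeq(st$ints))
        stDf <- data.frame(species = species,
                           gene = names(st$status),
                           status = unlist(st$status),
                           stringsAsFactors = FALSE, row.names = NULL)
        # genes never born in this lineage
        allG <- unique(c(geneIds, names(st$status)))
        truthStatus[[species]] <<- stDf
        if (nrow(st$anno)) {
            ex <- st$anno
            ex$species <- species
            truthExons[[species]] <<- ex
        }
        cdsV <- list()
        for (g in names(st$status)) {
            if (st$status[[g]] == "absent") next
            map <- .cdsMap(st$anno, g)
            if (!length(map)) next
            cdsInts <- st$ints[map]
            if (st$anno$strand[st$anno$gene == g][1L] == "-")
                cdsInts <- .complementInt(cdsInts)
            cdsV[[g]] <- .intToSeq(cdsInts)
        }
        truthCds[[species]] <<- cdsV
    }
    walk <- function(node, st) {
        if (node <= ntip) {
            recordLeaf(st, tree$tip.label[node])
            return(invisible())
        }
        for (child in children[[as.character(node)]]) {
            st2 <- st
            branchLabel <- if (child <= ntip) tree$tip.label[child] else
                paste(ape::extract.clade(tree, child)$tip.label,
                      collapse = ",")
            evs <- evByNode[[child]] %||% list()
            isConv <- vapply(evs, function(e) e$kind == "conversion",
                             logical(1))
            for (ev in evs[!isConv])
                st2 <- .applyEvent(st2, ev, branchLabel)
            t <- edgeLen[[as.character(child)]]
            # conversion tracts (newly initiated and inherited) are copied
            # at the branch midpoint: concerted evolution keeps
            # re-homogenizing the tract as lineages diverge
            if ((any(isConv) || length(st2$conv)) && t > 0) {
                st2 <- .evolveState(st2, t / 2, config$kappa)
                for (ev in evs[isConv])
                    st2 <- .applyEvent(st2, ev, branchLabel)
                st2 <- .reapplyConversions(st2)
                st2 <- .evolveState(st2, t / 2, config$kappa)
            } else {
                for (ev in evs[isConv])
                    st2 <- .applyEvent(st2, ev, branchLabel)
                st2 <- .evolveState(st2, t, config$kappa)
            }
            logAcc <<- rbind(logAcc, st2$log[seq_len(nrow(st2$log)) >
                                             nrow(st$log), , drop = FALSE])
            walk(child, st2)
        }
    }
    root <- ntip + 1L
    # events addressed to the whole tree (MRCA = root) shape the ancestor
    for (ev in evByNode[[root]] %||% list())
        st0 <- .applyEvent(st0, ev, "root")
    walk(root, st0)
    statusDf <- do.call(rbind, truthStatus)
    rownames(statusDf) <- NULL
    allGenes <- unique(statusDf$gene)
    # fill genes missing from a species (e.g. duplicates born elsewhere)
    full <- expand.grid(species = tree$tip.label, gene = allGenes,
                        stringsAsFactors = FALSE)
    statusDf <- merge(full, statusDf, all.x = TRUE)
    statusDf$status[is.na(statusDf$status)] <- "absent"
    exonsDf <- do.call(rbind, truthExons)
    rownames(exonsDf) <- NULL
    new("SimulationResult",
        loci = loci, tree = tree,
        truth = list(events = logAcc, status = statusDf, exons = exonsDf,
                     cds = truthCds, ancestralExons = refExonList,
                     omega = config$omegaProfiles),
        config = unclass(config))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reference gene set from a simulation
#'
#' Packages the ancestral exon sequences of a simulation as the
#' \linkS4class{ReferenceGeneSet} used by the annotation stage.
#'
#' @param sim a \linkS4class{SimulationResult}.
#' @return A \linkS4class{ReferenceGeneSet}.
#' @export
simReferenceGeneSet <- function(sim) {
    stopifnot(is(sim, "SimulationResult"))
    ref <- simTruth(sim)$ancestralExons
    strands <- vapply(sim@config$layout$genes, `[[`, character(1), "strand")
    referenceGeneSet(names(ref), ref, strand = strands)
}
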