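# Detection of extended intra-locus self-similarity (recent duplication /
# gene-conversion tracts) and of gene conversion via paralog-tree
# intermixing.

# chain seed pairs (a, b 0-based k-mer starts, same orientation space) into
# blocks; returns data.frame of chained spans
.chainPairs <- function(a, b, k, maxGap, diagTol = 0L) {
    if (!length(a)) return(NULL)
    dt <- data.table::data.table(a = a, b = b, diag = b - a)
    data.table::setorder(dt, diag, a)
    grp <- integer(nrow(dt)); g <- 0L
    lastDiag <- -Inf; lastA <- -Inf
    for (i in seq_len(nrow(dt))) {
        if (dt$diag[i] - lastDiag > diagTol || dt$a[i] - lastA > maxGap)
            g <- g + 1L
        grp[i] <- g
        lastDiag <- dt$diag[i]; lastA <- dt$a[i]
    }
    dt$grp <- grp
    res <- dt[, list(a1 = min(a), a2 = max(a) + k,
                     b1 = min(b), b2 = max(b) + k, n = .N), by = "grp"]
    as.data.frame(res)
}

#' Find intra-locus self-similarity blocks
#'
#' Exact k-mer seeds are chained along diagonals (maximum gap
#' \code{maxGap}); chains meeting the length threshold are scored by global
#' alignment of their two intervals, with gap columns counting as
#' mismatches. Both direct and inverted (reverse-complement) orientations
#' are searched; the trivial self-diagonal is excluded and overlapping
#' chains are merged.
#'
#' @param locus a \linkS4class{GenomicLocus}, \code{DNAString} or character.
#' @param config a \linkS4class{PipelineConfig} (thresholds
#'   \code{blockMinLen}, \code{blockMinIdentity}).
#' @param k seed length.
#' @param maxGap maximum bp between chained seeds.
#' @param maxOcc k-mers occurring more often than this are skipped
#'   (low-complexity guard).
#' @return data.frame of blocks: \code{aStart0}, \code{aEnd0},
#'   \code{bStart0}, \code{bEnd0} (0-based half-open; interval a
#'   lexicographically first), \code{orientation} ("direct"/"inverted"),
#'   \code{length}, \code{identity}.
#' @export
findSimilarityBlocks <- function(locus, config = pipelineConfig(), k = 12L,
                                 maxGap = 200L, maxOcc = 64L) {
    s <- if (is(locus, "GenomicLocus")) as.character(locusSeq(locus)) else
        as.character(locus)
    L <- nchar(s)
    minLen <- config@blockMinLen
    if (L < 2L * minLen)
        stop("locus shorter than twice blockMinLen")
    dtS <- .kmerTable(s, k)
    occ <- dtS[, list(nOcc = .N), by = "code"]
    dtS <- dtS[occ, on = "code"][nOcc <= maxOcc]
    blocks <- list()
    # direct orientation: ordered pairs p1 < p2
    dtJ <- dtS[dtS, on = "code", nomatch = NULL, allow.cartesian = TRUE]
    dtJ <- dtJ[dtJ$pos > dtJ$i.pos]
    ch <- .chainPairs(dtJ$i.pos - 1L, dtJ$pos - 1L, k, maxGap)
    if (!is.null(ch)) {
        ch <- ch[(ch$a2 - ch$a1) >= minLen & ch$b1 >= ch$a2, , drop = FALSE]
        if (nrow(ch))
            for (i in seq_len(nrow(ch)))
                blocks[[length(blocks) + 1L]] <- data.frame(
                    aStart0 = ch$a1[i], aEnd0 = ch$a2[i],
                    bStart0 = ch$b1[i], bEnd0 = ch$b2[i],
                    orientation = "direct", stringsAsFactors = FALSE)
    }
    # inverted orientation: seeds shared with the reverse complement
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    dtR <- .kmerTable(rc, k)
    occR <- dtR[, list(nOcc = .N), by = "code"]
    dtR <- dtR[occR, on = "code"][nOcc <= maxOcc]
    dtJ <- dtR[dtS, on = "code", nomatch = NULL, allow.cartesian = TRUE]
    # i.pos: position in s (1-based); pos: position in rc (1-based)
    if (nrow(dtJ)) {
        ch <- .chainPairs(dtJ$i.pos - 1L, dtJ$pos - 1L, k, maxGap)
        if (!is.null(ch)) {
            # map rc interval [b1, b2) back to s: [L - b2, L - b1)
            bS <- L - ch$b2
            bE <- L - ch$b1
            keep <- (ch$a2 - ch$a1) >= minLen & bS >= ch$a2
            ch <- ch[keep, , drop = FALSE]
            bS <- bS[keep]; bE <- bE[keep]
            if (nrow(ch))
                for (i in seq_len(nrow(ch)))
                    blocks[[length(blocks) + 1L]] <- data.frame(
                        aStart0 = ch$a1[i], aEnd0 = ch$a2[i],
                        bStart0 = bS[i], bEnd0 = bE[i],
                        orientation = "inverted", stringsAsFactors = FALSE)
        }
    }
    empty <- data.frame(aStart0 = integer(0), aEnd0 = integer(0),
                        bStart0 = integer(0), bEnd0 = integer(0),
                        orientation = character(0), length = integer(0),
                        identity = numeric(0))
    if (!length(blocks)) return(empty)
    bl <- unique(do.call(rbind, blocks))
    # merge blocks whose a- and b-intervals both overlap (same orientation)
    bl <- bl[order(bl$aStart0), , drop = FALSE]
    merged <- list()
    used <- rep(FALSE, nrow(bl))
    for (i in seq_len(nrow(bl))) {
        if (used[i]) next
        cur <- bl[i, ]
        repeat {
            cand <- which(!used & seq_len(nrow(bl)) > i &
                bl$orientation == cur$orientation &
                bl$aStart0 < cur$aEnd0 & bl$aEnd0 > cur$aStart0 &
                bl$bStart0 < cur$bEnd0 & bl$bEnd0 > cur$bStart0)
            if (!length(cand)) break
            for (j in cand) {
                cur$aStart0 <- min(cur$aStart0, bl$aStart0[j])
                cur$aEnd0 <- max(cur$aEnd0, bl$aEnd0[j])
                cur$bStart0 <- min(cur$bStart0, bl$bStart0[j])
                cur$bEnd0 <- max(cur$bEnd0, bl$bEnd0[j])
                used[j] <- TRUE
            }
        }
        used[i] <- TRUE
        merged[[length(merged) + 1L]] <- cur
    }
    bl <- do.call(rbind, merged)
    # identity over the chained alignment
    out <- list()
    for (i in seq_len(nrow(bl))) {
        sa <- substr(s, bl$aStart0[i] + 1L, bl$aEnd0[i])
        sb <- substr(s, bl$bStart0[i] + 1L, bl$bEnd0[i])
        if (bl$orientation[i] == "inverted")
            sb <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(sb)))
        pa <- .globalAlign(sa, sb)
        idy <- Biostrings::nmatch(pa) / Biostrings::nchar(pa)
        len <- max(bl$aEnd0[i] - bl$aStart0[i], bl$bEnd0[i] - bl$bStart0[i])
        if (len < config@blockMinLen || idy < config@blockMinIdentity) next
        out[[length(out) + 1L]] <- cbind(bl[i, ], length = len,
                                         identity = idy)
    }
    if (!length(out)) return(empty)
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Label block ends by gene overlap
#'
#' Each block end is labeled \code{coding} (overlaps an exon),
#' \code{intronic} (inside a gene span but no exon), \code{intergenic}, or
#' \code{mixed} (spans more than one class), with the ids of overlapped
#' genes (or the nearest gene for intergenic ends).
#'
#' @param blocks data.frame from \code{\link{findSimilarityBlocks}}.
#' @param exons data.frame of exon intervals: \code{gene}, \code{start0},
#'   \code{end0}.
#' @return \code{blocks} with added columns \code{aClass}, \code{aGenes},
#'   \code{bClass}, \code{bGenes}.
#' @export
annotateBlockGeneOverlap <- function(blocks, exons) {
    spans <- do.call(rbind, lapply(split(exons, exons$gene), function(e)
        data.frame(gene = e$gene[1L], start0 = min(e$start0),
                   end0 = max(e$end0), stringsAsFactors = FALSE)))
    classify <- function(s, e) {
        exOv <- exons[exons$start0 < e & exons$end0 > s, , drop = FALSE]
        spOv <- spans[spans$start0 < e & spans$end0 > s, , drop = FALSE]
        coding <- nrow(exOv) > 0L
        hasIntron <- FALSE
        if (nrow(spOv)) {
            exBp <- if (coding) sum(pmin(exOv$end0, e) -
                                    pmax(exOv$start0, s)) else 0L
            spBp <- sum(pmin(spOv$end0, e) - pmax(spOv$start0, s))
            hasIntron <- spBp > exBp
        }
        hasInter <- (e - s) > (if (nrow(spOv))
            sum(pmin(spOv$end0, e) - pmax(spOv$start0, s)) else 0L)
        classes <- c("coding", "intronic", "intergenic")[
            c(coding, hasIntron, hasInter)]
        cls <- if (length(classes) == 1L) classes else "mixed"
        genes <- if (nrow(spOv)) paste(sort(unique(spOv$gene)),
                                       collapse = ",")
        else {
            mid <- (s + e) / 2
            d <- pmin(abs(spans$start0 - mid), abs(spans$end0 - mid))
            paste0("near:", spans$gene[which.min(d)])
        }
        list(cls = cls, genes = genes)
    }
    aCls <- bCls <- aG <- bG <- character(nrow(blocks))
    for (i in seq_len(nrow(blocks))) {
        ca <- classify(blocks$aStart0[i], blocks$aEnd0[i])
        cb <- classify(blocks$bStart0[i], blocks$bEnd0[i])
        aCls[i] <- ca$cls; aG[i] <- ca$genes
        bCls[i] <- cb$cls; bG[i] <- cb$genes
    }
    blocks$aClass <- aCls; blocks$aGenes <- aG
    blocks$bClass <- bCls; blocks$bGenes <- bG
    blocks
}

.jcDist <- function(aln) {
    bin <- ape::as.DNAbin(Biostrings::DNAMultipleAlignment(aln))
    D <- as.matrix(ape::dist.dna(bin, model = "JC69",
                                 pairwise.deletion = TRUE))
    # saturated pairs (JC undefined) are simply "very far"
    D[is.na(D) | is.nan(D)] <- Inf
    D
}

#' Detect gene conversion from paralog-tree intermixing
#'
#' For every species s and gene pair (g, h) present in the alignment, a
#' conversion is called when the within-species cross-paralog distance
#' d(g_s, h_s) falls below the minimum cross-species within-gene distance
#' (Jukes-Cantor). Calls are merged onto the species tree into the minimum
#' number of clade-level events (a maximal clade whose leaves are all
#' called counts once).
#'
#' @param aln a named \link[Biostrings]{DNAStringSet} (aligned, equal
#'   widths); one sequence per gene copy.
#' @param geneLabels,speciesLabels character vectors parallel to \code{aln}.
#' @param tree species tree (\code{phylo}).
#' @return list with \code{calls} (per species x gene pair: support =
#'   baseline minus within-species paralog distance, and the call flag),
#'   \code{events} (merged clade-level events) and \code{nEvents}.
#' @export
detectTreeIntermixing <- function(aln, geneLabels, speciesLabels, tree) {
    if (length(unique(speciesLabels)) < 3L)
        stop("need at least 3 species for a cross-species baseline")
    if (length(unique(geneLabels)) < 2L)
        stop("need at least 2 gene families")
    if (is.character(aln)) aln <- Biostrings::DNAStringSet(aln)
    names(aln) <- paste(geneLabels, speciesLabels, sep = "|")
    D <- .jcDist(aln)
    key <- function(g, s) paste(g, s, sep = "|")
    genes <- sort(unique(geneLabels))
    spp <- unique(speciesLabels)
    calls <- list()
    for (gi in seq_along(genes)) for (hi in seq_along(genes)) {
        if (hi <= gi) next
        g <- genes[gi]; h <- genes[hi]
        for (s in spp) {
            if (!key(g, s) %in% rownames(D) ||
                !key(h, s) %in% rownames(D)) next
            dWithin <- D[key(g, s), key(h, s)]
            base <- Inf
            for (t in setdiff(spp, s)) {
                if (key(g, t) %in% rownames(D))
                    base <- min(base, D[key(g, s), key(g, t)])
                if (key(h, t) %in% rownames(D))
                    base <- min(base, D[key(h, s), key(h, t)])
            }
            called <- is.finite(dWithin) && dWithin < base
            support <- base - dWithin
            if (!is.finite(support)) support <- if (called) Inf else -Inf
            calls[[length(calls) + 1L]] <- data.frame(
                gene1 = g, gene2 = h, species = s,
                support = support, called = called,
                stringsAsFactors = FALSE)
        }
    }
    calls <- if (length(calls)) do.call(rbind, calls) else
        data.frame(gene1 = character(0), gene2 = character(0),
                   species = character(0), support = numeric(0),
                   called = logical(0))
    # merge called species into minimal clade events per gene pair
    events <- list()
    if (nrow(calls)) {
        for (pr in unique(paste(calls$gene1, calls$gene2))) {
            sub <- calls[paste(calls$gene1, calls$gene2) == pr &
                         calls$called, ]
            if (nrow(sub) == 0L) next
            clades <- .minimalCladeCover(tree, sub$species)
            for (cl in clades)
                events[[length(events) + 1L]] <- data.frame(
                    gene1 = sub$gene1[1L], gene2 = sub$gene2[1L],
                    clade = paste(cl, collapse = ","),
                    stringsAsFactors = FALSE)
        }
    }
    events <- if (length(events)) do.call(rbind, events) else
        data.frame(gene1 = character(0), gene2 = character(0),
                   clade = character(0))
    list(calls = calls, events = events, nEvents = nrow(events))
}

# minimal set of clades whose leaf sets exactly cover `leaves`
.minimalCladeCover <- function(tree, leaves) {
    ntip <- length(tree$tip.label)
    children <- split(tree$edge[, 2L], tree$edge[, 1L])
    res <- list()
    rec <- function(node) {
        # returns TRUE if all leaves below node are in `leaves`
        if (node <= ntip) return(tree$tip.label[node] %in% leaves)
        kids <- children[[as.character(node)]]
        allIn <- vapply(kids, rec, logical(1))
        if (all(allIn)) return(TRUE)
        for (kid in kids[allIn]) {
            tips <- if (kid <= ntip) tree$tip.label[kid] else
                ape::extract.clade(tree, kid)$tip.label
            res[[length(res) + 1L]] <<- tips
        }
        FALSE
    }
    if (rec(ntip + 1L))
        res[[length(res) + 1L]] <- tree$tip.label
    res
}

#' Neighbor-joining tree with bootstrap support
#'
#' NJ on Jukes-Cantor distances with nonparametric bootstrap support from
#' resampled alignment columns; deterministic given \code{seed}.
#'
#' @param aln named \link[Biostrings]{DNAStringSet} (aligned) or character.
#' @param bootstrap number of bootstrap resamples (0 to skip).
#' @param seed RNG seed.
#' @return a \code{phylo}; \code{node.label} carries bootstrap counts when
#'   requested.
#' @export
buildNjTree <- function(aln, bootstrap = 100L, seed = 1L) {
    if (is.character(aln)) aln <- Biostrings::DNAStringSet(aln)
    if (length(aln) < 3L) stop("need at least 3 sequences")
    bin <- ape::as.DNAbin(Biostrings::DNAMultipleAlignment(aln))
    D <- ape::dist.dna(bin, model = "JC69", pairwise.deletion = TRUE)
    D[is.na(D) | is.nan(D)] <- 0
    tr <- ape::nj(D)
    tr$edge.length[tr$edge.length < 0] <- 0
    if (bootstrap > 0L) {
        set.seed(seed)
        bp <- ape::boot.phylo(tr, as.matrix(bin), function(x) {
            d <- ape::dist.dna(x, model = "JC69",
                               pairwise.deletion = TRUE)
            d[is.na(d) | is.nan(d)] <- 0
            t2 <- ape::nj(d)
            t2$edge.length[t2$edge.length < 0] <- 0
            t2
        }, B = bootstrap, quiet = TRUE)
        tr$node.label <- bp
    }
    tr
}
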