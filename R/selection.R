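# Recombination-aware, counting-based selection analysis: Nei-Gojobori
# pairwise dN/dS with Jukes-Cantor correction, dS-based species filtering,
# breakpoint splitting, and a SLAC-style site test on parsimony-
# reconstructed substitutions with binomial significance.

#' Pairwise dN/dS by Nei-Gojobori (NG86) counting
#'
#' Synonymous and nonsynonymous sites are counted per codon (changes to
#' stop codons excluded from the mutational opportunity) and averaged over
#' the two sequences; differences at multi-hit codons are averaged over all
#' minimal mutational pathways that avoid stop codons; proportions are
#' Jukes-Cantor corrected.
#'
#' @param cdsA,cdsB equal-length coding sequences (character or
#'   \code{DNAString}); codons containing gaps or ambiguity characters, and
#'   codon pairs involving a stop, are dropped.
#' @return one-row data.frame: \code{dN}, \code{dS}, \code{omega} (NA when
#'   dS is 0), \code{NSites}, \code{SSites}, \code{NDiff}, \code{SDiff},
#'   \code{saturated} (TRUE when a JC correction was undefined).
#' @export
pairwiseDnDs <- function(cdsA, cdsB) {
    a <- .splitCodons(cdsA)
    b <- .splitCodons(cdsB)
    if (length(a) != length(b))
        stop("sequences must contain the same number of codons")
    ok <- grepl("^[ACGT]{3}$", a) & grepl("^[ACGT]{3}$", b)
    ia <- match(a, allCodons()); ib <- match(b, allCodons())
    aa <- .codonAA()
    ok <- ok & !is.na(ia) & !is.na(ib) & aa[ia] != "*" & aa[ib] != "*"
    ia <- ia[ok]; ib <- ib[ok]
    if (!length(ia))
        return(data.frame(dN = NA_real_, dS = NA_real_, omega = NA_real_,
                          NSites = 0, SSites = 0, NDiff = 0, SDiff = 0,
                          saturated = FALSE))
    sites <- .ngSites()
    S <- (sum(sites$S[ia]) + sum(sites$S[ib])) / 2
    N <- (sum(sites$N[ia]) + sum(sites$N[ib])) / 2
    paths <- .pathCounts()
    Nd <- sum(paths$Nd[cbind(ia, ib)])
    Sd <- sum(paths$Sd[cbind(ia, ib)])
    pN <- Nd / N
    pS <- Sd / S
    jc <- function(p) {
        if (p >= 0.75) return(NA_real_)
        -0.75 * log(1 - 4 * p / 3)
    }
    dN <- jc(pN); dS <- jc(pS)
    saturated <- is.na(dN) || is.na(dS)
    omega <- if (!saturated && dS > 0) dN / dS else NA_real_
    data.frame(dN = dN, dS = dS, omega = omega, NSites = N, SSites = S,
               NDiff = Nd, SDiff = Sd, saturated = saturated)
}

#' Filter species by pairwise dS to a reference
#'
#' @param cdsSet named character vector / \code{DNAStringSet} of aligned
#'   coding sequences (one per species).
#' @param referenceSpecies name of the reference sequence.
#' @param config a \linkS4class{PipelineConfig} (\code{maxPairwiseDs}).
#' @return list with \code{retained} (species names, reference included)
#'   and \code{table} (per-species dS and the decision).
#' @export
filterSpeciesByDs <- function(cdsSet, referenceSpecies,
                              config = pipelineConfig()) {
    seqs <- .seqVector(cdsSet)
    if (!referenceSpecies %in% names(seqs))
        stop("reference species not in the alignment")
    ref <- seqs[[referenceSpecies]]
    rows <- lapply(names(seqs), function(sp) {
        d <- pairwiseDnDs(ref, seqs[[sp]])
        data.frame(species = sp, dS = d$dS,
                   retained = !is.na(d$dS) & d$dS <= config@maxPairwiseDs,
                   stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    list(retained = tab$species[tab$retained], table = tab)
}

#' Split a codon alignment at recombination breakpoints
#'
#' Breakpoints are given in nucleotide alignment coordinates (0-based) and
#' snapped to the nearest codon boundary; the snap direction is reported.
#'
#' @param alignmentWidth nt width of the alignment (or an object with
#'   \code{nchar}/width to take it from).
#' @param breakpoints strictly increasing nt positions inside the
#'   alignment.
#' @return data.frame of segments: \code{segment}, \code{startCodon},
#'   \code{endCodon} (0-based half-open codon interval), plus an attribute
#'   \code{"snapped"} describing any moved breakpoints.
#' @export
splitAtBreakpoints <- function(alignmentWidth, breakpoints = numeric(0)) {
    if (!is.numeric(alignmentWidth)) {
        w <- if (is(alignmentWidth, "DNAStringSet"))
            unique(Biostrings::width(alignmentWidth)) else
            unique(nchar(as.character(alignmentWidth)))
        stopifnot(length(w) == 1L)
        alignmentWidth <- w
    }
    nCod <- alignmentWidth %/% 3L
    if (length(breakpoints)) {
        if (is.unsorted(breakpoints, strictly = TRUE))
            stop("breakpoints must be strictly increasing")
        if (any(breakpoints <= 0 | breakpoints >= alignmentWidth))
            stop("breakpoint outside alignment")
    }
    codBp <- as.integer(round(breakpoints / 3))
    snapped <- breakpoints != codBp * 3
    codBp <- unique(pmin(pmax(codBp, 1L), nCod - 1L))
    bounds <- c(0L, codBp, nCod)
    segs <- data.frame(segment = seq_len(length(bounds) - 1L),
                       startCodon = bounds[-length(bounds)],
                       endCodon = bounds[-1L])
    if (any(snapped))
        attr(segs, "snapped") <- sprintf(
            "breakpoint %g snapped to codon boundary %d",
            breakpoints[snapped], codBp[snapped])
    segs
}

# --- Fitch parsimony over nucleotide columns --------------------------------

.BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)
.lowBitState <- c(1L, 2L, 1L, 3L, 1L, 2L, 1L, 4L, 1L, 2L, 1L, 3L, 1L, 2L,
                  1L)  # lowest set bit (A<C<G<T) for masks 1..15

# Reconstruct ancestral nucleotide states for every column.
# mat: integer matrix (nSeq x nCol) of bitmasks (15 = missing).
# Returns states matrix ((ntip+Nnode) x nCol) of 1..4 state codes.
.fitchStates <- function(mat, tree) {
    ntip <- length(tree$tip.label)
    nNode <- tree$Nnode
    nCol <- ncol(mat)
    masks <- matrix(0L, ntip + nNode, nCol)
    masks[seq_len(ntip), ] <- mat
    post <- rev(tree$edge[, 2L][order(tree$edge[, 1L])])  # not reliable
    # proper postorder: process internal nodes in reverse breadth order
    children <- .treeChildren(tree)
    ord <- integer(0)
    stack <- ntip + 1L
    while (length(stack)) {
        node <- stack[[1L]]; stack <- stack[-1L]
        ord <- c(node, ord)
        kids <- children[[as.character(node)]]
        stack <- c(stack, kids[kids > ntip])
    }
    for (node in ord) {
        kids <- children[[as.character(node)]]
        m <- masks[kids[1L], ]
        for (kid in kids[-1L]) {
            inter <- bitwAnd(m, masks[kid, ])
            m <- ifelse(inter > 0L, inter, bitwOr(m, masks[kid, ]))
        }
        masks[node, ] <- m
    }
    states <- matrix(0L, ntip + nNode, nCol)
    bitOf <- function(state) bitwShiftL(1L, state - 1L)
    root <- ntip + 1L
    states[root, ] <- .lowBitState[masks[root, ]]
    pre <- rev(ord)
    for (node in pre) {
        for (kid in children[[as.character(node)]]) {
            pState <- states[node, ]
            keep <- bitwAnd(masks[kid, ], bitOf(pState)) > 0L
            states[kid, ] <- ifelse(keep, pState,
                                    .lowBitState[masks[kid, ]])
        }
    }
    states
}

.alnToMasks <- function(aln) {
    seqs <- .seqVector(aln)
    nCol <- unique(nchar(seqs))
    stopifnot(length(nCol) == 1L)
    t(vapply(seqs, function(s) {
        v <- .BITS[strsplit(s, "")[[1]]]
        v[is.na(v)] <- 15L
        unname(v)
    }, integer(nCol)))
}

#' SLAC-style site-wise positive selection scan
#'
#' Ancestral codons are reconstructed by Fitch parsimony on the fixed
#' species tree (ties resolved toward the parental state); substitutions on
#' every branch are classified synonymous/nonsynonymous along minimal
#' mutational pathways. The expected nonsynonymous fraction per site comes
#' from the site's codon composition (or a uniform code-wide value),
#' weighting transitions by a kappa estimated from the inferred
#' substitutions. Because the synonymous rate does not depend on omega, the
#' segment-wide mean synonymous count per site estimates every site's
#' substitution exposure; scaled by the site's expected N/S ratio it gives
#' the site's neutral nonsynonymous mean, and a one-sided (Poisson) test
#' flags nonsynonymous excess at \code{siteAlpha}, provided the site's N/S
#' ratio also exceeds the segment-wide ratio.
#'
#' @param aln named \link[Biostrings]{DNAStringSet} (or character vector):
#'   in-frame codon alignment, one sequence per species.
#' @param tree species tree (\code{phylo}) whose tips match \code{names(aln)}.
#' @param config a \linkS4class{PipelineConfig}.
#' @param expectedModel \code{"composition"} (per-site codon composition)
#'   or \code{"uniform"} (code-wide average).
#' @param mask optional integer vector of codon columns (1-based) to
#'   exclude before scanning (e.g. a lineage-specific insertion).
#' @return list with \code{sites} (per-site table: \code{site},
#'   \code{NObs}, \code{SObs}, \code{pExpected}, \code{p}, \code{flagged},
#'   \code{skipped}) and \code{segment} (totals, dN, dS, omega).
#' @export
sitewiseSelectionScan <- function(aln, tree, config = pipelineConfig(),
                                  expectedModel = c("composition",
                                                    "uniform"),
                                  mask = NULL) {
    expectedModel <- match.arg(expectedModel)
    seqs <- .seqVector(aln)
    if (length(seqs) < 6L) stop("need at least 6 sequences")
    if (!all(names(seqs) %in% tree$tip.label) ||
        !all(tree$tip.label %in% names(seqs)))
        stop("tree leaves must match alignment names")
    tree <- ape::reorder.phylo(tree, "cladewise")
    seqs <- seqs[tree$tip.label]
    nCod <- unique(nchar(seqs)) %/% 3L
    if (!is.null(mask)) {
        keepCod <- setdiff(seq_len(nCod), mask)
        seqs <- vapply(seqs, function(s) paste(
            .splitCodons(s)[keepCod], collapse = ""), character(1))
        nCod <- length(keepCod)
    }
    masks <- .alnToMasks(seqs)
    states <- .fitchStates(masks, tree)
    ntip <- length(tree$tip.label)
    cods <- allCodons()
    paths <- .pathCounts()
    # per-branch codon comparison
    NObs <- SObs <- numeric(nCod)
    codonOf <- function(stateRow, site) {
        idx <- (3L * (site - 1L) + 1L):(3L * site)
        s <- stateRow[idx]
        1L + (s[1L] - 1L) * 16L + (s[2L] - 1L) * 4L + (s[3L] - 1L)
    }
    stateCodon <- function(stateRow) {
        n3 <- nCod
        m <- matrix(stateRow[seq_len(3L * n3)], nrow = 3L)
        1L + (m[1L, ] - 1L) * 16L + (m[2L, ] - 1L) * 4L + (m[3L, ] - 1L)
    }
    nodeCodons <- t(apply(states, 1L, stateCodon))
    aaTab <- .codonAA()
    tsSteps <- 0
    for (e in seq_len(nrow(tree$edge))) {
        par <- tree$edge[e, 1L]; chi <- tree$edge[e, 2L]
        cp <- nodeCodons[par, ]; cc <- nodeCodons[chi, ]
        diffIdx <- which(cp != cc)
        if (!length(diffIdx)) next
        # leaves with missing data contribute nothing: their Fitch state
        # equals the parental state wherever the observed mask allowed it
        NObs[diffIdx] <- NObs[diffIdx] + paths$Nd[cbind(cp[diffIdx],
                                                        cc[diffIdx])]
        SObs[diffIdx] <- SObs[diffIdx] + paths$Sd[cbind(cp[diffIdx],
                                                        cc[diffIdx])]
        tsSteps <- tsSteps + sum(paths$Td[cbind(cp[diffIdx],
                                                cc[diffIdx])])
    }
    # expected nonsynonymous fraction under the observed mutation process:
    # the transition/transversion ratio is estimated from the inferred
    # substitutions (each position offers 1 transition and 2 transversion
    # neighbors, so tsFrac = kappa / (kappa + 2))
    totSteps <- sum(NObs) + sum(SObs)
    tsFrac <- if (totSteps > 0) tsSteps / totSteps else 1 / 3
    tsFrac <- min(max(tsFrac, 0.05), 0.95)
    kappaHat <- 2 * tsFrac / (1 - tsFrac)
    fracN <- .kappaWeightedNFrac(kappaHat)
    sense <- aaTab != "*"
    uniformP <- mean(fracN[sense])
    pExp <- numeric(nCod)
    skipped <- logical(nCod)
    leafCod <- matrix(match(unlist(lapply(seqs, .splitCodons)),
                            cods, nomatch = NA_integer_),
                      nrow = length(seqs), byrow = TRUE)
    for (i in seq_len(nCod)) {
        obs <- leafCod[, i]
        obs <- obs[!is.na(obs) & sense[obs]]
        if (!length(obs)) { skipped[i] <- TRUE; pExp[i] <- NA; next }
        pExp[i] <- if (expectedModel == "composition")
            mean(fracN[obs]) else uniformP
    }
    sites <- .ngSites()
    # Neutral expectation for the site's nonsynonymous count: the
    # synonymous rate is the same at every site regardless of omega, so the
    # segment-wide mean synonymous count per site estimates each site's
    # substitution exposure; scaling by the site's expected N/S ratio gives
    # the neutral nonsynonymous mean, against which the observed count is
    # compared one-sided (Poisson).
    lambdaS <- if (sum(!skipped) > 0) sum(SObs) / sum(!skipped) else 0
    NInt <- round(NObs)
    # cap the N:S odds for sites with (almost) no synonymous opportunity
    # (e.g. tryptophan codons), where the scaling would be unbounded
    muNull <- lambdaS * pExp / pmax(1 - pExp, 0.05)
    p <- rep(NA_real_, nCod)
    idx <- which(!skipped & muNull > 0)
    p[idx] <- stats::ppois(NInt[idx] - 1L, muNull[idx],
                           lower.tail = FALSE)
    p[!skipped & muNull == 0] <- 1
    segRatio <- if (sum(SObs) > 0) sum(NObs) / sum(SObs) else Inf
    siteRatio <- ifelse(SObs > 0, NObs / SObs,
                        ifelse(NObs > 0, Inf, 0))
    flagged <- !skipped & !is.na(p) & p <= config@siteAlpha &
        (siteRatio > segRatio | (is.infinite(siteRatio) & NObs > 0))
    # segment-level counting summary
    leafSense <- leafCod
    leafSense[!is.na(leafSense) & !sense[leafSense]] <- NA
    NSites <- mean(colSums(matrix(sites$N[leafSense],
                                  nrow = nrow(leafCod)), na.rm = TRUE) /
                   colSums(!is.na(leafSense)))
    SSitesPer <- colMeans(matrix(sites$S[leafSense], nrow = nrow(leafCod)),
                          na.rm = TRUE)
    NSitesPer <- colMeans(matrix(sites$N[leafSense], nrow = nrow(leafCod)),
                          na.rm = TRUE)
    NSitesTot <- sum(NSitesPer, na.rm = TRUE)
    SSitesTot <- sum(SSitesPer, na.rm = TRUE)
    dN <- if (NSitesTot > 0) sum(NObs) / NSitesTot else NA_real_
    dS <- if (SSitesTot > 0) sum(SObs) / SSitesTot else NA_real_
    omega <- if (!is.na(dS) && dS > 0) dN / dS else NA_real_
    list(sites = data.frame(site = seq_len(nCod), NObs = NObs, SObs = SObs,
                            pExpected = pExp, muNull = muNull, p = p,
                            flagged = flagged, skipped = skipped),
         segment = data.frame(NObs = sum(NObs), SObs = sum(SObs),
                              NSites = NSitesTot, SSites = SSitesTot,
                              dN = dN, dS = dS, omega = omega,
                              nFlagged = sum(flagged)))
}

#' Segment-level test of aggregate nonsynonymous excess
#'
#' Monte-Carlo test: under the null each site's substitutions are
#' nonsynonymous with its neutral expected fraction; the total
#' nonsynonymous count is compared to the resampled distribution
#' (one-sided). Significant at the Bonferroni-corrected gene level.
#'
#' @param scan result of \code{\link{sitewiseSelectionScan}}.
#' @param config a \linkS4class{PipelineConfig}
#'   (\code{geneAlphaBonferroni}).
#' @param nPerm number of resamples (>= 2000 recommended).
#' @param seed RNG seed.
#' @return list with \code{p}, \code{significant}, \code{TObs}.
#' @export
geneLevelTest <- function(scan, config = pipelineConfig(), nPerm = 2000L,
                          seed = 1L) {
    s <- scan$sites[!scan$sites$skipped, ]
    keep <- !is.na(s$muNull) & s$muNull > 0
    mu <- s$muNull[keep]
    TObs <- sum(round(s$NObs[keep]))
    if (!length(mu))
        return(list(p = 1, significant = FALSE, TObs = 0))
    set.seed(seed)
    Tnull <- vapply(seq_len(nPerm), function(i)
        sum(stats::rpois(length(mu), mu)), numeric(1))
    p <- (1 + sum(Tnull >= TObs)) / (nPerm + 1)
    list(p = p, significant = p <= config@geneAlphaBonferroni, TObs = TObs)
}

#' Robustness re-runs of the site scan over a settings grid
#'
#' The scan is repeated under both expected-fraction models and each seed
#' of the grid; a site is robust iff flagged under every setting.
#'
#' @param aln,tree,config,mask as in \code{\link{sitewiseSelectionScan}}.
#' @param seeds integer vector of permutation seeds for the accompanying
#'   segment-level tests.
#' @return data.frame per site: \code{site}, \code{nFlagged},
#'   \code{nSettings}, \code{robust}.
#' @export
robustnessRerun <- function(aln, tree, config = pipelineConfig(),
                            seeds = c(1L, 2L, 3L), mask = NULL) {
    settings <- expand.grid(model = c("composition", "uniform"),
                            seed = seeds, stringsAsFactors = FALSE)
    flags <- NULL
    for (i in seq_len(nrow(settings))) {
        sc <- sitewiseSelectionScan(aln, tree, config,
                                    expectedModel = settings$model[i],
                                    mask = mask)
        f <- sc$sites$flagged
        flags <- if (is.null(flags)) as.integer(f) else flags + f
    }
    data.frame(site = sc$sites$site, nFlagged = flags,
               nSettings = nrow(settings),
               robust = flags == nrow(settings))
}
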