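# Codon-alignment simulation and calibration of the site-wise selection
# test (type-I error under neutrality, power at strongly selected sites).

#' Balanced binary tree with constant branch lengths
#'
#' @param nTaxa number of leaves (4, 8, 12 or 16).
#' @param branchLength substitutions per nucleotide site per branch.
#' @return a \code{phylo} with tips \code{t1..tn}.
#' @export
balancedTree <- function(nTaxa = 12L, branchLength = 0.2) {
    topo <- switch(as.character(nTaxa),
        "4" = "((t1,t2),(t3,t4));",
        "8" = "(((t1,t2),(t3,t4)),((t5,t6),(t7,t8)));",
        "12" = paste0("((((t1,t2),(t3,t4)),((t5,t6),(t7,t8))),",
                      "((t9,t10),(t11,t12)));"),
        "16" = paste0("((((t1,t2),(t3,t4)),((t5,t6),(t7,t8))),",
                      "(((t9,t10),(t11,t12)),((t13,t14),(t15,t16))));"),
        stop("nTaxa must be one of 4, 8, 12, 16"))
    tr <- ape::read.tree(text = topo)
    tr$edge.length <- rep(branchLength, nrow(tr$edge))
    tr
}

#' Simulate a codon alignment along a tree
#'
#' Each codon site evolves independently under the package codon jump
#' process (HKY mutation, nonsynonymous rate multiplied by the site's
#' omega; changes to stop codons disallowed).
#'
#' @param tree a \code{phylo} with branch lengths (substitutions/nt site).
#' @param nCodons number of codon sites.
#' @param omega per-site dN/dS (recycled).
#' @param kappa HKY transition/transversion ratio.
#' @param seed RNG seed.
#' @return named character vector of in-frame coding sequences.
#' @export
simulateCodonAlignment <- function(tree, nCodons, omega = 1, kappa = 4,
                                   seed = 1L) {
    set.seed(seed)
    omega <- rep_len(omega, nCodons)
    sense <- setdiff(.senseCodons(), c("TAA", "TAG", "TGA"))
    anc <- match(sample(sense, nCodons, replace = TRUE), allCodons())
    ntip <- length(tree$tip.label)
    children <- .treeChildren(tree)
    elen <- stats::setNames(tree$edge.length, tree$edge[, 2L])
    out <- list()
    walk <- function(node, cod) {
        if (node <= ntip) {
            out[[tree$tip.label[node]]] <<- cod
            return(invisible())
        }
        for (k in children[[as.character(node)]])
            walk(k, .evolveCodons(cod, omega,
                                  elen[[as.character(k)]], kappa))
    }
    walk(ntip + 1L, anc)
    vapply(out, function(ci) paste(allCodons()[ci], collapse = ""),
           character(1))[tree$tip.label]
}

#' Calibrate the site-wise selection test by simulation
#'
#' Runs two simulation suites on a balanced tree: (1) neutral replicates
#' (omega = 1 everywhere) measuring the empirical per-site type-I error
#' and the gene-level significance rate; (2) power replicates with
#' \code{selOmega} at \code{nSelSites} designated sites on a purifying
#' background, measuring detection power and the false-flag rate at
#' background sites.
#'
#' @param nRep replicates per suite.
#' @param nTaxa,branchLength tree shape (see \code{\link{balancedTree}}).
#' @param nCodons codon sites per replicate.
#' @param selOmega omega at designated selected sites.
#' @param backgroundOmega omega elsewhere in the power suite.
#' @param nSelSites number of designated selected sites.
#' @param kappa HKY kappa.
#' @param config a \linkS4class{PipelineConfig}.
#' @param seed base RNG seed.
#' @return list with \code{typeI} (neutral per-site flag rate),
#'   \code{typeISE} (its binomial standard error), \code{geneLevelRate},
#'   \code{power}, \code{falseFlagRate}, and the per-replicate tables.
#' @export
siteTestCalibration <- function(nRep = 20L, nTaxa = 12L, nCodons = 300L,
                                branchLength = 0.15, selOmega = 4,
                                backgroundOmega = 0.2, nSelSites = 10L,
                                kappa = 4, config = pipelineConfig(),
                                seed = 1L) {
    tree <- balancedTree(nTaxa, branchLength)
    neutralFlags <- 0L; neutralSites <- 0L; geneSig <- 0L
    for (r in seq_len(nRep)) {
        aln <- simulateCodonAlignment(tree, nCodons, omega = 1,
                                      kappa = kappa, seed = seed + r)
        sc <- sitewiseSelectionScan(aln, tree, config)
        neutralFlags <- neutralFlags + sum(sc$sites$flagged)
        neutralSites <- neutralSites + sum(!sc$sites$skipped)
        gl <- geneLevelTest(sc, config, seed = seed + r)
        geneSig <- geneSig + gl$significant
    }
    selIdx <- as.integer(round(seq(nCodons / (2L * nSelSites), nCodons,
                                   length.out = nSelSites)))
    omega <- rep(backgroundOmega, nCodons)
    omega[selIdx] <- selOmega
    selFlag <- 0L; bgFlag <- 0L; bgSites <- 0L
    for (r in seq_len(nRep)) {
        aln <- simulateCodonAlignment(tree, nCodons, omega = omega,
                                      kappa = kappa,
                                      seed = seed + 1000L + r)
        sc <- sitewiseSelectionScan(aln, tree, config)
        selFlag <- selFlag + sum(sc$sites$flagged[selIdx])
        bgFlag <- bgFlag + sum(sc$sites$flagged[-selIdx])
        bgSites <- bgSites + sum(!sc$sites$skipped[-selIdx])
    }
    typeI <- neutralFlags / neutralSites
    list(typeI = typeI,
         typeISE = sqrt(config@siteAlpha * (1 - config@siteAlpha) /
                        neutralSites),
         geneLevelRate = geneSig / nRep,
         power = selFlag / (nRep * nSelSites),
         falseFlagRate = bgFlag / bgSites,
         nNeutralSites = neutralSites)
}
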