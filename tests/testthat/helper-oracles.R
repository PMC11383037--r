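# Independent oracles used by the tests. These re-derive expected values by
# brute force / closed form, structured differently from the package
# implementations they check.

oracleNT <- c("A", "C", "G", "T")
oracleCodons <- apply(expand.grid(oracleNT, oracleNT, oracleNT)[, 3:1], 1,
                      paste, collapse = "")
oracleAA <- unname(Biostrings::GENETIC_CODE[oracleCodons])

# --- NG86 oracle -------------------------------------------------------------

# synonymous site count of one codon: per position, the fraction of
# non-stop single-nucleotide changes that preserve the amino acid
oracleSynSites <- function(codon) {
    nts <- strsplit(codon, "")[[1]]
    aa0 <- Biostrings::GENETIC_CODE[[codon]]
    total <- 0
    for (pos in 1:3) {
        syn <- 0; nonStop <- 0
        for (nt in oracleNT[oracleNT != nts[pos]]) {
            alt <- nts; alt[pos] <- nt
            altC <- paste(alt, collapse = "")
            altAA <- Biostrings::GENETIC_CODE[[altC]]
            if (altAA == "*") next
            nonStop <- nonStop + 1
            if (altAA == aa0) syn <- syn + 1
        }
        if (nonStop > 0) total <- total + syn / nonStop
    }
    total
}

# recursive enumeration of all orderings of the differing positions,
# classifying each step; pathways through stop codons are dropped unless
# every pathway is blocked
oraclePathCounts <- function(a, b) {
    enum <- function(cur, target) {
        d <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
        if (!length(d))
            return(list(list(syn = 0, nonsyn = 0, blocked = FALSE)))
        out <- list()
        for (pos in d) {
            nxt <- strsplit(cur, "")[[1]]
            nxt[pos] <- strsplit(target, "")[[1]][pos]
            nxtC <- paste(nxt, collapse = "")
            stepSyn <- Biostrings::GENETIC_CODE[[cur]] ==
                Biostrings::GENETIC_CODE[[nxtC]] &&
                Biostrings::GENETIC_CODE[[nxtC]] != "*"
            blockedHere <- Biostrings::GENETIC_CODE[[nxtC]] == "*"
            for (tail in enum(nxtC, target)) {
                out[[length(out) + 1L]] <- list(
                    syn = tail$syn + as.numeric(stepSyn),
                    nonsyn = tail$nonsyn + as.numeric(!stepSyn),
                    blocked = tail$blocked || blockedHere)
            }
        }
        out
    }
    paths <- enum(a, b)
    ok <- !vapply(paths, `[[`, logical(1), "blocked")
    if (any(ok)) paths <- paths[ok]
    c(Nd = mean(vapply(paths, `[[`, numeric(1), "nonsyn")),
      Sd = mean(vapply(paths, `[[`, numeric(1), "syn")))
}

# full NG86 dN/dS for two sequences, from the primitives above
oracleDnDs <- function(a, b) {
    ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
    cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
    S <- mean(c(sum(vapply(ca, oracleSynSites, numeric(1))),
                sum(vapply(cb, oracleSynSites, numeric(1)))))
    N <- 3 * length(ca) - S
    Nd <- Sd <- 0
    for (i in seq_along(ca)) {
        if (ca[i] == cb[i]) next
        pc <- oraclePathCounts(ca[i], cb[i])
        Nd <- Nd + pc["Nd"]; Sd <- Sd + pc["Sd"]
    }
    jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
    c(dN = jc(Nd / N), dS = jc(Sd / S))
}

# --- Dollo brute force -------------------------------------------------------

# minimum number of branches (within the clade of the MRCA of intact
# leaves) whose removal explains all non-intact leaves
oracleDolloMin <- function(tree, presence) {
    intact <- names(presence)[presence]
    ntip <- length(tree$tip.label)
    origin <- if (length(intact) == 1L) match(intact, tree$tip.label) else
        ape::getMRCA(tree, intact)
    if (origin <= ntip)
        return(as.integer(!presence[[tree$tip.label[origin]]]))
    # edges within the origin subtree
    sub <- integer(0)
    gather <- function(node) {
        kids <- tree$edge[tree$edge[, 1L] == node, 2L]
        for (k in kids) {
            sub <<- c(sub, which(tree$edge[, 1L] == node &
                                 tree$edge[, 2L] == k))
            if (k > ntip) gather(k)
        }
    }
    gather(origin)
    # leaf x edge incidence over paths origin -> leaf inside the clade
    cladeTips <- match(ape::extract.clade(tree, origin)$tip.label,
                       tree$tip.label)
    inc <- matrix(FALSE, length(cladeTips), nrow(tree$edge))
    for (j in seq_along(cladeTips)) {
        p <- ape::nodepath(tree, origin, cladeTips[j])
        for (i in seq_len(length(p) - 1L))
            inc[j, tree$edge[, 1L] == p[i] &
                   tree$edge[, 2L] == p[i + 1L]] <- TRUE
    }
    need <- !presence[tree$tip.label[cladeTips]]
    explained <- function(cut) {
        hit <- if (length(cut) == 1L) inc[, cut] else
            rowSums(inc[, cut, drop = FALSE]) > 0L
        all(hit == need)
    }
    if (!any(need)) return(0L)
    for (k in seq_len(min(length(sub), 8L))) {
        combs <- utils::combn(sub, k)
        for (cc in seq_len(ncol(combs)))
            if (explained(combs[, cc])) return(k)
    }
    NA_integer_
}

# --- K80 closed form ---------------------------------------------------------

# expected transition / transversion observation probabilities after
# divergence t (substitutions/site) under kappa
k80ExpectedTsTv <- function(t, kappa) {
    beta <- 1 / (kappa + 2)
    alpha <- kappa * beta
    e1 <- exp(-4 * beta * t)
    e2 <- exp(-2 * (alpha + beta) * t)
    pTs <- 0.25 + 0.25 * e1 - 0.5 * e2
    pTv <- 0.5 - 0.5 * e1
    c(pTs = pTs, pTv = pTv)
}
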