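# Genetic-code machinery shared by the simulator and the selection scans.
# All tables are computed once per session and cached.

.caspevo_cache <- new.env(parent = emptyenv())

.NT <- c("A", "C", "G", "T")

.cached <- function(key, fn) {
    if (!exists(key, envir = .caspevo_cache, inherits = FALSE))
        assign(key, fn(), envir = .caspevo_cache)
    get(key, envir = .caspevo_cache, inherits = FALSE)
}

#' All 64 codons in lexicographic order
#' @return character vector of 64 codons.
#' @keywords internal
allCodons <- function() {
    .cached("codons", function() {
        g <- expand.grid(p3 = .NT, p2 = .NT, p1 = .NT,
                         stringsAsFactors = FALSE)
        paste0(g$p1, g$p2, g$p3)
    })
}

.codonAA <- function() {
    .cached("aa", function() {
        gc <- Biostrings::GENETIC_CODE
        unname(gc[allCodons()])
    })
}

.stopCodons <- function() allCodons()[.codonAA() == "*"]
.senseCodons <- function() allCodons()[.codonAA() != "*"]

.isTransitionPair <- function(a, b) {
    (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

# One row per single-nucleotide codon change: 64 codons x 3 positions x 3
# alternative nucleotides.
.neighborTable <- function() {
    .cached("neighbors", function() {
        cods <- allCodons()
        aa <- .codonAA()
        rows <- vector("list", 64L)
        for (i in seq_len(64L)) {
            from <- cods[i]
            nts <- strsplit(from, "")[[1]]
            out <- list()
            for (pos in 1:3) {
                for (nt in setdiff(.NT, nts[pos])) {
                    to <- nts
                    to[pos] <- nt
                    to <- paste(to, collapse = "")
                    out[[length(out) + 1L]] <- data.frame(
                        from = from, to = to, pos = pos,
                        fromNt = nts[pos], toNt = nt,
                        stringsAsFactors = FALSE)
                }
            }
            rows[[i]] <- do.call(rbind, out)
        }
        tab <- do.call(rbind, rows)
        tab$toAA <- aa[match(tab$to, cods)]
        tab$fromAA <- aa[match(tab$from, cods)]
        tab$isStop <- tab$toAA == "*"
        tab$isSyn <- !tab$isStop & tab$fromAA == tab$toAA
        tab$isTransition <- .isTransitionPair(tab$fromNt, tab$toNt)
        tab
    })
}

# Nei-Gojobori synonymous/nonsynonymous site counts per codon. At each codon
# position the three alternative nucleotides are considered; changes creating
# a stop codon are excluded from the mutational opportunity and the position
# contributes (syn changes)/(non-stop changes) synonymous sites.
.ngSites <- function() {
    .cached("ngsites", function() {
        nb <- .neighborTable()
        cods <- allCodons()
        S <- N <- rep(NA_real_, 64L)
        for (i in seq_len(64L)) {
            if (.codonAA()[i] == "*") next
            rows <- nb[nb$from == cods[i], ]
            s <- 0
            for (pos in 1:3) {
                pr <- rows[rows$pos == pos & !rows$isStop, ]
                if (nrow(pr) > 0L)
                    s <- s + sum(pr$isSyn) / nrow(pr)
            }
            S[i] <- s
            N[i] <- 3 - s
        }
        list(S = S, N = N)
    })
}

# Average numbers of synonymous and nonsynonymous steps between every pair of
# sense codons, averaged over all minimal mutational pathways that avoid stop
# codons (all pathways if every one passes through a stop).
.pathCounts <- function() {
    .cached("paths", function() {
        cods <- allCodons()
        aa <- .codonAA()
        Nd <- Sd <- matrix(0, 64L, 64L, dimnames = list(cods, cods))
        stepClass <- function(a, b) {
            # 1 = synonymous, 0 = nonsynonymous
            as.numeric(aa[match(a, cods)] == aa[match(b, cods)])
        }
        permsOf <- function(v) {
            if (length(v) <= 1L) return(list(v))
            out <- list()
            for (i in seq_along(v))
                for (p in permsOf(v[-i]))
                    out[[length(out) + 1L]] <- c(v[i], p)
            out
        }
        Td <- matrix(0, 64L, 64L, dimnames = list(cods, cods))
        for (i in seq_len(64L)) {
            if (aa[i] == "*") next
            a <- strsplit(cods[i], "")[[1]]
            for (j in seq_len(64L)) {
                if (aa[j] == "*" || i == j) next
                b <- strsplit(cods[j], "")[[1]]
                diffPos <- which(a != b)
                paths <- permsOf(diffPos)
                keep <- syn <- nonsyn <- trans <- numeric(0)
                for (p in paths) {
                    cur <- a
                    s <- n <- ts <- 0
                    blocked <- FALSE
                    for (pos in p) {
                        nxt <- cur
                        nxt[pos] <- b[pos]
                        curC <- paste(cur, collapse = "")
                        nxtC <- paste(nxt, collapse = "")
                        if (aa[match(nxtC, cods)] == "*") blocked <- TRUE
                        if (stepClass(curC, nxtC) == 1) s <- s + 1
                        else n <- n + 1
                        if (.isTransitionPair(cur[pos], b[pos]))
                            ts <- ts + 1
                        cur <- nxt
                    }
                    keep <- c(keep, !blocked)
                    syn <- c(syn, s)
                    nonsyn <- c(nonsyn, n)
                    trans <- c(trans, ts)
                }
                if (any(keep == 1)) {
                    syn <- syn[keep == 1]
                    nonsyn <- nonsyn[keep == 1]
                    trans <- trans[keep == 1]
                }
                Sd[i, j] <- mean(syn)
                Nd[i, j] <- mean(nonsyn)
                Td[i, j] <- mean(trans)
            }
        }
        list(Nd = Nd, Sd = Sd, Td = Td)
    })
}

# per-codon expected fraction of nonsynonymous changes among single-nt
# changes, weighting transitions by kappa and excluding changes to stops
.kappaWeightedNFrac <- function(kappa) {
    nb <- .neighborTable()
    nb <- nb[!nb$isStop, ]
    w <- ifelse(nb$isTransition, kappa, 1)
    idx <- match(nb$from, allCodons())
    num <- tapply(w * as.numeric(!nb$isSyn), idx, sum)
    den <- tapply(w, idx, sum)
    out <- rep(NA_real_, 64L)
    out[as.integer(names(num))] <- num / den
    out
}

.translateCodons <- function(codons) {
    aa <- .codonAA()[match(codons, allCodons())]
    aa[is.na(aa)] <- "X"
    aa
}

# Split a nucleotide string into codons (frame 0); trailing partial codon
# dropped.
.splitCodons <- function(x) {
    x <- as.character(x)
    n <- nchar(x) %/% 3L
    if (n == 0L) return(character(0))
    substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

.translateCDS <- function(x) {
    paste(.translateCodons(.splitCodons(x)), collapse = "")
}

# named sequence vector from character or XStringSet input (base
# as.character would strip names from a character vector)
.seqVector <- function(x) {
    if (is.character(x)) x else as.character(x)
}
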