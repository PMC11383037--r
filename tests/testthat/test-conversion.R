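plantTract <- function(bg, tract, at) {
    paste0(substr(bg, 1, at), tract,
           substr(bg, at + nchar(tract) + 1, nchar(bg)))
}

mutateTo <- function(s, identity, seed) {
    set.seed(seed)
    v <- strsplit(s, "")[[1]]
    k <- round(length(v) * (1 - identity))
    idx <- sample(length(v), k)
    for (i in idx) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
    paste(v, collapse = "")
}

test_that("random loci contain no blocks at default thresholds", {
    for (seed in 1:10) {
        s <- randomDna(50000, seed = seed)
        expect_equal(nrow(findSimilarityBlocks(s)), 0L, info = seed)
    }
})

test_that("a planted diverged duplication is recovered with its identity", {
    bg <- randomDna(60000, seed = 101)
    tract <- substr(bg, 10001, 12000)
    s <- plantTract(bg, mutateTo(tract, 0.85, 7), 40000)
    bl <- findSimilarityBlocks(s)
    expect_equal(nrow(bl), 1L)
    cover <- (min(bl$aEnd0, 12000) - max(bl$aStart0, 10000)) / 2000
    expect_gte(cover, 0.9)
    expect_lt(abs(bl$identity - 0.85), 0.03)
    expect_equal(bl$orientation, "direct")
    expect_true(bl$aEnd0 <= bl$bStart0)  # non-overlapping, a before b
})

test_that("inverted duplications are found and labeled", {
    bg <- randomDna(40000, seed = 102)
    tract <- substr(bg, 5001, 6500)
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(tract)))
    s <- plantTract(bg, rc, 25000)
    bl <- findSimilarityBlocks(s)
    expect_equal(nrow(bl), 1L)
    expect_equal(bl$orientation, "inverted")
    expect_gt(bl$identity, 0.99)
})

test_that("blocks mirror under reverse complement of the locus", {
    bg <- randomDna(30000, seed = 103)
    tract <- substr(bg, 4001, 5500)
    s <- plantTract(bg, mutateTo(tract, 0.9, 8), 20000)
    L <- nchar(s)
    bl <- findSimilarityBlocks(s)
    blRc <- findSimilarityBlocks(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s))))
    expect_equal(nrow(bl), nrow(blRc))
    # reflected coordinates of the rc blocks match the originals
    refl <- data.frame(aStart0 = L - blRc$bEnd0, aEnd0 = L - blRc$bStart0,
                       bStart0 = L - blRc$aEnd0, bEnd0 = L - blRc$aStart0)
    expect_lt(max(abs(sort(c(refl$aStart0, refl$bStart0)) -
                      sort(c(bl$aStart0, bl$bStart0)))), 30)
})

test_that("raising thresholds never increases the block count", {
    bg <- randomDna(40000, seed = 104)
    tract <- substr(bg, 3001, 5000)
    s <- plantTract(bg, mutateTo(tract, 0.8, 9), 22000)
    s <- plantTract(s, mutateTo(substr(bg, 9001, 10200), 0.9, 10), 30000)
    n1 <- nrow(findSimilarityBlocks(s, pipelineConfig()))
    n2 <- nrow(findSimilarityBlocks(s, pipelineConfig(
        blockMinIdentity = 0.85)))
    n3 <- nrow(findSimilarityBlocks(s, pipelineConfig(
        blockMinLen = 1500L)))
    expect_lte(n2, n1)
    expect_lte(n3, n1)
})

test_that("block detection agrees with a brute-force window scan", {
    # small locus, one planted tract; the oracle scans all window pairs
    bg <- randomDna(15000, seed = 105)
    tract <- substr(bg, 2001, 3200)
    s <- plantTract(bg, mutateTo(tract, 0.88, 11), 9000)
    bl <- findSimilarityBlocks(s)
    win <- 1000L; step <- 500L
    starts <- seq(0L, nchar(s) - win, by = step)
    oracleHits <- list()
    for (i in seq_along(starts)) for (j in seq_along(starts)) {
        if (starts[j] < starts[i] + win) next
        wa <- substr(s, starts[i] + 1L, starts[i] + win)
        wb <- substr(s, starts[j] + 1L, starts[j] + win)
        pa <- Biostrings::pairwiseAlignment(
            wa, wb, type = "local",
            substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
                1, -2, baseOnly = TRUE),
            gapOpening = 1, gapExtension = 1)
        matched <- Biostrings::nmatch(pa)
        if (matched >= 0.5 * win &&
            Biostrings::nchar(pa) >= 0.8 * win)
            oracleHits[[length(oracleHits) + 1L]] <- c(starts[i], starts[j])
    }
    expect_gt(length(oracleHits), 0)
    expect_equal(nrow(bl), 1L)
    # every oracle window pair falls inside the detected block pair
    for (h in oracleHits) {
        expect_true(h[1] >= bl$aStart0 - win & h[1] <= bl$aEnd0)
        expect_true(h[2] >= bl$bStart0 - win & h[2] <= bl$bEnd0)
    }
})

test_that("block ends are classified against gene annotations", {
    exons <- data.frame(gene = c("g1", "g1", "g2", "g2"),
                        start0 = c(1000L, 3000L, 20000L, 22000L),
                        end0 = c(1300L, 3300L, 20300L, 22300L))
    blocks <- data.frame(
        aStart0 = c(1500L, 900L, 5000L), aEnd0 = c(2500L, 3400L, 6500L),
        bStart0 = c(20500L, 19900L, 30000L),
        bEnd0 = c(21500L, 22400L, 31500L),
        orientation = "direct", length = 1000L, identity = 0.9)
    ann <- annotateBlockGeneOverlap(blocks, exons)
    expect_equal(ann$aClass[1], "intronic")
    expect_equal(ann$aClass[2], "mixed")
    expect_equal(ann$aClass[3], "intergenic")
    expect_match(ann$aGenes[3], "near:")
    expect_equal(ann$bClass[1], "intronic")
})

test_that("simulated rodent-like repeats stay confined to non-coding DNA", {
    tr <- sixSpeciesTree()
    lay <- compactLayout()
    # plant an intergenic repeat: copy 1.4 kb of intergenic sequence into
    # another intergenic position on the branch to all species
    cfg <- simConfig(tr, lay, events = list(
        list(kind = "segmental_insertion", branch = "A,B,C,D,E,F",
             srcStart = 200L, len = 1400L, insertAt = 2500L)), seed = 51L)
    sim <- simulateDataset(cfg)
    loc <- simLoci(sim)$A
    bl <- findSimilarityBlocks(loc)
    expect_gte(nrow(bl), 1L)
    ex <- simTruth(sim)$exons
    ex <- ex[ex$species == "A", ]
    ann <- annotateBlockGeneOverlap(bl, ex)
    expect_true(all(ann$aClass != "coding" & ann$bClass != "coding"))
})

test_that("paralog-tree intermixing recovers scripted conversions", {
    tr <- sixSpeciesTree()
    lay <- compactLayout()
    run <- function(events, seed) {
        sim <- simulateDataset(simConfig(tr, lay, events = events,
                                         seed = seed))
        tru <- simTruth(sim)
        seqs <- character(0); gl <- character(0); sl <- character(0)
        for (sp in names(tru$cds))
            for (g in c("casp1", "casp4", "casp5", "casp12")) {
                s <- tru$cds[[sp]][[g]]
                if (!is.null(s)) {
                    seqs <- c(seqs, s); gl <- c(gl, g); sl <- c(sl, sp)
                }
            }
        detectTreeIntermixing(seqs, gl, sl, tr)
    }
    expect_equal(run(list(), 61L)$nEvents, 0L)
    one <- run(list(list(kind = "conversion", branch = "D,E",
                         gene = "casp5", donor = "casp4", offset = 0L,
                         len = 5200L)), 62L)
    expect_equal(one$nEvents, 1L)
    expect_equal(one$events$clade, "D,E")
    three <- run(list(
        list(kind = "conversion", branch = "D,E", gene = "casp5",
             donor = "casp4", offset = 0L, len = 5200L),
        list(kind = "conversion", branch = "A,B", gene = "casp12",
             donor = "casp1", offset = 0L, len = 5200L),
        list(kind = "conversion", branch = "C", gene = "casp1",
             donor = "casp4", offset = 0L, len = 5200L)), 63L)
    expect_equal(three$nEvents, 3L)
})

test_that("intermixing requires a cross-species baseline", {
    expect_error(detectTreeIntermixing(
        c("ATG", "ATG", "ATG", "ATG"), c("a", "b", "a", "b"),
        c("s1", "s1", "s2", "s2"), sixSpeciesTree()), "3 species")
})

test_that("NJ recovers additive topologies and handles degenerate input", {
    set.seed(71)
    base <- randomDna(600)
    mk <- function(s, n) mutateTo(s, 1 - n / 600, seed = n)
    a <- mk(base, 5); b <- mk(a, 3); c <- mk(base, 40); d <- mk(c, 4)
    aln <- c(A = a, B = b, C = c, D = d)
    tr <- buildNjTree(aln, bootstrap = 20L, seed = 1L)
    expect_true(ape::is.monophyletic(tr, c("A", "B")) ||
                ape::is.monophyletic(tr, c("C", "D")))
    # identical pair: zero-length sister branches
    aln2 <- c(X = base, Y = base, Z = mk(base, 30))
    tr2 <- buildNjTree(aln2, bootstrap = 0L)
    xy <- tr2$edge.length[tr2$edge[, 2L] %in%
                          match(c("X", "Y"), tr2$tip.label)]
    expect_equal(unname(xy), c(0, 0))
})
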