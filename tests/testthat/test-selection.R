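test_that("NG86 handles identity, synonymous-only and example codons", {
    a <- paste(rep("GAA", 100), collapse = "")
    expect_equal(pairwiseDnDs(a, a)$dN, 0)
    expect_equal(pairwiseDnDs(a, a)$dS, 0)
    expect_true(is.na(pairwiseDnDs(a, a)$omega))
    b <- paste(c(rep("GAA", 99), "GAG"), collapse = "")
    d <- pairwiseDnDs(a, b)
    expect_equal(d$dN, 0)
    expect_gt(d$dS, 0)
})

test_that("NG86 is symmetric and matches the pathway-enumeration oracle", {
    # random codon pairs here; the exhaustive 61 x 61 comparison runs in
    # the acceptance suite
    paths <- caspevo:::.pathCounts()
    sense <- caspevo:::.senseCodons()
    set.seed(16)
    for (rep in 1:200) {
        a <- sample(sense, 1); b <- sample(sense, 1)
        o <- oraclePathCounts(a, b)
        expect_equal(paths$Nd[a, b], unname(o["Nd"]), info = paste(a, b))
        expect_equal(paths$Sd[a, b], unname(o["Sd"]), info = paste(a, b))
    }
    # per-codon site counts, exact
    ng <- caspevo:::.ngSites()
    for (a in sense) {
        i <- match(a, caspevo:::allCodons())
        expect_equal(ng$S[i], oracleSynSites(a), info = a)
    }
    # symmetry and full-sequence agreement on random pairs
    set.seed(17)
    for (rep in 1:5) {
        a <- paste(sample(sense, 30, replace = TRUE), collapse = "")
        b <- paste(sample(sense, 30, replace = TRUE), collapse = "")
        d1 <- pairwiseDnDs(a, b)
        d2 <- pairwiseDnDs(b, a)
        expect_equal(d1$dN, d2$dN)
        expect_equal(d1$dS, d2$dS)
        o <- oracleDnDs(a, b)
        if (!is.na(o["dN"])) expect_equal(d1$dN, unname(o["dN"]))
        if (!is.na(o["dS"])) expect_equal(d1$dS, unname(o["dS"]))
    }
})

test_that("saturated proportions are reported, not silently corrected", {
    # every 4-fold third position differs: pS = 1, beyond the JC domain
    a <- paste(rep("GGT", 100), collapse = "")
    b <- paste(rep("GGC", 100), collapse = "")
    d <- pairwiseDnDs(a, b)
    expect_true(d$saturated)
    expect_true(is.na(d$dS))
})

test_that("the dS filter retains to 0.3 and excludes beyond", {
    # GAT has one synonymous third-position change (GAT->GAC); mutating k
    # codons of 200 gives pS = k / (200 * S_per_codon)
    ref <- paste(rep("GAT", 200), collapse = "")
    mutateK <- function(k) {
        cods <- rep("GAT", 200)
        cods[seq_len(k)] <- "GAC"
        paste(cods, collapse = "")
    }
    near <- mutateK(16)   # dS = 0.289
    over <- mutateK(17)   # dS = 0.310
    expect_lt(pairwiseDnDs(ref, near)$dS, 0.3)
    expect_gt(pairwiseDnDs(ref, over)$dS, 0.3)
    flt <- filterSpeciesByDs(c(ref = ref, near = near, over = over), "ref")
    expect_setequal(flt$retained, c("ref", "near"))
    expect_equal(flt$table$dS[flt$table$species == "ref"], 0)
})

test_that("breakpoint splitting snaps to codon boundaries", {
    segs <- splitAtBreakpoints(900, c(300, 612))
    expect_equal(segs$startCodon, c(0L, 100L, 204L))
    expect_equal(segs$endCodon, c(100L, 204L, 300L))
    one <- splitAtBreakpoints(900)
    expect_equal(nrow(one), 1L)
    expect_equal(one$endCodon, 300L)
    snap <- splitAtBreakpoints(900, 301)
    expect_equal(snap$startCodon, c(0L, 100L))
    expect_match(attr(snap, "snapped"), "snapped")
    expect_error(splitAtBreakpoints(900, 1000), "outside")
    expect_error(splitAtBreakpoints(900, c(500, 300)), "increasing")
})

test_that("per-site substitution counts are additive over segments", {
    tr <- balancedTree(8, 0.1)
    aln <- simulateCodonAlignment(tr, 120, omega = 1, seed = 19)
    whole <- sitewiseSelectionScan(aln, tr)
    segs <- splitAtBreakpoints(360, c(180))
    parts <- lapply(seq_len(nrow(segs)), function(i) {
        cols <- (segs$startCodon[i] * 3 + 1):(segs$endCodon[i] * 3)
        sub <- vapply(aln, function(s) substr(s, min(cols), max(cols)),
                      character(1))
        sitewiseSelectionScan(sub, tr)
    })
    expect_equal(sum(whole$sites$NObs),
                 sum(vapply(parts, function(p) sum(p$sites$NObs),
                            numeric(1))))
    expect_equal(sum(whole$sites$SObs),
                 sum(vapply(parts, function(p) sum(p$sites$SObs),
                            numeric(1))))
})

test_that("parsimony substitution totals match an independent Fitch score", {
    skip_if_not_installed("phangorn")
    tr <- balancedTree(8, 0.05)
    aln <- simulateCodonAlignment(tr, 60, omega = 1, seed = 23)
    sc <- sitewiseSelectionScan(aln, tr)
    mat <- do.call(rbind, strsplit(unname(aln[tr$tip.label]), ""))
    rownames(mat) <- tr$tip.label
    pd <- phangorn::phyDat(mat, type = "DNA")
    fitchTotal <- phangorn::fitch(ape::unroot(tr), pd)
    # low divergence: nearly all codon diffs are single steps, so the
    # summed N+S counts equal the nucleotide parsimony score
    expect_equal(sum(sc$sites$NObs) + sum(sc$sites$SObs), fitchTotal,
                 tolerance = 0.02)
})

test_that("an invariant alignment yields no substitutions and no flags", {
    tr <- balancedTree(8, 0.1)
    aln <- stats::setNames(rep(strrep("ATGGCTAGT", 20), 8), tr$tip.label)
    sc <- sitewiseSelectionScan(aln, tr)
    expect_equal(sum(sc$sites$NObs), 0)
    expect_equal(sum(sc$sites$flagged), 0)
    expect_equal(geneLevelTest(sc)$p, 1)
})

test_that("all-gap codon columns are skipped and reported", {
    tr <- balancedTree(8, 0.1)
    aln <- simulateCodonAlignment(tr, 50, omega = 1, seed = 29)
    aln <- vapply(aln, function(s)
        paste0(substr(s, 1, 30), "---", substr(s, 34, nchar(s))),
        character(1))
    sc <- sitewiseSelectionScan(aln, tr)
    expect_true(sc$sites$skipped[11])
    expect_false(any(sc$sites$skipped[-11]))
})

test_that("fewer than six sequences is an error", {
    tr <- balancedTree(4, 0.1)
    aln <- simulateCodonAlignment(tr, 30, omega = 1, seed = 31)
    expect_error(sitewiseSelectionScan(aln, tr), "6 sequences")
})

test_that("the site test is calibrated and has power where designed", {
    cal <- siteTestCalibration(nRep = 5L, seed = 7L)
    expect_lte(cal$typeI, 0.05 + 2 * cal$typeISE)
    expect_gte(cal$power, 0.5)
    expect_lte(cal$falseFlagRate, 0.05)
})

test_that("segment-wide selection reaches gene-level significance", {
    tr <- balancedTree(12, 0.15)
    aln <- simulateCodonAlignment(tr, 150, omega = 3, seed = 37)
    sc <- sitewiseSelectionScan(aln, tr)
    gl <- geneLevelTest(sc)
    expect_true(gl$significant)
    neutral <- simulateCodonAlignment(tr, 150, omega = 1, seed = 38)
    glN <- geneLevelTest(sitewiseSelectionScan(neutral, tr))
    expect_false(glN$significant)
})

test_that("robust sites are exactly those flagged under every setting", {
    tr <- balancedTree(12, 0.15)
    om <- rep(0.2, 100); om[c(20, 60)] <- 6
    aln <- simulateCodonAlignment(tr, 100, omega = om, seed = 41)
    rb <- robustnessRerun(aln, tr, seeds = c(1L, 2L))
    expect_true(all(rb$robust == (rb$nFlagged == rb$nSettings)))
    sc1 <- sitewiseSelectionScan(aln, tr, expectedModel = "composition")
    sc2 <- sitewiseSelectionScan(aln, tr, expectedModel = "uniform")
    both <- sc1$sites$flagged & sc2$sites$flagged
    expect_equal(rb$robust, both)
})

test_that("the column mask excludes a lineage-specific insertion region", {
    tr <- balancedTree(12, 0.15)
    aln <- simulateCodonAlignment(tr, 80, omega = 1, seed = 43)
    scFull <- sitewiseSelectionScan(aln, tr)
    scMask <- sitewiseSelectionScan(aln, tr, mask = 1:10)
    expect_equal(nrow(scMask$sites), 70L)
    expect_equal(sum(scMask$sites$NObs),
                 sum(scFull$sites$NObs[-(1:10)]))
})
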