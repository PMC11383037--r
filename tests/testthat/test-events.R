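test_that("trivial loss histories are reconstructed directly", {
    tr <- ape::read.tree(text = "((A,B),(C,(D,E)));")
    all <- stats::setNames(rep(TRUE, 5), c("A", "B", "C", "D", "E"))
    expect_equal(dolloReconstruct(all, tr)$lossCount, 0L)
    one <- all; one["D"] <- FALSE
    r <- dolloReconstruct(one, tr)
    expect_equal(r$lossCount, 1L)
    expect_equal(r$lossBranches[[1L]], "D")
    none <- all; none[] <- FALSE
    expect_error(dolloReconstruct(none, tr), "forced origin")
})

test_that("Dollo loss counts equal the brute-force minimum", {
    # exhaustive over all presence patterns on an 8-leaf tree
    tr8 <- balancedTree(8, 1)
    tips <- tr8$tip.label
    for (code in 1:(2^8 - 1)) {
        pres <- stats::setNames(as.logical(bitwAnd(code,
                                                   2^(0:7)) > 0), tips)
        got <- dolloReconstruct(pres, tr8)$lossCount
        want <- oracleDolloMin(tr8, pres)
        expect_equal(got, want, info = code)
    }
    # random patterns on random 10-12 leaf trees
    set.seed(99)
    for (rep in 1:20) {
        n <- sample(10:12, 1)
        tr <- ape::rtree(n)
        pres <- stats::setNames(sample(c(TRUE, FALSE), n, replace = TRUE),
                                tr$tip.label)
        if (!any(pres)) pres[sample(n, 1)] <- TRUE
        expect_equal(dolloReconstruct(pres, tr)$lossCount,
                     oracleDolloMin(tr, pres), info = rep)
    }
})

test_that("an intact species inside a lost clade never lowers the count", {
    tr <- balancedTree(8, 1)
    pres <- stats::setNames(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
                              TRUE, TRUE), tr$tip.label)
    base <- dolloReconstruct(pres, tr)$lossCount
    pres2 <- pres; pres2["t4"] <- TRUE  # resurrect inside the lost clade
    expect_gte(dolloReconstruct(pres2, tr)$lossCount, base)
})

test_that("pseudogene and absent are equivalent non-intact states", {
    tr <- ape::read.tree(text = "((A,B),(C,D));")
    st1 <- data.frame(species = c("A", "B", "C", "D"), gene = "g",
                      status = c("present", "present", "pseudogene",
                                 "pseudogene"))
    st2 <- st1; st2$status[3:4] <- "absent"
    r1 <- dolloReconstruct(st1, tr, gene = "g")
    r2 <- dolloReconstruct(st2, tr, gene = "g")
    expect_equal(r1$lossCount, r2$lossCount)
    expect_equal(r1$lossBranches, r2$lossBranches)
})

test_that("duplications are dated to their origin branch interval", {
    tree <- readSpeciesTree(
        extdataPath("trees", "primate_tree_synthetic.nwk"),
        extdataPath("trees", "primate_node_ages_synthetic.tsv"))
    st <- readStatusTsv(extdataPath("status",
                                    "casp12_status_primates_synthetic.tsv"))
    dd <- dateDuplication(st, tree, gene = "CASP4")
    expect_equal(dd$ageLower, 43)
    expect_equal(dd$ageUpper, 69)
    # a gene in all leaves dates above the root: open-ended upper bound
    allSp <- unique(st$species)
    ddAll <- dateDuplication(stats::setNames(rep(TRUE, length(allSp)),
                                             allSp), tree)
    expect_true(is.na(ddAll$ageUpper))
    noAges <- ape::read.tree(text = "((A,B),C);")
    expect_error(dateDuplication(c(A = TRUE, B = TRUE, C = FALSE), noAges),
                 "ages")
})

test_that("simulated duplications bracket the scripted event age", {
    tr <- ape::read.tree(text =
        "(((A:0.02,B:0.02)AB:0.02,C:0.04)ABC:0.02,D:0.06)root;")
    tr <- setNodeAges(tr, c(root = 30, ABC = 20, AB = 10))
    cfg <- simConfig(tr, compactLayout(), events = list(
        list(kind = "duplication", branch = "A,B", gene = "casp4")),
        seed = 41L)
    sim <- simulateDataset(cfg)
    st <- simTruth(sim)$status
    dd <- dateDuplication(st, tr, gene = "casp4_dup")
    expect_equal(dd$ageLower, 10)  # duplicate fixed by the A,B ancestor
    expect_equal(dd$ageUpper, 20)  # on the branch below the ABC ancestor
})

test_that("event tabulation reports per-gene counts and branches", {
    tr <- ape::read.tree(text = "((A,B),(C,D));")
    st <- data.frame(species = rep(c("A", "B", "C", "D"), 2),
                     gene = rep(c("g1", "g2"), each = 4),
                     status = c("present", "present", "absent", "absent",
                                "present", "pseudogene", "present",
                                "present"))
    recs <- lapply(c("g1", "g2"), function(g)
        dolloReconstruct(st, tr, gene = g))
    tab <- countTotalEvents(recs, clade = "test")
    expect_equal(nrow(tab), 2L)
    # g1 is confined to the (A,B) clade: a single origin, no losses;
    # g2 lost once on the B branch
    expect_equal(tab$lossCount, c(0L, 1L))
    expect_equal(tab$clade, c("test", "test"))
})
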