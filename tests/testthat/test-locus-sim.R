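test_that("identical config and seed give byte-identical datasets", {
    tr <- sixSpeciesTree()
    cfg <- simConfig(tr, compactLayout(),
                     events = list(list(kind = "loss", branch = "A",
                                        gene = "casp12")), seed = 3L)
    s1 <- simulateDataset(cfg)
    s2 <- simulateDataset(cfg)
    for (sp in names(simLoci(s1)))
        expect_identical(as.character(locusSeq(simLoci(s1)[[sp]])),
                         as.character(locusSeq(simLoci(s2)[[sp]])))
    expect_identical(simTruth(s1)$status, simTruth(s2)$status)
})

test_that("zero branch lengths and no events leave every locus ancestral", {
    tr <- sixSpeciesTree()
    tr$edge.length[] <- 0
    sim <- simulateDataset(simConfig(tr, compactLayout(), seed = 5L))
    seqs <- vapply(simLoci(sim), function(l) as.character(locusSeq(l)),
                   character(1))
    expect_equal(length(unique(seqs)), 1L)
})

test_that("a scripted loss removes the gene only in the target lineage", {
    tr <- sixSpeciesTree()
    cfg <- simConfig(tr, compactLayout(),
                     events = list(list(kind = "loss", branch = "D,E",
                                        gene = "casp4")), seed = 9L)
    sim <- simulateDataset(cfg)
    st <- simTruth(sim)$status
    lost <- st$species[st$gene == "casp4" & st$status == "absent"]
    expect_setequal(lost, c("D", "E"))
    ex <- simTruth(sim)$exons
    expect_false(any(ex$gene == "casp4" & ex$species %in% c("D", "E")))
    expect_true(all(c("A", "B", "C", "F") %in%
                    ex$species[ex$gene == "casp4"]))
})

test_that("statuses are consistent with replaying the event log", {
    tr <- sixSpeciesTree()
    cfg <- simConfig(tr, compactLayout(), events = list(
        list(kind = "loss", branch = "A", gene = "casp12"),
        list(kind = "pseudogenize", branch = "C,D,E", gene = "casp5"),
        list(kind = "partial_loss", branch = "F", gene = "casp4",
             nDrop = 1L)), seed = 2L)
    sim <- simulateDataset(cfg)
    st <- simTruth(sim)$status
    log <- simTruth(sim)$events
    expect_equal(nrow(log), 3L)
    getStatus <- function(sp, g)
        st$status[st$species == sp & st$gene == g]
    expect_equal(getStatus("A", "casp12"), "absent")
    for (sp in c("C", "D", "E"))
        expect_equal(getStatus(sp, "casp5"), "pseudogene")
    expect_equal(getStatus("F", "casp4"), "partial_in_frame")
    # untouched lineages keep the gene
    expect_equal(getStatus("B", "casp12"), "present")
    expect_equal(getStatus("A", "casp5"), "present")
})

test_that("neutral HKY substitution matches the closed-form ts/tv split", {
    set.seed(41)
    n <- 30000L
    t <- 0.4
    kappa <- 4
    anc <- sample.int(4L, n, replace = TRUE)
    der <- caspevo:::.evolveNeutral(anc, t, kappa)
    isTs <- (anc == 1L & der == 3L) | (anc == 3L & der == 1L) |
        (anc == 2L & der == 4L) | (anc == 4L & der == 2L)
    isTv <- anc != der & !isTs
    exp <- k80ExpectedTsTv(t, kappa)
    seTs <- sqrt(exp[["pTs"]] * (1 - exp[["pTs"]]) / n)
    seTv <- sqrt(exp[["pTv"]] * (1 - exp[["pTv"]]) / n)
    expect_lt(abs(mean(isTs) - exp[["pTs"]]), 3 * seTs)
    expect_lt(abs(mean(isTv) - exp[["pTv"]]), 3 * seTv)
})

test_that("lesion operations mutate the CDS as specified", {
    cds <- paste(c("ATG", rep("GCT", 98), "TAA"), collapse = "")
    # frameshift at codon 10 changes the translation from there on
    fs <- applyLesion(cds, "frameshift_indel", position = 27, indelLen = 1)
    expect_equal(fs$lesion$length, -1)
    aa0 <- strsplit(caspevo:::.translateCDS(cds), "")[[1]]
    aa1 <- strsplit(caspevo:::.translateCDS(fs$cds), "")[[1]]
    expect_equal(aa1[1:9], aa0[1:9])
    expect_false(identical(aa1[10:min(length(aa1), 20)], aa0[10:20]))
    expect_error(applyLesion(cds, "frameshift_indel", 27, indelLen = 3),
                 "multiple of 3")

    ps <- applyLesion(cds, "premature_stop", position = 50)
    aa <- strsplit(caspevo:::.translateCDS(ps$cds), "")[[1]]
    expect_equal(which(aa == "*")[1L], 50L)
    expect_error(applyLesion(cds, "premature_stop", position = 100),
                 "upstream")

    exonLens <- c(120L, 90L, 90L)
    cds2 <- substr(cds, 1, 300)
    el <- applyLesion(cds2, "exon_loss", position = 3, exonLens = exonLens)
    expect_equal(nchar(el$cds), nchar(cds2) - 90L)
})

test_that("gene conversion overwrites the acceptor tract and nothing else", {
    s <- randomDna(6000, seed = 11)
    out <- applyGeneConversion(s, 100, 1600, 3100, 4600)
    expect_equal(substr(out, 3101, 4600), substr(s, 101, 1600))
    expect_equal(substr(out, 1, 3100), substr(s, 1, 3100))
    expect_equal(substr(out, 4601, 6000), substr(s, 4601, 6000))
    # idempotent when already identical
    expect_equal(applyGeneConversion(out, 100, 1600, 3100, 4600), out)
    expect_error(applyGeneConversion(s, 100, 1600, 1000, 2500),
                 "overlap")
    expect_error(applyGeneConversion(s, 100, 1600, 3100, 4000),
                 "equal length")
})

test_that("an event referencing a deleted gene is a config error", {
    tr <- sixSpeciesTree()
    cfg <- simConfig(tr, compactLayout(), events = list(
        list(kind = "loss", branch = "D,E", gene = "casp4"),
        list(kind = "pseudogenize", branch = "D", gene = "casp4")),
        seed = 1L)
    expect_error(simulateDataset(cfg), "not present")
})

test_that("total locus length changes only through logged indel events", {
    tr <- sixSpeciesTree()
    sim <- simulateDataset(simConfig(tr, compactLayout(), seed = 13L))
    lens <- vapply(simLoci(sim), function(l) length(locusSeq(l)),
                   integer(1))
    expect_equal(length(unique(lens)), 1L)  # substitution-only: conserved
})
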