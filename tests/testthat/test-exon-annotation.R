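test_that("a planted exact exon copy is recovered at its interval", {
    set.seed(21)
    exon <- randomDna(300)
    bg <- randomDna(12000)
    loc <- paste0(substr(bg, 1, 5000), exon, substr(bg, 5301, 12000))
    hits <- findExonHits(loc, list(g1 = Biostrings::DNAStringSet(exon)))
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$start0, 5000)
    expect_equal(hits$end0, 5300)
    expect_equal(hits$identity, 1)
    expect_equal(hits$strand, "+")
})

test_that("a reverse-complemented copy is found on the minus strand", {
    set.seed(22)
    exon <- randomDna(300)
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(exon)))
    bg <- randomDna(12000)
    loc <- paste0(substr(bg, 1, 5000), rc, substr(bg, 5301, 12000))
    hits <- findExonHits(loc, list(g1 = Biostrings::DNAStringSet(exon)))
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$strand, "-")
    expect_equal(hits$start0, 5000)
    expect_equal(hits$end0, 5300)
})

test_that("the identity threshold gates diverged exon copies", {
    set.seed(23)
    exon <- randomDna(300)
    # mutate exactly 45 positions (85% identity, substitutions only)
    mut <- strsplit(exon, "")[[1]]
    idx <- sample(300, 45)
    for (i in idx) mut[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                            mut[i]), 1)
    bg <- randomDna(12000)
    loc <- paste0(substr(bg, 1, 5000), paste(mut, collapse = ""),
                  substr(bg, 5301, 12000))
    refs <- list(g1 = Biostrings::DNAStringSet(exon))
    hits <- findExonHits(loc, refs, pipelineConfig())
    expect_equal(nrow(hits), 1L)
    expect_lt(abs(hits$identity - 0.85), 0.03)
    # raising the identity threshold above the planted identity removes it
    hits2 <- findExonHits(loc, refs, pipelineConfig(minExonIdentity = 0.9))
    expect_equal(nrow(hits2), 0L)
})

test_that("a locus shorter than the exon yields an empty result", {
    hits <- findExonHits("ACGTACGTAC",
                         list(g = Biostrings::DNAStringSet(randomDna(200))))
    expect_equal(nrow(hits), 0L)
})

test_that("annotating a locus and its reverse complement mirror", {
    tr <- sixSpeciesTree()
    sim <- simulateDataset(simConfig(tr, compactLayout(), seed = 31L))
    ref <- simReferenceGeneSet(sim)
    loc <- as.character(locusSeq(simLoci(sim)$A))
    L <- nchar(loc)
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(loc)))
    h1 <- findExonHits(loc, ref)
    h2 <- findExonHits(rc, ref)
    expect_equal(nrow(h1), nrow(h2))
    key1 <- sort(paste(h1$gene, h1$exon, h1$start0, h1$end0, h1$strand))
    flip <- data.frame(gene = h2$gene, exon = h2$exon,
                       start0 = L - h2$end0, end0 = L - h2$start0,
                       strand = ifelse(h2$strand == "+", "-", "+"))
    key2 <- sort(paste(flip$gene, flip$exon, flip$start0, flip$end0,
                       flip$strand))
    expect_equal(key1, key2)
})

test_that("synteny assignment resolves paralogs and tandem duplicates", {
    tr <- sixSpeciesTree()
    cfg <- simConfig(tr, compactLayout(), events = list(
        list(kind = "duplication", branch = "D,E", gene = "casp4")),
        seed = 33L)
    sim <- simulateDataset(cfg)
    ref <- simReferenceGeneSet(sim)
    hits <- findExonHits(simLoci(sim)$D, ref)
    asg <- assignHitsToGenes(hits, ref)
    expect_true("casp4_dup" %in% asg$models$gene)
    m <- asg$models
    expect_equal(m$gene[m$refGene == "casp4"], c("casp4", "casp4_dup"))
    # models appear in syntenic order along the locus
    expect_true(!is.unsorted(m$slot))
    expect_true(!is.unsorted(m$start0))
})

test_that("an isolated ambiguous hit breaks ties toward the upstream slot", {
    set.seed(34)
    exon <- randomDna(300)
    bg <- randomDna(20000)
    # two identical planted regions; the reference lists two genes with the
    # same exon sequence, so both clusters are ambiguous between the slots
    loc <- paste0(substr(bg, 1, 5000), exon,
                  substr(bg, 5301, 12000), exon, substr(bg, 12301, 20000))
    ref <- referenceGeneSet(c("gA", "gB"),
                            list(Biostrings::DNAStringSet(exon),
                                 Biostrings::DNAStringSet(exon)))
    hits <- findExonHits(loc, ref)
    asg <- assignHitsToGenes(hits, ref)
    m <- asg$models[order(asg$models$start0), ]
    expect_equal(m$gene, c("gA", "gB"))
})

test_that("assembled CDSs match the simulated truth exactly", {
    tr <- sixSpeciesTree()
    sim <- simulateDataset(simConfig(tr, compactLayout(), seed = 35L))
    ref <- simReferenceGeneSet(sim)
    tru <- simTruth(sim)
    for (sp in c("A", "D")) {
        hits <- findExonHits(simLoci(sim)[[sp]], ref)
        asg <- assignHitsToGenes(hits, ref)
        for (g in c("casp1", "card17", "casp12")) {
            ex <- asg$exons[asg$exons$model == g, ]
            cds <- assembleCds(ex, simLoci(sim)[[sp]])
            expect_equal(cds$seq, tru$cds[[sp]][[g]],
                         info = paste(sp, g))
            expect_equal(cds$frame, 0L)
        }
    }
})

test_that("minus-strand CDS equals revcomp of genome-order concatenation", {
    tr <- sixSpeciesTree()
    sim <- simulateDataset(simConfig(tr, compactLayout(), seed = 36L))
    ref <- simReferenceGeneSet(sim)
    loc <- simLoci(sim)$B
    hits <- findExonHits(loc, ref)
    asg <- assignHitsToGenes(hits, ref)
    ex <- asg$exons[asg$exons$model == "card17", ]
    expect_true(all(ex$strand == "-"))
    cds <- assembleCds(ex, loc)
    genomeOrder <- ex[order(ex$start0), ]
    concat <- paste(vapply(seq_len(nrow(genomeOrder)), function(i)
        substr(as.character(locusSeq(loc)), genomeOrder$start0[i] + 1L,
               genomeOrder$end0[i]), character(1)), collapse = "")
    expect_equal(cds$seq, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(concat))))
})

test_that("overlapping exon hits are a model error", {
    ex <- data.frame(exon = c(1L, 2L), start0 = c(0L, 50L),
                     end0 = c(100L, 150L), strand = "+")
    expect_error(assembleCds(ex, randomDna(200, seed = 1)), "overlapping")
})

test_that("a forced frameshift propagates into the assembled CDS", {
    tr <- sixSpeciesTree()
    cfg <- simConfig(tr, compactLayout(), events = list(
        list(kind = "pseudogenize", branch = "C", gene = "casp1",
             lesion = "frameshift_indel", len = 1L, pos = 200L)),
        seed = 37L)
    sim <- simulateDataset(cfg)
    ref <- simReferenceGeneSet(sim)
    refCds <- paste(as.character(refExons(ref, "casp1")), collapse = "")
    hits <- findExonHits(simLoci(sim)$C, ref)
    asg <- assignHitsToGenes(hits, ref)
    cds <- assembleCds(asg$exons[asg$exons$model == "casp1", ],
                       simLoci(sim)$C)
    les <- detectLesions(cds$seq, refCds)
    expect_true("frameshift_indel" %in% les$kind)
})
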