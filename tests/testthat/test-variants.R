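test_that("the three-way conservation rule fires in order", {
    # rule 1: invariant column, unobserved alternate -> potential impact
    c1 <- classifyVariant("N", rep("D", 10))
    expect_equal(c1$class, "potential_impact")
    # rule 2: alternate present in another species -> unlikely
    c2 <- classifyVariant("N", c(rep("D", 9), "N"))
    expect_equal(c2$class, "unlikely")
    # rule 3: variable column, alternate unobserved -> unknown
    c3 <- classifyVariant("W", c("D", "E", "N", rep("D", 7)))
    expect_equal(c3$class, "unknown")
    # all-gap column -> unknown with rationale
    c4 <- classifyVariant("N", rep("-", 10))
    expect_equal(c4$class, "unknown")
    expect_match(c4$rationale, "gapped")
    # near-invariance option
    col <- c(rep("D", 9), "E")
    expect_equal(classifyVariant("N", col)$class, "unknown")
    expect_equal(classifyVariant("N", col,
                                 nearInvariantFraction = 0.9)$class,
                 "potential_impact")
})

test_that("variant table parsing extracts missense fields", {
    v <- readVariantTable(extdataPath("tables", "table2_rat.tsv"))
    q <- v[v$variant == "Q343R", ][1L, ]
    expect_equal(q$type, "missense")
    expect_equal(q$refResidue, "Q")
    expect_equal(q$position, 343L)
    expect_equal(q$altResidue, "R")
    expect_equal(unique(v$type[v$variant == "1bp_ins"]), "indel")
})

test_that("the mouse panel reproduces the published strain lists", {
    v <- readVariantTable(extdataPath("tables", "table3_mouse.tsv"))
    strains <- unique(v$strain)
    expect_equal(length(strains), 16L)
    rec <- recommendStrains(v[v$gene != "none", ],
                            c("casp11", "casp12"), allStrains = strains)
    expect_equal(sum(rec$flag == "avoid"), 8L)
    expect_setequal(rec$strain[rec$flag == "avoid"],
                    c("129S1_SvImJ", "cAST_EiJ", "pWK_PhJ", "wSB_EiJ",
                      "aKR_J", "cBA_J", "nOD_ShiLtJ", "IP_J"))
    expect_equal(rec$flag[rec$strain == "sPRET_EiJ"], "caution")
    rec3 <- recommendStrains(v[v$gene != "none", ],
                             c("casp1", "casp11", "casp12"),
                             allStrains = strains)
    expect_equal(sum(rec3$flag == "clean"), 7L)
    expect_setequal(rec3$strain[rec3$flag == "clean"],
                    c("bALB_cJ", "c57BL_6NJ", "a_J", "nZO_HILtJ",
                      "fVB_NJ", "dBA_2J", "c3H_HeJ"))
})

test_that("reclassifying toward impact never moves avoid to clean", {
    v <- readVariantTable(extdataPath("tables", "table3_mouse.tsv"))
    v <- v[v$gene != "none", ]
    base <- recommendStrains(v, c("casp11", "casp12"),
                             allStrains = unique(v$strain))
    v2 <- v
    v2$class[v2$class == "unlikely"] <- "potential_impact"
    harder <- recommendStrains(v2, c("casp11", "casp12"),
                               allStrains = unique(v2$strain))
    rank <- c(clean = 0, caution = 1, avoid = 2)
    expect_true(all(rank[harder$flag] >= rank[base$flag]))
})

syntheticCasp12 <- function(seed = 55L) {
    # synthetic rat-like caspase-12 trio: intact homologs and a reference
    # CDS carrying a 1 bp deletion in the exon-7 region
    set.seed(seed)
    sense <- setdiff(names(Biostrings::GENETIC_CODE)[
        Biostrings::GENETIC_CODE != "*"], "ATG")
    homolog <- paste(c("ATG", sample(sense, 418, replace = TRUE), "TAA"),
                     collapse = "")
    delAt <- 900L
    refBroken <- paste0(substr(homolog, 1, delAt),
                        substr(homolog, delAt + 2, nchar(homolog)))
    list(homolog = homolog, refBroken = refBroken, delAt = delAt)
}

test_that("the strain-shared 1 bp insertion restores the rat frame", {
    v <- readVariantTable(extdataPath("tables", "table2_rat.tsv"))
    ins <- v[v$variant == "1bp_ins", ]
    expect_equal(nrow(ins), 8L)
    expect_setequal(ins$strain, unique(v$strain))
    cs <- syntheticCasp12()
    fr <- detectFrameRestoration(
        indelLen = 1L, cdsPos = cs$delAt, referenceCds = cs$refBroken,
        homologCds = c(mouse = cs$homolog),
        insertSeq = substr(cs$homolog, cs$delAt + 1, cs$delAt + 1),
        carriedByAllStrains = nrow(ins) == length(unique(v$strain)))
    expect_true(fr$restoresFrame)
    expect_match(fr$note, "assembly error")
})

test_that("an in-frame indel on an intact CDS restores nothing", {
    cs <- syntheticCasp12(56L)
    fr <- detectFrameRestoration(indelLen = 3L, cdsPos = 300L,
                                 referenceCds = cs$homolog,
                                 homologCds = c(m = cs$homolog))
    expect_false(fr$restoresFrame)
    expect_equal(fr$note, "")
})

test_that("a 2 bp deletion can restore a planted +2 frameshift", {
    cs <- syntheticCasp12(57L)
    plus2 <- paste0(substr(cs$homolog, 1, 600), "GT",
                    substr(cs$homolog, 601, nchar(cs$homolog)))
    fr <- detectFrameRestoration(indelLen = -2L, cdsPos = 600L,
                                 referenceCds = plus2,
                                 homologCds = c(m = cs$homolog))
    expect_true(fr$restoresFrame)
    expect_equal(fr$note, "")  # not strain-shared, no assembly note
})
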