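# Shared compact simulation configurations. Locus sizes are scaled down
# from the full-locus defaults so the suite runs quickly; thresholds and
# event scripts are unchanged.

compactLayout <- function() defaultLayout(intergenicLen = 3000L,
                                          intronLen = 800L)

sixSpeciesTree <- function() ape::read.tree(text = paste0(
    "(((A:0.03,B:0.03):0.03,(C:0.03,(D:0.02,E:0.02):0.02):0.02):0.02,",
    "F:0.08):0;"))

tenSpeciesTree <- function() ape::read.tree(text = paste0(
    "((((s1:0.02,s2:0.02):0.02,(s3:0.02,s4:0.02):0.02):0.02,",
    "((s5:0.02,s6:0.02):0.02,(s7:0.02,s8:0.02):0.02):0.02):0.01,",
    "(s9:0.05,s10:0.05):0.04):0;"))

extdataPath <- function(...) {
    system.file("extdata", ..., package = "caspevo", mustWork = TRUE)
}

randomDna <- function(n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
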