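# End-to-end orchestration: annotate -> status -> blocks/conversion ->
# events -> selection, with a machine-readable summary and run manifest.

#' Run the locus analysis pipeline
#'
#' Runs the selected stages over a set of per-species loci (typically a
#' \linkS4class{SimulationResult}) against a reference gene layout, and
#' collates a summary suitable for JSON serialization. Each stage is also
#' available as a standalone function.
#'
#' @param loci named list of \linkS4class{GenomicLocus}, or a
#'   \linkS4class{SimulationResult} (whose loci, tree and reference layout
#'   are then used).
#' @param reference a \linkS4class{ReferenceGeneSet}; taken from the
#'   simulation when \code{loci} is a \linkS4class{SimulationResult}.
#' @param tree species tree; taken from the simulation likewise.
#' @param config a \linkS4class{PipelineConfig}.
#' @param stages subset of \code{c("status", "blocks", "conversion",
#'   "events", "selection", "variants")}.
#' @param variantTable optional path to a strain variant TSV (stage
#'   "variants").
#' @param genesOfInterest genes for the strain report.
#' @param referenceSpecies species used as the dS-filter reference;
#'   defaults to the first locus.
#' @param clusterGap passed to \code{\link{assignHitsToGenes}}.
#' @param outDir optional directory: stage tables are written as TSV and
#'   the summary + manifest as JSON.
#' @return list with \code{manifest}, \code{status}, \code{blocks},
#'   \code{conversion}, \code{events}, \code{selection}, \code{strains},
#'   \code{summary}.
#' @export
runPipeline <- function(loci, reference = NULL, tree = NULL,
                        config = pipelineConfig(),
                        stages = c("status", "blocks", "conversion",
                                   "events", "selection"),
                        variantTable = NULL,
                        genesOfInterest = NULL,
                        referenceSpecies = NULL,
                        clusterGap = 2500L, outDir = NULL) {
    if (is(loci, "SimulationResult")) {
        sim <- loci
        loci <- simLoci(sim)
        if (is.null(reference)) reference <- simReferenceGeneSet(sim)
        if (is.null(tree)) tree <- simTree(sim)
    }
    bad <- setdiff(stages, c("status", "blocks", "conversion", "events",
                             "selection", "variants"))
    if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
    if (is.null(referenceSpecies)) referenceSpecies <- names(loci)[1L]
    res <- list()
    res$manifest <- list(
        package = as.character(utils::packageVersion("caspevo")),
        seed = config@rngSeed,
        stages = stages,
        thresholds = stats::setNames(
            lapply(slotNames(config), function(s) slot(config, s)),
            slotNames(config)),
        inputs = if (length(loci)) list(
            species = names(loci),
            locusLengths = vapply(loci, function(l)
                length(locusSeq(l)), integer(1))) else list())
    referenceCds <- NULL
    statusTab <- NULL
    cdsBySpecies <- NULL
    if (any(c("status", "events", "selection", "conversion") %in% stages)) {
        referenceCds <- stats::setNames(vapply(reference@exons, function(e)
            paste(as.character(e), collapse = ""), character(1)),
            reference@geneIds)
        statusTab <- geneStatusMatrix(loci, reference,
                                      referenceCds = referenceCds,
                                      config = config,
                                      clusterGap = clusterGap)
        res$status <- statusTab
        # assembled CDSs for downstream stages
        cdsBySpecies <- lapply(names(loci), function(sp) {
            hits <- findExonHits(loci[[sp]], reference, config)
            asg <- assignHitsToGenes(hits, reference,
                                     clusterGap = clusterGap)
            out <- list()
            for (g in unique(asg$exons$model)) {
                ex <- asg$exons[asg$exons$model == g, , drop = FALSE]
                out[[g]] <- assembleCds(ex, loci[[sp]])$seq
            }
            out
        })
        names(cdsBySpecies) <- names(loci)
    }
    if ("blocks" %in% stages) {
        res$blocks <- lapply(names(loci), function(sp) {
            bl <- tryCatch(findSimilarityBlocks(loci[[sp]], config),
                           error = function(e) NULL)
            if (!is.null(bl) && nrow(bl)) cbind(species = sp, bl) else NULL
        })
        res$blocks <- do.call(rbind, res$blocks)
    }
    if ("conversion" %in% stages && !is.null(cdsBySpecies)) {
        # compare paralogs of equal CDS length (alignable without indels)
        lens <- nchar(referenceCds)
        res$conversion <- list()
        for (L in unique(lens)) {
            fam <- names(lens)[lens == L]
            if (length(fam) < 2L) next
            seqs <- character(0); gl <- sl <- character(0)
            for (sp in names(cdsBySpecies)) for (g in fam) {
                s <- cdsBySpecies[[sp]][[g]]
                ok <- statusTab$status[statusTab$species == sp &
                                       statusTab$gene == g] %in%
                    c("present", "pseudogene")
                if (!is.null(s) && length(ok) && ok && nchar(s) == L) {
                    seqs <- c(seqs, s); gl <- c(gl, g); sl <- c(sl, sp)
                }
            }
            if (length(unique(sl)) < 3L || length(unique(gl)) < 2L) next
            im <- detectTreeIntermixing(seqs, gl, sl, tree)
            res$conversion[[as.character(L)]] <- im
        }
        res$nConversionEvents <- sum(vapply(res$conversion,
                                            function(x) x$nEvents,
                                            numeric(1)))
    }
    if ("events" %in% stages && !is.null(statusTab)) {
        recs <- list()
        for (g in unique(statusTab$gene)) {
            sub <- statusTab[statusTab$gene == g, ]
            if (!any(sub$status %in% c("present", "partial_in_frame")))
                next
            recs[[g]] <- dolloReconstruct(sub, tree, gene = g)
        }
        res$events <- countTotalEvents(recs)
    }
    if ("selection" %in% stages && !is.null(cdsBySpecies)) {
        sel <- list()
        for (g in reference@geneIds) {
            spOk <- statusTab$species[statusTab$gene == g &
                                      statusTab$status == "present"]
            seqs <- stats::setNames(lapply(spOk, function(sp)
                cdsBySpecies[[sp]][[g]]), spOk)
            seqs <- seqs[!vapply(seqs, is.null, logical(1))]
            lens <- vapply(seqs, nchar, integer(1))
            seqs <- seqs[lens == nchar(referenceCds[[g]])]
            if (length(seqs) < 6L) next
            refSp <- if (referenceSpecies %in% names(seqs))
                referenceSpecies else names(seqs)[1L]
            flt <- filterSpeciesByDs(unlist(seqs), refSp, config)
            seqs <- seqs[flt$retained]
            if (length(seqs) < 6L) next
            sub <- ape::keep.tip(tree, names(seqs))
            scan <- sitewiseSelectionScan(unlist(seqs), sub, config)
            gl <- geneLevelTest(scan, config, seed = config@rngSeed)
            sel[[g]] <- list(dsFilter = flt$table, scan = scan,
                             geneLevel = gl)
        }
        res$selection <- sel
    }
    if ("variants" %in% stages && !is.null(variantTable)) {
        v <- readVariantTable(variantTable)
        if (is.null(genesOfInterest))
            genesOfInterest <- unique(v$gene)
        res$strains <- recommendStrains(v, genesOfInterest,
                                        allStrains = unique(v$strain))
    }
    res$summary <- list(
        nSpecies = length(loci),
        statusCounts = if (!is.null(statusTab))
            as.list(table(statusTab$status)) else NULL,
        nBlocks = if (!is.null(res$blocks)) nrow(res$blocks) else NULL,
        nConversionEvents = res$nConversionEvents,
        lossCounts = if (!is.null(res$events))
            stats::setNames(as.list(res$events$lossCount),
                            res$events$gene) else NULL,
        selectionFlagged = if (!is.null(res$selection))
            stats::setNames(lapply(res$selection, function(x)
                x$scan$segment$nFlagged), names(res$selection)) else NULL,
        strainFlags = if (!is.null(res$strains))
            as.list(table(res$strains$flag)) else NULL)
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        if (!is.null(res$status))
            utils::write.table(res$status, file.path(outDir, "status.tsv"),
                               sep = "\t", quote = FALSE,
                               row.names = FALSE)
        if (!is.null(res$blocks) && NROW(res$blocks))
            utils::write.table(res$blocks, file.path(outDir, "blocks.tsv"),
                               sep = "\t", quote = FALSE,
                               row.names = FALSE)
        if (!is.null(res$events))
            utils::write.table(res$events, file.path(outDir, "events.tsv"),
                               sep = "\t", quote = FALSE,
                               row.names = FALSE)
        if (!is.null(res$strains))
            utils::write.table(res$strains,
                               file.path(outDir, "strains.tsv"),
                               sep = "\t", quote = FALSE,
                               row.names = FALSE)
        jsonlite::write_json(res$summary,
                             file.path(outDir, "summary.json"),
                             auto_unbox = TRUE, digits = NA, null = "null")
        jsonlite::write_json(res$manifest,
                             file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, null = "null")
    }
    res
}
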