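# Gene gain/loss reconstruction on the species tree under single-gain
# (Dollo) parsimony, and dating of duplications from node ages.

.treeChildren <- function(tree) split(tree$edge[, 2L], tree$edge[, 1L])

.cladeTips <- function(tree, node) {
    ntip <- length(tree$tip.label)
    if (node <= ntip) tree$tip.label[node] else
        ape::extract.clade(tree, node)$tip.label
}

#' Dollo parsimony reconstruction of a gene's loss history
#'
#' The gene is assumed to arise once, at the most recent common ancestor of
#' the intact species (or at \code{forcedOrigin}); the reported losses are
#' the minimum set of branches within that clade whose removal explains all
#' non-intact leaves: one loss per maximal all-non-intact clade. The result
#' is deterministic; this choice is automatically the one with fewest,
#' deepest branches.
#'
#' @param presence named logical vector (TRUE = intact) over tree leaves,
#'   or a long-format status data.frame (\code{species}, \code{status})
#'   where intact means present or partial in-frame.
#' @param tree species tree (\code{phylo}).
#' @param gene gene label (used when \code{presence} is a status
#'   data.frame with a \code{gene} column, and echoed in the result).
#' @param forcedOrigin optional: comma-joined leaf labels whose MRCA is the
#'   origin node.
#' @param intactStatuses statuses counting as intact when \code{presence}
#'   is a status data.frame.
#' @return list with \code{gene}, \code{originNode}, \code{originTips},
#'   \code{lossBranches} (list of clade tip sets), \code{lossCount}.
#' @export
dolloReconstruct <- function(presence, tree, gene = NA_character_,
                             forcedOrigin = NULL,
                             intactStatuses = c("present",
                                                "partial_in_frame")) {
    if (is.data.frame(presence)) {
        df <- presence
        if (!is.na(gene) && "gene" %in% names(df))
            df <- df[df$gene == gene, , drop = FALSE]
        presence <- stats::setNames(df$status %in% intactStatuses,
                                    df$species)
    }
    presence <- presence[names(presence) %in% tree$tip.label]
    intact <- names(presence)[presence]
    ntip <- length(tree$tip.label)
    if (length(intact) == 0L && is.null(forcedOrigin))
        stop("gene intact nowhere and no forced origin given")
    origin <- if (!is.null(forcedOrigin)) {
        sp <- strsplit(forcedOrigin, ",")[[1]]
        if (length(sp) == 1L) match(sp, tree$tip.label) else
            ape::getMRCA(tree, sp)
    } else if (length(intact) == 1L) {
        match(intact, tree$tip.label)
    } else ape::getMRCA(tree, intact)
    children <- .treeChildren(tree)
    losses <- list()
    rec <- function(node) {
        tips <- .cladeTips(tree, node)
        known <- tips[tips %in% names(presence)]
        if (length(known) && !any(presence[known])) {
            losses[[length(losses) + 1L]] <<- tips
            return(invisible())
        }
        if (node > ntip)
            for (kid in children[[as.character(node)]]) rec(kid)
    }
    if (origin <= ntip) {
        if (!isTRUE(presence[tree$tip.label[origin]]))
            losses <- list(tree$tip.label[origin])
    } else {
        for (kid in children[[as.character(origin)]]) rec(kid)
    }
    list(gene = gene, originNode = origin,
         originTips = .cladeTips(tree, origin),
         lossBranches = losses, lossCount = length(losses))
}

#' Date a duplication to a branch interval from node ages
#'
#' The duplicate arose on the branch above the MRCA of the species carrying
#' it: the age interval is (age of that node's parent, age of the node),
#' in Mya. A duplicate present in all leaves yields an open-ended upper
#' bound (NA).
#'
#' @param presence named logical vector (TRUE = carries the duplicate) or
#'   status data.frame as in \code{\link{dolloReconstruct}}.
#' @param tree species tree with a \code{node.age} component (see
#'   \code{\link{setNodeAges}}).
#' @param gene optional gene label for data.frame input.
#' @return list with \code{originNode}, \code{ageLower} (origin node age),
#'   \code{ageUpper} (parent node age; NA when the origin is the root).
#' @export
dateDuplication <- function(presence, tree, gene = NA_character_) {
    if (is.null(tree$node.age)) stop("tree carries no node ages")
    if (is.data.frame(presence)) {
        df <- presence
        if (!is.na(gene) && "gene" %in% names(df))
            df <- df[df$gene == gene, , drop = FALSE]
        presence <- stats::setNames(
            df$status %in% c("present", "partial_in_frame", "pseudogene"),
            df$species)
    }
    carriers <- names(presence)[presence]
    if (!length(carriers)) stop("duplicate carried by no species")
    ntip <- length(tree$tip.label)
    origin <- if (length(carriers) == 1L) match(carriers, tree$tip.label)
        else ape::getMRCA(tree, carriers)
    nodeAge <- function(node) {
        if (node <= ntip) 0 else tree$node.age[node - ntip]
    }
    root <- ntip + 1L
    lower <- nodeAge(origin)
    upper <- if (origin == root) NA_real_ else {
        par <- tree$edge[tree$edge[, 2L] == origin, 1L]
        nodeAge(par)
    }
    list(originNode = origin, ageLower = lower, ageUpper = upper)
}

#' Tabulate reconstructed events per gene and clade
#'
#' @param reconstructions list of results from
#'   \code{\link{dolloReconstruct}}.
#' @param clade label attached to the rows (e.g. "primates").
#' @return data.frame: \code{gene}, \code{clade}, \code{lossCount},
#'   \code{originTips}, \code{lossBranches} (semicolon-joined).
#' @export
countTotalEvents <- function(reconstructions, clade = NA_character_) {
    do.call(rbind, lapply(reconstructions, function(r) data.frame(
        gene = r$gene, clade = clade, lossCount = r$lossCount,
        originTips = paste(r$originTips, collapse = ","),
        lossBranches = paste(vapply(r$lossBranches, paste,
                                    character(1), collapse = ","),
                             collapse = ";"),
        stringsAsFactors = FALSE)))
}
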