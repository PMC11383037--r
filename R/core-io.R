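#' Read a FASTA file of locus (or CDS/exon) sequences
#'
#' Sequences are uppercased and any character outside A, C, G, T, N is
#' collapsed to N; the number of collapsed characters is reported via
#' \code{message()} and attached as attribute \code{"nNormalized"}.
#'
#' @param path path to a FASTA file.
#' @return A named \link[Biostrings]{DNAStringSet}.
#' @export
readLocusFasta <- function(path) {
    if (!file.exists(path)) stop("file does not exist: ", path)
    x <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA format error: ",
                                           conditionMessage(e)))
    if (length(x) == 0L) stop("FASTA format error: empty file: ", path)
    if (anyDuplicated(names(x)))
        stop("FASTA format error: duplicate labels in ", path)
    ch <- toupper(as.character(x))
    nBad <- sum(vapply(ch, function(s)
        nchar(gsub("[ACGTN]", "", s)), numeric(1)))
    if (nBad > 0) {
        ch <- gsub("[^ACGTN]", "N", ch)
        message(nBad, " non-ACGTN character(s) normalized to N")
    }
    out <- Biostrings::DNAStringSet(ch)
    names(out) <- names(x)
    attr(out, "nNormalized") <- nBad
    out
}

#' Write sequences to FASTA
#'
#' @param records a named \link[Biostrings]{DNAStringSet} (or named character
#'   vector).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeLocusFasta <- function(records, path) {
    if (is.character(records))
        records <- Biostrings::DNAStringSet(records)
    if (length(records) == 0L) stop("no records to write")
    if (is.null(names(records)) || anyDuplicated(names(records)))
        stop("records must carry unique names")
    Biostrings::writeXStringSet(records, path)
    invisible(path)
}

#' Read a species tree from Newick
#'
#' Leaf labels must be unique. Node ages in Mya may be supplied through a
#' side TSV (columns \code{node}, \code{age_mya}) keyed by internal node
#' labels present in the Newick string; ages must strictly decrease from
#' root to leaves.
#'
#' @param path path to a Newick file.
#' @param agesPath optional path to a node-age TSV.
#' @return An \code{ape} \code{phylo}; when ages are supplied, component
#'   \code{node.age} holds one age per internal node (NA when unknown),
#'   indexed in node-number order.
#' @export
readSpeciesTree <- function(path, agesPath = NULL) {
    tr <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick format error: ",
                                            conditionMessage(e)))
    if (is.null(tr)) stop("Newick format error: could not parse ", path)
    if (anyDuplicated(tr$tip.label))
        stop("Newick format error: duplicate leaf labels")
    if (!is.null(agesPath)) {
        ages <- utils::read.delim(agesPath, stringsAsFactors = FALSE)
        if (!all(c("node", "age_mya") %in% names(ages)))
            stop("ages TSV needs columns 'node' and 'age_mya'")
        tr <- setNodeAges(tr, stats::setNames(ages$age_mya, ages$node))
    }
    tr
}

#' Attach node ages (Mya) to a tree
#'
#' @param tree a \code{phylo} with internal node labels.
#' @param ages named numeric vector, names matching internal node labels.
#' @return the tree with a \code{node.age} component (one entry per internal
#'   node, NA when not given).
#' @export
setNodeAges <- function(tree, ages) {
    if (is.null(tree$node.label))
        stop("tree has no internal node labels to key ages by")
    nodeAge <- rep(NA_real_, tree$Nnode)
    hit <- match(names(ages), tree$node.label)
    if (anyNA(hit))
        stop("unknown node label(s): ",
             paste(names(ages)[is.na(hit)], collapse = ", "))
    nodeAge[hit] <- as.numeric(ages)
    ntip <- length(tree$tip.label)
    for (e in seq_len(nrow(tree$edge))) {
        par <- tree$edge[e, 1L] - ntip
        chi <- tree$edge[e, 2L]
        if (chi > ntip) {
            chi <- chi - ntip
            if (!is.na(nodeAge[par]) && !is.na(nodeAge[chi]) &&
                nodeAge[chi] >= nodeAge[par])
                stop("node ages must strictly decrease from root to leaves")
        }
    }
    tree$node.age <- nodeAge
    tree
}

#' Extract a locus slice around an anchor interval
#'
#' @param assemblySeq a \link[Biostrings]{DNAString} (or character) assembly
#'   sequence.
#' @param anchorStart,anchorEnd 0-based half-open anchor interval.
#' @param flank bp of flank either side; clipped at the sequence ends.
#' @param speciesName label for the returned locus.
#' @return A \linkS4class{GenomicLocus}; \code{originOffset} records the
#'   left clip position.
#' @examples
#' loc <- extractLocus(strrep("ACGT", 250), 100, 200, 50, "sp1")
#' originOffset(loc)  # 50
#' @export
extractLocus <- function(assemblySeq, anchorStart, anchorEnd, flank,
                         speciesName = "locus") {
    if (!is(assemblySeq, "DNAString"))
        assemblySeq <- Biostrings::DNAString(as.character(assemblySeq))
    L <- length(assemblySeq)
    if (anchorEnd <= anchorStart) stop("empty anchor interval")
    if (anchorStart < 0 || anchorEnd > L) stop("anchor outside sequence")
    s0 <- max(0L, as.integer(anchorStart) - as.integer(flank))
    e0 <- min(L, as.integer(anchorEnd) + as.integer(flank))
    genomicLocus(speciesName,
                 Biostrings::subseq(assemblySeq, s0 + 1L, e0),
                 originOffset = s0)
}

#' Write gene/exon annotations as GFF3
#'
#' Internal coordinates are 0-based half-open; the emitted GFF3 is 1-based
#' closed, handled by the GRanges conversion.
#'
#' @param anno data.frame with columns \code{seqid}, \code{type},
#'   \code{start0}, \code{end0}, \code{strand}, \code{gene} and optionally
#'   \code{exon}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotationGff3 <- function(anno, path) {
    gr <- GenomicRanges::GRanges(
        seqnames = anno$seqid,
        ranges = IRanges::IRanges(start = anno$start0 + 1L, end = anno$end0),
        strand = anno$strand)
    S4Vectors::mcols(gr)$type <- anno$type
    S4Vectors::mcols(gr)$ID <- if (!is.null(anno$exon))
        paste0(anno$gene, ".", anno$exon) else anno$gene
    S4Vectors::mcols(gr)$Parent <- anno$gene
    rtracklayer::export(gr, path, format = "gff3")
    invisible(path)
}

#' Read a GFF3 annotation into the internal 0-based convention
#'
#' @param path a GFF3 file.
#' @return data.frame with \code{seqid}, \code{type}, \code{start0},
#'   \code{end0}, \code{strand} and any attribute columns present.
#' @export
readAnnotationGff3 <- function(path) {
    gr <- rtracklayer::import(path, format = "gff3")
    out <- data.frame(
        seqid = as.character(GenomicRanges::seqnames(gr)),
        type = as.character(S4Vectors::mcols(gr)$type),
        start0 = GenomicRanges::start(gr) - 1L,
        end0 = GenomicRanges::end(gr),
        strand = as.character(GenomicRanges::strand(gr)),
        stringsAsFactors = FALSE)
    mc <- S4Vectors::mcols(gr)
    for (col in c("ID", "Parent"))
        if (col %in% names(mc))
            out[[col]] <- vapply(as.list(mc[[col]]), function(v)
                if (length(v)) as.character(v)[1] else NA_character_,
                character(1))
    out
}

#' Serialize / parse a PipelineConfig
#'
#' \code{writeConfig} writes a YAML snapshot; \code{readConfig} restores it.
#' Round-tripping a config is the identity.
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @param path file path.
#' @return \code{readConfig} returns a \linkS4class{PipelineConfig};
#'   \code{writeConfig} returns \code{path} invisibly.
#' @export
writeConfig <- function(config, path) {
    stopifnot(is(config, "PipelineConfig"))
    vals <- lapply(slotNames(config), function(s) slot(config, s))
    names(vals) <- slotNames(config)
    yaml::write_yaml(vals, path)
    invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    do.call(pipelineConfig, vals)
}
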