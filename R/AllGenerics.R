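#' @include AllClasses.R
NULL

#' Accessors for screen objects
#'
#' Small accessor generics for the classes of the package:
#' \code{geneId()} returns the gene identifier carried by an object,
#' \code{prefixKmer()}/\code{suffixKmer()} the anchor k-mers of a
#' \linkS4class{QueryGene}, \code{expectedSpan()} its intact
#' anchor-to-anchor span, \code{clusters()} the cluster summary table of
#' a \linkS4class{ClusterSet}, \code{assignment()} its per-genome
#' cluster assignment, \code{probMatrix()} the functionalization
#' probability matrix of a \linkS4class{SweepGrid} and
#' \code{truthTable()} the truth table of a
#' \linkS4class{SyntheticCollection}.
#'
#' @param x an object of the documented classes.
#' @return See the per-generic description.
#' @name accessors
#' @aliases geneId prefixKmer suffixKmer expectedSpan clusters assignment
#'   probMatrix truthTable
NULL

#' @rdname accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @rdname accessors
#' @export
setGeneric("prefixKmer", function(x) standardGeneric("prefixKmer"))
#' @rdname accessors
#' @export
setGeneric("suffixKmer", function(x) standardGeneric("suffixKmer"))
#' @rdname accessors
#' @export
setGeneric("expectedSpan", function(x) standardGeneric("expectedSpan"))
#' @rdname accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))
#' @rdname accessors
#' @export
setGeneric("assignment", function(x) standardGeneric("assignment"))
#' @rdname accessors
#' @export
setGeneric("probMatrix", function(x) standardGeneric("probMatrix"))
#' @rdname accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname accessors
#' @export
setMethod("geneId", "QueryGene", function(x) x@geneId)
#' @rdname accessors
#' @export
setMethod("geneId", "ClusterSet", function(x) x@geneId)
#' @rdname accessors
#' @export
setMethod("geneId", "GeneScreenCall", function(x) x@geneId)
#' @rdname accessors
#' @export
setMethod("geneId", "AncestralCall", function(x) x@geneId)
#' @rdname accessors
#' @export
setMethod("prefixKmer", "QueryGene", function(x) x@prefixKmer)
#' @rdname accessors
#' @export
setMethod("suffixKmer", "QueryGene", function(x) x@suffixKmer)
#' @rdname accessors
#' @export
setMethod("expectedSpan", "QueryGene", function(x) x@expectedSpan)
#' @rdname accessors
#' @export
setMethod("clusters", "ClusterSet", function(x) x@clusters)
#' @rdname accessors
#' @export
setMethod("assignment", "ClusterSet", function(x) {
    a <- x@assignment
    if (length(x@genomeIds)) names(a) <- x@genomeIds
    a
})
#' @rdname accessors
#' @export
setMethod("probMatrix", "SweepGrid", function(x) x@probMatrix)
#' @rdname accessors
#' @export
setMethod("truthTable", "SyntheticCollection", function(x) x@truth)

setMethod("show", "QueryGene", function(object) {
    cat("QueryGene", object@geneId, "\n")
    cat("  length:", length(object@sequence), "bp  k:", object@k,
        " gap:", object@g, "\n")
    cat("  prefix k-mer: ", as.character(object@prefixKmer), "\n", sep = "")
    cat("  suffix k-mer: ", as.character(object@suffixKmer), "\n", sep = "")
    cat("  expected span:", object@expectedSpan, "bp\n")
})

setMethod("show", "ClusterSet", function(object) {
    cat("ClusterSet for gene", object@geneId, "\n")
    cat(sprintf("  %d values, eps = %g bp, min_samples = %d\n",
        length(object@values), object@eps, object@minSamples))
    cat(sprintf("  %d cluster(s), %d noise point(s)\n",
        nrow(object@clusters), object@noiseCount))
    if (nrow(object@clusters)) {
        print(object@clusters, row.names = FALSE)
    }
})

setMethod("show", "GeneScreenCall", function(object) {
    cat("GeneScreenCall", object@geneId,
        sprintf("(stage %d)\n", object@stagePassed))
    cat("  multimodal:", object@multimodal,
        " zero cluster:", object@zeroClusterId,
        " positive clusters:",
        paste(object@positiveClusterIds, collapse = ","), "\n")
})

setMethod("show", "AncestralCall", function(object) {
    cat("AncestralCall", object@geneId, "\n")
    cat("  MRCA state set: {",
        paste(object@mrcaStates, collapse = ","), "}\n", sep = "")
    cat("  parsimony score:", object@parsimonyScore, "\n")
    cat("  classification:", object@classification, "\n")
})

setMethod("show", "WFParams", function(object) {
    cat("WFParams: N =", object@N, " cost =", object@cost,
        " pInit =", object@pInit, "\n")
    cat("  pPurge =", object@pPurge, " pFunc =", object@pFunc,
        " tMax =", object@tMax, " seed =", object@seed, "\n")
})

setMethod("show", "WFOutcome", function(object) {
    cat("WFOutcome:", object@endReason, "at generation",
        object@endGeneration, "\n")
})

setMethod("show", "SweepGrid", function(object) {
    cat(sprintf("SweepGrid %d x %d (pFunc x pPurge), %d replicates/cell\n",
        length(object@pFuncValues), length(object@pPurgeValues),
        object@replicates))
    cat("  functionalization probability range:",
        paste(range(object@probMatrix), collapse = " - "), "\n")
})

setMethod("show", "RootedStateTree", function(object) {
    cat("RootedStateTree with", length(object@tree$tip.label), "leaves\n")
    cat("  ingroup leaves with states:", length(object@leafStates), "\n")
    cat("  outgroup candidates:", paste(object@outgroupIds, collapse = ", "),
        " (rooted on ", object@rootedOn, ")\n", sep = "")
})

setMethod("show", "SyntheticCollection", function(object) {
    cat("SyntheticCollection:", length(object@genomes), "genomes,",
        length(object@queryGenes), "query gene(s)\n")
    cat("  events:\n")
    print(object@events, row.names = FALSE)
})
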