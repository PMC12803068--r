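#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
NULL

#' QueryGene: a gene with its prefix/suffix k-mer anchors
#'
#' Holds a coding nucleotide query sequence together with the two exact
#' k-mer anchors taken just inside its termini: the prefix k-mer at
#' positions \code{[g, g+k)} and the suffix k-mer at \code{[L-g-k, L-g)}
#' (0-based, half-open; \code{L} = gene length, \code{g} = terminal gap).
#' The gap shifts the anchors off the start/stop codons and, when not a
#' multiple of 3, out of frame relative to the CDS. \code{expectedSpan}
#' (= L - 2g) is the anchor-to-anchor span of an intact allele.
#'
#' @slot geneId character(1) gene identifier.
#' @slot sequence \link[Biostrings]{DNAString}, gene orientation.
#' @slot k integer(1) k-mer length (bp).
#' @slot g integer(1) terminal gap (bp).
#' @slot prefixKmer,suffixKmer \link[Biostrings]{DNAString} of length k.
#' @slot expectedSpan integer(1) bp, span of the intact configuration.
#' @exportClass QueryGene
setClass("QueryGene",
    representation(
        geneId = "character",
        sequence = "DNAString",
        k = "integer",
        g = "integer",
        prefixKmer = "DNAString",
        suffixKmer = "DNAString",
        expectedSpan = "integer"
    )
)

setValidity("QueryGene", function(object) {
    msg <- character(0)
    L <- length(object@sequence)
    k <- object@k
    g <- object@g
    if (length(object@geneId) != 1L || !nzchar(object@geneId))
        msg <- c(msg, "geneId must be a non-empty string")
    if (k < 1L || g < 0L)
        msg <- c(msg, "k must be >= 1 and g >= 0")
    if (L < 2L * (k + g))
        msg <- c(msg, sprintf("sequence length %d < 2(k+g) = %d", L, 2L * (k + g)))
    else {
        pref <- as.character(object@sequence[(g + 1L):(g + k)])
        suff <- as.character(object@sequence[(L - g - k + 1L):(L - g)])
        if (!identical(pref, as.character(object@prefixKmer)))
            msg <- c(msg, "prefixKmer does not equal sequence[g, g+k)")
        if (!identical(suff, as.character(object@suffixKmer)))
            msg <- c(msg, "suffixKmer does not equal sequence[L-g-k, L-g)")
        if (grepl("[^ACGT]", paste0(pref, suff)))
            msg <- c(msg, "k-mer windows contain non-ACGT characters")
        if (object@expectedSpan != L - 2L * g)
            msg <- c(msg, "expectedSpan must equal L - 2g")
    }
    if (length(msg)) msg else TRUE
})

#' ClusterSet: 1D density clusters over prefix-suffix differences
#'
#' Result of density-based (DBSCAN-style) clustering of the per-genome
#' difference values (observed span minus expected span) of one gene.
#' Each genome contributes one point; cluster ids are ordered by
#' ascending |mean difference| so cluster 0 is the intact-most cluster.
#'
#' @slot geneId character(1).
#' @slot values numeric, one difference value per non-missing genome.
#' @slot genomeIds character, parallel to \code{values} (may be empty).
#' @slot assignment integer, parallel to \code{values}; cluster id or
#'   \code{NA} for noise points.
#' @slot clusters data.frame with columns \code{cluster_id},
#'   \code{mean_difference}, \code{size}.
#' @slot noiseCount integer(1).
#' @slot eps numeric(1) neighbourhood radius (bp).
#' @slot minSamples integer(1) minimum neighbourhood size of a core point.
#' @exportClass ClusterSet
setClass("ClusterSet",
    representation(
        geneId = "character",
        values = "numeric",
        genomeIds = "character",
        assignment = "integer",
        clusters = "data.frame",
        noiseCount = "integer",
        eps = "numeric",
        minSamples = "integer"
    )
)

setValidity("ClusterSet", function(object) {
    msg <- character(0)
    n <- length(object@values)
    if (length(object@assignment) != n)
        msg <- c(msg, "assignment must be parallel to values")
    if (length(object@genomeIds) && length(object@genomeIds) != n)
        msg <- c(msg, "genomeIds must be empty or parallel to values")
    cl <- object@clusters
    if (nrow(cl)) {
        # a cluster's core neighbourhood has >= minSamples points, but
        # border points shared with an adjacent cluster are assigned
        # deterministically to the left cluster, so a final size may
        # fall below minSamples; sizes must only be positive
        if (any(cl$size < 1L))
            msg <- c(msg, "clusters must be non-empty")
        tab <- table(factor(object@assignment, levels = cl$cluster_id))
        if (!all(as.integer(tab) == cl$size))
            msg <- c(msg, "cluster sizes inconsistent with assignment")
    }
    if (object@noiseCount != sum(is.na(object@assignment)))
        msg <- c(msg, "noiseCount inconsistent with assignment")
    if (length(msg)) msg else TRUE
})

#' GeneScreenCall: multimodality and peak-shape screen decision
#'
#' Records how far a gene advances through the filtering cascade:
#' stage 1 requires a multimodal difference distribution (>= 2 non-noise
#' clusters), stage 2 additionally requires an intact-like cluster
#' centred near 0 and at least one cluster at a positive distance above
#' the threshold, stage 3 is reserved for the ancestral-state filter.
#'
#' @slot geneId character(1).
#' @slot multimodal logical(1).
#' @slot zeroClusterId integer(1), \code{NA} if no intact-like cluster.
#' @slot positiveClusterIds integer, clusters with mean above threshold.
#' @slot stagePassed integer(1) in 0:3.
#' @exportClass GeneScreenCall
setClass("GeneScreenCall",
    representation(
        geneId = "character",
        multimodal = "logical",
        zeroClusterId = "integer",
        positiveClusterIds = "integer",
        stagePassed = "integer"
    )
)

#' RootedStateTree: rooted tree with cluster-label leaf states
#'
#' A rooted (outgroup-rooted) tree whose ingroup leaves carry discrete
#' character states given by their distance-cluster assignment.
#'
#' @slot tree \link[ape]{phylo} object, rooted.
#' @slot leafStates named integer; names are ingroup leaf labels.
#' @slot outgroupIds character(2), candidate outgroup leaf labels.
#' @slot rootedOn character(1), the outgroup actually used for rooting.
#' @exportClass RootedStateTree
setClass("RootedStateTree",
    representation(
        tree = "ANY",
        leafStates = "integer",
        outgroupIds = "character",
        rootedOn = "character"
    )
)

setValidity("RootedStateTree", function(object) {
    msg <- character(0)
    tr <- object@tree
    if (!inherits(tr, "phylo"))
        msg <- c(msg, "tree must be a phylo object")
    else {
        if (!ape::is.rooted(tr)) msg <- c(msg, "tree must be rooted")
        ing <- setdiff(tr$tip.label, object@outgroupIds)
        if (!all(ing %in% names(object@leafStates)))
            msg <- c(msg, "every ingroup leaf must have a state")
        if (any(object@outgroupIds %in% names(object@leafStates)))
            msg <- c(msg, "outgroups must not carry states")
    }
    if (length(msg)) msg else TRUE
})

#' AncestralCall: Fitch parsimony state at the ingroup MRCA
#'
#' @slot geneId character(1).
#' @slot mrcaStates integer, the Fitch state set at the ingroup MRCA.
#' @slot parsimonyScore integer(1), minimum number of state changes.
#' @slot classification character(1): \code{"split_ancestor"},
#'   \code{"intact_ancestor"} or \code{"ambiguous"}.
#' @exportClass AncestralCall
setClass("AncestralCall",
    representation(
        geneId = "character",
        mrcaStates = "integer",
        parsimonyScore = "integer",
        classification = "character"
    )
)

setValidity("AncestralCall", function(object) {
    if (!object@classification %in%
        c("split_ancestor", "intact_ancestor", "ambiguous"))
        return("invalid classification")
    TRUE
})

#' WFParams: Wright-Fisher hitchhiking simulation parameters
#'
#' Parameters of a forward-time haploid Wright-Fisher model of a novel
#' (initially non-functional) gene. Individuals are in state 0 (no
#' gene, fitness 1) or state 1 (gene present, fitness 1-cost); each
#' generation state-1 individuals functionalize with probability
#' \code{pFunc} (the functionalization rate, called mu elsewhere) or
#' lose the gene with probability \code{pPurge}.
#'
#' @slot N integer(1) haploid population size.
#' @slot cost numeric(1) fitness cost of the non-functional gene.
#' @slot pInit numeric(1) initial gene frequency.
#' @slot pPurge numeric(1) per-individual per-generation loss probability.
#' @slot pFunc numeric(1) per-individual per-generation functionalization
#'   probability.
#' @slot tMax integer(1) generation cap.
#' @slot seed integer(1) RNG seed (\code{NA} = use current RNG state).
#' @exportClass WFParams
setClass("WFParams",
    representation(
        N = "integer",
        cost = "numeric",
        pInit = "numeric",
        pPurge = "numeric",
        pFunc = "numeric",
        tMax = "integer",
        seed = "integer"
    )
)

setValidity("WFParams", function(object) {
    msg <- character(0)
    if (object@N < 1L) msg <- c(msg, "N must be >= 1")
    if (object@cost < 0 || object@cost >= 1)
        msg <- c(msg, "cost must be in [0, 1)")
    for (p in c("pInit", "pPurge", "pFunc")) {
        v <- slot(object, p)
        if (v < 0 || v > 1) msg <- c(msg, paste(p, "must be in [0, 1]"))
    }
    if (object@tMax < 1L) msg <- c(msg, "tMax must be >= 1")
    if (length(msg)) msg else TRUE
})

#' WFOutcome: outcome of one Wright-Fisher replicate
#'
#' @slot functionalized logical(1); TRUE iff a state-2 individual (a
#'   functionalized copy) ever appeared.
#' @slot endGeneration integer(1) generation at which the run ended.
#' @slot endReason character(1): \code{"functionalized"}, \code{"lost"}
#'   or \code{"t_max"}.
#' @exportClass WFOutcome
setClass("WFOutcome",
    representation(
        functionalized = "logical",
        endGeneration = "integer",
        endReason = "character"
    )
)

#' SweepGrid: functionalization probabilities over a parameter grid
#'
#' @slot pFuncValues numeric, functionalization rates (rows).
#' @slot pPurgeValues numeric, purge rates (columns).
#' @slot replicates integer(1) replicates per grid cell.
#' @slot probMatrix numeric matrix, fraction of replicates that
#'   functionalized per cell.
#' @slot base \linkS4class{WFParams} shared by all cells.
#' @exportClass SweepGrid
setClass("SweepGrid",
    representation(
        pFuncValues = "numeric",
        pPurgeValues = "numeric",
        replicates = "integer",
        probMatrix = "matrix",
        base = "WFParams"
    )
)

setValidity("SweepGrid", function(object) {
    msg <- character(0)
    if (!all(dim(object@probMatrix) ==
            c(length(object@pFuncValues), length(object@pPurgeValues))))
        msg <- c(msg, "probMatrix dimensions must match grid values")
    pm <- object@probMatrix
    if (any(pm < 0 | pm > 1, na.rm = TRUE))
        msg <- c(msg, "probMatrix entries must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' SyntheticCollection: simulated genome collection with planted events
#'
#' A genome collection evolved along a known tree by point substitution,
#' with planted structural events (clade-restricted deletions that fuse
#' two gene fragments, or clade-restricted cargo insertions into intact
#' genes) and a machine-readable truth table of expected per-genome
#' prefix-suffix differences.
#'
#' @slot genomes named list of \link[Biostrings]{DNAStringSet}, one per
#'   ingroup genome.
#' @slot outgroups named list of \link[Biostrings]{DNAStringSet} (2).
#' @slot tree \link[ape]{phylo} generating tree (ingroup only).
#' @slot queryGenes \link[Biostrings]{DNAStringSet} of query gene CDSs.
#' @slot events data.frame describing the planted events.
#' @slot truth data.frame: gene_id, genome_id, expected_difference,
#'   in_clade, event_type.
#' @slot mgeFixture \link[Biostrings]{DNAStringSet} cargo sequence set.
#' @exportClass SyntheticCollection
setClass("SyntheticCollection",
    representation(
        genomes = "list",
        outgroups = "list",
        tree = "ANY",
        queryGenes = "DNAStringSet",
        events = "data.frame",
        truth = "data.frame",
        mgeFixture = "DNAStringSet"
    )
)
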