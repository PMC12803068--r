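#' @include AllClasses.R
NULL

#' Cluster, screen and ancestrally classify one gene
#'
#' Runs cascade stages 1-3 for a single gene: density clustering of its
#' difference distribution, the multimodality / peak-shape screen, and
#' (when stage 2 is reached) cluster-balanced genome sampling, locus
#' extraction and masking, sketch-distance tree building and Fitch
#' parsimony at the ingroup MRCA. A gene whose MRCA state is a single
#' positive-distance cluster with at least one intact descendant is a
#' putative deletion-born fusion (stage 3).
#'
#' @param query the \linkS4class{QueryGene}.
#' @param measurements measurement rows of this gene (all genomes).
#' @param collection named list of genomes (see
#'   \code{\link{readGenomeCollection}}).
#' @param outgroups named list of exactly two outgroup genomes.
#' @param eps,minSamples clustering parameters (bp / genomes).
#' @param posThreshold split-peak threshold in bp (default 800).
#' @param quota genomes sampled for tree building (default 300).
#' @param seed sampling seed.
#' @param sketchSize,sketchK min-hash sketch parameters.
#' @return list with elements \code{clusterSet}, \code{call},
#'   \code{sampled}, \code{stateTree}, \code{ancestralCall},
#'   \code{locusSeqs} (per sampled genome, gene orientation),
#'   \code{interveningSeqs}, \code{stagePassed}. Tree-stage elements
#'   are NULL for genes stopping before stage 2.
#' @export
classifyGeneAncestry <- function(query, measurements, collection,
        outgroups, eps = 800, minSamples = 25L, posThreshold = 800,
        quota = 300L, seed = 42L, sketchSize = 1000L, sketchK = 21L) {
    cs <- clusterDifferences(measurements, eps = eps,
        minSamples = minSamples, geneId = query@geneId)
    call <- screenGene(cs, posThreshold = posThreshold)
    res <- list(clusterSet = cs, call = call, sampled = NULL,
        stateTree = NULL, ancestralCall = NULL, locusSeqs = NULL,
        interveningSeqs = NULL, stagePassed = call@stagePassed)
    if (call@stagePassed < 2L) return(res)
    sampled <- sampleByCluster(cs, quota = quota, seed = seed)
    meas <- measurements[measurements$status == "ok", , drop = FALSE]
    rownames(meas) <- meas$genome_id
    masked <- list()
    locusSeqs <- list()
    intervening <- list()
    for (gid in sampled) {
        em <- extractAndMask(collection[[gid]], meas[gid, ], query)
        masked[[gid]] <- em$maskedGenome
        locusSeqs[[gid]] <- em$locusSeq
        intervening[[gid]] <- extractIntervening(collection[[gid]],
            meas[gid, ], query)
    }
    states <- assignment(cs)[sampled]
    tree <- buildRootedTree(masked, outgroups, states,
        sketchSize = sketchSize, k = sketchK)
    posIds <- cs@clusters$cluster_id[cs@clusters$mean_difference > 0]
    anc <- fitchMRCA(tree, call@zeroClusterId, posIds,
        geneId = query@geneId)
    res$sampled <- sampled
    res$stateTree <- tree
    res$ancestralCall <- anc
    res$locusSeqs <- locusSeqs
    res$interveningSeqs <- intervening
    if (anc@classification == "split_ancestor") res$stagePassed <- 3L
    res
}

#' Run the full screen and filtering cascade over a collection
#'
#' End-to-end convenience wrapper: anchor extraction, exact matching,
#' locus measurement, then per-gene clustering, screening and (for
#' genes reaching stage 2) ancestral-state classification.
#'
#' @param genes gene FASTA / \code{DNAStringSet} or list of
#'   \linkS4class{QueryGene}.
#' @param collection genome collection.
#' @param outgroups named list of two outgroup genomes.
#' @inheritParams classifyGeneAncestry
#' @inheritParams screenCollection
#' @return list with \code{screen} (matches + measurements) and
#'   \code{genes}: per-gene results of
#'   \code{\link{classifyGeneAncestry}}.
#' @export
runScreenPipeline <- function(genes, collection, outgroups, k = 27L,
        g = 4L, eps = 800, minSamples = 25L, posThreshold = 800,
        quota = 300L, seed = 42L, sketchSize = 1000L, sketchK = 21L) {
    collection <- readGenomeCollection(collection)
    scr <- screenCollection(genes, collection, k = k, g = g)
    perGene <- list()
    for (q in scr$queries) {
        m <- scr$measurements[
            scr$measurements$gene_id == q@geneId, , drop = FALSE]
        perGene[[q@geneId]] <- classifyGeneAncestry(q, m, collection,
            outgroups, eps = eps, minSamples = minSamples,
            posThreshold = posThreshold, quota = quota, seed = seed,
            sketchSize = sketchSize, sketchK = sketchK)
    }
    list(screen = scr, genes = perGene)
}
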