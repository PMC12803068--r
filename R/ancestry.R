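#' @include AllClasses.R
#' @importFrom ape nj root is.rooted getMRCA
NULL

#' Sample genomes evenly across distance clusters
#'
#' Draws up to \code{quota} genomes for tree building, split evenly
#' across the clusters of a \linkS4class{ClusterSet}. Clusters smaller
#' than their even share contribute all their members and the shortfall
#' is redistributed proportionally to the remaining cluster sizes.
#' Sampling is uniform within clusters and deterministic given the seed.
#'
#' @param clusterSet a \linkS4class{ClusterSet} built with genome ids.
#' @param quota total number of genomes to draw (default 300).
#' @param seed RNG seed.
#' @param allowlist optional character vector restricting sampling to a
#'   high-quality genome subset.
#' @return character vector of genome ids.
#' @export
sampleByCluster <- function(clusterSet, quota = 300L, seed = 42L,
        allowlist = NULL) {
    stopifnot(is(clusterSet, "ClusterSet"))
    if (!length(clusterSet@genomeIds))
        stop("clusterSet carries no genome ids", call. = FALSE)
    a <- assignment(clusterSet)
    a <- a[!is.na(a)]
    if (!is.null(allowlist)) a <- a[names(a) %in% allowlist]
    if (length(a) < 2L)
        stop("fewer than 2 clustered genomes available", call. = FALSE)
    byCl <- split(names(a), a)
    withLocalSeed(seed, {
        take <- integer(length(byCl))
        names(take) <- names(byCl)
        sizes <- lengths(byCl)
        remaining <- min(quota, sum(sizes))
        open <- rep(TRUE, length(byCl))
        # even split; undersized clusters give everything, surplus is
        # re-spread proportionally among clusters that still have members
        while (remaining > 0L && any(open & take < sizes)) {
            active <- which(open & take < sizes)
            share <- remaining %/% length(active)
            if (share == 0L) share <- 1L
            for (i in active) {
                add <- min(share, sizes[i] - take[i], remaining)
                take[i] <- take[i] + add
                remaining <- remaining - add
                if (take[i] == sizes[i]) open[i] <- FALSE
                if (remaining == 0L) break
            }
        }
        out <- character(0)
        for (i in seq_along(byCl)) {
            mem <- sort(byCl[[i]])
            out <- c(out, if (take[i] >= length(mem)) mem
                else sample(mem, take[i]))
        }
        sort(out)
    })
}

#' Extract a measured locus and mask it in the genome
#'
#' Cuts the sequence spanning the prefix-anchor start through the
#' suffix-anchor end (inclusive of both k-mers) out of the measured
#' contig and replaces that same region with N's in a copy of the
#' genome. Reverse-complement measurements return the locus in gene
#' orientation. Masking removes the locus-length signal from the genome
#' before sketch-based tree building, so the tree reflects genome-wide
#' relatedness rather than the structural event itself (a re-screen of
#' the masked genome finds no anchors).
#'
#' @param genome the genome (\code{DNAStringSet} of contigs).
#' @param measurement one \code{status == "ok"} row from
#'   \code{\link{measureLoci}}.
#' @param query the \linkS4class{QueryGene}.
#' @return list with \code{locusSeq} (\code{DNAString}, gene
#'   orientation) and \code{maskedGenome} (\code{DNAStringSet}).
#' @export
extractAndMask <- function(genome, measurement, query) {
    stopifnot(measurement$status == "ok")
    contigs <- asContigSet(genome)
    ct <- measurement$contig_id
    if (!ct %in% names(contigs))
        stop("contig ", ct, " not present in genome", call. = FALSE)
    k <- query@k
    seq <- contigs[[ct]]
    if (measurement$orientation == "forward") {
        from <- measurement$prefix_start + 1L
        to <- measurement$suffix_start + k
    } else {
        from <- measurement$suffix_start + 1L
        to <- measurement$prefix_start + k
    }
    if (from < 1L || to > length(seq))
        stop("measurement coordinates out of contig bounds", call. = FALSE)
    locus <- seq[from:to]
    if (measurement$orientation == "reverse_complement")
        locus <- Biostrings::reverseComplement(locus)
    masked <- seq
    Biostrings::subseq(masked, from, to) <-
        Biostrings::DNAString(strrep("N", to - from + 1L))
    contigs[[ct]] <- masked
    list(locusSeq = locus, maskedGenome = contigs)
}

#' Extract a measured locus together with flanking context
#'
#' Like \code{\link{extractAndMask}} but also returns the locus plus
#' \code{margin} bp of genomic context on both sides (clipped at contig
#' ends), in gene orientation. The flank restores the start/stop codons
#' that the anchor insets cut off the locus, which ORF prediction on
#' surrogate construction needs.
#'
#' @inheritParams extractAndMask
#' @param margin context on each side in bp (default 500).
#' @return list with \code{locusSeq} and \code{flankSeq}
#'   (\code{DNAString}s; the locus is an exact substring of the flank).
#' @export
extractLocusContext <- function(genome, measurement, query,
        margin = 500L) {
    stopifnot(measurement$status == "ok")
    contigs <- asContigSet(genome)
    seq <- contigs[[measurement$contig_id]]
    k <- query@k
    if (measurement$orientation == "forward") {
        from <- measurement$prefix_start + 1L
        to <- measurement$suffix_start + k
    } else {
        from <- measurement$suffix_start + 1L
        to <- measurement$prefix_start + k
    }
    ffrom <- max(1L, from - margin)
    fto <- min(length(seq), to + margin)
    locus <- seq[from:to]
    flank <- seq[ffrom:fto]
    if (measurement$orientation == "reverse_complement") {
        locus <- Biostrings::reverseComplement(locus)
        flank <- Biostrings::reverseComplement(flank)
    }
    list(locusSeq = locus, flankSeq = flank)
}

#' Extract the intervening sequence between the matched anchors
#'
#' The sequence strictly between the prefix and suffix k-mer matches
#' (anchors excluded), in gene orientation: the segment whose length
#' drives a positive prefix-suffix difference, used for mobile-element
#' annotation.
#'
#' @inheritParams extractAndMask
#' @return A \code{DNAString} (may be empty).
#' @export
extractIntervening <- function(genome, measurement, query) {
    loc <- extractAndMask(genome, measurement, query)$locusSeq
    k <- query@k
    n <- length(loc)
    if (n <= 2L * k) return(Biostrings::DNAString(""))
    loc[(k + 1L):(n - k)]
}

# -- min-hash bottom sketches -------------------------------------------------


# Bottom-s sketch of the canonical k-mer set of a sequence set.
# K-mers are packed into doubles (exact up to 2^53; 2k <= 52 bits) and
# mixed through a modular hash so the bottom of the hash order is an
# unbiased sample of the k-mer set.
minhashSketch <- function(seqs, sketchSize = 1000L, k = 21L) {
    stopifnot(k <= 26L)
    contigs <- asContigSet(seqs)
    lut <- rep(NA_integer_, 256)
    lut[utf8ToInt("A")] <- 0L; lut[utf8ToInt("C")] <- 1L
    lut[utf8ToInt("G")] <- 2L; lut[utf8ToInt("T")] <- 3L
    lut[utf8ToInt("a")] <- 0L; lut[utf8ToInt("c")] <- 1L
    lut[utf8ToInt("g")] <- 2L; lut[utf8ToInt("t")] <- 3L
    allHashes <- numeric(0)
    for (ci in seq_along(contigs)) {
        s <- as.character(contigs[[ci]])
        n <- nchar(s)
        if (n < k) next
        code <- lut[utf8ToInt(s)]
        bad <- is.na(code)
        code0 <- code
        code0[bad] <- 0L
        nk <- n - k + 1L
        val <- numeric(nk)
        rcv <- numeric(nk)
        nbad <- numeric(nk)
        for (j in 0:(k - 1L)) {
            idx <- (1L + j):(nk + j)
            val <- val + code0[idx] * 4^(k - 1L - j)
            rcv <- rcv + (3L - code0[idx]) * 4^j
            nbad <- nbad + bad[idx]
        }
        canon <- pmin(val, rcv)[nbad == 0]
        if (!length(canon)) next
        canon <- unique(canon)
        hi <- floor(canon / 2097152)  # 2^21
        lo <- canon %% 2097152
        h <- (1103515245 * hi + 976369 * lo + 12345) %% 2147483647
        allHashes <- c(allHashes, h)
    }
    h <- sort(unique(allHashes))
    h[seq_len(min(sketchSize, length(h)))]
}

# Mash distance between two bottom sketches: Jaccard is estimated on the
# bottom-s of the merged hash union, then d = -ln(2j/(1+j))/k, capped at 1.
mashDistance <- function(s1, s2, sketchSize, k) {
    merged <- sort(unique(c(s1, s2)))
    merged <- merged[seq_len(min(sketchSize, length(merged)))]
    shared <- sum(merged %in% s1 & merged %in% s2)
    j <- shared / length(merged)
    if (j <= 0) return(1)
    min(1, -log(2 * j / (1 + j)) / k)
}

#' Pairwise Mash distance matrix from min-hash sketches
#'
#' Fixed-size bottom-sketch Jaccard estimates converted to evolutionary
#' distances via the standard Mash transform
#' \eqn{d = -\ln(2j/(1+j))/k}.
#'
#' @param seqList named list of sequences/genomes.
#' @param sketchSize bottom sketch size (default 1000).
#' @param k sketch k-mer length (default 21).
#' @return symmetric numeric matrix of distances.
#' @export
sketchDistanceMatrix <- function(seqList, sketchSize = 1000L, k = 21L) {
    sketches <- lapply(seqList, minhashSketch, sketchSize = sketchSize, k = k)
    n <- length(sketches)
    D <- matrix(0, n, n, dimnames = list(names(seqList), names(seqList)))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        d <- mashDistance(sketches[[i]], sketches[[j]], sketchSize, k)
        D[i, j] <- D[j, i] <- d
    }
    D
}

#' Build a rooted tree with cluster-label leaf states
#'
#' Neighbour-joining on min-hash sketch Mash distances of masked
#' genomes, rooted on whichever of the two candidate outgroups has the
#' largest mean distance to the other leaves. Negative NJ branch
#' lengths are clamped to zero.
#'
#' @param maskedGenomes named list of masked ingroup genomes.
#' @param outgroups named list of exactly two outgroup genomes.
#' @param leafStates named integer vector: cluster id per ingroup
#'   genome.
#' @inheritParams sketchDistanceMatrix
#' @return A \linkS4class{RootedStateTree}.
#' @export
buildRootedTree <- function(maskedGenomes, outgroups, leafStates,
        sketchSize = 1000L, k = 21L) {
    stopifnot(length(outgroups) == 2L, length(maskedGenomes) >= 3L)
    stopifnot(all(names(maskedGenomes) %in% names(leafStates)))
    allSeqs <- c(maskedGenomes, outgroups)
    D <- sketchDistanceMatrix(allSeqs, sketchSize = sketchSize, k = k)
    if (all(D == 0))
        stop("identical sketches across all genomes: star tree", call. = FALSE)
    tr <- ape::nj(D)
    tr$edge.length[tr$edge.length < 0] <- 0
    ogIds <- names(outgroups)
    meanDist <- vapply(ogIds, function(og)
        mean(D[og, setdiff(rownames(D), og)]), 0)
    rootOn <- ogIds[which.max(meanDist)]
    tr <- ape::root(tr, outgroup = rootOn, resolve.root = TRUE)
    new("RootedStateTree", tree = tr,
        leafStates = leafStates[names(maskedGenomes)],
        outgroupIds = ogIds, rootedOn = rootOn)
}

# Bottom-up multi-state Fitch over the clade rooted at `node`.
# Leaves without a state (outgroups that tree noise pulled inside the
# clade) carry no information: standard missing-data handling, they
# constrain nothing and contribute no changes. Ingroup leaves are
# always labeled (RootedStateTree validity).
fitchPass <- function(tree, node, states) {
    nTip <- length(tree$tip.label)
    score <- 0L
    recurse <- function(v) {
        if (v <= nTip) {
            lab <- tree$tip.label[v]
            if (!lab %in% names(states)) return(NULL)
            return(states[[lab]])
        }
        kids <- tree$edge[tree$edge[, 1] == v, 2]
        cur <- NULL
        for (ch in kids) {
            s <- recurse(ch)
            if (is.null(s)) next
            if (is.null(cur)) cur <- s
            else {
                inter <- intersect(cur, s)
                if (length(inter)) cur <- inter
                else {
                    cur <- union(cur, s)
                    score <<- score + 1L
                }
            }
        }
        cur
    }
    rootSet <- recurse(node)
    if (is.null(rootSet))
        stop("no labeled leaves in the ingroup clade", call. = FALSE)
    list(set = sort(rootSet), score = score)
}

#' Fitch parsimony state at the ingroup MRCA
#'
#' Bottom-up multi-state Fitch parsimony over the clade spanned by the
#' ingroup leaves, using distance-cluster ids as discrete character
#' states. The MRCA state set is the Fitch set at the most recent
#' common ancestor of the ingroup; the parsimony score is the minimum
#' number of state changes within that clade. Classification:
#' \code{split_ancestor} iff the MRCA set is exactly one positive-mean
#' cluster and at least one ingroup leaf carries the zero (intact)
#' cluster; \code{intact_ancestor} iff the MRCA set is exactly the zero
#' cluster; anything else (including MRCA sets with more than one
#' state) is \code{ambiguous} and excluded from fusion calls.
#'
#' @param stateTree a \linkS4class{RootedStateTree}.
#' @param zeroClusterId id of the intact-like cluster.
#' @param positiveClusterIds ids of the positive-distance clusters.
#' @param geneId gene identifier for the result.
#' @return An \linkS4class{AncestralCall}.
#' @export
fitchMRCA <- function(stateTree, zeroClusterId, positiveClusterIds,
        geneId = "gene") {
    stopifnot(is(stateTree, "RootedStateTree"))
    tr <- stateTree@tree
    states <- stateTree@leafStates
    ing <- names(states)
    ing <- intersect(tr$tip.label, ing)
    if (!length(ing)) stop("no ingroup leaves in tree", call. = FALSE)
    mrca <- if (length(ing) == 1L) match(ing, tr$tip.label)
        else ape::getMRCA(tr, ing)
    res <- fitchPass(tr, mrca, states)
    cls <- "ambiguous"
    if (length(res$set) == 1L) {
        if (!is.na(zeroClusterId) && res$set == zeroClusterId)
            cls <- "intact_ancestor"
        else if (res$set %in% positiveClusterIds &&
                !is.na(zeroClusterId) && any(states == zeroClusterId))
            cls <- "split_ancestor"
    }
    new("AncestralCall", geneId = geneId,
        mrcaStates = as.integer(res$set),
        parsimonyScore = as.integer(res$score),
        classification = cls)
}
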