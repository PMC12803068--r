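#' @include AllClasses.R
NULL

# Sort-and-scan 1D DBSCAN. Returns an integer cluster label per input
# point (NA = noise), labels in left-to-right (value) order starting at 1.
# Core point: >= minSamples points (incl. itself) within distance <= eps.
# Border points attach to the leftmost reachable core's cluster so the
# result is deterministic and matches an ascending-order seeded scan.
dbscan1d <- function(x, eps, minSamples) {
    n <- length(x)
    ord <- order(x)
    xs <- x[ord]
    hi <- findInterval(xs + eps, xs)
    lo <- findInterval(xs - eps, xs, left.open = TRUE)
    counts <- hi - lo
    core <- counts >= minSamples
    lab <- rep(NA_integer_, n)
    cl <- 0L
    lastCoreVal <- NA_real_
    coreLab <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
        if (!core[i]) next
        if (is.na(lastCoreVal) || xs[i] - lastCoreVal > eps) cl <- cl + 1L
        coreLab[i] <- cl
        lastCoreVal <- xs[i]
    }
    lab[core] <- coreLab[core]
    coreIdx <- which(core)
    if (length(coreIdx)) {
        for (i in which(!core)) {
            pos <- findInterval(xs[i] - eps, xs[coreIdx],
                left.open = TRUE) + 1L
            if (pos <= length(coreIdx)) {
                j <- coreIdx[pos]  # leftmost core at value >= x - eps
                if (abs(xs[j] - xs[i]) <= eps) lab[i] <- coreLab[j]
            }
        }
    }
    out <- rep(NA_integer_, n)
    out[ord] <- lab
    out
}

#' Cluster the difference distribution of one gene
#'
#' Density-based 1D clustering (DBSCAN with neighbourhood radius
#' \code{eps} and core threshold \code{minSamples}) of per-genome
#' prefix-suffix difference values. Each genome contributes one point
#' (values supplied with multiplicities are expanded), so
#' \code{minSamples} counts genomes and cluster sizes are genome counts.
#' Noise points are excluded from cluster statistics. Cluster ids are
#' relabelled 0, 1, ... by ascending \code{|mean difference|}, so
#' cluster 0 is always the intact-most cluster.
#'
#' @param values numeric difference values (bp), or a measurements
#'   data.frame from \code{\link{measureLoci}} restricted to one gene
#'   (only \code{status == "ok"} rows are used).
#' @param multiplicity integer genome counts parallel to \code{values}
#'   (default all 1).
#' @param eps neighbourhood radius in bp (default 800).
#' @param minSamples core threshold in genomes (default 25).
#' @param geneId gene identifier for the result.
#' @param genomeIds optional genome ids parallel to the expanded values.
#' @return A \linkS4class{ClusterSet}.
#' @export
clusterDifferences <- function(values, multiplicity = NULL, eps = 800,
        minSamples = 25L, geneId = "gene", genomeIds = character(0)) {
    if (is.data.frame(values)) {
        df <- values[values$status == "ok", , drop = FALSE]
        if ("gene_id" %in% names(df) && length(unique(df$gene_id)) == 1L)
            geneId <- df$gene_id[1]
        genomeIds <- df$genome_id
        values <- df$difference
        multiplicity <- NULL
    }
    if (!is.null(multiplicity)) {
        stopifnot(length(multiplicity) == length(values),
            all(multiplicity >= 1))
        values <- rep(values, multiplicity)
    }
    if (!length(values)) stop("empty difference distribution", call. = FALSE)
    minSamples <- as.integer(minSamples)
    lab <- dbscan1d(values, eps, minSamples)
    ids <- sort(unique(lab[!is.na(lab)]))
    cl <- data.frame(cluster_id = integer(0), mean_difference = numeric(0),
        size = integer(0))
    if (length(ids)) {
        means <- vapply(ids, function(i) mean(values[lab == i & !is.na(lab)]),
            0)
        sizes <- vapply(ids, function(i) sum(lab == i, na.rm = TRUE), 0L)
        ord <- order(abs(means), means)
        relabel <- integer(max(ids))
        relabel[ids[ord]] <- seq_along(ids) - 1L
        lab[!is.na(lab)] <- relabel[lab[!is.na(lab)]]
        cl <- data.frame(cluster_id = seq_along(ids) - 1L,
            mean_difference = means[ord], size = sizes[ord])
    }
    new("ClusterSet", geneId = geneId, values = as.numeric(values),
        genomeIds = as.character(genomeIds), assignment = lab,
        clusters = cl, noiseCount = sum(is.na(lab)),
        eps = eps, minSamples = minSamples)
}

#' Apply the multimodality and peak-shape screen to a gene
#'
#' Stages of the filtering cascade encoded in the returned
#' \linkS4class{GeneScreenCall}: stage 1 requires a multimodal
#' difference distribution (at least two non-noise clusters); stage 2
#' additionally requires one cluster centred near 0 (the intact allele;
#' \code{|mean| <= zeroTol}) and at least one cluster at a positive mean
#' difference greater than \code{posThreshold}, the pattern expected
#' when a substantial intervening segment separates the anchors in the
#' ancestral (pre-deletion) configuration. Genes showing only small
#' positive shifts (internal-deletion scale) stop at stage 1.
#'
#' @param clusterSet a \linkS4class{ClusterSet}.
#' @param posThreshold minimum positive mean difference of the split
#'   cluster, bp (default 800).
#' @param zeroTol tolerance around 0 for the intact cluster, bp
#'   (default: \code{eps} of the cluster set, the only length scale in
#'   the clustering model).
#' @return A \linkS4class{GeneScreenCall}.
#' @export
screenGene <- function(clusterSet, posThreshold = 800, zeroTol = NULL) {
    stopifnot(is(clusterSet, "ClusterSet"))
    if (is.null(zeroTol)) zeroTol <- clusterSet@eps
    cl <- clusterSet@clusters
    multimodal <- nrow(cl) >= 2L
    zeroId <- NA_integer_
    if (nrow(cl)) {
        zc <- cl$cluster_id[abs(cl$mean_difference) <= zeroTol]
        if (length(zc)) zeroId <- zc[1L]
    }
    posIds <- cl$cluster_id[cl$mean_difference > posThreshold]
    stage <- 0L
    if (multimodal) {
        stage <- 1L
        if (!is.na(zeroId) && length(posIds)) stage <- 2L
    }
    new("GeneScreenCall", geneId = clusterSet@geneId,
        multimodal = multimodal, zeroClusterId = zeroId,
        positiveClusterIds = as.integer(posIds), stagePassed = stage)
}
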