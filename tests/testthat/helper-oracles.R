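# Independent brute-force oracles used by the tests. These deliberately
# avoid the package's own code paths.

BASES <- c("A", "C", "G", "T")

randSeq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

rcOracle <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# naive O(n*k) sliding-window exact matcher, both strands, 0-based starts
naiveMatches <- function(kmer, contig) {
    k <- nchar(kmer)
    n <- nchar(contig)
    out <- data.frame(start = integer(0), strand = character(0))
    if (n < k) return(out)
    rck <- rcOracle(kmer)
    for (i in seq_len(n - k + 1L)) {
        w <- substr(contig, i, i + k - 1L)
        if (w == kmer)
            out <- rbind(out, data.frame(start = i - 1L, strand = "forward"))
        if (w == rck)
            out <- rbind(out, data.frame(start = i - 1L,
                strand = "reverse_complement"))
    }
    out
}

# classic quadratic DBSCAN (BFS expansion, ascending-order seeds);
# returns integer labels, NA = noise
refDBSCAN <- function(x, eps, minPts) {
    n <- length(x)
    ord <- order(x)
    lab <- rep(NA_integer_, n)
    visited <- rep(FALSE, n)
    cl <- 0L
    neighbors <- function(i) which(abs(x - x[i]) <= eps)
    for (i in ord) {
        if (visited[i]) next
        visited[i] <- TRUE
        nb <- neighbors(i)
        if (length(nb) < minPts) next
        cl <- cl + 1L
        lab[i] <- cl
        queue <- setdiff(nb, i)
        while (length(queue)) {
            j <- queue[1L]
            queue <- queue[-1L]
            if (is.na(lab[j])) lab[j] <- cl
            if (!visited[j]) {
                visited[j] <- TRUE
                nbj <- neighbors(j)
                if (length(nbj) >= minPts)
                    queue <- c(queue, setdiff(nbj, which(!is.na(lab))))
            }
        }
    }
    lab
}

# two labelings describe the same clustering (same noise set, same
# partition of the clustered points)
samePartition <- function(a, b) {
    if (!identical(is.na(a), is.na(b))) return(FALSE)
    ok <- !is.na(a)
    if (!any(ok)) return(TRUE)
    ta <- as.integer(factor(a[ok], levels = unique(a[ok])))
    tb <- as.integer(factor(b[ok], levels = unique(b[ok])))
    identical(ta, tb)
}

# exhaustive Fitch parsimony oracle: minimum changes over all internal
# labelings of a rooted binary phylo tree, and the set of root states
# attaining the minimum
bruteFitch <- function(tree, tipStates, nStates) {
    nTip <- length(tree$tip.label)
    nNode <- tree$Nnode
    rootId <- nTip + 1L
    edges <- tree$edge
    labs <- as.matrix(expand.grid(rep(list(seq_len(nStates)), nNode)))
    stateOf <- function(node, row) {
        ifelse(node <= nTip, tipStates[tree$tip.label[node]],
            labs[row, node - nTip])
    }
    scores <- numeric(nrow(labs))
    for (e in seq_len(nrow(edges))) {
        pa <- edges[e, 1L]; ch <- edges[e, 2L]
        paS <- labs[, pa - nTip]
        chS <- if (ch <= nTip)
            rep(tipStates[[tree$tip.label[ch]]], nrow(labs))
        else labs[, ch - nTip]
        scores <- scores + (paS != chS)
    }
    best <- min(scores)
    rootStates <- sort(unique(labs[scores == best, rootId - nTip]))
    list(score = best, rootSet = rootStates)
}

# wrap a fully labeled rooted tree as a RootedStateTree with no outgroup
stateTreeOf <- function(tree, tipStates) {
    new("RootedStateTree", tree = tree, leafStates = tipStates,
        outgroupIds = character(0), rootedOn = character(0))
}

# small deterministic fusion-screen fixture shared by a few tests
makeToyQuery <- function(L = 1000L, k = 27L, g = 4L, seed = 99L) {
    set.seed(seed)
    queryGene(randSeq(L), "toy", k = k, g = g)
}
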