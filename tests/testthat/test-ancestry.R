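mkClusterSet <- function(sizes, means = seq_along(sizes) * 3000 - 3000) {
    vals <- rep(means, sizes)
    ids <- sprintf("g%04d", seq_along(vals))
    clusterDifferences(vals, genomeIds = ids, minSamples = 2L)
}

test_that("even cluster sampling splits the quota as published", {
    cs <- mkClusterSet(c(500L, 500L))
    s <- sampleByCluster(cs, quota = 300L, seed = 1L)
    expect_identical(length(s), 300L)
    expect_identical(as.integer(table(assignment(cs)[s])),
        c(150L, 150L))
})

test_that("undersized clusters give everything, surplus is redistributed", {
    cs <- mkClusterSet(c(40L, 5000L))
    s <- sampleByCluster(cs, quota = 300L, seed = 1L)
    tab <- table(assignment(cs)[s])
    expect_identical(as.integer(tab), c(40L, 260L))
})

test_that("sampling is deterministic in the seed and varies across seeds", {
    cs <- mkClusterSet(c(300L, 300L))
    s1 <- sampleByCluster(cs, quota = 100L, seed = 7L)
    s2 <- sampleByCluster(cs, quota = 100L, seed = 7L)
    s3 <- sampleByCluster(cs, quota = 100L, seed = 8L)
    expect_identical(s1, s2)
    expect_false(identical(s1, s3))
    # overlap consistent with hypergeometric expectation: drawing 50 of
    # 300 twice shares ~50*50/300 = 8.3 per cluster, ~17 overall
    ov <- length(intersect(s1, s3))
    expect_gt(ov, 2)
    expect_lt(ov, 50)
})

test_that("locus extraction and masking preserve the stated invariants", {
    set.seed(31)
    qg <- makeToyQuery()
    gene <- as.character(qg@sequence)
    contig <- paste0(randSeq(200), gene, randSeq(200))
    coll <- list(g1 = contig)
    meas <- measureLoci(findExactMatches(list(qg), coll), list(qg), "g1")
    em <- extractAndMask(coll$g1, meas[1, ], qg)
    expect_identical(length(em$locusSeq), as.integer(meas$span[1]))
    expect_identical(length(em$maskedGenome[[1]]), nchar(contig))
    masked <- as.character(em$maskedGenome[[1]])
    expect_identical(gsub("[ACGT]", "", substr(masked, 205, 1196)),
        strrep("N", 992))
    # re-screening the masked genome finds nothing: anchors destroyed
    m2 <- measureLoci(findExactMatches(list(qg),
        list(g1 = em$maskedGenome)), list(qg), "g1")
    expect_identical(m2$status, "missing")
})

test_that("reverse-complement loci come back in gene orientation", {
    set.seed(32)
    qg <- makeToyQuery()
    gene <- as.character(qg@sequence)
    contig <- rcOracle(paste0(randSeq(100), gene, randSeq(100)))
    coll <- list(g1 = contig)
    meas <- measureLoci(findExactMatches(list(qg), coll), list(qg), "g1")
    em <- extractAndMask(coll$g1, meas[1, ], qg)
    expect_identical(as.character(em$locusSeq), substr(gene, 5, 996))
})

test_that("an inserted cargo appears verbatim in the extracted locus", {
    set.seed(33)
    qg <- makeToyQuery()
    gene <- as.character(qg@sequence)
    cargo <- randSeq(5000)
    contig <- paste0(randSeq(120), substr(gene, 1, 500), cargo,
        substr(gene, 501, 1000), randSeq(120))
    coll <- list(g1 = contig)
    meas <- measureLoci(findExactMatches(list(qg), coll), list(qg), "g1")
    expect_identical(meas$difference, 5000L)
    em <- extractAndMask(coll$g1, meas[1, ], qg)
    expect_identical(length(em$locusSeq), 992L + 5000L)
    expect_true(grepl(cargo, as.character(em$locusSeq), fixed = TRUE))
})

test_that("sketch distances are zero on identical genomes", {
    set.seed(34)
    g <- randSeq(20000)
    D <- sketchDistanceMatrix(list(a = g, b = g, c = randSeq(20000)))
    expect_identical(D["a", "b"], 0)
    expect_gt(D["a", "c"], 0.1)
})

test_that("neighbour joining on sketches recovers a planted split", {
    set.seed(35)
    base1 <- randSeq(30000)
    base2 <- randSeq(30000)
    mut <- function(s, n) {
        ch <- strsplit(s, "")[[1]]
        i <- sample(length(ch), n)
        ch[i] <- sample(BASES, n, replace = TRUE)
        paste(ch, collapse = "")
    }
    coll <- list(A = mut(base1, 100), B = mut(base1, 100),
        C = mut(base2, 100), D = mut(base2, 100))
    og <- list(outgroup_1 = randSeq(30000), outgroup_2 = randSeq(30000))
    states <- setNames(c(0L, 0L, 1L, 1L), names(coll))
    rst <- buildRootedTree(coll, og, states)
    tr <- rst@tree
    expect_true(ape::is.rooted(tr))
    expect_true(ape::is.monophyletic(tr, c("A", "B")) ||
        ape::is.monophyletic(tr, c("C", "D")))
})

test_that("the farther candidate outgroup is chosen for rooting", {
    set.seed(36)
    base <- randSeq(20000)
    mut <- function(s, n) {
        ch <- strsplit(s, "")[[1]]
        i <- sample(length(ch), n)
        ch[i] <- sample(BASES, n, replace = TRUE)
        paste(ch, collapse = "")
    }
    for (rep in 1:5) {
        coll <- setNames(lapply(1:4, function(i) mut(base, 50)),
            c("A", "B", "C", "D"))
        og <- list(near = mut(base, 800), far = mut(base, 4000))
        rst <- buildRootedTree(coll, og,
            setNames(rep(0L, 4), names(coll)))
        expect_identical(rst@rootedOn, "far")
    }
})

test_that("uniform leaf states give score 0 but no split call", {
    tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
    st <- setNames(rep(1L, 4), c("a", "b", "c", "d"))
    anc <- fitchMRCA(stateTreeOf(tr, st), zeroClusterId = 0L,
        positiveClusterIds = 1L)
    expect_identical(anc@mrcaStates, 1L)
    expect_identical(anc@parsimonyScore, 0L)
    expect_identical(anc@classification, "ambiguous")
})

test_that("a zero cluster confined to a derived clade means split ancestry", {
    tr <- ape::read.tree(
        text = "(a:1,(b:1,(c:1,((d:1,e:1):1,f:1):1):1):1);")
    st <- setNames(c(1L, 1L, 1L, 0L, 0L, 1L), letters[1:6])
    anc <- fitchMRCA(stateTreeOf(tr, st), zeroClusterId = 0L,
        positiveClusterIds = 1L)
    expect_identical(anc@mrcaStates, 1L)
    expect_identical(anc@classification, "split_ancestor")
    # mirrored labels: intact ancestor
    st2 <- setNames(c(0L, 0L, 0L, 1L, 1L, 0L), letters[1:6])
    anc2 <- fitchMRCA(stateTreeOf(tr, st2), zeroClusterId = 0L,
        positiveClusterIds = 1L)
    expect_identical(anc2@classification, "intact_ancestor")
})

test_that("Fitch score and MRCA set match exhaustive enumeration", {
    set.seed(37)
    for (i in 1:50) {
        nTip <- sample(3:8, 1)
        nStates <- sample(2:4, 1)
        tr <- ape::rtree(nTip)
        st <- setNames(sample(seq_len(nStates), nTip, replace = TRUE),
            tr$tip.label)
        anc <- fitchMRCA(stateTreeOf(tr, st), zeroClusterId = 1L,
            positiveClusterIds = setdiff(seq_len(nStates), 1L))
        want <- bruteFitch(tr, st, nStates)
        expect_identical(anc@parsimonyScore, as.integer(want$score))
        expect_identical(anc@mrcaStates, as.integer(want$rootSet))
    }
})

test_that("Fitch score is bounded by leaves minus the majority state", {
    set.seed(38)
    for (i in 1:20) {
        nTip <- sample(4:8, 1)
        tr <- ape::rtree(nTip)
        st <- setNames(sample(1:3, nTip, replace = TRUE), tr$tip.label)
        anc <- fitchMRCA(stateTreeOf(tr, st), 1L, c(2L, 3L))
        bound <- nTip - max(table(st))
        expect_lte(anc@parsimonyScore, bound)
        expect_identical(anc@parsimonyScore == 0L,
            length(unique(st)) == 1L)
    }
})

test_that("rooting on either outgroup candidate leaves the MRCA set alone", {
    set.seed(39)
    base <- randSeq(20000)
    mut <- function(s, n) {
        ch <- strsplit(s, "")[[1]]
        i <- sample(length(ch), n)
        ch[i] <- sample(BASES, n, replace = TRUE)
        paste(ch, collapse = "")
    }
    coll <- setNames(lapply(1:5, function(i) mut(base, 60)),
        c("A", "B", "C", "D", "E"))
    og <- list(outgroup_1 = mut(base, 3000), outgroup_2 = mut(base, 3000))
    states <- setNames(c(0L, 0L, 1L, 1L, 1L), names(coll))
    rst <- buildRootedTree(coll, og, states)
    anc1 <- fitchMRCA(rst, 0L, 1L)
    # force the other candidate as root
    tr2 <- ape::root(ape::unroot(rst@tree),
        outgroup = setdiff(rst@outgroupIds, rst@rootedOn),
        resolve.root = TRUE)
    rst2 <- new("RootedStateTree", tree = tr2, leafStates = states,
        outgroupIds = rst@outgroupIds, rootedOn = "forced")
    anc2 <- fitchMRCA(rst2, 0L, 1L)
    expect_identical(anc1@mrcaStates, anc2@mrcaStates)
})

test_that("unlabeled ingroup leaves are rejected", {
    tr <- ape::read.tree(text = "((a:1,b:1):1,c:1);")
    st <- setNames(c(0L, 1L), c("a", "b"))
    expect_error(new("RootedStateTree", tree = tr,
        leafStates = st, outgroupIds = character(0),
        rootedOn = character(0)), "state")
})
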