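test_that("anchor windows follow the published geometry", {
    set.seed(1)
    qg <- queryGene(randSeq(1000), "g1", k = 27L, g = 4L)
    seq <- as.character(qg@sequence)
    # prefix window [4,31), suffix window [969,996), 0-based half-open
    expect_identical(as.character(prefixKmer(qg)), substr(seq, 5, 31))
    expect_identical(as.character(suffixKmer(qg)), substr(seq, 970, 996))
    expect_identical(expectedSpan(qg), 992L)
    # combined exact-match requirement is 2 * 27 = 54 bp
    expect_identical(length(prefixKmer(qg)) + length(suffixKmer(qg)), 54L)
})

test_that("the length bound 2(k+g) is sharp", {
    set.seed(2)
    ok <- queryGene(randSeq(62), "edge", k = 27L, g = 4L)
    # adjacent non-overlapping windows at the boundary length
    expect_identical(ok@g + ok@k, 31L)
    expect_identical(as.character(ok@prefixKmer),
        substr(as.character(ok@sequence), 5, 31))
    expect_identical(as.character(ok@suffixKmer),
        substr(as.character(ok@sequence), 32, 58))
    expect_error(queryGene(randSeq(61), "short"), "rejected.*length")
})

test_that("ambiguous bases in a window are rejected distinctly", {
    set.seed(3)
    s <- randSeq(200)
    substr(s, 10, 10) <- "N"
    genes <- Biostrings::DNAStringSet(c(bad = s, good = randSeq(200)))
    qs <- extractQueryKmers(genes)
    expect_named(qs, "good")
    rej <- attr(qs, "rejected")
    expect_identical(rej$gene_id, "bad")
    expect_identical(rej$reason, "ambiguous_base_in_window")
})

test_that("extracted anchors match an independent slicing oracle", {
    set.seed(4)
    s <- randSeq(500)
    for (i in 1:100) {
        k <- sample(15:40, 1)
        g <- sample(0:10, 1)
        qg <- queryGene(s, "r", k = k, g = g)
        expect_identical(as.character(qg@prefixKmer),
            substr(s, g + 1, g + k))
        expect_identical(as.character(qg@suffixKmer),
            substr(s, 500 - g - k + 1, 500 - g))
        expect_identical(qg@expectedSpan, 500L - 2L * g)
    }
})

test_that("a gene embedded in a contig is matched at its anchors", {
    set.seed(5)
    qg <- makeToyQuery()
    gene <- as.character(qg@sequence)
    m0 <- findExactMatches(list(qg), list(gid = gene))
    expect_identical(nrow(m0), 2L)
    expect_identical(m0$start[m0$role == "prefix"], 4L)
    expect_identical(m0$start[m0$role == "suffix"], 1000L - 4L - 27L)
    expect_true(all(m0$strand == "forward"))
    # reverse-complement contig: mirrored positions, rc strand
    mr <- findExactMatches(list(qg), list(gid = rcOracle(gene)))
    expect_identical(nrow(mr), 2L)
    expect_true(all(mr$strand == "reverse_complement"))
    expect_identical(sort(mr$start), sort(1000L - m0$start - 27L))
})

test_that("match sets equal the sliding-window oracle on planted contigs", {
    set.seed(6)
    qg <- makeToyQuery(L = 200L)
    pk <- as.character(qg@prefixKmer)
    sk <- as.character(qg@suffixKmer)
    contigs <- list()
    for (i in 1:50) {
        parts <- c(randSeq(sample(50:150, 1)))
        # plant k-mers at random, including duplicates and overlaps
        for (j in seq_len(sample(0:4, 1))) {
            kmer <- sample(c(pk, sk, rcOracle(pk), rcOracle(sk)), 1)
            parts <- append(parts, c(kmer, randSeq(sample(0:30, 1))))
        }
        contigs[[paste0("c", i)]] <- paste(parts, collapse = "")
    }
    genome <- Biostrings::DNAStringSet(unlist(contigs))
    got <- findExactMatches(list(qg), list(g1 = genome))
    for (cn in names(contigs)) {
        for (role in c("prefix", "suffix")) {
            kmer <- if (role == "prefix") pk else sk
            want <- naiveMatches(kmer, contigs[[cn]])
            have <- got[got$contig_id == cn & got$role == role,
                c("start", "strand")]
            want <- want[order(want$start, want$strand), ]
            have <- have[order(have$start, have$strand), ]
            expect_equal(unname(as.matrix(have)), unname(as.matrix(want)))
        }
    }
})

test_that("ambiguous bases in contigs never match", {
    set.seed(7)
    qg <- makeToyQuery(L = 100L)
    gene <- as.character(qg@sequence)
    broken <- gene
    substr(broken, 6, 6) <- "N"  # inside the prefix window
    m <- findExactMatches(list(qg), list(g = broken))
    expect_identical(unique(m$role), "suffix")
})

test_that("locus measurement recovers planted spans exactly", {
    set.seed(8)
    qg <- makeToyQuery()
    gene <- as.character(qg@sequence)
    flank <- randSeq(300)
    intact <- paste0(flank, gene, flank)
    m <- findExactMatches(list(qg), list(g = intact))
    r <- measureLocus(m, qg)
    expect_identical(r$status, "ok")
    expect_identical(r$difference, 0L)
    # inserting I bp strictly between the windows adds exactly +I
    for (I in c(1L, 57L, 5000L)) {
        cut <- 300L + 500L
        ins <- paste0(substr(intact, 1, cut), randSeq(I),
            substr(intact, cut + 1, nchar(intact)))
        ri <- measureLocus(findExactMatches(list(qg), list(g = ins)), qg)
        expect_identical(ri$difference, I)
    }
})

test_that("anchors split across contigs give a missing measurement", {
    set.seed(9)
    qg <- makeToyQuery()
    gene <- as.character(qg@sequence)
    genome <- Biostrings::DNAStringSet(c(
        cA = paste0(randSeq(50), substr(gene, 1, 100)),
        cB = paste0(substr(gene, 900, 1000), randSeq(50))))
    r <- measureLocus(findExactMatches(list(qg), list(g = genome)), qg)
    expect_identical(r$status, "missing")
})

test_that("opposite-orientation anchor pairs are flagged discordant", {
    set.seed(10)
    qg <- makeToyQuery()
    contig <- paste0(randSeq(100), as.character(qg@prefixKmer),
        randSeq(200), rcOracle(as.character(qg@suffixKmer)), randSeq(100))
    r <- measureLocus(findExactMatches(list(qg), list(g = contig)), qg)
    expect_identical(r$status, "discordant")
    # and disallowing reverse-complement placements drops rc-only loci
    rcContig <- rcOracle(paste0(randSeq(80), as.character(qg@sequence),
        randSeq(80)))
    mrc <- findExactMatches(list(qg), list(g = rcContig))
    expect_identical(measureLocus(mrc, qg)$status, "ok")
    expect_identical(measureLocus(mrc, qg, allowRC = FALSE)$status,
        "discordant")
})

test_that("among multiple anchor pairs the smallest |difference| wins", {
    set.seed(11)
    qg <- makeToyQuery()
    gene <- as.character(qg@sequence)
    sk <- as.character(qg@suffixKmer)
    # second, farther suffix copy downstream
    contig <- paste0(randSeq(60), gene, randSeq(40), sk, randSeq(60))
    r <- measureLocus(findExactMatches(list(qg), list(g = contig)), qg)
    expect_identical(r$difference, 0L)
})

test_that("differences are invariant to reverse-complementing contigs", {
    set.seed(12)
    qg <- makeToyQuery()
    gene <- as.character(qg@sequence)
    coll <- list(
        a = paste0(randSeq(100), gene, randSeq(100)),
        b = paste0(randSeq(50), substr(gene, 1, 500), randSeq(777),
            substr(gene, 501, 1000), randSeq(50)))
    fwd <- measureLoci(findExactMatches(list(qg), coll), list(qg),
        names(coll))
    rcColl <- lapply(coll, rcOracle)
    rev <- measureLoci(findExactMatches(list(qg), rcColl), list(qg),
        names(coll))
    expect_identical(fwd$difference, rev$difference)
    expect_identical(fwd$status, rev$status)
})

test_that("results are independent of genome batching order", {
    set.seed(13)
    qg <- makeToyQuery(L = 120L)
    coll <- lapply(1:6, function(i)
        paste0(randSeq(40), as.character(qg@sequence), randSeq(40)))
    names(coll) <- paste0("g", 1:6)
    a <- findExactMatches(list(qg), coll)
    b <- findExactMatches(list(qg), rev(coll))
    key <- function(d) d[order(d$genome_id, d$role, d$start), ]
    expect_equal(key(a), key(b), ignore_attr = TRUE)
})
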