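test_that("identical sequences yield zero counts", {
    cc <- countCodonDiffs("AAACCCGGG", "AAACCCGGG")
    expect_identical(unlist(cc),
        c(syn = 0, nonsyn = 0, stop_gains = 0, codons_skipped = 0))
})

test_that("the worked codon example gives dN/dS = 1", {
    # AAA->AAG is Lys->Lys (syn), CCC->ACC is Pro->Thr (nonsyn)
    cc <- countCodonDiffs("AAACCC", "AAGACC")
    expect_identical(cc$syn, 1)
    expect_identical(cc$nonsyn, 1)
    est <- weightedDnds(list(cc), 1L)
    expect_identical(est$ratio, 1)
})

test_that("codons overlapping gaps or ambiguity are only skipped", {
    cc <- countCodonDiffs("AAACCCGGG", "AAANCCGGG")
    expect_identical(cc$codons_skipped, 1L)
    expect_identical(cc$syn + cc$nonsyn, 0)
    cc2 <- countCodonDiffs("AAACCCGGG", "AAA--CGGG")
    expect_identical(cc2$codons_skipped, 1L)
    # insertion opposite a reference gap is a skipped codon too
    cc3 <- countCodonDiffs("AAA---CCC", "AAATTTCCC")
    expect_identical(cc3$codons_skipped, 1L)
    expect_identical(cc3$syn + cc3$nonsyn, 0)
})

test_that("stop gains are tracked separately from syn/nonsyn", {
    # TAC -> TAA creates a stop
    cc <- countCodonDiffs("AAATAC", "AAATAA")
    expect_identical(cc$stop_gains, 1L)
    expect_identical(cc$syn + cc$nonsyn, 0)
})

test_that("path-averaged counts sum to the nucleotide difference count", {
    set.seed(41)
    codons <- apply(expand.grid(BASES, BASES, BASES), 1, paste,
        collapse = "")
    code <- Biostrings::GENETIC_CODE
    nChecked <- 0L
    for (i in 1:300) {
        ref <- sample(codons, 1)
        alt <- sample(codons, 1)
        if (code[ref] == "*" || code[alt] == "*") next
        cc <- countCodonDiffs(ref, alt)
        d <- sum(strsplit(ref, "")[[1]] != strsplit(alt, "")[[1]])
        if (cc$stop_gains == 0) {
            expect_equal(cc$syn + cc$nonsyn, d)
            nChecked <- nChecked + 1L
        }
    }
    expect_gt(nChecked, 200L)
})

test_that("weighting multiplies counts by genome occurrence", {
    x <- list(syn = 0, nonsyn = 1, stop_gains = 0L, codons_skipped = 0L)
    y <- list(syn = 1, nonsyn = 0, stop_gains = 0L, codons_skipped = 0L)
    est <- weightedDnds(list(x, y), c(3L, 1L))
    expect_identical(est$ratio, 3)
    expect_identical(est$weighted_dN, 3)
    expect_identical(est$weighted_dS, 1)
    # doubling every weight leaves the ratio unchanged
    est2 <- weightedDnds(list(x, y), c(6L, 2L))
    expect_identical(est2$ratio, 3)
    # order of unique sequences is irrelevant
    est3 <- weightedDnds(list(y, x), c(1L, 3L))
    expect_identical(est3$ratio, 3)
})

test_that("dS = 0 leaves the ratio undefined with counts reported", {
    ref <- "ATGAAACCC"
    est <- estimateSelection(ref, c(ref, ref, ref))
    expect_true(is.na(est$ratio))
    expect_identical(est$weighted_dN, 0)
    expect_identical(est$weighted_dS, 0)
    expect_identical(est$n_unique, 1L)
    expect_identical(est$n_genomes, 3L)
})

test_that("deduplication retains genome counts", {
    d <- dedupSequences(c("AAA", "CCC", "AAA", "AAA"))
    expect_identical(sum(d$weight), 4L)
    expect_identical(d$weight[d$sequence == "AAA"], 3L)
})

test_that("simulation with known syn:nonsyn ratio is recovered", {
    # mutate fourfold-degenerate third positions (syn) and first
    # positions to a different aa (nonsyn) at a 1:2 ratio; the weighted
    # estimate over 200 replicate alleles must recover ratio ~2
    set.seed(42)
    nCod <- 200L
    fourfold <- c("GC", "GG", "CC", "CG", "CT", "GT", "TC", "AC")
    cods <- paste0(sample(fourfold, nCod, TRUE),
        sample(BASES, nCod, TRUE))
    ref <- paste(cods, collapse = "")
    alleles <- vapply(1:200, function(i) {
        ch <- strsplit(ref, "")[[1]]
        idx <- sample(nCod, 3)
        # one synonymous change at a third position
        p3 <- 3 * idx[1]
        ch[p3] <- sample(setdiff(BASES, ch[p3]), 1)
        # two nonsynonymous-prone changes at second positions
        for (j in idx[2:3]) {
            p2 <- 3 * j - 1
            ch[p2] <- sample(setdiff(BASES, ch[p2]), 1)
        }
        paste(ch, collapse = "")
    }, "")
    est <- estimateSelection(ref, alleles)
    # second-position changes are always nonsynonymous; third-position
    # changes in fourfold codons always synonymous -> expect ratio 2
    expect_gt(est$ratio, 1.7)
    expect_lt(est$ratio, 2.35)
})

test_that("the ORF finder respects starts, stops, strands and length", {
    set.seed(43)
    core <- PrefixSuffixScreen:::randomCDS(150)  # ATG...TAA, stop-free
    seq <- paste0("TTTTAA", core, "TTTT")
    orfs <- findOrfs(seq, minLen = 90L)
    plus <- orfs[orfs$strand == "+", ]
    expect_true(any(plus$start == 6 & plus$end == 6 + nchar(core)))
    expect_true(all(orfs$length >= 90))
    # every reported ORF translates without internal stops
    for (i in seq_len(nrow(orfs))) {
        aa <- as.character(Biostrings::translate(
            Biostrings::DNAString(orfs$sequence[i])))
        expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
        expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    }
})

test_that("a planted two-fragment locus yields a two-segment surrogate", {
    set.seed(44)
    fg <- PrefixSuffixScreen:::makeFusionGene(800)
    spacer <- paste0("TAA", randSeq(1994), "TAA")
    flank <- paste0(randSeq(300), "TAA", fg$fragA, spacer, fg$fragB,
        randSeq(300))
    locus <- paste0(fg$fragA, spacer, fg$fragB)
    sur <- buildSurrogate(fg$gene, locus, flank)
    expect_identical(nrow(sur$segments), 2L)
    expect_true(all(diff(sur$segments$query_start) > 0))
    stitched <- as.character(sur$stitchedSeq)
    expect_identical(lengths(regmatches(stitched,
        gregexpr("NNN", stitched, fixed = TRUE))), 1L)
    aln <- alignToRef(fg$gene, stitched)
    cc <- countCodonDiffs(aln$refAligned, aln$altAligned)
    expect_identical(cc$syn + cc$nonsyn, 0)
    expect_gt(cc$codons_skipped, 0L)
})

test_that("a query contained in one ORF gives a single joint-free segment", {
    set.seed(45)
    gene <- PrefixSuffixScreen:::randomCDS(300)
    flank <- paste0(randSeq(200), "TAA", gene, randSeq(200))
    sur <- buildSurrogate(gene, gene, flank)
    expect_identical(nrow(sur$segments), 1L)
    expect_false(grepl("NNN", as.character(sur$stitchedSeq), fixed = TRUE))
})

test_that("surrogates locate the locus in the flank on either strand", {
    set.seed(46)
    gene <- PrefixSuffixScreen:::randomCDS(300)
    flank <- paste0(randSeq(150), "TAA", gene, randSeq(150))
    surF <- buildSurrogate(gene, gene, flank)
    surR <- buildSurrogate(gene, gene, rcOracle(flank))
    expect_identical(as.character(surF$stitchedSeq),
        as.character(surR$stitchedSeq))
})
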