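#' @include AllClasses.R
#' @importFrom IRanges IRanges reduce
NULL

#' Fraction of a query covered by merged hit intervals
#'
#' Merges overlapping hit intervals along the query (0-based half-open
#' coordinates) and divides the union length by the query length.
#'
#' @param hits data.frame with columns \code{query_start},
#'   \code{query_end} (may have zero rows).
#' @param queryLen query length in bp.
#' @return list with \code{covered_bases}, \code{query_len},
#'   \code{fraction}.
#' @export
mergedCoverageFraction <- function(hits, queryLen) {
    stopifnot(queryLen >= 1)
    if (is.null(hits) || !nrow(hits))
        return(list(covered_bases = 0L, query_len = as.integer(queryLen),
            fraction = 0))
    if (any(hits$query_start < 0 | hits$query_end > queryLen |
            hits$query_start >= hits$query_end))
        stop("hit interval out of query bounds", call. = FALSE)
    ir <- IRanges::reduce(IRanges::IRanges(start = hits$query_start + 1L,
        end = hits$query_end))
    cov <- sum(IRanges::width(ir))
    list(covered_bases = as.integer(cov), query_len = as.integer(queryLen),
        fraction = cov / queryLen)
}

# Exact two-sided Mann-Whitney U by enumeration of all group
# assignments of the pooled values (handles ties exactly): p is the
# fraction of assignments whose U is at least as far from its null mean
# n1*n2/2 as the observed U.
exactMannWhitney <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    pooled <- c(x, y)
    r <- rank(pooled)
    Uobs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    combs <- utils::combn(n1 + n2, n1)
    dev <- apply(combs, 2L, function(idx)
        abs(sum(r[idx]) - n1 * (n1 + 1) / 2 - mu))
    p <- mean(dev >= abs(Uobs - mu) - 1e-9)
    list(U = Uobs, p = p, method = "exact enumeration")
}

#' Two-sided Mann-Whitney U comparison of coverage fractions
#'
#' Compares the mobile-element coverage fractions of loci with a split
#' ancestral state against those with an intact ancestral state. Small
#' samples (n1 + n2 <= 20) are tested by exact enumeration over all
#' group assignments of the pooled values, which remains exact under
#' ties; larger samples use the tie-corrected normal approximation.
#'
#' @param splitFracs,intactFracs numeric vectors, both non-empty.
#' @return list with \code{U} (statistic for the first group),
#'   \code{p} (two-sided), \code{method}.
#' @export
compareCoverageGroups <- function(splitFracs, intactFracs) {
    if (!length(splitFracs) || !length(intactFracs))
        stop("both groups must be non-empty", call. = FALSE)
    if (length(splitFracs) + length(intactFracs) <= 20L)
        return(exactMannWhitney(splitFracs, intactFracs))
    wt <- suppressWarnings(stats::wilcox.test(splitFracs, intactFracs,
        alternative = "two.sided", exact = FALSE, correct = TRUE))
    list(U = unname(wt$statistic), p = wt$p.value,
        method = "normal approximation (tie-corrected)")
}

#' Fragmented-alignment filter for putative deletion-born fusions
#'
#' Flags a gene-versus-genome hit set as consistent with a deletion-born
#' fusion when the gene aligns to the genome in separated fragments:
#' merged query coverage of at least \code{minCoverage}, no single hit
#' covering more than \code{maxBestHit} of the gene, and at least two
#' hits separated by \code{minSeparation} or more in genome coordinates.
#'
#' @param hits data.frame with query (\code{query_start},
#'   \code{query_end}) and genome (\code{genome_start},
#'   \code{genome_end}) coordinates, 0-based half-open.
#' @param geneLen gene length in bp.
#' @param minCoverage merged query coverage threshold (default 0.8).
#' @param maxBestHit maximum single-hit query span as a fraction of the
#'   gene (default 0.8).
#' @param minSeparation minimum genome-coordinate gap between two hits,
#'   bp (default 1000).
#' @return logical(1).
#' @export
splitAlignmentFilter <- function(hits, geneLen, minCoverage = 0.8,
        maxBestHit = 0.8, minSeparation = 1000L) {
    if (is.null(hits) || nrow(hits) < 1L) return(FALSE)
    cov <- mergedCoverageFraction(hits[, c("query_start", "query_end")],
        geneLen)$fraction
    if (cov < minCoverage) return(FALSE)
    if (max(hits$query_end - hits$query_start) > maxBestHit * geneLen)
        return(FALSE)
    if (nrow(hits) < 2L) return(FALSE)
    for (i in seq_len(nrow(hits) - 1L)) for (j in (i + 1L):nrow(hits)) {
        gap <- max(hits$genome_start[j] - hits$genome_end[i],
            hits$genome_start[i] - hits$genome_end[j])
        if (gap >= minSeparation) return(TRUE)
    }
    FALSE
}

#' Sample protein families under a sampling strategy
#'
#' Uniform sampling without replacement among eligible families:
#' \code{"all"} admits every family, \code{"non_singleton"} families
#' with at least two members, \code{"large"} families with strictly
#' more than 20 members.
#'
#' @param families data.frame with columns \code{family_id},
#'   \code{genome_id}, \code{species_id} (one row per member).
#' @param strategy one of \code{"all"}, \code{"non_singleton"},
#'   \code{"large"}.
#' @param n number of families to draw.
#' @param seed RNG seed.
#' @param largeThreshold membership threshold for \code{"large"}
#'   (strictly greater; default 20).
#' @return character vector of family ids.
#' @export
sampleFamilies <- function(families, strategy = c("all", "non_singleton",
        "large"), n, seed = 42L, largeThreshold = 20L) {
    strategy <- match.arg(strategy)
    sizes <- table(families$family_id)
    eligible <- switch(strategy,
        all = names(sizes),
        non_singleton = names(sizes)[sizes >= 2L],
        large = names(sizes)[sizes > largeThreshold])
    if (length(eligible) < n)
        stop(sprintf(
            "only %d eligible families under strategy '%s' (need %d)",
            length(eligible), strategy, n), call. = FALSE)
    withLocalSeed(seed, sample(sort(eligible), n))
}

#' Sampling depth score of protein families
#'
#' Number of distinct genomes containing members of a family divided by
#' the number of unique species represented. A score of 1 indicates a
#' family sampled once or spread across as many species as genomes;
#' higher scores indicate repeated within-species sampling. Duplicate
#' member rows from the same genome count once.
#'
#' @param families data.frame with columns \code{family_id},
#'   \code{genome_id}, \code{species_id}.
#' @return data.frame: family_id, n_genomes, n_species, score.
#' @export
samplingDepthScore <- function(families) {
    sp <- split(families, families$family_id)
    out <- do.call(rbind, lapply(sp, function(f) {
        ng <- length(unique(f$genome_id))
        ns <- length(unique(f$species_id))
        data.frame(family_id = f$family_id[1], n_genomes = ng,
            n_species = ns, score = ng / ns, stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Import 12-column tabular local-alignment hits
#'
#' Reads the standard 12-column tabular hit format (query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart,
#' qend, sstart, send, evalue, bitscore; 1-based inclusive coordinates)
#' and converts coordinates to 0-based half-open.
#'
#' @param path file path.
#' @return data.frame with query_id, subject_id, query_start,
#'   query_end, genome_start, genome_end, score columns.
#' @export
readTabularHits <- function(path) {
    cols <- c("query_id", "subject_id", "pident", "length", "mismatch",
        "gapopen", "qstart", "qend", "sstart", "send", "evalue", "bitscore")
    df <- utils::read.delim(path, header = FALSE, col.names = cols)
    data.frame(
        query_id = df$query_id, subject_id = df$subject_id,
        query_start = pmin(df$qstart, df$qend) - 1L,
        query_end = pmax(df$qstart, df$qend),
        genome_start = pmin(df$sstart, df$send) - 1L,
        genome_end = pmax(df$sstart, df$send),
        score = df$bitscore, stringsAsFactors = FALSE)
}

# K-mer prescreen before Smith-Waterman: the set of all word-size
# substrings of the query (both strands) intersected with a
# non-overlapping word grid of the subject. A shared exact block of
# >= 2*wordSize-1 bp is always detected.
queryWordSet <- function(query, wordSize = 15L) {
    n <- nchar(query)
    if (n < wordSize) return(character(0))
    unique(substring(query, 1:(n - wordSize + 1L), wordSize:n))
}

sharesWord <- function(qWords, subject, wordSize = 15L) {
    n <- nchar(subject)
    if (n < wordSize || !length(qWords)) return(FALSE)
    starts <- unique(c(seq(1L, n - wordSize + 1L, by = wordSize),
        n - wordSize + 1L))
    any(substring(subject, starts, starts + wordSize - 1L) %in% qWords)
}

#' Local-alignment hits of a database against an intervening sequence
#'
#' Smith-Waterman local alignment (match 2, mismatch -3, gap open 5,
#' extend 2) of each database sequence against the query, iterated with
#' query masking to report multiple non-overlapping hits per subject.
#' Database entries sharing no exact word with the query are skipped by
#' a prescreen. External tabular hits (\code{\link{readTabularHits}})
#' can be used interchangeably.
#'
#' @param query the intervening sequence (character or
#'   \code{DNAString}).
#' @param db named \code{DNAStringSet} (e.g. a mobile-element /
#'   prophage database).
#' @param minScore minimum alignment score to report (default 50).
#' @param maxHitsPerSubject cap on masked re-alignment rounds.
#' @return data.frame with subject_id, query_start, query_end, score
#'   (0-based half-open query coordinates).
#' @export
localAlignmentHits <- function(query, db, minScore = 50,
        maxHitsPerSubject = 5L) {
    query <- toupper(as.character(query))
    qWords <- queryWordSet(query)
    out <- list()
    for (i in seq_along(db)) {
        sid <- names(db)[i]
        subj <- as.character(db[[i]])
        if (!sharesWord(qWords, subj)) next
        cur <- query
        for (round in seq_len(maxHitsPerSubject)) {
            aln <- swLocal(cur, subj)
            sc <- BiocGenerics::score(aln)
            if (sc < minScore) break
            pa <- Biostrings::pattern(aln)
            qs <- BiocGenerics::start(pa) - 1L
            qe <- BiocGenerics::end(pa)
            out[[length(out) + 1L]] <- data.frame(subject_id = sid,
                query_start = qs, query_end = qe, score = sc,
                stringsAsFactors = FALSE)
            substr(cur, qs + 1L, qe) <- strrep("N", qe - qs)
        }
    }
    if (!length(out))
        return(data.frame(subject_id = character(0),
            query_start = integer(0), query_end = integer(0),
            score = numeric(0)))
    do.call(rbind, out)
}

#' Mobile-element coverage of an intervening sequence
#'
#' Aligns an intervening sequence against a mobile-element / prophage
#' database and returns the merged coverage fraction of the query.
#' Reverse-complement matches are found by also aligning against the
#' reverse complement of the query.
#'
#' @inheritParams localAlignmentHits
#' @return As \code{\link{mergedCoverageFraction}}.
#' @export
mgeCoverage <- function(query, db, minScore = 50) {
    query <- as.character(query)
    qLen <- nchar(query)
    if (qLen == 0L)
        return(list(covered_bases = 0L, query_len = 0L, fraction = 0))
    fwd <- localAlignmentHits(query, db, minScore = minScore)
    rev <- localAlignmentHits(revcompChar(query), db, minScore = minScore)
    if (nrow(rev)) {
        tmp <- qLen - rev$query_end
        rev$query_end <- qLen - rev$query_start
        rev$query_start <- tmp
    }
    mergedCoverageFraction(rbind(fwd, rev), qLen)
}
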