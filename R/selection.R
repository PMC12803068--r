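#' @include AllClasses.R
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

# amino acid (or "*") for a codon, via the standard genetic code
codonAA <- function(codon) {
    unname(Biostrings::GENETIC_CODE[codon])
}

# Path-averaged synonymous/nonsynonymous split for one differing codon
# (NG86 style): average the per-step classification over all orderings
# of the single-site changes, excluding orderings that pass through a
# stop codon. A codon that *is* a stop in alt, or whose every path
# passes through a stop, counts as one stop gain and contributes no
# syn/nonsyn.
codonPathCounts <- function(refCodon, altCodon) {
    rc <- strsplit(refCodon, "")[[1]]
    ac <- strsplit(altCodon, "")[[1]]
    diffPos <- which(rc != ac)
    if (!length(diffPos)) return(list(syn = 0, nonsyn = 0, stop = 0L))
    if (codonAA(altCodon) == "*")
        return(list(syn = 0, nonsyn = 0, stop = 1L))
    perms <- switch(as.character(length(diffPos)),
        "1" = list(diffPos),
        "2" = list(diffPos, rev(diffPos)),
        "3" = lapply(list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
            c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)),
            function(o) diffPos[o]))
    synTot <- 0; nonTot <- 0; nValid <- 0L
    for (path in perms) {
        cur <- rc
        syn <- 0; non <- 0; valid <- TRUE
        for (p in path) {
            aaBefore <- codonAA(paste(cur, collapse = ""))
            cur[p] <- ac[p]
            aaAfter <- codonAA(paste(cur, collapse = ""))
            if (aaAfter == "*" &&
                    !identical(paste(cur, collapse = ""), altCodon)) {
                valid <- FALSE
                break
            }
            if (aaAfter == aaBefore) syn <- syn + 1 else non <- non + 1
        }
        if (valid) {
            synTot <- synTot + syn
            nonTot <- nonTot + non
            nValid <- nValid + 1L
        }
    }
    if (nValid == 0L) return(list(syn = 0, nonsyn = 0, stop = 1L))
    list(syn = synTot / nValid, nonsyn = nonTot / nValid, stop = 0L)
}

#' Count synonymous/nonsynonymous differences over a codon alignment
#'
#' Walks the reference reading frame of a pairwise (gapped) alignment
#' and classifies each differing codon. Single-site differences are
#' classified directly by their amino-acid effect; codons differing at
#' several sites are averaged over all orderings of single-site
#' mutational paths (orderings passing through a stop are excluded, so
#' counts may be fractional). Codons overlapping alignment gaps,
#' insertions, or ambiguous bases contribute only to
#' \code{codons_skipped}; changes creating a stop codon are tracked in
#' \code{stop_gains} and excluded from syn/nonsyn.
#'
#' @param refAligned,altAligned equal-length gapped alignment strings;
#'   the ungapped reference must be a multiple of 3 (reference frame).
#' @return list with elements \code{syn}, \code{nonsyn},
#'   \code{stop_gains}, \code{codons_skipped}.
#' @examples
#' countCodonDiffs("AAACCC", "AAGACC")  # 1 syn (Lys), 1 nonsyn (Pro->Thr)
#' @export
countCodonDiffs <- function(refAligned, altAligned) {
    r <- strsplit(as.character(refAligned), "")[[1]]
    a <- strsplit(as.character(altAligned), "")[[1]]
    if (length(r) != length(a))
        stop("alignment strings differ in length", call. = FALSE)
    refCols <- which(r != "-")
    if (length(refCols) %% 3L != 0L)
        stop("frame-incompatible alignment: ungapped reference length ",
            length(refCols), " is not a multiple of 3", call. = FALSE)
    syn <- 0; nonsyn <- 0; stopGains <- 0L; skipped <- 0L
    for (cod in seq_len(length(refCols) %/% 3L)) {
        cols <- refCols[(3L * cod - 2L):(3L * cod)]
        refCodon <- paste(r[cols], collapse = "")
        altCodon <- paste(a[cols], collapse = "")
        insertionInside <- (cols[3L] - cols[1L]) > 2L
        if (insertionInside || grepl("[^ACGT]", refCodon) ||
                grepl("[^ACGT]", altCodon)) {
            skipped <- skipped + 1L
            next
        }
        if (refCodon == altCodon) next
        pc <- codonPathCounts(refCodon, altCodon)
        syn <- syn + pc$syn
        nonsyn <- nonsyn + pc$nonsyn
        stopGains <- stopGains + pc$stop
    }
    # alternate codons opposite reference gaps (insertions, e.g. NNN
    # surrogate joints) are skipped codons as well
    gapRuns <- rle(r == "-")
    skipped <- skipped +
        as.integer(sum(ceiling(gapRuns$lengths[gapRuns$values] / 3)))
    list(syn = syn, nonsyn = nonsyn, stop_gains = stopGains,
        codons_skipped = skipped)
}

# Expand a gapped amino-acid string back to nucleotides, consuming
# codons of ntSeq starting at codon index `fromCodon`.
backmapAA <- function(gappedAA, ntSeq, fromCodon) {
    chars <- strsplit(gappedAA, "")[[1]]
    out <- character(length(chars))
    cod <- fromCodon
    for (i in seq_along(chars)) {
        if (chars[i] == "-") out[i] <- "---"
        else {
            out[i] <- substr(ntSeq, 3L * cod - 2L, 3L * cod)
            cod <- cod + 1L
        }
    }
    paste(out, collapse = "")
}

#' Codon-aware pairwise alignment to a reference CDS
#'
#' Frame-preserving alignment of an observed allele to the canonical
#' query CDS, for downstream codon difference counting. When both
#' sequences are codon-sized (lengths multiples of 3) the sequences are
#' translated (ambiguous codons become X), aligned as proteins with
#' ends-free overlap alignment, and the alignment is mapped back onto
#' nucleotides; otherwise an ends-free nucleotide alignment is used
#' directly. The result is padded to cover the full reference, with
#' uncovered reference termini opposite gap characters (those codons are
#' skipped during counting, mirroring the exact-anchor design which
#' discards terminal variation).
#'
#' @param ref reference CDS (character or \code{DNAString}).
#' @param alt allele sequence (may contain N, e.g. surrogate joints).
#' @return list with \code{refAligned}, \code{altAligned} strings.
#' @export
alignToRef <- function(ref, alt) {
    ref <- as.character(ref)
    alt <- as.character(alt)
    nr <- nchar(ref)
    proteinRoute <- nr %% 3L == 0L && nchar(alt) %% 3L == 0L
    if (proteinRoute) {
        aaRef <- as.character(Biostrings::translate(
            Biostrings::DNAString(ref), if.fuzzy.codon = "solve"))
        aaAlt <- as.character(Biostrings::translate(
            Biostrings::DNAString(alt), if.fuzzy.codon = "solve"))
        data("BLOSUM62", package = "Biostrings", envir = environment())
        aln <- Biostrings::pairwiseAlignment(
            Biostrings::AAString(aaRef), Biostrings::AAString(aaAlt),
            substitutionMatrix = get("BLOSUM62", envir = environment()),
            type = "overlap", gapOpening = 10, gapExtension = 2)
        pa <- Biostrings::pattern(aln)
        sa <- Biostrings::subject(aln)
        refNtAln <- backmapAA(as.character(pa), ref, BiocGenerics::start(pa))
        altNtAln <- backmapAA(as.character(sa), alt, BiocGenerics::start(sa))
        preRef <- substr(ref, 1L, 3L * (BiocGenerics::start(pa) - 1L))
        postRef <- substr(ref, 3L * BiocGenerics::end(pa) + 1L, nr)
    } else {
        mat <- Biostrings::nucleotideSubstitutionMatrix(
            match = 2, mismatch = -3, baseOnly = FALSE)
        aln <- Biostrings::pairwiseAlignment(
            Biostrings::DNAString(ref), Biostrings::DNAString(alt),
            substitutionMatrix = mat, type = "overlap",
            gapOpening = 5, gapExtension = 2)
        pa <- Biostrings::pattern(aln)
        sa <- Biostrings::subject(aln)
        refNtAln <- as.character(pa)
        altNtAln <- as.character(sa)
        preRef <- substr(ref, 1L, BiocGenerics::start(pa) - 1L)
        postRef <- substr(ref, BiocGenerics::end(pa) + 1L, nr)
    }
    list(
        refAligned = paste0(preRef, refNtAln, postRef),
        altAligned = paste0(strrep("-", nchar(preRef)), altNtAln,
            strrep("-", nchar(postRef))))
}

#' Deduplicate sequences, retaining genome counts
#'
#' Collapses identical sequences and records how many genomes carried
#' each unique sequence, so downstream estimates can weight by
#' occurrence.
#'
#' @param seqs \code{DNAStringSet} or character vector (one entry per
#'   genome).
#' @return data.frame with columns \code{sequence} and \code{weight},
#'   weights summing to \code{length(seqs)}.
#' @export
dedupSequences <- function(seqs) {
    s <- as.character(seqs)
    tab <- table(s)
    data.frame(sequence = names(tab), weight = as.integer(tab),
        stringsAsFactors = FALSE, row.names = NULL)
}

#' Weighted dN/dS over a set of unique sequences
#'
#' Sums synonymous and nonsynonymous difference counts across unique
#' sequences, weighting each by the number of genomes in which it
#' occurred; the ratio is weighted nonsynonymous divided by weighted
#' synonymous changes (raw counts, uncorrected for site composition)
#' and is undefined (NA) when the weighted synonymous total is zero.
#'
#' @param counts list of per-unique-sequence count lists from
#'   \code{\link{countCodonDiffs}}.
#' @param weights integer genome counts parallel to \code{counts}.
#' @return list with \code{weighted_dN}, \code{weighted_dS},
#'   \code{ratio}, \code{stop_gains}, \code{n_unique}, \code{n_genomes}.
#' @export
weightedDnds <- function(counts, weights) {
    stopifnot(length(counts) == length(weights), all(weights >= 1))
    dN <- sum(vapply(counts, `[[`, 0, "nonsyn") * weights)
    dS <- sum(vapply(counts, `[[`, 0, "syn") * weights)
    sg <- sum(vapply(counts, function(x) as.numeric(x$stop_gains), 0) *
        weights)
    list(weighted_dN = dN, weighted_dS = dS,
        ratio = if (dS > 0) dN / dS else NA_real_,
        stop_gains = sg, n_unique = length(counts),
        n_genomes = sum(weights))
}

#' Weighted selection estimate for a set of allele sequences
#'
#' Deduplicates the per-genome allele sequences, codon-aligns each
#' unique sequence to the canonical query CDS, counts codon differences
#' and aggregates them into a genome-weighted dN/dS estimate.
#'
#' @param queryCds canonical query CDS.
#' @param alleleSeqs per-genome allele sequences (\code{DNAStringSet}
#'   or character).
#' @return As \code{\link{weightedDnds}}.
#' @export
estimateSelection <- function(queryCds, alleleSeqs) {
    uni <- dedupSequences(alleleSeqs)
    counts <- lapply(uni$sequence, function(s) {
        aln <- alignToRef(queryCds, s)
        countCodonDiffs(aln$refAligned, aln$altAligned)
    })
    weightedDnds(counts, uni$weight)
}

#' Exhaustive open reading frame finder
#'
#' Enumerates ORFs on both strands of a sequence: each ORF runs from
#' the first start codon (ATG/GTG/TTG by default) following the previous
#' in-frame stop, through the next in-frame stop codon (inclusive), and
#' must reach the minimum length. Coordinates are 0-based half-open on
#' the forward strand.
#'
#' @param seq character or \code{DNAString}.
#' @param minLen minimum ORF length in bp, including the stop codon
#'   (default 90).
#' @param starts permitted start codons.
#' @return data.frame: start, end, strand, length, sequence (ORF
#'   orientation).
#' @export
findOrfs <- function(seq, minLen = 90L,
        starts = c("ATG", "GTG", "TTG")) {
    seq <- toupper(as.character(seq))
    n <- nchar(seq)
    out <- list()
    for (strand in c("+", "-")) {
        s <- if (strand == "+") seq else revcompChar(seq)
        for (f in 0:2) {
            ncod <- (n - f) %/% 3L
            if (ncod < 2L) next
            pos <- f + 3L * (seq_len(ncod) - 1L) + 1L
            codons <- substring(s, pos, pos + 2L)
            stopIdx <- which(codons %in% STOP_CODONS)
            startIdx <- which(codons %in% starts)
            prev <- 0L
            for (q in stopIdx) {
                cand <- startIdx[startIdx > prev & startIdx < q]
                if (length(cand)) {
                    i0 <- cand[1L]
                    from <- pos[i0]
                    to <- pos[q] + 2L
                    len <- to - from + 1L
                    if (len >= minLen) {
                        if (strand == "+") {
                            st <- from - 1L; en <- to
                        } else {
                            st <- n - to; en <- n - from + 1L
                        }
                        out[[length(out) + 1L]] <- data.frame(
                            start = st, end = en, strand = strand,
                            length = len,
                            sequence = substr(s, from, to),
                            stringsAsFactors = FALSE)
                    }
                }
                prev <- q
            }
        }
    }
    if (!length(out))
        return(data.frame(start = integer(0), end = integer(0),
            strand = character(0), length = integer(0),
            sequence = character(0)))
    res <- do.call(rbind, out)
    res[order(res$start, res$end), , drop = FALSE]
}

# One round of local alignment of (masked) query against a subject.
swLocal <- function(query, subject, gapOpening = 5, gapExtension = 2) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
        mismatch = -3, baseOnly = FALSE)
    Biostrings::pairwiseAlignment(Biostrings::DNAString(query),
        Biostrings::DNAString(subject), type = "local",
        substitutionMatrix = mat, gapOpening = gapOpening,
        gapExtension = gapExtension)
}

#' Build a surrogate pre-deletion gene from a split-state locus
#'
#' Reconstructs a stand-in for the ancestral (pre-deletion) allele of a
#' fusion gene: local-alignment segments of the query CDS against the
#' split-state locus are collected greedily by score (each new segment
#' may overlap at most \code{overlapCap} of its length with previously
#' accepted query intervals), projected into the flanking sequence,
#' intersected with predicted ORFs (both strands, starts ATG/GTG/TTG,
#' minimum 90 bp), and the maximal-overlap ORF of each segment is
#' stitched in query order with \code{NNN} joints to preserve
#' codon-phase ambiguity at the junctions.
#'
#' @param queryCds the fused query CDS.
#' @param locusSeq locus sequence from a genome assigned to the
#'   inferred ancestral (split) cluster, gene orientation.
#' @param flankSeq sequence context containing \code{locusSeq}
#'   (default: the locus itself); located by exact substring match,
#'   reverse complement allowed.
#' @param minScore stop collecting segments below this local alignment
#'   score (match 2, mismatch -3, gap open 5, extend 2).
#' @param overlapCap maximum fraction of a segment's query interval
#'   already covered by accepted segments (default 0.2).
#' @param maxSegments cap on accepted segments.
#' @param orfMinLen minimum ORF length passed to \code{\link{findOrfs}}.
#' @return list with \code{stitchedSeq} (\code{DNAString}),
#'   \code{segments} (data.frame with query/locus/flank intervals and
#'   chosen ORF), or NULL when no alignment segment is found.
#' @export
buildSurrogate <- function(queryCds, locusSeq, flankSeq = NULL,
        minScore = 40, overlapCap = 0.2, maxSegments = 8L,
        orfMinLen = 90L) {
    queryCds <- as.character(queryCds)
    locusSeq <- as.character(locusSeq)
    if (is.null(flankSeq)) {
        flankSeq <- locusSeq
        offset <- 0L
        flankStrand <- "+"
    } else {
        flankSeq <- as.character(flankSeq)
        hit <- regexpr(locusSeq, flankSeq, fixed = TRUE)
        if (hit > 0) {
            offset <- as.integer(hit) - 1L
            flankStrand <- "+"
        } else {
            hit <- regexpr(revcompChar(locusSeq), flankSeq, fixed = TRUE)
            if (hit < 0)
                stop("locusSeq not found in flankSeq", call. = FALSE)
            offset <- as.integer(hit) - 1L
            flankStrand <- "-"
        }
    }
    lLen <- nchar(locusSeq)
    cur <- queryCds
    segs <- list()
    covered <- integer(0)
    for (round in seq_len(20L)) {
        if (length(segs) >= maxSegments) break
        aln <- swLocal(cur, locusSeq)
        if (BiocGenerics::score(aln) < minScore) break
        pa <- Biostrings::pattern(aln)
        sa <- Biostrings::subject(aln)
        qs <- BiocGenerics::start(pa) - 1L
        qe <- BiocGenerics::end(pa)
        ls <- BiocGenerics::start(sa) - 1L
        le <- BiocGenerics::end(sa)
        if (qe - qs < 12L) break
        newCov <- setdiff(seq.int(qs + 1L, qe), covered)
        overlapFrac <- 1 - length(newCov) / (qe - qs)
        if (overlapFrac <= overlapCap) {
            segs[[length(segs) + 1L]] <- data.frame(
                query_start = qs, query_end = qe,
                locus_start = ls, locus_end = le,
                score = BiocGenerics::score(aln))
            covered <- c(covered, newCov)
        }
        # mask this query interval so the next round finds a new segment
        substr(cur, qs + 1L, qe) <- strrep("N", qe - qs)
    }
    if (!length(segs)) return(NULL)
    segs <- do.call(rbind, segs)
    # project locus intervals into flank coordinates
    if (flankStrand == "+") {
        segs$flank_start <- offset + segs$locus_start
        segs$flank_end <- offset + segs$locus_end
    } else {
        segs$flank_start <- offset + (lLen - segs$locus_end)
        segs$flank_end <- offset + (lLen - segs$locus_start)
    }
    orfs <- findOrfs(flankSeq, minLen = orfMinLen)
    pick <- integer(nrow(segs))
    for (i in seq_len(nrow(segs))) {
        ov <- pmin(orfs$end, segs$flank_end[i]) -
            pmax(orfs$start, segs$flank_start[i])
        pick[i] <- if (nrow(orfs) && max(ov) > 0) which.max(ov) else NA_integer_
    }
    keep <- !is.na(pick)
    segs <- segs[keep, , drop = FALSE]
    pick <- pick[keep]
    if (!nrow(segs)) return(NULL)
    ord <- order(segs$query_start)
    segs <- segs[ord, , drop = FALSE]
    pick <- pick[ord]
    segs$orf_id <- pick
    segs$orf_start <- orfs$start[pick]
    segs$orf_end <- orfs$end[pick]
    stitched <- paste(orfs$sequence[pick], collapse = "NNN")
    rownames(segs) <- NULL
    list(stitchedSeq = Biostrings::DNAString(stitched), segments = segs)
}
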