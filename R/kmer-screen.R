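#' @include AllClasses.R
NULL

#' Construct a QueryGene from a coding sequence
#'
#' Extracts the prefix k-mer from positions \code{[g, g+k)} and the
#' suffix k-mer from positions \code{[L-g-k, L-g)} of the gene (0-based,
#' half-open), where \code{L} is the gene length. The terminal gap
#' \code{g} skips the start/stop codons and, when not a multiple of 3,
#' shifts the anchors out of frame relative to the CDS, which suppresses
#' spurious matches to homologous codon runs.
#'
#' @param sequence gene sequence (character, \code{DNAString}, or a
#'   length-1 \code{DNAStringSet}).
#' @param geneId gene identifier.
#' @param k k-mer length in bp (default 27).
#' @param g terminal gap in bp (default 4).
#' @return A \linkS4class{QueryGene}.
#' @examples
#' qg <- queryGene(paste(rep("ACGT", 250), collapse = ""), "toy")
#' expectedSpan(qg)  # 992 for a 1000 bp gene with default k, g
#' @export
queryGene <- function(sequence, geneId = "query", k = 27L, g = 4L) {
    k <- as.integer(k); g <- as.integer(g)
    if (is(sequence, "DNAStringSet")) {
        stopifnot(length(sequence) == 1L)
        if (!is.null(names(sequence)) && missing(geneId))
            geneId <- names(sequence)[1]
        sequence <- sequence[[1]]
    }
    if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
    L <- length(sequence)
    if (L < 2L * (k + g))
        stop("gene '", geneId, "' rejected: length ", L,
            " < 2(k+g) = ", 2L * (k + g), call. = FALSE)
    pref <- sequence[(g + 1L):(g + k)]
    suff <- sequence[(L - g - k + 1L):(L - g)]
    if (grepl("[^ACGT]", paste0(as.character(pref), as.character(suff))))
        stop("gene '", geneId,
            "' rejected: ambiguous base in a k-mer window", call. = FALSE)
    new("QueryGene", geneId = geneId, sequence = sequence, k = k, g = g,
        prefixKmer = pref, suffixKmer = suff,
        expectedSpan = L - 2L * g)
}

#' Extract prefix/suffix k-mer queries from a set of genes
#'
#' Builds a \linkS4class{QueryGene} for each entry of a gene FASTA /
#' \code{DNAStringSet}. Genes that are too short (length < 2(k+g)) or
#' whose k-mer windows contain ambiguous bases are rejected and reported
#' in the \code{"rejected"} attribute of the result rather than aborting
#' the run.
#'
#' @param genes a named \code{DNAStringSet} (or path to a FASTA file).
#' @inheritParams queryGene
#' @return A named list of \linkS4class{QueryGene} objects; attribute
#'   \code{"rejected"} is a data.frame (gene_id, reason) of rejections.
#' @export
extractQueryKmers <- function(genes, k = 27L, g = 4L) {
    if (is.character(genes) && length(genes) == 1L && file.exists(genes))
        genes <- Biostrings::readDNAStringSet(genes)
    if (is.null(names(genes)))
        names(genes) <- paste0("gene_", seq_along(genes))
    out <- list()
    rej <- data.frame(gene_id = character(0), reason = character(0))
    for (i in seq_along(genes)) {
        id <- names(genes)[i]
        qg <- tryCatch(queryGene(genes[[i]], id, k, g), error = function(e) e)
        if (is(qg, "error")) {
            reason <- if (grepl("ambiguous", conditionMessage(qg)))
                "ambiguous_base_in_window" else "sequence_too_short"
            rej <- rbind(rej, data.frame(gene_id = id, reason = reason))
        } else out[[id]] <- qg
    }
    attr(out, "rejected") <- rej
    out
}

#' Read a genome collection
#'
#' Reads a collection either from a directory of per-genome FASTA files
#' (genome id = file name without extension) or from a manifest TSV with
#' columns \code{genome_id} and \code{path}. Unreadable genomes are
#' skipped and reported in the \code{"failed"} attribute so a long run
#' survives isolated corrupt inputs.
#'
#' @param x directory, manifest TSV path, or a named list of
#'   \code{DNAStringSet} (returned unchanged).
#' @return Named list of \code{DNAStringSet}, one element per genome.
#' @export
readGenomeCollection <- function(x) {
    if (is.list(x)) return(lapply(x, asContigSet))
    stopifnotScalarString(x, "collection")
    if (dir.exists(x)) {
        paths <- list.files(x, pattern = "\\.(fa|fasta|fna)$",
            full.names = TRUE)
        ids <- sub("\\.[^.]*$", "", basename(paths))
    } else {
        man <- utils::read.delim(x, stringsAsFactors = FALSE)
        stopifnot(all(c("genome_id", "path") %in% names(man)))
        paths <- man$path
        ids <- man$genome_id
    }
    out <- list()
    failed <- character(0)
    for (i in seq_along(paths)) {
        g <- tryCatch(Biostrings::readDNAStringSet(paths[i]),
            error = function(e) NULL)
        if (is.null(g)) failed <- c(failed, ids[i]) else out[[ids[i]]] <- g
    }
    attr(out, "failed") <- failed
    out
}

# All exact occurrences of one k-mer on one contig set, both strands.
# Ambiguous bases in contigs never match (fixed = TRUE matching).
matchKmer <- function(kmer, contigs) {
    hits <- list()
    for (strand in c("forward", "reverse_complement")) {
        pat <- if (strand == "forward") kmer
            else Biostrings::reverseComplement(kmer)
        m <- Biostrings::vmatchPattern(pat, contigs, fixed = TRUE)
        st <- Biostrings::startIndex(m)
        for (ci in seq_along(contigs)) {
            s <- st[[ci]]
            if (length(s))
                hits[[length(hits) + 1L]] <- data.frame(
                    contig_id = names(contigs)[ci],
                    start = s - 1L, strand = strand,
                    stringsAsFactors = FALSE)
        }
    }
    if (length(hits)) do.call(rbind, hits)
    else data.frame(contig_id = character(0), start = integer(0),
        strand = character(0))
}

#' Find all exact k-mer anchor matches in a genome collection
#'
#' Reports every exact occurrence of every prefix and suffix k-mer of
#' the queries, on both strands of every contig of every genome, exactly
#' once. Positions are 0-based contig coordinates of the match start;
#' matches on the reverse strand are reported at the position of the
#' reverse complement on the forward contig. Results are independent of
#' genome batching order.
#'
#' @param queries list of \linkS4class{QueryGene} (see
#'   \code{\link{extractQueryKmers}}).
#' @param collection named list of \code{DNAStringSet} (see
#'   \code{\link{readGenomeCollection}}).
#' @return data.frame with columns gene_id, genome_id, contig_id, role
#'   (\code{"prefix"}/\code{"suffix"}), start, strand
#'   (\code{"forward"}/\code{"reverse_complement"}).
#' @export
findExactMatches <- function(queries, collection) {
    collection <- readGenomeCollection(collection)
    if (is(queries, "QueryGene")) queries <- list(queries)
    res <- list()
    for (gid in names(collection)) {
        contigs <- asContigSet(collection[[gid]])
        for (q in queries) {
            for (role in c("prefix", "suffix")) {
                kmer <- if (role == "prefix") q@prefixKmer else q@suffixKmer
                h <- matchKmer(kmer, contigs)
                if (nrow(h)) {
                    h$gene_id <- q@geneId
                    h$genome_id <- gid
                    h$role <- role
                    res[[length(res) + 1L]] <- h
                }
            }
        }
    }
    cols <- c("gene_id", "genome_id", "contig_id", "role", "start", "strand")
    if (!length(res))
        return(stats::setNames(data.frame(character(0), character(0),
            character(0), character(0), integer(0), character(0)), cols))
    out <- do.call(rbind, res)[, cols]
    rownames(out) <- NULL
    out
}

#' Measure the prefix-suffix locus span in one genome
#'
#' Combines the anchor matches of one (gene, genome) pair into a single
#' locus measurement. A span is computed only for a prefix and a suffix
#' match on the same contig with the same orientation: forward pairs
#' span from the prefix match start to the suffix match end, reverse
#' pairs mirror this, so an intact gene always yields
#' \code{difference = 0}. Among all positive-span candidate pairs the
#' pair minimising \code{|difference|} is chosen (ties broken by the
#' smallest prefix start), a conservative choice that favours the intact
#' interpretation. Genomes whose anchors fall on different contigs are
#' treated as missing; anchors found only in opposite orientations are
#' flagged discordant (inversions are outside the distance model).
#'
#' @param matches data.frame of matches for one (gene, genome) pair (as
#'   from \code{\link{findExactMatches}}).
#' @param query the \linkS4class{QueryGene}.
#' @param allowRC also consider reverse-complement placements
#'   (default TRUE).
#' @param tieBreak how to resolve equal \code{|difference|}:
#'   \code{"smallest_prefix_start"} (default) or \code{"first"}.
#' @return One-row data.frame: gene_id, genome_id, contig_id,
#'   prefix_start, suffix_start, orientation, span, difference, status
#'   (\code{ok}/\code{missing}/\code{discordant}). Coordinate columns
#'   are NA unless status is \code{ok}.
#' @export
measureLocus <- function(matches, query, allowRC = TRUE,
        tieBreak = c("smallest_prefix_start", "first")) {
    tieBreak <- match.arg(tieBreak)
    k <- query@k
    gid <- if (nrow(matches)) matches$genome_id[1] else NA_character_
    stopifnot(length(unique(matches$genome_id)) <= 1L)
    empty <- function(status) data.frame(
        gene_id = query@geneId, genome_id = gid, contig_id = NA_character_,
        prefix_start = NA_integer_, suffix_start = NA_integer_,
        orientation = NA_character_, span = NA_integer_,
        difference = NA_integer_, status = status,
        stringsAsFactors = FALSE)
    if (!nrow(matches)) return(empty("missing"))
    strands <- if (allowRC) c("forward", "reverse_complement") else "forward"
    cand <- list()
    sharedContig <- FALSE
    for (ct in unique(matches$contig_id)) {
        mc <- matches[matches$contig_id == ct, ]
        if (!all(c("prefix", "suffix") %in% mc$role)) next
        sharedContig <- TRUE
        for (or in strands) {
            p <- mc$start[mc$role == "prefix" & mc$strand == or]
            s <- mc$start[mc$role == "suffix" & mc$strand == or]
            if (!length(p) || !length(s)) next
            grid <- expand.grid(prefix_start = p, suffix_start = s)
            grid$span <- if (or == "forward")
                grid$suffix_start + k - grid$prefix_start
            else grid$prefix_start + k - grid$suffix_start
            grid <- grid[grid$span > 0L, , drop = FALSE]
            if (!nrow(grid)) next
            grid$contig_id <- ct
            grid$orientation <- or
            cand[[length(cand) + 1L]] <- grid
        }
    }
    if (!length(cand))
        return(empty(if (sharedContig) "discordant" else "missing"))
    cand <- do.call(rbind, cand)
    cand$difference <- cand$span - query@expectedSpan
    ord <- if (tieBreak == "smallest_prefix_start")
        order(abs(cand$difference), cand$prefix_start, cand$suffix_start)
    else order(abs(cand$difference))
    best <- cand[ord[1L], ]
    data.frame(
        gene_id = query@geneId, genome_id = gid,
        contig_id = best$contig_id,
        prefix_start = as.integer(best$prefix_start),
        suffix_start = as.integer(best$suffix_start),
        orientation = best$orientation,
        span = as.integer(best$span),
        difference = as.integer(best$difference),
        status = "ok", stringsAsFactors = FALSE)
}

#' Measure all loci of a screen
#'
#' Applies \code{\link{measureLocus}} to every (gene, genome) pair of a
#' match table, emitting exactly one row per pair (genomes without any
#' match get a \code{missing} row).
#'
#' @inheritParams measureLocus
#' @param matches full match table from \code{\link{findExactMatches}}.
#' @param queries list of \linkS4class{QueryGene}.
#' @param genomeIds all genome ids of the collection (so genomes with
#'   zero matches are still reported as missing).
#' @return data.frame of measurements, one row per (gene, genome).
#' @export
measureLoci <- function(matches, queries, genomeIds, allowRC = TRUE) {
    if (is(queries, "QueryGene")) queries <- list(queries)
    out <- vector("list", length(queries) * length(genomeIds))
    i <- 0L
    for (q in queries) {
        mq <- matches[matches$gene_id == q@geneId, , drop = FALSE]
        for (gid in genomeIds) {
            m <- mq[mq$genome_id == gid, , drop = FALSE]
            row <- measureLocus(m, q, allowRC = allowRC)
            row$genome_id <- gid
            i <- i + 1L
            out[[i]] <- row
        }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Run the prefix-suffix screen over a collection
#'
#' Convenience wrapper: extracts anchors (unless ready-made queries are
#' given), finds all exact matches and measures every locus.
#'
#' @param genes gene FASTA / \code{DNAStringSet}, or a list of
#'   \linkS4class{QueryGene}.
#' @param collection genome collection (see
#'   \code{\link{readGenomeCollection}}).
#' @inheritParams queryGene
#' @inheritParams measureLocus
#' @return list with elements \code{queries}, \code{matches},
#'   \code{measurements}.
#' @export
screenCollection <- function(genes, collection, k = 27L, g = 4L,
        allowRC = TRUE) {
    queries <- if (is.list(genes) && all(vapply(genes, is, TRUE, "QueryGene")))
        genes else extractQueryKmers(genes, k = k, g = g)
    collection <- readGenomeCollection(collection)
    matches <- findExactMatches(queries, collection)
    measurements <- measureLoci(matches, queries, names(collection),
        allowRC = allowRC)
    list(queries = queries, matches = matches, measurements = measurements)
}
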