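#' @include AllClasses.R
NULL

#' Fixed cargo sequence set standing in for an MGE/prophage database
#'
#' A bundled set of random-but-fixed cargo sequences used as the mobile
#' genetic element database of the synthetic collections (synthetic
#' stand-in; no curated MGE/prophage content is shipped). The default
#' seed is fixed so the fixture is identical across sessions.
#'
#' @param n number of cargo sequences (default 20).
#' @param lenRange length range in bp (default 1-10 kb).
#' @param seed fixed RNG seed for the fixture.
#' @return named \code{DNAStringSet} (\code{mge_01} ...).
#' @export
mgeFixture <- function(n = 20L, lenRange = c(1000L, 10000L),
        seed = 987654L) {
    withLocalSeed(seed, {
        lens <- as.integer(round(seq(lenRange[1], lenRange[2],
            length.out = n)))
        seqs <- vapply(lens, randomDNA, "")
        names(seqs) <- sprintf("mge_%02d", seq_len(n))
        Biostrings::DNAStringSet(seqs)
    })
}

#' Describe a planted structural event
#'
#' @param eventType \code{"deletion_fusion"} (the event clade carries a
#'   deletion joining the two gene fragments into the fused query gene;
#'   all other genomes retain the ancestral split configuration) or
#'   \code{"cargo_insertion"} (the event clade carries a cargo sequence
#'   inserted inside an intact query gene).
#' @param cladeSize number of ingroup genomes in the (monophyletic)
#'   event clade.
#' @param size event size in bp: length of the intervening spacer
#'   removed by the deletion, or of the inserted cargo.
#' @param clade label; events sharing a label share one clade.
#' @param cargoId optional \code{\link{mgeFixture}} entry name to use
#'   as cargo (cargo_insertion only).
#' @return one-row data.frame.
#' @export
plantedEvent <- function(eventType = c("deletion_fusion", "cargo_insertion"),
        cladeSize, size, clade = "A", cargoId = NA_character_) {
    eventType <- match.arg(eventType)
    stopifnot(size >= 9L, cladeSize >= 1L)
    data.frame(event_type = eventType, clade = clade,
        clade_size = as.integer(cladeSize), size = as.integer(size),
        cargo_id = cargoId, stringsAsFactors = FALSE)
}

# Random coding fragments composing a fusion query gene:
# fragA = ATG + stop-free codons, fragB = ATG + stop-free codons + TAA.
# The internal ATG at the fragment junction gives the downstream
# fragment its own start codon, so ORF prediction on a split-state
# locus recovers the two fragments cleanly.
makeFusionGene <- function(geneLen) {
    lenA <- 3L * (ceiling(geneLen / 2) %/% 3L)
    lenB <- 3L * ceiling((geneLen - lenA) / 3)
    fragA <- substr(randomCDS(lenA + 3L), 1L, lenA)  # drop terminal stop
    fragB <- randomCDS(lenB)
    list(fragA = fragA, fragB = fragB, gene = paste0(fragA, fragB))
}

# Ultrametric-ish tree with prescribed monophyletic event clades, each
# nested inside the remainder diversity: the remainder is split into a
# basal and a distal block and the event clades attach on the backbone
# between them, so genomes in the ancestral state are paraphyletic with
# respect to each event clade (as at a real recurrent-SV locus). With
# the clade sister to everything else the MRCA state would be
# irreducibly ambiguous under parsimony.
buildCladeTree <- function(clades, rest, subtreeDepth = 0.25,
        joinStep = 0.1) {
    scale <- function(tr, depth) {
        if (is.null(tr$edge.length)) tr$edge.length <- rep(1, nrow(tr$edge))
        d <- max(ape::node.depth.edgelength(tr))
        if (d > 0) tr$edge.length <- tr$edge.length / d * depth
        tr
    }
    newickOf <- function(tips) {
        if (length(tips) == 1L)
            return(sprintf("%s:%g", tips, subtreeDepth))
        tr <- scale(ape::rcoal(length(tips), tip.label = tips), subtreeDepth)
        gsub(";$", "", ape::write.tree(tr))
    }
    if (length(rest) < 2L)
        stop("need at least 2 non-clade genomes", call. = FALSE)
    half <- ceiling(length(rest) / 2)
    restA <- rest[seq_len(half)]
    restB <- rest[(half + 1L):length(rest)]
    parts <- lapply(c(list(restA), clades, list(restB)), newickOf)
    cur <- parts[[length(parts)]]
    depth <- subtreeDepth
    for (i in rev(seq_len(length(parts) - 1L))) {
        extra <- depth + joinStep - subtreeDepth
        cur <- sprintf("(%s:%g,%s:%g)", parts[[i]], extra, cur, joinStep)
        depth <- depth + joinStep
    }
    ape::read.tree(text = paste0(cur, ";"))
}

# Point substitutions on a char vector, restricted to allowed positions.
mutateSeq <- function(chars, allowedIdx, expSubsPerSite) {
    if (expSubsPerSite <= 0 || !length(allowedIdx)) return(chars)
    nMut <- stats::rbinom(1L, length(allowedIdx),
        min(1, expSubsPerSite))
    if (nMut == 0L) return(chars)
    pos <- sample(allowedIdx, nMut)
    bases <- c("A", "C", "G", "T")
    old <- match(chars[pos], bases)
    shift <- sample.int(3L, nMut, replace = TRUE)
    chars[pos] <- bases[((old - 1L + shift) %% 4L) + 1L]
    chars
}

#' Generate a synthetic genome collection with planted events
#'
#' Simulates a genome collection evolved along a known tree with
#' Jukes-Cantor point substitutions only (indels enter solely through
#' the planted events, keeping truth differences exact), plus two more
#' distant outgroup genomes retaining the ancestral configuration.
#' For every \code{deletion_fusion} event the ancestor carries the two
#' gene fragments of the fused query gene separated by a spacer of the
#' event size; genomes of the event clade carry the deletion that joins
#' the fragments into the fused gene (difference 0) while all others
#' retain the split state (difference +size). For every
#' \code{cargo_insertion} event the ancestor carries the intact gene and
#' the event clade carries a cargo sequence from the MGE fixture
#' inserted between the anchor windows (difference +size).
#' The anchor k-mer windows (in fact the whole engineered loci) sit in
#' protected zones that point mutations never touch, so anchor survival
#' is guaranteed by construction at any substitution rate.
#'
#' @param nGenomes number of ingroup genomes.
#' @param genomeLen approximate genome length in bp.
#' @param subRate expected substitutions per site per unit branch
#'   length (default 0.01, within-species scale for bacteria).
#' @param events data.frame of \code{\link{plantedEvent}} rows (one
#'   query gene per event).
#' @param geneLen query gene length in bp (default 800; rounded to
#'   codons).
#' @param k,gap anchor parameters used for the protected zones.
#' @param seed RNG seed.
#' @param outgroupDepths branch lengths of the two outgroups (the
#'   second is farther and becomes the rooting outgroup).
#' @return A \linkS4class{SyntheticCollection}.
#' @export
generateCollection <- function(nGenomes = 120L, genomeLen = 200000L,
        subRate = 0.01, events = plantedEvent("deletion_fusion", 40L, 5000L),
        geneLen = 800L, k = 27L, gap = 4L, seed = 1L,
        outgroupDepths = c(0.7, 0.9)) {
    stopifnot(nrow(events) >= 1L)
    fixture <- mgeFixture()
    withLocalSeed(seed, {
        E <- nrow(events)
        # clade membership: disjoint blocks of tips per clade label
        cladeLabs <- unique(events$clade)
        cladeSizes <- vapply(cladeLabs, function(cl)
            events$clade_size[match(cl, events$clade)], 0L)
        if (sum(cladeSizes) >= nGenomes)
            stop("clades must leave at least one non-clade genome",
                call. = FALSE)
        ids <- sprintf("g%03d", seq_len(nGenomes))
        cladeTips <- list()
        at <- 1L
        for (ci in seq_along(cladeLabs)) {
            cladeTips[[cladeLabs[ci]]] <- ids[at:(at + cladeSizes[ci] - 1L)]
            at <- at + cladeSizes[ci]
        }
        rest <- ids[at:nGenomes]
        tree <- buildCladeTree(cladeTips, rest)

        # engineered loci on the ancestor
        genes <- list()
        locusParts <- character(E)
        meta <- vector("list", E)
        for (e in seq_len(E)) {
            fg <- makeFusionGene(geneLen)
            genes[[e]] <- fg
            type <- events$event_type[e]
            size <- events$size[e]
            if (type == "deletion_fusion") {
                # split configuration: fragA | spacer | fragB; the spacer
                # begins and ends with in-frame stops so ORFs predicted on
                # the split locus terminate/start at the fragment edges
                spacer <- paste0("TAA", randomDNA(size - 6L), "TAA")
                locus <- paste0("TAA", fg$fragA, spacer, fg$fragB)
            } else {
                cargoId <- events$cargo_id[e]
                if (is.na(cargoId)) {
                    w <- which(Biostrings::width(fixture) >= size)
                    if (!length(w)) stop("no fixture cargo long enough")
                    cargoId <- names(fixture)[w[1L]]
                }
                events$cargo_id[e] <- cargoId
                locus <- paste0("TAA", fg$gene)
            }
            locusParts[e] <- locus
            meta[[e]] <- list(type = type, size = size,
                cargo_id = events$cargo_id[e])
        }

        # assemble ancestor: random chunks interleaved with loci
        chunkLen <- max(1000L, (genomeLen - sum(nchar(locusParts))) %/%
            (E + 1L))
        anc <- character(2L * E + 1L)
        locusStart <- integer(E)
        cursor <- 0L
        for (e in seq_len(E)) {
            chunk <- randomDNA(chunkLen)
            anc[2L * e - 1L] <- chunk
            cursor <- cursor + chunkLen
            locusStart[e] <- cursor + 3L  # skip the leading TAA guard
            anc[2L * e] <- locusParts[e]
            cursor <- cursor + nchar(locusParts[e])
        }
        anc[2L * E + 1L] <- randomDNA(chunkLen)
        ancestor <- paste(anc, collapse = "")
        ancLen <- nchar(ancestor)

        # protected zones = engineered loci incl. the stop guards
        protected <- logical(ancLen)
        for (e in seq_len(E)) {
            from <- locusStart[e] - 2L
            to <- locusStart[e] + nchar(locusParts[e]) - 3L
            protected[from:to] <- TRUE
        }
        allowedIdx <- which(!protected)

        # per-event edit instructions in ancestral coordinates
        edits <- vector("list", E)
        for (e in seq_len(E)) {
            fg <- genes[[e]]
            lenA <- nchar(fg$fragA)
            if (meta[[e]]$type == "deletion_fusion") {
                # removes the whole spacer (its stop guards are part of
                # the spacer's stated size), re-joining fragA to fragB
                from <- locusStart[e] + lenA  # first spacer base (0-based)
                edits[[e]] <- list(type = "del", from = from,
                    len = meta[[e]]$size,
                    tips = cladeTips[[events$clade[e]]])
            } else {
                cargo <- substr(as.character(
                    fixture[[meta[[e]]$cargo_id]]), 1L, meta[[e]]$size)
                edits[[e]] <- list(type = "ins",
                    at = locusStart[e] + lenA, cargo = cargo,
                    tips = cladeTips[[events$clade[e]]])
            }
        }

        # evolve along the tree; apply clade edits at the tips
        applyEdits <- function(seqStr, tip) {
            todo <- Filter(function(ed) tip %in% ed$tips, edits)
            if (!length(todo)) return(seqStr)
            ord <- order(vapply(todo, function(ed)
                if (ed$type == "del") ed$from else ed$at, 0), decreasing = TRUE)
            for (ed in todo[ord]) {
                if (ed$type == "del") {
                    seqStr <- paste0(substr(seqStr, 1L, ed$from),
                        substr(seqStr, ed$from + ed$len + 1L, nchar(seqStr)))
                } else {
                    seqStr <- paste0(substr(seqStr, 1L, ed$at),
                        ed$cargo,
                        substr(seqStr, ed$at + 1L, nchar(seqStr)))
                }
            }
            seqStr
        }

        ancChars <- strsplit(ancestor, "", fixed = TRUE)[[1]]
        nTip <- length(tree$tip.label)
        genomes <- vector("list", nTip)
        names(genomes) <- tree$tip.label
        rootNode <- nTip + 1L
        walk <- function(node, chars) {
            kids <- tree$edge[tree$edge[, 1] == node, 2]
            for (i in seq_along(kids)) {
                ch <- kids[i]
                el <- tree$edge.length[which(tree$edge[, 1] == node &
                    tree$edge[, 2] == ch)[1L]]
                mutated <- mutateSeq(chars, allowedIdx, subRate * el)
                if (ch <= nTip) {
                    tip <- tree$tip.label[ch]
                    genomes[[tip]] <<- applyEdits(
                        paste(mutated, collapse = ""), tip)
                } else walk(ch, mutated)
            }
        }
        walk(rootNode, ancChars)

        outNames <- c("outgroup_1", "outgroup_2")
        outgroups <- list()
        for (i in 1:2) {
            chars <- mutateSeq(ancChars, allowedIdx,
                subRate * outgroupDepths[i])
            outgroups[[outNames[i]]] <- paste(chars, collapse = "")
        }

        # truth table
        truth <- do.call(rbind, lapply(seq_len(E), function(e) {
            inClade <- ids %in% cladeTips[[events$clade[e]]]
            expDiff <- if (meta[[e]]$type == "deletion_fusion")
                ifelse(inClade, 0L, meta[[e]]$size)
            else ifelse(inClade, meta[[e]]$size, 0L)
            data.frame(gene_id = sprintf("gene_%d", e), genome_id = ids,
                expected_difference = expDiff, in_clade = inClade,
                event_type = meta[[e]]$type, stringsAsFactors = FALSE)
        }))

        queryGenes <- Biostrings::DNAStringSet(vapply(genes, `[[`, "",
            "gene"))
        names(queryGenes) <- sprintf("gene_%d", seq_len(E))
        events$gene_id <- sprintf("gene_%d", seq_len(E))
        events$clade_tips <- vapply(events$clade, function(cl)
            paste(cladeTips[[cl]], collapse = ","), "")

        new("SyntheticCollection",
            genomes = lapply(genomes, asContigSet),
            outgroups = lapply(outgroups, asContigSet),
            tree = tree, queryGenes = queryGenes,
            events = events, truth = truth, mgeFixture = fixture)
    })
}

#' Write a synthetic collection to disk
#'
#' Writes \code{genomes/<id>.fa}, \code{outgroups/<id>.fa},
#' \code{genes.fa}, \code{tree.nwk}, \code{truth.tsv} and
#' \code{mge_fixture.fa} under a directory.
#'
#' @param collection a \linkS4class{SyntheticCollection}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCollection <- function(collection, dir) {
    gdir <- file.path(dir, "genomes")
    odir <- file.path(dir, "outgroups")
    dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
    dir.create(odir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(collection@genomes))
        Biostrings::writeXStringSet(collection@genomes[[id]],
            file.path(gdir, paste0(id, ".fa")))
    for (id in names(collection@outgroups))
        Biostrings::writeXStringSet(collection@outgroups[[id]],
            file.path(odir, paste0(id, ".fa")))
    Biostrings::writeXStringSet(collection@queryGenes,
        file.path(dir, "genes.fa"))
    ape::write.tree(collection@tree, file.path(dir, "tree.nwk"))
    utils::write.table(collection@truth, file.path(dir, "truth.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    Biostrings::writeXStringSet(collection@mgeFixture,
        file.path(dir, "mge_fixture.fa"))
    invisible(dir)
}
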