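# Internal helpers shared across modules.

# Evaluate `expr` with a temporarily seeded RNG, restoring the caller's
# RNG state afterwards. seed = NA leaves the current stream untouched.
withLocalSeed <- function(seed, expr) {
    if (is.null(seed) || is.na(seed)) return(expr)
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Derive a bounded child seed from a root seed and stream indices.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
deriveSeed <- function(root, ...) {
    idx <- c(...)
    h <- as.numeric(root) %% 2147483629
    for (v in idx) {
        h <- (h * 48271 + as.numeric(v) + 1) %% 2147483629
    }
    as.integer(h)
}

logSpace <- function(from, to, length.out) {
    10^seq(log10(from), log10(to), length.out = length.out)
}

revcompChar <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Random ACGT string, GC ~ 0.5 (uses the current RNG stream).
randomDNA <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random in-frame coding sequence: ATG + stop-free codons + TAA.
# n is rounded up to a multiple of 3.
randomCDS <- function(n) {
    n <- 3L * ceiling(n / 3)
    ncod <- n / 3L - 2L
    stopifnot(ncod >= 1L)
    bases <- c("A", "C", "G", "T")
    codons <- apply(matrix(sample(bases, 3L * ncod, replace = TRUE),
        ncol = 3L), 1L, paste, collapse = "")
    stops <- c("TAA", "TAG", "TGA")
    while (any(bad <- codons %in% stops)) {
        codons[bad] <- apply(matrix(sample(bases, 3L * sum(bad),
            replace = TRUE), ncol = 3L), 1L, paste, collapse = "")
    }
    paste0("ATG", paste(codons, collapse = ""), "TAA")
}

stopifnotScalarString <- function(x, what) {
    if (!is.character(x) || length(x) != 1L || is.na(x))
        stop(what, " must be a single string", call. = FALSE)
}

# Coerce a genome to a named DNAStringSet of contigs.
asContigSet <- function(genome) {
    if (is(genome, "DNAStringSet")) {
        if (is.null(names(genome)))
            names(genome) <- paste0("contig_", seq_along(genome))
        return(genome)
    }
    if (is(genome, "DNAString"))
        return(Biostrings::DNAStringSet(stats::setNames(list(genome), "contig_1")))
    if (is.character(genome)) {
        dss <- Biostrings::DNAStringSet(genome)
        if (is.null(names(dss))) names(dss) <- paste0("contig_", seq_along(dss))
        return(dss)
    }
    stop("cannot interpret genome of class ", class(genome)[1])
}
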