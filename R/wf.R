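#' @include AllClasses.R
NULL

#' Construct Wright-Fisher simulation parameters
#'
#' @param N haploid population size (default 1e6).
#' @param cost fitness cost of the non-functional gene (state 1 has
#'   relative fitness 1 - cost).
#' @param pInit initial gene frequency; deletion-born fusions start at
#'   the post-sweep frequency of their causal deletion, other gene-birth
#'   mechanisms at 1/N (a lone carrier).
#' @param pPurge per-individual per-generation gene-loss probability.
#' @param pFunc per-individual per-generation functionalization
#'   probability (the rate often written mu).
#' @param tMax generation cap (default 100000).
#' @param seed RNG seed (NA: use the current RNG stream).
#' @return A \linkS4class{WFParams}.
#' @export
wfParams <- function(N = 1e6, cost = 0, pInit = 1e-6, pPurge = 0,
        pFunc = 0, tMax = 100000L, seed = NA_integer_) {
    new("WFParams", N = as.integer(N), cost = cost, pInit = pInit,
        pPurge = pPurge, pFunc = pFunc, tMax = as.integer(tMax),
        seed = as.integer(seed))
}

#' Run one Wright-Fisher replicate
#'
#' Forward-time haploid Wright-Fisher dynamics of a novel gene. Each
#' generation: (1) fitness-proportionate multinomial resampling of the
#' state-0 / state-1 counts (selection + drift; state 1 has fitness
#' 1 - cost); (2) each surviving state-1 individual functionalizes with
#' probability \code{pFunc} or loses the gene with probability
#' \code{pPurge}, drawn as mutually exclusive outcomes of one trinomial
#' split. The replicate ends at the first appearance of any
#' functionalized (state 2) individual, at state-1 extinction, or at
#' \code{tMax}. The initial state-1 count is \code{round(N * pInit)},
#' with a minimum of one carrier whenever \code{pInit > 0}.
#'
#' @param params a \linkS4class{WFParams}.
#' @param trace if TRUE, return a list with the outcome and the
#'   per-generation state-1 count trajectory (\code{n1}); the state-0
#'   count is \code{N - n1} by construction, so state counts always sum
#'   to N.
#' @return A \linkS4class{WFOutcome}, or a list
#'   \code{(outcome, n1)} when \code{trace = TRUE}.
#' @examples
#' runWFReplicate(wfParams(N = 1000, pInit = 1, pFunc = 1e-3, seed = 1))
#' @export
runWFReplicate <- function(params, trace = FALSE) {
    stopifnot(is(params, "WFParams"))
    validObject(params)
    withLocalSeed(params@seed, {
        N <- params@N
        w1 <- 1 - params@cost
        n1 <- if (params@pInit > 0) max(1L, as.integer(round(N * params@pInit)))
            else 0L
        hist <- if (trace) integer(0) else NULL
        done <- function(func, gen, reason) {
            out <- new("WFOutcome", functionalized = func,
                endGeneration = gen, endReason = reason)
            if (trace) list(outcome = out, n1 = hist) else out
        }
        if (n1 == 0L) return(done(FALSE, 0L, "lost"))
        pf <- params@pFunc
        pp <- params@pPurge
        for (gen in seq_len(params@tMax)) {
            # selection + drift
            p1 <- n1 * w1 / (n1 * w1 + (N - n1))
            n1 <- stats::rbinom(1L, N, p1)
            if (trace) hist <- c(hist, n1)
            if (n1 == 0L) return(done(FALSE, gen, "lost"))
            # trinomial split: functionalize, purge, stay
            nFunc <- stats::rbinom(1L, n1, pf)
            if (nFunc >= 1L) return(done(TRUE, gen, "functionalized"))
            nPurge <- if (pf < 1) stats::rbinom(1L, n1, pp / (1 - pf)) else 0L
            n1 <- n1 - nPurge
            if (trace) hist[length(hist)] <- n1
            if (n1 == 0L) return(done(FALSE, gen, "lost"))
        }
        done(FALSE, params@tMax, "t_max")
    })
}

#' Sweep functionalization probability over a parameter grid
#'
#' Runs replicate simulations on a grid of functionalization and purge
#' rates and records the fraction of replicates in which the gene
#' functionalized before loss. Every (cell, replicate) gets its own
#' seed derived deterministically from the top-level seed, so serial
#' and parallel execution orders give identical results.
#'
#' @param base a \linkS4class{WFParams} providing N, cost, pInit, tMax.
#' @param pFuncValues grid of functionalization rates (default 20
#'   log-spaced points in [1e-16, 1e-2]).
#' @param pPurgeValues grid of purge rates (default 20 log-spaced
#'   points in [1e-8, 1e-2]).
#' @param replicates replicates per grid cell (default 100).
#' @param seed top-level seed (default 42).
#' @return A \linkS4class{SweepGrid} (rows = pFunc, columns = pPurge).
#' @export
sweepFunctionalization <- function(base = wfParams(),
        pFuncValues = logSpace(1e-16, 1e-2, 20L),
        pPurgeValues = logSpace(1e-8, 1e-2, 20L),
        replicates = 100L, seed = 42L) {
    stopifnot(is(base, "WFParams"))
    nf <- length(pFuncValues)
    np <- length(pPurgeValues)
    pm <- matrix(NA_real_, nf, np,
        dimnames = list(signif(pFuncValues, 3), signif(pPurgeValues, 3)))
    for (i in seq_len(nf)) for (j in seq_len(np)) {
        cell <- (i - 1L) * np + j
        hits <- 0L
        for (r in seq_len(replicates)) {
            p <- wfParams(N = base@N, cost = base@cost, pInit = base@pInit,
                pPurge = pPurgeValues[j], pFunc = pFuncValues[i],
                tMax = base@tMax, seed = deriveSeed(seed, cell, r))
            if (runWFReplicate(p)@functionalized) hits <- hits + 1L
        }
        pm[i, j] <- hits / replicates
    }
    new("SweepGrid", pFuncValues = pFuncValues, pPurgeValues = pPurgeValues,
        replicates = as.integer(replicates), probMatrix = pm, base = base)
}
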