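## Count-level pileup simulator for the feasibility framework.
##
## Generative procedure per site i:
##   * each haplotype carries a germline SNP with probability pi and its
##     somatic copy a mutation with probability mu (mutant base uniform over
##     the three non-current bases);
##   * depth d_i ~ Poisson(lambda), split d_i0 ~ Binom(d_i, 1/2);
##   * reads on a somatically mutated haplotype carry the mutant base with
##     probability alpha (tumour cell sampled), else the germline base;
##   * every drawn base is flipped to one of the three other bases uniformly
##     with probability epsilon.
##
## Sites are simulated in strata (pure reference / single germline SNP /
## single somatic mutation / rare compound sites) with vectorised binomial
## splits; the law per site is identical to the read-by-read procedure.
## Counts at reference and het sites do not depend on alpha, which
## puritySweep() exploits by re-drawing only somatic sites per purity point.

## split n (vector) uniformly into three bins
.split3 <- function(n) {
    k1 <- rbinom(length(n), n, 1 / 3)
    k2 <- rbinom(length(n), n - k1, 1 / 2)
    list(k1, k2, n - k1 - k2)
}

## germline part of the simulation: depths, site strata, and counts for the
## pure-reference and het strata. Somatic-site counts depend on alpha and are
## drawn separately (see .simSomatic). Caller manages the RNG seed.
.simBase <- function(params) {
    G <- as.integer(params@G)
    eps <- params@epsilon
    d <- rpois(G, params@lambda)
    d0 <- rbinom(G, d, 0.5)
    d1 <- d - d0

    drawPos <- function(rate) {
        n <- rbinom(1L, G, rate)
        if (n > 0L) sort(sample.int(G, n)) else integer(0)
    }
    het0 <- drawPos(params@pi); het1 <- drawPos(params@pi)
    som0 <- drawPos(params@mu); som1 <- drawPos(params@mu)

    flagged <- c(het0, het1, som0, som1)
    multi <- unique(flagged[duplicated(flagged)])
    hetB <- list(setdiff(het0, multi), setdiff(het1, multi))
    somC <- list(setdiff(som0, multi), setdiff(som1, multi))

    ## --- stratum A: pure reference sites ---------------------------------
    isVar <- logical(G)
    isVar[unique(flagged)] <- TRUE
    refPos <- which(!isVar)
    simRefHap <- function(dj) {
        e <- rbinom(length(dj), dj, eps)
        x <- .split3(e)
        list(r = dj - e, x1 = x[[1L]], x2 = x[[2L]], x3 = x[[3L]])
    }
    h0 <- simRefHap(d0[refPos]); h1 <- simRefHap(d1[refPos])
    refA <- list(
        a0 = pmax(h0$x1, h0$x2, h0$x3), r0 = h0$r,
        a1 = pmax(h1$x1, h1$x2, h1$x3), r1 = h1$r,
        a = pmax(h0$x1 + h1$x1, h0$x2 + h1$x2, h0$x3 + h1$x3),
        r = h0$r + h1$r, pos = refPos
    )

    ## --- stratum B: single germline SNP on one haplotype -----------------
    ## buckets: R (reference base), B (SNP base), O2/O3 (the other two)
    simHet <- function(pos, hap) {
        n <- length(pos)
        if (n == 0L)
            return(DataFrame(pos = integer(0), hap = integer(0),
                             a0 = integer(0), r0 = integer(0),
                             a1 = integer(0), r1 = integer(0),
                             a = integer(0), r = integer(0)))
        dh <- if (hap == 0L) d0[pos] else d1[pos]
        do <- if (hap == 0L) d1[pos] else d0[pos]
        e <- rbinom(n, dh, eps);  k <- .split3(e)    # SNP hap: err -> {R,O2,O3}
        ep <- rbinom(n, do, eps); kp <- .split3(ep)  # ref hap: err -> {B,O2,O3}
        bH <- dh - e; rH <- k[[1L]]
        aH <- pmax(bH, k[[2L]], k[[3L]])
        rO <- do - ep
        aO <- pmax(kp[[1L]], kp[[2L]], kp[[3L]])
        aU <- pmax(bH + kp[[1L]], k[[2L]] + kp[[2L]], k[[3L]] + kp[[3L]])
        rU <- rH + rO
        if (hap == 0L)
            DataFrame(pos = pos, hap = hap, a0 = aH, r0 = rH, a1 = aO,
                      r1 = rO, a = aU, r = rU)
        else
            DataFrame(pos = pos, hap = hap, a0 = aO, r0 = rO, a1 = aH,
                      r1 = rH, a = aU, r = rU)
    }
    hetRows <- rbind(simHet(hetB[[1L]], 0L), simHet(hetB[[2L]], 1L))

    list(G = G, params = params, d0 = d0, d1 = d1, refA = refA,
         hetRows = hetRows, somC = somC, multi = multi,
         het0 = het0, het1 = het1, som0 = som0, som1 = som1)
}

## somatic stratum (and rare compound sites), for a given purity.
## Caller manages the RNG seed.
.simSomatic <- function(base, alpha) {
    eps <- base$params@epsilon
    d0 <- base$d0; d1 <- base$d1
    ## buckets: R, S (somatic base), O2/O3
    simSom <- function(pos, hap) {
        n <- length(pos)
        if (n == 0L)
            return(DataFrame(pos = integer(0), hap = integer(0),
                             a0 = integer(0), r0 = integer(0),
                             a1 = integer(0), r1 = integer(0),
                             a = integer(0), r = integer(0)))
        dh <- if (hap == 0L) d0[pos] else d1[pos]
        do <- if (hap == 0L) d1[pos] else d0[pos]
        t <- rbinom(n, dh, alpha)                  # reads sampling tumour cells
        eS <- rbinom(n, t, eps);      kS <- .split3(eS)  # err from S -> {R,O2,O3}
        eR <- rbinom(n, dh - t, eps); kR <- .split3(eR)  # err from R -> {S,O2,O3}
        sH <- t - eS + kR[[1L]]
        rH <- dh - t - eR + kS[[1L]]
        o2H <- kS[[2L]] + kR[[2L]]; o3H <- kS[[3L]] + kR[[3L]]
        aH <- pmax(sH, o2H, o3H)
        ep <- rbinom(n, do, eps); kp <- .split3(ep)      # other hap errors
        rO <- do - ep
        aO <- pmax(kp[[1L]], kp[[2L]], kp[[3L]])
        aU <- pmax(sH + kp[[1L]], o2H + kp[[2L]], o3H + kp[[3L]])
        rU <- rH + rO
        if (hap == 0L)
            DataFrame(pos = pos, hap = hap, a0 = aH, r0 = rH, a1 = aO,
                      r1 = rO, a = aU, r = rU)
        else
            DataFrame(pos = pos, hap = hap, a0 = aO, r0 = rO, a1 = aH,
                      r1 = rH, a = aU, r = rU)
    }
    somRows <- rbind(simSom(base$somC[[1L]], 0L), simSom(base$somC[[2L]], 1L))

    ## compound sites (SNP+mutation or flags on both haplotypes): exact
    ## read-by-read simulation; these are O(G * pi * mu) and almost never occur
    xRows <- NULL
    if (length(base$multi)) {
        xRows <- do.call(rbind, lapply(base$multi, function(p) {
            .simSiteGeneral(p, d0[p], d1[p],
                            p %in% base$het0, p %in% base$het1,
                            p %in% base$som0, p %in% base$som1,
                            alpha, eps)
        }))
    }
    list(somRows = somRows, xRows = xRows)
}

## read-by-read simulation of one (rare) compound site; bases coded 1..4
## with 1 = reference
.simSiteGeneral <- function(pos, d0, d1, isHet0, isHet1, isSom0, isSom1,
                            alpha, eps) {
    germ <- c(1L, 1L)
    if (isHet0) germ[1L] <- sample(2:4, 1L)
    if (isHet1) germ[2L] <- sample(2:4, 1L)
    som <- germ
    if (isSom0) som[1L] <- sample(setdiff(1:4, germ[1L]), 1L)
    if (isSom1) som[2L] <- sample(setdiff(1:4, germ[2L]), 1L)
    counts <- matrix(0L, nrow = 2L, ncol = 4L)
    for (j in 1:2) {
        dj <- if (j == 1L) d0 else d1
        if (dj == 0L) next
        intended <- rep(germ[j], dj)
        if (som[j] != germ[j]) {
            tum <- runif(dj) < alpha
            intended[tum] <- som[j]
        }
        err <- runif(dj) < eps
        if (any(err))
            intended[err] <- vapply(intended[err], function(b)
                sample(setdiff(1:4, b), 1L), integer(1))
        counts[j, ] <- tabulate(intended, nbins = 4L)
    }
    somatic <- som[1L] != germ[1L] || som[2L] != germ[2L]
    het <- !somatic && germ[1L] != germ[2L]
    tot <- colSums(counts)
    DataFrame(pos = pos,
              label = if (somatic) "somatic" else if (het) "het" else "reference",
              a0 = max(counts[1L, 2:4]), r0 = counts[1L, 1L],
              a1 = max(counts[2L, 2:4]), r1 = counts[2L, 1L],
              a = max(tot[2:4]), r = tot[1L])
}

#' Simulate a pileup of allele counts over a diploid genome
#'
#' Draws, for every position of a simulated tumour/normal read mixture, the
#' number of reads supporting the reference base and the most frequent
#' non-reference base, in total and per haplotype, together with the true
#' site class. The generative model places heterozygous SNPs at rate
#' \code{pi} on each haplotype, somatic mutations at rate \code{mu} on each
#' somatic haplotype copy, draws depth from Poisson(\code{lambda}) split
#' Binomially across haplotypes, samples the mutant allele on a mutated
#' haplotype with probability \code{alpha}, and flips every base to one of
#' the three others with probability \code{epsilon}.
#'
#' @param params a \linkS4class{SimParams} object.
#' @param reference optional reference base string (a character string or
#'   \code{DNAString}) of length at least \code{G}; by default a uniform
#'   random base string is implied. Only base identities are affected; all
#'   counts are independent of sequence content.
#' @return A \code{DataFrame} with one row per genome position: \code{pos}
#'   (0-based), \code{label} (truth class: somatic/het/reference), total
#'   counts \code{a}, \code{r}, depth \code{d}, and per-haplotype counts
#'   \code{a0}, \code{r0}, \code{d0}, \code{a1}, \code{r1}, \code{d1}.
#'   Somatic sites carry the originating haplotype in \code{som_hap} (NA
#'   elsewhere). The seed and parameters are stored in \code{metadata()}.
#' @examples
#' sp <- simPileup(SimParams(G = 1e4, lambda = 30, seed = 7))
#' table(sp$label)
#' @export
simPileup <- function(params, reference = NULL) {
    stopifnot(is(params, "SimParams"))
    validObject(params)
    if (!is.null(reference) && nchar(as.character(reference)[1L]) < params@G)
        stop("'reference' shorter than G")
    runWithSeed(params@seed, {
        base <- .simBase(params)
        som <- .simSomatic(base, params@alpha)
    })
    G <- base$G
    lab <- rep.int(3L, G)      # 1 somatic, 2 het, 3 reference
    a0 <- r0 <- a1 <- r1 <- a <- r <- integer(G)
    fill <- function(rows) {
        p <- rows$pos
        a0[p] <<- rows$a0; r0[p] <<- rows$r0
        a1[p] <<- rows$a1; r1[p] <<- rows$r1
        a[p] <<- rows$a;   r[p] <<- rows$r
    }
    p <- base$refA$pos
    a0[p] <- base$refA$a0; r0[p] <- base$refA$r0
    a1[p] <- base$refA$a1; r1[p] <- base$refA$r1
    a[p] <- base$refA$a;   r[p] <- base$refA$r
    if (nrow(base$hetRows)) { fill(base$hetRows); lab[base$hetRows$pos] <- 2L }
    somHap <- rep.int(NA_integer_, G)
    if (nrow(som$somRows)) {
        fill(som$somRows); lab[som$somRows$pos] <- 1L
        somHap[som$somRows$pos] <- som$somRows$hap
    }
    if (!is.null(som$xRows) && nrow(som$xRows)) {
        fill(som$xRows)
        lab[som$xRows$pos] <- match(som$xRows$label, .CLASS_LEVELS)
    }
    out <- DataFrame(pos = seq_len(G) - 1L,
                     label = factor(.CLASS_LEVELS[lab], levels = .CLASS_LEVELS),
                     a = a, r = r, d = base$d0 + base$d1,
                     a0 = a0, r0 = r0, d0 = base$d0,
                     a1 = a1, r1 = r1, d1 = base$d1,
                     som_hap = somHap)
    metadata(out) <- list(params = params, seed = params@seed)
    out
}

## evaluate a seeded expression without disturbing the caller's RNG stream
runWithSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    eval.parent(substitute(expr))
}
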