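# Independent oracles used by the test suite. These deliberately avoid the
# package's computational paths: plain (non-log) arithmetic for the
# classifier posteriors, explicit path enumeration for the pair-HMM, and an
# explicit fine-grid sum for the CCF integral.

# three-class posterior by direct evaluation with exact binomial PMFs
oracleClassify <- function(a, r, alpha, eps, mu, pi, phased) {
    n <- a + r
    pmf <- function(p) choose(n, a) * p^a * (1 - p)^(n - a)
    if (phased) {
        ps <- (1 - eps) * alpha + eps * (1 - alpha); ph <- 1 - eps
    } else {
        ps <- (1 - eps) * alpha / 2 + eps * (1 - alpha / 2); ph <- 0.5
    }
    w <- c(somatic = pmf(ps) * mu, het = pmf(ph) * pi,
           reference = pmf(eps) * (1 - mu - pi))
    w / sum(w)
}

# pair-HMM forward probability by exhaustive path enumeration.
# States M/I/D, transitions M->I = M->D = go, M->M = 1 - 2*go,
# I->I = D->D = ge, I->M = D->M = 1 - ge; the path starts from a virtual
# deletion state carrying 1/L mass at every haplotype column (free left
# flank) and ends in a match state after consuming the read (free right
# flank).
# Match emission from capped base quality; insertions emit 1/4.
oraclePhmm <- function(read, qual, hap, go = 1e-3, ge = 1e-1,
                       maxQual = 40L) {
    rb <- strsplit(read, "")[[1L]]
    hb <- strsplit(hap, "")[[1L]]
    n <- length(rb); L <- length(hb)
    q <- pmin(qual, maxQual)
    pe <- 10^(-q / 10)
    em <- function(i, j) if (rb[i] == hb[j]) 1 - pe[i] else pe[i] / 3
    tMM <- 1 - 2 * go
    # recursive sum over continuations from state `st` at read pos i,
    # hap pos j (both already consumed by st)
    rec <- function(i, j, st) {
        if (i == n) {
            if (st == "M") return(1)
            return(0)   # paths end in a match state
        }
        tot <- 0
        trans <- switch(st,
            M = c(M = tMM, I = go, D = go),
            I = c(M = 1 - ge, I = ge),
            D = c(M = 1 - ge, D = ge))
        for (nx in names(trans)) {
            if (nx == "M" && j < L)
                tot <- tot + trans[[nx]] * em(i + 1, j + 1) * rec(i + 1, j + 1, "M")
            if (nx == "I")
                tot <- tot + trans[[nx]] * 0.25 * rec(i + 1, j, "I")
            if (nx == "D" && j < L)
                tot <- tot + trans[[nx]] * rec(i, j + 1, "D")
        }
        tot
    }
    tot <- 0
    for (j0 in 0:(L - 1))   # virtual start deletion before column j0 + 1
        tot <- tot + (1 / L) * (1 - ge) * em(1, j0 + 1) * rec(1, j0 + 1, "M")
    log(tot)
}

# somatic log-likelihood with the CCF integral evaluated on an explicit
# fine midpoint grid (plus the clonal point mass), per read
oracleSomaticLik <- function(logRef, logAlt, alpha, rho, a, b,
                             nBins = 1e5) {
    phi <- (seq_len(nBins) - 0.5) / nBins
    w <- (1 - rho) * dbeta(phi, a, b) / nBins
    sum(vapply(seq_along(logRef), function(k) {
        pR <- exp(logRef[k]); pA <- exp(logAlt[k])
        v <- sum(w * (pR * (1 - alpha * phi) + pA * alpha * phi)) +
            rho * (pR * (1 - alpha) + pA * alpha)
        log(v)
    }, numeric(1)))
}
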