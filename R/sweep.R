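## Purity/depth/error sweeps of the phased and unphased classifiers.

## linear index of (a, r) count pairs into a decision table with aMax rows
.countIndex <- function(a, r, aMax) a + 1L + (aMax + 1L) * r

#' Sweep classifier accuracy over depth, error rate and tumour purity
#'
#' For every (depth, error rate, purity) cell, simulates a genome of pileups
#' under the count-level model and scores somatic-site detection with both
#' the phased and the unphased classifier, using the maximum-posterior label
#' rule with classifier priors matched to the simulation. Sites with zero
#' total depth are uncallable and excluded.
#'
#' The simulation is stratified: read counts at reference and heterozygous
#' sites are independent of purity, so they are drawn once per
#' (depth, error rate) and only somatic sites and the classifier decision
#' tables are recomputed per purity point. Each unique (a, r) count pair is
#' classified once via a lookup table; this is exactly equivalent to
#' classifying every site.
#'
#' @param depths numeric vector of mean depths (lambda).
#' @param epsilons numeric vector of per-base error rates.
#' @param purities numeric vector of tumour purities in \[0,1\].
#' @param params a \linkS4class{SimParams} giving G, mu, pi and the base
#'   seed; its alpha/lambda/epsilon are overridden by the grid.
#' @param csv optional path; when given the result table is also written as
#'   CSV.
#' @return A \code{data.frame} with columns \code{depth}, \code{error_rate},
#'   \code{purity}, \code{mode} ("phased"/"unphased"), \code{precision},
#'   \code{recall}, \code{f1} and \code{n_truth_somatic}.
#' @examples
#' sw <- puritySweep(40, 0.01, c(0.3, 0.5), SimParams(G = 2e5, seed = 3))
#' subset(sw, mode == "phased")
#' @export
puritySweep <- function(depths, epsilons, purities,
                        params = SimParams(), csv = NULL) {
    stopifnot(all(purities >= 0 & purities <= 1))
    out <- vector("list", 0L)
    cell <- 0L
    for (lambda in depths) for (eps in epsilons) {
        cell <- cell + 1L
        p2 <- SimParams(G = params@G, lambda = lambda, alpha = 0.5,
                        epsilon = eps, mu = params@mu, pi = params@pi,
                        seed = params@seed)
        baseSeed <- (params@seed + 7919L * cell) %% .Machine$integer.max
        runWithSeed(baseSeed, base <- .simBase(p2))

        ## table size and precomputed lookup indices (purity-independent)
        dMax <- as.integer(max(base$d0 + base$d1))
        aMax <- dMax; rMax <- dMax
        refA <- base$refA
        liRef0 <- .countIndex(refA$a0, refA$r0, aMax)
        liRef1 <- .countIndex(refA$a1, refA$r1, aMax)
        liRefU <- .countIndex(refA$a, refA$r, aMax)
        het <- base$hetRows
        liHet0 <- .countIndex(het$a0, het$r0, aMax)
        liHet1 <- .countIndex(het$a1, het$r1, aMax)
        liHetU <- .countIndex(het$a, het$r, aMax)

        for (k in seq_along(purities)) {
            alpha <- purities[k]
            runWithSeed(baseSeed + k, som <- .simSomatic(base, alpha))
            dtP <- .decisionTable(aMax, rMax, TRUE, alpha, eps,
                                  p2@mu, p2@pi)
            dtU <- .decisionTable(aMax, rMax, FALSE, alpha, eps,
                                  p2@mu, p2@pi)
            sr <- som$somRows
            dSom <- base$d0[sr$pos] + base$d1[sr$pos]
            predP <- dtP[.countIndex(sr$a0, sr$r0, aMax)] == 1L |
                dtP[.countIndex(sr$a1, sr$r1, aMax)] == 1L
            predU <- dtU[.countIndex(sr$a, sr$r, aMax)] == 1L
            tpP <- sum(predP & dSom > 0L); tpU <- sum(predU & dSom > 0L)
            nSom <- sum(dSom > 0L)
            fpP <- sum(dtP[liRef0] == 1L | dtP[liRef1] == 1L) +
                sum(dtP[liHet0] == 1L | dtP[liHet1] == 1L)
            fpU <- sum(dtU[liRefU] == 1L) + sum(dtU[liHetU] == 1L)
            ## rare compound sites, classified directly
            if (!is.null(som$xRows) && nrow(som$xRows)) {
                x <- som$xRows
                xa <- dtP[.countIndex(x$a0, x$r0, aMax)] == 1L |
                    dtP[.countIndex(x$a1, x$r1, aMax)] == 1L
                xu <- dtU[.countIndex(x$a, x$r, aMax)] == 1L
                xsom <- x$label == "somatic" & (x$a + x$r) > 0L
                nSom <- nSom + sum(xsom)
                tpP <- tpP + sum(xa & xsom); fpP <- fpP + sum(xa & !xsom)
                tpU <- tpU + sum(xu & xsom); fpU <- fpU + sum(xu & !xsom)
            }
            resP <- .prf(tpP, fpP, nSom - tpP)
            resU <- .prf(tpU, fpU, nSom - tpU)
            out[[length(out) + 1L]] <- data.frame(
                depth = lambda, error_rate = eps, purity = alpha,
                mode = c("phased", "unphased"),
                precision = c(resP$precision, resU$precision),
                recall = c(resP$recall, resU$recall),
                f1 = c(resP$f1, resU$f1),
                n_truth_somatic = nSom)
        }
    }
    res <- do.call(rbind, out)
    if (!is.null(csv)) utils::write.csv(res, csv, row.names = FALSE)
    res
}

#' Purity interval where F1 exceeds a threshold
#'
#' @param sweep a sweep table from \code{\link{puritySweep}}.
#' @param mode "phased" or "unphased".
#' @param threshold F1 threshold (default 0.9).
#' @return Named numeric vector \code{c(lower, upper)}: the smallest and
#'   largest swept purity with F1 strictly above the threshold (NA if none).
#' @examples
#' sw <- puritySweep(80, 0.01, c(0.4, 0.5, 0.6), SimParams(G = 2e5, seed = 3))
#' f1Interval(sw, "phased")
#' @export
f1Interval <- function(sweep, mode = c("phased", "unphased"),
                       threshold = 0.9) {
    mode <- match.arg(mode)
    s <- sweep[sweep$mode == mode & sweep$f1 > threshold, , drop = FALSE]
    if (!nrow(s)) return(c(lower = NA_real_, upper = NA_real_))
    c(lower = min(s$purity), upper = max(s$purity))
}
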