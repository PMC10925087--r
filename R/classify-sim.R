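## Closed-form three-class pileup classifiers for the feasibility model.
## Both classifiers compare binomial likelihoods for the somatic, heterozygous
## and reference states of a site given alternate/reference read counts, in
## log space, with priors (mu, pi, 1 - mu - pi).

.CLASS_LEVELS <- c("somatic", "het", "reference")

## log-space three-class posterior given per-class binomial success
## probabilities; a, r vectors, p a 3-column matrix (recycled rows allowed).
.posterior3 <- function(a, r, pSom, pHet, pRef, mu, pi) {
    n <- a + r
    ll <- cbind(
        dbinom(a, n, pSom, log = TRUE) + log(mu),
        dbinom(a, n, pHet, log = TRUE) + log(pi),
        dbinom(a, n, pRef, log = TRUE) + log1p(-mu - pi)
    )
    m <- pmax(ll[, 1L], ll[, 2L], ll[, 3L])
    w <- exp(ll - m)
    w / rowSums(w)
}

.posteriorFrame <- function(post) {
    lab <- .CLASS_LEVELS[max.col(post, ties.method = "first")]
    ## ties between somatic and het resolve to somatic (column order above)
    DataFrame(p_somatic = post[, 1L], p_het = post[, 2L],
              p_reference = post[, 3L],
              label = factor(lab, levels = .CLASS_LEVELS))
}

.checkClassifyArgs <- function(a, r, alpha, epsilon, mu, pi) {
    if (any(a < 0) || any(r < 0) || any((a + r) < 1))
        stop("undefined site: need a >= 0, r >= 0 and a + r >= 1")
    for (m in list(.checkProb(alpha, "alpha"),
                   .checkProb(epsilon, "epsilon", open1 = TRUE),
                   .checkProb(mu, "mu"), .checkProb(pi, "pi")))
        if (!is.null(m)) stop(m)
    if (mu + pi >= 1) stop("'mu' + 'pi' must be < 1")
}

#' Classify a pileup site from unphased read counts
#'
#' Posterior probability that a site is a somatic mutation, a heterozygous
#' SNP, or reference, given \code{a} reads supporting the most frequent
#' non-reference base and \code{r} reads supporting the reference base.
#' The three states use binomial observation models with success
#' probabilities \eqn{(1-\epsilon)\alpha/2 + \epsilon(1-\alpha/2)} (somatic),
#' \eqn{1/2} (het) and \eqn{\epsilon} (reference), and priors
#' \eqn{(\mu, \pi, 1-\mu-\pi)}.
#'
#' @param a,r integer vectors of alternate- and reference-supporting read
#'   counts; \code{a + r} must be at least 1 at every site.
#' @param alpha tumour purity.
#' @param epsilon per-base sequencing error rate.
#' @param mu somatic prior (mutation rate per base).
#' @param pi heterozygous SNP prior (SNP rate per base).
#' @return A \code{DataFrame} with columns \code{p_somatic}, \code{p_het},
#'   \code{p_reference} (rows sum to 1) and \code{label}, the
#'   maximum-posterior class (somatic wins ties against het).
#' @examples
#' classifyUnphased(12, 17, alpha = 0.5, epsilon = 0.01)
#' @seealso \code{\link{classifyPhased}} for per-haplotype counts.
#' @export
classifyUnphased <- function(a, r, alpha, epsilon, mu = 5e-6, pi = 1e-3) {
    .checkClassifyArgs(a, r, alpha, epsilon, mu, pi)
    pSom <- (1 - epsilon) * alpha / 2 + epsilon * (1 - alpha / 2)
    .posteriorFrame(.posterior3(a, r, pSom, 0.5, epsilon, mu, pi))
}

#' Classify a haplotype-resolved pileup from per-haplotype read counts
#'
#' Same three-state model as \code{\link{classifyUnphased}}, but for counts
#' restricted to a single haplotype, where the factor of 2 from not knowing
#' the read's haplotype disappears: success probabilities are
#' \eqn{(1-\epsilon)\alpha + \epsilon(1-\alpha)} (somatic mutation on this
#' haplotype, mutant allele present in the tumour cells only),
#' \eqn{1-\epsilon} (het: every read on this haplotype carries the alternate
#' allele) and \eqn{\epsilon} (reference).
#'
#' @inheritParams classifyUnphased
#' @param a,r per-haplotype alternate and reference read counts.
#' @return A \code{DataFrame} as for \code{\link{classifyUnphased}}.
#' @examples
#' ## 11 alt / 5 ref on one haplotype at 50% purity: somatic
#' classifyPhased(11, 5, alpha = 0.5, epsilon = 0.01)
#' @export
classifyPhased <- function(a, r, alpha, epsilon, mu = 5e-6, pi = 1e-3) {
    .checkClassifyArgs(a, r, alpha, epsilon, mu, pi)
    pSom <- (1 - epsilon) * alpha + epsilon * (1 - alpha)
    .posteriorFrame(.posterior3(a, r, pSom, 1 - epsilon, epsilon, mu, pi))
}

## Decision lookup tables: class label for every (a, r) with a <= aMax,
## r <= rMax. Used by the sweep so each unique count pair is classified once.
## Returns an (aMax+1) x (rMax+1) integer matrix of class codes 1/2/3
## (somatic/het/reference); the [1,1] cell (a=r=0) is code 3 by convention
## (no reads, never somatic).
.decisionTable <- function(aMax, rMax, phased, alpha, epsilon, mu, pi) {
    grid <- expand.grid(a = 0:aMax, r = 0:rMax)
    keep <- grid$a + grid$r >= 1L
    fn <- if (phased) classifyPhased else classifyUnphased
    lab <- fn(grid$a[keep], grid$r[keep], alpha, epsilon, mu, pi)$label
    out <- matrix(3L, nrow = aMax + 1L, ncol = rMax + 1L)
    out[cbind(grid$a[keep] + 1L, grid$r[keep] + 1L)] <- as.integer(lab)
    out
}
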