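#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom stats dbinom dbeta rbinom rpois runif rbeta fisher.test setNames
#' @importClassesFrom GenomicRanges GRanges
#' @useDynLib hapsomatic, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.checkProb <- function(x, name, open0 = FALSE, open1 = FALSE) {
    if (length(x) != 1L || is.na(x)) return(sprintf("'%s' must be a single number", name))
    lo <- if (open0) x > 0 else x >= 0
    hi <- if (open1) x < 1 else x <= 1
    if (!lo || !hi) return(sprintf("'%s' out of range", name))
    NULL
}

#' Simulation parameters for the pileup feasibility model
#'
#' Bundles the generative parameters of the count-level tumour sequencing
#' simulation: genome length, mean depth, tumour purity, per-base sequencing
#' error rate, somatic mutation rate and heterozygous SNP rate, plus the RNG
#' seed.
#'
#' @slot G integer, genome length in bases.
#' @slot lambda numeric, mean sequencing depth (reads per site, Poisson mean).
#' @slot alpha numeric in \[0,1\], tumour purity (fraction of cells that are
#'   cancerous).
#' @slot epsilon numeric in \[0,1), per-base sequencing error rate.
#' @slot mu numeric, somatic mutation rate per base per haplotype copy.
#' @slot pi numeric, heterozygous SNP rate per base per haplotype (default
#'   1/1000).
#' @slot seed integer RNG seed.
#'
#' @export
setClass("SimParams", representation(
    G = "numeric", lambda = "numeric", alpha = "numeric", epsilon = "numeric",
    mu = "numeric", pi = "numeric", seed = "integer"
))

setValidity("SimParams", function(object) {
    msgs <- c(
        .checkProb(object@alpha, "alpha"),
        .checkProb(object@epsilon, "epsilon", open1 = TRUE),
        .checkProb(object@mu, "mu"),
        .checkProb(object@pi, "pi")
    )
    if (length(object@G) != 1L || is.na(object@G) || object@G < 1)
        msgs <- c(msgs, "'G' must be >= 1")
    if (length(object@lambda) != 1L || is.na(object@lambda) || object@lambda <= 0)
        msgs <- c(msgs, "'lambda' must be > 0")
    if (is.null(msgs) || length(msgs) == 0L) {
        if (object@mu + object@pi >= 1) msgs <- "'mu' + 'pi' must be < 1"
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct simulation parameters
#'
#' @param G genome length in bases.
#' @param lambda mean sequencing depth.
#' @param alpha tumour purity in \[0,1\].
#' @param epsilon per-base sequencing error rate in \[0,1).
#' @param mu somatic mutation rate per base per haplotype copy.
#' @param pi heterozygous SNP rate per base per haplotype.
#' @param seed integer RNG seed.
#' @return A \linkS4class{SimParams} object.
#' @examples
#' SimParams(G = 1e5, lambda = 80, alpha = 0.5)
#' @export
SimParams <- function(G = 1e6, lambda = 80, alpha = 0.5, epsilon = 0.01,
                      mu = 5e-6, pi = 1e-3, seed = 1L) {
    new("SimParams", G = as.numeric(G), lambda = as.numeric(lambda),
        alpha = as.numeric(alpha), epsilon = as.numeric(epsilon),
        mu = as.numeric(mu), pi = as.numeric(pi), seed = as.integer(seed))
}

setMethod("show", "SimParams", function(object) {
    cat("SimParams: G=", object@G, " lambda=", object@lambda,
        " alpha=", object@alpha, " epsilon=", object@epsilon,
        " mu=", object@mu, " pi=", object@pi, " seed=", object@seed, "\n", sep = "")
})

#' Pair-HMM parameters for read-haplotype realignment
#'
#' @slot gapOpen probability of opening an insertion or deletion.
#' @slot gapExtend probability of extending an open gap.
#' @slot band integer band half-width for the banded forward pass.
#' @slot maxQual base-quality cap applied before computing emission
#'   probabilities (guards against overconfident emissions).
#'
#' @export
setClass("HmmParams", representation(
    gapOpen = "numeric", gapExtend = "numeric", band = "integer",
    maxQual = "integer"
))

setValidity("HmmParams", function(object) {
    msgs <- c(
        .checkProb(object@gapOpen, "gapOpen", open0 = TRUE, open1 = TRUE),
        .checkProb(object@gapExtend, "gapExtend", open0 = TRUE, open1 = TRUE)
    )
    if (object@band < 1L) msgs <- c(msgs, "'band' must be >= 1")
    if (object@maxQual < 1L) msgs <- c(msgs, "'maxQual' must be >= 1")
    if (length(msgs)) msgs else TRUE
})

#' Construct pair-HMM parameters
#'
#' @param gapOpen gap open probability.
#' @param gapExtend gap extension probability.
#' @param band band half-width (columns either side of the diagonal).
#' @param maxQual base-quality cap.
#' @return An \linkS4class{HmmParams} object.
#' @examples
#' HmmParams()
#' @export
HmmParams <- function(gapOpen = 1e-3, gapExtend = 1e-1, band = 20L,
                      maxQual = 40L) {
    new("HmmParams", gapOpen = gapOpen, gapExtend = gapExtend,
        band = as.integer(band), maxQual = as.integer(maxQual))
}

#' Genotyper configuration
#'
#' Settings for genotyping known population SNP sites under possibly
#' unbalanced copy number. \code{f} is the probability that a read is drawn
#' from the haplotype with the higher copy number; 0.5 recovers the standard
#' balanced diploid genotyper.
#'
#' @slot f probability of drawing a read from the higher-copy haplotype.
#' @slot priorVariant prior probability a site is a variant.
#' @slot priorHetGivenVariant prior probability a variant site is heterozygous.
#' @slot strandBiasP Fisher strand-bias p-value below which a site is left
#'   uncalled.
#' @slot minDepth minimum number of informative reads for a call.
#' @slot mapqMin minimum mapping quality for reads used in genotyping.
#'
#' @export
setClass("GenotyperConfig", representation(
    f = "numeric", priorVariant = "numeric", priorHetGivenVariant = "numeric",
    strandBiasP = "numeric", minDepth = "integer", mapqMin = "integer"
))

setValidity("GenotyperConfig", function(object) {
    msgs <- c(
        .checkProb(object@f, "f", open0 = TRUE, open1 = TRUE),
        .checkProb(object@priorVariant, "priorVariant", open0 = TRUE, open1 = TRUE),
        .checkProb(object@priorHetGivenVariant, "priorHetGivenVariant",
                   open0 = TRUE, open1 = TRUE),
        .checkProb(object@strandBiasP, "strandBiasP", open0 = TRUE, open1 = TRUE)
    )
    if (object@minDepth < 1L) msgs <- c(msgs, "'minDepth' must be >= 1")
    if (length(msgs)) msgs else TRUE
})

#' Construct a genotyper configuration
#'
#' @param f major-haplotype read draw probability (0.25 by default, which
#'   keeps sensitivity at loss-of-heterozygosity sites where one haplotype is
#'   underrepresented).
#' @param priorVariant site-is-variant prior.
#' @param priorHetGivenVariant heterozygous-given-variant prior.
#' @param strandBiasP strand-bias skip threshold (Fisher p-value).
#' @param minDepth minimum informative reads.
#' @param mapqMin minimum mapping quality.
#' @return A \linkS4class{GenotyperConfig} object.
#' @examples
#' GenotyperConfig(f = 0.25)
#' @export
GenotyperConfig <- function(f = 0.25, priorVariant = 1e-3,
                            priorHetGivenVariant = 2 / 3,
                            strandBiasP = 1e-4, minDepth = 8L,
                            mapqMin = 20L) {
    new("GenotyperConfig", f = f, priorVariant = priorVariant,
        priorHetGivenVariant = priorHetGivenVariant,
        strandBiasP = strandBiasP, minDepth = as.integer(minDepth),
        mapqMin = as.integer(mapqMin))
}

#' Cancer cell fraction prior
#'
#' Mixture prior over the cancer cell fraction phi of a somatic mutation: a
#' point mass \code{rho} at phi = 1 (clonal mutations) and the remaining mass
#' on a Beta(\code{a}, \code{b}) distribution over (0, 1) for subclonal
#' mutations.
#'
#' @slot rho clonal mass in \[0,1\].
#' @slot a,b Beta shape parameters (> 0).
#' @slot nBins number of equal-width midpoint bins used to integrate the Beta
#'   component.
#'
#' @export
setClass("CCFPrior", representation(
    rho = "numeric", a = "numeric", b = "numeric", nBins = "integer"
))

setValidity("CCFPrior", function(object) {
    msgs <- .checkProb(object@rho, "rho")
    if (object@a <= 0 || object@b <= 0) msgs <- c(msgs, "'a' and 'b' must be > 0")
    if (object@nBins < 10L) msgs <- c(msgs, "'nBins' must be >= 10")
    if (length(msgs)) msgs else TRUE
})

#' Construct a cancer cell fraction prior
#'
#' @param rho clonal mass.
#' @param a,b Beta shape parameters for the subclonal component.
#' @param nBins integration grid size.
#' @return A \linkS4class{CCFPrior} object.
#' @examples
#' CCFPrior(rho = 0.95, a = 2, b = 2)
#' @export
CCFPrior <- function(rho = 0.95, a = 2, b = 2, nBins = 100L) {
    new("CCFPrior", rho = rho, a = a, b = b, nBins = as.integer(nBins))
}

#' Somatic caller configuration
#'
#' @slot alpha tumour purity used by the classifier; must satisfy
#'   0 < alpha < 1 (classification relies on contaminating normal cells, so a
#'   purely tumour sample is uninformative).
#' @slot minHapDepth minimum assigned depth per haplotype for a position to be
#'   callable (10).
#' @slot maxTotalDepth maximum summed haplotype depth for callability (400).
#' @slot candMinFraction candidate discovery: modal non-reference base must
#'   exceed this fraction of the haplotype's reads (0.10).
#' @slot candMinObs candidate discovery: minimum observations of the modal
#'   non-reference base (3).
#' @slot qualThreshold PHRED QUAL below which the LowQual filter fires (20).
#' @slot muPrior,piPrior class priors for somatic and heterozygous states.
#' @slot ccf a \linkS4class{CCFPrior}.
#' @slot maxOtherHapObs,maxOtherHapFrac MaxOtherHaplotypeObservations filter
#'   thresholds (more than 2 reads, or more than 20 percent).
#' @slot strandBiasP StrandBias filter Fisher p-value threshold.
#' @slot artifactMismatchRate,artifactReadFrac PossibleAlignmentArtifact
#'   thresholds: filter when more than \code{artifactReadFrac} of
#'   alt-supporting reads have window mismatch rate above
#'   \code{artifactMismatchRate}.
#' @slot qualCap cap applied to the PHRED QUAL.
#' @slot flank realignment window half-width in bp.
#' @slot hmm an \linkS4class{HmmParams}.
#' @slot mapqMin minimum mapping quality for reads used by the caller.
#'
#' @export
setClass("CallerConfig", representation(
    alpha = "numeric", minHapDepth = "integer", maxTotalDepth = "integer",
    candMinFraction = "numeric", candMinObs = "integer",
    qualThreshold = "numeric", muPrior = "numeric", piPrior = "numeric",
    ccf = "CCFPrior", maxOtherHapObs = "integer", maxOtherHapFrac = "numeric",
    strandBiasP = "numeric", artifactMismatchRate = "numeric",
    artifactReadFrac = "numeric", qualCap = "numeric", flank = "integer",
    hmm = "HmmParams", mapqMin = "integer"
))

setValidity("CallerConfig", function(object) {
    msgs <- NULL
    if (!(object@alpha > 0 && object@alpha < 1))
        msgs <- c(msgs, "'alpha' must satisfy 0 < alpha < 1")
    if (object@minHapDepth < 1L || object@maxTotalDepth < object@minHapDepth)
        msgs <- c(msgs, "depth bounds must be positive and consistent")
    if (object@muPrior + object@piPrior >= 1)
        msgs <- c(msgs, "class priors must leave mass for the reference state")
    if (length(msgs)) msgs else TRUE
})

#' Construct a somatic caller configuration
#'
#' @param alpha tumour purity (default 0.5).
#' @param minHapDepth,maxTotalDepth callability depth bounds.
#' @param candMinFraction,candMinObs candidate discovery thresholds.
#' @param qualThreshold LowQual threshold.
#' @param muPrior,piPrior class priors for the somatic and heterozygous
#'   states; the reference state receives the remaining mass.
#' @param ccf cancer cell fraction prior.
#' @param maxOtherHapObs,maxOtherHapFrac other-haplotype control thresholds.
#' @param strandBiasP strand bias Fisher p-value threshold.
#' @param artifactMismatchRate,artifactReadFrac alignment-artifact thresholds.
#' @param qualCap QUAL cap.
#' @param flank realignment window half-width.
#' @param hmm pair-HMM parameters.
#' @param mapqMin minimum mapping quality.
#' @return A \linkS4class{CallerConfig} object.
#' @examples
#' CallerConfig(alpha = 0.5)
#' @export
CallerConfig <- function(alpha = 0.5, minHapDepth = 10L, maxTotalDepth = 400L,
                         candMinFraction = 0.10, candMinObs = 3L,
                         qualThreshold = 20, muPrior = 1e-5, piPrior = 1e-3,
                         ccf = CCFPrior(), maxOtherHapObs = 2L,
                         maxOtherHapFrac = 0.20, strandBiasP = 1e-3,
                         artifactMismatchRate = 0.15, artifactReadFrac = 0.5,
                         qualCap = 60, flank = 20L, hmm = HmmParams(),
                         mapqMin = 20L) {
    new("CallerConfig", alpha = alpha, minHapDepth = as.integer(minHapDepth),
        maxTotalDepth = as.integer(maxTotalDepth),
        candMinFraction = candMinFraction, candMinObs = as.integer(candMinObs),
        qualThreshold = qualThreshold, muPrior = muPrior, piPrior = piPrior,
        ccf = ccf, maxOtherHapObs = as.integer(maxOtherHapObs),
        maxOtherHapFrac = maxOtherHapFrac, strandBiasP = strandBiasP,
        artifactMismatchRate = artifactMismatchRate,
        artifactReadFrac = artifactReadFrac, qualCap = qualCap,
        flank = as.integer(flank), hmm = hmm, mapqMin = as.integer(mapqMin))
}

setMethod("show", "CallerConfig", function(object) {
    cat("CallerConfig: alpha=", object@alpha,
        " hap depth [", object@minHapDepth, ",", object@maxTotalDepth, "]",
        " candidates >", object@candMinFraction * 100, "% & >=", object@candMinObs,
        " QUAL>=", object@qualThreshold, "\n", sep = "")
})

#' Specification of a synthetic diploid sequencing fixture
#'
#' Describes a fully synthetic tumour-only sequencing experiment over one
#' diploid region: heterozygous SNPs at rate \code{pi}, somatic mutations at
#' rate \code{mu} on a single haplotype with cancer cell fractions drawn from
#' a clonal/Beta mixture, and long reads sampled at a target depth from a
#' tumour/normal cell mixture of purity \code{alpha}.
#'
#' @slot regionLength region length in bases.
#' @slot pi heterozygous SNP rate per base.
#' @slot mu somatic mutation rate per base (per haplotype copy).
#' @slot nSomatic optional exact number of somatic mutations to place
#'   (overrides \code{mu} when non-NA).
#' @slot ccf clonal/subclonal CCF mixture for placed mutations.
#' @slot alpha tumour purity of the read mixture.
#' @slot depth target mean sequencing depth of the merged sample.
#' @slot readLength mean read length in bases.
#' @slot epsilon per-base sequencing error rate.
#' @slot hap0Fraction probability a read samples haplotype 0 (0.5 for a
#'   copy-number balanced region; values far from 0.5 emulate allelic
#'   imbalance up to loss of heterozygosity).
#' @slot seed RNG seed.
#'
#' @export
setClass("FixtureSpec", representation(
    regionLength = "numeric", pi = "numeric", mu = "numeric",
    nSomatic = "numeric", ccf = "CCFPrior", alpha = "numeric",
    depth = "numeric", readLength = "numeric", epsilon = "numeric",
    hap0Fraction = "numeric", seed = "integer"
))

setValidity("FixtureSpec", function(object) {
    msgs <- c(
        .checkProb(object@alpha, "alpha"),
        .checkProb(object@epsilon, "epsilon", open1 = TRUE),
        .checkProb(object@mu, "mu"), .checkProb(object@pi, "pi"),
        .checkProb(object@hap0Fraction, "hap0Fraction",
                   open0 = TRUE, open1 = TRUE)
    )
    if (object@depth <= 0) msgs <- c(msgs, "'depth' must be > 0")
    if (object@readLength < 100) msgs <- c(msgs, "'readLength' must be >= 100")
    if (object@regionLength < 1000) msgs <- c(msgs, "'regionLength' must be >= 1000")
    if (length(msgs)) msgs else TRUE
})

#' Construct a fixture specification
#'
#' @param regionLength region length in bases.
#' @param pi heterozygous SNP rate.
#' @param mu somatic mutation rate per haplotype copy.
#' @param nSomatic exact somatic mutation count (NA to use \code{mu}).
#' @param ccf CCF mixture prior used to draw per-mutation cancer cell
#'   fractions.
#' @param alpha tumour purity.
#' @param depth target merged depth.
#' @param readLength mean read length.
#' @param epsilon per-base error rate.
#' @param hap0Fraction probability a read samples haplotype 0.
#' @param seed RNG seed.
#' @return A \linkS4class{FixtureSpec} object.
#' @examples
#' FixtureSpec(regionLength = 5e4, depth = 40)
#' @export
FixtureSpec <- function(regionLength = 1e6, pi = 1e-3, mu = 5e-5,
                        nSomatic = NA_real_, ccf = CCFPrior(rho = 1),
                        alpha = 0.5, depth = 80, readLength = 20000,
                        epsilon = 0.005, hap0Fraction = 0.5, seed = 1L) {
    new("FixtureSpec", regionLength = as.numeric(regionLength), pi = pi,
        mu = mu, nSomatic = as.numeric(nSomatic), ccf = ccf, alpha = alpha,
        depth = as.numeric(depth), readLength = as.numeric(readLength),
        epsilon = epsilon, hap0Fraction = hap0Fraction,
        seed = as.integer(seed))
}

setMethod("show", "FixtureSpec", function(object) {
    cat("FixtureSpec: ", object@regionLength, " bp, depth ", object@depth,
        "x, purity ", object@alpha, ", eps ", object@epsilon,
        ", read length ", object@readLength, "\n", sep = "")
})
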