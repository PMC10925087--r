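## Tumour-only somatic mutation calling over haplotagged long reads:
## callable-region detection, permissive candidate discovery, per-haplotype
## Bayesian classification with a clonal/subclonal cancer-cell-fraction
## prior, and hard filtering.

#' Container for somatic calls from one calling window
#'
#' @slot calls width-1 \code{GRanges} of candidate somatic mutations with
#'   metadata columns \code{ref}, \code{alt}, \code{hap}, \code{qual},
#'   \code{filter}, class posteriors and count annotations.
#' @slot callable \code{GRanges} of positions where calling was performed
#'   (both haplotypes adequately covered).
#' @slot config the \linkS4class{CallerConfig} used.
#'
#' @export
setClass("SomaticCalls", representation(
    calls = "GRanges", callable = "GRanges", config = "CallerConfig"
))

#' @describeIn SomaticCalls-class the call table as a \code{GRanges}
#' @param x a \code{SomaticCalls} object.
#' @export
calls <- function(x) { stopifnot(is(x, "SomaticCalls")); x@calls }

#' @describeIn SomaticCalls-class callable positions as a \code{GRanges}
#' @export
callableRegions <- function(x) { stopifnot(is(x, "SomaticCalls")); x@callable }

setMethod("show", "SomaticCalls", function(object) {
    np <- sum(object@calls$filter == "PASS")
    cat("SomaticCalls: ", length(object@calls), " candidate calls (",
        np, " PASS), ", sum(GenomicRanges::width(object@callable)),
        " callable bases\n", sep = "")
})

#' Callable positions from per-haplotype depth
#'
#' A position is callable when both haplotypes have at least
#' \code{config@minHapDepth} assigned reads and the summed haplotype depth
#' does not exceed \code{config@maxTotalDepth}.
#'
#' @param d0,d1 integer vectors of per-position assigned read depth for
#'   haplotype 0 and 1 over a contiguous window.
#' @param config a \linkS4class{CallerConfig}.
#' @param seqname contig name for the returned ranges.
#' @param offset 1-based position of the first element of \code{d0}.
#' @return A list: \code{mask} (logical per position) and \code{regions}
#'   (merged \code{GRanges} of callable runs, BED-ready).
#' @examples
#' findCallable(c(12, 9, 250), c(11, 100, 200), CallerConfig())$mask
#' @export
findCallable <- function(d0, d1, config = CallerConfig(),
                         seqname = "region", offset = 1L) {
    stopifnot(length(d0) == length(d1))
    mask <- d0 >= config@minHapDepth & d1 >= config@minHapDepth &
        (d0 + d1) <= config@maxTotalDepth
    r <- IRanges::reduce(IRanges::IRanges(which(mask) + offset - 1L, width = 1L))
    list(mask = mask,
         regions = GenomicRanges::GRanges(rep(seqname, length(r)), r))
}

#' Discover candidate variant positions from per-haplotype pileups
#'
#' On each haplotype, the most frequently observed non-reference base at a
#' callable position becomes a candidate when it is seen in more than
#' \code{config@candMinFraction} of the haplotype's reads and at least
#' \code{config@candMinObs} times. This stage is deliberately permissive;
#' classification and filtering do the discrimination.
#'
#' @param counts0,counts1 4 x L integer matrices of base counts (rows A, C,
#'   G, T) for haplotype 0 and 1, e.g. from assigned-read pileups.
#' @param refBases character vector (length L) of reference bases.
#' @param mask logical vector of callable positions (length L).
#' @param config a \linkS4class{CallerConfig}.
#' @param seqname,offset coordinates of the window.
#' @return A \code{DataFrame} with one row per candidate: \code{pos}
#'   (1-based), \code{hap}, \code{ref}, \code{alt}, \code{altObs},
#'   \code{hapDepth}. Ties between non-reference bases break by base order
#'   A, C, G, T.
#' @export
discoverCandidates <- function(counts0, counts1, refBases, mask,
                               config = CallerConfig(),
                               seqname = "region", offset = 1L) {
    L <- length(refBases)
    stopifnot(ncol(counts0) == L, ncol(counts1) == L, length(mask) == L)
    bases <- c("A", "C", "G", "T")
    refIdx <- match(refBases, bases)
    onehap <- function(counts, hap) {
        depth <- colSums(counts)
        masked <- counts
        masked[cbind(refIdx, seq_len(L))] <- -1L
        altObs <- pmax(masked[1L, ], masked[2L, ], masked[3L, ], masked[4L, ])
        altIdx <- ifelse(masked[1L, ] == altObs, 1L,
                  ifelse(masked[2L, ] == altObs, 2L,
                  ifelse(masked[3L, ] == altObs, 3L, 4L)))
        hit <- mask & altObs >= config@candMinObs &
            altObs > config@candMinFraction * depth
        w <- which(hit)
        DataFrame(pos = w + offset - 1L, hap = rep(hap, length(w)),
                  ref = refBases[w], alt = bases[altIdx[w]],
                  altObs = altObs[w], hapDepth = depth[w])
    }
    out <- rbind(onehap(counts0, 0L), onehap(counts1, 1L))
    metadata(out) <- list(seqname = seqname)
    out[order(out$pos, out$hap), ]
}

#' Classify a candidate site from its haplotype's read-allele likelihoods
#'
#' Three-state classification of a candidate on one haplotype. The
#' reference state expects every read to match the reference allele, the
#' het state expects every read to match the alternate allele, and the
#' somatic state models each read as a mixture: with probability
#' \eqn{\alpha\phi} it samples a mutated tumour cell and carries the
#' alternate allele. The unknown cancer cell fraction \eqn{\phi} is
#' integrated out per read under the clonal/Beta mixture prior, the clonal
#' point mass at \eqn{\phi = 1} analytically and the Beta component by a
#' midpoint rule on \code{config@ccf@nBins} equal-width bins (the binned
#' sum collapses to the bin-weighted first moment because the integrand is
#' linear in \eqn{\phi}).
#'
#' @param logRef,logAlt per-read log allele likelihoods for reads assigned
#'   to the candidate's haplotype.
#' @param config a \linkS4class{CallerConfig} (purity, CCF prior, class
#'   priors, QUAL cap).
#' @return A list: \code{posterior} (named: somatic, het, reference),
#'   \code{qual} (PHRED-scaled confidence that the site is somatic, capped
#'   at \code{config@qualCap}), and the three log-likelihoods.
#' @examples
#' lr <- c(rep(-9, 11), rep(-0.01, 5)); la <- c(rep(-0.01, 11), rep(-9, 5))
#' classifyCandidate(lr, la, CallerConfig(alpha = 0.5))$posterior
#' @export
classifyCandidate <- function(logRef, logAlt, config = CallerConfig()) {
    n <- length(logRef)
    if (n == 0L) stop("no informative reads on the candidate haplotype")
    stopifnot(length(logAlt) == n)
    ccf <- config@ccf
    alpha <- config@alpha
    nB <- ccf@nBins
    phi <- (seq_len(nB) - 0.5) / nB
    w <- (1 - ccf@rho) * dbeta(phi, ccf@a, ccf@b) / nB
    W <- sum(w) + ccf@rho          # total (approximate) prior mass
    M <- sum(w * phi) + ccf@rho    # prior mass-weighted mean of phi
    m <- pmax(logRef, logAlt)
    pR <- exp(logRef - m); pA <- exp(logAlt - m)
    llSom <- sum(m + log(pR * (W - alpha * M) + pA * alpha * M))
    llHet <- sum(logAlt)
    llRef <- sum(logRef)
    lp <- c(somatic = llSom + log(config@muPrior),
            het = llHet + log(config@piPrior),
            reference = llRef + log1p(-config@muPrior - config@piPrior))
    z <- .logsumexp(lp)
    post <- exp(lp - z)
    lpNotSom <- .logsumexp(lp[c("het", "reference")]) - z
    qual <- min(max(-10 / log(10) * lpNotSom, 0), config@qualCap)
    list(posterior = post, qual = qual, llSomatic = llSom, llHet = llHet,
         llRef = llRef)
}

.FILTERS <- c("MaxOtherHaplotypeObservations", "MinObsPerStrand",
              "PossibleAlignmentArtifact", "LowQual", "MinHaplotypeDepth",
              "StrandBias")

#' Apply the hard filters to somatic call statistics
#'
#' Evaluates the six filters independently for each call and returns the
#' triggered set (or "PASS"):
#' \itemize{
#'   \item MaxOtherHaplotypeObservations: the variant appears on the
#'     non-called haplotype more than 2 times or in more than 20 percent of
#'     its reads (the other haplotype is an internal control: true somatic
#'     mutations are haplotype-specific).
#'   \item MinObsPerStrand: the variant is not observed on both sequencing
#'     strands.
#'   \item PossibleAlignmentArtifact: most alt-supporting reads have a high
#'     mismatch rate in the realignment window (characteristic of reads
#'     crossing structural variant breakpoints).
#'   \item LowQual: QUAL below the calling threshold.
#'   \item MinHaplotypeDepth: either haplotype below the callable depth.
#'   \item StrandBias: Fisher exact p-value of the allele-by-strand table
#'     below the threshold.
#' }
#'
#' @param stats a data.frame-like object with columns \code{qual},
#'   \code{otherHapObs}, \code{otherHapDepth}, \code{altFwd},
#'   \code{altRev}, \code{refFwd}, \code{refRev}, \code{dp0}, \code{dp1},
#'   \code{artifactFrac}.
#' @param config a \linkS4class{CallerConfig}.
#' @return Character vector: semicolon-joined filter names, or "PASS".
#' @examples
#' applyFilters(data.frame(qual = 35, otherHapObs = 3, otherHapDepth = 20,
#'   altFwd = 5, altRev = 6, refFwd = 4, refRev = 5, dp0 = 15, dp1 = 15,
#'   artifactFrac = 0), CallerConfig())
#' @export
applyFilters <- function(stats, config = CallerConfig()) {
    n <- nrow(stats)
    vapply(seq_len(n), function(i) {
        s <- stats[i, ]
        fired <- character(0)
        if (s$otherHapObs > config@maxOtherHapObs ||
            (s$otherHapDepth > 0 &&
             s$otherHapObs / s$otherHapDepth > config@maxOtherHapFrac))
            fired <- c(fired, "MaxOtherHaplotypeObservations")
        if (!(s$altFwd > 0 && s$altRev > 0))
            fired <- c(fired, "MinObsPerStrand")
        if (s$artifactFrac > config@artifactReadFrac)
            fired <- c(fired, "PossibleAlignmentArtifact")
        if (s$qual < config@qualThreshold)
            fired <- c(fired, "LowQual")
        if (s$dp0 < config@minHapDepth || s$dp1 < config@minHapDepth)
            fired <- c(fired, "MinHaplotypeDepth")
        sb <- fisher.test(matrix(c(s$altFwd, s$altRev, s$refFwd, s$refRev),
                                 nrow = 2L))$p.value
        if (sb < config@strandBiasP)
            fired <- c(fired, "StrandBias")
        if (length(fired)) paste(fired, collapse = ";") else "PASS"
    }, character(1))
}

## reference-space projection of read sequences (deletions as '-',
## insertions removed), for pileup counting and window mismatch rates
.projectReads <- function(galn) {
    as.character(GenomicAlignments::sequenceLayer(
        S4Vectors::mcols(galn)$seq, GenomicAlignments::cigar(galn),
        from = "query", to = "reference"))
}

## mismatch fraction of projected read segments against a haplotype window
.windowMismatch <- function(projSeq, readStart, winSeq, winStart) {
    vapply(seq_along(projSeq), function(i) {
        ws <- max(winStart, readStart[i])
        we <- min(winStart + nchar(winSeq) - 1L,
                  readStart[i] + nchar(projSeq[i]) - 1L)
        if (we < ws) return(NA_real_)
        a <- charToRaw(substr(projSeq[i], ws - readStart[i] + 1L,
                              we - readStart[i] + 1L))
        b <- charToRaw(substr(winSeq, ws - winStart + 1L,
                              we - winStart + 1L))
        mean(a != b)
    }, numeric(1))
}

#' Call somatic mutations in a genomic window
#'
#' Runs the full tumour-only calling procedure over one window: haplotags
#' the reads against the phased heterozygous SNPs, computes per-haplotype
#' pileups from the assigned reads, records callable positions (both
#' haplotypes adequately covered), discovers candidate variants, classifies
#' each candidate from realignment likelihoods of the reads on its
#' haplotype, and applies the hard filters. Deterministic given inputs and
#' configuration.
#'
#' @param bam path to the coordinate-sorted, indexed BAM.
#' @param fasta path to the indexed reference FASTA.
#' @param phasedVcf path to the phased heterozygous-SNP VCF (GT with "|",
#'   PS), or a \code{GRanges} from \code{\link{readPhasedHaplotypes}}.
#' @param region optional \code{GRanges} (single range) restricting
#'   calling; by default the first contig of the FASTA. Production runs
#'   process the genome in windows (10 Mbp by default upstream).
#' @param config a \linkS4class{CallerConfig}.
#' @return A \linkS4class{SomaticCalls} object.
#' @seealso \code{\link{writeCallsVcf}}, \code{\link{writeCallableBed}},
#'   \code{\link{estimateTMB}}.
#' @export
callWindow <- function(bam, fasta, phasedVcf, region = NULL,
                       config = CallerConfig()) {
    validObject(config)
    fa <- if (is(fasta, "FaFile")) fasta else Rsamtools::FaFile(fasta)
    if (!file.exists(paste0(BiocGenerics::path(fa), ".fai")))
        Rsamtools::indexFa(BiocGenerics::path(fa))
    fai <- Rsamtools::scanFaIndex(fa)
    if (is.null(region)) region <- fai[1L]
    stopifnot(length(region) == 1L)
    seqname <- as.character(GenomeInfoDb::seqnames(region))
    offset <- GenomicRanges::start(region)
    L <- GenomicRanges::width(region)

    galn <- .readAlignments(bam, region, config@mapqMin)
    phased <- if (is(phasedVcf, "GRanges")) phasedVcf
              else readPhasedHaplotypes(phasedVcf)
    emptyCalls <- GenomicRanges::GRanges()
    if (length(galn) == 0L)
        return(new("SomaticCalls", calls = emptyCalls,
                   callable = GenomicRanges::GRanges(), config = config))
    tags <- tagReads(galn, fa, phased, flank = config@flank,
                     hmm = config@hmm)
    hapOf <- setNames(tags$hap, tags$qname)
    readHap <- unname(hapOf[S4Vectors::mcols(galn)$qname])

    ## per-haplotype pileups from assigned reads
    proj <- .projectReads(galn)
    starts <- GenomicRanges::start(galn)
    hapCounts <- lapply(0:1, function(h) {
        i <- which(!is.na(readHap) & readHap == h)
        .pileupCounts(starts[i], proj[i], offset, L)
    })
    d0 <- colSums(hapCounts[[1L]]); d1 <- colSums(hapCounts[[2L]])
    callable <- findCallable(d0, d1, config, seqname, offset)

    refBases <- strsplit(as.character(Rsamtools::getSeq(fa, region)), "")[[1L]]
    cand <- discoverCandidates(hapCounts[[1L]], hapCounts[[2L]], refBases,
                               callable$mask, config, seqname, offset)
    if (nrow(cand) == 0L)
        return(new("SomaticCalls", calls = emptyCalls,
                   callable = callable$regions, config = config))

    candSites <- GenomicRanges::GRanges(seqname,
                                        IRanges::IRanges(cand$pos, width = 1L))
    S4Vectors::mcols(candSites) <- DataFrame(ref = cand$ref, alt = cand$alt)
    ## one likelihood extraction per unique position/allele
    key <- paste(cand$pos, cand$alt)
    uniq <- !duplicated(key)
    uSites <- candSites[uniq]
    frags <- .fragments(galn, fa, uSites, config@flank, config@hmm)
    frags$hap <- unname(hapOf[frags$qname])
    siteOf <- match(key, key[uniq])
    fragsBySite <- split(seq_len(nrow(frags)), frags$site)
    readIdx <- setNames(seq_along(galn), S4Vectors::mcols(galn)$qname)
    bases <- c("A", "C", "G", "T")

    rows <- vector("list", nrow(cand))
    for (k in seq_len(nrow(cand))) {
        u <- siteOf[k]
        i <- fragsBySite[[as.character(u)]]
        i <- i[!is.na(frags$hap[i]) & frags$hap[i] == cand$hap[k]]
        if (length(i) == 0L) next
        cl <- classifyCandidate(frags$logRef[i], frags$logAlt[i], config)
        col <- cand$pos[k] - offset + 1L
        otherCounts <- hapCounts[[2L - cand$hap[k]]]
        oao <- otherCounts[match(cand$alt[k], bases), col]
        oaoDepth <- if (cand$hap[k] == 0L) d1[col] else d0[col]
        supAlt <- frags$logAlt[i] > frags$logRef[i]
        altFwd <- sum(supAlt & frags$strand[i] == "+")
        altRev <- sum(supAlt & frags$strand[i] == "-")
        refFwd <- sum(!supAlt & frags$strand[i] == "+")
        refRev <- sum(!supAlt & frags$strand[i] == "-")
        ## mismatch rate of alt reads in the alt-substituted window
        artifactFrac <- 0
        ai <- i[supAlt]
        if (length(ai)) {
            ws <- max(cand$pos[k] - config@flank, offset)
            we <- min(cand$pos[k] + config@flank, offset + L - 1L)
            win <- paste(refBases[(ws - offset + 1L):(we - offset + 1L)],
                         collapse = "")
            substr(win, cand$pos[k] - ws + 1L, cand$pos[k] - ws + 1L) <-
                cand$alt[k]
            ri <- readIdx[frags$qname[ai]]
            mm <- .windowMismatch(proj[ri], starts[ri], win, ws)
            artifactFrac <- mean(mm > config@artifactMismatchRate,
                                 na.rm = TRUE)
            if (is.nan(artifactFrac)) artifactFrac <- 0
        }
        rows[[k]] <- data.frame(
            pos = cand$pos[k], ref = cand$ref[k], alt = cand$alt[k],
            hap = cand$hap[k],
            psom = round(unname(cl$posterior["somatic"]), 6),
            phet = round(unname(cl$posterior["het"]), 6),
            pref = round(unname(cl$posterior["reference"]), 6),
            qual = round(cl$qual, 2),
            dp0 = as.integer(d0[col]), dp1 = as.integer(d1[col]),
            altObs = cand$altObs[k],
            otherHapObs = as.integer(oao), otherHapDepth = as.integer(oaoDepth),
            altFwd = altFwd, altRev = altRev, refFwd = refFwd,
            refRev = refRev, artifactFrac = round(artifactFrac, 4))
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows))
        return(new("SomaticCalls", calls = emptyCalls,
                   callable = callable$regions, config = config))
    st <- do.call(rbind, rows)
    st$filter <- applyFilters(st, config)

    ## when both haplotypes yield a candidate at one position, keep the
    ## higher-QUAL call, annotated
    st$bothHap <- st$pos %in% st$pos[duplicated(st$pos)]
    st <- st[order(st$pos, -st$qual), ]
    st <- st[!duplicated(st$pos), ]

    gr <- GenomicRanges::GRanges(seqname, IRanges::IRanges(st$pos, width = 1L))
    S4Vectors::mcols(gr) <- DataFrame(
        ref = st$ref, alt = st$alt, hap = st$hap, qual = st$qual,
        filter = st$filter, psom = st$psom, phet = st$phet, pref = st$pref,
        dp0 = st$dp0, dp1 = st$dp1, altObs = st$altObs,
        otherHapObs = st$otherHapObs, altFwd = st$altFwd,
        altRev = st$altRev, refFwd = st$refFwd, refRev = st$refRev,
        artifactFrac = st$artifactFrac, bothHap = st$bothHap)
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(fai)
    GenomeInfoDb::seqlengths(gr) <- GenomeInfoDb::seqlengths(fai)
    new("SomaticCalls", calls = gr, callable = callable$regions,
        config = config)
}
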