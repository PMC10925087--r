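## Haplotagging: assigning each read to a parental haplotype using the
## phased heterozygous SNPs it overlaps. The phased haplotypes are treated
## as a pair of allele strings B0, B1 over the phased het sites, with
## B0[i] != B1[i] everywhere; reads crossing phase-set boundaries are
## handled by the QC rejection rules rather than by modelling inter-block
## phase.

#' Read phased heterozygous SNPs from a VCF
#'
#' Parses a phased VCF (the output of an external phasing tool) and returns
#' the heterozygous sites with their per-haplotype alleles and phase sets.
#'
#' @param phasedVcf path to a VCF with phased GT (\code{0|1} / \code{1|0})
#'   and PS (phase set) FORMAT fields.
#' @param region optional \code{GRanges} restriction.
#' @return A width-1 \code{GRanges} with metadata columns \code{ref},
#'   \code{alt}, \code{b0}, \code{b1} (alleles "R"/"A" carried by haplotype
#'   0 and 1) and \code{ps} (phase set identifier).
#' @export
readPhasedHaplotypes <- function(phasedVcf, region = NULL) {
    vcf <- VariantAnnotation::readVcf(phasedVcf)
    g <- VariantAnnotation::geno(vcf)
    if (!"PS" %in% names(g))
        stop("phased VCF lacks PS (phase set) FORMAT field")
    gt <- g$GT[, 1L]
    ps <- g$PS[, 1L]
    phasedHet <- gt %in% c("0|1", "1|0")
    rr <- SummarizedExperiment::rowRanges(vcf)
    ref <- as.character(VariantAnnotation::ref(vcf))
    altL <- VariantAnnotation::alt(vcf)
    ok <- phasedHet & lengths(altL) == 1L & nchar(ref) == 1L
    alt <- rep(NA_character_, length(rr))
    alt[lengths(altL) == 1L] <- as.character(unlist(altL[lengths(altL) == 1L]))
    ok <- ok & !is.na(alt) & nchar(alt) == 1L
    sites <- GenomicRanges::granges(rr)[ok]
    S4Vectors::mcols(sites) <- DataFrame(
        ref = ref[ok], alt = alt[ok],
        b0 = ifelse(gt[ok] == "0|1", "R", "A"),
        b1 = ifelse(gt[ok] == "0|1", "A", "R"),
        ps = as.integer(ps[ok]))
    names(sites) <- NULL
    sites <- GenomicRanges::sort(sites)
    if (!is.null(region)) sites <- IRanges::subsetByOverlaps(sites, region)
    sites
}

#' Assign one read to a haplotype
#'
#' Given a read's allele log-likelihoods over the phased heterozygous sites
#' it spans, computes the posterior over the two haplotypes as the product
#' of the read-allele likelihoods selected by each haplotype's allele
#' string, assigns the maximum-posterior haplotype, and applies the QC
#' rejection rules: the read is left unassigned when the PHRED-scaled
#' assignment quality (of the competing haplotype's posterior) is below
#' \code{minQual}, when the alleles best supported by the read mismatch
#' more than \code{maxMismatch} of the assigned haplotype's alleles, or
#' when no informative site is spanned.
#'
#' @param logRef,logAlt per-site read-allele log-likelihoods.
#' @param b0,b1 haplotype allele strings over the same sites ("R"/"A"
#'   vectors, opposite at every site).
#' @param prior haplotype prior, default uniform.
#' @param minQual assignment quality threshold (PHRED, default 20).
#' @param maxMismatch maximum tolerated mismatch fraction (default 0.10,
#'   strict inequality).
#' @return A list: \code{hap} (0L, 1L or NA), \code{qual} (PHRED-scaled
#'   probability of mis-assignment), \code{nSites},
#'   \code{mismatchFrac}, \code{posterior} (length-2 numeric).
#' @examples
#' lr <- rep(c(-0.01, -8), 5); la <- rep(c(-8, -0.01), 5)
#' assignRead(lr, la, b0 = rep(c("R", "A"), 5), b1 = rep(c("A", "R"), 5))
#' @export
assignRead <- function(logRef, logAlt, b0, b1, prior = c(0.5, 0.5),
                       minQual = 20, maxMismatch = 0.10) {
    n <- length(logRef)
    stopifnot(length(logAlt) == n, length(b0) == n, length(b1) == n)
    if (any(b0 == b1)) stop("b0 and b1 must differ at every phased het site")
    if (n == 0L)
        return(list(hap = NA_integer_, qual = 0, nSites = 0L,
                    mismatchFrac = NA_real_, posterior = c(0.5, 0.5)))
    ll0 <- sum(ifelse(b0 == "R", logRef, logAlt))
    ll1 <- sum(ifelse(b1 == "R", logRef, logAlt))
    lp <- c(log(prior[1L]) + ll0, log(prior[2L]) + ll1)
    z <- .logsumexp(lp)
    post <- exp(lp - z)
    hap <- which.max(lp) - 1L
    lpOther <- lp[2L - hap] - z      # log posterior of the competing haplotype
    qual <- -10 / log(10) * lpOther
    supported <- ifelse(logAlt > logRef, "A", "R")
    bAssigned <- if (hap == 0L) b0 else b1
    mismatchFrac <- mean(supported != bAssigned)
    if (qual < minQual || mismatchFrac > maxMismatch) hap <- NA_integer_
    list(hap = hap, qual = qual, nSites = n, mismatchFrac = mismatchFrac,
         posterior = post)
}

#' Haplotag all reads against a phased heterozygous-SNP VCF
#'
#' Computes read-allele likelihoods at the phased het sites each read spans
#' and assigns every read to haplotype 0, haplotype 1 or leaves it
#' unassigned via \code{\link{assignRead}}. Reads spanning multiple phase
#' sets are scored against the phase set contributing the most overlapping
#' sites; sites from other phase sets are ignored and the QC rules then
#' apply.
#'
#' @param bam path to the indexed BAM, or a \code{GAlignments} object.
#' @param fasta indexed reference FASTA path or \code{FaFile}.
#' @param phasedVcf path to the phased VCF (GT with "|" and PS), or a
#'   \code{GRanges} from \code{\link{readPhasedHaplotypes}}.
#' @param region optional \code{GRanges} restriction.
#' @param minQual,maxMismatch QC rejection thresholds.
#' @param flank,hmm,mapqMin realignment settings.
#' @return A \code{DataFrame} with one row per read: \code{qname},
#'   \code{hap} (0/1/NA), \code{qual}, \code{nSites}, \code{mismatchFrac},
#'   \code{ps} (phase set used). The fragment table is attached as
#'   \code{metadata()$fragments} with a \code{hap} column giving each
#'   read's assignment.
#' @export
tagReads <- function(bam, fasta, phasedVcf, region = NULL, minQual = 20,
                     maxMismatch = 0.10, flank = 20L, hmm = HmmParams(),
                     mapqMin = 20L) {
    sites <- if (is(phasedVcf, "GRanges")) phasedVcf
             else readPhasedHaplotypes(phasedVcf)
    galn <- if (is(bam, "GAlignments")) bam
            else .readAlignments(bam, region, mapqMin)
    frags <- .fragments(galn, if (is(fasta, "FaFile")) fasta
                              else Rsamtools::FaFile(fasta),
                        sites, flank, hmm)
    .assignReads(frags, sites, minQual, maxMismatch)
}

.assignReads <- function(frags, sites, minQual = 20, maxMismatch = 0.10) {
    empty <- DataFrame(qname = character(0), hap = integer(0),
                       qual = numeric(0), nSites = integer(0),
                       mismatchFrac = numeric(0), ps = integer(0))
    if (nrow(frags) == 0L) {
        metadata(empty) <- list(fragments = frags)
        return(empty)
    }
    ## majority phase set per read (ties break to the smaller identifier);
    ## fragments from other phase sets are ignored and QC applies
    ps <- sites$ps[frags$site]
    qn <- factor(frags$qname)
    cnt <- table(qn, ps)
    psLevels <- as.integer(colnames(cnt))
    psUse <- psLevels[max.col(cnt, ties.method = "first")]  # rows = levels(qn)
    keep <- ps == psUse[as.integer(qn)]
    f <- frags[keep, , drop = FALSE]
    qn <- factor(f$qname)
    s <- f$site
    contrib0 <- ifelse(sites$b0[s] == "R", f$logRef, f$logAlt)
    contrib1 <- ifelse(sites$b1[s] == "R", f$logRef, f$logAlt)
    ll0 <- rowsum(contrib0, qn)[, 1L]
    ll1 <- rowsum(contrib1, qn)[, 1L]
    n <- as.integer(table(qn))
    lp0 <- log(0.5) + ll0; lp1 <- log(0.5) + ll1
    m <- pmax(lp0, lp1)
    z <- m + log(exp(lp0 - m) + exp(lp1 - m))
    hap <- ifelse(lp1 > lp0, 1L, 0L)
    lpOther <- ifelse(hap == 1L, lp0, lp1) - z
    qual <- -10 / log(10) * lpOther
    supported <- ifelse(f$logAlt > f$logRef, "A", "R")
    bAssigned <- ifelse(hap[as.integer(qn)] == 0L, sites$b0[s], sites$b1[s])
    mismatchFrac <- rowsum((supported != bAssigned) + 0, qn)[, 1L] / n
    hap[qual < minQual | mismatchFrac > maxMismatch] <- NA_integer_
    out <- DataFrame(qname = levels(qn), hap = unname(hap),
                     qual = unname(qual), nSites = unname(n),
                     mismatchFrac = unname(mismatchFrac),
                     ps = unname(psUse[match(levels(qn),
                                             levels(factor(frags$qname)))]))
    rownames(out) <- NULL
    hapOf <- setNames(out$hap, out$qname)
    frags$hap <- unname(hapOf[frags$qname])
    metadata(out) <- list(fragments = frags)
    out
}
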