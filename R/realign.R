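## Quality-aware windowed realignment: read-haplotype and read-allele
## likelihoods. Raw pileup counts are unreliable where the BAM alignment is
## locally wrong, so candidate alleles are scored by realigning each read
## segment against short windowed haplotypes with a banded pair-HMM.

.qualToInt <- function(qual) {
    if (is.numeric(qual)) return(as.integer(qual))
    as.integer(charToRaw(as.character(qual))) - 33L
}

#' Read-haplotype likelihood by banded pair-HMM forward algorithm
#'
#' Computes \eqn{\log P(R_k \mid H)}: the probability of observing read
#' segment \code{read} given haplotype sequence \code{hap}, summed over all
#' alignments within a diagonal band. Match emissions use the per-base
#' qualities (correct base \eqn{1 - 10^{-q/10}}, each other base
#' \eqn{10^{-q/10}/3}, qualities capped at \code{params@maxQual});
#' insertions emit uniformly. The haplotype flanks are free, so the read may
#' align anywhere inside the window.
#'
#' @param read character read segment (bases).
#' @param qual integer vector of PHRED base qualities (one per read base),
#'   or a PHRED+33 encoded string.
#' @param hap character haplotype window sequence.
#' @param params an \linkS4class{HmmParams}.
#' @return The log-probability (a single negative number).
#' @examples
#' realignLikelihood("ACGTACGT", rep(30L, 8), "TTACGTACGTTT")
#' @export
realignLikelihood <- function(read, qual, hap, params = HmmParams()) {
    stopifnot(is(params, "HmmParams"))
    if (!nzchar(read)) stop("empty read segment")
    if (!nzchar(hap)) stop("empty haplotype window")
    q <- .qualToInt(qual)
    if (length(q) != nchar(read)) stop("quality length must match read length")
    n <- nchar(read); L <- nchar(hap)
    if (L - n + 2L * params@band < 0L)
        stop("band overflow: band width ", params@band,
             " cannot connect a ", n, " bp read to a ", L, " bp window")
    qs <- rawToChar(as.raw(pmin(pmax(q, 0L), 93L) + 33L))
    out <- .phmmForwardBatch(read, qs, hap, params@gapOpen, params@gapExtend,
                             params@band, params@maxQual)
    if (!is.finite(out)) stop("no alignment path within the band")
    out
}

## batch wrapper used internally (qualStrings are PHRED+33)
.phmmBatch <- function(reads, qualStrings, haps, params) {
    .phmmForwardBatch(reads, qualStrings, haps, params@gapOpen,
                      params@gapExtend, params@band, params@maxQual)
}

## Read alignments with the fields the pipeline needs, applying the standard
## QC: mapping quality threshold, no duplicates/secondary/supplementary.
.readAlignments <- function(bam, region = NULL, mapqMin = 20L) {
    flags <- Rsamtools::scanBamFlag(isDuplicate = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE,
                                    isUnmappedQuery = FALSE)
    param <- Rsamtools::ScanBamParam(
        flag = flags, what = c("qname", "mapq", "seq", "qual"),
        which = if (is.null(region)) IRanges::IRangesList() else region)
    if (is.null(region))
        param <- Rsamtools::ScanBamParam(flag = flags,
                                         what = c("qname", "mapq", "seq", "qual"))
    galn <- GenomicAlignments::readGAlignments(bam, param = param,
                                               use.names = FALSE)
    galn[S4Vectors::mcols(galn)$mapq >= mapqMin]
}

## query-space coordinates of reference ranges, per (read, range) pair.
## galnIdx selects the alignment for each range. Fast path for
## ungapped (all-M) alignments; otherwise cigar-aware mapping.
.queryCoords <- function(galn, galnIdx, refStart, refEnd) {
    cig <- GenomicAlignments::cigar(galn)
    if (all(grepl("^[0-9]+M$", cig))) {
        off <- GenomicAlignments::start(galn)[galnIdx]
        return(list(qs = refStart - off + 1L, qe = refEnd - off + 1L))
    }
    n <- length(refStart)
    x <- GenomicRanges::GRanges(as.character(galnIdx),
                                IRanges::IRanges(refStart, refEnd))
    aln <- galn
    names(aln) <- as.character(seq_along(aln))
    m <- GenomicAlignments::mapToAlignments(
        GenomicRanges::GRanges(GenomeInfoDb::seqnames(galn)[galnIdx],
                               IRanges::IRanges(refStart, refEnd)), aln)
    keep <- S4Vectors::mcols(m)$alignmentsHits == galnIdx[S4Vectors::mcols(m)$xHits]
    m <- m[keep]
    qs <- qe <- rep(NA_integer_, n)
    i <- S4Vectors::mcols(m)$xHits
    qs[i] <- GenomicRanges::start(m)
    qe[i] <- GenomicRanges::end(m)
    list(qs = qs, qe = qe)
}

#' Read-allele likelihoods over candidate or known variant sites
#'
#' For every (read, site) pair where a QC-passing read spans a biallelic SNV
#' site, realigns the read segment around the site against two windowed
#' haplotypes -- the reference window and the window with the alternate
#' allele substituted -- and records
#' \eqn{\log P(R_k \mid V_i^R)} and \eqn{\log P(R_k \mid V_i^A)}.
#'
#' Windows span \code{flank} bases either side of the site, clipped to the
#' read and the contig. Other variant sites falling inside a window are left
#' at the reference base in both hypotheses.
#'
#' @param bam path to a coordinate-sorted, indexed BAM, or a
#'   \code{GAlignments} object carrying \code{qname}, \code{mapq},
#'   \code{seq} and \code{qual} metadata columns.
#' @param fasta path to the indexed reference FASTA, or an open
#'   \code{FaFile}.
#' @param sites width-1 \code{GRanges} of biallelic SNV sites with metadata
#'   columns \code{ref} and \code{alt} (single bases).
#' @param flank window half-width in bp.
#' @param hmm an \linkS4class{HmmParams}.
#' @param mapqMin minimum mapping quality (applied when \code{bam} is a
#'   path).
#' @param region optional \code{GRanges} restricting the BAM scan.
#' @return A \code{DataFrame} with one row per informative (read, site)
#'   pair: \code{qname}, \code{site} (index into \code{sites}), \code{pos},
#'   \code{strand}, \code{logRef}, \code{logAlt}.
#' @examples
#' ## see the fixture-based examples in the package vignette
#' @export
extractFragments <- function(bam, fasta, sites, flank = 20L,
                             hmm = HmmParams(), mapqMin = 20L,
                             region = NULL) {
    if (!is(sites, "GRanges") || is.null(sites$ref) || is.null(sites$alt))
        stop("'sites' must be a GRanges with 'ref' and 'alt' metadata columns")
    if (any(GenomicRanges::width(sites) != 1L))
        stop("'sites' must contain width-1 SNV positions")
    if (any(nchar(sites$ref) != 1L) || any(nchar(sites$alt) != 1L) ||
        any(sites$ref == sites$alt))
        stop("malformed site records: need single-base ref != alt")
    galn <- if (is(bam, "GAlignments")) bam
            else .readAlignments(bam, region, mapqMin)
    fa <- if (is(fasta, "FaFile")) fasta else Rsamtools::FaFile(fasta)
    if (!file.exists(paste0(BiocGenerics::path(fa), ".fai")))
        Rsamtools::indexFa(BiocGenerics::path(fa))
    .fragments(galn, fa, sites, flank, hmm)
}

.fragments <- function(galn, fa, sites, flank, hmm) {
    empty <- DataFrame(qname = character(0), site = integer(0),
                       pos = integer(0), strand = character(0),
                       logRef = numeric(0), logAlt = numeric(0))
    if (length(galn) == 0L || length(sites) == 0L) return(empty)
    hits <- GenomicRanges::findOverlaps(GenomicRanges::granges(sites),
                                        GenomicRanges::granges(galn))
    if (length(hits) == 0L) return(empty)
    si <- S4Vectors::queryHits(hits)
    ri <- S4Vectors::subjectHits(hits)
    pos <- GenomicRanges::start(sites)[si]
    rStart <- GenomicRanges::start(galn)[ri]
    rEnd <- GenomicRanges::end(galn)[ri]
    contigLen <- GenomeInfoDb::seqlengths(Rsamtools::scanFaIndex(fa))
    cl <- contigLen[as.character(GenomeInfoDb::seqnames(sites))[si]]
    ws <- pmax(pos - flank, rStart, 1L)
    we <- pmin(pos + flank, rEnd, cl)
    qc <- .queryCoords(galn, ri, ws, we)
    ok <- !is.na(qc$qs) & !is.na(qc$qe) & qc$qe >= qc$qs
    if (!all(ok)) {
        si <- si[ok]; ri <- ri[ok]; pos <- pos[ok]
        ws <- ws[ok]; we <- we[ok]
        qc <- list(qs = qc$qs[ok], qe = qc$qe[ok])
    }
    if (length(si) == 0L) return(empty)

    refWin <- as.character(Rsamtools::getSeq(
        fa, GenomicRanges::GRanges(GenomeInfoDb::seqnames(sites)[si],
                                   IRanges::IRanges(ws, we))))
    siteRef <- substr(refWin, pos - ws + 1L, pos - ws + 1L)
    bad <- siteRef != sites$ref[si]
    if (any(bad))
        stop("reference mismatch at ",
             paste0(GenomeInfoDb::seqnames(sites)[si[bad][1L]], ":",
                    pos[bad][1L]),
             ": FASTA has ", siteRef[bad][1L], ", site record says ",
             sites$ref[si[bad][1L]])
    altWin <- refWin
    substr(altWin, pos - ws + 1L, pos - ws + 1L) <- sites$alt[si]

    seqs <- as.character(S4Vectors::mcols(galn)$seq)[ri]
    quals <- as.character(S4Vectors::mcols(galn)$qual)[ri]
    segs <- substr(seqs, qc$qs, qc$qe)
    qsegs <- substr(quals, qc$qs, qc$qe)
    logRef <- .phmmBatch(segs, qsegs, refWin, hmm)
    logAlt <- .phmmBatch(segs, qsegs, altWin, hmm)
    out <- DataFrame(qname = S4Vectors::mcols(galn)$qname[ri], site = si,
                     pos = pos,
                     strand = as.character(BiocGenerics::strand(galn))[ri],
                     logRef = logRef, logAlt = logAlt)
    metadata(out) <- list(flank = flank)
    out
}
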