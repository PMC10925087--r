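## Tumour mutation burden and the 96-context mutation spectrum.

#' The 96 trinucleotide mutation context labels
#'
#' Pyrimidine-centred substitution contexts in COSMIC-style order: six
#' substitution types (C>A, C>G, C>T, T>A, T>C, T>G), each with the 16
#' combinations of one preceding and one following base.
#'
#' @return Character vector of 96 labels like \code{"A[C>T]G"}.
#' @examples
#' head(spectrumContexts())
#' @export
spectrumContexts <- function() {
    subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
    bases <- c("A", "C", "G", "T")
    unlist(lapply(subs, function(s)
        unlist(lapply(bases, function(p)
            paste0(p, "[", s, "]", vapply(bases, identity, character(1)))))))
}

.callsAsGRanges <- function(calls) {
    if (is(calls, "SomaticCalls")) return(calls(calls))
    if (is(calls, "GRanges")) return(calls)
    if (is.character(calls)) return(readCallsVcf(calls))
    stop("'calls' must be a SomaticCalls, GRanges or VCF path")
}

.bedAsGRanges <- function(bed) {
    if (is(bed, "GRanges")) return(bed)
    if (is.character(bed)) return(rtracklayer::import(bed, format = "BED"))
    stop("'callable' must be a GRanges or BED path")
}

#' Estimate tumour mutation burden
#'
#' TMB is the number of QC-PASS mutation calls with QUAL at or above the
#' threshold, divided by the number of megabases where mutation calling was
#' performed (the callable footprint). Because mutation burden is a
#' genome-wide property, the burden measured on the callable (phased)
#' subset extrapolates to the genome.
#'
#' @param calls a \linkS4class{SomaticCalls}, a calls \code{GRanges}, or a
#'   path to a calls VCF.
#' @param callable a \code{GRanges} of callable positions or a BED path;
#'   defaults to the callable regions of a \code{SomaticCalls} input.
#' @param qualThreshold minimum QUAL (default 20).
#' @return A list: \code{tmb} (mutations per megabase), \code{nCalls},
#'   \code{callableBases}.
#' @examples
#' gr <- GenomicRanges::GRanges("r", IRanges::IRanges(c(10, 20), width = 1),
#'   qual = c(45, 18), filter = c("PASS", "LowQual"))
#' bed <- GenomicRanges::GRanges("r", IRanges::IRanges(1, 1e6))
#' estimateTMB(gr, bed)$tmb  # 1 call in 1 Mbp
#' @export
estimateTMB <- function(calls, callable = NULL, qualThreshold = 20) {
    if (is.null(callable)) {
        if (!is(calls, "SomaticCalls"))
            stop("'callable' is required unless 'calls' is a SomaticCalls")
        callable <- callableRegions(calls)
    }
    bed <- .bedAsGRanges(callable)
    footprint <- sum(as.numeric(GenomicRanges::width(
        GenomicRanges::reduce(bed))))
    if (footprint == 0)
        stop("undefined TMB: empty callable footprint")
    gr <- .callsAsGRanges(calls)
    n <- sum(gr$filter == "PASS" & gr$qual >= qualThreshold)
    list(tmb = n / (footprint / 1e6), nCalls = n, callableBases = footprint)
}

#' 96-context mutation spectrum of a call set
#'
#' Maps each passing SNV call to its pyrimidine-centred trinucleotide
#' context (calls with a purine reference base are reverse-complemented)
#' and accumulates counts over the 96 contexts.
#'
#' @param calls as in \code{\link{estimateTMB}}; needs \code{ref},
#'   \code{alt}, \code{qual}, \code{filter} metadata.
#' @param fasta indexed reference FASTA path or \code{FaFile} (for the
#'   flanking bases).
#' @param qualThreshold,passOnly call-set restriction, matching the TMB
#'   call set by default.
#' @param tsv optional path; when given the spectrum is written as a
#'   two-column TSV (context, count).
#' @return Named numeric vector of length 96 (counts, in
#'   \code{\link{spectrumContexts}} order).
#' @export
mutationSpectrum <- function(calls, fasta, qualThreshold = 20,
                             passOnly = TRUE, tsv = NULL) {
    gr <- .callsAsGRanges(calls)
    keep <- gr$qual >= qualThreshold
    if (passOnly) keep <- keep & gr$filter == "PASS"
    gr <- gr[keep]
    ctx <- spectrumContexts()
    counts <- setNames(numeric(96L), ctx)
    if (length(gr)) {
        fa <- if (is(fasta, "FaFile")) fasta else Rsamtools::FaFile(fasta)
        fai <- Rsamtools::scanFaIndex(fa)
        lens <- GenomeInfoDb::seqlengths(fai)
        pos <- GenomicRanges::start(gr)
        cl <- lens[as.character(GenomeInfoDb::seqnames(gr))]
        inside <- pos > 1L & pos < cl
        if (any(!inside)) {
            warning(sum(!inside), " call(s) too close to a contig edge for ",
                    "context extraction; skipped")
            gr <- gr[inside]; pos <- pos[inside]
        }
        tri <- as.character(Rsamtools::getSeq(
            fa, GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                                       IRanges::IRanges(pos - 1L, pos + 1L))))
        ref <- gr$ref; alt <- gr$alt
        pur <- ref %in% c("A", "G")
        tri[pur] <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(tri[pur])))
        rc <- c(A = "T", C = "G", G = "C", T = "A")
        ref[pur] <- rc[ref[pur]]
        alt[pur] <- rc[alt[pur]]
        lab <- paste0(substr(tri, 1, 1), "[", ref, ">", alt, "]",
                      substr(tri, 3, 3))
        tab <- table(factor(lab, levels = ctx))
        counts[] <- as.numeric(tab)
    }
    if (!is.null(tsv))
        utils::write.table(
            data.frame(context = names(counts), count = counts),
            tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    counts
}

#' Cosine similarity of two mutation spectra
#'
#' @param u,v non-negative numeric vectors of equal length (e.g. 96-context
#'   counts or frequencies); neither may be all zero.
#' @return Cosine of the angle between the vectors, in \[0,1\] for
#'   non-negative input.
#' @examples
#' cosineSimilarity(c(1, 1, 0), c(1, 1, 0))      # 1
#' cosineSimilarity(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 0.5
#' @export
cosineSimilarity <- function(u, v) {
    if (length(u) != length(v)) stop("'u' and 'v' must have equal length")
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) stop("undefined for a zero vector")
    sum(u * v) / (nu * nv)
}
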