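## Serialization of somatic call sets: VCF 4.2 for calls, BED for the
## callable footprint.

.callInfoHeader <- function() DataFrame(
    Number = c("1", "1", "1", "1", "1", "1", "1", "1", "1", "1", "1", "1",
               "1", "0"),
    Type = c("Integer", "Float", "Float", "Float", "Integer", "Integer",
             "Integer", "Integer", "Integer", "Integer", "Integer",
             "Integer", "Float", "Flag"),
    Description = c(
        "Haplotype carrying the mutation (0/1)",
        "Posterior probability of the somatic class",
        "Posterior probability of the heterozygous class",
        "Posterior probability of the reference class",
        "Assigned read depth on haplotype 0",
        "Assigned read depth on haplotype 1",
        "Alternate observations on the called haplotype",
        "Alternate observations on the other haplotype",
        "Alt-supporting reads on the forward strand",
        "Alt-supporting reads on the reverse strand",
        "Ref-supporting reads on the forward strand",
        "Ref-supporting reads on the reverse strand",
        "Fraction of alt reads with high window mismatch rate",
        "Both haplotypes produced a candidate at this position"),
    row.names = c("HAP", "PSOM", "PHET", "PREF", "DP0", "DP1", "AO", "OAO",
                  "SAF", "SAR", "SRF", "SRR", "ARTF", "BOTHHAP"))

#' Write somatic calls as VCF 4.2
#'
#' Serializes every candidate call (passing and filtered) with its QUAL,
#' class posteriors, per-haplotype depths, strand counts and the FILTER
#' column holding the triggered filter names (or PASS).
#'
#' @param x a \linkS4class{SomaticCalls}.
#' @param path output VCF path.
#' @param sample sample name recorded in the header.
#' @return The path, invisibly.
#' @seealso \code{\link{readCallsVcf}} for the inverse.
#' @export
writeCallsVcf <- function(x, path, sample = "TUMOUR") {
    stopifnot(is(x, "SomaticCalls"))
    gr <- x@calls
    n <- length(gr)
    rr <- GenomicRanges::granges(gr)
    names(rr) <- if (n) paste0("call", seq_len(n)) else character(0)
    hdr <- VariantAnnotation::VCFHeader(samples = sample)
    VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
        fileformat = DataFrame(Value = "VCFv4.2", row.names = "fileformat"))
    VariantAnnotation::info(hdr) <- .callInfoHeader()
    VariantAnnotation::fixed(hdr) <- IRanges::DataFrameList(
        FILTER = DataFrame(Description = c("All filters passed", .FILTERS),
                           row.names = c("PASS", .FILTERS)))
    VariantAnnotation::geno(hdr) <- DataFrame(
        Number = "1", Type = "String", Description = "Genotype",
        row.names = "GT")
    mk <- function(v) matrix(v, ncol = 1L, dimnames = list(names(rr), sample))
    v <- VariantAnnotation::VCF(
        rowRanges = rr,
        colData = DataFrame(Samples = 1L, row.names = sample),
        fixed = DataFrame(
            REF = Biostrings::DNAStringSet(gr$ref),
            ALT = Biostrings::DNAStringSetList(as.list(gr$alt)),
            QUAL = gr$qual, FILTER = gr$filter),
        info = DataFrame(HAP = gr$hap, PSOM = gr$psom, PHET = gr$phet,
                         PREF = gr$pref, DP0 = gr$dp0, DP1 = gr$dp1,
                         AO = gr$altObs, OAO = gr$otherHapObs,
                         SAF = gr$altFwd, SAR = gr$altRev, SRF = gr$refFwd,
                         SRR = gr$refRev, ARTF = gr$artifactFrac,
                         BOTHHAP = gr$bothHap),
        geno = S4Vectors::SimpleList(GT = mk(rep("0/1", n))))
    VariantAnnotation::header(v) <- hdr
    VariantAnnotation::writeVcf(v, path)
    invisible(path)
}

#' Read a somatic calls VCF back into a GRanges
#'
#' @param path VCF written by \code{\link{writeCallsVcf}}.
#' @return Width-1 \code{GRanges} with the same metadata columns as
#'   \code{calls()} of the originating object.
#' @export
readCallsVcf <- function(path) {
    vcf <- VariantAnnotation::readVcf(path)
    gr <- GenomicRanges::granges(SummarizedExperiment::rowRanges(vcf))
    names(gr) <- NULL
    fx <- VariantAnnotation::fixed(vcf)
    inf <- VariantAnnotation::info(vcf)
    u <- function(x) if (is(x, "List")) unlist(x) else x
    S4Vectors::mcols(gr) <- DataFrame(
        ref = as.character(VariantAnnotation::ref(vcf)),
        alt = as.character(u(VariantAnnotation::alt(vcf))),
        hap = u(inf$HAP), qual = fx$QUAL, filter = fx$FILTER,
        psom = u(inf$PSOM), phet = u(inf$PHET), pref = u(inf$PREF),
        dp0 = u(inf$DP0), dp1 = u(inf$DP1), altObs = u(inf$AO),
        otherHapObs = u(inf$OAO), altFwd = u(inf$SAF), altRev = u(inf$SAR),
        refFwd = u(inf$SRF), refRev = u(inf$SRR), artifactFrac = u(inf$ARTF),
        bothHap = inf$BOTHHAP)
    gr
}

#' Write the callable footprint as BED
#'
#' Emits the maximal merged intervals of callable positions, 0-based
#' half-open as BED requires.
#'
#' @param x a \linkS4class{SomaticCalls} or a \code{GRanges}.
#' @param path output BED path.
#' @return The path, invisibly.
#' @export
writeCallableBed <- function(x, path) {
    gr <- if (is(x, "SomaticCalls")) x@callable else x
    rtracklayer::export(GenomicRanges::reduce(gr), path, format = "BED")
    invisible(path)
}
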