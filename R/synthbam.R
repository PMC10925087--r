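## Synthetic truth-annotated pipeline fixtures: a diploid region with
## heterozygous SNPs, somatic mutations on one haplotype with
## clonal/subclonal cancer cell fractions, and pre-aligned long reads
## sampled from a tumour/normal mixture, emitted as FASTA + BAM + truth
## VCFs. Reads are generated already aligned (perfect coordinates, pure-M
## CIGARs), sidestepping an aligner dependency.

.BASES <- c("A", "C", "G", "T")

## germline + somatic architecture of the region (no reads)
.genGenome <- function(spec) {
    L <- as.integer(spec@regionLength)
    refSeq <- sample(.BASES, L, replace = TRUE)
    nHet <- rbinom(1L, L, spec@pi)
    hetPos <- if (nHet) sort(sample.int(L, nHet)) else integer(0)
    hetAlt <- vapply(hetPos, function(p)
        sample(setdiff(.BASES, refSeq[p]), 1L), character(1))
    hetHap <- rbinom(length(hetPos), 1L, 0.5)   # haplotype carrying the alt
    nSom <- if (is.na(spec@nSomatic)) rbinom(1L, L, spec@mu)
            else as.integer(spec@nSomatic)
    avail <- setdiff(seq_len(L), hetPos)
    somPos <- sort(sample(avail, min(nSom, length(avail))))
    somAlt <- vapply(somPos, function(p)
        sample(setdiff(.BASES, refSeq[p]), 1L), character(1))
    somHap <- rbinom(length(somPos), 1L, 0.5)
    ccf <- spec@ccf
    clonal <- runif(length(somPos)) < ccf@rho
    somCcf <- ifelse(clonal, 1, rbeta(length(somPos), ccf@a, ccf@b))
    ## haplotype germline sequences
    hap <- list(refSeq, refSeq)
    for (j in 0:1) {
        i <- hetHap == j
        hap[[j + 1L]][hetPos[i]] <- hetAlt[i]
    }
    list(L = L, refSeq = refSeq, hap = hap,
         het = DataFrame(pos = hetPos, ref = refSeq[hetPos], alt = hetAlt,
                         hap = hetHap),
         som = DataFrame(pos = somPos, ref = refSeq[somPos], alt = somAlt,
                         hap = somHap, ccf = somCcf))
}

## sample reads from the tumour/normal mixture over a genome architecture
.genReads <- function(genome, spec) {
    L <- genome$L
    rl <- as.integer(spec@readLength)
    if (rl > L) stop("read length exceeds region length")
    ## reads lie fully inside the region; the count targets the requested
    ## depth on the coverage plateau away from the region edges
    nReads <- max(1L, round(spec@depth * (L - rl + 1L) / rl))
    starts <- sample.int(L - rl + 1L, nReads, replace = TRUE)
    hapIdx <- rbinom(nReads, 1L, 1 - spec@hap0Fraction)
    tumour <- runif(nReads) < spec@alpha
    rev <- runif(nReads) < 0.5
    q <- min(60L, as.integer(round(-10 * log10(max(spec@epsilon, 1e-6)))))
    qualStr <- strrep(rawToChar(as.raw(q + 33L)), rl)
    som <- genome$som
    seqs <- character(nReads)
    for (k in seq_len(nReads)) {
        s <- starts[k]; e <- s + rl - 1L
        bases <- genome$hap[[hapIdx[k] + 1L]][s:e]
        if (tumour[k]) {
            i <- which(som$hap == hapIdx[k] & som$pos >= s & som$pos <= e)
            if (length(i)) {
                carry <- runif(length(i)) < som$ccf[i]
                bases[som$pos[i][carry] - s + 1L] <- som$alt[i][carry]
            }
        }
        nErr <- rbinom(1L, rl, spec@epsilon)
        if (nErr) {
            ep <- sample.int(rl, nErr)
            bases[ep] <- vapply(bases[ep], function(b)
                sample(setdiff(.BASES, b), 1L), character(1))
        }
        seqs[k] <- paste(bases, collapse = "")
    }
    DataFrame(qname = sprintf("read%05d", seq_len(nReads)), start = starts,
              end = starts + rl - 1L, hap = hapIdx, tumour = tumour,
              strand = ifelse(rev, "-", "+"), seq = seqs, qual = qualStr)
}

.writeFixtureFiles <- function(genome, reads, outdir, contig = "synth1") {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    paths <- list(
        fasta = file.path(outdir, "reference.fa"),
        bam = file.path(outdir, "reads.bam"),
        germlineVcf = file.path(outdir, "germline_truth.vcf"),
        somaticVcf = file.path(outdir, "somatic_truth.vcf"),
        readTable = file.path(outdir, "reads_truth.tsv"))
    ## reference
    ref <- Biostrings::DNAStringSet(paste(genome$refSeq, collapse = ""))
    names(ref) <- contig
    Biostrings::writeXStringSet(ref, paths$fasta)
    Rsamtools::indexFa(paths$fasta)
    ## alignments: SAM text -> sorted, indexed BAM
    sam <- file.path(outdir, "reads.sam")
    hdr <- c("@HD\tVN:1.6\tSO:unknown",
             paste0("@SQ\tSN:", contig, "\tLN:", genome$L))
    recs <- paste(reads$qname, ifelse(reads$strand == "-", 16L, 0L), contig,
                  reads$start, 60L, paste0(nchar(reads$seq), "M"), "*", 0L,
                  0L, reads$seq, reads$qual, sep = "\t")
    writeLines(c(hdr, recs), sam)
    tmp <- Rsamtools::asBam(sam, file.path(outdir, "reads_unsorted"),
                            indexDestination = FALSE, overwrite = TRUE)
    Rsamtools::sortBam(tmp, sub("\\.bam$", "", paths$bam))
    Rsamtools::indexBam(paths$bam)
    unlink(c(sam, tmp))
    ## truth VCFs
    .writePhasedTruthVcf(genome$het, contig, genome$L, paths$germlineVcf)
    .writeSomaticTruthVcf(genome$som, contig, genome$L, paths$somaticVcf)
    utils::write.table(as.data.frame(reads[, c("qname", "start", "end",
                                               "hap", "tumour", "strand")]),
                       paths$readTable, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths
}

.vcfSkeleton <- function(pos, ref, alt, contig, contigLen, sample = NULL) {
    gr <- GenomicRanges::GRanges(rep(contig, length(pos)),
                                 IRanges::IRanges(pos, width = 1L))
    GenomeInfoDb::seqlevels(gr) <- contig
    names(gr) <- if (length(gr)) paste0("v", seq_along(gr)) else character(0)
    GenomeInfoDb::seqlengths(gr) <- contigLen
    hdr <- VariantAnnotation::VCFHeader(
        samples = if (is.null(sample)) character(0) else sample)
    VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
        fileformat = DataFrame(Value = "VCFv4.2", row.names = "fileformat"))
    list(gr = gr, hdr = hdr,
         fixed = DataFrame(REF = Biostrings::DNAStringSet(ref),
                           ALT = Biostrings::DNAStringSetList(as.list(alt)),
                           QUAL = rep(60, length(gr)),
                           FILTER = rep("PASS", length(gr))))
}

## truth heterozygous SNPs as a phased VCF (single phase set: the truth
## phase is known over the whole region)
.writePhasedTruthVcf <- function(het, contig, contigLen, path) {
    sk <- .vcfSkeleton(het$pos, het$ref, het$alt, contig, contigLen, "TRUTH")
    hdr <- sk$hdr
    VariantAnnotation::geno(hdr) <- DataFrame(
        Number = c("1", "1"), Type = c("String", "Integer"),
        Description = c("Genotype", "Phase set"), row.names = c("GT", "PS"))
    mk <- function(x) matrix(x, ncol = 1L,
                             dimnames = list(names(sk$gr), "TRUTH"))
    ## haplotype 0 allele written first: alt on hap 0 is "1|0"
    gt <- ifelse(het$hap == 0L, "1|0", "0|1")
    v <- VariantAnnotation::VCF(
        rowRanges = sk$gr,
        colData = DataFrame(Samples = 1L, row.names = "TRUTH"),
        fixed = sk$fixed,
        geno = S4Vectors::SimpleList(GT = mk(gt),
                                     PS = mk(rep(1L, nrow(het)))))
    VariantAnnotation::header(v) <- hdr
    VariantAnnotation::writeVcf(v, path)
}

.writeSomaticTruthVcf <- function(som, contig, contigLen, path) {
    sk <- .vcfSkeleton(som$pos, som$ref, som$alt, contig, contigLen)
    hdr <- sk$hdr
    VariantAnnotation::info(hdr) <- DataFrame(
        Number = c("1", "1"), Type = c("Integer", "Float"),
        Description = c("Haplotype of origin (0/1)",
                        "Cancer cell fraction"),
        row.names = c("HAP", "CCF"))
    v <- VariantAnnotation::VCF(
        rowRanges = sk$gr, fixed = sk$fixed,
        info = DataFrame(HAP = som$hap, CCF = round(som$ccf, 4)),
        collapsed = TRUE)
    VariantAnnotation::header(v) <- hdr
    VariantAnnotation::writeVcf(v, path)
}

#' Generate a synthetic truth-annotated sequencing fixture
#'
#' Builds a diploid region with heterozygous SNPs and haplotype-specific
#' somatic mutations, samples pre-aligned long reads from a tumour/normal
#' mixture, and writes an indexed reference FASTA, a sorted indexed BAM, a
#' phased germline truth VCF (GT|GT with PS), a somatic truth VCF (INFO
#' HAP, CCF) and a per-read truth table. Byte-identical outputs for
#' identical spec and seed.
#'
#' @param spec a \linkS4class{FixtureSpec}.
#' @param outdir output directory (created if needed).
#' @param contig contig name used in all outputs.
#' @return Named list of output paths (\code{fasta}, \code{bam},
#'   \code{germlineVcf}, \code{somaticVcf}, \code{readTable}) with the
#'   genome architecture attached as attribute \code{"genome"}.
#' @examples
#' \donttest{
#' fx <- makeFixture(FixtureSpec(regionLength = 2e4, depth = 20, seed = 1),
#'                   tempfile("fx"))
#' }
#' @export
makeFixture <- function(spec, outdir, contig = "synth1") {
    stopifnot(is(spec, "FixtureSpec"))
    validObject(spec)
    runWithSeed(spec@seed, {
        genome <- .genGenome(spec)
        reads <- .genReads(genome, spec)
    })
    paths <- .writeFixtureFiles(genome, reads, outdir, contig)
    attr(paths, "genome") <- genome
    attr(paths, "reads") <- reads[, c("qname", "start", "end", "hap",
                                      "tumour", "strand")]
    paths
}

#' Generate a purity/depth mixture series of fixtures
#'
#' One fixture per (purity, depth) grid cell, all sharing the same genome
#' architecture (identical germline and somatic truth variants) but with
#' independently sampled read mixtures, emulating titration experiments
#' where one tumour/normal pair is remixed at several purities and depths.
#'
#' @param spec base \linkS4class{FixtureSpec} (its alpha/depth are
#'   overridden per cell).
#' @param purities,depths numeric vectors defining the grid.
#' @param outdir parent output directory; each cell writes to
#'   \code{purity<p>_depth<d>/}.
#' @param contig contig name.
#' @return A \code{data.frame} with one row per cell: \code{purity},
#'   \code{depth}, \code{dir}, plus the per-fixture file paths.
#' @export
makeMixtureSeries <- function(spec, purities, depths, outdir,
                              contig = "synth1") {
    stopifnot(length(purities) > 0, length(depths) > 0)
    runWithSeed(spec@seed, genome <- .genGenome(spec))
    rows <- list()
    cell <- 0L
    for (p in purities) for (d in depths) {
        cell <- cell + 1L
        s2 <- spec; s2@alpha <- p; s2@depth <- d
        validObject(s2)
        runWithSeed(spec@seed + cell, reads <- .genReads(genome, s2))
        dir <- file.path(outdir, sprintf("purity%g_depth%g", p, d))
        paths <- .writeFixtureFiles(genome, reads, dir, contig)
        rows[[cell]] <- data.frame(purity = p, depth = d, dir = dir,
                                   fasta = paths$fasta, bam = paths$bam,
                                   germlineVcf = paths$germlineVcf,
                                   somaticVcf = paths$somaticVcf,
                                   stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    attr(out, "genome") <- genome
    out
}

#' Write a panel of candidate SNP sites as a VCF
#'
#' Serializes width-1 sites with ref/alt alleles as a minimal sites-only
#' VCF, emulating a population SNP panel (the known-sites input of the
#' genotyper).
#'
#' @param sites width-1 \code{GRanges} with \code{ref} and \code{alt}
#'   metadata columns; seqlengths must be set.
#' @param path output VCF path.
#' @return The path, invisibly.
#' @export
writeSitesVcf <- function(sites, path) {
    stopifnot(is(sites, "GRanges"), !is.null(sites$ref), !is.null(sites$alt))
    sk <- .vcfSkeleton(GenomicRanges::start(sites), sites$ref, sites$alt,
                       as.character(GenomeInfoDb::seqnames(sites))[1L],
                       GenomeInfoDb::seqlengths(sites)[1L])
    v <- VariantAnnotation::VCF(rowRanges = sk$gr, fixed = sk$fixed,
                                collapsed = TRUE)
    VariantAnnotation::header(v) <- sk$hdr
    VariantAnnotation::writeVcf(v, path)
    invisible(path)
}

#' Read a somatic truth VCF as a GRanges
#'
#' @param path somatic truth VCF from \code{\link{makeFixture}}.
#' @return Width-1 \code{GRanges} with \code{ref}, \code{alt}, \code{hap},
#'   \code{ccf}.
#' @export
readSomaticTruth <- function(path) {
    vcf <- VariantAnnotation::readVcf(path)
    gr <- GenomicRanges::granges(SummarizedExperiment::rowRanges(vcf))
    S4Vectors::mcols(gr) <- DataFrame(
        ref = as.character(VariantAnnotation::ref(vcf)),
        alt = as.character(unlist(VariantAnnotation::alt(vcf))),
        hap = unlist(VariantAnnotation::info(vcf)$HAP),
        ccf = unlist(VariantAnnotation::info(vcf)$CCF))
    names(gr) <- NULL
    gr
}
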