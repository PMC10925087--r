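## Genotyping known population SNP sites under possibly unbalanced copy
## number. Tumour genomes can underrepresent one parental haplotype (in the
## extreme, loss of heterozygosity), so the heterozygous likelihood draws
## reads from the higher-copy haplotype with probability f rather than 1/2.
## The output is deliberately conservative: only confident 0/1 calls are
## emitted, since false heterozygous sites corrupt downstream phasing and
## haplotagging.

.logsumexp <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
}

#' Genotype one SNP site from read-allele likelihoods
#'
#' Computes genotype posteriors for a biallelic site from per-read
#' log-likelihoods of the reference and alternate alleles. Homozygous
#' likelihoods are products of the per-read allele likelihoods. The
#' heterozygous likelihood averages the two copy-number orientations, each a
#' product of per-read mixtures
#' \eqn{f P(R_k \mid major) + (1-f) P(R_k \mid minor)}, where \code{f} is
#' the probability of drawing a read from the higher-copy haplotype
#' (\code{f = 0.5} recovers the balanced diploid model, for which the two
#' orientations coincide).
#'
#' Priors: a site is a variant with probability \code{priorVariant}, and
#' heterozygous with probability \code{priorHetGivenVariant} given variant.
#'
#' @param logRef,logAlt numeric vectors of per-read log allele likelihoods.
#' @param strand optional character vector ("+"/"-") per read; when given,
#'   sites with significant allele-by-strand association (Fisher exact
#'   p-value below \code{config@strandBiasP}) are left uncalled.
#' @param config a \linkS4class{GenotyperConfig}.
#' @return A list with \code{genotype} ("0/0", "0/1", "1/1" or "uncalled"),
#'   \code{posterior} (named numeric, sums to 1), \code{depth} and
#'   \code{reason} (NA unless uncalled).
#' @examples
#' ## 15 alt reads, 5 ref reads with near-certain per-read likelihoods
#' lr <- c(rep(-10, 15), rep(-0.001, 5))
#' la <- c(rep(-0.001, 15), rep(-10, 5))
#' genotypeSite(lr, la, config = GenotyperConfig(f = 0.25))$genotype
#' @export
genotypeSite <- function(logRef, logAlt, strand = NULL,
                         config = GenotyperConfig()) {
    stopifnot(is(config, "GenotyperConfig"))
    n <- length(logRef)
    if (n != length(logAlt)) stop("logRef and logAlt must have equal length")
    uncalled <- function(reason, post = c(`0/0` = NA_real_, `0/1` = NA_real_,
                                          `1/1` = NA_real_))
        list(genotype = "uncalled", posterior = post, depth = n,
             reason = reason)
    if (n == 0L) return(uncalled("no informative reads"))
    if (n < config@minDepth) return(uncalled("below minimum depth"))

    if (!is.null(strand)) {
        supportsAlt <- logAlt > logRef
        tab <- table(factor(supportsAlt, levels = c(FALSE, TRUE)),
                     factor(strand, levels = c("+", "-")))
        if (all(dim(tab) == c(2L, 2L)) && all(rowSums(tab) > 0L)) {
            p <- fisher.test(tab)$p.value
            if (p < config@strandBiasP) return(uncalled("strand bias"))
        }
    }

    f <- config@f
    ll00 <- sum(logRef)
    ll11 <- sum(logAlt)
    ## per-read mixtures in log space for the two orientations
    mixRA <- .rowLogSumExp2(log(f) + logRef, log1p(-f) + logAlt)  # ref-major
    mixAR <- .rowLogSumExp2(log(f) + logAlt, log1p(-f) + logRef)  # alt-major
    ll01 <- .logsumexp(c(log(0.5) + sum(mixRA), log(0.5) + sum(mixAR)))

    pv <- config@priorVariant; ph <- config@priorHetGivenVariant
    lp <- c(`0/0` = ll00 + log1p(-pv),
            `0/1` = ll01 + log(pv) + log(ph),
            `1/1` = ll11 + log(pv) + log1p(-ph))
    post <- exp(lp - .logsumexp(lp))
    list(genotype = names(which.max(post)), posterior = post, depth = n,
         reason = NA_character_)
}

## elementwise log(exp(a) + exp(b))
.rowLogSumExp2 <- function(a, b) {
    m <- pmax(a, b)
    m + log1p(exp(pmin(a, b) - m))
}

#' Genotype a panel of known SNP sites and emit heterozygous calls
#'
#' Runs \code{\link{extractFragments}} over the sites of a population SNP
#' VCF, genotypes each site with \code{\link{genotypeSite}}, and returns
#' (and optionally writes) a VCF containing only the confident heterozygous
#' calls, suitable as input to an external phasing tool. Sites with no
#' coverage, below the depth threshold, or with strand bias are omitted.
#'
#' @param bam path to the indexed BAM.
#' @param fasta path to the indexed reference FASTA.
#' @param sitesVcf path to a VCF of known biallelic SNP sites (e.g. a
#'   population panel restricted to allele frequency above 0.1 percent).
#' @param config a \linkS4class{GenotyperConfig}.
#' @param region optional \code{GRanges} restriction.
#' @param outVcf optional output path; when given, the heterozygous-site
#'   VCF (FORMAT fields GT/DP/AD) is written there.
#' @param flank,hmm realignment window and pair-HMM settings.
#' @return Invisibly, a \code{DataFrame} with one row per called
#'   heterozygous site: \code{seqnames}, \code{pos}, \code{ref}, \code{alt},
#'   \code{depth}, \code{adRef}, \code{adAlt}, \code{posterior}.
#' @export
genotypeSites <- function(bam, fasta, sitesVcf, config = GenotyperConfig(),
                          region = NULL, outVcf = NULL, flank = 20L,
                          hmm = HmmParams()) {
    vcf <- VariantAnnotation::readVcf(sitesVcf)
    rr <- SummarizedExperiment::rowRanges(vcf)
    ref <- as.character(VariantAnnotation::ref(vcf))
    altL <- VariantAnnotation::alt(vcf)
    biallelic <- lengths(altL) == 1L
    alt <- rep(NA_character_, length(rr))
    alt[biallelic] <- as.character(unlist(altL[biallelic]))
    keep <- biallelic & nchar(ref) == 1L & !is.na(alt) & nchar(alt) == 1L &
        ref != alt
    sites <- GenomicRanges::granges(rr)[keep]
    S4Vectors::mcols(sites) <- DataFrame(ref = ref[keep], alt = alt[keep])
    if (!is.null(region))
        sites <- IRanges::subsetByOverlaps(sites, region)
    frags <- extractFragments(bam, fasta, sites, flank = flank, hmm = hmm,
                              mapqMin = config@mapqMin, region = region)

    rows <- vector("list", length(sites))
    bySite <- split(seq_len(nrow(frags)), frags$site)
    for (s in names(bySite)) {
        i <- bySite[[s]]
        g <- genotypeSite(frags$logRef[i], frags$logAlt[i],
                          strand = frags$strand[i], config = config)
        if (g$genotype != "0/1") next
        k <- as.integer(s)
        nAlt <- sum(frags$logAlt[i] > frags$logRef[i])
        rows[[k]] <- DataFrame(
            seqnames = as.character(GenomeInfoDb::seqnames(sites))[k],
            pos = GenomicRanges::start(sites)[k],
            ref = sites$ref[k], alt = sites$alt[k], depth = g$depth,
            adRef = g$depth - nAlt, adAlt = nAlt,
            posterior = unname(g$posterior["0/1"]))
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    het <- if (length(rows)) do.call(rbind, rows) else
        DataFrame(seqnames = character(0), pos = integer(0),
                  ref = character(0), alt = character(0), depth = integer(0),
                  adRef = integer(0), adAlt = integer(0),
                  posterior = numeric(0))
    if (!is.null(outVcf)) .writeHetVcf(het, fasta, outVcf)
    invisible(het)
}

## serialize heterozygous genotype calls as an unphased VCF 4.2
.writeHetVcf <- function(het, fasta, path, sample = "SAMPLE") {
    n <- nrow(het)
    gr <- GenomicRanges::GRanges(
        het$seqnames, IRanges::IRanges(het$pos, width = 1L))
    names(gr) <- if (n) paste0("site", seq_len(n)) else character(0)
    fai <- Rsamtools::scanFaIndex(
        if (is(fasta, "FaFile")) BiocGenerics::path(fasta) else fasta)
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(fai)
    GenomeInfoDb::seqlengths(gr) <- GenomeInfoDb::seqlengths(fai)
    hdr <- VariantAnnotation::VCFHeader(samples = sample)
    VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
        fileformat = DataFrame(Value = "VCFv4.2", row.names = "fileformat"))
    VariantAnnotation::geno(hdr) <- DataFrame(
        Number = c("1", "1", "R"), Type = c("String", "Integer", "Integer"),
        Description = c("Genotype", "Read depth",
                        "Allelic depths for the ref and alt alleles"),
        row.names = c("GT", "DP", "AD"))
    mk <- function(x) matrix(x, ncol = 1L, dimnames = list(names(gr), sample))
    ad <- mk(lapply(seq_len(n), function(i) c(het$adRef[i], het$adAlt[i])))
    v <- VariantAnnotation::VCF(
        rowRanges = gr,
        colData = DataFrame(Samples = 1L, row.names = sample),
        fixed = DataFrame(
            REF = Biostrings::DNAStringSet(het$ref),
            ALT = Biostrings::DNAStringSetList(as.list(het$alt)),
            QUAL = round(-10 * log10(pmax(1 - het$posterior, 1e-10)), 1),
            FILTER = rep("PASS", n)),
        geno = S4Vectors::SimpleList(GT = mk(rep("0/1", n)),
                                     DP = mk(het$depth), AD = ad))
    VariantAnnotation::header(v) <- hdr
    VariantAnnotation::writeVcf(v, path)
    invisible(path)
}
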