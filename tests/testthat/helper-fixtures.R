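# Shared synthetic fixtures, generated once per test session and cached.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, spec) {
    if (!exists(name, envir = .fixtureCache)) {
        fx <- makeFixture(spec, file.path(tempdir(), paste0("hsfx_", name)))
        assign(name, fx, envir = .fixtureCache)
    }
    get(name, envir = .fixtureCache)
}

# 100 kb diploid region, 40x, 5 kb reads, 10 clonal somatic mutations
smallFixture <- function() {
    cachedFixture("small", FixtureSpec(
        regionLength = 1e5, pi = 1e-3, nSomatic = 10,
        ccf = CCFPrior(rho = 1), alpha = 0.5, depth = 40,
        readLength = 5000, epsilon = 0.005, seed = 42))
}

smallCalls <- function() {
    if (!exists("smallCalls", envir = .fixtureCache)) {
        fx <- smallFixture()
        res <- callWindow(fx$bam, fx$fasta, fx$germlineVcf)
        assign("smallCalls", res, envir = .fixtureCache)
    }
    get("smallCalls", envir = .fixtureCache)
}

# a sites VCF emulating a population SNP panel: the fixture's true hets
# plus an equal number of hom-ref decoy positions
sitesVcfFor <- function(fx, seed = 9L) {
    path <- file.path(dirname(fx$fasta), "sites.vcf")
    if (file.exists(path)) return(path)
    g <- attr(fx, "genome")
    het <- g$het
    set.seed(seed)
    decoy <- sort(sample(setdiff(seq(50L, g$L - 50L), het$pos),
                         max(nrow(het), 50L)))
    decoyRef <- g$refSeq[decoy]
    decoyAlt <- vapply(decoyRef, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    pos <- c(het$pos, decoy)
    o <- order(pos)
    sites <- GenomicRanges::GRanges(
        rep("synth1", length(pos)), IRanges::IRanges(pos[o], width = 1L),
        ref = c(het$ref, decoyRef)[o], alt = c(het$alt, decoyAlt)[o])
    GenomeInfoDb::seqlengths(sites) <- g$L
    writeSitesVcf(sites, path)
    path
}
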