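# Copy-number-aware genotyping of known SNP sites.

test_that("genotype posteriors are coherent and match direct evaluation", {
    # all reads strongly support the reference
    g <- genotypeSite(rep(-1e-3, 20), rep(-8, 20))
    expect_equal(g$genotype, "0/0")
    expect_equal(sum(g$posterior), 1, tolerance = 1e-9)

    # 15 alt / 5 ref with near-certain reads at f = 0.25: heterozygous
    lr <- c(rep(-10, 15), rep(-1e-3, 5))
    la <- c(rep(-1e-3, 15), rep(-10, 5))
    cfg <- GenotyperConfig(f = 0.25)
    g <- genotypeSite(lr, la, config = cfg)
    expect_equal(g$genotype, "0/1")
    # direct evaluation of the three genotype likelihoods with the stated
    # priors, in plain arithmetic
    pR <- exp(lr); pA <- exp(la)
    l00 <- prod(pR); l11 <- prod(pA)
    l01 <- 0.5 * prod(0.25 * pR + 0.75 * pA) +
        0.5 * prod(0.25 * pA + 0.75 * pR)
    w <- c(l00 * (1 - 1e-3), l01 * 1e-3 * 2 / 3, l11 * 1e-3 * 1 / 3)
    expect_equal(unname(g$posterior), w / sum(w), tolerance = 1e-9)
})

test_that("f = 0.5 reduces the het likelihood to the balanced mixture", {
    set.seed(5)
    lr <- log(runif(12)); la <- log(runif(12))
    g <- genotypeSite(lr, la, config = GenotyperConfig(f = 0.5))
    balanced <- prod(0.5 * exp(lr) + 0.5 * exp(la))
    w <- c(prod(exp(lr)) * (1 - 1e-3), balanced * 1e-3 * 2 / 3,
           prod(exp(la)) * 1e-3 / 3)
    expect_equal(unname(g$posterior), w / sum(w), tolerance = 1e-9)
})

test_that("swapping allele roles swaps the homozygous posteriors exactly", {
    set.seed(6)
    lr <- log(runif(15)); la <- log(runif(15))
    # priors symmetric in the homozygous classes: P(0/0) = P(1/1) = 1/3
    cfg <- GenotyperConfig(f = 0.25, priorHetGivenVariant = 0.5,
                           priorVariant = 2 / 3)
    g1 <- genotypeSite(lr, la, config = cfg)
    g2 <- genotypeSite(la, lr, config = cfg)
    expect_equal(unname(g1$posterior["0/0"]), unname(g2$posterior["1/1"]),
                 tolerance = 1e-12)
    expect_equal(unname(g1$posterior["0/1"]), unname(g2$posterior["0/1"]),
                 tolerance = 1e-12)
})

test_that("degenerate sites are left uncalled with a reason", {
    g <- genotypeSite(numeric(0), numeric(0))
    expect_equal(g$genotype, "uncalled")
    expect_match(g$reason, "no informative reads")
    g <- genotypeSite(-1, -1)   # below minimum depth
    expect_equal(g$genotype, "uncalled")
    # one-sided strand support with allele association triggers the skip
    lr <- c(rep(-9, 10), rep(-1e-3, 10))
    la <- c(rep(-1e-3, 10), rep(-9, 10))
    strand <- c(rep("+", 10), rep("-", 10))
    g <- genotypeSite(lr, la, strand, GenotyperConfig(strandBiasP = 0.05))
    expect_equal(g$genotype, "uncalled")
    expect_match(g$reason, "strand bias")
})

test_that("genotypeSites recovers true hets with no false het calls", {
    fx <- smallFixture()
    g <- attr(fx, "genome")
    sitesPath <- sitesVcfFor(fx)
    het <- genotypeSites(fx$bam, fx$fasta, sitesPath,
                         outVcf = file.path(dirname(fx$fasta), "het_out.vcf"))
    trueHet <- attr(fx, "genome")$het$pos
    # recovery: at least 95% of the true het sites
    expect_gte(sum(het$pos %in% trueHet), floor(0.95 * length(trueHet)))
    # conservativeness: no het call at hom-ref decoy sites
    expect_equal(sum(!het$pos %in% trueHet), 0)
    # output VCF round-trips as valid input
    v <- VariantAnnotation::readVcf(file.path(dirname(fx$fasta),
                                              "het_out.vcf"))
    expect_equal(nrow(v), nrow(het))
    expect_true(all(VariantAnnotation::geno(v)$GT == "0/1"))
})

test_that("f = 0.25 outperforms the balanced genotyper under allele imbalance", {
    fx <- cachedFixture("loh", FixtureSpec(
        regionLength = 6e4, pi = 2e-3, nSomatic = 0, alpha = 0.5,
        depth = 40, readLength = 3000, epsilon = 0.005,
        hap0Fraction = 0.1, seed = 13))
    sitesPath <- sitesVcfFor(fx)
    hetSkewed <- genotypeSites(fx$bam, fx$fasta, sitesPath,
                               config = GenotyperConfig(f = 0.25))
    hetBalanced <- genotypeSites(fx$bam, fx$fasta, sitesPath,
                                 config = GenotyperConfig(f = 0.5))
    trueHet <- attr(fx, "genome")$het$pos
    recovered <- function(h) sum(h$pos %in% trueHet)
    expect_gt(recovered(hetSkewed), recovered(hetBalanced))
    # neither configuration invents het calls at hom sites
    expect_equal(sum(!hetSkewed$pos %in% trueHet), 0)
})
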