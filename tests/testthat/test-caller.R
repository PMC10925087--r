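# Somatic calling: callability, candidate discovery, classification with
# the CCF prior, filtering, and the end-to-end window caller.

test_that("callable rule enforces the per-haplotype and total depth bounds", {
    cfg <- CallerConfig()
    m <- findCallable(c(12, 9, 250, 10, 0), c(11, 100, 200, 390, 0), cfg)$mask
    expect_equal(m, c(TRUE, FALSE, FALSE, TRUE, FALSE))
    # merged intervals are 1-based closed GRanges over the callable runs
    r <- findCallable(c(12, 12, 9, 12), c(12, 12, 12, 12), cfg,
                      seqname = "c", offset = 101L)$regions
    expect_equal(GenomicRanges::start(r), c(101L, 104L))
    expect_equal(GenomicRanges::end(r), c(102L, 104L))
})

test_that("candidate discovery applies the >10% and >=3 thresholds", {
    mkCounts <- function(depth, alt, L = 1L) {
        m <- matrix(0L, 4, L)
        m[1L, ] <- depth - alt   # ref A
        m[3L, ] <- alt           # alt G
        m
    }
    cfg <- CallerConfig()
    hit <- function(depth, alt)
        nrow(discoverCandidates(mkCounts(depth, alt), matrix(0L, 4, 1),
                                "A", TRUE, cfg))
    expect_equal(hit(20, 3), 1L)    # 15% and >= 3: candidate
    expect_equal(hit(40, 3), 0L)    # 7.5%: fails the fraction rule
    expect_equal(hit(20, 2), 0L)    # 10% and 2 obs: fails both rules
    expect_equal(hit(29, 3), 1L)    # 10.3% and 3 obs: passes both
    # non-callable positions are never candidates
    expect_equal(nrow(discoverCandidates(mkCounts(20, 10), matrix(0L, 4, 1),
                                         "A", FALSE, cfg)), 0L)
    # the discovered alt is the modal non-reference base, ties to A<C<G<T
    m <- matrix(c(10L, 3L, 3L, 0L), 4, 1)   # C and G tie under ref A
    cand <- discoverCandidates(m, matrix(0L, 4, 1), "A", TRUE, cfg)
    expect_equal(cand$alt, "C")
})

test_that("candidate classification matches the fine-grid CCF oracle", {
    cfg <- CallerConfig(alpha = 0.5, ccf = CCFPrior(rho = 0.95, a = 2, b = 2,
                                                    nBins = 100L))
    # 16 reads on the haplotype: 11 decisive alt, 5 decisive ref
    lr <- c(rep(-9, 11), rep(-1e-3, 5))
    la <- c(rep(-1e-3, 11), rep(-9, 5))
    got <- classifyCandidate(lr, la, cfg)
    expect_equal(as.character(which.max(got$posterior)), "1")  # somatic first
    # fine-grid oracle for the somatic likelihood, then the posterior
    llSom <- oracleSomaticLik(lr, la, 0.5, 0.95, 2, 2, nBins = 1e5)
    w <- c(exp(llSom) * cfg@muPrior,
           prod(exp(la)) * cfg@piPrior,
           prod(exp(lr)) * (1 - cfg@muPrior - cfg@piPrior))
    pSom <- w[1] / sum(w)
    expect_equal(got$posterior[["somatic"]], pSom, tolerance = 1e-4)
    # integration convergence: 100 bins vs 10^5 bins within 1e-3
    set.seed(19)
    for (k in 1:25) {
        n <- sample(10:30, 1)
        nAlt <- sample(0:n, 1)
        lr <- c(rep(log(2e-3), nAlt), rep(log(0.99), n - nAlt)) +
            rnorm(n, 0, 0.2)
        la <- c(rep(log(0.99), nAlt), rep(log(2e-3), n - nAlt)) +
            rnorm(n, 0, 0.2)
        alpha <- runif(1, 0.2, 0.8)
        c100 <- classifyCandidate(lr, la, CallerConfig(alpha = alpha))
        cOra <- oracleSomaticLik(lr, la, alpha, 0.95, 2, 2, nBins = 1e5)
        w <- c(exp(cOra) * 1e-5, prod(exp(la)) * 1e-3,
               prod(exp(lr)) * (1 - 1e-5 - 1e-3))
        expect_lt(abs(c100$posterior[["somatic"]] - w[1] / sum(w)), 1e-3)
    }
})

test_that("rho = 1 reduces the somatic likelihood to the clonal form", {
    set.seed(23)
    lr <- log(runif(18)); la <- log(runif(18))
    cfg <- CallerConfig(alpha = 0.4, ccf = CCFPrior(rho = 1))
    got <- classifyCandidate(lr, la, cfg)
    clonal <- sum(log(exp(lr) * (1 - 0.4) + exp(la) * 0.4))
    expect_equal(got$llSomatic, clonal, tolerance = 1e-9)
    # an all-alt candidate is a het, not a mutation: no reference
    # contamination signal on the haplotype
    lrA <- rep(-9, 20); laA <- rep(-1e-3, 20)
    cl <- classifyCandidate(lrA, laA, CallerConfig(alpha = 0.5))
    expect_gt(cl$posterior[["het"]], cl$posterior[["somatic"]])
    expect_error(classifyCandidate(numeric(0), numeric(0)), "no informative")
})

test_that("increasing clonal mass raises p_somatic for a clonal candidate", {
    lr <- c(rep(-9, 10), rep(-1e-3, 10))
    la <- c(rep(-1e-3, 10), rep(-9, 10))
    lls <- vapply(c(0.5, 0.8, 0.95, 1), function(rho)
        classifyCandidate(lr, la, CallerConfig(
            alpha = 0.5, ccf = CCFPrior(rho = rho)))$llSomatic,
        numeric(1))
    expect_true(all(diff(lls) > 0))
})

test_that("each filter fires exactly on its boundary condition", {
    cfg <- CallerConfig()
    base <- data.frame(qual = 35, otherHapObs = 0, otherHapDepth = 20,
                       altFwd = 5, altRev = 6, refFwd = 4, refRev = 5,
                       dp0 = 15, dp1 = 15, artifactFrac = 0)
    expect_equal(applyFilters(base, cfg), "PASS")
    # other-haplotype control: > 2 observations, or > 20% of its reads
    s <- base; s$otherHapObs <- 3
    expect_match(applyFilters(s, cfg), "MaxOtherHaplotypeObservations")
    s <- base; s$otherHapObs <- 2
    expect_equal(applyFilters(s, cfg), "PASS")   # 2 of 20 = 10%: allowed
    s <- base; s$otherHapObs <- 2; s$otherHapDepth <- 9   # 22%
    expect_match(applyFilters(s, cfg), "MaxOtherHaplotypeObservations")
    # strand presence
    s <- base; s$altRev <- 0
    expect_match(applyFilters(s, cfg), "MinObsPerStrand")
    # alignment artifact
    s <- base; s$artifactFrac <- 0.6
    expect_match(applyFilters(s, cfg), "PossibleAlignmentArtifact")
    # low quality
    s <- base; s$qual <- 19.9
    expect_match(applyFilters(s, cfg), "LowQual")
    # haplotype depth
    s <- base; s$dp1 <- 9
    expect_match(applyFilters(s, cfg), "MinHaplotypeDepth")
    # strand bias: strong allele-by-strand association
    s <- base; s$altFwd <- 30; s$altRev <- 0; s$refFwd <- 0; s$refRev <- 30
    expect_match(applyFilters(s, cfg), "StrandBias")
    # filters are independent: several can fire together, idempotently
    s <- base; s$qual <- 5; s$dp0 <- 3; s$altRev <- 0
    f1 <- applyFilters(s, cfg)
    expect_true(all(c("LowQual", "MinHaplotypeDepth", "MinObsPerStrand") %in%
                    strsplit(f1, ";")[[1]]))
    expect_identical(applyFilters(s, cfg), f1)
})

test_that("callWindow calls clonal mutations and respects containment", {
    fx <- smallFixture()
    res <- smallCalls()
    cc <- calls(res)
    tr <- readSomaticTruth(fx$somaticVcf)
    pass <- cc[cc$filter == "PASS" & cc$qual >= 20]
    inCallable <- IRanges::overlapsAny(tr, callableRegions(res))
    tp <- sum(GenomicRanges::start(pass) %in% GenomicRanges::start(tr))
    expect_gte(tp / sum(inCallable), 0.8)
    expect_gte(tp / length(pass), 0.9)
    # calls are confined to callable intervals (exact containment)
    expect_true(all(IRanges::overlapsAny(cc, callableRegions(res))))
    # deterministic: rerunning yields identical calls
    res2 <- callWindow(fx$bam, fx$fasta, fx$germlineVcf)
    expect_identical(as.data.frame(calls(res2)), as.data.frame(cc))
})

test_that("calls VCF round-trips bit-exactly and BED export is well-formed", {
    res <- smallCalls()
    vcf <- file.path(tempdir(), "calls_roundtrip.vcf")
    writeCallsVcf(res, vcf)
    back <- readCallsVcf(vcf)
    cc <- calls(res)
    expect_equal(GenomicRanges::start(back), GenomicRanges::start(cc))
    for (col in c("ref", "alt", "hap", "qual", "filter", "psom", "phet",
                  "pref", "dp0", "dp1", "altObs", "otherHapObs", "altFwd",
                  "altRev", "refFwd", "refRev", "artifactFrac", "bothHap")) {
        expect_identical(
            unname(as.vector(S4Vectors::mcols(back)[[col]])),
            unname(as.vector(S4Vectors::mcols(cc)[[col]])),
            info = col)
    }
    bed <- file.path(tempdir(), "callable.bed")
    writeCallableBed(res, bed)
    imported <- rtracklayer::import(bed, format = "BED")
    expect_equal(sum(GenomicRanges::width(imported)),
                 sum(GenomicRanges::width(callableRegions(res))))
})
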