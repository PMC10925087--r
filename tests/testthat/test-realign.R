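# Banded quality-aware pair-HMM and read-allele likelihood extraction.

test_that("forward probability equals exhaustive path enumeration", {
    set.seed(31)
    bases <- c("A", "C", "G", "T")
    cases <- list()
    for (k in 1:40) {
        n <- sample(1:6, 1); L <- sample(n:8, 1)
        cases[[k]] <- list(
            read = paste(sample(bases, n, TRUE), collapse = ""),
            qual = sample(5:40, n, TRUE),
            hap = paste(sample(bases, L, TRUE), collapse = ""))
    }
    # plus exact-match and all-mismatch corners
    cases <- c(cases, list(
        list(read = "ACGTAC", qual = rep(40L, 6), hap = "ACGTAC"),
        list(read = "AAAAAA", qual = rep(10L, 6), hap = "CCCCCCCC"),
        list(read = "A", qual = 20L, hap = "T")))
    hm <- HmmParams(band = 20L)   # band wide enough to be unrestricted
    for (cs in cases) {
        got <- realignLikelihood(cs$read, cs$qual, cs$hap, hm)
        want <- oraclePhmm(cs$read, cs$qual, cs$hap,
                           go = hm@gapOpen, ge = hm@gapExtend)
        expect_equal(got, want, tolerance = 1e-10)
    }
})

test_that("perfect matches score near zero and alt alleles are discriminated", {
    read <- "ACGTACGTACGTACGTACGT"
    q <- rep(40L, 20)
    lp <- realignLikelihood(read, q, read)
    # bounded below by the gap-free path mass at q = 40
    expect_gt(lp, 20 * log(1 - 1e-4) + log(1e-3))
    expect_lt(lp, 0)
    # a high-quality alt base prefers the alt haplotype
    alt <- read; substr(alt, 10, 10) <- "T"
    lpRef <- realignLikelihood(alt, q, read)
    lpAlt <- realignLikelihood(alt, q, alt)
    expect_gt(lpAlt, lpRef)
    # lowering the quality of the discriminating base shrinks the margin
    q2 <- q; q2[10] <- 5L
    margin40 <- lpAlt - lpRef
    margin5 <- realignLikelihood(alt, q2, alt) -
        realignLikelihood(alt, q2, read)
    expect_lt(margin5, margin40)
    expect_gt(margin5, 0)
})

test_that("likelihood is invariant under reverse complement of read and window", {
    set.seed(77)
    bases <- c("A", "C", "G", "T")
    rc <- function(s) {
        comp <- c(A = "T", C = "G", G = "C", T = "A")
        paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
    }
    for (k in 1:10) {
        n <- sample(5:15, 1); L <- n + sample(0:6, 1)
        read <- paste(sample(bases, n, TRUE), collapse = "")
        hap <- paste(sample(bases, L, TRUE), collapse = "")
        q <- sample(10:40, n, TRUE)
        expect_equal(realignLikelihood(read, q, hap),
                     realignLikelihood(rc(read), rev(q), rc(hap)),
                     tolerance = 1e-12)
    }
})

test_that("degenerate inputs raise explicit errors", {
    expect_error(realignLikelihood("", integer(0), "ACGT"), "empty read")
    expect_error(realignLikelihood("ACGT", rep(30L, 4), ""), "empty haplotype")
    expect_error(realignLikelihood(strrep("A", 50), rep(30L, 50), "ACGT",
                                   HmmParams(band = 2L)), "band overflow")
    expect_error(realignLikelihood("ACGT", rep(30L, 2), "ACGT"),
                 "quality length")
})

test_that("extractFragments recovers the true allele on synthetic reads", {
    fx <- smallFixture()
    g <- attr(fx, "genome")
    het <- g$het
    sites <- GenomicRanges::GRanges(
        rep("synth1", nrow(het)), IRanges::IRanges(het$pos, width = 1L),
        ref = het$ref, alt = het$alt)
    frags <- extractFragments(fx$bam, fx$fasta, sites)
    expect_true(all(c("qname", "site", "logRef", "logAlt") %in%
                    colnames(frags)))
    expect_true(all(frags$logRef <= 0 & frags$logAlt <= 0))
    expect_true(all(is.finite(frags$logRef) & is.finite(frags$logAlt)))
    # sign of logAlt - logRef recovers each read's true allele; the truth
    # is each read's haplotype vs the haplotype carrying the alt
    truth <- attr(fx, "reads")
    hapOf <- setNames(truth$hap, truth$qname)
    altHap <- het$hap[frags$site]
    carriesAlt <- hapOf[frags$qname] == altHap
    agree <- (frags$logAlt > frags$logRef) == carriesAlt
    expect_gt(mean(agree), 0.99)
    # malformed site records are rejected
    bad <- GenomicRanges::GRanges("synth1", IRanges::IRanges(500, width = 1),
                                  ref = g$refSeq[500], alt = g$refSeq[500])
    expect_error(extractFragments(fx$bam, fx$fasta, bad), "malformed")
    # a reference mismatch between FASTA and site record is reported
    wrongRef <- setdiff(c("A", "C", "G", "T"), g$refSeq[500])[1:2]
    bad2 <- GenomicRanges::GRanges("synth1", IRanges::IRanges(500, width = 1),
                                   ref = wrongRef[1], alt = wrongRef[2])
    expect_error(extractFragments(fx$bam, fx$fasta, bad2),
                 "reference mismatch")
})
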