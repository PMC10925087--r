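# Tumour mutation burden and the 96-context mutation spectrum.

test_that("TMB is PASS+QUAL calls per callable megabase", {
    bed <- GenomicRanges::GRanges("r", IRanges::IRanges(1, 1e7))
    mkCalls <- function(n, qual = 45, filter = "PASS")
        GenomicRanges::GRanges(rep("r", n),
                               IRanges::IRanges(seq_len(n) * 10, width = 1),
                               qual = rep(qual, n), filter = rep(filter, n))
    expect_equal(estimateTMB(mkCalls(0), bed)$tmb, 0)
    expect_equal(estimateTMB(mkCalls(140), bed)$tmb, 14)
    # filtered or low-qual calls do not count
    expect_equal(estimateTMB(mkCalls(50, filter = "LowQual"), bed)$tmb, 0)
    expect_equal(estimateTMB(mkCalls(50, qual = 19), bed)$tmb, 0)
    # linearity: doubling calls and footprint leaves TMB unchanged
    bed2 <- GenomicRanges::GRanges("r", IRanges::IRanges(1, 2e7))
    expect_equal(estimateTMB(mkCalls(280), bed2)$tmb,
                 estimateTMB(mkCalls(140), bed)$tmb)
    # empty footprint is an error
    expect_error(estimateTMB(mkCalls(1), GenomicRanges::GRanges()),
                 "undefined TMB")
})

test_that("spectrum labels, canonicalization and cosine identities hold", {
    ctx <- spectrumContexts()
    expect_length(ctx, 96)
    expect_length(unique(ctx), 96)
    expect_equal(ctx[1], "A[C>A]A")

    # reference with a known local context: positions 1..9
    dir <- file.path(tempdir(), "spec_ctx")
    dir.create(dir, showWarnings = FALSE)
    fa <- file.path(dir, "ctx.fa")
    # sequence: A G T A C T T C T ; G>A at position 2 has 5'-A G T-3',
    # which canonicalizes (reverse complement) to A C T with C>T
    Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(c(ctxseq = "AGTACTTCT")), fa)
    Rsamtools::indexFa(fa)
    gr <- GenomicRanges::GRanges("ctxseq", IRanges::IRanges(2, width = 1),
                                 ref = "G", alt = "A", qual = 60,
                                 filter = "PASS")
    sp <- mutationSpectrum(gr, fa)
    expect_equal(sum(sp), 1)
    expect_equal(unname(sp["A[C>T]T"]), 1)
    # a pyrimidine-reference call maps directly: C>T at position 8 (T C T)
    gr2 <- GenomicRanges::GRanges("ctxseq", IRanges::IRanges(8, width = 1),
                                  ref = "C", alt = "T", qual = 60,
                                  filter = "PASS")
    sp2 <- mutationSpectrum(gr2, fa)
    expect_equal(unname(sp2["T[C>T]T"]), 1)
    # strand canonicalization is an involution: applying the purine->
    # pyrimidine mapping to an already-pyrimidine context changes nothing,
    # and every purine-reference SNV lands in the 96-context space
    expect_equal(sum(sp), sum(sp2))

    # cosine identities
    expect_equal(cosineSimilarity(sp, sp), 1)
    expect_equal(cosineSimilarity(c(1, 1, 0, 0), c(0, 0, 1, 2)), 0)
    expect_equal(cosineSimilarity(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.5)
    expect_error(cosineSimilarity(c(0, 0), c(1, 1)), "zero")
})

test_that("a sampled call set reproduces its generating spectrum", {
    # build a reference, enumerate contexts, and sample 1000 mutations from
    # a concentrated spectrum (UV-like: C>T in T_T / C_T contexts)
    set.seed(29)
    L <- 2e4
    dir <- file.path(tempdir(), "spec_sample")
    dir.create(dir, showWarnings = FALSE)
    fa <- file.path(dir, "ref.fa")
    seqc <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(c(samp = seqc)), fa)
    Rsamtools::indexFa(fa)
    chars <- strsplit(seqc, "")[[1]]
    gen <- setNames(numeric(96), spectrumContexts())
    gen["T[C>T]T"] <- 0.6; gen["T[C>T]C"] <- 0.25; gen["C[C>T]T"] <- 0.1
    gen["A[T>G]A"] <- 0.05
    # positions whose pyrimidine-strand context matches each target
    rcBase <- c(A = "T", C = "G", G = "C", T = "A")
    ctxAt <- function(i) {
        tri <- chars[(i - 1):(i + 1)]
        if (tri[2] %in% c("C", "T"))
            paste0(tri[1], "[", tri[2], ">*]", tri[3])
        else
            paste0(rcBase[tri[3]], "[", rcBase[tri[2]], ">*]", rcBase[tri[1]])
    }
    allCtx <- vapply(2:(L - 1), ctxAt, character(1))
    draws <- sample(names(gen)[gen > 0], 1000, TRUE, prob = gen[gen > 0])
    pos <- ref <- alt <- character(0)
    posv <- integer(0); refv <- altv <- character(0)
    for (d in draws) {
        want <- sub("\\[([CT])>([ACGT])\\]", "[\\1>*]", d)
        cands <- which(allCtx == want) + 1L
        i <- sample(cands, 1)
        posv <- c(posv, i)
        pyr <- chars[i] %in% c("C", "T")
        mutTo <- sub(".*>([ACGT])\\].*", "\\1", d)
        refv <- c(refv, chars[i])
        altv <- c(altv, if (pyr) mutTo else unname(rcBase[mutTo]))
    }
    gr <- GenomicRanges::GRanges(rep("samp", length(posv)),
                                 IRanges::IRanges(posv, width = 1),
                                 ref = refv, alt = altv,
                                 qual = rep(60, length(posv)),
                                 filter = rep("PASS", length(posv)))
    sp <- mutationSpectrum(gr, fa)
    expect_equal(sum(sp), 1000)
    expect_gt(cosineSimilarity(sp, gen), 0.98)
})
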