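# Pileup simulator and the closed-form phased/unphased classifiers.

test_that("posteriors match the direct-evaluation oracle on the worked example", {
    # 29 reads, 12 supporting the alternate base: ambiguous without phasing
    u <- classifyUnphased(12, 17, alpha = 0.5, epsilon = 0.01,
                          mu = 5e-6, pi = 1e-3)
    expect_equal(u$p_somatic, 1.3595270209e-03, tolerance = 1e-8)
    expect_equal(u$p_het, 9.9864047298e-01, tolerance = 1e-8)
    expect_equal(u$p_reference, 4.5148222865e-13, tolerance = 1e-6)
    expect_equal(as.character(u$label), "het")
    # the same site split by haplotype: 11 alt / 5 ref on one haplotype
    p <- classifyPhased(11, 5, alpha = 0.5, epsilon = 0.01,
                        mu = 5e-6, pi = 1e-3)
    expect_equal(p$p_somatic, 9.9882783782e-01, tolerance = 1e-8)
    expect_equal(as.character(p$label), "somatic")
})

test_that("classifier edge behaviour is correct", {
    # no alternate support: reference
    expect_equal(as.character(
        classifyUnphased(0, 50, 0.5, 0.01, 1e-5, 1e-3)$label), "reference")
    # pure alternate support on a haplotype: het
    expect_equal(as.character(
        classifyPhased(30, 0, 0.5, 0.01)$label), "het")
    # het likelihood is Bin(a; n, 1/2) for any epsilon (the eps terms cancel):
    # posteriors with different eps keep the same het likelihood factor
    for (eps in c(0, 0.02, 0.1)) {
        u <- classifyUnphased(10, 10, alpha = 0.3, epsilon = eps)
        direct <- oracleClassify(10, 10, 0.3, eps, 5e-6, 1e-3, FALSE)
        expect_equal(u$p_het, unname(direct["het"]), tolerance = 1e-9)
    }
    # undefined site
    expect_error(classifyUnphased(0, 0, 0.5, 0.01), "undefined")
    expect_error(classifyPhased(1, 1, 1.5, 0.01), "out of range")
})

test_that("log-space posteriors agree with the oracle over random tuples", {
    set.seed(101)
    for (k in seq_len(1000)) {
        n <- sample(1:150, 1)
        a <- sample(0:n, 1); r <- n - a
        alpha <- runif(1); eps <- runif(1, 1e-4, 0.2)
        mu <- 10^runif(1, -8, -3); pi <- 10^runif(1, -5, -2)
        phased <- k %% 2 == 0
        got <- if (phased) classifyPhased(a, r, alpha, eps, mu, pi)
               else classifyUnphased(a, r, alpha, eps, mu, pi)
        want <- oracleClassify(a, r, alpha, eps, mu, pi, phased)
        for (cls in 1:3) {
            w <- unname(want[cls])
            g <- c(got$p_somatic, got$p_het, got$p_reference)[cls]
            if (w > 1e-280)   # below that the plain-arithmetic oracle underflows
                expect_lt(abs(g - w) / w, 1e-6)
        }
    }
})

test_that("posteriors normalise and are monotone in the expected directions", {
    grid <- expand.grid(a = 0:60, r = c(0:10, 20, 50, 200))
    grid <- grid[grid$a + grid$r >= 1, ]
    for (alpha in c(0.2, 0.5, 0.8)) {
        u <- classifyUnphased(grid$a, grid$r, alpha, 0.01)
        p <- classifyPhased(grid$a, grid$r, alpha, 0.01)
        expect_true(all(abs(u$p_somatic + u$p_het + u$p_reference - 1) < 1e-9))
        expect_true(all(abs(p$p_somatic + p$p_het + p$p_reference - 1) < 1e-9))
    }
    # for fixed r, phased p_somatic rises out of the reference regime and
    # falls into the het regime (unimodal); p_reference is non-increasing
    r <- 20
    p <- classifyPhased(0:80, rep(r, 81), alpha = 0.5, epsilon = 0.01)
    ps <- p$p_somatic
    peak <- which.max(ps)
    expect_true(all(diff(ps[seq_len(peak)]) >= -1e-12))
    expect_true(all(diff(ps[peak:81]) <= 1e-12))
    expect_true(all(diff(p$p_reference) <= 1e-12))
})

test_that("at alpha = 1 phased somatic:het posterior odds equal mu:pi exactly", {
    mu <- 3e-6; pi <- 2e-3
    for (ar in list(c(10, 5), c(30, 0), c(1, 7))) {
        p <- classifyPhased(ar[1], ar[2], alpha = 1, epsilon = 0.01,
                            mu = mu, pi = pi)
        expect_equal(p$p_somatic / p$p_het, mu / pi, tolerance = 1e-9)
    }
})

test_that("simPileup honours its degenerate and rate contracts", {
    # no variation, no errors: everything reference with zero alt reads
    sp0 <- simPileup(SimParams(G = 5000, lambda = 30, epsilon = 0, mu = 0,
                               pi = 0, seed = 5))
    expect_true(all(sp0$a == 0))
    expect_true(all(sp0$label == "reference"))
    expect_true(all(sp0$a0 == 0 & sp0$a1 == 0))
    # het sites appear at rate pi per haplotype: ~2*pi*G sites in total,
    # within a 99% binomial interval
    G <- 1e6
    sp <- simPileup(SimParams(G = G, lambda = 10, pi = 1e-3, mu = 0,
                              seed = 11))
    nh <- sum(sp$label == "het")
    expval <- 2 * 1e-3 * G
    halfwidth <- qnorm(0.995) * sqrt(expval)
    expect_gt(nh, expval - halfwidth)
    expect_lt(nh, expval + halfwidth)
    # determinism: identical stream under the same seed
    sp2 <- simPileup(SimParams(G = G, lambda = 10, pi = 1e-3, mu = 0,
                               seed = 11))
    expect_identical(sp$a, sp2$a)
    expect_identical(sp$label, sp2$label)
    # count consistency: phased counts decompose the total depth
    expect_true(all(sp$d == sp$d0 + sp$d1))
    expect_true(all(sp$a + sp$r <= sp$d))
    # invalid parameters rejected
    expect_error(simPileup(SimParams(G = 100, lambda = 10, mu = 0.6, pi = 0.5)))
})

test_that("evaluateCalls computes precision/recall/F1 with documented conventions", {
    r <- evaluateCalls(c("somatic", "somatic", "het", "somatic"),
                       c("somatic", "somatic", "somatic", "reference"))
    expect_equal(r$precision, 2 / 3)
    expect_equal(r$recall, 2 / 3)
    expect_equal(r$f1, 2 / 3)
    # all correct
    expect_equal(evaluateCalls(c("somatic", "het"), c("somatic", "het"))$f1, 1)
    # nothing to find, nothing found
    expect_equal(evaluateCalls(c("het", "reference"), c("het", "het"))$f1, 1)
    # positives exist but none predicted
    expect_equal(evaluateCalls(c("somatic"), c("het"))$f1, 0)
})

test_that("phased classification dominates unphased across a coarse sweep", {
    sw <- puritySweep(depths = c(30, 60), epsilons = 0.01,
                      purities = c(0.2, 0.5, 0.8),
                      params = SimParams(G = 5e5, mu = 2e-5, seed = 17))
    wide <- merge(subset(sw, mode == "phased"),
                  subset(sw, mode == "unphased"),
                  by = c("depth", "error_rate", "purity"))
    expect_true(all(wide$f1.x >= wide$f1.y - 0.02))
    expect_true(all(sw$n_truth_somatic > 0))
    # CSV emission round-trips
    csv <- tempfile(fileext = ".csv")
    sw2 <- puritySweep(30, 0.01, 0.5, SimParams(G = 1e5, mu = 2e-5, seed = 1),
                       csv = csv)
    expect_equal(read.csv(csv)$f1, sw2$f1)
})
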