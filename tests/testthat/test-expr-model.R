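mc_from <- function(y, condition, replicate_class = NULL, experiment = NULL) {
    n <- ncol(y)
    if (is.null(colnames(y))) colnames(y) <- paste0("s", seq_len(n))
    if (is.null(rownames(y))) rownames(y) <- paste0("p", seq_len(nrow(y)))
    cd <- data.frame(sample = colnames(y), condition = condition,
                     stringsAsFactors = FALSE)
    if (!is.null(replicate_class)) cd$replicate_class <- replicate_class
    if (!is.null(experiment)) cd$experiment <- experiment
    MoleculeCounts(y, cd)
}

test_that("molecules-per-million normalization is exact and equivariant", {
    one <- normalizeMpm(matrix(7, 1, 1))
    expect_equal(as.vector(one), 1e6)

    y <- matrix(c(1, 1, 2), 3, 1)
    expect_equal(as.vector(normalizeMpm(y)), c(250000, 250000, 500000))

    set.seed(3)
    y2 <- matrix(rpois(30, 50), 10, 3)
    mpm <- normalizeMpm(y2)
    expect_equal(colSums(mpm), rep(1e6, 3))
    perm <- sample(10)
    expect_equal(normalizeMpm(y2[perm, ]), mpm[perm, ])
    ## rescaling a replicate leaves its mpm column unchanged
    y3 <- y2; y3[, 2] <- y3[, 2] * 17L
    expect_equal(normalizeMpm(y3)[, 2], mpm[, 2])

    y4 <- cbind(y2, 0)
    expect_warning(m4 <- normalizeMpm(y4), "zero-depth")
    expect_equal(ncol(m4), 3L)
})

test_that("probe-bias covariate captures systematic class differences", {
    set.seed(4)
    base <- matrix(rep(c(100, 400, 900, 1600), 4), 4, 4)
    cd <- list(condition = rep(c("c1", "c2"), each = 2),
               class = rep(c("A", "B"), 2))

    ## identical replicates -> zero covariate
    mc0 <- mc_from(base, cd$condition, cd$class)
    expect_equal(unname(estimateBias(mc0)), rep(0, 4))

    ## probe 1 doubled in class A in both conditions -> x1 = log(2)/2 + centering
    yb <- base
    yb[1, cd$class == "A"] <- yb[1, cd$class == "A"] * 2L
    mcb <- mc_from(yb, cd$condition, cd$class)
    x <- estimateBias(mcb)
    expect_equal(mean(x), 0)
    ## compute the expected value by direct plug-in of the definition
    mpm <- normalizeMpm(molecules(mcb))
    lg <- log(1 + mpm)
    raw <- sapply(c("c1", "c2"), function(cc) {
        A <- cd$condition == cc & cd$class == "A"
        B <- cd$condition == cc & cd$class == "B"
        0.5 * (rowMeans(lg[, A, drop = FALSE]) - rowMeans(lg[, B, drop = FALSE]))
    })
    want <- rowMeans(raw); want <- want - mean(want)
    expect_equal(unname(x), unname(want))
    expect_gt(x[1], 0.25)   # close to log(2)/2, minus centering

    ## opposite-sign class effects across conditions cancel in expectation
    yc <- base
    yc[1, cd$class == "A" & cd$condition == "c1"] <-
        yc[1, cd$class == "A" & cd$condition == "c1"] * 2L
    yc[1, cd$class == "B" & cd$condition == "c2"] <-
        yc[1, cd$class == "B" & cd$condition == "c2"] * 2L
    xc <- estimateBias(mc_from(yc, cd$condition, cd$class))
    expect_lt(abs(xc[1]), abs(x[1]) / 2)

    ## single replicate class -> all-zero covariate
    mc1 <- mc_from(base, cd$condition)
    expect_equal(unname(estimateBias(mc1)), rep(0, 4))
})

test_that("posterior matches 2-D grid integration on a two-probe fit", {
    ## two probes, three replicates: enough data to identify the dispersion,
    ## so both inference routes must agree tightly
    y <- matrix(c(28L, 72L,
                  33L, 67L,
                  30L, 70L), 2, 3)
    mc <- mc_from(y, "c1")
    fit <- fitCondition(mc, "c1", config = mcmcConfig(seed = 5))
    got <- mean(exp(muSamples(fit)[, 1]))

    ## independent oracle: given phi the likelihood factorises over probes,
    ## so E[exp(mu1)] needs only 1-D integrals per phi grid point
    N <- colSums(y); mu0 <- log(1 / 2); mu_sd <- 5
    mugrid <- seq(-7, 1, length.out = 1600)
    dmu <- diff(mugrid)[1]
    phigrid <- exp(seq(log(0.001), log(50000), length.out = 600))
    dlphi <- diff(log(phigrid))[1]
    prior_phi <- 2 / (pi * 5 * (1 + (phigrid / 5)^2))   # half-Cauchy(0, 5)
    lik <- function(p, phi) {
        L <- dnorm(mugrid, mu0, mu_sd)
        for (r in seq_len(ncol(y)))
            L <- L * dnbinom(y[p, r], mu = N[r] * exp(mugrid), size = phi)
        L
    }
    num <- den <- 0
    for (i in seq_along(phigrid)) {
        L1 <- lik(1, phigrid[i]); L2 <- lik(2, phigrid[i])
        w <- prior_phi[i] * phigrid[i] * dlphi        # log-grid Jacobian
        den <- den + w * sum(L1) * sum(L2) * dmu^2
        num <- num + w * sum(exp(mugrid) * L1) * sum(L2) * dmu^2
    }
    oracle <- num / den
    expect_equal(got, oracle, tolerance = 0.03)
    ## and the point estimate sits near the pooled plug-in fraction
    expect_equal(got, sum(y[1, ]) / sum(N), tolerance = 0.1)
})

test_that("near-Poisson data drive the dispersion posterior up without hurting mu", {
    set.seed(6)
    P <- 20
    f <- rep(1 / P, P)
    y <- matrix(rpois(P * 4, 2000 * f), P, 4)   # Poisson = infinite-phi limit
    mc <- mc_from(y, "c1")
    fit <- fitCondition(mc, "c1", config = mcmcConfig(seed = 6))
    expect_gt(median(fit@phi), 50)
    expect_equal(unname(colMeans(muSamples(fit))), rep(log(1 / P), P),
                 tolerance = 0.1)
})

test_that("differential expression is an exact paired contrast", {
    set.seed(7)
    S <- 100; P <- 5
    mu <- matrix(rnorm(S * P), S, P,
                 dimnames = list(NULL, paste0("p", 1:P)))
    mk <- function(m, cond) new("PosteriorFit", condition = cond,
                                probes = colnames(m), mu = m,
                                lambda = matrix(0, S, 1),
                                phi = matrix(1, S, 1), bias = rep(0, P),
                                diagnostics = data.frame())
    fit <- mk(mu, "a")
    self <- differentialExpression(fit, fit)
    expect_true(all(deSamples(self) == 0))

    ## +1 natural-log shift in every mu_A = +1/ln2 log2 units
    shifted <- differentialExpression(mk(mu + 1, "a2"), fit)
    expect_equal(deSamples(shifted), matrix(1 / log(2), S, P,
                                            dimnames = dimnames(mu)),
                 tolerance = 1e-12)

    ## probe-set mismatch
    bad <- mk(mu[, 1:3], "b")
    expect_error(differentialExpression(fit, bad), "probe sets")
})

test_that("gene aggregation averages posterior samples across probes", {
    S <- 50
    de <- new("DeEstimate",
              samples = cbind(pA = rep(1, S), pB = rep(3, S), pC = rep(5, S)),
              units = c("pA", "pB", "pC"), quantity = "log2 fold change")
    map <- c(pA = "g1", pB = "g1", pC = "g2")

    g <- geneSummary(de, map)
    tab <- deTable(g)
    expect_equal(tab$unit, c("g1", "g2"))
    expect_equal(tab$mean, c(2, 5))       # mean of (1, 3); single probe passes
    expect_true(all(tab$lower <= tab$mean & tab$mean <= tab$upper))

    expect_error(geneSummary(de, map[1:2]), "unmapped")

    ## gene-level CI is tighter than the median probe-level CI when probe
    ## samples are independent
    set.seed(8)
    noisy <- new("DeEstimate",
                 samples = matrix(rnorm(S * 6), S, 6,
                                  dimnames = list(NULL, paste0("p", 1:6))),
                 units = paste0("p", 1:6), quantity = "log2 fold change")
    gmap <- setNames(rep("g1", 6), paste0("p", 1:6))
    gt <- deTable(geneSummary(noisy, gmap))
    pt <- deTable(noisy)
    expect_lt(gt$upper - gt$lower, median(pt$upper - pt$lower))
})

test_that("relative expression reports gene-level log2(1 + mpm)", {
    S <- 40
    mu <- cbind(p1 = rep(log(0.2), S), p2 = rep(log(0.2), S),
                p3 = rep(log(0.05), S))
    fit <- new("PosteriorFit", condition = "c1", probes = colnames(mu),
               mu = mu, lambda = matrix(0, S, 1), phi = matrix(1, S, 1),
               bias = rep(0, 3), diagnostics = data.frame())
    rel <- relativeExpression(fit, c(p1 = "g1", p2 = "g1", p3 = "g2"))
    tab <- deTable(rel)
    expect_equal(tab$mean[tab$unit == "g1"], log2(1 + 0.2 * 1e6))
    expect_equal(tab$mean[tab$unit == "g2"], log2(1 + 0.05 * 1e6))
})

test_that("rescaling one replicate leaves posterior expression unchanged", {
    set.seed(9)
    P <- 25
    f <- exp(rnorm(P)); f <- f / sum(f)
    y <- matrix(rnbinom(P * 3, mu = 3e4 * f, size = 30), P, 3)
    y2 <- y; y2[, 2] <- y2[, 2] * 5L
    fitA <- fitCondition(mc_from(y, "c1"), "c1", config = mcmcConfig(seed = 9))
    fitB <- fitCondition(mc_from(y2, "c1"), "c1", config = mcmcConfig(seed = 9))
    expect_equal(colMeans(muSamples(fitA)), colMeans(muSamples(fitB)),
                 tolerance = 0.05)
})

test_that("gene-level relative expression tracks true abundance across orders of magnitude", {
    set.seed(21)
    n_tx <- 30L; ppt <- 5L
    ab <- 10^runif(n_tx, 0, 4)
    eff <- exp(rnorm(n_tx * ppt, 0, 0.7))
    gid <- rep(sprintf("g%02d", seq_len(n_tx)), each = ppt)
    f <- ab[rep(seq_len(n_tx), each = ppt)] * eff
    f <- f / sum(f)
    y <- matrix(rnbinom(length(f) * 4, mu = rep(5e4 * f, 4), size = 50),
                ncol = 4, dimnames = list(sprintf("p%03d", seq_along(f)),
                                          paste0("s", 1:4)))
    mc <- MoleculeCounts(y, data.frame(sample = colnames(y), condition = "c"))
    fit <- suppressWarnings(fitCondition(mc, "c", config = mcmcConfig(seed = 21)))
    rel <- deTable(relativeExpression(fit, setNames(gid, rownames(y))))
    truth <- log2(ab)[match(rel$unit, sprintf("g%02d", seq_len(n_tx)))]
    expect_gte(cor(rel$mean, truth), 0.95)
})
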