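## Bayesian hierarchical negative-binomial expression model.
##
## Molecule counts y[p, r] for probe p in replicate r of one condition are
## modelled as
##
##   y[p, r] ~ NegBin(mean = m[p, r], dispersion = phi[experiment(r)])
##   log m[p, r] = log N[r] + mu[p] + lambda[class(r)] * x[p]
##
## with N[r] the replicate's total molecule count (depth), mu[p] the probe's
## log mean normalized expression in the condition, x[p] a condition-
## independent probe-bias covariate estimated from between-replicate-class
## differences in normalized counts, lambda a per-replicate-class bias
## loading, and a single dispersion phi shared by all probes of an experiment
## (NB parameterized so that Var = m + m^2 / phi). Each condition is fit
## independently by MCMC; differential expression is a cross-condition
## contrast of the mu samples.

#' MCMC configuration for the expression model
#'
#' Defaults give 4 chains x 250 kept draws = 1,000 posterior samples.
#'
#' @param chains Number of MCMC chains (default 4).
#' @param warmup Adaptation + burn-in iterations per chain (default 1,000).
#' @param samples_per_chain Kept draws per chain (default 250).
#' @param thin Thinning interval (default 2).
#' @param seed Base RNG seed; chain c uses \code{seed + c} (default 1).
#' @param mu_sd,lambda_sd Normal prior standard deviations for probe
#'   log-expression (centered at \code{log(1/P)}) and for the bias loading.
#' @param phi_scale Half-Cauchy prior scale for the dispersion.
#' @param rhat_limit Warn when any split-chain scale reduction factor exceeds
#'   this (default 1.05).
#' @return A named list of class \code{McmcConfig}.
#' @export
mcmcConfig <- function(chains = 4L, warmup = 1000L, samples_per_chain = 250L,
                       thin = 2L, seed = 1L, mu_sd = 5, lambda_sd = 1,
                       phi_scale = 5, rhat_limit = 1.05) {
    structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                   samples_per_chain = as.integer(samples_per_chain),
                   thin = as.integer(thin), seed = as.integer(seed),
                   mu_sd = mu_sd, lambda_sd = lambda_sd,
                   phi_scale = phi_scale, rhat_limit = rhat_limit),
              class = "McmcConfig")
}

#' Normalize molecule counts to molecules per million (mpm)
#'
#' @param counts A [MoleculeCounts-class] or a probes x samples matrix.
#' @return Matrix of molecules per million molecules; each column sums to
#'   1e6. Zero-depth samples are dropped with a warning.
#' @export
normalizeMpm <- function(counts) {
    y <- if (is(counts, "MoleculeCounts")) molecules(counts) else as.matrix(counts)
    N <- colSums(y)
    if (any(N == 0)) {
        warning("excluding zero-depth replicate(s): ",
                paste(colnames(y)[N == 0], collapse = ", "))
        y <- y[, N > 0, drop = FALSE]
        N <- N[N > 0]
    }
    sweep(y, 2L, N, "/") * 1e6
}

#' Estimate the condition-independent probe-bias covariate
#'
#' Probes can deviate between replicate classes (e.g. different input
#' amounts) in the same direction in every condition. The covariate is, per
#' probe, the mean over conditions of half the difference in mean
#' log(1 + mpm) between the first two replicate classes, centered to mean
#' zero over probes. With fewer than two replicate classes the covariate is
#' all-zero.
#'
#' @param counts A [MoleculeCounts-class].
#' @return Numeric vector (one value per probe, mean zero), named by probe.
#' @export
estimateBias <- function(counts) {
    stopifnot(is(counts, "MoleculeCounts"))
    cd <- as.data.frame(SummarizedExperiment::colData(counts))
    mpm <- normalizeMpm(counts)
    cd <- cd[colnames(mpm), , drop = FALSE]
    lg <- log(1 + mpm)
    x <- rep(0, nrow(mpm))
    n_used <- 0L
    for (cond in unique(cd$condition)) {
        sel <- cd$condition == cond
        classes <- sort(unique(cd$replicate_class[sel]))
        if (length(classes) < 2L) next
        A <- sel & cd$replicate_class == classes[1]
        B <- sel & cd$replicate_class == classes[2]
        xc <- 0.5 * (rowMeans(lg[, A, drop = FALSE]) -
                     rowMeans(lg[, B, drop = FALSE]))
        x <- x + xc
        n_used <- n_used + 1L
    }
    if (n_used > 0L) x <- x / n_used
    x <- x - mean(x)
    setNames(x, rownames(mpm))
}

#' PosteriorFit: posterior samples of the expression model for one condition
#'
#' @slot condition The fitted condition.
#' @slot probes Probe names (columns of \code{mu}).
#' @slot mu Matrix (samples x probes) of probe log mean normalized expression
#'   (natural log of the molecule fraction; \code{exp(mu) * 1e6} is on the
#'   mpm scale).
#' @slot lambda Matrix (samples x replicate classes) of bias loadings.
#' @slot phi Matrix (samples x experiments) of NB dispersions
#'   (Var = m + m^2/phi).
#' @slot bias The probe-bias covariate used in the fit.
#' @slot diagnostics data.frame of convergence diagnostics.
#' @export
setClass("PosteriorFit",
         representation(condition = "character", probes = "character",
                        mu = "matrix", lambda = "matrix", phi = "matrix",
                        bias = "numeric", diagnostics = "data.frame"))

setValidity("PosteriorFit", function(object) {
    if (ncol(object@mu) != length(object@probes))
        return("mu columns must match probes")
    if (any(object@phi <= 0)) return("phi must be positive")
    TRUE
})

setMethod("show", "PosteriorFit", function(object) {
    cat("PosteriorFit for condition '", object@condition, "': ",
        nrow(object@mu), " posterior samples, ", length(object@probes),
        " probes, ", ncol(object@lambda), " replicate class(es), ",
        ncol(object@phi), " experiment(s)\n", sep = "")
    if (nrow(object@diagnostics))
        cat("  max split-Rhat:",
            round(max(object@diagnostics$rhat, na.rm = TRUE), 3), "\n")
})

#' Posterior samples of probe log-expression
#' @param fit A [PosteriorFit-class].
#' @return Matrix samples x probes.
#' @export
muSamples <- function(fit) fit@mu

## The first replicate class is the reference (lambda = 0): with every class
## loading free, adding c * x[p] to mu and subtracting c from all lambdas
## leaves the likelihood unchanged, so the model would be unidentified.
.jags_model_string <- function(K) {
    lambda_block <- if (K >= 2L)
        "lambda[1] <- 0\n  for (j in 2:K) { lambda[j] ~ dnorm(0, lambda_prec) }"
    else "lambda[1] <- 0"
    sprintf("
model {
  for (i in 1:Nobs) {
    y[i] ~ dnegbin(pnb[i], phi[e[i]])
    pnb[i] <- phi[e[i]] / (phi[e[i]] + m[i])
    log(m[i]) <- logN[i] + mu[probe[i]] + lambda[k[i]] * x[probe[i]]
  }
  for (p in 1:P) { mu[p] ~ dnorm(mu0, mu_prec) }
  %s
  for (s in 1:E) { phi[s] ~ dt(0, phi_prec, 1) T(0.001,) }
}
", lambda_block)
}

## order coda columns like "mu[1]", "mu[2]", ... and return samples x n matrix
.extract_indexed <- function(draws, prefix, n) {
    cols <- paste0(prefix, "[", seq_len(n), "]")
    if (n == 1L && !any(cols %in% colnames(draws))) cols <- prefix
    draws[, cols, drop = FALSE]
}

#' Fit the expression model for one condition
#'
#' Runs MCMC on the hierarchical negative-binomial model for all replicates
#' of one condition, with per-replicate-class bias loadings and
#' per-experiment dispersions. Zero counts are retained (they are within NB
#' support). Convergence is checked with split-chain scale-reduction factors;
#' values above \code{config$rhat_limit} raise a warning.
#'
#' @param counts A [MoleculeCounts-class].
#' @param condition The condition (in \code{colData(counts)$condition}) to
#'   fit.
#' @param bias Probe-bias covariate as returned by [estimateBias]; defaults
#'   to all-zero (no bias correction).
#' @param config An [mcmcConfig] list.
#' @return A [PosteriorFit-class] with \code{chains * samples_per_chain}
#'   posterior samples.
#' @export
fitCondition <- function(counts, condition, bias = NULL,
                         config = mcmcConfig()) {
    stopifnot(is(counts, "MoleculeCounts"))
    cd <- as.data.frame(SummarizedExperiment::colData(counts))
    sel <- which(cd$condition == condition)
    if (!length(sel)) stop("no replicates for condition '", condition, "'")
    y <- molecules(counts)[, sel, drop = FALSE]
    N <- colSums(y)
    if (any(N == 0)) {
        warning("excluding zero-depth replicate(s): ",
                paste(colnames(y)[N == 0], collapse = ", "))
        keep <- N > 0
        y <- y[, keep, drop = FALSE]
        sel <- sel[keep]
        N <- N[keep]
    }
    P <- nrow(y); R <- ncol(y)
    probes <- rownames(y)
    if (is.null(probes)) probes <- paste0("probe", seq_len(P))
    if (is.null(bias)) bias <- rep(0, P)
    if (!is.null(names(bias))) bias <- bias[probes]
    stopifnot(length(bias) == P)
    kfac <- factor(cd$replicate_class[sel])
    efac <- factor(cd$experiment[sel])
    K <- nlevels(kfac); E <- nlevels(efac)

    dat <- list(y = as.vector(y),
                logN = rep(log(N), each = P),
                probe = rep(seq_len(P), R),
                k = rep(as.integer(kfac), each = P),
                e = rep(as.integer(efac), each = P),
                x = as.numeric(bias),
                Nobs = P * R, P = P, E = E,
                mu0 = log(1 / P),
                mu_prec = 1 / config$mu_sd^2,
                phi_prec = 1 / config$phi_scale^2)
    if (K >= 2L) {
        dat$K <- K
        dat$lambda_prec <- 1 / config$lambda_sd^2
    }

    inits <- lapply(seq_len(config$chains), function(ch)
        list(.RNG.name = "base::Mersenne-Twister",
             .RNG.seed = config$seed + ch,
             mu = log((rowMeans(y) + 0.5) / sum(rowMeans(y) + 0.5)),
             phi = rep(10, E)))

    jm <- rjags::jags.model(textConnection(.jags_model_string(K)), data = dat,
                            inits = inits, n.chains = config$chains,
                            n.adapt = max(100L, config$warmup %/% 2L),
                            quiet = TRUE)
    update(jm, config$warmup - config$warmup %/% 2L, progress.bar = "none")
    samp <- rjags::coda.samples(jm, c("mu", "lambda", "phi"),
                                n.iter = config$samples_per_chain * config$thin,
                                thin = config$thin, progress.bar = "none")

    diagnostics <- data.frame(parameter = character(), rhat = numeric())
    if (config$chains >= 2L) {
        gd <- try(coda::gelman.diag(samp, autoburnin = FALSE,
                                    multivariate = FALSE), silent = TRUE)
        if (!inherits(gd, "try-error")) {
            diagnostics <- data.frame(parameter = rownames(gd$psrf),
                                      rhat = gd$psrf[, 1])
            bad <- diagnostics$rhat > config$rhat_limit
            if (any(bad, na.rm = TRUE))
                warning(sum(bad, na.rm = TRUE),
                        " parameter(s) with split-chain Rhat > ",
                        config$rhat_limit,
                        "; consider more warmup iterations")
        }
    }
    draws <- as.matrix(do.call(rbind, lapply(samp, as.matrix)))
    mu <- as.matrix(.extract_indexed(draws, "mu", P))
    colnames(mu) <- probes
    lambda <- as.matrix(.extract_indexed(draws, "lambda", K))
    colnames(lambda) <- levels(kfac)
    phi <- as.matrix(.extract_indexed(draws, "phi", E))
    colnames(phi) <- levels(efac)
    new("PosteriorFit", condition = as.character(condition), probes = probes,
        mu = mu, lambda = lambda, phi = phi, bias = as.numeric(bias),
        diagnostics = diagnostics)
}

#' DeEstimate: posterior samples of a per-unit quantity
#'
#' Holds posterior samples of a per-probe or per-gene quantity (log2 fold
#' change, or expression values) together with the unit names; summaries are
#' computed by [deTable].
#'
#' @slot samples Matrix (samples x units).
#' @slot units Unit (probe or gene) names.
#' @slot quantity Short description of the sampled quantity.
#' @export
setClass("DeEstimate",
         representation(samples = "matrix", units = "character",
                        quantity = "character"))

setMethod("show", "DeEstimate", function(object) {
    cat("DeEstimate (", object@quantity, "): ", length(object@units),
        " unit(s), ", nrow(object@samples), " posterior samples\n", sep = "")
})

#' Posterior summary table of a DeEstimate
#'
#' @param x A [DeEstimate-class].
#' @param level Credible level (default 0.95, central interval).
#' @return data.frame with \code{unit}, \code{mean}, \code{sd}, \code{lower},
#'   \code{upper}.
#' @export
deTable <- function(x, level = 0.95) {
    a <- (1 - level) / 2
    data.frame(unit = x@units,
               mean = colMeans(x@samples),
               sd = apply(x@samples, 2L, sd),
               lower = apply(x@samples, 2L, quantile, probs = a),
               upper = apply(x@samples, 2L, quantile, probs = 1 - a),
               row.names = NULL)
}

#' Posterior samples held by a DeEstimate
#' @param x A [DeEstimate-class].
#' @return Matrix samples x units.
#' @export
deSamples <- function(x) x@samples

#' Differential expression between two independently fitted conditions
#'
#' Pairs the s-th posterior sample of each fit (valid because the conditions
#' are fit independently) and forms per-probe log2 fold-change samples
#' \code{(mu_A - mu_B) / ln 2}.
#'
#' @param fitA,fitB [PosteriorFit-class] objects sharing the probe set and
#'   sample count.
#' @return A [DeEstimate-class] of per-probe log2 fold changes (A vs B).
#' @export
differentialExpression <- function(fitA, fitB) {
    if (!identical(fitA@probes, fitB@probes))
        stop("input error: fits have different probe sets")
    if (nrow(fitA@mu) != nrow(fitB@mu))
        stop("input error: fits have different posterior sample counts")
    delta <- (fitA@mu - fitB@mu) / log(2)
    new("DeEstimate", samples = delta, units = fitA@probes,
        quantity = paste0("log2 fold change (", fitA@condition, " vs ",
                          fitB@condition, ")"))
}

.gene_map <- function(geneMap) {
    if (is(geneMap, "MipPanel")) {
        p <- probeTable(geneMap)
        setNames(p$gene, p$name)
    } else if (is.data.frame(geneMap)) {
        setNames(as.character(geneMap$gene), geneMap$name)
    } else {
        geneMap
    }
}

#' Aggregate probe-level posterior samples to gene level
#'
#' Averages the probe-level posterior samples of the genes' probes
#' sample-wise; single-probe genes pass through unchanged.
#'
#' @param x A [DeEstimate-class] with probe units.
#' @param geneMap A [MipPanel-class], a data.frame with \code{name} and
#'   \code{gene} columns, or a named character vector probe -> gene.
#' @return A [DeEstimate-class] with gene units.
#' @export
geneSummary <- function(x, geneMap) {
    map <- .gene_map(geneMap)
    genes <- map[x@units]
    if (any(is.na(genes)))
        stop("input error: unmapped probe(s): ",
             paste(x@units[is.na(genes)], collapse = ", "))
    glev <- unique(unname(genes))
    out <- vapply(glev, function(g)
        rowMeans(x@samples[, genes == g, drop = FALSE]),
        numeric(nrow(x@samples)))
    new("DeEstimate", samples = as.matrix(out), units = glev,
        quantity = paste("gene-level", x@quantity))
}

#' Gene-level relative expression from a condition fit
#'
#' Converts probe log-expression samples to the molecules-per-million scale,
#' averages over each gene's probes sample-wise, and reports
#' \code{log2(1 + mpm)} values. These are comparable to external expression
#' measures (e.g. log2(1 + RPKM)) only up to an affine transform.
#'
#' @param fit A [PosteriorFit-class].
#' @param geneMap As in [geneSummary].
#' @return A [DeEstimate-class] of gene-level log2(1 + mpm) values.
#' @export
relativeExpression <- function(fit, geneMap) {
    map <- .gene_map(geneMap)
    genes <- map[fit@probes]
    if (any(is.na(genes)))
        stop("input error: unmapped probe(s): ",
             paste(fit@probes[is.na(genes)], collapse = ", "))
    mpm <- exp(fit@mu) * 1e6
    glev <- unique(unname(genes))
    out <- vapply(glev, function(g)
        log2(1 + rowMeans(mpm[, genes == g, drop = FALSE])),
        numeric(nrow(mpm)))
    new("DeEstimate", samples = as.matrix(out), units = glev,
        quantity = paste0("log2(1 + mpm), condition ", fit@condition))
}
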