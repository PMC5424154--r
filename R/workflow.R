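## End-to-end orchestration: panel -> counting -> bias -> per-condition fits
## -> differential expression -> gene summaries, with a machine-readable run
## manifest (resolved parameters, seeds, input/output checksums) so that runs
## are reproducible and comparable.

#' Run configuration for the full pipeline
#'
#' @param panel Path to a panel TSV ([readMipPanel] dialect).
#' @param samples Path to a sample-sheet TSV with columns \code{sample},
#'   \code{fastq1}, \code{fastq2}, \code{condition} and optionally
#'   \code{replicate_class}, \code{experiment}.
#' @param out_dir Output directory (created if needed).
#' @param conditions Optional character pair: the two conditions to contrast
#'   (default: the first two conditions of the sheet, in sheet order).
#' @param umi_fraction Read fraction for [errorCorrectedCount] (default 0.95).
#' @param max_mismatches Per-arm mismatch allowance (default 2).
#' @param min_insert Dimer threshold (default 20).
#' @param mcmc An [mcmcConfig] list.
#' @return A validated named list of class \code{RunConfig}.
#' @export
runConfig <- function(panel, samples, out_dir, conditions = NULL,
                      umi_fraction = 0.95, max_mismatches = 2L,
                      min_insert = 20L, mcmc = mcmcConfig()) {
    for (f in c(panel, samples))
        if (!file.exists(f)) stop("input file not found: ", f)
    structure(list(panel = panel, samples = samples, out_dir = out_dir,
                   conditions = conditions, umi_fraction = umi_fraction,
                   max_mismatches = as.integer(max_mismatches),
                   min_insert = as.integer(min_insert), mcmc = mcmc),
              class = "RunConfig")
}

#' Load a run configuration from YAML
#'
#' All fields of [runConfig]; the \code{mcmc} block holds [mcmcConfig]
#' fields.
#'
#' @param path YAML file path.
#' @return A \code{RunConfig} list.
#' @export
readRunConfig <- function(path) {
    y <- read_yaml(path)
    mcmc <- do.call(mcmcConfig, if (is.null(y$mcmc)) list() else y$mcmc)
    runConfig(panel = y$panel, samples = y$samples, out_dir = y$out_dir,
              conditions = y$conditions,
              umi_fraction = if (is.null(y$umi_fraction)) 0.95 else y$umi_fraction,
              max_mismatches = if (is.null(y$max_mismatches)) 2L else y$max_mismatches,
              min_insert = if (is.null(y$min_insert)) 20L else y$min_insert,
              mcmc = mcmc)
}

.write_tsv <- function(x, path) {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

.stage <- function(name, manifest, expr) {
    tryCatch(expr, error = function(e) {
        manifest$failed_stage <- name
        manifest$error <- conditionMessage(e)
        write_json(manifest, file.path(manifest$out_dir, "manifest.json"),
                   auto_unbox = TRUE, pretty = TRUE, digits = NA)
        stop("pipeline aborted at stage '", name, "': ",
             conditionMessage(e), call. = FALSE)
    })
}

#' Run the full smMIP quantification pipeline
#'
#' Executes, in order: panel loading and validation, per-sample molecule
#' counting, probe-bias estimation, per-condition model fits, differential
#' expression of the configured condition pair and gene-level summaries.
#' Every stage writes its outputs under \code{out_dir}; a \code{manifest.json}
#' records resolved parameters, seeds and MD5 checksums of inputs and
#' outputs. Re-running with unchanged inputs reproduces identical count
#' tables, and (fixed MCMC seed) identical posterior summaries.
#'
#' @param config A [runConfig] list or a path to a YAML file for
#'   [readRunConfig].
#' @return The manifest, invisibly.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- readRunConfig(config)
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(out_dir = config$out_dir,
                     package_version = as.character(utils::packageVersion("smMIPseq")),
                     started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                     parameters = config[setdiff(names(config), "mcmc")],
                     mcmc = unclass(config$mcmc),
                     inputs = as.list(tools::md5sum(c(config$panel,
                                                      config$samples))),
                     outputs = list())

    layout <- readLayout(max_arm_mismatches = config$max_mismatches,
                         min_insert = config$min_insert)
    panel <- .stage("panel", manifest, readMipPanel(config$panel))

    sheet <- .stage("samples", manifest, {
        s <- read.table(config$samples, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
        need <- c("sample", "fastq1", "fastq2", "condition")
        if (!all(need %in% colnames(s)))
            stop("sample sheet lacks columns: ",
                 paste(setdiff(need, colnames(s)), collapse = ", "))
        s
    })

    mc <- .stage("count", manifest,
                 countSamples(sheet, panel, layout,
                              fraction = config$umi_fraction))
    f_counts <- .write_tsv(data.frame(probe = rownames(molecules(mc)),
                                      molecules(mc), check.names = FALSE),
                           file.path(config$out_dir, "molecule_counts.tsv"))
    f_qc <- .write_tsv(S4Vectors::metadata(mc)$qc,
                       file.path(config$out_dir, "qc.tsv"))

    bias <- .stage("bias", manifest, estimateBias(mc))
    f_bias <- .write_tsv(data.frame(probe = names(bias), bias = bias),
                         file.path(config$out_dir, "probe_bias.tsv"))

    conds <- config$conditions
    if (is.null(conds)) conds <- unique(sheet$condition)
    fits <- .stage("fit", manifest, {
        lapply(setNames(conds, conds), function(cc)
            fitCondition(mc, cc, bias = bias, config = config$mcmc))
    })
    post <- do.call(rbind, lapply(fits, function(f) {
        tab <- deTable(new("DeEstimate", samples = muSamples(f),
                           units = f@probes, quantity = "mu"))
        cbind(condition = f@condition, tab)
    }))
    f_post <- .write_tsv(post, file.path(config$out_dir,
                                         "posterior_summary.tsv"))

    f_de <- f_gene <- NULL
    if (length(conds) >= 2L) {
        de <- .stage("de", manifest,
                     differentialExpression(fits[[conds[1]]],
                                            fits[[conds[2]]]))
        f_de <- .write_tsv(deTable(de),
                           file.path(config$out_dir, "de_probes.tsv"))
        gde <- geneSummary(de, panel)
        f_gene <- .write_tsv(deTable(gde),
                             file.path(config$out_dir, "de_genes.tsv"))
    }

    outs <- c(f_counts, f_qc, f_bias, f_post, f_de, f_gene)
    manifest$outputs <- as.list(setNames(unname(tools::md5sum(outs)),
                                         basename(outs)))
    manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    write_json(manifest, file.path(config$out_dir, "manifest.json"),
               auto_unbox = TRUE, pretty = TRUE, digits = NA)
    write_yaml(c(manifest$parameters, list(mcmc = unclass(config$mcmc))),
               file.path(config$out_dir, "resolved_config.yaml"))
    invisible(manifest)
}

#' Fold-change recovery benchmark on a simulated two-mix experiment
#'
#' Runs the complete chain on a simulated two-mix (spike-in style) design:
#' read simulation, alignment-free molecule counting, probe-bias estimation,
#' per-condition model fits, differential expression and gene-level
#' aggregation, then summarises recovery per fold-change group. Genes too
#' lowly expressed to quantify are excluded (as published fold-change
#' comparisons do), and each group's common fold change is estimated by a
#' precision-weighted mean of its gene-level estimates (weights = inverse
#' posterior variance).
#'
#' @param seed Seed for the simulation and the MCMC.
#' @param config A [simConfig]; the default is the benchmark design (40
#'   transcripts in four equal groups at ratios 0.5/0.67/1/4, five probes per
#'   transcript, 1e5 molecules per replicate, 0.2\% sequencing errors).
#' @param mcmc An [mcmcConfig] (seeded from \code{seed} by default).
#' @param min_mean_molecules Low-expression floor: a gene is kept when its
#'   mean molecules per probe per replicate reaches this value in both
#'   conditions (default 3).
#' @param out_dir Scratch directory for the simulated FASTQ.
#' @return A list with \code{groups} (data.frame: \code{group} nominal ratio,
#'   \code{n_genes}, \code{log2fc} weighted estimate, \code{fold},
#'   \code{err_log2} vs nominal), \code{per_gene} (filtered [deTable] with
#'   \code{group}), \code{n_kept}, and \code{qc}.
#' @export
foldChangeBenchmark <- function(seed = 1L,
                                config = simConfig(
                                    seed = seed, n_transcripts = 40L,
                                    probes_per_transcript = c(5L, 5L),
                                    n_molecules = 1e5),
                                mcmc = mcmcConfig(seed = seed),
                                min_mean_molecules = 3,
                                out_dir = tempfile("fcbench")) {
    sim <- simulateExpressionExperiment(config, out_dir = out_dir)
    on.exit(unlink(out_dir, recursive = TRUE), add = TRUE)
    mc <- countSamples(sim$sample_sheet, sim$panel)
    bias <- estimateBias(mc)
    fit1 <- suppressWarnings(fitCondition(mc, "cond1", bias, mcmc))
    fit2 <- suppressWarnings(fitCondition(mc, "cond2", bias, mcmc))
    tab <- deTable(geneSummary(differentialExpression(fit1, fit2), sim$panel))

    p <- probeTable(sim$panel)
    sheet <- sim$sample_sheet
    y <- molecules(mc)
    gid <- p$gene[match(rownames(y), p$name)]
    per <- function(cond)
        tapply(rowMeans(y[, sheet$condition == cond, drop = FALSE]), gid, mean)
    keep <- names(which(per("cond1") >= min_mean_molecules &
                        per("cond2") >= min_mean_molecules))
    tab <- tab[tab$unit %in% keep, ]
    tab$group <- sim$truth$fold_group[match(tab$unit,
                                            rownames(sim$truth$abundance))]
    w <- 1 / tab$sd^2
    groups <- do.call(rbind, lapply(split(seq_len(nrow(tab)), tab$group),
        function(i) {
            wm <- sum(tab$mean[i] * w[i]) / sum(w[i])
            se <- sqrt(1 / sum(w[i]))   # fixed-effect meta-analytic se
            data.frame(group = tab$group[i][1], n_genes = length(i),
                       log2fc = wm, fold = 2^wm,
                       err_log2 = wm - log2(tab$group[i][1]),
                       lower = wm - 1.96 * se, upper = wm + 1.96 * se)
        }))
    rownames(groups) <- NULL
    list(groups = groups, per_gene = tab, n_kept = nrow(tab),
         qc = S4Vectors::metadata(mc)$qc)
}

#' Dilution-series benchmark for allelic-ratio linearity
#'
#' Simulates the two-genotype serial dilution, counts allele-specific
#' molecules by per-UMI majority vote for every sample, and summarises the
#' consecutive-step ratio of allelic ratios (expected to equal the dilution
#' rate) and the concordance (squared Pearson correlation of the per-step
#' allelic ratios) between the two independent probes of each SNP.
#'
#' @param seed Simulation seed.
#' @param n_snps,n_steps,rate,start,molecules_per_snp Passed to
#'   [simulateDilution].
#' @param config A [simConfig] (error and duplication parameters).
#' @param out_dir Scratch directory for FASTQ.
#' @return A list: \code{geometric_mean} of consecutive-step ratios across
#'   steps and SNPs, \code{n_pairs}, \code{mean_r2} between probe pairs,
#'   \code{ratios} (step x snp x probe table), \code{controls} (pure-pool
#'   allelic ratios).
#' @export
dilutionBenchmark <- function(seed = 1L, n_snps = 32L, n_steps = 8L,
                              rate = 0.75, start = 0.75,
                              molecules_per_snp = 2000,
                              config = simConfig(seed = seed),
                              out_dir = tempfile("dilbench")) {
    sim <- simulateDilution(n_snps = n_snps, n_steps = n_steps, rate = rate,
                            start = start,
                            molecules_per_snp = molecules_per_snp,
                            config = config, out_dir = out_dir, seed = seed)
    on.exit(unlink(out_dir, recursive = TRUE), add = TRUE)
    sheet <- sim$sample_sheet
    ratios <- vector("list", nrow(sheet))
    for (i in seq_len(nrow(sheet))) {
        cnt <- countAlleles(sheet$fastq1[i], sheet$fastq2[i], sim$panel,
                            sim$snps, sample = sheet$sample[i])
        r <- allelicRatio(cnt)
        r$step <- sheet$step[i]
        ratios[[i]] <- r
    }
    ratios <- do.call(rbind, ratios)
    series <- ratios[ratios$step >= 1L & ratios$step <= n_steps, ]
    rr <- dilutionRatioOfRatios(series)

    ## concordance between the two probes of each SNP across the series
    r2 <- vapply(unique(series$snp_id), function(s) {
        sub <- series[series$snp_id == s, ]
        pr <- sort(unique(sub$probe))
        if (length(pr) != 2L) return(NA_real_)
        a <- sub$ratio[sub$probe == pr[1]][order(sub$step[sub$probe == pr[1]])]
        b <- sub$ratio[sub$probe == pr[2]][order(sub$step[sub$probe == pr[2]])]
        cor(a, b)^2
    }, numeric(1))

    list(geometric_mean = rr$geometric_mean, n_pairs = rr$n_pairs,
         mean_r2 = mean(r2, na.rm = TRUE),
         ratios = ratios,
         controls = ratios[ratios$step < 1L | ratios$step > n_steps, ],
         truth = sim$truth)
}
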