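## Ground-truth simulator. Emulates the two-mix spike-in design used to
## benchmark the method: transcript abundances spanning several orders of
## magnitude, fixed fold-change groups between two conditions, per-probe
## capture-efficiency variation, a condition-independent replicate-class
## probe bias, PCR duplication with a heavy-tailed reads-per-molecule
## distribution, substitution sequencing errors, and UMI tagging. Every
## emitted read is recountable against the returned ground truth.

#' Simulation configuration
#'
#' Defaults reproduce the benchmark design: two mixes of the same transcripts
#' in four equal fold-change groups (0.5, 0.67, 1.0 and 4.0), abundances
#' spanning four orders of magnitude, 5-9 probes per transcript, log-normal
#' per-probe capture efficiency, a log-normal probe bias applied to one
#' replicate class in every condition, heavy-tailed PCR duplication and a
#' 0.2% per-base substitution error rate with 9-nt UMIs.
#'
#' @param seed Integer RNG seed; identical configs give identical output.
#' @param n_transcripts Number of simulated transcripts (default 40).
#' @param tx_length_range Min/max transcript length in nt (default 400-1200).
#' @param abundance_orders Span of true abundances in orders of magnitude
#'   (default 4; abundances are log-uniform over that span).
#' @param fold_change_groups Condition-1 : condition-2 abundance ratios, one
#'   group per value, equal membership (default \code{c(0.5, 0.67, 1, 4)}).
#' @param probes_per_transcript Length-2 range of probes per transcript
#'   (default \code{c(5, 9)}).
#' @param capture_eff_sdlog Log-normal sd of per-probe capture efficiency
#'   (default 0.7, giving the several-fold between-probe variation seen in
#'   capture data).
#' @param class_bias_sdlog Log-normal sd of the per-probe replicate-class
#'   bias factor (default 0.25), applied to class A in every condition.
#' @param n_molecules Captured molecules per replicate (default 5e4).
#' @param dup_mean Mean sequencing reads per molecule (default 4).
#' @param dup_size Negative-binomial size of the reads-per-molecule
#'   distribution (reads = 1 + NB; small values give the heavy tail the
#'   95\% coverage threshold is designed for; default 0.8).
#' @param seq_error_rate Per-base substitution error rate (default 0.002).
#' @param umi_length UMI length (default 9).
#' @return A named list of class \code{SimConfig}.
#' @export
simConfig <- function(seed = 1L, n_transcripts = 40L,
                      tx_length_range = c(400L, 1200L),
                      abundance_orders = 4,
                      fold_change_groups = c(0.5, 0.67, 1, 4),
                      probes_per_transcript = c(5L, 9L),
                      capture_eff_sdlog = 0.7, class_bias_sdlog = 0.25,
                      n_molecules = 5e4, dup_mean = 4, dup_size = 0.8,
                      seq_error_rate = 0.002, umi_length = 9L) {
    stopifnot(all(fold_change_groups > 0), seq_error_rate >= 0,
              seq_error_rate <= 1, dup_mean >= 1, n_molecules >= 0)
    structure(list(seed = as.integer(seed),
                   n_transcripts = as.integer(n_transcripts),
                   tx_length_range = as.integer(tx_length_range),
                   abundance_orders = abundance_orders,
                   fold_change_groups = fold_change_groups,
                   probes_per_transcript = as.integer(probes_per_transcript),
                   capture_eff_sdlog = capture_eff_sdlog,
                   class_bias_sdlog = class_bias_sdlog,
                   n_molecules = n_molecules, dup_mean = dup_mean,
                   dup_size = dup_size, seq_error_rate = seq_error_rate,
                   umi_length = as.integer(umi_length)),
              class = "SimConfig")
}

.random_dna <- function(n, lengths) {
    vapply(lengths, function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              collapse = ""), character(1))
}

.random_umis <- function(n, U) {
    if (n == 0L) return(character())
    m <- matrix(sample(c("A", "C", "G", "T"), n * U, replace = TRUE),
                nrow = n)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

## i.i.d. substitution errors; vectorised single-substitution path, short loop
## for the rare multi-error reads
.add_errors <- function(seqs, rate) {
    if (rate <= 0 || !length(seqs)) return(seqs)
    L <- nchar(seqs)
    nerr <- rbinom(length(seqs), L, rate)
    bases <- c("A", "C", "G", "T")
    one <- which(nerr == 1L)
    if (length(one)) {
        pos <- ceiling(runif(length(one)) * L[one])
        cur <- substr(seqs[one], pos, pos)
        new <- bases[(match(cur, bases) - 1L +
                      sample.int(3L, length(one), replace = TRUE)) %% 4L + 1L]
        substr(seqs[one], pos, pos) <- new
    }
    multi <- which(nerr >= 2L)
    for (i in multi) {
        pos <- sample.int(L[i], nerr[i])
        for (p in pos) {
            cur <- substr(seqs[i], p, p)
            new <- bases[(match(cur, bases) - 1L + sample.int(3L, 1L)) %% 4L + 1L]
            substr(seqs[i], p, p) <- new
        }
    }
    seqs
}

#' Simulate a transcriptome with two-condition abundances
#'
#' Random transcript sequences plus true abundance vectors for two conditions
#' respecting the configured fold-change groups (group ratio = condition-1
#' abundance / condition-2 abundance; transcripts are assigned to groups in
#' equal numbers).
#'
#' @param config A [simConfig] list.
#' @param seed Seed (default \code{config$seed}); \code{NULL} leaves the RNG
#'   state untouched (for use inside larger simulations).
#' @return A list: \code{sequences} ([Biostrings::DNAStringSet]),
#'   \code{abundance} (transcripts x 2 matrix, arbitrary units),
#'   \code{fold_group} (the group ratio of each transcript).
#' @export
makeTranscriptome <- function(config = simConfig(), seed = config$seed) {
    if (!is.null(seed)) set.seed(seed)
    n <- config$n_transcripts
    lr <- config$tx_length_range
    lens <- if (lr[1] == lr[2]) rep(lr[1], n) else
        sample(seq(lr[1], lr[2]), n, replace = TRUE)
    seqs <- DNAStringSet(.random_dna(n, lens))
    names(seqs) <- sprintf("tx%03d", seq_len(n))
    a1 <- 10^runif(n, 0, config$abundance_orders)
    ## two-mix design: every fold-change group spans the full abundance range
    ## (groups are assigned within blocks of similar abundance), and the
    ## highest-ratio group is scaled -- in both mixes, preserving its exact
    ## ratio -- so that the two mixes contain the same total amount
    fcg <- config$fold_change_groups
    G <- length(fcg)
    ord <- order(a1, decreasing = TRUE)
    groups <- numeric(n)
    for (b in seq_len(ceiling(n / G))) {
        idx <- ord[seq.int((b - 1L) * G + 1L, min(b * G, n))]
        groups[idx] <- sample(fcg)[seq_along(idx)]
    }
    if (length(unique(fcg)) > 1L) {
        hi <- groups == max(fcg)
        deficit <- sum(a1[!hi] / groups[!hi] - a1[!hi])
        s <- deficit / sum(a1[hi] - a1[hi] / max(fcg))
        if (is.finite(s) && s > 0) a1[hi] <- a1[hi] * s
    }
    a2 <- a1 / groups
    abundance <- cbind(cond1 = a1, cond2 = a2)
    rownames(abundance) <- names(seqs)
    list(sequences = seqs, abundance = abundance, fold_group = groups)
}

#' Simulate an expression probe panel over a transcriptome
#'
#' Places the configured number of probes per transcript at evenly spread
#' gap-fill positions with random admissible arm-length splits.
#'
#' @param sequences A named [Biostrings::DNAStringSet] of transcripts.
#' @param config A [simConfig] list.
#' @param constraints A [designConstraints] list.
#' @param seed As in [makeTranscriptome].
#' @return A [MipPanel-class].
#' @export
simulatePanel <- function(sequences, config = simConfig(),
                          constraints = designConstraints(),
                          seed = config$seed) {
    if (!is.null(seed)) set.seed(seed)
    Tlen <- constraints$target_length
    splits <- .arm_splits(constraints)
    rows <- list()
    for (t in seq_along(sequences)) {
        L <- width(sequences)[t]
        id <- names(sequences)[t]
        ppt <- config$probes_per_transcript
        npp <- if (ppt[1] == ppt[2]) ppt[1] else
            sample(seq(ppt[1], ppt[2]), 1L)
        g_lo <- constraints$arm_max
        g_hi <- L - Tlen - constraints$arm_max
        if (g_hi < g_lo) next
        g <- unique(round(seq(g_lo, g_hi, length.out = npp)))
        sp <- splits[sample.int(nrow(splits), length(g), replace = TRUE), ]
        seqchr <- as.character(sequences[[t]])
        rows[[t]] <- data.frame(
            name = sprintf("%s_p%d", id, seq_along(g)),
            gene = id, target_id = id,
            target_start = g, target_end = g + Tlen,
            extension_arm = substring(seqchr, g - sp$ext + 1L, g),
            ligation_arm = substring(seqchr, g + Tlen + 1L, g + Tlen + sp$lig),
            umi_length = config$umi_length,
            junction_crossing = FALSE,
            stringsAsFactors = FALSE)
    }
    MipPanel(do.call(rbind, rows))
}

#' Simulate captured molecules for one replicate
#'
#' Molecule counts per probe follow a multinomial over probes with weights
#' abundance x capture efficiency x replicate-class bias; each molecule gets
#' an independent uniform random UMI (collisions possible, as in real data).
#'
#' @param abundance Named numeric vector of transcript abundances (one
#'   condition).
#' @param panel A [MipPanel-class].
#' @param efficiencies Per-probe capture efficiencies (named by probe).
#' @param class_bias Per-probe class-bias factors applied to this replicate
#'   (use 1 for unbiased classes).
#' @param n_molecules Total molecules captured in the replicate.
#' @param umi_length UMI length.
#' @param seed Optional seed (\code{NULL}: leave RNG state alone).
#' @return A list: \code{counts} (named per-probe molecule counts) and
#'   \code{molecules} (data.frame \code{probe}, \code{umi}, one row per
#'   molecule).
#' @export
simulateCapture <- function(abundance, panel, efficiencies, class_bias = 1,
                            n_molecules, umi_length = 9L, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    p <- probeTable(panel)
    stopifnot(all(p$target_id %in% names(abundance)))
    w <- abundance[p$target_id] * efficiencies[p$name] *
        rep(class_bias, length.out = nrow(p))
    counts <- if (n_molecules > 0)
        as.integer(rmultinom(1L, n_molecules, w)) else integer(nrow(p))
    names(counts) <- p$name
    molecules <- data.frame(
        probe = rep(p$name, counts),
        umi = .random_umis(sum(counts), umi_length),
        stringsAsFactors = FALSE)
    list(counts = counts, molecules = molecules)
}

#' Simulate paired reads for captured molecules
#'
#' Each molecule yields \code{1 + NB(dup_size, dup_mean - 1)} read pairs.
#' Mate 1 is the ligation arm followed by the gap-fill (transcript
#' orientation); mate 2 is the UMI, the reverse complement of the extension
#' arm, then the reverse complement of the gap-fill. Substitution errors are
#' applied i.i.d. at \code{seq_error_rate}; qualities are constant.
#'
#' @param molecules \code{molecules} data.frame from [simulateCapture] (a
#'   \code{gapfill} column, when present, overrides the transcript-derived
#'   gap-fill per molecule, e.g. to carry SNP alleles).
#' @param panel A [MipPanel-class].
#' @param sequences Transcript sequences (named DNAStringSet) for the
#'   gap-fills.
#' @param config A [simConfig] list (duplication and error parameters).
#' @param fastq1,fastq2 Optional output FASTQ paths (gzip when ending in
#'   \code{.gz}); when omitted the reads are returned in memory.
#' @param seed Optional seed.
#' @return Invisibly, a list with \code{mate1}, \code{mate2} (character
#'   vectors, empty when written to files), \code{n_reads}, and the output
#'   paths when given.
#' @export
simulateReads <- function(molecules, panel, sequences, config = simConfig(),
                          fastq1 = NULL, fastq2 = NULL, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    p <- probeTable(panel)
    seqchr <- setNames(as.character(sequences), names(sequences))
    gap <- substring(seqchr[p$target_id], p$target_start + 1L, p$target_end)
    m1_tpl <- setNames(paste0(p$ligation_arm, gap), p$name)
    ext_rc <- .revcomp_chr(p$extension_arm)
    gap_rc <- .revcomp_chr(gap)
    m2_tpl <- setNames(paste0(ext_rc, gap_rc), p$name)

    M <- nrow(molecules)
    nreads <- if (M) 1L + rnbinom(M, size = config$dup_size,
                                  mu = config$dup_mean - 1) else integer()
    mol_of_read <- rep(seq_len(M), nreads)
    probe_of_read <- molecules$probe[mol_of_read]
    if (!is.null(molecules$gapfill)) {
        lig <- setNames(p$ligation_arm, p$name)
        m1 <- paste0(lig[probe_of_read], molecules$gapfill[mol_of_read])
        m2 <- paste0(molecules$umi[mol_of_read], ext_rc[match(probe_of_read, p$name)],
                     .revcomp_chr(molecules$gapfill)[mol_of_read])
    } else {
        m1 <- unname(m1_tpl[probe_of_read])
        m2 <- paste0(molecules$umi[mol_of_read], unname(m2_tpl[probe_of_read]))
    }
    m1 <- .add_errors(m1, config$seq_error_rate)
    m2 <- .add_errors(m2, config$seq_error_rate)
    ids <- sprintf("sim%07d:mol%d", seq_along(m1), mol_of_read)
    out <- list(mate1 = m1, mate2 = m2, n_reads = length(m1),
                mol_of_read = mol_of_read)
    if (!is.null(fastq1)) {
        s1 <- DNAStringSet(m1); names(s1) <- ids
        s2 <- DNAStringSet(m2); names(s2) <- ids
        writeXStringSet(s1, fastq1, format = "fastq",
                        qualities = BStringSet(strrep("I", nchar(m1))),
                        compress = grepl("\\.gz$", fastq1))
        writeXStringSet(s2, fastq2, format = "fastq",
                        qualities = BStringSet(strrep("I", nchar(m2))),
                        compress = grepl("\\.gz$", fastq2))
        out$mate1 <- character(); out$mate2 <- character()
        out$fastq1 <- fastq1; out$fastq2 <- fastq2
    }
    invisible(out)
}

#' Simulate a complete two-condition capture experiment
#'
#' End-to-end generator: transcriptome with fold-change groups, probe panel,
#' per-probe efficiencies and class biases, and per-replicate captured
#' molecules and paired FASTQ. The default replicate design is two conditions
#' with four technical replicates each, two per replicate class (emulating
#' two input amounts), one experiment.
#'
#' @param config A [simConfig] list.
#' @param out_dir Directory for FASTQ output (default a fresh tempdir).
#' @param n_replicates Replicates per condition (default 4; classes A/B are
#'   assigned alternately).
#' @param constraints Panel [designConstraints].
#' @param write_reads Write FASTQ files (default \code{TRUE}); otherwise only
#'   ground-truth molecule counts are generated.
#' @return A list with \code{transcriptome}, \code{panel},
#'   \code{efficiencies}, \code{class_bias}, \code{sample_sheet} (with
#'   \code{fastq1}/\code{fastq2} paths), and \code{truth} (a list with the
#'   per-replicate true molecule counts matrix \code{molecule_counts}, the
#'   abundance matrix and fold groups).
#' @export
simulateExpressionExperiment <- function(config = simConfig(),
                                         out_dir = tempfile("simexp"),
                                         n_replicates = 4L,
                                         constraints = designConstraints(),
                                         write_reads = TRUE) {
    set.seed(config$seed)
    txome <- makeTranscriptome(config, seed = NULL)
    panel <- simulatePanel(txome$sequences, config, constraints, seed = NULL)
    p <- probeTable(panel)
    eff <- setNames(exp(rnorm(nrow(p), 0, config$capture_eff_sdlog)), p$name)
    bias <- setNames(exp(rnorm(nrow(p), 0, config$class_bias_sdlog)), p$name)
    ## refine the two-mix balance in capture-weight terms: with per-probe
    ## efficiencies the captured totals of the two mixes differ slightly from
    ## the molar balance; rescale the highest-ratio group (both conditions,
    ## ratios preserved) so the total captureable signal is equal. Only
    ## composition is identifiable from capture data, so this is what makes
    ## the nominal group ratios the estimand.
    fcg <- config$fold_change_groups
    if (length(unique(fcg)) > 1L) {
        grp_tx <- txome$fold_group[match(p$target_id,
                                         rownames(txome$abundance))]
        w1 <- txome$abundance[p$target_id, 1] * eff
        w2 <- txome$abundance[p$target_id, 2] * eff
        hi <- grp_tx == max(fcg)
        deficit <- sum(w2[!hi] - w1[!hi])
        s <- deficit / sum(w1[hi] - w2[hi])
        if (is.finite(s) && s > 0) {
            hit <- txome$fold_group == max(fcg)
            txome$abundance[hit, ] <- txome$abundance[hit, ] * s
        }
    }
    if (write_reads) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

    sheet <- expand.grid(replicate = seq_len(n_replicates),
                         condition = colnames(txome$abundance),
                         stringsAsFactors = FALSE)
    sheet$replicate_class <- ifelse(sheet$replicate %% 2L == 1L, "classA", "classB")
    sheet$experiment <- "exp1"
    sheet$sample <- sprintf("%s_rep%d", sheet$condition, sheet$replicate)
    sheet$fastq1 <- if (write_reads)
        file.path(out_dir, paste0(sheet$sample, "_1.fastq.gz")) else NA
    sheet$fastq2 <- if (write_reads)
        file.path(out_dir, paste0(sheet$sample, "_2.fastq.gz")) else NA

    mol_counts <- matrix(0L, nrow(p), nrow(sheet),
                         dimnames = list(p$name, sheet$sample))
    for (i in seq_len(nrow(sheet))) {
        cb <- if (sheet$replicate_class[i] == "classA") bias[p$name] else 1
        cap <- simulateCapture(txome$abundance[, sheet$condition[i]], panel,
                               eff, cb, config$n_molecules,
                               config$umi_length, seed = NULL)
        mol_counts[, i] <- cap$counts
        if (write_reads)
            simulateReads(cap$molecules, panel, txome$sequences, config,
                          fastq1 = sheet$fastq1[i], fastq2 = sheet$fastq2[i],
                          seed = NULL)
    }
    list(transcriptome = txome, panel = panel, efficiencies = eff,
         class_bias = bias, sample_sheet = sheet,
         truth = list(molecule_counts = mol_counts,
                      abundance = txome$abundance,
                      fold_group = txome$fold_group))
}

#' Simulate a two-genotype serial dilution series
#'
#' Two haplotype pools carry opposite homozygous alleles at every SNP. The
#' pool-A fraction at step k is \code{start * rate^(k-1)} (default: start at
#' 75\% pool A, each step retains 75\% of the previous mix); pure-A and
#' pure-B control samples are included. Each SNP is covered by two probes
#' with non-overlapping extension arms and non-overlapping ligation arms,
#' giving independent molecule counts.
#'
#' @param n_snps Number of SNPs (default 32).
#' @param n_steps Dilution steps (default 8).
#' @param rate Retained fraction per step (default 0.75).
#' @param start Pool-A fraction at step 1 (default 0.75).
#' @param molecules_per_snp Molecules per SNP per sample, split equally over
#'   the SNP's probes (default 2000).
#' @param config A [simConfig] list (error/duplication/UMI parameters).
#' @param constraints SNP-panel [designConstraints] (default 100-nt target).
#' @param out_dir FASTQ output directory (default fresh tempdir).
#' @param write_reads Write FASTQ (default TRUE).
#' @param seed Seed (default \code{config$seed}).
#' @return A list with \code{panel}, \code{snps} ([snpTargets] table),
#'   \code{sequences}, \code{sample_sheet} (\code{sample}, \code{step} with
#'   0 = pure A and \code{n_steps + 1} = pure B, \code{true_fraction},
#'   FASTQ paths), and \code{truth} (per sample x snp true ref-molecule
#'   fractions).
#' @export
simulateDilution <- function(n_snps = 32L, n_steps = 8L, rate = 0.75,
                             start = 0.75, molecules_per_snp = 2000,
                             config = simConfig(),
                             constraints = designConstraints(target_length = 100L),
                             out_dir = tempfile("simdil"),
                             write_reads = TRUE, seed = config$seed) {
    set.seed(seed)
    Tlen <- constraints$target_length
    arm <- 20L
    L <- 2L * Tlen + 4L * arm + 20L
    seqs <- DNAStringSet(.random_dna(n_snps, rep(L, n_snps)))
    names(seqs) <- sprintf("snp_tx%02d", seq_len(n_snps))
    s_off <- as.integer(L / 2L)            # SNP offset, 0-based
    seqchr <- as.character(seqs)
    ref <- substr(seqchr, s_off + 1L, s_off + 1L)
    alt <- c(A = "C", C = "G", G = "T", T = "A")[ref]
    snps <- snpTargets(data.frame(snp_id = sprintf("snp%02d", seq_len(n_snps)),
                                  target_id = names(seqs), offset = s_off,
                                  ref = ref, alt = alt))
    ## two probes per SNP, gap-fills shifted so that arms cannot overlap
    shift <- as.integer(Tlen / 2L) - 10L
    g1 <- s_off - as.integer(Tlen / 2L) - shift %/% 2L
    g2 <- g1 + shift
    rows <- do.call(rbind, lapply(seq_len(n_snps), function(t) {
        g <- c(g1, g2)
        data.frame(name = sprintf("%s_p%d", names(seqs)[t], 1:2),
                   gene = names(seqs)[t], target_id = names(seqs)[t],
                   target_start = g, target_end = g + Tlen,
                   extension_arm = substring(seqchr[t], g - arm + 1L, g),
                   ligation_arm = substring(seqchr[t], g + Tlen + 1L,
                                            g + Tlen + arm),
                   umi_length = config$umi_length, junction_crossing = FALSE,
                   stringsAsFactors = FALSE)
    }))
    panel <- MipPanel(rows)
    p <- probeTable(panel)

    steps <- c(0L, seq_len(n_steps), n_steps + 1L)
    frac <- c(1, start * rate^(seq_len(n_steps) - 1L), 0)
    sheet <- data.frame(sample = c("pureA", sprintf("step%d", seq_len(n_steps)),
                                   "pureB"),
                        step = steps, true_fraction = frac,
                        stringsAsFactors = FALSE)
    sheet$fastq1 <- if (write_reads)
        file.path(out_dir, paste0(sheet$sample, "_1.fastq.gz")) else NA
    sheet$fastq2 <- if (write_reads)
        file.path(out_dir, paste0(sheet$sample, "_2.fastq.gz")) else NA
    if (write_reads) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

    n_per_probe <- as.integer(round(molecules_per_snp / 2L))
    gap_tpl <- substring(seqchr[p$target_id], p$target_start + 1L, p$target_end)
    snp_in_gap <- s_off - p$target_start   # 0-based offset inside gap-fill
    truth <- matrix(NA_real_, nrow(sheet), n_snps,
                    dimnames = list(sheet$sample, snps$snp_id))
    reads_out <- vector("list", nrow(sheet))
    for (i in seq_len(nrow(sheet))) {
        f <- sheet$true_fraction[i]
        nref <- rbinom(nrow(p), n_per_probe, f)
        mol <- data.frame(
            probe = rep(p$name, each = n_per_probe),
            allele = unlist(lapply(seq_len(nrow(p)), function(j)
                c(rep("ref", nref[j]), rep("alt", n_per_probe - nref[j])))),
            stringsAsFactors = FALSE)
        mol$umi <- .random_umis(nrow(mol), config$umi_length)
        j <- match(mol$probe, p$name)
        tx <- match(p$target_id[j], names(seqs))
        base <- ifelse(mol$allele == "ref", snps$ref[tx], snps$alt[tx])
        mol$gapfill <- gap_tpl[j]
        substr(mol$gapfill, snp_in_gap[j] + 1L, snp_in_gap[j] + 1L) <- base
        rr <- simulateReads(mol, panel, seqs, config,
                            fastq1 = if (write_reads) sheet$fastq1[i] else NULL,
                            fastq2 = if (write_reads) sheet$fastq2[i] else NULL,
                            seed = NULL)
        if (!write_reads) reads_out[[i]] <- rr
        ## per-SNP true ref fraction (over both probes)
        byt <- tapply(nref, p$target_id, sum)[snps$target_id]
        truth[i, ] <- byt / (2 * n_per_probe)
    }
    list(panel = panel, snps = snps, sequences = seqs, sample_sheet = sheet,
         truth = truth,
         reads = if (!write_reads) reads_out else NULL)
}

#' Write the artifacts of a simulated experiment to disk
#'
#' Writes the transcriptome FASTA, the panel TSV, the sample sheet, the
#' ground-truth molecule counts and abundances, and an echo of the
#' configuration, alongside the FASTQ files of
#' [simulateExpressionExperiment].
#'
#' @param sim Return value of [simulateExpressionExperiment].
#' @param config The [simConfig] used.
#' @param out_dir Output directory.
#' @return The directory, invisibly.
#' @export
writeSimulationArtifacts <- function(sim, config, out_dir) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeXStringSet(sim$transcriptome$sequences,
                    file.path(out_dir, "transcriptome.fasta"))
    writeMipPanel(sim$panel, file.path(out_dir, "panel.tsv"))
    write.table(sim$sample_sheet, file.path(out_dir, "samples.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    tm <- sim$truth$molecule_counts
    write.table(data.frame(probe = rownames(tm), tm, check.names = FALSE),
                file.path(out_dir, "truth_molecules.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    ab <- sim$truth$abundance
    write.table(data.frame(transcript = rownames(ab), ab,
                           fold_group = sim$truth$fold_group,
                           efficiency_mean = tapply(
                               sim$efficiencies,
                               probeTable(sim$panel)$target_id,
                               mean)[rownames(ab)],
                           check.names = FALSE),
                file.path(out_dir, "truth_abundance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_yaml(unclass(config), file.path(out_dir, "sim_config.yaml"))
    invisible(out_dir)
}
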