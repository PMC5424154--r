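write_fastq <- function(seqs, path, ids = sprintf("r%03d", seq_along(seqs))) {
    s <- Biostrings::DNAStringSet(seqs)
    names(s) <- ids
    Biostrings::writeXStringSet(s, path, format = "fastq",
                                qualities = Biostrings::BStringSet(
                                    strrep("I", nchar(seqs))))
    path
}

test_that("UMI moves from the read sequence into the identifier", {
    m1 <- c("ACGTACGTACGTACGTACGT", "TTTTGGGGCCCCAAAATTTT")
    m2 <- c(paste0("AAACCCGGG", "TGCATGCATGCA"),
            paste0("TTTAAACCC", "GGGGCCCCAAAA"))
    f1 <- write_fastq(m1, tempfile(fileext = ".fastq"))
    f2 <- write_fastq(m2, tempfile(fileext = ".fastq"))
    o1 <- tempfile(fileext = ".fastq"); o2 <- tempfile(fileext = ".fastq")

    rewriteUmiToHeader(f1, f2, o1, o2)
    r1 <- Biostrings::readDNAStringSet(o1, format = "fastq", with.qualities = TRUE)
    r2 <- Biostrings::readDNAStringSet(o2, format = "fastq", with.qualities = TRUE)
    expect_equal(names(r2), c("r001:AAACCCGGG", "r002:TTTAAACCC"))
    expect_equal(names(r1), names(r2))
    expect_equal(as.character(r2), setNames(substr(m2, 10, 21), names(r2)))
    expect_equal(nchar(as.character(S4Vectors::mcols(r2)$qualities)),
                 unname(nchar(m2) - 9L))
    ## read count preserved, mate 1 sequences untouched
    expect_equal(as.character(r1), setNames(m1, names(r1)))

    ## umi_length 0: byte-identical records
    o3 <- tempfile(fileext = ".fastq"); o4 <- tempfile(fileext = ".fastq")
    rewriteUmiToHeader(f1, f2, o3, o4, readLayout(umi_length = 0L))
    expect_identical(readLines(o3), readLines(f1))
    expect_identical(readLines(o4), readLines(f2))

    ## malformed record is reported with its number
    bad <- tempfile(fileext = ".fastq")
    writeLines(c("@r001", "ACGT", "+", "IIII", "@r002", "ACGT", "+", "III"),
               bad)
    expect_error(rewriteUmiToHeader(bad, f2, o1, o2), "#2")
})

test_that("simulated UMIs round-trip through the header rewrite", {
    fx <- tiny_panel(n_tx = 1L, probes_per_tx = 1L)
    cfg <- simConfig(seed = 31, seq_error_rate = 0, dup_mean = 1,
                     dup_size = 1e6)
    set.seed(31)
    mols <- data.frame(probe = rep("tx1_p1", 50),
                       umi = smMIPseq:::.random_umis(50, 9L))
    d <- tempfile(); dir.create(d)
    rr <- simulateReads(mols, fx$panel, fx$sequences, cfg,
                        fastq1 = file.path(d, "r1.fastq"),
                        fastq2 = file.path(d, "r2.fastq"))
    o1 <- file.path(d, "o1.fastq"); o2 <- file.path(d, "o2.fastq")
    rewriteUmiToHeader(rr$fastq1, rr$fastq2, o1, o2)
    out <- Biostrings::readDNAStringSet(o2, format = "fastq")
    got_umi <- sub(".*:", "", names(out))
    expect_equal(got_umi, mols$umi[rr$mol_of_read])
})

test_that("the SNP base is classified by gap-fill offset arithmetic", {
    ## probe: 4-nt ligation arm, gap-fill starts at transcript offset 10
    m1 <- c("ACGTTTTTTATTTT",   # ref A at offset 15 -> read pos 4 + 5 + 1
            "ACGTTTTTTCTTTT",   # alt C
            "ACGTTTTTTGTTTT")   # other G
    al <- alleleOfRead(m1, lig_len = 4L, target_start = 10L, offset = 15L,
                       ref = "A", alt = "C")
    expect_equal(al, c("ref", "alt", "other"))
    ## position beyond the read end -> other
    expect_equal(alleleOfRead("ACGT", 4L, 10L, 15L, "A", "C"), "other")
})

test_that("majority vote calls molecules and honours tie policy", {
    calls <- data.frame(
        snp_id = "s1",
        probe = c(rep("pA", 4), rep("pA", 4), rep("pA", 2), rep("pB", 3)),
        umi = c(rep("u1", 4), rep("u2", 4), rep("u3", 2), rep("u1", 3)),
        allele = c("ref", "ref", "ref", "alt",     # u1: ref wins 3-1
                   "ref", "ref", "alt", "alt",     # u2: exact tie
                   "other", "other",               # u3: other
                   "alt", "alt", "ref"),           # pB/u1: independent, alt
        stringsAsFactors = FALSE)
    got <- smMIPseq:::.vote(calls)
    gA <- got[got$probe == "pA", ]
    expect_equal(gA$ref_molecules, 1L)
    expect_equal(gA$tied_molecules, 1L)
    expect_equal(gA$other_molecules, 1L)
    gB <- got[got$probe == "pB", ]
    expect_equal(gB$alt_molecules, 1L)   # same UMI as pA/u1, counted separately

    ## random tie resolution never leaves tied molecules and is seeded
    r1 <- smMIPseq:::.vote(calls, tie = "random", seed = 7)
    r2 <- smMIPseq:::.vote(calls, tie = "random", seed = 7)
    expect_identical(r1, r2)
    expect_equal(sum(r1$tied_molecules), 0L)
})

test_that("majority vote equals the naive per-group tally on random groups", {
    set.seed(33)
    n <- 3000L
    calls <- data.frame(
        snp_id = sample(c("s1", "s2"), n, TRUE),
        probe = sample(c("pA", "pB", "pC"), n, TRUE),
        umi = sample(sprintf("u%02d", 1:40), n, TRUE),
        allele = sample(c("ref", "alt", "other"), n, TRUE,
                        prob = c(.5, .4, .1)),
        stringsAsFactors = FALSE)
    got <- smMIPseq:::.vote(calls)
    want <- oracle_vote(calls)
    for (grp in split(want, paste(want$snp_id, want$probe))) {
        row <- got[got$snp_id == grp$snp_id[1] & got$probe == grp$probe[1], ]
        expect_equal(row$ref_molecules, sum(grp$call == "ref"))
        expect_equal(row$alt_molecules, sum(grp$call == "alt"))
        expect_equal(row$other_molecules, sum(grp$call == "other"))
        expect_equal(row$tied_molecules, sum(grp$call == "tied"))
    }
    ## every (probe, UMI) group is counted exactly once
    expect_equal(sum(got$ref_molecules + got$alt_molecules +
                     got$other_molecules + got$tied_molecules),
                 nrow(unique(calls[, c("snp_id", "probe", "umi")])))
})

test_that("error-free allele counting reproduces the simulated truth exactly", {
    cfg <- simConfig(seed = 41, seq_error_rate = 0, dup_mean = 3,
                     dup_size = 1e6)
    ## few molecules per probe, so a UMI collision (which would merge two
    ## molecules) has negligible probability
    sim <- simulateDilution(n_snps = 4L, n_steps = 1L, molecules_per_snp = 60,
                            config = cfg, write_reads = FALSE, seed = 41)
    i <- which(sim$sample_sheet$sample == "step1")
    rr <- sim$reads[[i]]
    counts <- countAlleles(list(rr$mate1, rr$mate2), NULL, sim$panel,
                           sim$snps, sample = "step1")
    expect_equal(sum(counts$other_molecules), 0L)
    expect_equal(sum(counts$tied_molecules), 0L)
    ## per-SNP ref fraction equals the recorded truth (UMI collisions aside,
    ## none expected at 100 molecules/probe)
    agg <- allelicRatio(counts, collapse = "snp")
    expect_equal(setNames(agg$ratio, agg$snp_id)[colnames(sim$truth)],
                 sim$truth[i, ], ignore_attr = TRUE)
    expect_equal(sum(counts$ref_molecules + counts$alt_molecules), 4L * 60L)
})

test_that("SAM-based counting agrees exactly with the alignment-free route", {
    cfg <- simConfig(seed = 43, seq_error_rate = 0, dup_mean = 2,
                     dup_size = 1e6)
    sim <- simulateDilution(n_snps = 3L, n_steps = 1L, molecules_per_snp = 150,
                            config = cfg, write_reads = FALSE, seed = 43)
    i <- which(sim$sample_sheet$sample == "step1")
    rr <- sim$reads[[i]]
    free <- countAlleles(list(rr$mate1, rr$mate2), NULL, sim$panel, sim$snps,
                         sample = "s")

    ## construct the mapped representation: mate 1 aligned to its transcript
    ## with the (non-collinear) ligation arm soft-clipped, UMI in the name
    asg <- assignProbe(rr$mate1, rr$mate2, sim$panel)
    p <- probeTable(sim$panel)
    j <- match(asg$probe, p$name)
    b <- nchar(p$ligation_arm)[j]
    sam <- tempfile(fileext = ".sam")
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", names(sim$sequences),
                        Biostrings::width(sim$sequences)))
    rec <- sprintf("%s\t0\t%s\t%d\t60\t%dS%dM\t*\t0\t0\t%s\t%s",
                   sprintf("r%06d:%s", seq_along(rr$mate1), asg$umi),
                   p$target_id[j], p$target_start[j] + 1L, b,
                   nchar(rr$mate1) - b, rr$mate1,
                   strrep("I", nchar(rr$mate1)))
    writeLines(c(header, rec), sam)
    mapped <- countAllelesSam(sam, sim$panel, sim$snps, sample = "s")

    key <- function(x) x[order(x$snp_id, x$probe),
                         c("snp_id", "probe", "ref_molecules", "alt_molecules",
                           "other_molecules", "tied_molecules")]
    expect_equal(key(mapped), key(free), ignore_attr = TRUE)
})

test_that("allelic ratios carry exact binomial intervals", {
    counts <- data.frame(snp_id = c("s1", "s2"), probe = "p", sample = "x",
                         ref_molecules = c(75L, 0L),
                         alt_molecules = c(25L, 50L),
                         other_molecules = 0L, tied_molecules = 0L)
    rat <- allelicRatio(counts)
    expect_equal(rat$ratio, c(0.75, 0))
    expect_equal(rat$lower[2], 0)
    expect_lt(rat$upper[2], 0.08)   # one-sided upper bound near 3/n
    ## matches the canonical Clopper-Pearson construction
    ci <- stats::binom.test(75, 100)$conf.int
    expect_equal(c(rat$lower[1], rat$upper[1]), as.numeric(ci))

    ## interval coverage at the nominal level on simulated molecule counts
    set.seed(45)
    n <- 2000L; reps <- 400L
    r <- rbinom(reps, n, 0.6)
    sim <- allelicRatio(data.frame(snp_id = "s", probe = "p", sample = "x",
                                   ref_molecules = r,
                                   alt_molecules = n - r,
                                   other_molecules = 0L, tied_molecules = 0L))
    cover <- mean(sim$lower <= 0.6 & 0.6 <= sim$upper)
    expect_gt(cover, 0.92)

    none <- allelicRatio(data.frame(snp_id = "s", probe = "p", sample = "x",
                                    ref_molecules = 0L, alt_molecules = 0L,
                                    other_molecules = 3L, tied_molecules = 0L))
    expect_true(is.na(none$ratio))
})

test_that("ratio of ratios recovers the dilution rate on an ideal series", {
    steps <- 1:8
    ideal <- data.frame(step = steps, snp_id = "s1", probe = "p1",
                        ratio = 0.8 * 0.75^steps)
    res <- dilutionRatioOfRatios(ideal)
    expect_equal(res$step_ratios$step_ratio, rep(0.75, 7))
    expect_equal(res$geometric_mean, 0.75)
    expect_equal(res$n_pairs, 7L)

    ## a missing step is reported as a gap and its pairs skipped
    gap <- ideal[ideal$step != 4, ]
    res2 <- dilutionRatioOfRatios(gap)
    expect_equal(res2$n_pairs, 5L)
    expect_equal(nrow(res2$gaps), 1L)
    expect_equal(res2$geometric_mean, 0.75)
})
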