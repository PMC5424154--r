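ref_seq <- function(n, seed = 11L) {
    set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

test_that("splicing concatenates exons and honours strand", {
    g <- ref_seq(50)
    one <- spliceTranscript(data.frame(start = 1, end = 10), g, "+")
    expect_equal(txSequence(one), substr(g, 1, 10))

    two <- spliceTranscript(data.frame(start = c(1, 9), end = c(5, 13)), g, "+")
    expect_equal(nchar(txSequence(two)), 10L)
    expect_equal(txSequence(two),
                 paste0(substr(g, 1, 5), substr(g, 9, 13)))

    minus <- spliceTranscript(data.frame(start = c(1, 9), end = c(5, 13)),
                              g, "-")
    expect_equal(txSequence(minus), revcomp(txSequence(two)))

    expect_error(spliceTranscript(data.frame(start = 40, end = 60), g, "+"),
                 "coordinate")
    expect_error(spliceTranscript(data.frame(start = c(1, 4), end = c(5, 9)),
                                  g, "+"), "overlap")
})

test_that("genomic and transcript coordinates are mutually inverse", {
    g <- ref_seq(60)
    tx <- spliceTranscript(data.frame(start = c(1, 9), end = c(5, 13)), g, "+")
    expect_equal(genomicToTranscript(1, tx), 0L)     # first exonic base
    expect_true(is.na(genomicToTranscript(6, tx)))   # intronic
    ## base in exon 2 (genomic pos 9..13 -> offsets 5..9)
    expect_equal(genomicToTranscript(11, tx), 5L + (11L - 9L))

    set.seed(19)
    for (i in 1:40) {
        n_ex <- sample(1:5, 1)
        strand <- sample(c("+", "-"), 1)
        starts <- sort(sample(seq(1, 400, by = 12), n_ex))
        ends <- starts + sample(3:10, n_ex, TRUE)
        gg <- ref_seq(500, seed = 100 + i)
        txi <- spliceTranscript(data.frame(start = starts, end = ends), gg,
                                strand)
        offs <- seq_len(length(txi)) - 1L
        gpos <- transcriptToGenomic(offs, txi)
        expect_false(anyDuplicated(gpos) > 0)
        expect_equal(genomicToTranscript(gpos, txi), offs)
        ## every exonic genomic base maps back
        exonic <- unlist(Map(seq, starts, ends))
        expect_equal(sort(gpos), sort(exonic))
    }
})

test_that("segmentation emits full windows plus a flagged partial remainder", {
    s400 <- segmentTargets(400L, 200L)
    expect_equal(nrow(s400), 2L)
    expect_false(any(s400$partial))

    s450 <- segmentTargets(450L, 200L)
    expect_equal(nrow(s450), 3L)
    expect_equal(sum(!s450$partial), 2L)
    expect_equal(s450$end[3] - s450$start[3], 50L)

    ## a synthetic transcript set sized to yield 370 full 200-nt segments
    set.seed(5)
    lens <- sample(200:1200, 92, TRUE)
    full <- sum(lens %/% 200L)
    deficit <- 370L - full
    lens[1] <- lens[1] + deficit * 200L
    segs <- lapply(lens, segmentTargets, segment_length = 200L)
    expect_equal(sum(vapply(segs, function(s) sum(!s$partial), integer(1))),
                 370L)
})

test_that("candidate enumeration matches the naive scan and flags junctions", {
    cons <- designConstraints()
    ## minimal transcript: one placement per admissible arm split
    g <- ref_seq(152, seed = 21)
    tx <- spliceTranscript(data.frame(start = 1, end = 152), g, "+")
    cand <- enumerateCandidates(tx, list(segment = c(0L, 152L)), cons)
    expect_equal(nrow(cand), 9L)   # ext arm length 16..24
    expect_setequal(cand$ext_end - cand$ext_start, 16:24)
    expect_true(all(cand$target_end - cand$target_start == 112L))
    expect_true(all((cand$ext_end - cand$ext_start) +
                    (cand$lig_end - cand$lig_start) == 40L))
    ## every candidate reconstructs its window from the transcript sequence
    sc <- txSequence(tx)
    expect_identical(cand$extension_arm,
                     substring(sc, cand$ext_start + 1, cand$ext_end))
    expect_identical(cand$ligation_arm,
                     substring(sc, cand$lig_start + 1, cand$lig_end))

    ## equality with the brute-force enumerator on random transcripts
    set.seed(31)
    for (i in 1:12) {
        L <- sample(150:500, 1)
        gg <- ref_seq(L, seed = 300 + i)
        txi <- spliceTranscript(data.frame(start = 1, end = L), gg, "+")
        anchor <- if (i %% 2 == 0)
            list(segment = sort(sample(0:L, 2))) else
            list(snp_offset = sample(0:(L - 1), 1))
        got <- enumerateCandidates(txi, anchor, cons)
        expect_equal(nrow(got), oracle_enumerate(gg, anchor, cons),
                     info = paste("case", i))
    }

    ## SNP near the transcript start admits fewer placements
    L <- 400L
    gg <- ref_seq(L, seed = 77)
    txi <- spliceTranscript(data.frame(start = 1, end = L), gg, "+")
    near <- enumerateCandidates(txi, list(snp_offset = 10L), cons)
    interior <- enumerateCandidates(txi, list(snp_offset = 200L), cons)
    expect_lt(nrow(near), nrow(interior))
    expect_true(all(near$target_start <= 10L & near$target_end > 10L))

    ## too-short transcript: empty, not an error
    short <- spliceTranscript(data.frame(start = 1, end = 100),
                              ref_seq(100, seed = 9), "+")
    expect_equal(nrow(enumerateCandidates(short, NULL, cons)), 0L)
})

test_that("junction-crossing candidates are flagged", {
    cons <- designConstraints()
    g <- ref_seq(400, seed = 41)
    ## two exons; boundary at transcript offset 100
    tx <- spliceTranscript(data.frame(start = c(1, 151), end = c(100, 350)),
                           g, "+")
    expect_equal(exonBoundaries(tx), 100L)
    cand <- enumerateCandidates(tx, NULL, cons)
    inside_gap <- cand$target_start < 100L & cand$target_end > 100L
    expect_true(all(cand$junction_crossing[inside_gap]))
    clear <- cand$ext_start >= 100L | cand$lig_end <= 100L
    expect_false(any(cand$junction_crossing[clear]))
})

test_that("arm copy number counts both strands exactly", {
    ## non-palindromic arm in homopolymer flanks that cannot shadow it
    arm2 <- "CGTCGTCGTCGTCGTCGT"
    refs2 <- c(chr1 = paste0(strrep("A", 30), arm2, strrep("A", 30)))
    expect_equal(armCopyNumber(arm2, refs2), 1L)
    refs3 <- c(chr1 = paste0(arm2, strrep("T", 10), revcomp(arm2)))
    expect_equal(armCopyNumber(arm2, refs3), 2L)
    expect_equal(armCopyNumber(strrep("G", 18), refs2), 0L)
    expect_error(armCopyNumber("", refs2), "empty arm")
    expect_error(armCopyNumber(arm2, character()), "reference")

    ## brute-force scan oracle on random references
    set.seed(55)
    for (i in 1:10) {
        ref <- ref_seq(300, seed = 500 + i)
        arm <- substr(ref, 50, 67)
        naive <- 0L
        for (s in 1:(300 - 17)) {
            w <- substr(ref, s, s + 17)
            if (w == arm) naive <- naive + 1L
            if (w == revcomp(arm)) naive <- naive + 1L
        }
        expect_equal(armCopyNumber(arm, c(x = ref)), naive)
    }
})

test_that("copy-number filtering keeps only unique-arm candidates", {
    cons <- designConstraints()
    L <- 300L
    gg <- ref_seq(L, seed = 61)
    txi <- spliceTranscript(data.frame(start = 1, end = L), gg, "+")
    cand <- enumerateCandidates(txi, list(snp_offset = 150L), cons)
    ## against the transcript itself every arm occurs exactly once
    kept <- filterCandidates(cand, references = c(tx = gg), constraints = cons)
    expect_equal(nrow(kept), nrow(cand))
    ## a duplicated reference makes every arm copy number 2 -> all filtered
    dup <- filterCandidates(cand, references = c(a = gg, b = gg),
                            constraints = cons)
    expect_equal(nrow(dup), 0L)
    ## variant under an arm is dropped
    v <- filterCandidates(cand, variant_offsets = cand$ext_start[1],
                          constraints = cons)
    expect_true(all(v$ext_start > cand$ext_start[1] |
                    v$ext_end <= cand$ext_start[1]))
})

test_that("SNP probe pairs have disjoint arms and maximal summed score", {
    base <- data.frame(
        name = c("c1", "c2", "c3"),
        ext_start = c(0, 30, 5), ext_end = c(20, 50, 25),
        lig_start = c(120, 150, 125), lig_end = c(140, 170, 145),
        stringsAsFactors = FALSE)

    ## two candidates shifted well apart -> accepted
    pair <- designSnpPair(base[1:2, ])
    expect_setequal(pair$name, c("c1", "c2"))

    ## identical extension placements -> infeasible
    same <- base[1:2, ]
    same$ext_start <- c(0, 0); same$ext_end <- c(20, 20)
    expect_error(designSnpPair(same), "infeasible")

    ## scores 0.9/0.8/0.7 with only (0.9, 0.7)-compatible geometry:
    ## c1-c2 and c2-c3 overlap, c1-c3 disjoint
    tri <- data.frame(
        name = c("c1", "c2", "c3"),
        score = c(0.9, 0.8, 0.7),
        ext_start = c(0, 10, 25), ext_end = c(20, 30, 45),
        lig_start = c(120, 130, 145), lig_end = c(140, 150, 165),
        stringsAsFactors = FALSE)
    ## exhaustive oracle: feasible pairs and their scores
    feas <- list()
    for (i in 1:2) for (j in (i + 1):3) {
        ed <- tri$ext_end[i] <= tri$ext_start[j] ||
            tri$ext_end[j] <= tri$ext_start[i]
        ld <- tri$lig_end[i] <= tri$lig_start[j] ||
            tri$lig_end[j] <= tri$lig_start[i]
        if (ed && ld) feas[[length(feas) + 1]] <-
            list(pair = c(i, j), s = tri$score[i] + tri$score[j])
    }
    expect_equal(length(feas), 1L)
    expect_equal(feas[[1]]$pair, c(1L, 3L))
    got <- designSnpPair(tri)
    expect_setequal(got$name, tri$name[feas[[1]]$pair])
})

test_that("transcript models load from FASTA plus GFF3 or BED-like tables", {
    g1 <- ref_seq(120, seed = 91)
    g2 <- ref_seq(80, seed = 92)
    fa <- tempfile(fileext = ".fasta")
    writeLines(c(">chr1 test", g1, ">chr2", g2), fa)

    gff <- tempfile(fileext = ".gff3")
    writeLines(c(
        "##gff-version 3",
        "chr1\tsrc\tmRNA\t11\t70\t.\t+\t.\tID=txA",
        "chr1\tsrc\texon\t11\t30\t.\t+\t.\tParent=txA",
        "chr1\tsrc\texon\t41\t70\t.\t+\t.\tParent=txA",
        "chr2\tsrc\texon\t5\t40\t.\t-\t.\tParent=txB"), gff)
    tx <- readTranscriptModels(fa, gff)
    expect_setequal(names(tx), c("txA", "txB"))
    expect_equal(txSequence(tx$txA),
                 paste0(substr(g1, 11, 30), substr(g1, 41, 70)))
    expect_equal(txSequence(tx$txB), revcomp(substr(g2, 5, 40)))

    bed <- tempfile(fileext = ".tsv")
    write.table(data.frame(chrom = "chr1", start = c(10, 40), end = c(30, 70),
                           transcript = "txA", strand = "+"),
                bed, sep = "\t", quote = FALSE, row.names = FALSE)
    tx2 <- readTranscriptModels(fa, bed, format = "bed")
    expect_equal(txSequence(tx2$txA), txSequence(tx$txA))
})

test_that("VCF variants convert to transcript-coordinate SNP targets", {
    g1 <- ref_seq(120, seed = 93)
    tx <- spliceTranscript(data.frame(start = c(11, 41), end = c(30, 70)),
                           g1, "+", id = "txA", chrom = "chr1")
    ref15 <- substr(g1, 15, 15)
    alt15 <- setdiff(c("A", "C", "G", "T"), ref15)[1]
    vcf <- tempfile(fileext = ".vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
        sprintf("chr1\t15\trs1\t%s\t%s\t.\t.\t.", ref15, alt15),
        sprintf("chr1\t35\trs_intron\t%s\tA\t.\t.\t.",
                substr(g1, 35, 35)),             # intronic: dropped
        "chr1\t50\trs_indel\tAC\tA\t.\t.\t."),   # not a SNV: dropped
        vcf)
    v <- readVariantTargets(vcf, transcripts = list(tx))
    expect_equal(nrow(v), 1L + (substr(g1, 35, 35) != "A") * 0L)
    expect_equal(v$snp_id[1], "rs1")
    expect_equal(v$offset[1], 4L)          # genomic 15 -> 0-based offset 4
    expect_equal(v$ref[1], ref15)
    ## round-trip: the transcript base at the offset is the REF allele
    expect_equal(substr(txSequence(tx), v$offset[1] + 1, v$offset[1] + 1),
                 v$ref[1])
})
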