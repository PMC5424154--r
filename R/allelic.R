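## Allele-specific molecule counting. Reads are grouped per (probe, UMI); a
## majority vote over the base observed at the SNP calls each molecule's
## allele. Groups with the same UMI but from different probes are independent
## molecules. Two counting backends share the vote logic: alignment-free
## (offset arithmetic inside the designed gap-fill; default) and SAM/BAM input
## with the UMI carried in the read identifier (mirrors a mapper-based
## route).

#' Define SNP targets on transcripts
#'
#' @param snps A data.frame with columns \code{snp_id}, \code{target_id},
#'   \code{offset} (0-based transcript offset of the SNP), \code{ref},
#'   \code{alt} (single, distinct bases).
#' @return The validated data.frame (alleles upper-cased).
#' @export
snpTargets <- function(snps) {
    snps <- as.data.frame(snps)
    need <- c("snp_id", "target_id", "offset", "ref", "alt")
    if (!all(need %in% colnames(snps)))
        stop("snp table lacks columns: ",
             paste(setdiff(need, colnames(snps)), collapse = ", "))
    snps$ref <- toupper(snps$ref); snps$alt <- toupper(snps$alt)
    if (any(nchar(snps$ref) != 1L | nchar(snps$alt) != 1L))
        stop("ref and alt must be single bases")
    if (any(snps$ref == snps$alt))
        stop("ref and alt must differ")
    snps$offset <- as.integer(snps$offset)
    snps
}

## validating FASTQ reader (gzip-transparent): returns ids, sequences and
## quality strings, reporting the first malformed record by number
.read_fastq_q <- function(path) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    lines <- readLines(con)
    n <- length(lines)
    bad <- NA_integer_
    if (n %% 4L != 0L) bad <- n %/% 4L + 1L
    nrec <- n %/% 4L
    i1 <- seq_len(nrec) * 4L - 3L
    if (is.na(bad) && nrec) {
        ok <- startsWith(lines[i1], "@") & startsWith(lines[i1 + 2L], "+") &
            nchar(lines[i1 + 1L]) == nchar(lines[i1 + 3L])
        if (!all(ok)) bad <- which(!ok)[1]
    }
    if (!is.na(bad))
        stop("input error: malformed FASTQ record #", bad, " in ", path)
    list(id = substring(lines[i1], 2L), seq = lines[i1 + 1L],
         qual = lines[i1 + 3L])
}

#' Move the UMI from the read sequence into the read identifier
#'
#' Excises the UMI from the sequence and quality strings of the UMI-carrying
#' mate and appends it to the identifiers of both mates after
#' \code{layout$umi_delim}, so that the pair can be mapped without the UMI
#' affecting alignment while the molecule tag is preserved. With
#' \code{umi_length = 0} the output is identical to the input.
#'
#' @param fastq1,fastq2 Input mate FASTQ paths (mate 2 carries the UMI).
#' @param out1,out2 Output FASTQ paths.
#' @param layout A [readLayout] list.
#' @return \code{c(out1, out2)}, invisibly.
#' @export
rewriteUmiToHeader <- function(fastq1, fastq2, out1, out2,
                               layout = readLayout()) {
    r1 <- .read_fastq_q(fastq1)
    r2 <- .read_fastq_q(fastq2)
    if (length(r1$id) != length(r2$id))
        stop("input error: mate files contain different numbers of reads")
    U <- layout$umi_length
    if (U > 0L) {
        umi <- substr(r2$seq, 1L, U)
        r2$seq <- substring(r2$seq, U + 1L)
        r2$qual <- substring(r2$qual, U + 1L)
        r1$id <- paste0(r1$id, layout$umi_delim, umi)
        r2$id <- paste0(r2$id, layout$umi_delim, umi)
    }
    for (side in list(list(r1, out1), list(r2, out2))) {
        s <- DNAStringSet(side[[1]]$seq)
        names(s) <- side[[1]]$id
        writeXStringSet(s, side[[2]], format = "fastq",
                        qualities = BStringSet(side[[1]]$qual),
                        compress = grepl("\\.gz$", side[[2]]))
    }
    invisible(c(out1, out2))
}

#' Classify the allele observed by reads at a SNP
#'
#' Alignment-free: the SNP sits at a fixed offset inside the designed
#' gap-fill, so on mate 1 (ligation arm + gap-fill) its base is at position
#' \code{ligation-arm length + (offset - target_start) + 1}.
#'
#' @param mate1 Mate-1 sequences (character vector).
#' @param lig_len Ligation-arm length of the assigned probe.
#' @param target_start 0-based gap-fill start of the assigned probe.
#' @param offset 0-based transcript offset of the SNP.
#' @param ref,alt The two alleles (single bases).
#' @return Character vector \code{"ref"}, \code{"alt"} or \code{"other"}
#'   (also \code{"other"} when the position falls beyond the read).
#' @export
alleleOfRead <- function(mate1, lig_len, target_start, offset, ref, alt) {
    pos <- lig_len + (offset - target_start) + 1L
    base <- substr(as.character(mate1), pos, pos)
    out <- rep("other", length(base))
    out[base == ref] <- "ref"
    out[base == alt] <- "alt"
    out
}

## majority vote over a table of (snp_id, probe, umi, allele) read-level calls
.vote <- function(calls, tie = c("drop", "random"), seed = 1L) {
    tie <- match.arg(tie)
    if (!nrow(calls))
        return(data.frame(snp_id = character(), probe = character(),
                          ref_molecules = integer(), alt_molecules = integer(),
                          other_molecules = integer(),
                          tied_molecules = integer()))
    dt <- as.data.table(calls)
    tal <- dt[, list(n = .N), by = c("snp_id", "probe", "umi", "allele")]
    win <- tal[, {
        mx <- max(n)
        w <- allele[n == mx]
        if (length(w) == 1L) list(call = w)
        else if (tie == "random") {
            set.seed(seed + .GRP)
            list(call = sample(w, 1L))
        } else list(call = "tied")
    }, by = c("snp_id", "probe", "umi")]
    out <- win[, list(ref_molecules = sum(call == "ref"),
                      alt_molecules = sum(call == "alt"),
                      other_molecules = sum(call == "other"),
                      tied_molecules = sum(call == "tied")),
               by = c("snp_id", "probe")]
    as.data.frame(out)
}

## one-sided probe assignment on mate 1 (used by the SAM backend, where the
## UMI mate has already been rewritten)
.assign_mate1 <- function(m1, panel, layout) {
    p <- probeTable(panel)
    lig <- p$ligation_arm
    blen <- nchar(lig)
    mx <- layout$max_arm_mismatches
    n <- length(m1)
    probe <- rep(NA_character_, n)
    for (bb in unique(blen)) {
        sel <- which(blen == bb)
        idx <- match(substr(m1, 1L, bb), lig[sel])
        hit <- !is.na(idx) & is.na(probe)
        probe[hit] <- p$name[sel[idx[hit]]]
    }
    rem <- which(is.na(probe) & nchar(m1) >= min(blen))
    if (length(rem)) {
        maxb <- max(blen)
        M1 <- .char_matrix(substr(m1[rem], 1L, maxb), maxb)
        bestT <- rep(Inf, length(rem)); bestP <- rep(NA_integer_, length(rem))
        tied <- rep(FALSE, length(rem))
        for (j in seq_len(nrow(p))) {
            lc <- strsplit(lig[j], "", fixed = TRUE)[[1]]
            mm <- colSums(M1[seq_len(blen[j]), , drop = FALSE] != lc)
            mm[mm > mx] <- Inf
            eq <- which(mm == bestT & is.finite(mm))
            lt <- which(mm < bestT)
            tied[eq] <- TRUE; tied[lt] <- FALSE
            bestT[lt] <- mm[lt]; bestP[lt] <- j
        }
        ok <- is.finite(bestT) & !tied
        probe[rem[ok]] <- p$name[bestP[ok]]
    }
    probe
}

#' Allele-specific molecule counts from paired reads (alignment-free)
#'
#' Assigns read pairs to probes by arm matching, looks up the base at each
#' targeted SNP by gap-fill offset arithmetic, and collapses reads to
#' molecules by per-(probe, UMI) majority vote. Exact vote ties are excluded
#' from ratio estimation as \code{tied_molecules} by default.
#'
#' @param fastq1,fastq2 FASTQ paths, or \code{fastq1} a list of two read sets
#'   (see [countSample]).
#' @param panel A [MipPanel-class].
#' @param snps A [snpTargets] data.frame.
#' @param layout A [readLayout] list.
#' @param sample Sample name recorded in the output.
#' @param tie \code{"drop"} (default: ties become \code{tied_molecules}) or
#'   \code{"random"} (seeded random resolution, for sensitivity checks).
#' @param seed Seed for \code{tie = "random"}.
#' @return data.frame: \code{snp_id}, \code{probe}, \code{sample},
#'   \code{ref_molecules}, \code{alt_molecules}, \code{other_molecules},
#'   \code{tied_molecules}. Probes covering no targeted SNP do not appear.
#' @export
countAlleles <- function(fastq1, fastq2 = NULL, panel, snps,
                         layout = readLayout(), sample = "sample1",
                         tie = c("drop", "random"), seed = 1L) {
    tie <- match.arg(tie)
    snps <- snpTargets(snps)
    reads <- .read_pair_input(fastq1, fastq2)
    asg <- assignProbe(reads[[1]], reads[[2]], panel, layout)
    asg$dimer <- detectDimer(asg, reads[[1]], panel, layout)
    p <- probeTable(panel)
    keep <- asg$reason == "assigned" & !asg$dimer &
        (layout$keep_n_umis | !grepl("N", asg$umi, fixed = TRUE))
    calls <- vector("list", nrow(snps) * 4L); ci <- 0L
    for (s in seq_len(nrow(snps))) {
        cover <- which(p$target_id == snps$target_id[s] &
                       p$target_start <= snps$offset[s] &
                       p$target_end > snps$offset[s])
        for (j in cover) {
            idx <- which(keep & asg$probe == p$name[j])
            if (!length(idx)) next
            al <- alleleOfRead(reads[[1]][idx], nchar(p$ligation_arm[j]),
                               p$target_start[j], snps$offset[s],
                               snps$ref[s], snps$alt[s])
            ci <- ci + 1L
            calls[[ci]] <- data.frame(snp_id = snps$snp_id[s],
                                      probe = p$name[j],
                                      umi = asg$umi[idx], allele = al,
                                      stringsAsFactors = FALSE)
        }
    }
    calls <- if (ci) do.call(rbind, calls[seq_len(ci)]) else
        data.frame(snp_id = character(), probe = character(),
                   umi = character(), allele = character())
    out <- .vote(calls, tie = tie, seed = seed)
    if (nrow(out)) out$sample <- sample else out$sample <- character()
    out[, c("snp_id", "probe", "sample", "ref_molecules", "alt_molecules",
            "other_molecules", "tied_molecules")]
}

#' Allele-specific molecule counts from a SAM/BAM file
#'
#' Mapper-based backend sharing the vote logic of [countAlleles]. Expects
#' reads aligned to the transcript sequences (reference names = target ids,
#' ungapped alignments) with the UMI appended to the read identifier by
#' [rewriteUmiToHeader]. Only mate-1 records (FLAG 0x40, or unpaired reads)
#' are used; each is assigned to a probe by ligation-arm matching at the read
#' start (allowing \code{max_arm_mismatches}), and the SNP base is looked up
#' via the reference coordinate.
#'
#' @param file Path to a SAM or BAM file.
#' @param panel,snps,layout,sample,tie,seed As in [countAlleles].
#' @return As [countAlleles].
#' @export
countAllelesSam <- function(file, panel, snps, layout = readLayout(),
                            sample = "sample1", tie = c("drop", "random"),
                            seed = 1L) {
    tie <- match.arg(tie)
    if (!requireNamespace("Rsamtools", quietly = TRUE))
        stop("countAllelesSam requires the Rsamtools package")
    snps <- snpTargets(snps)
    if (grepl("\\.sam$", file))
        file <- Rsamtools::asBam(file, tempfile(), overwrite = TRUE,
                                 indexDestination = FALSE)
    b <- Rsamtools::scanBam(file,
        param = Rsamtools::ScanBamParam(
            what = c("qname", "flag", "rname", "pos", "cigar", "seq")))[[1]]
    first <- bitwAnd(b$flag, 1L) == 0L | bitwAnd(b$flag, 64L) == 64L
    mapped <- bitwAnd(b$flag, 4L) == 0L
    use <- which(first & mapped & !is.na(b$pos))
    if (!length(use))
        return(countAlleles(list(character(), character()), NULL, panel,
                            snps, layout, sample, tie, seed))
    m1 <- as.character(b$seq[use])
    rn <- as.character(b$rname[use])
    pos <- b$pos[use]
    ## a leading soft-clip (e.g. the non-collinear ligation arm) shifts the
    ## read index of every reference position
    clip <- integer(length(use))
    lead <- regmatches(b$cigar[use], regexpr("^[0-9]+S", b$cigar[use]))
    has <- grepl("^[0-9]+S", b$cigar[use])
    clip[has] <- as.integer(sub("S", "", lead))
    umi <- sub(paste0(".*\\", layout$umi_delim), "", b$qname[use])
    probe <- .assign_mate1(m1, panel, layout)
    p <- probeTable(panel)
    keep <- !is.na(probe) &
        (layout$keep_n_umis | !grepl("N", umi, fixed = TRUE))
    calls <- list(); ci <- 0L
    for (s in seq_len(nrow(snps))) {
        cover <- which(p$target_id == snps$target_id[s] &
                       p$target_start <= snps$offset[s] &
                       p$target_end > snps$offset[s])
        for (j in cover) {
            idx <- which(keep & probe == p$name[j] &
                         rn == snps$target_id[s])
            if (!length(idx)) next
            at <- snps$offset[s] + 1L - pos[idx] + 1L + clip[idx]  # 1-based in read
            base <- substr(m1[idx], at, at)
            al <- rep("other", length(base))
            al[base == snps$ref[s]] <- "ref"
            al[base == snps$alt[s]] <- "alt"
            ci <- ci + 1L
            calls[[ci]] <- data.frame(snp_id = snps$snp_id[s],
                                      probe = p$name[j], umi = umi[idx],
                                      allele = al, stringsAsFactors = FALSE)
        }
    }
    calls <- if (ci) do.call(rbind, calls) else
        data.frame(snp_id = character(), probe = character(),
                   umi = character(), allele = character())
    out <- .vote(calls, tie = tie, seed = seed)
    if (nrow(out)) out$sample <- sample else out$sample <- character()
    out[, c("snp_id", "probe", "sample", "ref_molecules", "alt_molecules",
            "other_molecules", "tied_molecules")]
}

#' Allelic ratio with exact binomial interval
#'
#' Ratio = ref / (ref + alt) per (snp, probe, sample) row, with a central
#' Clopper-Pearson interval on the molecule counts. Tied and \code{other}
#' molecules are excluded. Rows without informative molecules get \code{NA}.
#'
#' @param counts Output of [countAlleles] (or rows thereof).
#' @param level Confidence level (default 0.95).
#' @param collapse \code{"probe"} (default, one ratio per snp x probe x
#'   sample) or \code{"snp"} (molecule counts summed over probes first;
#'   molecules from different probes are independent).
#' @return The input rows with \code{ratio}, \code{lower}, \code{upper} and
#'   \code{n_informative} columns appended.
#' @export
allelicRatio <- function(counts, level = 0.95, collapse = c("probe", "snp")) {
    collapse <- match.arg(collapse)
    if (collapse == "snp" && nrow(counts)) {
        dt <- as.data.table(counts)
        counts <- as.data.frame(dt[, list(
            ref_molecules = sum(ref_molecules),
            alt_molecules = sum(alt_molecules),
            other_molecules = sum(other_molecules),
            tied_molecules = sum(tied_molecules)),
            by = c("snp_id", "sample")])
    }
    r <- counts$ref_molecules; a <- counts$alt_molecules
    n <- r + a
    alpha <- 1 - level
    counts$ratio <- ifelse(n > 0, r / n, NA_real_)
    counts$lower <- ifelse(n > 0,
                           ifelse(r == 0, 0, qbeta(alpha / 2, r, a + 1)),
                           NA_real_)
    counts$upper <- ifelse(n > 0,
                           ifelse(a == 0, 1, qbeta(1 - alpha / 2, r + 1, a)),
                           NA_real_)
    counts$n_informative <- n
    counts
}

#' Ratio of allelic ratios across a serial dilution
#'
#' In a two-genotype serial dilution where each step retains \code{rate} of
#' the previous mix, the ratio of allelic ratios between consecutive steps is
#' expected to equal \code{rate}; the absolute ratio of the first step is not
#' predictable a priori (it depends on the relative expression of each gene
#' in the two genotypes). Computes per-pair step ratios and their geometric
#' mean across steps and SNPs.
#'
#' @param ratios A data.frame with columns \code{step} (integer step order),
#'   \code{snp_id}, \code{ratio} and optionally \code{probe} (series are
#'   formed within snp x probe when present).
#' @return A list with \code{step_ratios} (data.frame: series keys,
#'   \code{step_from}, \code{step_to}, \code{step_ratio}),
#'   \code{geometric_mean}, \code{n_pairs}, \code{gaps} (skipped step pairs)
#'   and \code{note}.
#' @export
dilutionRatioOfRatios <- function(ratios) {
    stopifnot(all(c("step", "snp_id", "ratio") %in% colnames(ratios)))
    keys <- c("snp_id", if ("probe" %in% colnames(ratios)) "probe")
    dt <- as.data.table(ratios)[order(step)]
    pairs <- dt[, {
        ok <- !is.na(ratio) & ratio > 0
        st <- step[ok]; rt <- ratio[ok]
        if (length(st) >= 2L) {
            list(step_from = st[-length(st)], step_to = st[-1],
                 step_ratio = rt[-1] / rt[-length(rt)])
        } else list(step_from = integer(), step_to = integer(),
                    step_ratio = numeric())
    }, by = keys]
    pairs <- as.data.frame(pairs)
    consecutive <- pairs$step_to == pairs$step_from + 1L
    gaps <- pairs[!consecutive, , drop = FALSE]
    pairs <- pairs[consecutive, , drop = FALSE]
    gm <- if (nrow(pairs)) exp(mean(log(pairs$step_ratio))) else NA_real_
    list(step_ratios = pairs, geometric_mean = gm, n_pairs = nrow(pairs),
         gaps = gaps,
         note = paste("The absolute allelic ratio of the first dilution step",
                      "is not predictable a priori; only consecutive-step",
                      "ratios of ratios are compared to the dilution rate."))
}
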