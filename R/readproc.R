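## Alignment-free conversion of paired-end capture reads into per-probe
## error-corrected unique-molecule counts. Reads are never mapped to a
## reference: each pair is matched directly against the designed arm
## sequences, which avoids mapping biases.
##
## Read layout (configurable via readLayout): mate 1 begins with the ligation
## arm followed by the gap-fill in transcript orientation; mate 2 begins with
## the UMI, followed by the reverse complement of the extension arm and then
## the reverse complement of the gap-fill.

#' Read layout of an smMIP sequencing library
#'
#' @param umi_length UMI length in nucleotides (default 9).
#' @param max_arm_mismatches Maximum Hamming mismatches tolerated per arm when
#'   assigning a read pair to a probe (default 2).
#' @param min_insert Minimum gap-fill length below which a read pair is
#'   treated as an extension-ligation dimer (default 20 nt: well below the
#'   100-112 nt designed gap-fills, well above read-start noise).
#' @param umi_delim Delimiter used when moving the UMI into the read
#'   identifier (default \code{":"}).
#' @param keep_n_umis Keep reads whose UMI contains an N as distinct UMIs
#'   (default \code{FALSE}: such reads are dropped).
#' @return A named list of class \code{ReadLayout}.
#' @export
readLayout <- function(umi_length = 9L, max_arm_mismatches = 2L,
                       min_insert = 20L, umi_delim = ":",
                       keep_n_umis = FALSE) {
    stopifnot(umi_length >= 0L, max_arm_mismatches >= 0L, min_insert >= 0L)
    structure(list(umi_length = as.integer(umi_length),
                   max_arm_mismatches = as.integer(max_arm_mismatches),
                   min_insert = as.integer(min_insert),
                   umi_delim = umi_delim,
                   keep_n_umis = isTRUE(keep_n_umis)),
              class = "ReadLayout")
}

.revcomp_chr <- function(x) {
    if (!length(x)) return(character())
    as.character(reverseComplement(DNAStringSet(x)))
}

## Pad strings on the right with '?' to a common width (so that short reads
## accumulate mismatches against long arms instead of erroring).
.pad <- function(x, width) {
    d <- pmax(0L, width - nchar(x))
    paste0(x, strrep("?", d))
}

## character matrix (width x n) from equal-width strings
.char_matrix <- function(x, width) {
    matrix(unlist(strsplit(.pad(x, width), "", fixed = TRUE), use.names = FALSE),
           nrow = width)
}

#' Assign read pairs to panel probes by arm matching
#'
#' Compares each mate's expected arm prefix (after removing the UMI from
#' mate 2) to every probe in the panel under Hamming distance. A pair is
#' assigned to the probe minimising the total number of arm mismatches among
#' the probes for which both arms are within \code{max_arm_mismatches};
#' exact ties are left unassigned with reason \code{"ambiguous"}. Pairs too
#' short to contain any probe's arms get reason \code{"short"}; pairs matching
#' no probe get \code{"no_match"}.
#'
#' @param mate1,mate2 Character vectors or [Biostrings::DNAStringSet]s of
#'   equal length: the two mates of each pair, in order.
#' @param panel A [MipPanel-class].
#' @param layout A [readLayout] list.
#' @return A data.frame with one row per pair: \code{probe} (NA when
#'   unassigned), \code{mm_ext}, \code{mm_lig}, \code{umi}, \code{reason}
#'   (\code{"assigned"}, \code{"ambiguous"}, \code{"short"} or
#'   \code{"no_match"}).
#' @export
assignProbe <- function(mate1, mate2, panel, layout = readLayout()) {
    m1 <- as.character(mate1)
    m2 <- as.character(mate2)
    if (length(m1) != length(m2))
        stop("input error: mate vectors differ in length")
    n <- length(m1)
    p <- probeTable(panel)
    U <- layout$umi_length
    mx <- layout$max_arm_mismatches
    lig <- p$ligation_arm
    extrc <- .revcomp_chr(p$extension_arm)
    blen <- nchar(lig)
    alen <- nchar(extrc)

    res <- data.frame(probe = rep(NA_character_, n),
                      mm_ext = rep(NA_integer_, n),
                      mm_lig = rep(NA_integer_, n),
                      umi = substr(m2, 1L, U),
                      reason = rep("no_match", n),
                      stringsAsFactors = FALSE)
    if (n == 0L || nrow(p) == 0L) return(res)

    short <- nchar(m1) < min(blen) | nchar(m2) < U + min(alen)
    res$reason[short] <- "short"

    ## ---- exact pass: hash lookup per (ligation, extension) length group ----
    nhit <- integer(n)
    hit <- rep(NA_integer_, n)
    grp <- paste(blen, alen)
    for (g in unique(grp)) {
        sel <- which(grp == g)
        bb <- blen[sel[1]]; aa <- alen[sel[1]]
        keys_probe <- paste0(lig[sel], "|", extrc[sel])
        keys_read <- paste0(substr(m1, 1L, bb), "|",
                            substr(m2, U + 1L, U + aa))
        idx <- match(keys_read, keys_probe)
        found <- which(!is.na(idx) & !short)
        if (!length(found)) next
        dupkey <- keys_probe %in% keys_probe[duplicated(keys_probe)]
        amb <- dupkey[idx[found]]
        nhit[found] <- nhit[found] + 1L + amb
        hit[found] <- sel[idx[found]]
    }
    exact <- which(nhit == 1L)
    res$probe[exact] <- p$name[hit[exact]]
    res$mm_ext[exact] <- 0L
    res$mm_lig[exact] <- 0L
    res$reason[exact] <- "assigned"
    res$reason[nhit >= 2L] <- "ambiguous"

    ## ---- Hamming pass over the remainder ----
    rem <- which(nhit == 0L & !short)
    if (length(rem)) {
        maxb <- max(blen); maxa <- max(alen)
        M1 <- .char_matrix(substr(m1[rem], 1L, maxb), maxb)
        M2 <- .char_matrix(substr(m2[rem], U + 1L, U + maxa), maxa)
        nr <- length(rem)
        bestT <- rep(Inf, nr)
        bestP <- rep(NA_integer_, nr)
        bestE <- bestL <- rep(NA_integer_, nr)
        tied <- rep(FALSE, nr)
        for (j in seq_len(nrow(p))) {
            lc <- strsplit(lig[j], "", fixed = TRUE)[[1]]
            ec <- strsplit(extrc[j], "", fixed = TRUE)[[1]]
            mmL <- colSums(M1[seq_len(blen[j]), , drop = FALSE] != lc)
            mmE <- colSums(M2[seq_len(alen[j]), , drop = FALSE] != ec)
            tot <- ifelse(mmL <= mx & mmE <= mx, mmL + mmE, Inf)
            eq <- which(tot == bestT & is.finite(tot))
            lt <- which(tot < bestT)
            tied[eq] <- TRUE
            tied[lt] <- FALSE
            bestT[lt] <- tot[lt]
            bestP[lt] <- j
            bestE[lt] <- mmE[lt]
            bestL[lt] <- mmL[lt]
        }
        ok <- is.finite(bestT) & !tied
        res$probe[rem[ok]] <- p$name[bestP[ok]]
        res$mm_ext[rem[ok]] <- bestE[ok]
        res$mm_lig[rem[ok]] <- bestL[ok]
        res$reason[rem[ok]] <- "assigned"
        res$reason[rem[is.finite(bestT) & tied]] <- "ambiguous"
    }
    res
}

#' Flag extension-ligation dimers
#'
#' A dimer is a capture product without a genuine gap-fill: the sequence
#' immediately following the ligation arm on mate 1 is the extension arm
#' itself (insert effectively absent or shorter than
#' \code{layout$min_insert}). Flagged pairs are excluded from UMI tallies.
#'
#' @param assignments Output of [assignProbe].
#' @param mate1 Mate-1 sequences (character or DNAStringSet), same order.
#' @param panel A [MipPanel-class].
#' @param layout A [readLayout] list.
#' @return Logical vector, \code{TRUE} for dimers (always \code{FALSE} for
#'   unassigned pairs).
#' @export
detectDimer <- function(assignments, mate1, panel, layout = readLayout()) {
    m1 <- as.character(mate1)
    p <- probeTable(panel)
    dimer <- rep(FALSE, length(m1))
    if (layout$min_insert <= 0L) return(dimer)
    idx <- which(assignments$reason == "assigned")
    if (!length(idx)) return(dimer)
    pi <- match(assignments$probe[idx], p$name)
    for (j in unique(pi)) {
        sel <- idx[pi == j]
        b <- nchar(p$ligation_arm[j])
        arm <- p$extension_arm[j]
        window <- substr(m1[sel], b + 1L,
                         b + layout$min_insert + nchar(arm) - 1L)
        pos <- regexpr(arm, window, fixed = TRUE)
        dimer[sel] <- pos > 0L & pos <= layout$min_insert
    }
    dimer
}

#' Tally reads per (probe, UMI)
#'
#' Groups retained (assigned, non-dimer) reads of one sample by probe and
#' exact UMI sequence. UMIs containing \code{N} are dropped by default
#' (\code{layout$keep_n_umis} keeps them as distinct UMIs).
#'
#' @param assignments Output of [assignProbe], optionally with a logical
#'   \code{dimer} column ([detectDimer] output).
#' @param layout A [readLayout] list.
#' @return A data.frame \code{probe}, \code{umi}, \code{reads}; one row per
#'   observed (probe, UMI) pair.
#' @export
tallyUmis <- function(assignments, layout = readLayout()) {
    keep <- assignments$reason == "assigned"
    if (!is.null(assignments$dimer)) keep <- keep & !assignments$dimer
    if (!layout$keep_n_umis) keep <- keep & !grepl("N", assignments$umi,
                                                   fixed = TRUE)
    if (!any(keep))
        return(data.frame(probe = character(), umi = character(),
                          reads = integer(), stringsAsFactors = FALSE))
    dt <- data.table(probe = assignments$probe[keep],
                     umi = assignments$umi[keep])
    out <- dt[, list(reads = .N), by = c("probe", "umi")]
    as.data.frame(out)
}

#' Sequencing-error correction of UMI counts by read-coverage threshold
#'
#' Sequencing errors inside the UMI create phantom UMIs that inflate molecule
#' counts; these phantoms tend to have low read coverage. For a probe's UMI
#' coverage multiset the threshold R is the largest integer such that the
#' UMIs with coverage >= R still account for at least \code{fraction} (default
#' 95\%) of all the probe's reads; only those UMIs are counted as molecules.
#' The retained-read fraction is therefore >= \code{fraction} by construction.
#'
#' @param coverages Integer vector of reads per UMI (all >= 1).
#' @param fraction Minimum fraction of reads the retained UMIs must account
#'   for (default 0.95).
#' @param strict Use a strictly-greater-than threshold (coverage > R) instead
#'   of the default >= reading (default \code{FALSE}).
#' @return A list with \code{threshold_R} and \code{molecules}. Empty input
#'   gives \code{threshold_R = NA} and 0 molecules.
#' @export
#' @examples
#' errorCorrectedCount(c(100, 50, 1, 1, 1, 1, 1))  # R = 50, 2 molecules
errorCorrectedCount <- function(coverages, fraction = 0.95, strict = FALSE) {
    if (!length(coverages))
        return(list(threshold_R = NA_integer_, molecules = 0L))
    coverages <- as.integer(coverages)
    if (any(coverages < 1L)) stop("coverages must all be >= 1")
    total <- sum(coverages)
    if (strict) {
        ## sum(c > r) is constant on [u_{k-1}, u_k - 1]; the largest feasible
        ## r is therefore one below a coverage value
        for (r in sort(unique(coverages) - 1L, decreasing = TRUE)) {
            if (sum(coverages[coverages > r]) >= fraction * total)
                return(list(threshold_R = r,
                            molecules = sum(coverages > r)))
        }
        return(list(threshold_R = 0L, molecules = length(coverages)))
    }
    for (r in sort(unique(coverages), decreasing = TRUE)) {
        if (sum(coverages[coverages >= r]) >= fraction * total)
            return(list(threshold_R = r, molecules = sum(coverages >= r)))
    }
    list(threshold_R = 1L, molecules = length(coverages))
}

.read_pair_input <- function(fastq1, fastq2 = NULL) {
    if (is.list(fastq1) && length(fastq1) == 2L && is.null(fastq2)) {
        m1 <- fastq1[[1]]; m2 <- fastq1[[2]]
    } else {
        m1 <- readDNAStringSet(fastq1, format = "fastq")
        m2 <- readDNAStringSet(fastq2, format = "fastq")
    }
    if (length(m1) != length(m2))
        stop("input error: mate files contain different numbers of reads")
    list(as.character(m1), as.character(m2))
}

#' Count error-corrected molecules for one sample
#'
#' Runs the full alignment-free counting chain on a paired FASTQ sample:
#' probe assignment, dimer removal, per-probe UMI tallies and the
#' read-coverage threshold. Probes absent from the sample get zero counts.
#'
#' @param fastq1,fastq2 Paths to the two mate FASTQ files (plain or gzip), or
#'   \code{fastq1} may be a list of two DNAStringSets/character vectors (in
#'   which case \code{fastq2} is omitted).
#' @param panel A [MipPanel-class].
#' @param layout A [readLayout] list.
#' @param fraction,strict Passed to [errorCorrectedCount].
#' @return A list with \code{counts} (data.frame: \code{probe},
#'   \code{raw_umis}, \code{threshold_R}, \code{molecules},
#'   \code{total_reads}) and \code{qc} (one-row data.frame of read-fate
#'   fractions and the molecules-to-reads ratio).
#' @export
countSample <- function(fastq1, fastq2 = NULL, panel, layout = readLayout(),
                        fraction = 0.95, strict = FALSE) {
    reads <- .read_pair_input(fastq1, fastq2)
    asg <- assignProbe(reads[[1]], reads[[2]], panel, layout)
    asg$dimer <- detectDimer(asg, reads[[1]], panel, layout)
    umis <- tallyUmis(asg, layout)
    p <- probeTable(panel)
    counts <- data.frame(probe = p$name, raw_umis = 0L,
                         threshold_R = NA_integer_, molecules = 0L,
                         total_reads = 0L, stringsAsFactors = FALSE)
    if (nrow(umis)) {
        by_probe <- split(umis$reads, umis$probe)
        for (nm in names(by_probe)) {
            i <- match(nm, counts$probe)
            cc <- errorCorrectedCount(by_probe[[nm]], fraction, strict)
            counts$raw_umis[i] <- length(by_probe[[nm]])
            counts$threshold_R[i] <- cc$threshold_R
            counts$molecules[i] <- cc$molecules
            counts$total_reads[i] <- sum(by_probe[[nm]])
        }
    }
    n <- length(reads[[1]])
    qc <- data.frame(
        n_pairs = n,
        frac_assigned = if (n) mean(asg$reason == "assigned") else NA_real_,
        frac_ambiguous = if (n) mean(asg$reason == "ambiguous") else NA_real_,
        frac_short = if (n) mean(asg$reason == "short") else NA_real_,
        frac_no_match = if (n) mean(asg$reason == "no_match") else NA_real_,
        frac_dimer = if (n) mean(asg$dimer) else NA_real_,
        molecules_per_read = if (sum(counts$total_reads) > 0)
            sum(counts$molecules) / sum(counts$total_reads) else NA_real_)
    list(counts = counts, qc = qc)
}

#' MoleculeCounts: error-corrected molecule counts per probe and sample
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass with assays
#' \code{molecules} (the quantification currency), \code{rawUmis},
#' \code{thresholdR} and \code{totalReads}; probes on rows, samples on
#' columns. \code{colData} carries at least \code{condition},
#' \code{replicate_class} and \code{experiment}.
#'
#' @export
setClass("MoleculeCounts", contains = "SummarizedExperiment")

setValidity("MoleculeCounts", function(object) {
    a <- SummarizedExperiment::assayNames(object)
    need <- c("molecules", "rawUmis", "thresholdR", "totalReads")
    if (!all(need %in% a))
        return(paste("missing assays:", paste(setdiff(need, a), collapse = ", ")))
    m <- SummarizedExperiment::assay(object, "molecules")
    if (any(m < 0)) return("molecule counts must be non-negative")
    if (any(m > SummarizedExperiment::assay(object, "rawUmis")))
        return("molecules must not exceed raw UMI counts")
    need_cd <- c("condition", "replicate_class", "experiment")
    if (!all(need_cd %in% colnames(SummarizedExperiment::colData(object))))
        return(paste("colData must contain",
                     paste(need_cd, collapse = ", ")))
    TRUE
})

#' Construct a MoleculeCounts object
#'
#' @param molecules Integer matrix, probes x samples.
#' @param colData A data.frame (samples in rows) with at least
#'   \code{condition}; missing \code{replicate_class}/\code{experiment}
#'   default to a single class/experiment.
#' @param rawUmis,thresholdR,totalReads Optional matching matrices; defaults
#'   treat \code{molecules} as uncorrected (rawUmis = molecules).
#' @param probeData Optional data.frame of per-probe annotation (rowData),
#'   e.g. a [probeTable].
#' @return A [MoleculeCounts-class] object.
#' @export
MoleculeCounts <- function(molecules, colData, rawUmis = NULL,
                           thresholdR = NULL, totalReads = NULL,
                           probeData = NULL) {
    molecules <- as.matrix(molecules)
    if (is.null(rawUmis)) rawUmis <- molecules
    if (is.null(thresholdR))
        thresholdR <- matrix(1L, nrow(molecules), ncol(molecules),
                             dimnames = dimnames(molecules))
    if (is.null(totalReads)) totalReads <- molecules
    colData <- as.data.frame(colData)
    if (is.null(colData$sample))
        colData$sample <- colnames(molecules)
    if (is.null(colData$replicate_class)) colData$replicate_class <- "class1"
    if (is.null(colData$experiment)) colData$experiment <- "exp1"
    rownames(colData) <- colData$sample
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(molecules = molecules, rawUmis = rawUmis,
                      thresholdR = thresholdR, totalReads = totalReads),
        colData = DataFrame(colData))
    if (!is.null(probeData))
        SummarizedExperiment::rowData(se) <-
            DataFrame(probeData[match(rownames(molecules), probeData$name), ,
                                drop = FALSE])
    as(se, "MoleculeCounts")
}

#' Molecule-count assay
#' @param object A [MoleculeCounts-class].
#' @return Integer matrix probes x samples.
#' @export
molecules <- function(object) SummarizedExperiment::assay(object, "molecules")

#' Count molecules for all samples of a sample sheet
#'
#' @param sampleSheet A data.frame with columns \code{sample}, \code{fastq1},
#'   \code{fastq2}, \code{condition} and optionally \code{replicate_class},
#'   \code{experiment}.
#' @param panel A [MipPanel-class].
#' @param layout A [readLayout] list.
#' @param fraction,strict Passed to [errorCorrectedCount].
#' @return A [MoleculeCounts-class]; per-sample QC is stored in
#'   \code{metadata(x)$qc}.
#' @export
countSamples <- function(sampleSheet, panel, layout = readLayout(),
                         fraction = 0.95, strict = FALSE) {
    sampleSheet <- as.data.frame(sampleSheet)
    P <- length(panel)
    nms <- names(panel)
    ns <- nrow(sampleSheet)
    mk <- function() matrix(0L, P, ns, dimnames = list(nms, sampleSheet$sample))
    mol <- mk(); raw <- mk(); thr <- mk(); tot <- mk()
    thr[] <- NA_integer_
    qc <- vector("list", ns)
    for (i in seq_len(ns)) {
        res <- countSample(sampleSheet$fastq1[i], sampleSheet$fastq2[i],
                           panel, layout, fraction, strict)
        mol[, i] <- res$counts$molecules
        raw[, i] <- res$counts$raw_umis
        thr[, i] <- res$counts$threshold_R
        tot[, i] <- res$counts$total_reads
        qc[[i]] <- cbind(sample = sampleSheet$sample[i], res$qc)
    }
    mc <- MoleculeCounts(mol, sampleSheet, rawUmis = raw, thresholdR = thr,
                         totalReads = tot, probeData = probeTable(panel))
    S4Vectors::metadata(mc)$qc <- do.call(rbind, qc)
    mc
}
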