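## Probe design against spliced transcript models: splicing and coordinate
## conversion, target segmentation, exhaustive candidate enumeration, arm
## copy-number filtering and SNP probe-pair selection.
##
## Genomic exon coordinates follow the Bioconductor convention (1-based
## closed, IRanges); transcript offsets and probe target coordinates are
## 0-based half-open, matching the panel TSV. VCF positions are 1-based and
## converted at the boundary only.

#' TranscriptModel: a spliced transcript on a reference
#'
#' @slot id Transcript identifier.
#' @slot chrom Reference sequence name.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot exons Genomic exon intervals (1-based closed [IRanges::IRanges],
#'   sorted, non-overlapping).
#' @slot sequence Spliced transcript sequence (character; reverse complement
#'   of the exon concatenation for \code{"-"} strand).
#' @slot txmap Integer vector: for each transcript offset (0-based, in
#'   transcript order) the corresponding 1-based genomic position.
#' @export
setClass("TranscriptModel",
         representation(id = "character", chrom = "character",
                        strand = "character", exons = "IRanges",
                        sequence = "character", txmap = "integer"))

setValidity("TranscriptModel", function(object) {
    w <- sum(IRanges::width(object@exons))
    if (nchar(object@sequence) != w)
        return("sequence length must equal total exon length")
    if (!object@strand %in% c("+", "-"))
        return("strand must be '+' or '-'")
    if (length(object@txmap) != w)
        return("coordinate map length must equal transcript length")
    TRUE
})

setMethod("show", "TranscriptModel", function(object) {
    cat("TranscriptModel", object@id, "on", object@chrom, object@strand,
        "|", length(object@exons), "exon(s),",
        nchar(object@sequence), "nt\n")
})

#' @describeIn TranscriptModel Spliced length in nucleotides.
#' @param x A \code{TranscriptModel}.
#' @export
setMethod("length", "TranscriptModel", function(x) nchar(x@sequence))

#' Transcript sequence as character
#' @param tx A [TranscriptModel-class].
#' @return The spliced sequence.
#' @export
txSequence <- function(tx) tx@sequence

#' Transcript-order offsets of internal exon-exon boundaries
#'
#' A boundary at offset \code{b} separates transcript bases \code{b - 1} and
#' \code{b} (0-based).
#' @param tx A [TranscriptModel-class].
#' @return Integer vector (empty for single-exon transcripts).
#' @export
exonBoundaries <- function(tx) {
    w <- IRanges::width(tx@exons)
    if (tx@strand == "-") w <- rev(w)
    if (length(w) < 2L) return(integer())
    as.integer(cumsum(w)[-length(w)])
}

#' Splice a transcript model out of a reference sequence
#'
#' Extracts and concatenates the exon sequences; for minus-strand transcripts
#' the concatenation is reverse-complemented and the exon order in transcript
#' coordinates is reversed accordingly. The genomic<->transcript coordinate
#' maps are mutually inverse on every exonic base.
#'
#' @param exons Exon intervals, as an [IRanges::IRanges] (1-based closed) or
#'   a two-column matrix/data.frame of \code{start}, \code{end}.
#' @param genome Reference sequence: a [Biostrings::DNAStringSet] (in which
#'   case \code{chrom} selects the sequence), a \code{DNAString}, or a
#'   character string.
#' @param strand \code{"+"} or \code{"-"}.
#' @param id Transcript identifier.
#' @param chrom Reference name (used to index \code{genome} when it is a set).
#' @return A [TranscriptModel-class].
#' @export
spliceTranscript <- function(exons, genome, strand = "+", id = "tx",
                             chrom = "ref") {
    if (!is(exons, "IRanges")) {
        exons <- as.data.frame(exons)
        exons <- IRanges(start = exons[[1]], end = exons[[2]])
    }
    exons <- exons[order(IRanges::start(exons))]
    if (length(exons) > 1L &&
        any(IRanges::start(exons)[-1] <= IRanges::end(exons)[-length(exons)]))
        stop("coordinate error: exons overlap")
    refseq <- if (is(genome, "DNAStringSet")) {
        if (!chrom %in% names(genome))
            stop("coordinate error: reference '", chrom, "' not found")
        as.character(genome[[chrom]])
    } else as.character(genome)
    if (min(IRanges::start(exons)) < 1L ||
        max(IRanges::end(exons)) > nchar(refseq))
        stop("coordinate error: exon outside reference bounds")
    pieces <- substring(refseq, IRanges::start(exons), IRanges::end(exons))
    seq_plus <- paste(pieces, collapse = "")
    map_plus <- unlist(lapply(seq_len(length(exons)), function(i)
        seq.int(IRanges::start(exons)[i], IRanges::end(exons)[i])))
    if (strand == "-") {
        sequence <- as.character(reverseComplement(DNAStringSet(seq_plus))[[1]])
        txmap <- rev(map_plus)
    } else {
        sequence <- seq_plus
        txmap <- map_plus
    }
    new("TranscriptModel", id = id, chrom = chrom, strand = strand,
        exons = exons, sequence = sequence, txmap = as.integer(txmap))
}

#' Convert genomic positions to transcript offsets
#'
#' @param pos 1-based genomic position(s), e.g. VCF \code{POS}.
#' @param tx A [TranscriptModel-class].
#' @return Integer 0-based transcript offset(s); \code{NA} for intronic or
#'   out-of-transcript positions.
#' @export
genomicToTranscript <- function(pos, tx) {
    idx <- match(as.integer(pos), tx@txmap)
    as.integer(idx - 1L)
}

#' Convert transcript offsets to genomic positions
#'
#' Inverse of [genomicToTranscript] on every exonic base.
#' @param offset 0-based transcript offset(s).
#' @param tx A [TranscriptModel-class].
#' @return 1-based genomic position(s); \code{NA} outside the transcript.
#' @export
transcriptToGenomic <- function(offset, tx) {
    offset <- as.integer(offset)
    out <- rep(NA_integer_, length(offset))
    ok <- !is.na(offset) & offset >= 0L & offset < length(tx@txmap)
    out[ok] <- tx@txmap[offset[ok] + 1L]
    out
}

#' Design constraints for smMIP enumeration
#'
#' @param arm_min,arm_max Minimum/maximum length of each individual arm
#'   (defaults 16 and 24 nt).
#' @param arm_total Combined length of the two arms (default 40 nt).
#' @param target_length Gap-fill length between the arms (default 112 nt for
#'   expression panels; SNP panels use 100 nt).
#' @param max_copy_number Maximum reference copy number allowed for each arm
#'   (default 1: both arms must be unique in the reference).
#' @param segment_length Length of the non-overlapping transcript segments
#'   used to spread expression probes along a target (default 200 nt).
#' @return A named list of class \code{DesignConstraints}.
#' @export
designConstraints <- function(arm_min = 16L, arm_max = 24L, arm_total = 40L,
                              target_length = 112L, max_copy_number = 1L,
                              segment_length = 200L) {
    if (arm_min > arm_max)
        stop("arm_min must be <= arm_max")
    if (2L * arm_min > arm_total || arm_total > 2L * arm_max)
        stop("arm_total must lie in [2*arm_min, 2*arm_max]")
    structure(list(arm_min = as.integer(arm_min), arm_max = as.integer(arm_max),
                   arm_total = as.integer(arm_total),
                   target_length = as.integer(target_length),
                   max_copy_number = as.integer(max_copy_number),
                   segment_length = as.integer(segment_length)),
              class = "DesignConstraints")
}

#' Divide a transcript into non-overlapping segments
#'
#' Consecutive windows of \code{segment_length} nucleotides; a trailing
#' remainder shorter than \code{segment_length} is emitted flagged as partial
#' rather than silently dropped.
#'
#' @param tx A [TranscriptModel-class], or an integer transcript length.
#' @param segment_length Window size in nucleotides (>= 1).
#' @return A data.frame with 0-based half-open \code{start}, \code{end} and a
#'   logical \code{partial} column.
#' @export
segmentTargets <- function(tx, segment_length = 200L) {
    stopifnot(segment_length >= 1L)
    L <- if (is(tx, "TranscriptModel")) length(tx) else as.integer(tx)
    if (L <= 0L)
        return(data.frame(start = integer(), end = integer(),
                          partial = logical()))
    starts <- seq.int(0L, L - 1L, by = segment_length)
    ends <- pmin(starts + as.integer(segment_length), L)
    data.frame(start = as.integer(starts), end = as.integer(ends),
               partial = (ends - starts) < segment_length)
}

## All (ext_len, lig_len) splits allowed by the constraints.
.arm_splits <- function(constraints) {
    a <- seq.int(constraints$arm_min, constraints$arm_max)
    a <- a[constraints$arm_total - a >= constraints$arm_min &
           constraints$arm_total - a <= constraints$arm_max]
    data.frame(ext = a, lig = constraints$arm_total - a)
}

#' Exhaustively enumerate candidate smMIPs around an anchor
#'
#' Enumerates every placement and arm-length split consistent with the
#' constraints. A candidate consists of an extension arm annealing directly
#' upstream (5', in transcript orientation) of the gap-fill and a ligation arm
#' directly downstream; the gap-fill has exactly \code{target_length}
#' nucleotides. For a segment anchor the gap-fill must lie inside the segment;
#' for a SNP anchor the SNP offset must fall inside the gap-fill (never inside
#' an arm). Candidates whose arm or gap-fill straddles an exon-exon boundary
#' are flagged \code{junction_crossing}.
#'
#' @param tx A [TranscriptModel-class].
#' @param anchor Either \code{list(segment = c(start, end))} (0-based
#'   half-open) or \code{list(snp_offset = o)} (0-based transcript offset).
#'   \code{NULL} anchors the whole transcript.
#' @param constraints A [designConstraints] list.
#' @return A data.frame of candidates: probe fields (as in
#'   [MipPanel-class]) plus arm placements \code{ext_start}, \code{ext_end},
#'   \code{lig_start}, \code{lig_end} (0-based half-open transcript
#'   coordinates). Zero rows when the transcript cannot accommodate any
#'   placement.
#' @export
enumerateCandidates <- function(tx, anchor = NULL,
                                constraints = designConstraints()) {
    stopifnot(is(tx, "TranscriptModel"))
    L <- length(tx)
    Tlen <- constraints$target_length
    splits <- .arm_splits(constraints)
    bnd <- exonBoundaries(tx)
    out <- vector("list", nrow(splits))
    for (i in seq_len(nrow(splits))) {
        a <- splits$ext[i]; b <- splits$lig[i]
        ## gap-fill start g must leave room for both arms
        g_lo <- a
        g_hi <- L - Tlen - b           # last admissible g (0-based)
        if (!is.null(anchor$segment)) {
            g_lo <- max(g_lo, anchor$segment[1])
            g_hi <- min(g_hi, anchor$segment[2] - Tlen)
        }
        if (!is.null(anchor$snp_offset)) {
            s <- anchor$snp_offset
            g_lo <- max(g_lo, s - Tlen + 1L)
            g_hi <- min(g_hi, s)
        }
        if (g_hi < g_lo) next
        g <- seq.int(g_lo, g_hi)
        cross <- if (length(bnd)) {
            vapply(g, function(gg) any(bnd > gg - a & bnd < gg + Tlen + b &
                                       bnd != gg & bnd != gg + Tlen),
                   logical(1))
        } else rep(FALSE, length(g))
        out[[i]] <- data.frame(
            target_id = tx@id,
            target_start = g, target_end = g + Tlen,
            ext_start = g - a, ext_end = g,
            lig_start = g + Tlen, lig_end = g + Tlen + b,
            extension_arm = substring(tx@sequence, g - a + 1L, g),
            ligation_arm = substring(tx@sequence, g + Tlen + 1L, g + Tlen + b),
            junction_crossing = cross,
            stringsAsFactors = FALSE)
    }
    cand <- do.call(rbind, out)
    if (is.null(cand))
        return(data.frame(name = character(), gene = character(),
                          target_id = character(), target_start = integer(),
                          target_end = integer(), ext_start = integer(),
                          ext_end = integer(), lig_start = integer(),
                          lig_end = integer(), extension_arm = character(),
                          ligation_arm = character(),
                          junction_crossing = logical()))
    cand <- cand[order(cand$target_start, cand$ext_start), , drop = FALSE]
    cand$name <- sprintf("%s_g%d_e%d", tx@id, cand$target_start,
                         cand$ext_end - cand$ext_start)
    cand$gene <- tx@id
    rownames(cand) <- NULL
    cand[, c("name", "gene", "target_id", "target_start", "target_end",
             "ext_start", "ext_end", "lig_start", "lig_end",
             "extension_arm", "ligation_arm", "junction_crossing")]
}

#' Reference copy number of a probe arm
#'
#' Counts exact occurrences of the arm and of its reverse complement across a
#' set of reference sequences. This deterministic exact-match count stands in
#' for read-mapper-based copy estimation; externally computed copy numbers can
#' be supplied to [filterCandidates] instead.
#'
#' @param arm Arm sequence (character, ACGT).
#' @param references A [Biostrings::DNAStringSet] (or character vector) of
#'   reference sequences.
#' @return Integer occurrence count (both strands).
#' @export
armCopyNumber <- function(arm, references) {
    if (!nzchar(arm)) stop("input error: empty arm")
    if (is.character(references)) references <- DNAStringSet(references)
    if (!length(references)) stop("input error: empty reference set")
    fwd <- sum(vcountPattern(arm, references))
    rc <- as.character(reverseComplement(DNAStringSet(arm))[[1]])
    fwd + sum(vcountPattern(rc, references))
}

#' Filter candidate probes on arm copy number and arm variants
#'
#' Keeps candidates whose arms each occur between once and
#' \code{max_copy_number} times in the reference set (an absent arm is also
#' rejected), and optionally removes candidates whose arms overlap known
#' variant positions, so that common polymorphisms cannot disturb arm
#' hybridization.
#'
#' @param candidates Output of [enumerateCandidates].
#' @param references Reference sequences for [armCopyNumber]; omit to skip the
#'   copy-number filter.
#' @param copy_numbers Optional externally computed data.frame with columns
#'   \code{ext_copies}, \code{lig_copies} (one row per candidate), used
#'   instead of \code{references}.
#' @param variant_offsets Optional integer vector of 0-based transcript
#'   offsets of known variants to keep out of the arms.
#' @param constraints A [designConstraints] list (for
#'   \code{max_copy_number}).
#' @param variant_action \code{"drop"} (default) removes candidates with a
#'   variant under an arm; \code{"flag"} only records them.
#' @return The filtered candidate data.frame, with columns
#'   \code{ext_copies}/\code{lig_copies} (when computed) and
#'   \code{arm_variant}.
#' @export
filterCandidates <- function(candidates, references = NULL,
                             copy_numbers = NULL, variant_offsets = NULL,
                             constraints = designConstraints(),
                             variant_action = c("drop", "flag")) {
    variant_action <- match.arg(variant_action)
    if (!nrow(candidates)) return(candidates)
    if (!is.null(copy_numbers)) {
        candidates$ext_copies <- copy_numbers$ext_copies
        candidates$lig_copies <- copy_numbers$lig_copies
    } else if (!is.null(references)) {
        if (is.character(references)) references <- DNAStringSet(references)
        candidates$ext_copies <- vapply(candidates$extension_arm,
                                        armCopyNumber, integer(1),
                                        references = references)
        candidates$lig_copies <- vapply(candidates$ligation_arm,
                                        armCopyNumber, integer(1),
                                        references = references)
    }
    if (!is.null(candidates$ext_copies)) {
        keep <- candidates$ext_copies >= 1L &
            candidates$ext_copies <= constraints$max_copy_number &
            candidates$lig_copies >= 1L &
            candidates$lig_copies <= constraints$max_copy_number
        candidates <- candidates[keep, , drop = FALSE]
    }
    candidates$arm_variant <- logical(nrow(candidates))
    if (!is.null(variant_offsets) && nrow(candidates)) {
        hit <- vapply(seq_len(nrow(candidates)), function(i) {
            any((variant_offsets >= candidates$ext_start[i] &
                 variant_offsets < candidates$ext_end[i]) |
                (variant_offsets >= candidates$lig_start[i] &
                 variant_offsets < candidates$lig_end[i]))
        }, logical(1))
        candidates$arm_variant <- hit
        if (variant_action == "drop")
            candidates <- candidates[!hit, , drop = FALSE]
    }
    rownames(candidates) <- NULL
    candidates
}

#' Select two probes with non-overlapping arms for one SNP
#'
#' Searches all candidate pairs whose extension arms do not overlap in
#' transcript coordinates and whose ligation arms do not overlap either, so
#' that the two probes yield independent estimates of the allelic ratio.
#' Within the feasible set the pair with the highest summed performance
#' \code{score} wins (absent scores count as 0); a \code{n_transcripts}
#' column, when present, breaks score ties in favour of candidates valid in
#' more annotated transcripts, and remaining ties are broken lexicographically
#' by probe name.
#'
#' @param candidates Candidate data.frame ([enumerateCandidates] output,
#'   optionally with \code{score} and \code{n_transcripts} columns) covering
#'   one SNP.
#' @return A two-row data.frame (the selected pair).
#' @export
designSnpPair <- function(candidates) {
    n <- nrow(candidates)
    if (n < 2L) stop("design-infeasible: fewer than two candidates")
    score <- if (!is.null(candidates$score)) candidates$score else rep(0, n)
    ntx <- if (!is.null(candidates$n_transcripts))
        candidates$n_transcripts else rep(0, n)
    best <- NULL
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
        ext_disjoint <- candidates$ext_end[i] <= candidates$ext_start[j] ||
            candidates$ext_end[j] <= candidates$ext_start[i]
        lig_disjoint <- candidates$lig_end[i] <= candidates$lig_start[j] ||
            candidates$lig_end[j] <= candidates$lig_start[i]
        if (!ext_disjoint || !lig_disjoint) next
        key <- list(score = score[i] + score[j],
                    ntx = ntx[i] + ntx[j],
                    names = sort(c(candidates$name[i], candidates$name[j])))
        if (is.null(best) ||
            key$score > best$key$score ||
            (key$score == best$key$score && key$ntx > best$key$ntx) ||
            (key$score == best$key$score && key$ntx == best$key$ntx &&
             paste(key$names, collapse = "\r") <
             paste(best$key$names, collapse = "\r"))) {
            best <- list(pair = c(i, j), key = key)
        }
    }
    if (is.null(best))
        stop("design-infeasible: no pair with non-overlapping arms exists")
    out <- candidates[best$pair, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Read transcript models from a reference FASTA and exon annotation
#'
#' Builds spliced [TranscriptModel-class] objects from a genome (or any
#' reference) FASTA plus exon structures in GFF3 (via
#' \pkg{rtracklayer}) or a BED-like tab-separated table with columns
#' \code{chrom}, \code{start}, \code{end}, \code{transcript} (BED convention:
#' 0-based half-open) and optional \code{strand}.
#'
#' @param fasta Path to the reference FASTA.
#' @param annotation Path to a GFF3 file (\code{type == "exon"} records are
#'   used, grouped by their \code{Parent} or \code{transcript_id} attribute)
#'   or to a BED-like TSV.
#' @param format \code{"gff3"} or \code{"bed"}; guessed from the file
#'   extension by default.
#' @return A named list of [TranscriptModel-class] objects.
#' @export
readTranscriptModels <- function(fasta, annotation,
                                 format = c("auto", "gff3", "bed")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.gff3?(\\.gz)?$", annotation)) "gff3" else "bed"
    genome <- readDNAStringSet(fasta)
    names(genome) <- sub("\\s.*", "", names(genome))
    if (format == "gff3") {
        if (!requireNamespace("rtracklayer", quietly = TRUE))
            stop("GFF3 input requires the rtracklayer package")
        gr <- rtracklayer::import(annotation)
        gr <- gr[tolower(as.character(gr$type)) == "exon"]
        parent <- if (!is.null(gr$Parent) && any(lengths(gr$Parent) > 0))
            vapply(as.list(gr$Parent), function(x)
                if (length(x)) x[[1]] else NA_character_, character(1))
        else as.character(gr$transcript_id)
        tab <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                          start = GenomicRanges::start(gr),
                          end = GenomicRanges::end(gr),
                          transcript = sub("^transcript:", "", parent),
                          strand = as.character(GenomicRanges::strand(gr)),
                          stringsAsFactors = FALSE)
        tab$strand[!tab$strand %in% c("+", "-")] <- "+"
    } else {
        tab <- read.table(annotation, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
        need <- c("chrom", "start", "end", "transcript")
        if (!all(need %in% colnames(tab)))
            stop("BED-like exon table lacks columns: ",
                 paste(setdiff(need, colnames(tab)), collapse = ", "))
        tab$start <- tab$start + 1L          # BED 0-based half-open -> 1-based
        if (is.null(tab$strand)) tab$strand <- "+"
    }
    out <- lapply(split(tab, tab$transcript), function(tt)
        spliceTranscript(data.frame(start = tt$start, end = tt$end),
                         genome, strand = tt$strand[1], id = tt$transcript[1],
                         chrom = tt$chrom[1]))
    out[order(names(out))]
}

#' Read variant targets from a VCF
#'
#' Reads CHROM/POS/REF/ALT (only biallelic SNVs are kept) and, when
#' transcript models are supplied, converts genomic to transcript
#' coordinates.
#'
#' @param vcf Path to a VCF file.
#' @param transcripts Optional list of [TranscriptModel-class]; adds one row
#'   per (variant, transcript) with the 0-based transcript \code{offset}
#'   (variants outside a transcript are dropped for that transcript).
#' @return A data.frame with \code{snp_id}, \code{chrom}, \code{pos}
#'   (1-based), \code{ref}, \code{alt}, and with \code{target_id} +
#'   \code{offset} when transcripts are given (a [snpTargets]-ready table).
#' @export
readVariantTargets <- function(vcf, transcripts = NULL) {
    if (!requireNamespace("vcfR", quietly = TRUE))
        stop("VCF input requires the vcfR package")
    v <- vcfR::read.vcfR(vcf, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    out <- data.frame(snp_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                      paste0(fix$CHROM, ":", fix$POS), fix$ID),
                      chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = toupper(fix$REF), alt = toupper(fix$ALT),
                      stringsAsFactors = FALSE)
    out <- out[nchar(out$ref) == 1L & nchar(out$alt) == 1L &
               !grepl(",", out$alt), , drop = FALSE]
    if (is.null(transcripts)) return(out)
    rows <- list()
    for (tx in transcripts) {
        sel <- out$chrom == tx@chrom
        off <- genomicToTranscript(out$pos[sel], tx)
        hit <- which(!is.na(off))
        if (!length(hit)) next
        r <- out[sel, , drop = FALSE][hit, , drop = FALSE]
        r$target_id <- tx@id
        r$offset <- off[hit]
        ## a minus-strand transcript reads the complementary base
        if (tx@strand == "-") {
            comp <- c(A = "T", C = "G", G = "C", T = "A")
            r$ref <- comp[r$ref]; r$alt <- comp[r$alt]
        }
        rows[[tx@id]] <- r
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
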