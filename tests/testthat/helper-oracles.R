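# Independent brute-force oracles used to cross-check the vectorised
# implementations, plus small fixture builders. These are deliberately naive
# (per-element loops, exhaustive scans) and share no code with the package
# internals.

# substitute a different base at each given position
mutate_at <- function(x, pos) {
    for (p in pos) {
        cur <- substr(x, p, p)
        substr(x, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
    }
    x
}

hamming <- function(a, b) {
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    sum(av != bv)
}

revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# exhaustive threshold search: largest r >= 1 whose >= r UMIs retain at least
# `fraction` of reads
oracle_threshold <- function(cov, fraction = 0.95) {
    total <- sum(cov)
    best <- 1L
    for (r in seq_len(max(cov))) {
        if (sum(cov[cov >= r]) >= fraction * total) best <- r
    }
    list(threshold_R = best, molecules = sum(cov >= best))
}

# per-read brute-force probe assignment under the minimal-total-mismatch rule
oracle_assign <- function(m1, m2, panel, max_mm = 2L, umi_len = 9L) {
    p <- probeTable(panel)
    extrc <- revcomp(p$extension_arm)
    out <- character(length(m1))
    for (i in seq_along(m1)) {
        tots <- rep(NA_real_, nrow(p))
        for (j in seq_len(nrow(p))) {
            b <- nchar(p$ligation_arm[j]); a <- nchar(extrc[j])
            if (nchar(m1[i]) < b || nchar(m2[i]) < umi_len + a) next
            mmL <- hamming(substr(m1[i], 1, b), p$ligation_arm[j])
            mmE <- hamming(substr(m2[i], umi_len + 1, umi_len + a), extrc[j])
            if (mmL <= max_mm && mmE <= max_mm) tots[j] <- mmL + mmE
        }
        if (all(is.na(tots))) { out[i] <- NA_character_; next }
        best <- which(tots == min(tots, na.rm = TRUE))
        out[i] <- if (length(best) == 1L) p$name[best] else "ambiguous"
    }
    out
}

# naive per-group majority vote
oracle_vote <- function(calls) {
    out <- list()
    for (key in unique(paste(calls$snp_id, calls$probe, calls$umi, sep = "\r"))) {
        parts <- strsplit(key, "\r")[[1]]
        sel <- calls$snp_id == parts[1] & calls$probe == parts[2] &
            calls$umi == parts[3]
        tab <- table(calls$allele[sel])
        winners <- names(tab)[tab == max(tab)]
        call <- if (length(winners) == 1L) winners else "tied"
        out[[key]] <- data.frame(snp_id = parts[1], probe = parts[2],
                                 call = call, stringsAsFactors = FALSE)
    }
    do.call(rbind, unname(out))
}

# naive candidate enumeration: scan every gap-fill start and arm split
oracle_enumerate <- function(txseq, anchor, cons) {
    L <- nchar(txseq)
    T <- cons$target_length
    out <- 0L
    for (a in cons$arm_min:cons$arm_max) {
        b <- cons$arm_total - a
        if (b < cons$arm_min || b > cons$arm_max) next
        for (g in 0:L) {
            if (g - a < 0 || g + T + b > L) next
            if (!is.null(anchor$segment) &&
                (g < anchor$segment[1] || g + T > anchor$segment[2])) next
            if (!is.null(anchor$snp_offset) &&
                (anchor$snp_offset < g || anchor$snp_offset >= g + T)) next
            out <- out + 1L
        }
    }
    out
}

# a small valid panel for unit tests (arm sums of 40, 112-nt gap-fills on a
# shared synthetic transcript set)
tiny_panel <- function(n_tx = 3L, probes_per_tx = 2L, seed = 42L,
                       target_length = 112L) {
    set.seed(seed)
    tx_len <- 400L
    seqs <- Biostrings::DNAStringSet(vapply(seq_len(n_tx), function(i)
        paste(sample(c("A", "C", "G", "T"), tx_len, TRUE), collapse = ""),
        character(1)))
    names(seqs) <- sprintf("tx%d", seq_len(n_tx))
    rows <- do.call(rbind, lapply(seq_len(n_tx), function(t) {
        g <- seq(24L, tx_len - target_length - 24L,
                 length.out = probes_per_tx)
        g <- as.integer(round(g))
        a <- rep(c(20L, 18L), length.out = probes_per_tx)
        b <- 40L - a
        sc <- as.character(seqs[[t]])
        data.frame(name = sprintf("tx%d_p%d", t, seq_along(g)),
                   gene = sprintf("tx%d", t), target_id = sprintf("tx%d", t),
                   target_start = g, target_end = g + target_length,
                   extension_arm = substring(sc, g - a + 1L, g),
                   ligation_arm = substring(sc, g + target_length + 1L,
                                            g + target_length + b),
                   umi_length = 9L, junction_crossing = FALSE,
                   stringsAsFactors = FALSE)
    }))
    list(panel = MipPanel(rows), sequences = seqs)
}

# construct error-free read pairs for given molecules of a tiny_panel fixture
make_reads <- function(panel, sequences, probe, umi, n_per = 1L) {
    p <- probeTable(panel)
    j <- match(probe, p$name)
    sc <- as.character(sequences)
    gap <- substring(sc[p$target_id[j]], p$target_start[j] + 1L,
                     p$target_end[j])
    m1 <- rep(paste0(p$ligation_arm[j], gap), n_per)
    m2 <- rep(paste0(umi, revcomp(p$extension_arm[j]), revcomp(gap)), n_per)
    list(m1 = m1, m2 = m2)
}
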