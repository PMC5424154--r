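## Probe panel container, panel TSV I/O, oligo assembly and capture-protocol
## arithmetic.
##
## Coordinate convention: probe target (gap-fill) coordinates are 0-based
## half-open offsets on the spliced transcript, i.e. the gap-fill covers
## transcript bases [target_start, target_end). This is also the convention of
## the panel TSV on disk.

#' The common smMIP backbone sequence
#'
#' The 30-nt universal backbone carrying the amplification-primer binding
#' sites that joins the two targeting arms of every smMIP oligo.
#'
#' @return A length-one character vector (30 nt).
#' @export
#' @examples
#' nchar(smmipBackbone())  # 30
smmipBackbone <- function() "CTTCAGCTTCCCGATATCCGACGGTAGTGT"

.PANEL_COLUMNS <- c("name", "gene", "target_id", "target_start", "target_end",
                    "extension_arm", "ligation_arm", "umi_length",
                    "junction_crossing")

.valid_dna <- function(x) grepl("^[ACGT]+$", x)

#' MipPanel: a panel of smMIP probes
#'
#' An ordered collection of smMIP probes. Each probe is defined by its two
#' targeting arms (extension and ligation, stored 5'->3' as they appear in the
#' assembled oligo), the UMI length, the identifier of the targeted transcript
#' and the 0-based half-open transcript coordinates of the gap-fill region,
#' plus a gene identifier used for gene-level aggregation and a flag marking
#' probes whose span crosses an exon-exon junction.
#'
#' @slot probes A [S4Vectors::DataFrame] with one row per probe and columns
#'   \code{name}, \code{gene}, \code{target_id}, \code{target_start},
#'   \code{target_end}, \code{extension_arm}, \code{ligation_arm},
#'   \code{umi_length}, \code{junction_crossing}.
#'
#' @export
setClass("MipPanel", representation(probes = "DataFrame"))

setValidity("MipPanel", function(object) {
    p <- object@probes
    msg <- character()
    missing_cols <- setdiff(.PANEL_COLUMNS, colnames(p))
    if (length(missing_cols))
        return(paste("missing probe columns:",
                     paste(missing_cols, collapse = ", ")))
    if (nrow(p) == 0L) return(TRUE)
    if (anyDuplicated(p$name))
        msg <- c(msg, "duplicate probe names")
    if (!all(.valid_dna(p$extension_arm)) || !all(.valid_dna(p$ligation_arm)))
        msg <- c(msg, "probe arms must be non-empty ACGT sequences")
    if (length(unique(p$umi_length)) > 1L)
        msg <- c(msg, "all probes must share one umi_length")
    if (any(p$umi_length < 0L))
        msg <- c(msg, "umi_length must be >= 0")
    if (any(p$target_end < p$target_start))
        msg <- c(msg, "target_end must be >= target_start")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a MipPanel
#'
#' @param probes A data.frame (or DataFrame) with the probe columns documented
#'   in [MipPanel-class]. Missing \code{gene} defaults to \code{target_id},
#'   missing \code{umi_length} to 9, missing \code{junction_crossing} to
#'   \code{FALSE}. Arm sequences are upper-cased.
#' @return A [MipPanel-class] object.
#' @export
#' @examples
#' p <- MipPanel(data.frame(name = "p1", target_id = "tx1",
#'                          target_start = 20, target_end = 132,
#'                          extension_arm = "ACGTACGTACGTACGTACGT",
#'                          ligation_arm  = "TGCATGCATGCATGCATGCA"))
#' length(p)
MipPanel <- function(probes) {
    probes <- as.data.frame(probes)
    if (is.null(probes$gene)) probes$gene <- probes$target_id
    if (is.null(probes$umi_length)) probes$umi_length <- 9L
    if (is.null(probes$junction_crossing)) probes$junction_crossing <- FALSE
    probes$extension_arm <- toupper(as.character(probes$extension_arm))
    probes$ligation_arm <- toupper(as.character(probes$ligation_arm))
    probes$name <- as.character(probes$name)
    probes$gene <- as.character(probes$gene)
    probes$target_id <- as.character(probes$target_id)
    probes$target_start <- as.integer(probes$target_start)
    probes$target_end <- as.integer(probes$target_end)
    probes$umi_length <- as.integer(probes$umi_length)
    probes$junction_crossing <- as.logical(probes$junction_crossing)
    new("MipPanel", probes = DataFrame(probes[, .PANEL_COLUMNS, drop = FALSE]))
}

#' @describeIn MipPanel Number of probes in the panel.
#' @param x,object A \code{MipPanel}.
#' @export
setMethod("length", "MipPanel", function(x) nrow(x@probes))

#' @describeIn MipPanel Probe names.
#' @export
setMethod("names", "MipPanel", function(x) x@probes$name)

#' @describeIn MipPanel Subset a panel by probe index or name.
#' @param i Probe indices or names.
#' @param j,drop Ignored.
#' @param ... Ignored.
#' @export
setMethod("[", "MipPanel", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, x@probes$name)
    initialize(x, probes = x@probes[i, , drop = FALSE])
})

setMethod("show", "MipPanel", function(object) {
    p <- object@probes
    cat("MipPanel with", nrow(p), "probes,",
        length(unique(p$gene)), "genes\n")
    if (nrow(p)) {
        cat("  umi_length:", p$umi_length[1],
            "| arm lengths:", paste(range(nchar(p$extension_arm),
                                          nchar(p$ligation_arm)),
                                    collapse = "-"),
            "| junction-crossing:", sum(p$junction_crossing), "\n")
    }
})

#' Probe table of a panel
#'
#' @param panel A [MipPanel-class].
#' @return A plain \code{data.frame} with one row per probe.
#' @export
probeTable <- function(panel) {
    stopifnot(is(panel, "MipPanel"))
    as.data.frame(panel@probes)
}

#' Read a probe panel from a tab-separated file
#'
#' The panel dialect is tab-separated with a header line; lines starting with
#' \code{#} are comments. One probe per row. A trailing \code{oligo} column
#' (written by [writeMipPanel]) is ignored on input.
#'
#' @param path Path to the panel TSV.
#' @return A [MipPanel-class].
#' @export
readMipPanel <- function(path) {
    if (!file.exists(path)) stop("panel file not found: ", path)
    tab <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                      stringsAsFactors = FALSE, quote = "")
    required <- c("name", "extension_arm", "ligation_arm", "target_id",
                  "target_start", "target_end")
    missing_cols <- setdiff(required, colnames(tab))
    if (length(missing_cols))
        stop("panel file lacks required columns: ",
             paste(missing_cols, collapse = ", "))
    if (anyDuplicated(tab$name))
        stop("panel format error: duplicate probe name(s): ",
             paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
    bad <- !.valid_dna(toupper(tab$extension_arm)) |
        !.valid_dna(toupper(tab$ligation_arm))
    if (any(bad))
        stop("sequence error: arm with non-ACGT characters in probe(s): ",
             paste(tab$name[bad], collapse = ", "))
    MipPanel(tab)
}

#' Write a probe panel to a tab-separated file
#'
#' Writes the panel in the dialect read by [readMipPanel], with a comment
#' header documenting the oligo part order, plus a derived \code{oligo}
#' column holding the assembled oligo sequence.
#'
#' @param panel A [MipPanel-class].
#' @param path Output path.
#' @param backbone Backbone sequence used for the \code{oligo} column.
#' @return \code{path}, invisibly.
#' @export
writeMipPanel <- function(panel, path, backbone = smmipBackbone()) {
    stopifnot(is(panel, "MipPanel"))
    tab <- probeTable(panel)
    tab$oligo <- assembleOligo(panel, backbone = backbone)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        "# smMIP panel: one probe per row, tab-separated.",
        "# Oligo part order 5'->3': ligation_arm | backbone | UMI (N x umi_length) | extension_arm.",
        "# target_start/target_end are 0-based half-open transcript coordinates of the gap-fill."),
        con)
    write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Assemble full-length smMIP oligo sequences
#'
#' Concatenates, 5' to 3': ligation arm, backbone, a UMI placeholder of
#' \code{umi_length} \code{N}s (the UMI sits between the extension arm and the
#' universal amplification primer on the backbone), and the extension arm.
#' With 40 nt of arms, a 9-nt UMI and the 30-nt backbone this yields the
#' standard 79-nt oligo.
#'
#' @param panel A [MipPanel-class].
#' @param backbone Common backbone sequence (default [smmipBackbone]).
#' @return Character vector of oligo sequences, named by probe.
#' @export
#' @examples
#' p <- MipPanel(data.frame(name = "p1", target_id = "t",
#'                          target_start = 20, target_end = 132,
#'                          extension_arm = strrep("A", 20),
#'                          ligation_arm = strrep("C", 20)))
#' nchar(assembleOligo(p))  # 79
assembleOligo <- function(panel, backbone = smmipBackbone()) {
    stopifnot(is(panel, "MipPanel"))
    if (!is.character(backbone) || length(backbone) != 1L || !nzchar(backbone))
        stop("configuration error: backbone must be a non-empty sequence")
    p <- probeTable(panel)
    setNames(paste0(p$ligation_arm, backbone,
                    strrep("N", p$umi_length), p$extension_arm),
             p$name)
}

#' Capture-protocol parameters
#'
#' @param gdna_molecules_per_ng smMIP molecules per ng of genomic DNA input
#'   (default 264,000, i.e. an 800:1 MIP:molecule ratio).
#' @param cdna_multiplier Extra factor applied for cDNA input (default 10,
#'   compensating the larger number of RNA than DNA molecules per cell).
#' @param aliquot_ul_per_probe Volume (microlitre) of each probe taken into
#'   the phosphorylation reaction (default 0.5).
#' @return A named list of class \code{ProtocolParams}.
#' @export
protocolParams <- function(gdna_molecules_per_ng = 264000,
                           cdna_multiplier = 10,
                           aliquot_ul_per_probe = 0.5) {
    if (gdna_molecules_per_ng <= 0 || cdna_multiplier <= 0 ||
        aliquot_ul_per_probe <= 0)
        stop("protocol parameters must be strictly positive")
    structure(list(gdna_molecules_per_ng = gdna_molecules_per_ng,
                   cdna_multiplier = cdna_multiplier,
                   aliquot_ul_per_probe = aliquot_ul_per_probe),
              class = "ProtocolParams")
}

#' Pool volume and concentration from individual probe aliquots
#'
#' Applies conservation of moles: volume_i x concentration_i summed over
#' probes equals pool volume x pool concentration. Units are microlitre and
#' micromolar; no unit conversion is performed.
#'
#' @param volumes Per-probe volumes (ul).
#' @param concentrations Per-probe molar concentrations (uM).
#' @return A list with \code{pool_volume} (ul), \code{per_species}
#'   (uM, each probe's concentration in the pool) and
#'   \code{total_concentration} (uM, total oligo concentration of the pool).
#' @export
#' @examples
#' poolConcentration(rep(5, 95), rep(100, 95))$total_concentration  # 100
poolConcentration <- function(volumes, concentrations) {
    if (length(volumes) != length(concentrations))
        stop("input error: volumes and concentrations differ in length")
    if (!length(volumes) || any(volumes <= 0) || any(concentrations <= 0))
        stop("input error: volumes and concentrations must be positive")
    v <- sum(volumes)
    list(pool_volume = v,
         per_species = volumes * concentrations / v,
         total_concentration = sum(volumes * concentrations) / v)
}

#' Number of smMIP molecules for a given template input
#'
#' 264,000 smMIP molecules per ng of gDNA; 10-fold more (2,640,000 per ng)
#' for cDNA.
#'
#' @param input_ng Template mass in ng (> 0).
#' @param template \code{"cdna"} or \code{"gdna"}.
#' @param params A [protocolParams] list.
#' @return Number of smMIP molecules.
#' @export
#' @examples
#' smmipMoleculesForInput(1, "cdna")  # 2,640,000
smmipMoleculesForInput <- function(input_ng, template = c("cdna", "gdna"),
                                   params = protocolParams()) {
    if (!is.numeric(input_ng) || input_ng <= 0)
        stop("input error: input_ng must be > 0")
    template <- match.arg(template)
    base <- input_ng * params$gdna_molecules_per_ng
    if (template == "cdna") base * params$cdna_multiplier else base
}

#' Phosphorylation reaction volume for a probe pool
#'
#' An aliquot of \code{aliquot_ul_per_probe} microlitre per probe; 95 probes
#' at the default 0.5 ul therefore give 47.5 ul.
#'
#' @param n_probes Number of probes in the pool (>= 1).
#' @param params A [protocolParams] list.
#' @return Volume in microlitre.
#' @export
phosphorylationVolume <- function(n_probes, params = protocolParams()) {
    if (!is.numeric(n_probes) || n_probes < 1)
        stop("input error: n_probes must be >= 1")
    n_probes * params$aliquot_ul_per_probe
}
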