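#' Germline V/J segment reference
#'
#' A [Biostrings::DNAStringSet] of germline V and J alleles with per-allele
#' metadata columns: \code{segment} (gene segment name, e.g. "TRBV05"),
#' \code{allele} (allele id, e.g. "01"), \code{kind} ("V" or "J"),
#' \code{anchor_offset} (0-based offset of the first base of the conserved
#' anchor codon: Cys for V, Phe for J), \code{functional} (logical),
#' \code{rss_weight} (non-negative relative rearrangement propensity; 0 means
#' the allele never rearranges) and \code{prior} (existing database-style
#' annotation: F, ORF, P, F/P, F/ORF or none).
#'
#' @slot .Data inherited from \code{DNAStringSet}.
#' @seealso [GermlineReference()], [buildToyReference()],
#'   [readGermlineReference()]
#' @exportClass GermlineReference
setClass("GermlineReference", contains = "DNAStringSet")

.required_ref_cols <- c("segment", "allele", "kind", "anchor_offset",
                        "functional", "rss_weight", "prior")

setValidity("GermlineReference", function(object) {
    mc <- mcols(object)
    missing_cols <- setdiff(.required_ref_cols, colnames(mc))
    if (length(missing_cols) > 0L)
        return(paste("missing metadata columns:",
                     paste(missing_cols, collapse = ", ")))
    if (length(object) == 0L)
        return(TRUE)
    if (!all(mc$kind %in% c("V", "J")))
        return("kind must be 'V' or 'J'")
    if (any(mc$rss_weight < 0))
        return("rss_weight must be >= 0")
    if (!all(mc$prior %in% PRIOR_LEVELS))
        return(paste("prior must be one of",
                     paste(PRIOR_LEVELS, collapse = ", ")))
    if (any(mc$anchor_offset < 0) ||
        any(mc$anchor_offset + 3L > width(object)))
        return("anchor codon must lie within the sequence")
    seqs <- as.character(object)
    anchor <- substring(seqs, mc$anchor_offset + 1L, mc$anchor_offset + 3L)
    bad_v <- mc$kind == "V" & !(anchor %in% V_ANCHORS)
    bad_j <- mc$kind == "J" & !(anchor %in% J_ANCHORS)
    if (any(bad_v))
        return("V anchor codon must be TGT or TGC (conserved Cys)")
    if (any(bad_j))
        return("J anchor codon must be TTT or TTC (conserved Phe)")
    TRUE
})

#' Construct a germline reference
#'
#' @param sequences character vector or \code{DNAStringSet} of allele
#'   sequences.
#' @param segment character vector of segment names.
#' @param allele character vector of allele identifiers (default "01").
#' @param kind "V" or "J" per allele.
#' @param anchor_offset 0-based offset of the anchor codon (Cys/Phe) first
#'   base within each sequence.
#' @param functional logical; can the allele encode a working chain?
#' @param rss_weight non-negative relative rearrangement propensity.
#' @param prior prior annotation code (F, ORF, P, F/P, F/ORF, none).
#' @return a [GermlineReference-class] object, named
#'   \code{segment*allele}.
#' @examples
#' ref <- GermlineReference(
#'   sequences = c("AAACGATGTGCAGCA", "CAGACATTTGCAGGAGCA"),
#'   segment = c("TRBVX", "TRBJX"), kind = c("V", "J"),
#'   anchor_offset = c(6L, 6L), functional = c(TRUE, TRUE))
#' ref
#' @export
GermlineReference <- function(sequences, segment, kind, anchor_offset,
                              functional,
                              allele = rep("01", length(sequences)),
                              rss_weight = rep(1, length(sequences)),
                              prior = ifelse(functional, "F", "P")) {
    dss <- if (is(sequences, "DNAStringSet")) sequences
           else DNAStringSet(sequences)
    names(dss) <- paste0(segment, "*", allele)
    mcols(dss) <- DataFrame(segment = as.character(segment),
                            allele = as.character(allele),
                            kind = as.character(kind),
                            anchor_offset = as.integer(anchor_offset),
                            functional = as.logical(functional),
                            rss_weight = as.numeric(rss_weight),
                            prior = as.character(prior))
    new("GermlineReference", dss)
}

setMethod("show", "GermlineReference", function(object) {
    mc <- mcols(object)
    cat("GermlineReference with", length(object), "alleles (",
        sum(mc$kind == "V"), "V,", sum(mc$kind == "J"), "J )\n")
    cat("  functional:", sum(mc$functional),
        " non-functional:", sum(!mc$functional), "\n")
    if (length(object) > 0L) {
        n <- min(length(object), 5L)
        for (i in seq_len(n))
            cat(sprintf("  %-12s %s anchor=%d func=%s rss=%.2f prior=%s\n",
                        names(object)[i], mc$kind[i], mc$anchor_offset[i],
                        mc$functional[i], mc$rss_weight[i], mc$prior[i]))
        if (length(object) > n) cat("  ...\n")
    }
    invisible(NULL)
})

#' Per-segment cohort container
#'
#' A [SummarizedExperiment::SummarizedExperiment] with V gene segments as
#' rows and individuals as columns. Assays: \code{nUnique} (unique scored
#' rearrangements per segment and individual), \code{nProductive}, and
#' \code{proportion} (= nProductive / nUnique; \code{NA} where the segment
#' was not observed in that individual). Row metadata carries prior
#' annotations and cohort summaries (total rearrangements, mean/SD of the
#' productive proportion, number of individuals observed); [annotateSegments()]
#' adds the final annotation calls.
#'
#' @seealso [SegmentCohort()], [abundanceFilter()], [annotateSegments()]
#' @exportClass SegmentCohort
setClass("SegmentCohort", contains = "SummarizedExperiment")

setValidity("SegmentCohort", function(object) {
    need <- c("nUnique", "nProductive", "proportion")
    if (!all(need %in% assayNames(object)))
        return(paste("assays must include",
                     paste(need, collapse = ", ")))
    p <- assay(object, "proportion")
    if (any(p < 0 | p > 1, na.rm = TRUE))
        return("proportions must lie in [0, 1]")
    nu <- assay(object, "nUnique")
    np <- assay(object, "nProductive")
    if (any(np > nu, na.rm = TRUE))
        return("nProductive cannot exceed nUnique")
    TRUE
})

setMethod("show", "SegmentCohort", function(object) {
    cat("SegmentCohort:", nrow(object), "segments x", ncol(object),
        "individuals\n")
    rd <- rowData(object)
    if ("call" %in% colnames(rd)) {
        tab <- table(rd$call, useNA = "ifany")
        cat("  calls:", paste(names(tab), tab, sep = "=", collapse = " "),
            "\n")
    }
    md <- metadata(object)
    if (!is.null(md$abundance_filter))
        cat("  abundance filter: mean >=",
            md$abundance_filter$min_mean_per_individual,
            "per individual;", nrow(md$abundance_filter$excluded),
            "segments excluded\n")
    invisible(NULL)
})
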