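## Presentation artifacts: histograms, ranked abundance, heat-map matrix,
## TSV reports.

#' Bin productive proportions in 10 % increments
#'
#' Left-open, right-closed bins (0, 0.1], (0.1, 0.2], ..., labelled by
#' their upper bound times 100; a value of exactly 0 falls in bin "10".
#'
#' @param proportions numeric vector in [0, 1].
#' @return named integer vector of 10 bin counts ("10" ... "100").
#' @examples
#' histogramBins(c(0.05, 0.10, 0.95))
#' @export
histogramBins <- function(proportions) {
    if (any(is.na(proportions)) ||
        any(proportions < 0 | proportions > 1))
        stop("proportions must lie in [0, 1]")
    idx <- pmax(ceiling(round(proportions * 10, 9)), 1L)
    setNames(tabulate(idx, nbins = 10L), as.character(seq_len(10L) * 10L))
}

#' Ranked abundance table with largest-gap diagnostic
#'
#' Orders segments by total rearrangement count (descending) and flags the
#' largest adjacent log10 ratio -- the natural discontinuity separating
#' segments used by the recombination machinery from those that align only
#' through errors or defective recombination signals.
#'
#' @param cohort a [SegmentCohort-class].
#' @return data.frame: \code{segment}, \code{total_rearrangements},
#'   \code{mean_per_individual}, \code{prior}, \code{log10_gap_to_next}
#'   (NA for the last row), \code{largest_gap} (logical).
#' @export
rankedAbundanceTable <- function(cohort) {
    stopifnot(is(cohort, "SegmentCohort"))
    if (nrow(cohort) < 2L) stop("need at least two segments")
    rd <- rowData(cohort)
    ord <- order(-rd$total_rearrangements, rownames(cohort))
    tot <- rd$total_rearrangements[ord]
    gaps <- c(log10(tot[-length(tot)] / tot[-1L]), NA_real_)
    out <- data.frame(segment = rownames(cohort)[ord],
                      total_rearrangements = tot,
                      mean_per_individual = tot / ncol(cohort),
                      prior = rd$prior[ord],
                      log10_gap_to_next = gaps,
                      largest_gap = FALSE, row.names = NULL)
    if (any(is.finite(gaps)))
        out$largest_gap[which.max(gaps)] <- TRUE
    out
}

#' Individuals-by-segments proportion matrix
#'
#' The per-individual productive proportion matrix, individuals as rows,
#' segments as columns; unobserved cells are NA. Segments are grouped by
#' prior annotation category (pure functional, mixed, pure non-functional,
#' unannotated) and sorted by mean productive proportion within each
#' category, the layout used for cohort heat maps.
#'
#' @param cohort a [SegmentCohort-class].
#' @return numeric matrix individuals x segments.
#' @export
heatmapMatrix <- function(cohort) {
    stopifnot(is(cohort, "SegmentCohort"))
    rd <- rowData(cohort)
    cat_rank <- ifelse(rd$prior %in% .PURE_F, 1L,
                ifelse(rd$prior %in% .MIXED, 2L,
                ifelse(rd$prior %in% .PURE_NF, 3L, 4L)))
    ord <- order(cat_rank, -rd$mean_proportion)
    t(productiveProportion(cohort)[ord, , drop = FALSE])
}

#' Write the cohort report files
#'
#' Writes the tab-separated artifacts of a processed cohort:
#' per-individual segment statistics, per-segment cohort statistics,
#' annotation calls (with thresholds used and a prior-discrepancy flag),
#' binary-status correlations, the abundance test, the ranked abundance
#' table, proportion histogram bins, the individuals-by-segments matrix
#' and, when available, per-individual exclusion counts.
#'
#' @param cohort an annotated [SegmentCohort-class] (see
#'   [annotateSegments()]).
#' @param out_dir output directory.
#' @param individual_stats optional data.frame from
#'   [perIndividualProportions()].
#' @param exclusions optional per-individual exclusion counts (the
#'   \code{exclusions} attribute of [processCohort()]).
#' @param functional_threshold threshold for binary status artifacts;
#'   defaults to the annotated threshold.
#' @return invisibly, the named vector of files written.
#' @export
writeCohortReports <- function(cohort, out_dir, individual_stats = NULL,
                               exclusions = NULL,
                               functional_threshold = NULL) {
    if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", out_dir)
    rd <- rowData(cohort)
    if (is.null(functional_threshold))
        functional_threshold <-
            if ("functional_threshold_used" %in% colnames(rd))
                rd$functional_threshold_used[1] else 0.567
    tsv <- function(df, name) {
        path <- file.path(out_dir, name)
        write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
        path
    }
    files <- c()
    if (!is.null(individual_stats))
        files["individual_segment_stats"] <-
            tsv(individual_stats, "individual_segment_stats.tsv")
    files["segment_cohort_stats"] <-
        tsv(segmentStats(cohort), "segment_cohort_stats.tsv")
    if ("call" %in% colnames(rd))
        files["annotation_calls"] <-
            tsv(annotationCalls(cohort), "annotation_calls.tsv")
    files["status_correlation"] <-
        tsv(statusCorrelation(cohort, functional_threshold),
            "status_correlation.tsv")
    files["ranked_abundance"] <-
        tsv(rankedAbundanceTable(cohort), "ranked_abundance.tsv")

    props <- as.vector(productiveProportion(cohort))
    bins <- histogramBins(props[!is.na(props)])
    files["proportion_histogram"] <-
        tsv(data.frame(bin = names(bins), count = as.integer(bins)),
            "proportion_histogram.tsv")

    hm <- heatmapMatrix(cohort)
    files["heatmap_matrix"] <-
        tsv(data.frame(individual = rownames(hm), hm, check.names = FALSE),
            "heatmap_matrix.tsv")

    ab <- annotationAbundanceTest(cohort)
    ab_path <- file.path(out_dir, "abundance_test.txt")
    writeLines(c(
        "Mann-Whitney U test: total rearrangements, prior functional vs",
        "prior pseudogene/ORF segments",
        sprintf("n_functional = %d", ab$n_functional),
        sprintf("n_nonfunctional = %d", ab$n_nonfunctional),
        sprintf("U = %g", ab$U),
        sprintf("p_two_tailed = %g", ab$p),
        sprintf("method = %s", ab$method)), ab_path)
    files["abundance_test"] <- ab_path

    if (!is.null(exclusions))
        files["exclusions"] <- tsv(exclusions, "exclusions.tsv")
    invisible(files)
}
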