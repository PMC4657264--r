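## Cohort statistics and functional/pseudogene/segregating annotation.

#' Per-individual productive proportions
#'
#' Counts, per individual and V segment, the unique scored rearrangements
#' and the productive ones among them. Only records with a concrete V call
#' and a defined productivity flag enter either count; weighting is by
#' unique sequence, not read count (see \code{weight_by_count}).
#'
#' @param tables named list of processed tables (see
#'   [processRearrangements()]); names are individual ids.
#' @param weight_by_count if TRUE, weight each unique sequence by its read
#'   count instead of counting it once.
#' @return data.frame: \code{individual}, \code{segment}, \code{n_unique},
#'   \code{n_productive}, \code{proportion}.
#' @export
perIndividualProportions <- function(tables, weight_by_count = FALSE) {
    stopifnot(!is.null(names(tables)))
    out <- vector("list", length(tables))
    for (i in seq_along(tables)) {
        tab <- tables[[i]]
        keep <- !(tab$v_call %in% c("NONE", "AMBIGUOUS")) &
            !is.na(tab$productive)
        tab <- tab[keep, , drop = FALSE]
        if (nrow(tab) == 0L) next
        w <- if (weight_by_count) tab$count else rep(1L, nrow(tab))
        nu <- tapply(w, tab$v_call, sum)
        np <- tapply(w * as.integer(tab$productive), tab$v_call, sum)
        out[[i]] <- data.frame(individual = names(tables)[i],
                               segment = names(nu),
                               n_unique = as.integer(nu),
                               n_productive = as.integer(np),
                               proportion = as.numeric(np / nu),
                               stringsAsFactors = FALSE, row.names = NULL)
    }
    do.call(rbind, out)
}

#' Assemble a SegmentCohort from per-individual statistics
#'
#' @param stats data.frame from [perIndividualProportions()].
#' @param priors optional named character vector (or data.frame with
#'   columns \code{segment_name}, \code{prior_annotation}) of prior
#'   annotations; segments without a prior get "none".
#' @param individuals optional character vector fixing the full cohort
#'   (defaults to the individuals present in \code{stats}); individuals
#'   with no observation of a segment hold \code{NA}, not 0.
#' @return a [SegmentCohort-class].
#' @export
SegmentCohort <- function(stats, priors = NULL, individuals = NULL) {
    if (is.null(stats) || nrow(stats) == 0L) stop("empty cohort")
    if (is.data.frame(priors))
        priors <- setNames(priors$prior_annotation, priors$segment_name)
    segs <- sort(unique(stats$segment))
    if (is.null(individuals)) individuals <- sort(unique(stats$individual))
    S <- length(segs); I <- length(individuals)
    shape <- function() matrix(NA_real_, S, I,
                               dimnames = list(segs, individuals))
    nu <- shape(); np <- shape()
    ri <- match(stats$segment, segs)
    ci <- match(stats$individual, individuals)
    nu[cbind(ri, ci)] <- stats$n_unique
    np[cbind(ri, ci)] <- stats$n_productive
    prop <- np / nu

    prior <- rep("none", S)
    if (!is.null(priors)) {
        hit <- match(segs, names(priors))
        prior[!is.na(hit)] <- unname(priors[hit[!is.na(hit)]])
    }
    total <- rowSums(nu, na.rm = TRUE)
    rd <- DataFrame(prior = prior,
                    total_rearrangements = total,
                    mean_per_individual = total / I,
                    mean_proportion = rowMeans(prop, na.rm = TRUE),
                    sd_proportion = apply(prop, 1L, sd, na.rm = TRUE),
                    n_individuals_observed = rowSums(!is.na(nu)),
                    row.names = segs)
    new("SegmentCohort", SummarizedExperiment(
        assays = list(nUnique = nu, nProductive = np, proportion = prop),
        rowData = rd,
        colData = DataFrame(individual = individuals,
                            row.names = individuals)))
}

#' Exclude low-abundance segments
#'
#' Segments are retained iff their mean number of unique rearrangements per
#' individual (total across the cohort divided by cohort size) reaches
#' \code{min_mean_per_individual}. Segments rarely seen across a whole
#' cohort tend to carry defective recombination signal sequences and their
#' productive proportions are too noisy to interpret. The largest adjacent
#' log10 gap of the ranked abundance curve is reported as a diagnostic of
#' the natural discontinuity, but the decision uses the fixed threshold.
#'
#' @param cohort a [SegmentCohort-class].
#' @param min_mean_per_individual abundance threshold (default 20).
#' @return the filtered [SegmentCohort-class]; exclusions and the gap
#'   diagnostic are stored in \code{metadata(x)$abundance_filter} and
#'   available via [excludedSegments()].
#' @export
abundanceFilter <- function(cohort, min_mean_per_individual = 20) {
    stopifnot(is(cohort, "SegmentCohort"))
    if (nrow(cohort) == 0L) stop("empty cohort")
    rd <- rowData(cohort)
    mean_pi <- rd$total_rearrangements / ncol(cohort)
    keep <- mean_pi >= min_mean_per_individual

    ord <- order(-rd$total_rearrangements)
    tot <- rd$total_rearrangements[ord]
    gap <- NULL
    if (length(tot) >= 2L && all(tot > 0)) {
        ratios <- log10(tot[-length(tot)] / tot[-1L])
        g <- which.max(ratios)
        gap <- list(after_segment = rownames(cohort)[ord][g],
                    before_segment = rownames(cohort)[ord][g + 1L],
                    log10_ratio = unname(ratios[g]))
    }
    out <- cohort[keep, ]
    metadata(out)$abundance_filter <- list(
        min_mean_per_individual = min_mean_per_individual,
        excluded = data.frame(
            segment = rownames(cohort)[!keep],
            total_rearrangements = rd$total_rearrangements[!keep],
            mean_per_individual = mean_pi[!keep], row.names = NULL),
        largest_gap = gap)
    out
}

.PURE_F <- "F"
.PURE_NF <- c("P", "ORF")
.MIXED <- c("F/P", "F/ORF")

#' Derive classification thresholds from prior annotations
#'
#' Assuming the existing annotations are mostly correct, the functional
#' threshold is the midpoint of the median cohort-mean productive
#' proportion of segments currently annotated purely functional ("F") and
#' of those annotated purely non-functional ("P"/"ORF"); mixed-annotation
#' segments ("F/P", "F/ORF") are ignored for this median. The
#' fixed-vs-segregating SD threshold is the midpoint of the median
#' proportion SD of pure-annotation segments and of mixed-annotation
#' segments (whose alleles are expected to segregate). When a needed class
#' is empty or priors are absent, fixed defaults (0.567 and 0.05) are used
#' with a warning.
#'
#' @param cohort a [SegmentCohort-class] (after [abundanceFilter()]).
#' @param default_functional,default_sd fallback thresholds.
#' @return list with \code{functional_threshold}, \code{sd_threshold},
#'   logical \code{derived} flags and the class medians used.
#' @export
deriveThresholds <- function(cohort, default_functional = 0.567,
                             default_sd = 0.05) {
    rd <- rowData(cohort)
    med <- function(x) if (length(x) == 0L) NA_real_ else median(x)
    m_f <- med(rd$mean_proportion[rd$prior %in% .PURE_F])
    m_nf <- med(rd$mean_proportion[rd$prior %in% .PURE_NF])
    s_pure <- med(rd$sd_proportion[rd$prior %in% c(.PURE_F, .PURE_NF)])
    s_mixed <- med(rd$sd_proportion[rd$prior %in% .MIXED])

    if (is.na(m_f) || is.na(m_nf)) {
        warning("pure functional or non-functional prior class empty; ",
                "using default functional threshold ", default_functional)
        functional <- default_functional
        derived_f <- FALSE
    } else {
        if (m_f == m_nf)
            warning("prior class medians are equal; threshold poorly ",
                    "determined")
        functional <- (m_f + m_nf) / 2
        derived_f <- TRUE
    }
    if (is.na(s_pure) || is.na(s_mixed)) {
        warning("fixed or mixed-annotation class empty; using default SD ",
                "threshold ", default_sd)
        sd_thr <- default_sd
        derived_s <- FALSE
    } else {
        sd_thr <- (s_pure + s_mixed) / 2
        derived_s <- TRUE
    }
    list(functional_threshold = functional, sd_threshold = sd_thr,
         derived = c(functional = derived_f, sd = derived_s),
         class_medians = c(functional = m_f, nonfunctional = m_nf,
                           sd_pure = s_pure, sd_mixed = s_mixed))
}

#' Classify segments from cohort mean and SD
#'
#' SD strictly above the SD threshold means both allele types segregate in
#' the cohort; otherwise the segment is fixed, and it is functional iff its
#' mean productive proportion reaches the functional threshold (inclusive).
#'
#' @param mean_proportion,sd_proportion numeric vectors.
#' @param functional_threshold,sd_threshold thresholds in (0, 1).
#' @return character vector: "functional", "pseudogene" or "segregating".
#' @examples
#' classifySegment(c(0.864, 0.218, 0.60), c(0.03, 0.03, 0.12))
#' @export
classifySegment <- function(mean_proportion, sd_proportion,
                            functional_threshold = 0.567,
                            sd_threshold = 0.05) {
    stopifnot(functional_threshold > 0, functional_threshold < 1,
              sd_threshold > 0, sd_threshold < 1)
    ifelse(sd_proportion > sd_threshold, "segregating",
           ifelse(mean_proportion >= functional_threshold,
                  "functional", "pseudogene"))
}

#' Annotate all segments of a cohort
#'
#' Derives thresholds (unless supplied), classifies every segment observed
#' in enough individuals, and records the calls in the cohort's row
#' metadata (retrieved via [annotationCalls()]). A call is \code{NA} when
#' the segment was observed in fewer than \code{min_individuals}
#' individuals (SD would be meaningless). The \code{discrepant} flag marks
#' calls that contradict the prior annotation.
#'
#' @param cohort a [SegmentCohort-class].
#' @param thresholds optional list as returned by [deriveThresholds()] (or
#'   with elements \code{functional_threshold}, \code{sd_threshold}).
#' @param min_individuals minimum individuals observed (default 10).
#' @return the cohort with annotation columns added to its row metadata.
#' @export
annotateSegments <- function(cohort, thresholds = NULL,
                             min_individuals = 10L) {
    stopifnot(is(cohort, "SegmentCohort"))
    if (is.null(thresholds)) thresholds <- deriveThresholds(cohort)
    rd <- rowData(cohort)
    enough <- rd$n_individuals_observed >= max(2L, min_individuals)
    call <- rep(NA_character_, nrow(cohort))
    call[enough] <- classifySegment(rd$mean_proportion[enough],
                                    rd$sd_proportion[enough],
                                    thresholds$functional_threshold,
                                    thresholds$sd_threshold)
    expected <- ifelse(rd$prior %in% .PURE_F, "functional",
                ifelse(rd$prior %in% .PURE_NF, "pseudogene",
                ifelse(rd$prior %in% .MIXED, "segregating", NA)))
    rd$call <- call
    rd$functional_threshold_used <- thresholds$functional_threshold
    rd$sd_threshold_used <- thresholds$sd_threshold
    rd$discrepant <- !is.na(call) & !is.na(expected) & call != expected
    rowData(cohort) <- rd
    metadata(cohort)$thresholds <- thresholds
    metadata(cohort)$min_individuals <- min_individuals
    cohort
}

#' Per-individual binary functional status
#'
#' A segment is functional in an individual iff that individual's
#' productive proportion reaches the functional threshold (inclusive).
#'
#' @param cohort a [SegmentCohort-class].
#' @param functional_threshold threshold (default 0.567).
#' @return logical matrix (segments x individuals; NA where unobserved):
#'   TRUE = functional.
#' @export
binaryStatus <- function(cohort, functional_threshold = 0.567) {
    productiveProportion(cohort) >= functional_threshold
}

#' Correlation of binary status between segments
#'
#' For segments whose binary status is functional in an intermediate
#' fraction of individuals (inside \code{selection_band}), computes the
#' pairwise Pearson correlation of the 0/1 status over individuals observed
#' for both segments, with a two-tailed p-value. Correlated status between
#' segments suggests haplotype linkage of their allele types.
#'
#' @param cohort a [SegmentCohort-class].
#' @param functional_threshold threshold for [binaryStatus()].
#' @param selection_band keep segments functional in between
#'   \code{band[1]} and \code{band[2]} (inclusive) of observed individuals.
#' @param p_method "fisher_z" (default): z = atanh(r) * sqrt(N - 3), normal
#'   reference; "naive": z = r * sqrt(N), for sensitivity analysis.
#' @return long-format data.frame: \code{seg_a}, \code{seg_b}, \code{n},
#'   \code{r}, \code{p} (NA with zero variance), plus a Bonferroni column
#'   for transparency (not used for any call).
#' @export
statusCorrelation <- function(cohort, functional_threshold = 0.567,
                              selection_band = c(0.10, 0.90),
                              p_method = c("fisher_z", "naive")) {
    p_method <- match.arg(p_method)
    status <- binaryStatus(cohort, functional_threshold)
    frac <- rowMeans(status, na.rm = TRUE)
    sel <- which(!is.na(frac) & frac >= selection_band[1] &
                 frac <= selection_band[2])
    if (length(sel) < 2L)
        return(data.frame(seg_a = character(0), seg_b = character(0),
                          n = integer(0), r = numeric(0), p = numeric(0),
                          p_bonferroni = numeric(0)))
    pairs <- combn(sel, 2L)
    res <- apply(pairs, 2L, function(ij) {
        a <- status[ij[1], ]; b <- status[ij[2], ]
        ok <- !is.na(a) & !is.na(b)
        n <- sum(ok)
        if (n < 4L || sd(a[ok]) == 0 || sd(b[ok]) == 0)
            return(c(n, NA_real_, NA_real_))
        r <- cor(as.numeric(a[ok]), as.numeric(b[ok]))
        z <- switch(p_method,
                    fisher_z = atanh(min(max(r, -1), 1)) * sqrt(n - 3),
                    naive = r * sqrt(n))
        c(n, r, 2 * pnorm(-abs(z)))
    })
    out <- data.frame(seg_a = rownames(status)[pairs[1, ]],
                      seg_b = rownames(status)[pairs[2, ]],
                      n = as.integer(res[1, ]), r = res[2, ],
                      p = res[3, ], row.names = NULL)
    out$p_bonferroni <- pmin(1, out$p * nrow(out))
    out
}

#' Mann-Whitney U test (two-tailed)
#'
#' Rank-sum comparison of two samples. For groups of at most 8 each the
#' two-tailed p-value comes from exact enumeration of all group assignments
#' of the pooled values (ties handled by enumeration); otherwise from the
#' normal approximation with tie correction (no continuity correction).
#'
#' @param x,y numeric vectors.
#' @param exact force exact enumeration (TRUE/FALSE); default: exact iff
#'   both groups have 8 or fewer values.
#' @return list: \code{U} (the smaller of the two U statistics),
#'   \code{U_x} (U of the first sample), \code{p}, \code{method}.
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(10, 11, 12))  # U = 0, exact p = 0.1
#' @export
mannWhitneyU <- function(x, y, exact = NULL) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    n1 <- length(x); n2 <- length(y)
    if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
    if (is.null(exact)) exact <- n1 <= 8L && n2 <= 8L
    pooled <- c(x, y)
    rk <- rank(pooled)
    U_x <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
    U <- min(U_x, n1 * n2 - U_x)
    if (exact) {
        idx <- combn(n1 + n2, n1)
        Us <- apply(idx, 2L, function(ii)
            sum(rk[ii]) - n1 * (n1 + 1) / 2)
        p <- min(1, 2 * mean(Us <= U + 1e-9))
        method <- "exact enumeration"
    } else {
        N <- n1 + n2
        ties <- table(pooled)
        sigma2 <- n1 * n2 / 12 *
            ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
        z <- (U_x - n1 * n2 / 2) / sqrt(sigma2)
        p <- 2 * pnorm(-abs(z))
        method <- "normal approximation with tie correction"
    }
    list(U = U, U_x = U_x, p = p, method = method)
}

#' Test prior annotation against segment abundance
#'
#' Mann-Whitney U comparison of total rearrangement counts between
#' retained segments annotated purely functional and those annotated
#' pseudogene/ORF, probing whether non-functional segments are also used
#' less often (as expected if their recombination signal sequences are
#' under no selection).
#'
#' @param cohort a [SegmentCohort-class] (after [abundanceFilter()]).
#' @return list: \code{U}, \code{p}, \code{n_functional},
#'   \code{n_nonfunctional}, \code{method}; NULL components with a warning
#'   if a class is empty.
#' @export
annotationAbundanceTest <- function(cohort) {
    rd <- rowData(cohort)
    a <- rd$total_rearrangements[rd$prior %in% .PURE_F]
    b <- rd$total_rearrangements[rd$prior %in% .PURE_NF]
    if (length(a) == 0L || length(b) == 0L) {
        warning("a prior class is empty; abundance test undefined")
        return(list(U = NA_real_, p = NA_real_, n_functional = length(a),
                    n_nonfunctional = length(b), method = "undefined"))
    }
    res <- mannWhitneyU(a, b)
    list(U = res$U, p = res$p, n_functional = length(a),
         n_nonfunctional = length(b), method = res$method)
}

#' Expected in-frame fraction for a functional segment
#'
#' If a fraction \code{p} of a functional segment's observed rearrangements
#' is productive (selected), the remaining \code{1 - p} behave like
#' unselected junctions and are in frame about a third of the time, so the
#' overall in-frame fraction is \code{p + (1 - p) / 3}. At \code{p = 0} the
#' value is the pure unselected null, 1/3.
#'
#' @param p_productive post-selection productive fraction in [0, 1].
#' @return numeric in [1/3, 1].
#' @examples
#' expectedProductiveFraction(0.80)  # ~0.867
#' @export
expectedProductiveFraction <- function(p_productive) {
    if (any(p_productive < 0 | p_productive > 1))
        stop("p_productive must lie in [0, 1]")
    p_productive + (1 - p_productive) / 3
}
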