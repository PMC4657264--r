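## small helper: wrap a long-format stats table into a cohort
stats_df <- function(individual, segment, n_unique, n_productive) {
    data.frame(individual = individual, segment = segment,
               n_unique = n_unique, n_productive = n_productive,
               proportion = n_productive / n_unique,
               stringsAsFactors = FALSE)
}

test_that("per-individual proportions count unique scored records", {
    tab <- data.frame(
        sequence = c("A", "B", "C", "D", "E", "F", "G"),
        count = c(5L, 1L, 1L, 1L, 9L, 1L, 2L),
        v_call = c("V1", "V1", "V1", "V1", "V2", "NONE", "V2"),
        j_call = "J1",
        productive = c(TRUE, TRUE, TRUE, FALSE, FALSE, NA, NA))
    st <- perIndividualProportions(list(I1 = tab))
    v1 <- st[st$segment == "V1", ]
    expect_equal(v1$n_unique, 4L)
    expect_equal(v1$proportion, 0.75)
    ## the NONE record and the NA-productive record are excluded entirely
    v2 <- st[st$segment == "V2", ]
    expect_equal(v2$n_unique, 1L)
    expect_equal(v2$proportion, 0)
    ## read-count weighting is the documented alternative
    stw <- perIndividualProportions(list(I1 = tab),
                                    weight_by_count = TRUE)
    expect_equal(stw$n_unique[stw$segment == "V1"], 8L)
    expect_equal(stw$proportion[stw$segment == "V1"], 7 / 8)
})

test_that("cohort container holds NA for unobserved pairs", {
    st <- stats_df(c("I1", "I1", "I2"), c("V1", "V2", "V1"),
                   c(10L, 20L, 40L), c(9L, 5L, 36L))
    coh <- SegmentCohort(st)
    expect_s4_class(coh, "SegmentCohort")
    p <- productiveProportion(coh)
    expect_equal(dim(p), c(2L, 2L))
    expect_true(is.na(p["V2", "I2"]))
    expect_equal(p["V1", "I2"], 0.9)
    rd <- segmentStats(coh)
    expect_equal(rd$total_rearrangements[rd$segment == "V1"], 50)
    expect_equal(rd$n_individuals_observed[rd$segment == "V2"], 1)
})

test_that("cohort mean and SD use the sample (n-1) convention", {
    st <- stats_df(rep(c("I1", "I2", "I3"), 2),
                   rep(c("V1", "V2"), each = 3),
                   rep(10L, 6), c(9L, 9L, 9L, 2L, 9L, 4L))
    coh <- SegmentCohort(st)
    rd <- segmentStats(coh)
    expect_equal(rd$mean_proportion[rd$segment == "V1"], 0.9)
    expect_equal(rd$sd_proportion[rd$segment == "V1"], 0)
    expect_equal(rd$mean_proportion[rd$segment == "V2"], 0.5)
    expect_equal(rd$sd_proportion[rd$segment == "V2"],
                 sd(c(0.2, 0.9, 0.4)))
    ## {0.2, 0.9}: closed-form sample SD = |0.9 - 0.2| / sqrt(2)
    st2 <- stats_df(c("I1", "I2"), "V1", c(10L, 10L), c(2L, 9L))
    rd2 <- segmentStats(SegmentCohort(st2))
    expect_equal(rd2$mean_proportion, 0.55)
    expect_equal(rd2$sd_proportion, 0.7 / sqrt(2))
    ## permutation invariance
    coh_perm <- SegmentCohort(st[sample(nrow(st)), ])
    expect_equal(segmentStats(coh_perm), rd)
})

test_that("abundance filter applies the mean-per-individual rule", {
    ## 10 individuals; V1 averages 125/individual, V2 only 12
    st <- stats_df(rep(sprintf("I%02d", 1:10), 3),
                   rep(c("V1", "V2", "V3"), each = 10),
                   c(rep(125L, 10), rep(12L, 10), rep(500L, 10)),
                   c(rep(100L, 10), rep(4L, 10), rep(450L, 10)))
    coh <- SegmentCohort(st)
    filt <- abundanceFilter(coh, min_mean_per_individual = 20)
    expect_setequal(rownames(filt), c("V1", "V3"))
    expect_equal(excludedSegments(filt), "V2")
    ## the largest log10 gap sits between V1 (1250) and V2 (120)
    gap <- S4Vectors::metadata(filt)$abundance_filter$largest_gap
    expect_equal(gap$after_segment, "V1")
    expect_equal(gap$before_segment, "V2")
    expect_equal(gap$log10_ratio, log10(1250 / 120))
    ## threshold 0 excludes nothing
    expect_equal(nrow(abundanceFilter(coh, 0)), 3L)
    expect_error(abundanceFilter(SegmentCohort(st)[0, ]), "empty")
})

test_that("thresholds derive from class medians with fixed fallbacks", {
    segs <- sprintf("V%d", 1:7)
    st <- stats_df(rep(c("I1", "I2", "I3"), each = 7),
                   rep(segs, 3), rep(100L, 21),
                   rep(c(90L, 88L, 92L, 30L, 28L, 60L, 55L), 3))
    ## plant SD by varying I3
    st$n_productive[15:21] <- c(90L, 86L, 92L, 32L, 28L, 20L, 95L)
    st$proportion <- st$n_productive / st$n_unique
    priors <- c(V1 = "F", V2 = "F", V3 = "F", V4 = "P", V5 = "ORF",
                V6 = "F/P", V7 = "F/ORF")
    coh <- SegmentCohort(st, priors = priors)
    thr <- deriveThresholds(coh)
    rd <- segmentStats(coh)
    m_f <- median(rd$mean_proportion[1:3])
    m_nf <- median(rd$mean_proportion[4:5])
    expect_equal(thr$functional_threshold, (m_f + m_nf) / 2)
    s_pure <- median(rd$sd_proportion[1:5])
    s_mixed <- median(rd$sd_proportion[6:7])
    expect_equal(thr$sd_threshold, (s_pure + s_mixed) / 2)
    expect_true(all(thr$derived))
    ## no priors at all -> printed defaults, one warning per threshold
    coh2 <- SegmentCohort(st)
    w <- capture_warnings(thr2 <- deriveThresholds(coh2))
    expect_length(w, 2L)
    expect_match(w, "default", all = TRUE)
    expect_equal(thr2$functional_threshold, 0.567)
    expect_equal(thr2$sd_threshold, 0.05)
    expect_false(any(thr2$derived))
})

test_that("midpoint arithmetic for class medians is exact", {
    ## medians 0.90 and 0.30 -> threshold 0.60
    segs <- c("A1", "A2", "B1", "B2", "M1")
    st <- stats_df(rep(c("I1", "I2"), each = 5), rep(segs, 2),
                   rep(10L, 10), rep(c(9L, 9L, 3L, 3L, 6L), 2))
    coh <- SegmentCohort(st, priors = c(A1 = "F", A2 = "F", B1 = "P",
                                        B2 = "P", M1 = "F/P"))
    thr <- deriveThresholds(coh)
    expect_equal(thr$functional_threshold, 0.60)
})

test_that("segment classification follows the SD-then-mean rule", {
    expect_equal(classifySegment(0.864, 0.03), "functional")
    expect_equal(classifySegment(0.218, 0.03), "pseudogene")
    expect_equal(classifySegment(0.60, 0.12), "segregating")
    ## mean threshold is inclusive, SD threshold strict
    expect_equal(classifySegment(0.567, 0.03), "functional")
    expect_equal(classifySegment(0.566, 0.03), "pseudogene")
    expect_equal(classifySegment(0.90, 0.05), "functional")
    expect_equal(classifySegment(0.90, 0.0500001), "segregating")
    expect_error(classifySegment(0.5, 0.03, functional_threshold = 1.2))
})

test_that("annotateSegments records calls, thresholds and discrepancies", {
    segs <- c("F1", "F2", "P1", "P2", "S1")
    props <- list(F1 = c(0.90, 0.88, 0.91), F2 = c(0.85, 0.86, 0.84),
                  P1 = c(0.30, 0.31, 0.29), P2 = c(0.25, 0.27, 0.26),
                  S1 = c(0.90, 0.30, 0.85))
    st <- do.call(rbind, lapply(seq_along(segs), function(k)
        stats_df(c("I1", "I2", "I3"), segs[k], rep(100L, 3),
                 as.integer(props[[k]] * 100))))
    coh <- SegmentCohort(st, priors = c(F1 = "F", F2 = "F", P1 = "P",
                                        P2 = "P", S1 = "F"))
    coh <- annotateSegments(coh, thresholds = list(
        functional_threshold = 0.567, sd_threshold = 0.05),
        min_individuals = 2L)
    calls <- annotationCalls(coh)
    expect_equal(setNames(calls$call, calls$segment),
                 c(F1 = "functional", F2 = "functional",
                   P1 = "pseudogene", P2 = "pseudogene",
                   S1 = "segregating"))
    ## S1 is prior-F but behaves as segregating -> flagged
    expect_equal(calls$discrepant, c(FALSE, FALSE, FALSE, FALSE, TRUE))
    expect_true(all(calls$functional_threshold_used == 0.567))
    ## pseudogene calls imply a mean below the functional threshold
    ps <- calls$call == "pseudogene"
    expect_true(all(calls$mean_proportion[ps] < 0.567))
    ## under-observed segments stay uncalled
    coh2 <- annotateSegments(SegmentCohort(st), thresholds = list(
        functional_threshold = 0.567, sd_threshold = 0.05),
        min_individuals = 10L)
    expect_true(all(is.na(annotationCalls(coh2)$call)))
})

test_that("classification is invariant to cohort duplication and scale", {
    set.seed(13)
    segs <- sprintf("V%02d", 1:6)
    inds <- sprintf("I%02d", 1:12)
    st <- do.call(rbind, lapply(segs, function(s) {
        p <- runif(1, 0.2, 0.9)
        stats_df(inds, s, rep(200L, 12),
                 as.integer(pmin(200, rbinom(12, 200, p))))
    }))
    thr <- list(functional_threshold = 0.567, sd_threshold = 0.05)
    base_calls <- annotationCalls(
        annotateSegments(SegmentCohort(st), thr))$call
    ## duplicate the whole cohort under new individual ids
    st2 <- st
    st2$individual <- paste0(st2$individual, "bis")
    dup <- rbind(st, st2)
    dup_calls <- annotationCalls(
        annotateSegments(SegmentCohort(dup), thr))$call
    expect_equal(dup_calls, base_calls)
    ## scaling every abundance leaves calls unchanged
    st3 <- st
    st3$n_unique <- st3$n_unique * 10L
    st3$n_productive <- st3$n_productive * 10L
    scale_calls <- annotationCalls(
        annotateSegments(SegmentCohort(st3), thr))$call
    expect_equal(scale_calls, base_calls)
})

test_that("binary status applies the inclusive functional threshold", {
    st <- stats_df(c("I1", "I2", "I3"), "V1", rep(1000L, 3),
                   c(900L, 300L, 567L))
    bs <- binaryStatus(SegmentCohort(st), 0.567)
    expect_equal(unname(bs["V1", ]), c(TRUE, FALSE, TRUE))
})

test_that("status correlation handles identity and degenerate input", {
    ## two segments with identical binary patterns, one anticorrelated
    inds <- sprintf("I%02d", 1:20)
    pat <- rep(c(TRUE, FALSE), 10)
    mk <- function(seg, p) stats_df(inds, seg, rep(100L, 20),
                                    ifelse(p, 90L, 30L))
    coh <- SegmentCohort(rbind(mk("A", pat), mk("B", pat),
                               mk("C", !pat)))
    res <- statusCorrelation(coh, 0.567, selection_band = c(0.1, 0.9))
    ab <- res[res$seg_a == "A" & res$seg_b == "B", ]
    expect_equal(ab$r, 1)
    expect_lt(ab$p, 1e-6)
    ac <- res[res$seg_a == "A" & res$seg_b == "C", ]
    expect_equal(ac$r, -1)
    ## segments outside the 10-90 % band are dropped
    cohD <- SegmentCohort(rbind(mk("A", pat), mk("B", pat),
                                mk("D", rep(TRUE, 20))))
    resD <- statusCorrelation(cohD, 0.567)
    expect_false("D" %in% c(resD$seg_a, resD$seg_b))
    ## zero variance within the band cannot happen, but pairwise-complete
    ## subsets can degenerate; those pairs come back NA
    stE <- rbind(mk("A", pat), mk("E", pat)[1:2, ])
    resE <- statusCorrelation(SegmentCohort(stE), 0.567,
                              selection_band = c(0.05, 0.95))
    expect_equal(nrow(resE), 1L)
    expect_true(is.na(resE$r))   # only 2 complete pairs: undefined
})

test_that("Mann-Whitney matches exact enumeration and wilcox.test", {
    res <- mannWhitneyU(c(1, 2, 3), c(10, 11, 12))
    expect_equal(res$U, 0)
    expect_equal(res$p, 0.1)
    expect_match(res$method, "exact")
    ## parameterised cross-check against wilcox.test (exact, no ties)
    set.seed(17)
    for (k in 1:6) {
        x <- sample(100, sample(3:8, 1))
        y <- sample(200:300, sample(3:8, 1))
        w <- wilcox.test(x, y, exact = TRUE)
        got <- mannWhitneyU(x, y)
        expect_equal(got$p, w$p.value, tolerance = 1e-12,
                     label = paste("exact case", k))
    }
    ## large-sample path against the tie-corrected normal approximation
    set.seed(19)
    x <- rpois(30, 10)
    y <- rpois(25, 14)
    w <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                      correct = FALSE))
    got <- mannWhitneyU(x, y)
    expect_equal(got$p, w$p.value, tolerance = 1e-12)
    expect_match(got$method, "normal")
    ## rank test is invariant under monotone transforms
    expect_equal(mannWhitneyU(exp(x), exp(y))$p, got$p)
    ## identical samples carry no evidence
    expect_equal(mannWhitneyU(1:5, 1:5)$p, 1, tolerance = 0.05)
})

test_that("annotation-vs-abundance test needs both prior classes", {
    segs <- c("F1", "F2", "F3", "P1", "P2", "P3")
    st <- do.call(rbind, lapply(seq_along(segs), function(k)
        stats_df("I1", segs[k], c(500L, 400L, 300L, 50L, 40L, 30L)[k],
                 10L)))
    coh <- SegmentCohort(st, priors = c(F1 = "F", F2 = "F", F3 = "F",
                                        P1 = "P", P2 = "P", P3 = "ORF"))
    res <- annotationAbundanceTest(coh)
    expect_equal(res$U, 0)
    expect_equal(res$p, 0.1)
    coh2 <- SegmentCohort(st, priors = c(F1 = "F", F2 = "F", F3 = "F",
                                         P1 = "F", P2 = "F", P3 = "F"))
    expect_warning(res2 <- annotationAbundanceTest(coh2), "empty")
    expect_true(is.na(res2$p))
})

test_that("the selection arithmetic interpolates between 1/3 and 1", {
    expect_equal(expectedProductiveFraction(0.80), 0.80 + 0.20 / 3)
    expect_equal(expectedProductiveFraction(1), 1)
    expect_equal(expectedProductiveFraction(0), 1 / 3)
    expect_error(expectedProductiveFraction(1.1), "0, 1")
})
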