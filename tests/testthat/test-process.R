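test_that("error collapsing merges neighbours into the dominant sequence", {
    expect_equal(collapseErrors(c(AAAA = 100L, AAAT = 1L)),
                 c(AAAA = 101L))
    expect_equal(collapseErrors(c(AAAA = 10L, TTTT = 10L)),
                 c(AAAA = 10L, TTTT = 10L))
    ## greedy order: AAAT merges into AAAA first, then AATT (distance 2
    ## from AAAA, 1 from the already-merged AAAT) survives on its own
    expect_equal(collapseErrors(c(AAAA = 100L, AAAT = 2L, AATT = 1L)),
                 c(AAAA = 102L, AATT = 1L))
    ## different lengths never merge
    expect_equal(collapseErrors(c(AAAA = 5L, AAA = 1L)),
                 c(AAAA = 5L, AAA = 1L))
})

test_that("collapsing agrees with a brute-force all-pairs oracle", {
    for (seed in 1:4) {
        set.seed(seed)
        n <- 60
        seqs <- unique(random_dna(n, 8))
        counts <- setNames(sample(1:50, length(seqs), replace = TRUE),
                           seqs)
        got <- collapseErrors(counts)
        want <- collapse_oracle(counts)
        expect_equal(got, want, label = paste("seed", seed))
        expect_equal(sum(got), sum(counts))
        ## idempotence
        expect_equal(collapseErrors(got), got)
    }
    ## larger Hamming radius goes through the generic path
    set.seed(9)
    seqs <- unique(random_dna(40, 6))
    counts <- setNames(sample(1:20, length(seqs), replace = TRUE), seqs)
    expect_equal(collapseErrors(counts, max_distance = 2L),
                 collapse_oracle(counts, max_distance = 2L))
})

test_that("segment assignment honours match length and ambiguity rules", {
    ref <- hand_reference()
    ## 10-nt exact copy of the V1 3' end (with 2 deletions) at read start
    read <- paste0(substring("ACGACGACGTGTACCGCA", 7, 16), "GGATTCGCAGCA")
    res <- assignSegment(read, ref, "V")
    expect_equal(res$call, "TRBV01")
    expect_equal(res$match_len, 10L)
    ## a 6-nt prefix present in both V segments ties -> AMBIGUOUS
    amb_ref <- GermlineReference(
        sequences = c("ACGACGGGGGGCTGTACC", "TTCTTCGGGGGCTGCAGG",
                      "ACCGGATTCGCAGCAGCA"),
        segment = c("TRBV01", "TRBV02", "TRBJ01"),
        kind = c("V", "V", "J"),
        anchor_offset = c(12L, 12L, 6L),
        functional = TRUE)
    res2 <- assignSegment("GGGGGCATTTTTTTTT", amb_ref, "V")
    expect_equal(res2$call, "AMBIGUOUS")
    expect_equal(res2$match_len, 6L)
    ## best match below the 6-nt minimum -> NONE
    res3 <- assignSegment("ACGACTTTTTTTTTTT", ref, "V")
    expect_equal(res3$call, "NONE")
    ## J matching is anchored at the read's 3' end
    ## the read ends with the complete J1 sequence (the V part supplies
    ## J1's first three bases by construction)
    readj <- paste0("ACGACGACGTGTACC", "GGATTCGCAGCAGCA")
    resj <- assignSegment(readj, ref, "J")
    expect_equal(resj$call, "TRBJ01")
    expect_equal(resj$match_len, 18L)
    expect_error(assignSegment("ACGT", vAlleles(ref), "J"), "no candidate")
})

test_that("lowering min_match never increases the NONE count", {
    ref <- buildToyReference(6, 2, fraction_pseudogenic = 0, seed = 30)
    set.seed(7)
    jn <- simulateJunctions(ref, simulationConfig(), n = 400)
    reads <- vapply(jn$sequence, function(s) {
        p <- sample.int(nchar(s), 3)
        for (q in p) substr(s, q, q) <- sample(c("A", "C", "G", "T"), 1)
        s
    }, character(1), USE.NAMES = FALSE)
    nones <- vapply(c(4L, 6L, 9L, 12L), function(mm)
        sum(assignSegment(reads, ref, "V", min_match = mm)$call == "NONE"),
        integer(1))
    expect_true(all(diff(nones) >= 0))
})

test_that("CDR3 extraction matches the simulator's truth records", {
    ref <- buildToyReference(6, 2, fraction_pseudogenic = 0.5, seed = 33)
    cfg <- simulationConfig(n_individuals = 1,
                            n_cells_per_individual = 1500,
                            sequencing_error_rate = 0, seed = 51)
    dir <- tempfile("coh")
    out <- simulateCohort(ref, cfg, dir)
    truth <- utils::read.delim(file.path(dir, "truth_records.tsv"),
                               stringsAsFactors = FALSE)
    aref <- readGermlineReference(out$reference)
    tab <- utils::read.delim(out$individual_files[1],
                             colClasses = c("character", "integer"))
    p <- processRearrangements(tab, aref, collapse = FALSE)
    expect_true(all(!(p$v_call %in% c("NONE", "AMBIGUOUS"))))
    expect_true(all(!(p$j_call %in% c("NONE", "AMBIGUOUS"))))
    m <- match(p$sequence, truth$read)
    expect_false(anyNA(m))
    expect_equal(p$v_call, truth$v_segment[m])
    expect_equal(p$j_call, truth$j_segment[m])
    expect_equal(p$cdr3_start, truth$cdr3_start[m])
    expect_equal(p$cdr3_end, truth$cdr3_end[m])
    expect_equal(p$productive, truth$productive[m])
})

test_that("CDR3 is undefined when an anchor is deleted or uncovered", {
    ref <- hand_reference()
    ## read whose V region starts after the Cys codon: anchor not covered
    read <- paste0(substring("ACGACGACGTGTACCGCA", 13, 18),
                   "GGA", "ACCGGATTCGCAGCAGCA")
    av <- assignSegment(read, ref, "V")
    expect_equal(av$call, "TRBV01")
    sp <- extractCDR3(read, "TRBV01*01", "TRBJ01*01",
                      av$match_len, 18L, ref)
    expect_true(is.na(sp$cdr3_start))
    ## fully covered anchors give the expected span
    full <- paste0("ACGACGACGTGTACCGCA", "ACCGGATTCGCAGCAGCA")
    sp2 <- extractCDR3(full, "TRBV01*01", "TRBJ01*01", 18L, 18L, ref)
    expect_equal(sp2$cdr3_start, 9L)
    expect_equal(sp2$cdr3_end, 18L + 9L)
})

test_that("anchor-adjacent junctions give the minimal 6-nt CDR3", {
    ## anchors at the V 3' terminus and J 5' terminus, no editing
    ref <- buildToyReference(2, 1, fraction_pseudogenic = 0, seed = 40,
                             v_tail = 0L, j_lead = 0L)
    cfg <- simulationConfig(max_v_deletion = 0, max_j_deletion = 0,
                            max_n_insertion = 0)
    set.seed(8)
    jn <- simulateJunctions(ref, cfg, n = 50)
    expect_true(all(jn$cdr3_end - jn$cdr3_start == 6L))
    expect_true(all(jn$productive))
})

test_that("productivity scoring follows the frame and stop rules", {
    ## 45-nt stop-free CDR3 in frame
    cdr3 <- paste(rep("TGTGCAGCAGCAGCA", 3), collapse = "")
    expect_true(classifyProductive(cdr3, 0, 45))
    ## 44 nt cannot be in frame
    expect_false(classifyProductive(substring(cdr3, 1, 44), 0, 44))
    ## in-frame stop codon
    expect_false(classifyProductive("TGTGCCTGATTC", 0, 12))
    ## stop out of frame does not count
    expect_true(classifyProductive("TGTGTGAGCTTC", 0, 12))
    expect_true(is.na(classifyProductive("TGTGCA", NA, NA)))
})

test_that("productivity equals the translation oracle on random spans", {
    set.seed(11)
    seqs <- random_dna(400, 36)
    start0 <- sample(0:6, 400, replace = TRUE)
    end0 <- start0 + 3 * sample(2:9, 400, replace = TRUE)
    end0 <- pmin(end0, 36L)
    keep <- (end0 - start0) > 0
    got <- classifyProductive(seqs[keep], start0[keep], end0[keep])
    want <- translation_oracle(seqs[keep], start0[keep], end0[keep])
    ## oracle translates only multiples of three; emulate the frame rule
    len3 <- (end0[keep] - start0[keep]) %% 3 == 0
    expect_equal(got[len3], want[len3])
    expect_true(all(!got[!len3]))
})

test_that("processing reports exclusion counts that add up", {
    ref <- buildToyReference(5, 2, fraction_pseudogenic = 0.2, seed = 44)
    cfg <- simulationConfig(n_individuals = 2,
                            n_cells_per_individual = 800, seed = 61)
    dir <- tempfile("coh")
    simulateCohort(ref, cfg, dir, write_truth_records = FALSE)
    aref <- readGermlineReference(file.path(dir, "reference.fasta"))
    tabs <- processCohort(dir, aref)
    excl <- attr(tabs, "exclusions")
    expect_equal(nrow(excl), 2L)
    for (i in seq_along(tabs)) {
        tab <- tabs[[i]]
        expect_equal(excl$n_scored[i], sum(!is.na(tab$productive)))
        expect_equal(excl$n_input[i] - excl$n_collapsed[i], nrow(tab))
        ## productive is only defined for concrete assignments
        defined_p <- !is.na(tab$productive)
        expect_true(all(!(tab$v_call[defined_p] %in%
                          c("NONE", "AMBIGUOUS"))))
        concrete <- !(tab$v_call %in% c("NONE", "AMBIGUOUS")) &
            !(tab$j_call %in% c("NONE", "AMBIGUOUS"))
        expect_true(all(is.na(tab$productive[!concrete])))
        defined <- !is.na(tab$cdr3_start)
        expect_equal(tab$cdr3_length[defined],
                     tab$cdr3_end[defined] - tab$cdr3_start[defined])
    }
})
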