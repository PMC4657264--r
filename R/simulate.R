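## Mechanistic simulator: two-allele VDJ rearrangement with thymic selection.

#' Simulation configuration
#'
#' Collects the simulator's tunable parameters. Junctional deletion and
#' insertion lengths are uniform on \code{0..max}; deletions never cut into
#' the anchor codon (the draw is uniform on \code{0..min(max, distance to
#' the anchor)}).
#'
#' @param n_individuals number of individuals in the cohort.
#' @param n_cells_per_individual number of developing T cells simulated per
#'   individual (cells that fail selection emit nothing).
#' @param max_v_deletion,max_j_deletion,max_n_insertion junctional editing
#'   maxima in nt.
#' @param pseudogene_allele_frequencies named numeric vector, per V segment,
#'   of the population frequency of the non-functional allele. Defaults to 0
#'   for segments whose reference allele is functional and 1 otherwise;
#'   intermediate values plant segregating segments (sampled under
#'   Hardy-Weinberg equilibrium).
#' @param sequencing_error_rate per-base substitution probability applied to
#'   emitted reads.
#' @param read_length reads keep the last \code{read_length} bases of the
#'   rearrangement (V 3' region, junction, J), emulating short-read assays
#'   anchored at the junction.
#' @param seed master seed; per-individual streams are derived from it so
#'   cohorts are reproducible.
#' @param linkage_groups optional list of character vectors of V segment
#'   names; segments in one group have their allele status drawn from a
#'   single uniform variate per haplotype (comonotone coupling), planting
#'   haplotype linkage.
#' @return a list of class \code{segfunc_config}.
#' @export
simulationConfig <- function(n_individuals = 50L,
                             n_cells_per_individual = 12000L,
                             max_v_deletion = 6L,
                             max_j_deletion = 6L,
                             max_n_insertion = 10L,
                             pseudogene_allele_frequencies = NULL,
                             sequencing_error_rate = 0.001,
                             read_length = 87L,
                             seed = 1L,
                             linkage_groups = NULL) {
    cfg <- list(n_individuals = as.integer(n_individuals),
                n_cells_per_individual = as.integer(n_cells_per_individual),
                max_v_deletion = as.integer(max_v_deletion),
                max_j_deletion = as.integer(max_j_deletion),
                max_n_insertion = as.integer(max_n_insertion),
                pseudogene_allele_frequencies =
                    pseudogene_allele_frequencies,
                sequencing_error_rate = sequencing_error_rate,
                read_length = as.integer(read_length),
                seed = as.integer(seed),
                linkage_groups = linkage_groups)
    stopifnot(cfg$n_individuals >= 0, cfg$n_cells_per_individual >= 0,
              cfg$max_v_deletion >= 0, cfg$max_j_deletion >= 0,
              cfg$max_n_insertion >= 0, cfg$read_length > 0,
              cfg$sequencing_error_rate >= 0, cfg$sequencing_error_rate < 1)
    f <- cfg$pseudogene_allele_frequencies
    if (!is.null(f) && (any(f < 0) || any(f > 1)))
        stop("allele frequencies must lie in [0, 1]")
    class(cfg) <- "segfunc_config"
    cfg
}

## deterministic per-individual seed stream
.derive_seed <- function(seed, i) {
    as.integer(((as.double(seed) %% 2147483647) * 48271 +
                (as.double(i) + 1) * 16807) %% 2147483647L + 1)
}

## flat lookup tables for fast vectorized simulation
.ref_cache <- function(reference) {
    mc <- mcols(reference)
    list(name = names(reference),
         seq = as.character(reference),
         width = width(reference),
         segment = mc$segment,
         kind = mc$kind,
         anchor = mc$anchor_offset,
         functional = mc$functional,
         rss = mc$rss_weight)
}

.rand_dna_strings <- function(lens) {
    total <- sum(lens)
    if (total == 0L) return(rep("", length(lens)))
    big <- paste(sample(c("A", "C", "G", "T"), total, replace = TRUE),
                 collapse = "")
    ends <- cumsum(lens)
    substring(big, ends - lens + 1L, ends)
}

## uniform integer on 0..k, vectorized over k
.runif_int <- function(k) {
    as.integer(floor(runif(length(k)) * (k + 1L)))
}

## assemble junctions for paired allele index vectors; returns the full
## rearranged sequence plus the CDR3 span (0-based, half-open) and the
## sequence-level productivity flag
.make_junctions <- function(v_idx, j_idx, cache, config) {
    n <- length(v_idx)
    av <- cache$anchor[v_idx]
    aj <- cache$anchor[j_idx]
    wv <- cache$width[v_idx]
    wj <- cache$width[j_idx]
    d_v <- .runif_int(pmin(config$max_v_deletion, wv - (av + 3L)))
    d_j <- .runif_int(pmin(config$max_j_deletion, aj))
    m <- .runif_int(rep(config$max_n_insertion, n))
    ins <- .rand_dna_strings(m)
    seqs <- paste0(substring(cache$seq[v_idx], 1L, wv - d_v), ins,
                   substring(cache$seq[j_idx], d_j + 1L, wj))
    start0 <- av
    end0 <- (wv - d_v) + m + (aj + 3L - d_j)
    list(sequence = seqs, cdr3_start = start0, cdr3_end = end0,
         productive = .productive_span(seqs, start0, end0))
}

## weighted allele pick within an index pool; returns integer(0)-safe picks
.pick_alleles <- function(pool, w, n) {
    keep <- w > 0
    if (!any(keep) || n == 0L) return(rep(NA_integer_, n))
    pool <- pool[keep]
    w <- w[keep]
    pool[sample.int(length(pool), n, replace = TRUE, prob = w)]
}

#' Simulate developing T cells for one genotype
#'
#' Each cell rearranges once: a V allele is drawn across all the cell's V
#' allele copies with probability proportional to its RSS weight, a J allele
#' likewise; junctional deletion and non-templated insertion are applied.
#' The rearrangement is \emph{expressible} if its CDR3 is in frame and
#' stop-free (see [classifyProductive()]) \emph{and} the V allele is
#' functional. If the first attempt is not expressible, the second
#' chromosome rearranges the same way. Cells with no expressible
#' rearrangement undergo apoptosis and emit nothing; surviving cells emit
#' all rearrangements they made, including non-productive or pseudogenic
#' ones -- the signal the annotation method relies on.
#'
#' @param genotype list with \code{v} and \code{j}: character matrices of
#'   allele names (rows = segments, two columns = the two chromosomes; J may
#'   repeat one allele).
#' @param reference a [GermlineReference-class] containing those alleles.
#' @param config a [simulationConfig()].
#' @param n_cells number of cells to simulate.
#' @return data.frame with one row per emitted rearrangement: \code{cell},
#'   \code{attempt}, \code{v_allele}, \code{v_segment}, \code{j_allele},
#'   \code{j_segment}, \code{sequence}, \code{cdr3_start}, \code{cdr3_end}
#'   (0-based half-open, over \code{sequence}), \code{productive} (sequence
#'   level), \code{expressible}.
#' @examples
#' ref <- buildToyReference(2, 1, fraction_pseudogenic = 0, seed = 1)
#' gt <- list(v = cbind(c("TRBV01*01", "TRBV02*01"),
#'                      c("TRBV01*01", "TRBV02*01")),
#'            j = cbind("TRBJ01*01", "TRBJ01*01"))
#' set.seed(1)
#' head(simulateCells(gt, ref, simulationConfig(), n_cells = 10))
#' @export
simulateCells <- function(genotype, reference, config = simulationConfig(),
                          n_cells = 1L) {
    cache <- .ref_cache(reference)
    .simulate_cells_cached(genotype, cache, config, n_cells)
}

.simulate_cells_cached <- function(genotype, cache, config, n_cells) {
    n <- as.integer(n_cells)
    empty <- data.frame(cell = integer(0), attempt = integer(0),
                        v_allele = character(0), v_segment = character(0),
                        j_allele = character(0), j_segment = character(0),
                        sequence = character(0), cdr3_start = integer(0),
                        cdr3_end = integer(0), productive = logical(0),
                        expressible = logical(0),
                        stringsAsFactors = FALSE)
    if (n == 0L) return(empty)
    v_mat <- matrix(match(genotype$v, cache$name), ncol = 2L)
    j_mat <- matrix(match(genotype$j, cache$name), ncol = 2L)
    if (any(is.na(v_mat)) || any(is.na(j_mat)))
        stop("genotype refers to alleles absent from the reference")
    S <- nrow(v_mat)

    ## attempt 1: all V copies of both chromosomes compete
    v_pool <- as.vector(v_mat)           # chr 1 copies then chr 2 copies
    chr_of <- rep(1:2, each = S)
    j_pool <- as.vector(j_mat)
    pick1 <- .pick_alleles(seq_along(v_pool), cache$rss[v_pool], n)
    if (all(is.na(pick1))) return(empty)
    v1 <- v_pool[pick1]
    chr1 <- chr_of[pick1]
    j1 <- .pick_alleles(j_pool, cache$rss[j_pool], n)
    jun1 <- .make_junctions(v1, j1, cache, config)
    expr1 <- jun1$productive & cache$functional[v1]

    ## attempt 2 on the other chromosome for cells not yet expressing
    need2 <- which(!expr1)
    v2 <- j2 <- rep(NA_integer_, n)
    expr2 <- rep(FALSE, n)
    jun2 <- NULL
    if (length(need2) > 0L) {
        chr2 <- 3L - chr1[need2]
        v2n <- rep(NA_integer_, length(need2))
        for (cc in 1:2) {
            sub <- which(chr2 == cc)
            if (length(sub) > 0L)
                v2n[sub] <- .pick_alleles(v_mat[, cc],
                                          cache$rss[v_mat[, cc]],
                                          length(sub))
        }
        j2n <- .pick_alleles(j_pool, cache$rss[j_pool], length(need2))
        ok <- !is.na(v2n)
        jun2 <- .make_junctions(v2n[ok], j2n[ok], cache, config)
        v2[need2[ok]] <- v2n[ok]
        j2[need2[ok]] <- j2n[ok]
        expr2[need2[ok]] <- jun2$productive & cache$functional[v2n[ok]]
    }
    survive <- expr1 | expr2

    rec1 <- which(survive)               # first attempt always emitted
    if (length(rec1) == 0L) return(empty)
    rec2 <- which(survive & !expr1 & !is.na(v2))
    row2 <- match(rec2, need2[!is.na(v2[need2])])

    build <- function(cells, attempt, v, j, jun, rows, expr) {
        data.frame(cell = cells, attempt = attempt,
                   v_allele = cache$name[v], v_segment = cache$segment[v],
                   j_allele = cache$name[j], j_segment = cache$segment[j],
                   sequence = jun$sequence[rows],
                   cdr3_start = jun$cdr3_start[rows],
                   cdr3_end = jun$cdr3_end[rows],
                   productive = jun$productive[rows],
                   expressible = expr, stringsAsFactors = FALSE)
    }
    out <- rbind(
        build(rec1, 1L, v1[rec1], j1[rec1], jun1, rec1, expr1[rec1]),
        if (length(rec2) > 0L)
            build(rec2, 2L, v2[rec2], j2[rec2], jun2, row2, expr2[rec2]))
    out[order(out$cell, out$attempt), , drop = FALSE]
}

#' Simulate unselected junctions
#'
#' Emits raw rearrangements with no thymic selection: V and J alleles are
#' drawn across the whole reference proportional to RSS weight. This is the
#' null process against which the "< 1/3 productive" arithmetic for
#' pseudogenes is checked; compare with [unselectedProductiveRate()].
#'
#' @inheritParams simulateCells
#' @param n number of junctions.
#' @return data.frame as in [simulateCells()] minus the selection columns.
#' @export
simulateJunctions <- function(reference, config = simulationConfig(),
                              n = 1000L) {
    cache <- .ref_cache(reference)
    v_all <- which(cache$kind == "V")
    j_all <- which(cache$kind == "J")
    v <- .pick_alleles(v_all, cache$rss[v_all], n)
    j <- .pick_alleles(j_all, cache$rss[j_all], n)
    jun <- .make_junctions(v, j, cache, config)
    data.frame(v_allele = cache$name[v], v_segment = cache$segment[v],
               j_allele = cache$name[j], j_segment = cache$segment[j],
               sequence = jun$sequence, cdr3_start = jun$cdr3_start,
               cdr3_end = jun$cdr3_end, productive = jun$productive,
               stringsAsFactors = FALSE)
}

## Add, where needed, a same-sequence allele of opposite functionality so a
## segment can segregate: the simulator distinguishes the alleles, the
## sequence data cannot -- exactly the situation the annotation method is
## built for.
.augment_reference <- function(reference, freqs) {
    mc <- mcols(reference)
    v_idx <- which(mc$kind == "V")
    add <- list()
    for (i in v_idx) {
        seg <- mc$segment[i]
        f <- freqs[[seg]]
        need_pseudo <- f > 0 && mc$functional[i]
        need_func <- f < 1 && !mc$functional[i]
        if (need_pseudo || need_func) {
            add[[length(add) + 1L]] <- data.frame(
                sequence = as.character(reference[[i]]),
                segment = seg, allele = "02s", kind = "V",
                anchor_offset = mc$anchor_offset[i],
                functional = !mc$functional[i],
                rss_weight = mc$rss_weight[i],
                prior = mc$prior[i], stringsAsFactors = FALSE)
        }
    }
    if (length(add) == 0L) return(reference)
    add <- do.call(rbind, add)
    GermlineReference(
        sequences = c(as.character(reference), add$sequence),
        segment = c(mc$segment, add$segment),
        allele = c(mc$allele, add$allele),
        kind = c(mc$kind, add$kind),
        anchor_offset = c(mc$anchor_offset, add$anchor_offset),
        functional = c(mc$functional, add$functional),
        rss_weight = c(mc$rss_weight, add$rss_weight),
        prior = c(mc$prior, add$prior))
}

## per-V-segment names of the functional and the non-functional allele in
## an augmented reference (NA when that type does not exist)
.allele_table <- function(reference) {
    mc <- mcols(reference)
    v <- which(mc$kind == "V")
    segs <- unique(mc$segment[v])
    func <- pseudo <- setNames(rep(NA_character_, length(segs)), segs)
    for (i in v) {
        s <- mc$segment[i]
        if (mc$functional[i]) {
            if (is.na(func[s])) func[s] <- names(reference)[i]
        } else if (is.na(pseudo[s])) pseudo[s] <- names(reference)[i]
    }
    list(segments = segs, functional = func, pseudogenic = pseudo)
}

## Hardy-Weinberg genotype for one individual; linked segments share one
## uniform draw per haplotype
.sample_genotype <- function(tab, freqs, linkage_groups) {
    segs <- tab$segments
    group <- setNames(seq_along(segs), segs)   # singleton groups
    if (!is.null(linkage_groups)) {
        for (k in seq_along(linkage_groups)) {
            members <- intersect(linkage_groups[[k]], segs)
            group[members] <- length(segs) + k
        }
    }
    hap <- function() {
        u_group <- runif(length(unique(group)))
        names(u_group) <- as.character(unique(group))
        u <- u_group[as.character(group[segs])]
        carrier <- u < freqs[segs]
        ifelse(carrier, tab$pseudogenic[segs], tab$functional[segs])
    }
    v <- cbind(hap(), hap())
    rownames(v) <- segs
    v
}

#' Simulate a seeded synthetic cohort
#'
#' Generates a cohort of individuals at a reduced but structurally faithful
#' scale: Hardy-Weinberg genotypes from per-segment non-functional allele
#' frequencies, per-cell two-allele rearrangement with thymic selection
#' ([simulateCells()]), per-base substitution sequencing error, junction
#' anchored read windowing, and per-individual rearrangement tables. A truth
#' file records genotypes and planted labels (functional when the
#' non-functional allele frequency is 0, pseudogene when it is 1,
#' segregating otherwise); per-record provenance goes to a separate TSV.
#' Identical seed and config give byte-identical output.
#'
#' @inheritParams simulateCells
#' @param out_dir output directory (created if missing).
#' @param segregating_prior prior annotation written for planted segregating
#'   segments (default "F/P", i.e. the database already lists alleles of
#'   both kinds; set to "F" to plant undescribed non-functional alleles).
#' @param write_truth_records write per-record provenance TSV (can be large).
#' @return invisibly, a list with the output paths, the planted labels and
#'   allele frequencies, and the per-individual genotypes.
#' @export
simulateCohort <- function(reference, config = simulationConfig(),
                           out_dir, segregating_prior = "F/P",
                           write_truth_records = TRUE) {
    stopifnot(is(reference, "GermlineReference"))
    if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", out_dir)

    mc <- mcols(reference)
    v_segs <- unique(mc$segment[mc$kind == "V"])
    ## default frequency: the reference allele's own functionality
    freqs <- setNames(
        as.numeric(!mc$functional[mc$kind == "V"][
            match(v_segs, mc$segment[mc$kind == "V"])]), v_segs)
    user <- config$pseudogene_allele_frequencies
    if (!is.null(user)) {
        bad <- setdiff(names(user), v_segs)
        if (length(bad) > 0)
            stop("frequencies given for unknown segments: ",
                 paste(bad, collapse = ", "))
        freqs[names(user)] <- user
    }
    labels <- ifelse(freqs == 0, "functional",
                     ifelse(freqs == 1, "pseudogene", "segregating"))

    aug <- .augment_reference(reference, freqs)
    cache <- .ref_cache(aug)
    tab <- .allele_table(aug)
    j_mc <- mcols(reference)
    j_idx <- which(j_mc$kind == "J")
    j_names <- names(reference)[j_idx]
    j_mat <- cbind(j_names, j_names)

    ## analysis-facing reference: original sequences, priors reflecting what
    ## a database would say (segregating plants get segregating_prior)
    analysis_ref <- reference
    pr <- mcols(analysis_ref)$prior
    pr[mcols(analysis_ref)$kind == "V" &
       mcols(analysis_ref)$segment %in% v_segs[labels == "segregating"]] <-
        segregating_prior
    mcols(analysis_ref)$prior <- pr

    ids <- sprintf("I%03d", seq_len(config$n_individuals))
    genotypes <- vector("list", config$n_individuals)
    names(genotypes) <- ids
    truth_records <- vector("list", config$n_individuals)
    files <- character(config$n_individuals)

    for (i in seq_len(config$n_individuals)) {
        set.seed(.derive_seed(config$seed, i))
        gv <- .sample_genotype(tab, freqs, config$linkage_groups)
        genotypes[[i]] <- gv
        recs <- .simulate_cells_cached(
            list(v = gv, j = j_mat), cache, config,
            config$n_cells_per_individual)

        ## junction-anchored read window, then sequencing error
        len <- nchar(recs$sequence)
        offset <- pmax(0L, len - config$read_length)
        clean <- substring(recs$sequence, offset + 1L, len)
        reads <- .apply_seq_errors(clean, config$sequencing_error_rate)
        cs <- recs$cdr3_start - offset
        ce <- recs$cdr3_end - offset
        lost <- cs < 0L
        cs[lost] <- NA_integer_
        ce[lost] <- NA_integer_

        if (length(reads) == 0L) {
            df <- data.frame(sequence = character(0), count = integer(0))
        } else {
            tabulated <- table(reads)
            df <- data.frame(sequence = names(tabulated),
                             count = as.integer(tabulated),
                             stringsAsFactors = FALSE)
            df <- df[order(-df$count, df$sequence), , drop = FALSE]
        }
        files[i] <- file.path(out_dir, paste0("individual_", ids[i], ".tsv"))
        write.table(df, files[i], sep = "\t", quote = FALSE,
                    row.names = FALSE)

        if (write_truth_records && nrow(recs) > 0L)
            truth_records[[i]] <- data.frame(
                individual = ids[i], cell = recs$cell,
                attempt = recs$attempt,
                v_segment = recs$v_segment, v_allele = recs$v_allele,
                j_segment = recs$j_segment, j_allele = recs$j_allele,
                productive = recs$productive,
                expressible = recs$expressible,
                read = clean, cdr3_start = cs, cdr3_end = ce,
                stringsAsFactors = FALSE)
    }

    ref_path <- file.path(out_dir, "reference.fasta")
    writeGermlineReference(analysis_ref, ref_path)
    priors_path <- file.path(out_dir, "priors.tsv")
    pr_v <- mcols(analysis_ref)$kind == "V"
    write.table(data.frame(
        segment_name = mcols(analysis_ref)$segment[pr_v],
        prior_annotation = mcols(analysis_ref)$prior[pr_v]),
        priors_path, sep = "\t", quote = FALSE, row.names = FALSE)

    truth_path <- file.path(out_dir, "truth.json")
    write_json(list(
        seed = config$seed,
        labels = as.list(labels),
        pseudogene_allele_frequencies = as.list(freqs),
        linkage_groups = config$linkage_groups,
        genotypes = lapply(genotypes, function(g)
            list(segment = rownames(g), hap1 = unname(g[, 1]),
                 hap2 = unname(g[, 2])))),
        truth_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)

    records_path <- NULL
    if (write_truth_records) {
        records_path <- file.path(out_dir, "truth_records.tsv")
        all_rec <- do.call(rbind, truth_records)
        write.table(all_rec, records_path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }

    invisible(list(individual_files = setNames(files, ids),
                   reference = ref_path, priors = priors_path,
                   truth = truth_path, truth_records = records_path,
                   labels = labels,
                   pseudogene_allele_frequencies = freqs,
                   genotypes = genotypes))
}

.apply_seq_errors <- function(reads, rate) {
    if (rate <= 0 || length(reads) == 0L) return(reads)
    len <- nchar(reads)
    k <- rbinom(length(reads), len, rate)
    hit <- which(k > 0L)
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
        pos <- sample.int(len[i], k[i])
        for (p in pos) {
            old <- substring(reads[i], p, p)
            new <- sample(setdiff(bases, old), 1L)
            substr(reads[i], p, p) <- new
        }
    }
    reads
}
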