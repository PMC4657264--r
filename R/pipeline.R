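## End-to-end orchestration from a config list / YAML file.

#' Read a priors table
#'
#' @param file tab-separated file with columns \code{segment_name},
#'   \code{prior_annotation} (codes F, ORF, P, F/P, F/ORF, none).
#' @return named character vector.
#' @export
readPriors <- function(file) {
    df <- read.delim(file, stringsAsFactors = FALSE)
    stopifnot(all(c("segment_name", "prior_annotation") %in% colnames(df)))
    bad <- setdiff(unique(df$prior_annotation), PRIOR_LEVELS)
    if (length(bad) > 0)
        stop("unknown prior codes: ", paste(bad, collapse = ", "))
    setNames(df$prior_annotation, df$segment_name)
}

.cfg_get <- function(cfg, path, default = NULL) {
    for (key in path) {
        if (is.null(cfg[[key]])) return(default)
        cfg <- cfg[[key]]
    }
    cfg
}

#' Run the full annotation pipeline
#'
#' Orchestrates simulate -> process -> annotate -> report from a config
#' list (or YAML file path). With a \code{simulate} section a synthetic
#' cohort is generated into \code{<out_dir>/cohort}; otherwise
#' \code{paths$cohort_dir} and \code{paths$reference} (and optionally
#' \code{paths$priors}) must point at existing inputs. Reports are written
#' to \code{<out_dir>/report}. A fixed seed makes the whole run
#' deterministic, byte for byte.
#'
#' @param config list or path to a YAML file. Recognised sections:
#'   \code{seed}, \code{out_dir}, \code{paths} (\code{cohort_dir},
#'   \code{reference}, \code{priors}), \code{simulate} (fields of
#'   [simulationConfig()] plus a \code{reference} sub-list passed to
#'   [buildToyReference()]), \code{process} (\code{min_match},
#'   \code{max_distance}), \code{annotate}
#'   (\code{min_mean_per_individual}, \code{min_individuals},
#'   \code{functional_threshold}, \code{sd_threshold},
#'   \code{selection_band}).
#' @param step one of "all", "simulate", "process" (process + annotate +
#'   report on an existing cohort).
#' @param out_dir,seed optional overrides of the config values.
#' @return invisibly, a list: the annotated [SegmentCohort-class], the
#'   per-individual stats, the correlation table, the abundance test, and
#'   the files written.
#' @export
runPipeline <- function(config, step = c("all", "simulate", "process"),
                        out_dir = NULL, seed = NULL) {
    step <- match.arg(step)
    cfg <- if (is.character(config)) read_yaml(config) else config
    if (is.null(out_dir)) out_dir <- .cfg_get(cfg, "out_dir")
    if (is.null(out_dir)) stop("out_dir must be given")
    if (is.null(seed)) seed <- .cfg_get(cfg, "seed", 1L)

    cohort_dir <- .cfg_get(cfg, c("paths", "cohort_dir"))
    ref_path <- .cfg_get(cfg, c("paths", "reference"))
    priors_path <- .cfg_get(cfg, c("paths", "priors"))

    sim_out <- NULL
    if (step %in% c("all", "simulate") && !is.null(cfg$simulate)) {
        sim <- cfg$simulate
        ref_cfg <- sim$reference
        if (is.null(ref_cfg) && is.null(ref_path))
            stop("simulate needs a reference sub-config or paths$reference")
        reference <- if (!is.null(ref_cfg)) {
            do.call(buildToyReference, c(
                ref_cfg[setdiff(names(ref_cfg), "seed")],
                list(seed = .cfg_get(ref_cfg, "seed", seed))))
        } else readGermlineReference(ref_path)
        freqs <- sim$pseudogene_allele_frequencies
        if (!is.null(freqs)) freqs <- unlist(freqs)
        scfg <- simulationConfig(
            n_individuals = .cfg_get(sim, "n_individuals", 50L),
            n_cells_per_individual =
                .cfg_get(sim, "n_cells_per_individual", 12000L),
            max_v_deletion = .cfg_get(sim, "max_v_deletion", 6L),
            max_j_deletion = .cfg_get(sim, "max_j_deletion", 6L),
            max_n_insertion = .cfg_get(sim, "max_n_insertion", 10L),
            pseudogene_allele_frequencies = freqs,
            sequencing_error_rate =
                .cfg_get(sim, "sequencing_error_rate", 0.001),
            read_length = .cfg_get(sim, "read_length", 87L),
            seed = seed,
            linkage_groups = sim$linkage_groups)
        cohort_dir <- file.path(out_dir, "cohort")
        sim_out <- simulateCohort(reference, scfg, cohort_dir)
        ref_path <- sim_out$reference
        priors_path <- sim_out$priors
        if (step == "simulate")
            return(invisible(list(simulation = sim_out)))
    }
    if (is.null(cohort_dir) || is.null(ref_path))
        stop("paths$cohort_dir and paths$reference are required without a ",
             "simulate section")

    reference <- readGermlineReference(ref_path)
    tables <- processCohort(cohort_dir, reference,
                            min_match = .cfg_get(cfg, c("process",
                                                        "min_match"), 6L),
                            max_distance = .cfg_get(cfg, c("process",
                                                   "max_distance"), 1L))
    stats <- perIndividualProportions(tables)
    priors <- if (!is.null(priors_path)) readPriors(priors_path) else NULL
    cohort <- SegmentCohort(stats, priors = priors)
    cohort <- abundanceFilter(cohort, .cfg_get(
        cfg, c("annotate", "min_mean_per_individual"), 20))

    f_thr <- .cfg_get(cfg, c("annotate", "functional_threshold"))
    s_thr <- .cfg_get(cfg, c("annotate", "sd_threshold"))
    thresholds <- if (!is.null(f_thr) && !is.null(s_thr)) {
        list(functional_threshold = f_thr, sd_threshold = s_thr,
             derived = c(functional = FALSE, sd = FALSE))
    } else NULL
    cohort <- annotateSegments(
        cohort, thresholds = thresholds,
        min_individuals = .cfg_get(cfg, c("annotate", "min_individuals"),
                                   10L))

    report_dir <- file.path(out_dir, "report")
    thr_used <- rowData(cohort)$functional_threshold_used[1]
    band <- .cfg_get(cfg, c("annotate", "selection_band"), c(0.10, 0.90))
    files <- writeCohortReports(cohort, report_dir,
                                individual_stats = stats,
                                exclusions = attr(tables, "exclusions"),
                                functional_threshold = thr_used)
    invisible(list(cohort = cohort,
                   individual_stats = stats,
                   correlation = statusCorrelation(cohort, thr_used, band),
                   abundance_test = annotationAbundanceTest(cohort),
                   simulation = sim_out,
                   files = files))
}
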