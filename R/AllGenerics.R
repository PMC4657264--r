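#' @name accessors
#' @title Accessors for GermlineReference and SegmentCohort
#' @param x a [GermlineReference-class] or [SegmentCohort-class] object.
#' @param ... unused.
#' @description Small accessor generics so downstream code never touches
#'   slots or metadata columns directly.
NULL

#' @rdname accessors
#' @export
setGeneric("segmentNames", function(x, ...) standardGeneric("segmentNames"))

#' @rdname accessors
#' @export
setGeneric("anchorOffset", function(x, ...) standardGeneric("anchorOffset"))

#' @rdname accessors
#' @export
setGeneric("isFunctionalAllele",
           function(x, ...) standardGeneric("isFunctionalAllele"))

#' @rdname accessors
#' @export
setGeneric("rssWeight", function(x, ...) standardGeneric("rssWeight"))

#' @rdname accessors
#' @export
setGeneric("priorAnnotation",
           function(x, ...) standardGeneric("priorAnnotation"))

#' @rdname accessors
#' @export
setGeneric("vAlleles", function(x, ...) standardGeneric("vAlleles"))

#' @rdname accessors
#' @export
setGeneric("jAlleles", function(x, ...) standardGeneric("jAlleles"))

#' @rdname accessors
#' @export
setGeneric("productiveProportion",
           function(x, ...) standardGeneric("productiveProportion"))

#' @rdname accessors
#' @export
setGeneric("segmentStats", function(x, ...) standardGeneric("segmentStats"))

#' @rdname accessors
#' @export
setGeneric("annotationCalls",
           function(x, ...) standardGeneric("annotationCalls"))

#' @rdname accessors
#' @export
setGeneric("excludedSegments",
           function(x, ...) standardGeneric("excludedSegments"))

#' @rdname accessors
#' @export
setMethod("segmentNames", "GermlineReference",
          function(x, ...) unique(mcols(x)$segment))

#' @rdname accessors
#' @export
setMethod("anchorOffset", "GermlineReference",
          function(x, ...) setNames(mcols(x)$anchor_offset, names(x)))

#' @rdname accessors
#' @export
setMethod("isFunctionalAllele", "GermlineReference",
          function(x, ...) setNames(mcols(x)$functional, names(x)))

#' @rdname accessors
#' @export
setMethod("rssWeight", "GermlineReference",
          function(x, ...) setNames(mcols(x)$rss_weight, names(x)))

#' @rdname accessors
#' @export
setMethod("priorAnnotation", "GermlineReference",
          function(x, ...) setNames(mcols(x)$prior, names(x)))

#' @rdname accessors
#' @export
setMethod("vAlleles", "GermlineReference",
          function(x, ...) x[mcols(x)$kind == "V"])

#' @rdname accessors
#' @export
setMethod("jAlleles", "GermlineReference",
          function(x, ...) x[mcols(x)$kind == "J"])

#' @rdname accessors
#' @export
setMethod("segmentNames", "SegmentCohort", function(x, ...) rownames(x))

#' @rdname accessors
#' @export
setMethod("productiveProportion", "SegmentCohort",
          function(x, ...) assay(x, "proportion"))

#' @rdname accessors
#' @export
setMethod("segmentStats", "SegmentCohort", function(x, ...) {
    rd <- rowData(x)
    data.frame(segment = rownames(x),
               prior = rd$prior,
               total_rearrangements = rd$total_rearrangements,
               mean_per_individual = rd$mean_per_individual,
               mean_proportion = rd$mean_proportion,
               sd_proportion = rd$sd_proportion,
               n_individuals_observed = rd$n_individuals_observed,
               row.names = NULL)
})

#' @rdname accessors
#' @export
setMethod("annotationCalls", "SegmentCohort", function(x, ...) {
    rd <- rowData(x)
    if (!"call" %in% colnames(rd))
        stop("no annotation calls yet; run annotateSegments() first")
    data.frame(segment = rownames(x),
               call = rd$call,
               mean_proportion = rd$mean_proportion,
               sd_proportion = rd$sd_proportion,
               n_individuals_observed = rd$n_individuals_observed,
               functional_threshold_used = rd$functional_threshold_used,
               sd_threshold_used = rd$sd_threshold_used,
               prior = rd$prior,
               discrepant = rd$discrepant,
               row.names = NULL)
})

#' @rdname accessors
#' @export
setMethod("excludedSegments", "SegmentCohort", function(x, ...) {
    af <- metadata(x)$abundance_filter
    if (is.null(af)) character(0) else af$excluded$segment
})
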