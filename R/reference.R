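## Toy germline construction and FASTA round-trip.

.rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## 6-mers of one sequence
.kmers <- function(s, k = 6L) {
    L <- nchar(s)
    if (L < k) return(character(0))
    unique(substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L))
}

#' Build a toy germline V/J reference
#'
#' Generates a synthetic germline reference with valid anchor codons
#' (Cys TGT/TGC for V, Phe TTT/TTC for J) and guarantees that every segment
#' carries at least one 6-mer found in no other segment, so that error-free
#' reads are unambiguously assignable. Sequences are random and deliberately
#' not modelled on real germline genes. The bases flanking the anchors on the
#' CDR3 side are drawn from \{A, C, G\} so that germline-encoded CDR3 codons
#' aligned to the anchor frame cannot be stop codons; stop codons in
#' simulated junctions therefore arise from non-templated inserted bases, as
#' they mostly do at a real locus.
#'
#' @param n_v_segments number of V segments (>= 2).
#' @param n_j_segments number of J segments (>= 1).
#' @param fraction_pseudogenic fraction of V segments flagged non-functional
#'   (rounded to the nearest whole segment).
#' @param seed integer seed.
#' @param v_length,j_length allele lengths in nt. V alleles keep
#'   \code{v_tail} nt after the anchor codon; J alleles keep
#'   \code{j_lead} nt before theirs, which bounds how far junctional
#'   deletion can go without destroying an anchor.
#' @param v_tail,j_lead nt retained 3' of the V anchor / 5' of the J anchor.
#' @param rss_weights optional named numeric vector of per-segment
#'   rearrangement propensities (default 1 for every segment).
#' @param max_tries resampling attempts for the uniqueness constraint before
#'   failing with a sizing error.
#' @return a [GermlineReference-class] with one allele ("01") per segment.
#'   Pseudogenic V segments get prior annotation "P", functional ones "F".
#' @examples
#' ref <- buildToyReference(4, 2, fraction_pseudogenic = 0.5, seed = 1)
#' ref
#' @export
buildToyReference <- function(n_v_segments, n_j_segments,
                              fraction_pseudogenic = 0, seed = 1,
                              v_length = 45L, j_length = 30L,
                              v_tail = 6L, j_lead = 6L,
                              rss_weights = NULL, max_tries = 200L) {
    stopifnot(n_v_segments >= 2, n_j_segments >= 1,
              fraction_pseudogenic >= 0, fraction_pseudogenic <= 1)
    if (v_length < v_tail + 9L || j_length < j_lead + 3L)
        stop("segment lengths too short for anchors")
    set.seed(seed)
    no_t <- c("A", "C", "G")

    make_v <- function() {
        paste0(.rand_seq(v_length - v_tail - 3L),
               sample(V_ANCHORS, 1L),
               .rand_seq(v_tail, no_t))
    }
    make_j <- function() {
        paste0(.rand_seq(j_lead, no_t),
               sample(J_ANCHORS, 1L),
               .rand_seq(j_length - j_lead - 3L))
    }

    ## draw, then repair segments lacking a private 6-mer
    draw_unique <- function(n, maker) {
        seqs <- vapply(seq_len(n), function(i) maker(), character(1))
        for (try in seq_len(max_tries)) {
            km <- lapply(seqs, .kmers)
            all_counts <- table(unlist(km))
            has_private <- vapply(km, function(k) {
                any(all_counts[k] == 1L)
            }, logical(1))
            if (all(has_private)) return(seqs)
            idx <- which(!has_private)
            seqs[idx] <- vapply(idx, function(i) maker(), character(1))
        }
        stop("could not satisfy the unique 6-mer constraint; ",
             "use fewer or longer segments")
    }

    v_seqs <- draw_unique(n_v_segments, make_v)
    j_seqs <- draw_unique(n_j_segments, make_j)

    n_pseudo <- round(fraction_pseudogenic * n_v_segments)
    pseudo <- rep(FALSE, n_v_segments)
    if (n_pseudo > 0)
        pseudo[sample.int(n_v_segments, n_pseudo)] <- TRUE

    v_names <- sprintf("TRBV%02d", seq_len(n_v_segments))
    j_names <- sprintf("TRBJ%02d", seq_len(n_j_segments))
    segs <- c(v_names, j_names)
    rss <- rep(1, length(segs))
    names(rss) <- segs
    if (!is.null(rss_weights)) {
        bad <- setdiff(names(rss_weights), segs)
        if (length(bad) > 0)
            stop("unknown segments in rss_weights: ",
                 paste(bad, collapse = ", "))
        rss[names(rss_weights)] <- rss_weights
    }

    GermlineReference(
        sequences = c(v_seqs, j_seqs),
        segment = segs,
        kind = rep(c("V", "J"), c(n_v_segments, n_j_segments)),
        anchor_offset = c(rep(v_length - v_tail - 3L, n_v_segments),
                          rep(j_lead, n_j_segments)),
        functional = c(!pseudo, rep(TRUE, n_j_segments)),
        rss_weight = unname(rss),
        prior = c(ifelse(pseudo, "P", "F"), rep("F", n_j_segments)))
}

#' Read / write a germline reference as FASTA
#'
#' Headers are pipe-delimited:
#' \code{>TRBV05|01|V|anchor=36|func=T|rss=1.0|prior=F} with the anchor
#' offset 0-based.
#'
#' @param file path to a FASTA file.
#' @param x a [GermlineReference-class].
#' @return \code{readGermlineReference} returns a
#'   [GermlineReference-class]; \code{writeGermlineReference} returns the
#'   file path invisibly.
#' @export
readGermlineReference <- function(file) {
    dss <- readDNAStringSet(file)
    parts <- strsplit(names(dss), "|", fixed = TRUE)
    if (any(lengths(parts) != 7L))
        stop("malformed reference header; expected 7 pipe-delimited fields")
    field <- function(i) vapply(parts, `[[`, character(1), i)
    kv <- function(s, key) {
        if (!all(startsWith(s, paste0(key, "="))))
            stop("malformed reference header field: expected ", key, "=")
        sub(paste0("^", key, "="), "", s)
    }
    GermlineReference(
        sequences = unname(as.character(dss)),
        segment = field(1), allele = field(2), kind = field(3),
        anchor_offset = as.integer(kv(field(4), "anchor")),
        functional = kv(field(5), "func") == "T",
        rss_weight = as.numeric(kv(field(6), "rss")),
        prior = kv(field(7), "prior"))
}

#' @rdname readGermlineReference
#' @export
writeGermlineReference <- function(x, file) {
    stopifnot(is(x, "GermlineReference"))
    mc <- mcols(x)
    out <- DNAStringSet(as.character(x))
    names(out) <- sprintf("%s|%s|%s|anchor=%d|func=%s|rss=%s|prior=%s",
                          mc$segment, mc$allele, mc$kind, mc$anchor_offset,
                          ifelse(mc$functional, "T", "F"),
                          format(mc$rss_weight, trim = TRUE),
                          mc$prior)
    writeXStringSet(out, file)
    invisible(file)
}
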