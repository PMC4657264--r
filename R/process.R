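## Read processing: error collapsing, exact V/J matching, CDR3 extraction,
## productivity scoring.

.revstr <- function(x) {
    vapply(strsplit(x, NULL), function(ch) paste(rev(ch), collapse = ""),
           character(1))
}

## vectorized productivity over CDR3 spans (0-based half-open over `seqs`);
## NA spans give NA. Grouped by CDR3 length so codon checks stay vectorized.
.productive_span <- function(seqs, start0, end0) {
    n <- length(seqs)
    out <- rep(NA, n)
    ok <- !is.na(start0) & !is.na(end0) & start0 >= 0 & end0 <= nchar(seqs) &
        end0 > start0
    if (!any(ok)) return(out)
    cdr3 <- substring(seqs[ok], start0[ok] + 1L, end0[ok])
    len <- nchar(cdr3)
    res <- len %% 3L == 0L
    for (L in unique(len[res])) {
        idx <- which(res & len == L)
        for (j in seq_len(L %/% 3L)) {
            codon <- substring(cdr3[idx], 3L * j - 2L, 3L * j)
            res[idx[codon %in% STOP_CODONS]] <- FALSE
        }
    }
    out[ok] <- res
    out
}

#' Score a CDR3 span as productive
#'
#' A rearrangement is productive iff the CDR3 span (second conserved Cys of
#' the V segment through the conserved Phe of the J segment, both codons
#' included) has a length that is a multiple of three -- i.e. V and J are in
#' the same coding frame -- and contains no stop codon (TAA, TAG, TGA) in
#' the frame anchored at the Cys codon. Because both anchors are whole
#' codons and neither TGT/TGC nor TTT/TTC is a stop, including them changes
#' neither the frame test nor the stop test.
#'
#' @param read character vector of nucleotide sequences.
#' @param cdr3_start,cdr3_end 0-based half-open CDR3 span over \code{read};
#'   \code{NA} yields \code{NA}.
#' @return logical vector.
#' @examples
#' classifyProductive("TGTGCCTGATTC", 0, 12)  # in frame but TGA -> FALSE
#' @export
classifyProductive <- function(read, cdr3_start, cdr3_end) {
    .productive_span(read, cdr3_start, cdr3_end)
}

#' Collapse sequencing/PCR errors by nearest neighbour merging
#'
#' Greedy nearest-neighbour collapse: sequences are processed in descending
#' count (ties broken lexicographically); a sequence within Hamming distance
#' \code{max_distance} of an already-retained sequence of the same length
#' (necessarily of higher or equal count) is merged into the
#' earliest-processed such neighbour, adding its count. Total count is
#' conserved and the operation is idempotent.
#'
#' @param counts named integer vector: names are sequences, values counts.
#' @param max_distance maximal Hamming distance merged (default 1).
#' @return named integer vector of retained sequences, in processing order.
#' @examples
#' collapseErrors(c(AAAA = 100L, AAAT = 2L, AATT = 1L))
#' @export
collapseErrors <- function(counts, max_distance = 1L) {
    stopifnot(all(counts > 0), !is.null(names(counts)))
    if (anyDuplicated(names(counts)))
        stop("input sequences must be unique")
    if (length(counts) <= 1L) return(counts)
    ord <- order(-counts, names(counts))
    seqs <- names(counts)[ord]
    cnt <- as.integer(counts[ord])
    n <- length(seqs)
    if (max_distance == 1L) {
        neighbours <- .hamming1_neighbours(seqs)
    } else {
        neighbours <- .hamming_neighbours_brute(seqs, max_distance)
    }
    retained <- logical(n)
    target <- seq_len(n)
    for (j in seq_len(n)) {
        cand <- neighbours[[j]]
        cand <- cand[cand < j & retained[cand]]
        if (length(cand) > 0L) {
            target[j] <- min(cand)     # earliest retained = highest count
        } else {
            retained[j] <- TRUE
        }
    }
    out <- cnt
    for (j in which(!retained)) {
        out[target[j]] <- out[target[j]] + out[j]
    }
    out <- setNames(out[retained], seqs[retained])
    out[order(-out, names(out))]   # canonical order: merged count, name
}

## adjacency lists (indices into seqs) of same-length Hamming-1 neighbours,
## via position-masked keys: two equal-length sequences are at distance <= 1
## iff they share a key with one position wildcarded
.hamming1_neighbours <- function(seqs) {
    n <- length(seqs)
    len <- nchar(seqs)
    pieces <- list()
    k <- 0L
    for (L in unique(len)) {
        idx <- which(len == L)
        for (p in seq_len(L)) {
            k <- k + 1L
            masked <- seqs[idx]
            substr(masked, p, p) <- "*"
            pieces[[k]] <- setNames(masked, idx)
        }
    }
    all_keys <- unlist(pieces, use.names = TRUE)
    members <- as.integer(names(all_keys))
    dup <- all_keys %in% unique(all_keys[duplicated(all_keys)])
    neighbours <- vector("list", n)
    if (any(dup)) {
        groups <- split(members[dup], all_keys[dup])
        for (g in groups) {            # groups are tiny (<= 4 sequences)
            for (j in g) neighbours[[j]] <- c(neighbours[[j]],
                                              setdiff(g, j))
        }
    }
    lapply(neighbours, function(x) sort(unique(x)))
}

.hamming_dist <- function(a, b) {
    if (nchar(a) != nchar(b)) return(Inf)
    sum(strsplit(a, NULL)[[1]] != strsplit(b, NULL)[[1]])
}

.hamming_neighbours_brute <- function(seqs, max_distance) {
    n <- length(seqs)
    neighbours <- vector("list", n)
    for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
            if (.hamming_dist(seqs[i], seqs[j]) <= max_distance) {
                neighbours[[i]] <- c(neighbours[[i]], j)
                neighbours[[j]] <- c(neighbours[[j]], i)
            }
        }
    }
    neighbours
}

## ---- exact V/J matching -------------------------------------------------

## side = "V": longest exact match between a suffix of the germline V
## (allowing any number of 3' deletions) and the read's 5' region anchored
## at the read start, i.e. the longest read prefix occurring as a germline
## substring. side = "J" is the mirror image at the read's 3' end. Any
## qualifying match of length >= min_match fixes the read's first (last)
## min_match bases, so a seed lookup of that k-mer followed by extension is
## exact, not heuristic.
.match_side_cache <- function(reference, side, k) {
    mc <- mcols(reference)
    idx <- which(mc$kind == side)
    seqs <- as.character(reference)[idx]
    if (side == "J") seqs <- .revstr(seqs)
    index <- new.env(hash = TRUE, parent = emptyenv())
    for (a in seq_along(seqs)) {
        L <- nchar(seqs[a])
        if (L < k) next
        pos <- seq_len(L - k + 1L)
        kms <- substring(seqs[a], pos, pos + k - 1L)
        for (t in seq_along(kms)) {
            key <- kms[t]
            index[[key]] <- rbind(index[[key]], c(a, pos[t]))
        }
    }
    list(allele_idx = idx, allele = names(reference)[idx],
         segment = mc$segment[idx], seqs = seqs,
         chars = strsplit(seqs, NULL), width = nchar(seqs),
         anchor = mc$anchor_offset[idx], index = index, k = k)
}

## extend matches for a group of reads sharing seed hit (allele a, pos)
.extend_match <- function(reads, a, pos, cache) {
    k <- cache$k
    n <- length(reads)
    gch <- cache$chars[[a]]
    L <- cache$width[a]
    rl <- nchar(reads)
    alive <- rep(TRUE, n)
    len <- rep(k, n)
    j <- k + 1L
    while (any(alive) && pos + j - 1L <= L) {
        alive <- alive & j <= rl &
            substring(reads, j, j) == gch[pos + j - 1L]
        len[alive] <- j
        j <- j + 1L
    }
    len
}

.assign_side <- function(reads, cache, min_match) {
    n <- length(reads)
    res <- data.frame(call = rep("NONE", n),
                      match_len = rep(0L, n),
                      allele = rep(NA_character_, n),
                      germ_start = rep(NA_integer_, n),
                      stringsAsFactors = FALSE)
    k <- cache$k
    long_enough <- nchar(reads) >= k
    seeds <- rep(NA_character_, n)
    seeds[long_enough] <- substring(reads[long_enough], 1L, k)
    hits_r <- hits_a <- hits_p <- hits_l <- list()
    h <- 0L
    for (s in unique(seeds[!is.na(seeds)])) {
        tab <- cache$index[[s]]
        if (is.null(tab)) next
        grp <- which(seeds == s)
        for (r in seq_len(nrow(tab))) {
            a <- tab[r, 1L]
            pos <- tab[r, 2L]
            h <- h + 1L
            hits_r[[h]] <- grp
            hits_a[[h]] <- rep(a, length(grp))
            hits_p[[h]] <- rep(pos, length(grp))
            hits_l[[h]] <- .extend_match(reads[grp], a, pos, cache)
        }
    }
    if (h == 0L) return(res)
    ri <- unlist(hits_r)
    ai <- unlist(hits_a)
    pi <- unlist(hits_p)
    li <- unlist(hits_l)
    keep <- li >= min_match
    if (!any(keep)) return(res)
    ri <- ri[keep]; ai <- ai[keep]; pi <- pi[keep]; li <- li[keep]

    best <- tapply(li, ri, max)
    best_of <- setNames(as.integer(best), names(best))
    is_best <- li == best_of[as.character(ri)]
    ri_b <- ri[is_best]; ai_b <- ai[is_best]
    pi_b <- pi[is_best]; li_b <- li[is_best]
    seg_b <- cache$segment[ai_b]

    u <- !duplicated(paste(ri_b, seg_b, sep = "\r"))
    nseg <- table(ri_b[u])
    ambiguous <- as.integer(names(nseg)[nseg >= 2L])

    ## deterministic representative: largest germline offset (fewest
    ## deletions), then first allele
    ord <- order(ri_b, -pi_b, ai_b)
    first <- !duplicated(ri_b[ord])
    rep_rows <- ord[first]
    rr <- ri_b[rep_rows]
    res$call[rr] <- seg_b[rep_rows]
    res$match_len[rr] <- li_b[rep_rows]
    res$allele[rr] <- cache$allele[ai_b[rep_rows]]
    res$germ_start[rr] <- pi_b[rep_rows]
    res$call[ambiguous] <- "AMBIGUOUS"
    res$allele[ambiguous] <- NA_character_
    res$germ_start[ambiguous] <- NA_integer_
    res
}

#' Assign the V or J segment of reads by exact matching
#'
#' For V, the longest exact match between a suffix of a germline V sequence
#' (truncated by any number of 3' deletions) and the read's 5' region
#' anchored at the read start is sought; for J, the mirror image at the
#' read's 3' end. The segment with the strictly longest match of at least
#' \code{min_match} nt wins; if two or more distinct segments tie at the
#' maximum, the read is \code{AMBIGUOUS}; if the maximum falls below
#' \code{min_match} the call is \code{NONE}. Matching is exact -- errors are
#' expected to have been removed by [collapseErrors()] -- and ambiguous
#' reads are meant to be excluded downstream rather than rescued.
#'
#' @param read character vector of reads.
#' @param reference a [GermlineReference-class].
#' @param kind "V" or "J".
#' @param min_match minimum match length in nt (default 6).
#' @return data.frame with one row per read: \code{call} (segment name,
#'   "AMBIGUOUS" or "NONE"), \code{match_len}, \code{allele} (matched allele
#'   name) and \code{germ_start} (1-based germline offset of the match in
#'   V orientation, or in the reversed sequence for J).
#' @export
assignSegment <- function(read, reference, kind = c("V", "J"),
                          min_match = 6L) {
    kind <- match.arg(kind)
    stopifnot(is(reference, "GermlineReference"))
    if (sum(mcols(reference)$kind == kind) == 0L)
        stop("no candidate alleles of kind ", kind)
    cache <- .match_side_cache(reference, kind, k = min(6L, min_match))
    reads <- if (kind == "J") .revstr(read) else read
    .assign_side(reads, cache, min_match)
}

## CDR3 span from both side assignments; V germ offsets are in forward
## orientation, J offsets in reversed orientation (as .assign_side returns)
.cdr3_from_matches <- function(read_len, v_cache, v_allele, v_pos, v_len,
                               j_cache, j_allele, j_pos, j_len) {
    n <- length(read_len)
    start0 <- end0 <- rep(NA_integer_, n)
    va <- match(v_allele, v_cache$allele)
    ja <- match(j_allele, j_cache$allele)
    ok <- !is.na(va) & !is.na(ja)
    if (!any(ok)) return(list(start = start0, end = end0))
    i <- which(ok)
    av <- v_cache$anchor[va[i]]                 # 0-based
    ## V: read prefix of length v_len matches germline [v_pos, v_pos+v_len-1]
    cov_v <- v_pos[i] <= av + 1L & av + 3L <= v_pos[i] + v_len[i] - 1L
    s0 <- av + 1L - v_pos[i]                    # 0-based read position
    ## J: work in reversed coordinates; reversed anchor offset of the Phe
    ## codon start (0-based): wj - (aj + 3)
    wj <- j_cache$width[ja[i]]
    aj_rev <- wj - (j_cache$anchor[ja[i]] + 3L)
    cov_j <- j_pos[i] <= aj_rev + 1L & aj_rev + 3L <= j_pos[i] + j_len[i] - 1L
    ## reversed-read 0-based start of the (reversed) anchor codon
    s_rev <- aj_rev + 1L - j_pos[i]
    e0 <- read_len[i] - s_rev                   # half-open end, forward
    good <- cov_v & cov_j & s0 < e0
    start0[i[good]] <- s0[good]
    end0[i[good]] <- e0[good]
    list(start = start0, end = end0)
}

#' Extract the CDR3 span of a read
#'
#' Locates the CDR3: from the first base of the V segment's second conserved
#' Cys codon through the last base of the J segment's conserved Phe codon
#' (both anchor codons included), using the germline match frame. Undefined
#' (NA) when either anchor codon was deleted or is not covered by the
#' matched region.
#'
#' @param read character vector of reads.
#' @param v_allele,j_allele allele names (as in the reference) assigned to
#'   each read.
#' @param v_match_len,j_match_len exact match lengths from
#'   [assignSegment()].
#' @param reference a [GermlineReference-class].
#' @return data.frame with 0-based half-open \code{cdr3_start},
#'   \code{cdr3_end} (NA when undefined).
#' @export
extractCDR3 <- function(read, v_allele, j_allele, v_match_len, j_match_len,
                        reference) {
    stopifnot(is(reference, "GermlineReference"))
    v_cache <- .match_side_cache(reference, "V", k = 1L)
    j_cache <- .match_side_cache(reference, "J", k = 1L)
    n <- length(read)
    v_pos <- j_pos <- rep(NA_integer_, n)
    ## recover the germline offset of each match (largest offset = fewest
    ## deletions, matching the assignment's tie-break)
    find_pos <- function(query, germ) {
        m <- gregexpr(query, germ, fixed = TRUE)[[1]]
        if (m[1] == -1L) NA_integer_ else max(m)
    }
    for (i in seq_len(n)) {
        va <- match(v_allele[i], v_cache$allele)
        if (!is.na(va) && !is.na(v_match_len[i]) && v_match_len[i] > 0L)
            v_pos[i] <- find_pos(substring(read[i], 1L, v_match_len[i]),
                                 v_cache$seqs[va])
        ja <- match(j_allele[i], j_cache$allele)
        if (!is.na(ja) && !is.na(j_match_len[i]) && j_match_len[i] > 0L) {
            rrev <- .revstr(read[i])
            j_pos[i] <- find_pos(substring(rrev, 1L, j_match_len[i]),
                                 j_cache$seqs[ja])
        }
    }
    sp <- .cdr3_from_matches(nchar(read), v_cache, v_allele, v_pos,
                             v_match_len, j_cache, j_allele, j_pos,
                             j_match_len)
    data.frame(cdr3_start = sp$start, cdr3_end = sp$end)
}

#' Process one individual's rearrangement table
#'
#' Runs the full read-processing chain: nearest-neighbour error collapsing,
#' V and J assignment by exact matching, CDR3 extraction and productivity
#' scoring. Records without a concrete V and J call, or with an undefined
#' CDR3, keep \code{NA} productivity and are excluded from proportion
#' counting downstream (both numerator and denominator).
#'
#' @param x data.frame with columns \code{sequence} and \code{count}, or a
#'   named count vector.
#' @param reference a [GermlineReference-class].
#' @param min_match minimum exact match length (nt).
#' @param max_distance Hamming radius for collapsing; set collapse = FALSE
#'   to skip collapsing.
#' @param collapse logical.
#' @return AIRR-flavoured data.frame: \code{sequence}, \code{count},
#'   \code{v_call}, \code{j_call}, \code{cdr3_start}, \code{cdr3_end}
#'   (0-based half-open), \code{cdr3_length}, \code{productive}, plus an
#'   \code{exclusions} attribute counting dropped categories.
#' @export
processRearrangements <- function(x, reference, min_match = 6L,
                                  max_distance = 1L, collapse = TRUE) {
    if (is.data.frame(x)) {
        counts <- setNames(as.integer(x$count), x$sequence)
    } else counts <- x
    n_input <- length(counts)
    if (collapse && length(counts) > 1L)
        counts <- collapseErrors(counts, max_distance)
    seqs <- names(counts)

    v_cache <- .match_side_cache(reference, "V", k = min(6L, min_match))
    j_cache <- .match_side_cache(reference, "J", k = min(6L, min_match))
    av <- .assign_side(seqs, v_cache, min_match)
    aj <- .assign_side(.revstr(seqs), j_cache, min_match)

    concrete <- !(av$call %in% c("NONE", "AMBIGUOUS")) &
        !(aj$call %in% c("NONE", "AMBIGUOUS"))
    sp <- .cdr3_from_matches(nchar(seqs), v_cache,
                             ifelse(concrete, av$allele, NA),
                             av$germ_start, av$match_len,
                             j_cache,
                             ifelse(concrete, aj$allele, NA),
                             aj$germ_start, aj$match_len)
    productive <- .productive_span(seqs, sp$start, sp$end)
    out <- data.frame(sequence = seqs, count = as.integer(counts),
                      v_call = av$call, j_call = aj$call,
                      v_match_len = av$match_len,
                      j_match_len = aj$match_len,
                      cdr3_start = sp$start, cdr3_end = sp$end,
                      cdr3_length = sp$end - sp$start,
                      productive = productive,
                      stringsAsFactors = FALSE, row.names = NULL)
    attr(out, "exclusions") <- c(
        n_input = n_input, n_collapsed = n_input - length(counts),
        v_none = sum(av$call == "NONE"),
        v_ambiguous = sum(av$call == "AMBIGUOUS"),
        j_none = sum(aj$call == "NONE"),
        j_ambiguous = sum(aj$call == "AMBIGUOUS"),
        cdr3_undefined = sum(concrete & is.na(sp$start)),
        n_scored = sum(!is.na(productive)))
    out
}

#' Process a directory or list of per-individual tables
#'
#' @param x either a directory containing \code{individual_*.tsv} files
#'   (columns \code{sequence}, \code{count}), a named character vector of
#'   file paths, or a named list of data.frames.
#' @inheritParams processRearrangements
#' @return named list of processed tables (see [processRearrangements()]),
#'   with an \code{exclusions} attribute: one row of exclusion counts per
#'   individual.
#' @export
processCohort <- function(x, reference, min_match = 6L, max_distance = 1L,
                          collapse = TRUE) {
    if (is.character(x) && length(x) == 1L && dir.exists(x)) {
        files <- list.files(x, pattern = "^individual_.*\\.tsv$",
                            full.names = TRUE)
        ids <- sub("^individual_(.*)\\.tsv$", "\\1", basename(files))
        x <- setNames(as.list(files), ids)
    }
    if (is.character(x)) x <- as.list(x)
    out <- vector("list", length(x))
    names(out) <- names(x)
    excl <- vector("list", length(x))
    for (i in seq_along(x)) {
        tab <- x[[i]]
        if (is.character(tab))
            tab <- read.delim(tab, stringsAsFactors = FALSE,
                              colClasses = c("character", "integer"))
        out[[i]] <- processRearrangements(tab, reference,
                                          min_match = min_match,
                                          max_distance = max_distance,
                                          collapse = collapse)
        excl[[i]] <- attr(out[[i]], "exclusions")
    }
    excl <- as.data.frame(do.call(rbind, excl))
    excl <- cbind(individual = names(out), excl)
    rownames(excl) <- NULL
    attr(out, "exclusions") <- excl
    out
}
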