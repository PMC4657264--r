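## Shared fixtures and independent oracles, all built in code.

## A hand-crafted two-V / one-J reference with known anchors:
## V1 = ACGACGACG TGT ACCGCA   (anchor offset 9, 6-nt tail)
## V2 = GTCGTCGTC TGC AGGCAG
## J1 = ACCGGA TTC GCAGCAGCA   (anchor offset 6)
hand_reference <- function() {
    GermlineReference(
        sequences = c("ACGACGACGTGTACCGCA",
                      "GTCGTCGTCTGCAGGCAG",
                      "ACCGGATTCGCAGCAGCA"),
        segment = c("TRBV01", "TRBV02", "TRBJ01"),
        kind = c("V", "V", "J"),
        anchor_offset = c(9L, 9L, 6L),
        functional = c(TRUE, TRUE, TRUE))
}

## homozygous genotype across all V segments of a reference
homozygous_genotype <- function(reference) {
    mc <- S4Vectors::mcols(reference)
    v <- names(reference)[mc$kind == "V"]
    j <- names(reference)[mc$kind == "J"]
    list(v = cbind(v, v), j = cbind(j, j))
}

## Brute-force greedy collapse: same merging rule as collapseErrors but via
## all-pairs Hamming comparison, no hashing.
collapse_oracle <- function(counts, max_distance = 1L) {
    hamming <- function(a, b) {
        if (nchar(a) != nchar(b)) return(Inf)
        sum(strsplit(a, NULL)[[1]] != strsplit(b, NULL)[[1]])
    }
    ord <- order(-counts, names(counts))
    seqs <- names(counts)[ord]
    cnt <- as.integer(counts[ord])
    retained <- integer(0)
    for (j in seq_along(seqs)) {
        tgt <- NA_integer_
        for (r in retained) {
            if (hamming(seqs[r], seqs[j]) <= max_distance) {
                tgt <- r
                break            # earliest retained = highest count
            }
        }
        if (is.na(tgt)) retained <- c(retained, j)
        else cnt[tgt] <- cnt[tgt] + cnt[j]
    }
    out <- setNames(cnt[retained], seqs[retained])
    out[order(-out, names(out))]
}

## Translation oracle for productivity: translate the CDR3 span and demand
## a multiple-of-three length with no stop ('*') anywhere.
translation_oracle <- function(seqs, start0, end0) {
    vapply(seq_along(seqs), function(i) {
        if (is.na(start0[i]) || is.na(end0[i])) return(NA)
        cdr3 <- substring(seqs[i], start0[i] + 1L, end0[i])
        if (nchar(cdr3) %% 3L != 0L) return(FALSE)
        aa <- as.character(Biostrings::translate(
            Biostrings::DNAString(cdr3)))
        !grepl("*", aa, fixed = TRUE)
    }, logical(1))
}

random_dna <- function(n, len) {
    vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = ""), character(1))
}
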