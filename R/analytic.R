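## Closed-form productive rate of unselected junctions.

## stop probability of one codon whose three source characters are either
## fixed bases or "N" (uniform random); exact enumeration of the randoms
.codon_stop_prob <- function(chars) {
    rand <- chars == "N"
    if (!any(rand))
        return(as.numeric(paste(chars, collapse = "") %in% STOP_CODONS))
    bases <- c("A", "C", "G", "T")
    opts <- lapply(seq_along(chars),
                   function(i) if (rand[i]) bases else chars[i])
    grid <- expand.grid(opts, stringsAsFactors = FALSE)
    mean(paste0(grid[[1]], grid[[2]], grid[[3]]) %in% STOP_CODONS)
}

#' Analytic productive rate of unselected junctions
#'
#' Enumerates every (V allele, J allele, V deletion, J deletion, insertion
#' length) combination under the configured uniform junctional
#' distributions, weighting allele picks by RSS weight, and computes
#' exactly the probability that the resulting CDR3 is in frame, and in
#' frame with no stop codon (inserted bases are i.i.d. uniform, so the stop
#' probability of each codon factorizes over codons). This is the analytic
#' counterpart of [simulateJunctions()]: without selection the productive
#' rate equals P(in frame) * P(no stop | in frame), slightly below 1/3
#' times a no-stop factor -- the arithmetic behind the "< 1/3" signature of
#' pseudogenic segments.
#'
#' @inheritParams simulateCells
#' @return list: \code{p_productive}, \code{p_inframe},
#'   \code{p_nostop_given_inframe}.
#' @export
unselectedProductiveRate <- function(reference,
                                     config = simulationConfig()) {
    cache <- .ref_cache(reference)
    v_idx <- which(cache$kind == "V")
    j_idx <- which(cache$kind == "J")
    wv <- cache$rss[v_idx]; wv <- wv / sum(wv)
    wj <- cache$rss[j_idx]; wj <- wj / sum(wj)
    p_inframe <- 0
    p_prod <- 0
    for (a in seq_along(v_idx)) {
        if (wv[a] == 0) next
        va <- v_idx[a]
        avo <- cache$anchor[va]
        vw <- cache$width[va]
        v_cdr3_full <- substring(cache$seq[va], avo + 1L, vw)
        max_dv <- min(config$max_v_deletion, vw - (avo + 3L))
        for (b in seq_along(j_idx)) {
            if (wj[b] == 0) next
            jb <- j_idx[b]
            ajo <- cache$anchor[jb]
            j_cdr3_full <- substring(cache$seq[jb], 1L, ajo + 3L)
            max_dj <- min(config$max_j_deletion, ajo)
            w_ab <- wv[a] * wj[b]
            for (dv in 0:max_dv) {
                vpart <- substring(v_cdr3_full, 1L,
                                   nchar(v_cdr3_full) - dv)
                for (dj in 0:max_dj) {
                    jpart <- substring(j_cdr3_full, dj + 1L)
                    for (m in 0:config$max_n_insertion) {
                        w <- w_ab / ((max_dv + 1) * (max_dj + 1) *
                                     (config$max_n_insertion + 1))
                        len <- nchar(vpart) + m + nchar(jpart)
                        if (len %% 3L != 0L) next
                        p_inframe <- p_inframe + w
                        chars <- c(strsplit(vpart, NULL)[[1]],
                                   rep("N", m),
                                   strsplit(jpart, NULL)[[1]])
                        p_ns <- 1
                        for (cd in seq_len(len %/% 3L)) {
                            p_stop <- .codon_stop_prob(
                                chars[(3L * cd - 2L):(3L * cd)])
                            p_ns <- p_ns * (1 - p_stop)
                            if (p_ns == 0) break
                        }
                        p_prod <- p_prod + w * p_ns
                    }
                }
            }
        }
    }
    list(p_productive = p_prod, p_inframe = p_inframe,
         p_nostop_given_inframe = if (p_inframe > 0) p_prod / p_inframe
                                  else NA_real_)
}
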