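#' @include synthcohort.R
NULL

#' Length-normalize a count vector
#'
#' Divides each gene's read count by its coding-sequence length and scales
#' by a library-size factor. With \code{libFactor = 1} the rate is simply
#' count / length; [callUpregulated()] uses a counts-per-million-like
#' factor computed from the per-sample total of length-normalized counts.
#'
#' @param counts named non-negative numeric vector of read counts.
#' @param lengths named positive numeric vector of coding-sequence lengths;
#'   must cover every counted gene.
#' @param libFactor multiplicative library-size factor.
#' @return named numeric vector of expression rates.
#' @export
lengthNormalize <- function(counts, lengths, libFactor = 1) {
    missing <- setdiff(names(counts), names(lengths))
    if (length(missing))
        stop(sprintf("missing coding-sequence length for %d gene(s): %s",
                     length(missing),
                     paste(utils::head(missing, 5L), collapse = ", ")))
    len <- lengths[names(counts)]
    if (any(len <= 0)) stop("coding-sequence lengths must be positive")
    counts / len * libFactor
}

#' Per-gene log differential expression of a tumor/control pair
#'
#' \code{log2((tumor + pseudocount) / (control + pseudocount))}, computed on
#' length-normalized rates. Antisymmetric under swapping tumor and control.
#'
#' @param tumorRates,controlRates named rate vectors over the same genes.
#' @param pseudocount positive stabilizer added to both rates.
#' @return named numeric vector of log2 differentials.
#' @export
logDifferential <- function(tumorRates, controlRates, pseudocount = 0.5) {
    if (pseudocount <= 0) stop("'pseudocount' must be positive")
    if (!setequal(names(tumorRates), names(controlRates)))
        stop("tumor and control must cover the same genes")
    ctl <- controlRates[names(tumorRates)]
    log2((tumorRates + pseudocount) / (ctl + pseudocount))
}

#' Critical upregulation threshold of a log-differential distribution
#'
#' Default ("normal") rule: mean + z(1 - alpha) * sd of the per-pair
#' log-differential values, i.e. the upper-tail normal critical value at
#' significance \code{alpha}. The "quantile" rule uses the empirical
#' (1 - alpha) quantile instead. A degenerate (zero-variance) input under
#' the parametric rule falls back to the empirical quantile with a warning.
#'
#' @param values numeric log differentials (at least 30 finite values).
#' @param alpha upper-tail significance level in (0, 1).
#' @param rule \code{"normal"} (parametric, default) or \code{"quantile"}.
#' @return a single numeric threshold.
#' @export
criticalThreshold <- function(values, alpha = 0.025,
                              rule = c("normal", "quantile")) {
    rule <- match.arg(rule)
    stopifnot(alpha > 0, alpha < 1)
    v <- values[is.finite(values)]
    if (length(v) < 30L)
        stop("need at least 30 finite log-differential values")
    if (rule == "normal") {
        s <- stats::sd(v)
        if (s == 0) {
            warning("zero-variance log differentials; ",
                    "falling back to the empirical quantile rule")
            return(unname(stats::quantile(v, 1 - alpha)))
        }
        return(mean(v) + stats::qnorm(1 - alpha) * s)
    }
    unname(stats::quantile(v, 1 - alpha))
}

#' Call upregulated genes for one tumor/control pair
#'
#' Length-normalizes both count vectors (counts-per-million-like scaling),
#' computes the per-gene log2 differential, derives the pair's critical
#' threshold at level \code{alpha}, and calls upregulated exactly the genes
#' whose log differential strictly exceeds the threshold.
#'
#' @param tumorCounts,controlCounts named count vectors over the same genes.
#' @param lengths named coding-sequence lengths covering those genes.
#' @param alpha upper-tail significance level (default 0.025).
#' @param pseudocount positive stabilizer for the log ratio.
#' @param rule threshold rule, see [criticalThreshold()].
#' @param universe optional character vector (e.g. the interactome's
#'   genes); genes outside it are dropped before calling, with a message
#'   reporting how many.
#' @param pairId identifier recorded in the result.
#' @return list with \code{pairId}, \code{values} (named log
#'   differentials), \code{threshold} and \code{upregulated} (character).
#' @export
callUpregulated <- function(tumorCounts, controlCounts, lengths,
                            alpha = 0.025, pseudocount = 0.5,
                            rule = c("normal", "quantile"),
                            universe = NULL, pairId = "pair") {
    rule <- match.arg(rule)
    if (!setequal(names(tumorCounts), names(controlCounts)))
        stop("tumor and control must cover the same genes")
    if (!is.null(universe)) {
        keep <- names(tumorCounts) %in% universe
        if (any(!keep))
            message(sprintf("%s: dropped %d gene(s) outside the universe",
                            pairId, sum(!keep)))
        tumorCounts <- tumorCounts[keep]
        controlCounts <- controlCounts[names(tumorCounts)]
    }
    cpmLike <- function(counts) {
        raw <- lengthNormalize(counts, lengths)
        tot <- sum(raw)
        if (tot == 0) raw else raw / tot * 1e6
    }
    values <- logDifferential(cpmLike(tumorCounts),
                              cpmLike(controlCounts[names(tumorCounts)]),
                              pseudocount = pseudocount)
    threshold <- criticalThreshold(values, alpha = alpha, rule = rule)
    list(pairId = pairId, values = values, threshold = threshold,
         upregulated = names(values)[values > threshold])
}

#' Write per-pair upregulation calls as TSV
#'
#' @param calls a list of results from [callUpregulated()].
#' @param file path to a TSV file (columns: pair_id, gene, log_diff,
#'   threshold, upregulated).
#' @export
writeCalls <- function(calls, file) {
    rows <- lapply(calls, function(cl) {
        data.frame(pair_id = cl$pairId, gene = names(cl$values),
                   log_diff = unname(cl$values),
                   threshold = cl$threshold,
                   upregulated = names(cl$values) %in% cl$upregulated)
    })
    utils::write.table(do.call(rbind, rows), file, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(file)
}
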