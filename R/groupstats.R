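#' @include score.R
NULL

#' Connection-count observations of upregulated genes
#'
#' Builds the observation table for the nonparametric cross-type
#' comparisons: one row per upregulated-gene occurrence (default, one per
#' sample in which the gene is upregulated) or one per distinct gene per
#' cancer type, carrying the gene's connection number. When pathways are
#' given, observations are replicated into every pathway the gene belongs
#' to.
#'
#' @param cohort a [SampleCohort-class].
#' @param connections an [Interactome-class] or named degree vector.
#' @param pathways optional named list of pathway gene sets.
#' @param perOccurrence logical; \code{FALSE} collapses to one observation
#'   per distinct (cancer type, gene).
#' @return data.frame with columns \code{pathway} (or \code{"all"}),
#'   \code{cancer_type}, \code{gene}, \code{connections}.
#' @export
connectionObservations <- function(cohort, connections, pathways = NULL,
                                   perOccurrence = TRUE) {
    deg <- if (methods::is(connections, "Interactome"))
        geneDegree(connections)
    else unlist(connections)
    s <- sampleInfo(cohort)
    ups <- cohort@upregulated[s$sample_id]
    obs <- data.frame(cancer_type = rep(as.character(s$cancer_type),
                                        lengths(ups)),
                      gene = unlist(ups, use.names = FALSE))
    obs <- obs[obs$gene %in% names(deg), , drop = FALSE]
    if (!perOccurrence) obs <- unique(obs)
    if (is.null(pathways)) {
        obs$pathway <- "all"
    } else {
        memb <- data.frame(
            pathway = rep(names(pathways), lengths(pathways)),
            gene = unlist(pathways, use.names = FALSE))
        obs <- merge(obs, memb, by = "gene")
    }
    obs$connections <- as.numeric(deg[obs$gene])
    obs[, c("pathway", "cancer_type", "gene", "connections")]
}

#' Kruskal-Wallis comparison of connection counts per pathway
#'
#' For every pathway, tests whether the connection-count distributions of
#' upregulated genes differ among cancer types (tie-corrected H statistic,
#' chi-squared p-value with k - 1 degrees of freedom). Pathways with fewer
#' than two groups of at least two observations are flagged and receive no
#' p-value.
#'
#' @param obs observation table from [connectionObservations()].
#' @return data.frame with columns \code{pathway}, \code{statistic},
#'   \code{df}, \code{p_value}, \code{n_groups}, \code{n_obs},
#'   \code{flagged}.
#' @export
kruskalByPathway <- function(obs) {
    out <- lapply(split(obs, obs$pathway), function(d) {
        sz <- table(d$cancer_type)
        ok <- sum(sz >= 2L) >= 2L
        if (!ok)
            return(data.frame(pathway = d$pathway[1L],
                              statistic = NA_real_, df = NA_integer_,
                              p_value = NA_real_,
                              n_groups = length(sz), n_obs = nrow(d),
                              flagged = TRUE))
        kt <- stats::kruskal.test(d$connections,
                                  factor(d$cancer_type))
        data.frame(pathway = d$pathway[1L],
                   statistic = unname(kt$statistic),
                   df = as.integer(kt$parameter),
                   p_value = kt$p.value,
                   n_groups = length(sz), n_obs = nrow(d),
                   flagged = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Pairwise Wilcoxon rank-sum comparisons with Bonferroni correction
#'
#' Rank-sum test for every unordered pair of cancer types within each
#' pathway. The Bonferroni multiplier is the number of pairs actually
#' tested within that pathway; adjusted p-values are capped at 1.
#'
#' @param obs observation table from [connectionObservations()].
#' @param correction currently \code{"bonferroni"} (hook for alternatives
#'   accepted by [stats::p.adjust()]).
#' @return data.frame with columns \code{pathway}, \code{group_a},
#'   \code{group_b}, \code{raw_p}, \code{adj_p}, \code{n_comparisons}.
#' @export
pairwiseWilcoxon <- function(obs, correction = "bonferroni") {
    out <- lapply(split(obs, obs$pathway), function(d) {
        types <- sort(unique(d$cancer_type))
        if (length(types) < 2L) return(NULL)
        pairs <- utils::combn(types, 2L)
        raw <- apply(pairs, 2L, function(p) {
            a <- d$connections[d$cancer_type == p[1L]]
            b <- d$connections[d$cancer_type == p[2L]]
            if (length(a) < 2L || length(b) < 2L) return(NA_real_)
            suppressWarnings(stats::wilcox.test(a, b)$p.value)
        })
        nComp <- sum(!is.na(raw))
        adj <- if (identical(correction, "bonferroni"))
            pmin(1, raw * nComp)
        else stats::p.adjust(raw, method = correction)
        data.frame(pathway = d$pathway[1L], group_a = pairs[1L, ],
                   group_b = pairs[2L, ], raw_p = raw, adj_p = adj,
                   n_comparisons = nComp)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
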