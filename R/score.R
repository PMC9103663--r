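#' @include upcall.R
NULL

#' Restrict a cohort to signaling-pathway genes
#'
#' Intersects every sample's upregulated set with the union of the pathway
#' gene lists and summarizes how the retained genes distribute over the H
#' and L classes (shared, H-only, L-only).
#'
#' @param cohort a [SampleCohort-class].
#' @param pathways named list of character vectors (pathway -> genes).
#' @return list with \code{cohort} (filtered [SampleCohort-class]) and
#'   \code{summary}: \code{total}, \code{shared}, \code{hOnly},
#'   \code{lOnly} gene counts plus \code{unionSize} (pathway union size).
#'   \code{shared + hOnly + lOnly == total} always.
#' @export
filterToPathways <- function(cohort, pathways) {
    union <- unique(unlist(pathways, use.names = FALSE))
    if (!length(union)) stop("empty pathway union")
    if (!nSamples(cohort)) stop("empty cohort")
    ups <- lapply(cohort@upregulated, intersect, y = union)
    filtered <- SampleCohort(sampleInfo(cohort), ups)
    s <- sampleInfo(filtered)
    inClass <- function(cl)
        unique(unlist(ups[s$sample_id[s$class == cl]], use.names = FALSE))
    hGenes <- inClass("H"); lGenes <- inClass("L")
    shared <- intersect(hGenes, lGenes)
    summary <- list(total = length(union(hGenes, lGenes)),
                    inH = length(hGenes), inL = length(lGenes),
                    shared = length(shared),
                    hOnly = length(setdiff(hGenes, lGenes)),
                    lOnly = length(setdiff(lGenes, hGenes)),
                    unionSize = length(union))
    list(cohort = filtered, summary = summary)
}

#' Per-gene normalized counts by class or cancer type
#'
#' For each gene and group, the number of samples of the group in which the
#' gene is upregulated divided by the group size. A gene never observed in
#' a group receives a normalized count of zero (null imputation), so the
#' output is a dense gene x group grid over all genes observed anywhere in
#' the cohort.
#'
#' @param cohort a [SampleCohort-class].
#' @param groupBy \code{"class"} (H/L, default) or \code{"cancer_type"}.
#' @return data.frame with columns \code{gene}, \code{group}, \code{n},
#'   \code{group_size}, \code{norm_count}.
#' @examples
#' ## a gene upregulated in 1 of 125 H samples has normalized count 0.008
#' @export
classNormCounts <- function(cohort, groupBy = c("class", "cancer_type")) {
    groupBy <- match.arg(groupBy)
    s <- sampleInfo(cohort)
    grp <- as.character(s[[groupBy]])
    if (anyNA(grp) || any(!nzchar(grp)))
        stop("profile with unknown group label")
    ups <- cohort@upregulated[s$sample_id]
    long <- data.frame(
        group = rep(grp, lengths(ups)),
        gene = unlist(ups, use.names = FALSE))
    genes <- sort(unique(long$gene))
    groups <- sort(unique(grp))
    sizes <- table(factor(grp, levels = groups))
    cnt <- table(factor(long$gene, levels = genes),
                 factor(long$group, levels = groups))
    out <- data.frame(
        gene = rep(genes, times = length(groups)),
        group = rep(groups, each = length(genes)),
        n = as.integer(cnt),
        group_size = rep(as.integer(sizes), each = length(genes)))
    out$norm_count <- out$n / out$group_size
    rownames(out) <- NULL
    out
}

#' Attach connection numbers and compute normalized connections
#'
#' Multiplies each (gene, group) normalized count by the gene's connection
#' number in the full interactome: \code{norm_connections = norm_count *
#' degree}, the combined frequency-connectivity PPI score. Genes absent
#' from the interactome are excluded with a warning reporting the count.
#'
#' @param stats output of [classNormCounts()].
#' @param connections an [Interactome-class], or a named numeric vector of
#'   per-gene connection numbers (as tabulated interactome releases
#'   provide).
#' @return the stats data.frame with added \code{degree} and
#'   \code{norm_connections} columns.
#' @export
normConnections <- function(stats, connections) {
    deg <- if (methods::is(connections, "Interactome"))
        geneDegree(connections)
    else unlist(connections)
    if (is.null(names(deg))) stop("'connections' must be named by gene")
    missing <- setdiff(unique(stats$gene), names(deg))
    if (length(missing)) {
        warning(sprintf(
            "%d gene(s) absent from the interactome were excluded: %s",
            length(missing),
            paste(utils::head(missing, 5L), collapse = ", ")))
        stats <- stats[!stats$gene %in% missing, , drop = FALSE]
    }
    stats$degree <- as.numeric(deg[stats$gene])
    stats$norm_connections <- stats$norm_count * stats$degree
    rownames(stats) <- NULL
    stats
}

.splitClasses <- function(stats) {
    if (!all(c("H", "L") %in% stats$group))
        stop("stats must contain both classes H and L")
    list(H = stats[stats$group == "H", , drop = FALSE],
         L = stats[stats$group == "L", , drop = FALSE])
}

#' Variance filter with class-exclusive gene handling
#'
#' Selects the genes whose cross-class variance of the chosen quantity
#' strictly exceeds \code{threshold}, plus every gene upregulated in
#' exactly one class (class-exclusive genes are always retained, as they
#' may be decisive severity indicators). Variance is the unbiased sample
#' variance over the two class values, \code{(x_H - x_L)^2 / 2}.
#'
#' @param stats class-grouped stats from [classNormCounts()] (optionally
#'   through [normConnections()] when filtering on connection-weighted
#'   values).
#' @param threshold strict lower variance bound (default 0.005).
#' @param on quantity whose variance is filtered: \code{"norm_count"}
#'   (default) or \code{"norm_connections"}.
#' @return list with \code{genes} (selected character vector),
#'   \code{detail} (per-gene data.frame: values, variance, status) and
#'   \code{summary} (counts of both-class-selected, H-only, L-only genes).
#' @export
varianceFilter <- function(stats, threshold = 0.005,
                           on = c("norm_count", "norm_connections")) {
    on <- match.arg(on)
    if (!on %in% names(stats))
        stop(sprintf("stats lack a '%s' column", on))
    cl <- .splitClasses(stats)
    genes <- sort(unique(stats$gene))
    xH <- stats::setNames(cl$H[[on]], cl$H$gene)[genes]
    xL <- stats::setNames(cl$L[[on]], cl$L$gene)[genes]
    nH <- stats::setNames(cl$H$n, cl$H$gene)[genes]
    nL <- stats::setNames(cl$L$n, cl$L$gene)[genes]
    presentH <- !is.na(nH) & nH > 0
    presentL <- !is.na(nL) & nL > 0
    xH[is.na(xH)] <- 0; xL[is.na(xL)] <- 0
    variance <- (xH - xL)^2 / 2
    status <- ifelse(presentH & presentL, "both",
                     ifelse(presentH, "H-only",
                            ifelse(presentL, "L-only", "absent")))
    selected <- (status == "both" & variance > threshold) |
        status %in% c("H-only", "L-only")
    detail <- data.frame(gene = genes, value_H = unname(xH),
                         value_L = unname(xL),
                         variance = unname(variance), status = status,
                         selected = unname(selected))
    list(genes = genes[selected], detail = detail,
         summary = list(bothSelected = sum(selected & status == "both"),
                        hOnly = sum(status == "H-only"),
                        lOnly = sum(status == "L-only")))
}

#' @describeIn HubBoundary-class the qualifying exclusive-hub genes.
#' @export
setMethod("boundaryGenes", "HubBoundary", function(x, ...) x@genes)

setMethod("show", "HubBoundary", function(object) {
    cat(sprintf(paste0(
        "HubBoundary: %d exclusive H hub(s) at norm_connections >= %s ",
        "and norm_count >= %s\n"),
        length(object@genes),
        format(object@connThreshold), format(object@freqThreshold)))
})

#' Search for the exclusive hub boundary
#'
#' Grid search over all observed (normalized connections, normalized count)
#' value pairs of the H class for the inclusive boundary (c*, f*) that
#' maximizes the number of H-class genes with \code{norm_connections >= c*}
#' and \code{norm_count >= f*} subject to no L-class gene satisfying both
#' conditions — the region of hubs exclusive to the aggressive class. Ties
#' are broken in favor of larger c*, then larger f*; the reported
#' thresholds are tightened to the minima over the qualifying genes.
#'
#' @param stats class-grouped stats with \code{norm_connections} (from
#'   [normConnections()]); only genes with \code{n > 0} in a class count as
#'   present in it.
#' @return a [HubBoundary-class]; when no exclusive boundary exists, an
#'   empty gene list with objective 0 and \code{NA} thresholds.
#' @export
hubBoundarySearch <- function(stats) {
    cl <- .splitClasses(stats)
    H <- cl$H[cl$H$n > 0, , drop = FALSE]
    L <- cl$L[cl$L$n > 0, , drop = FALSE]
    if (!nrow(H))
        return(methods::new("HubBoundary", connThreshold = NA_real_,
                            freqThreshold = NA_real_, genes = character(),
                            objective = 0))
    ncH <- H$norm_connections; fH <- H$norm_count
    ncL <- L$norm_connections; fL <- L$norm_count
    best <- list(count = 0L, c = NA_real_, f = NA_real_,
                 genes = character())
    for (c0 in sort(unique(ncH))) {
        inL <- ncL >= c0
        lMax <- if (any(inL)) max(fL[inL]) else -Inf
        feasible <- sort(unique(fH[fH > lMax]))
        if (!length(feasible)) next
        f0 <- feasible[1L]
        qual <- ncH >= c0 & fH >= f0
        count <- sum(qual)
        if (!count) next
        cTight <- min(ncH[qual]); fTight <- min(fH[qual])
        better <- count > best$count ||
            (count == best$count &&
             (cTight > best$c ||
              (cTight == best$c && fTight > best$f)))
        if (better)
            best <- list(count = count, c = cTight, f = fTight,
                         genes = sort(H$gene[qual]))
    }
    methods::new("HubBoundary", connThreshold = best$c,
                 freqThreshold = best$f, genes = best$genes,
                 objective = as.numeric(best$count))
}

#' Class score totals over a gene list
#'
#' Sums the normalized connections of the listed genes within each class
#' (zero where a gene is absent from a class) and reports the H-relative
#' difference in percent, \code{(H - L) / H * 100}.
#'
#' @param stats class-grouped stats with \code{norm_connections}.
#' @param genes character vector of genes to total.
#' @return list with \code{totals} (named numeric, H and L) and
#'   \code{relativeDifference} (percent; \code{NA} for an empty list).
#' @export
classScore <- function(stats, genes) {
    cl <- .splitClasses(stats)
    tot <- function(d) {
        v <- stats::setNames(d$norm_connections, d$gene)[genes]
        sum(v, na.rm = TRUE)
    }
    totals <- c(H = tot(cl$H), L = tot(cl$L))
    rel <- if (length(genes) && totals[["H"]] != 0)
        (totals[["H"]] - totals[["L"]]) / totals[["H"]] * 100
    else NA_real_
    list(totals = totals, relativeDifference = rel)
}

#' Write a gene-group statistics table as TSV
#'
#' @param stats data.frame from [classNormCounts()] / [normConnections()].
#' @param file path to a TSV file.
#' @export
writeStats <- function(stats, file) {
    utils::write.table(stats, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}
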