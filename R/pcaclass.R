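#' @include groupstats.R
NULL

#' Build the cancer-type x gene normalized-connection matrix
#'
#' Dense feature matrix for ordination: one row per cancer type, one
#' column per selected gene, cell = the gene's normalized connections in
#' that type (zero where the gene was never upregulated there).
#'
#' @param stats cancer-type-grouped stats with \code{norm_connections}
#'   (from [classNormCounts()] with \code{groupBy = "cancer_type"} through
#'   [normConnections()]).
#' @param genes character vector of selected genes (column set, order
#'   preserved).
#' @param classOf optional named character vector mapping cancer type to
#'   class (H/L); attached as the \code{"class"} attribute, aligned to the
#'   rows.
#' @return numeric matrix with cancer types as rownames and genes as
#'   colnames.
#' @export
buildFeatureMatrix <- function(stats, genes, classOf = NULL) {
    if (!length(genes)) stop("empty gene selection")
    if (!"norm_connections" %in% names(stats))
        stop("stats lack a 'norm_connections' column; run normConnections()")
    types <- sort(unique(stats$group))
    m <- matrix(0, nrow = length(types), ncol = length(genes),
                dimnames = list(types, genes))
    d <- stats[stats$gene %in% genes, , drop = FALSE]
    m[cbind(match(d$group, types), match(d$gene, genes))] <-
        d$norm_connections
    if (!is.null(classOf))
        attr(m, "class_label") <- stats::setNames(
            as.character(classOf[types]), types)
    m
}

#' Principal component analysis of a feature matrix
#'
#' Singular value decomposition of the (column-centered, optionally
#' scaled) matrix. For reproducibility the sign of each component is fixed
#' so that its largest-magnitude loading is positive. Variance proportions
#' are the squared singular-value shares.
#'
#' @param mat numeric matrix (rows = cancer types, columns = genes), at
#'   least 2 x 2.
#' @param center,scale passed to [stats::prcomp()] (centering on and
#'   scaling off by default).
#' @return a [PCADecomposition-class].
#' @export
runPCA <- function(mat, center = TRUE, scale = FALSE) {
    if (nrow(mat) < 2L || ncol(mat) < 2L)
        stop("need at least 2 rows and 2 columns")
    p <- stats::prcomp(mat, center = center, scale. = scale)
    totVar <- sum(p$sdev^2)
    if (totVar == 0)
        warning("constant matrix: zero variance, proportions undefined")
    for (k in seq_along(p$sdev)) {
        j <- which.max(abs(p$rotation[, k]))
        if (p$rotation[j, k] < 0) {
            p$rotation[, k] <- -p$rotation[, k]
            p$x[, k] <- -p$x[, k]
        }
    }
    prop <- if (totVar > 0) p$sdev^2 / totVar else rep(0, length(p$sdev))
    ctr <- if (isFALSE(p$center)) rep(0, ncol(mat)) else p$center
    cls <- attr(mat, "class_label")
    methods::new("PCADecomposition", sdev = p$sdev, rotation = p$rotation,
                 x = p$x, proportions = prop, cumulative = cumsum(prop),
                 center = ctr,
                 rowClass = if (is.null(cls)) character() else cls)
}

#' @describeIn PCADecomposition-class per-component variance proportions.
#' @export
setMethod("varianceProportions", "PCADecomposition",
          function(x, ...) x@proportions)

#' @describeIn PCADecomposition-class the gene x component loading matrix.
#' @export
setMethod("pcaLoadings", "PCADecomposition", function(x, ...) x@rotation)

#' @describeIn PCADecomposition-class row (cancer type) coordinates.
#' @export
setMethod("sampleCoordinates", "PCADecomposition", function(x, ...) x@x)

setMethod("show", "PCADecomposition", function(object) {
    k <- min(3L, length(object@sdev))
    cat(sprintf("PCADecomposition: %d components over %d genes\n",
                length(object@sdev), nrow(object@rotation)))
    cat("  proportion of variance:",
        paste(sprintf("PC%d %.3f", seq_len(k), object@proportions[seq_len(k)]),
              collapse = ", "),
        sprintf("(cumulative %.3f)\n", object@cumulative[k]))
})

#' Per-gene contributions to the principal components
#'
#' A gene's contribution to a component is its squared-loading share,
#' \code{100 * loading^2 / sum(loading^2)}, in percent (contributions sum
#' to 100 within each component). Its share of the total variance is the
#' contribution-weighted sum of the component variance proportions over
#' the retained components: a gene carrying 50\% of a component that holds
#' 70\% of the variance carries 35\% of the total. The captured-variance
#' share rescales by the cumulative proportion of the retained components.
#'
#' @param pca a [PCADecomposition-class].
#' @param retained number of leading components summarized (default 3).
#' @return data.frame, one row per gene: contribution columns
#'   \code{PC1..PCk}, \code{pct_total_variance},
#'   \code{pct_captured_variance}; sorted by decreasing total-variance
#'   share.
#' @export
geneContributions <- function(pca, retained = 3L) {
    retained <- as.integer(retained)
    if (retained < 1L) stop("'retained' must be at least 1")
    if (retained > length(pca@sdev))
        stop("'retained' exceeds the number of components")
    rot <- pca@rotation[, seq_len(retained), drop = FALSE]
    contrib <- 100 * sweep(rot^2, 2L, colSums(rot^2), "/")
    prop <- pca@proportions[seq_len(retained)]
    totShare <- as.numeric(contrib %*% prop)
    captShare <- totShare / pca@cumulative[retained]
    out <- data.frame(gene = rownames(rot), contrib,
                      pct_total_variance = totShare,
                      pct_captured_variance = captShare,
                      row.names = NULL, check.names = FALSE)
    out[order(-out$pct_total_variance, out$gene), , drop = FALSE]
}

#' Hierarchical clustering of cancer types
#'
#' Agglomerates the cancer-type rows of the feature matrix (default) or of
#' the retained principal-component coordinates, using manhattan distance
#' and complete linkage by default, and reports whether cutting the tree
#' into two branches separates the H and L classes exactly.
#'
#' @param x a feature matrix from [buildFeatureMatrix()] or a
#'   [PCADecomposition-class] (with \code{on = "pcs"}).
#' @param distance distance method for [stats::dist()].
#' @param linkage agglomeration method for [stats::hclust()].
#' @param on \code{"matrix"} (cluster the rows of \code{x}) or
#'   \code{"pcs"} (cluster retained PC coordinates).
#' @param retained components used when \code{on = "pcs"}.
#' @param classOf optional named character vector (cancer type -> class);
#'   defaults to the class annotation carried by \code{x}.
#' @return list with \code{tree} (an \code{hclust}), \code{assignment}
#'   (two-branch cut labels) and \code{purity} (weighted mean majority
#'   fraction of the two branches; 1 means a perfect H/L split; \code{NA}
#'   without class labels).
#' @export
hierarchicalCluster <- function(x, distance = "manhattan",
                                linkage = "complete",
                                on = c("matrix", "pcs"), retained = 3L,
                                classOf = NULL) {
    on <- match.arg(on)
    if (methods::is(x, "PCADecomposition")) {
        cls <- if (is.null(classOf)) x@rowClass else classOf
        x <- if (on == "pcs")
            sampleCoordinates(x)[, seq_len(min(retained,
                                               length(x@sdev))),
                                 drop = FALSE]
        else stop("pass the feature matrix itself for on = 'matrix'")
    } else {
        cls <- if (is.null(classOf)) attr(x, "class_label") else classOf
    }
    if (nrow(x) < 2L) stop("need at least 2 rows to cluster")
    tree <- stats::hclust(stats::dist(x, method = distance),
                          method = linkage)
    cut <- stats::cutree(tree, k = 2L)
    purity <- NA_real_
    if (!is.null(cls) && length(cls)) {
        cls <- cls[rownames(x)]
        frac <- vapply(split(cls, cut), function(v)
            max(table(v)) / length(v), 0)
        purity <- stats::weighted.mean(frac, table(cut))
    }
    list(tree = tree, assignment = cut, purity = purity)
}

#' Export a dendrogram in Newick format
#'
#' @param tree an \code{hclust} (e.g. from [hierarchicalCluster()]).
#' @param file output path.
#' @export
writeNewick <- function(tree, file) {
    ape::write.tree(ape::as.phylo(tree), file)
    invisible(file)
}
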