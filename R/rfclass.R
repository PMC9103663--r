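#' @include pcaclass.R
NULL

#' Build the per-sample feature matrix for classification
#'
#' One row per sample, one column per gene; the cell holds the gene's
#' connection number in the full interactome when the gene is upregulated
#' in that sample and 0 otherwise (presence/absence weighted by
#' connectivity). Genes absent from the interactome are dropped with a
#' warning.
#'
#' @param cohort a [SampleCohort-class].
#' @param connections an [Interactome-class] or named degree vector.
#' @param genes character vector of feature genes (column order kept).
#' @return list with \code{features} (samples x genes numeric matrix) and
#'   \code{labels} (factor of H/L class per sample).
#' @export
buildSampleFeatures <- function(cohort, connections, genes) {
    deg <- if (methods::is(connections, "Interactome"))
        geneDegree(connections)
    else unlist(connections)
    missing <- setdiff(genes, names(deg))
    if (length(missing)) {
        warning(sprintf(
            "dropped %d feature gene(s) absent from the interactome",
            length(missing)))
        genes <- setdiff(genes, missing)
    }
    if (!length(genes)) stop("no feature genes left")
    s <- sampleInfo(cohort)
    m <- matrix(0, nrow = nrow(s), ncol = length(genes),
                dimnames = list(s$sample_id, genes))
    for (i in seq_len(nrow(s))) {
        up <- intersect(cohort@upregulated[[s$sample_id[i]]], genes)
        m[i, up] <- deg[up]
    }
    list(features = m,
         labels = factor(s$class, levels = c("H", "L")))
}

#' Train the H/L random-forest classifier
#'
#' Grows a seeded forest of \code{ntree} classification trees (Gini
#' impurity splitting, \code{mtry} candidate features per split, bootstrap
#' resampling) and evaluates it by the out-of-bag (OOB) route only: each
#' sample is predicted by the trees whose bootstrap omitted it, so no
#' train/test split is needed.
#'
#' @param features samples x genes matrix from [buildSampleFeatures()].
#' @param labels factor of H/L labels aligned to the rows.
#' @param mtry candidate features per split (default 8); must not exceed
#'   the feature count.
#' @param ntree number of trees (default 50).
#' @param seed integer seed; identical inputs reproduce identical forests.
#' @return an [RFClassResult-class].
#' @export
trainRFC <- function(features, labels, mtry = 8L, ntree = 50L, seed = 1L) {
    labels <- droplevels(as.factor(labels))
    if (nlevels(labels) < 2L)
        stop("both classes must be represented in the labels")
    if (mtry > ncol(features))
        stop(sprintf("mtry (%d) exceeds the feature count (%d)",
                     mtry, ncol(features)))
    fit <- withr::with_seed(seed,
        randomForest::randomForest(x = features, y = labels,
                                   mtry = mtry, ntree = ntree))
    lev <- levels(labels)
    conf <- table(truth = labels, predicted = fit$predicted)
    conf <- matrix(as.integer(conf[lev, lev]), 2L, 2L,
                   dimnames = list(truth = lev, predicted = lev))
    err <- confusionErrorRates(conf)
    imp <- stats::setNames(as.numeric(fit$importance[, "MeanDecreaseGini"]),
                           rownames(fit$importance))
    methods::new("RFClassResult", confusion = conf,
                 classErrors = err$classErrors, oobError = err$overall,
                 importance = imp,
                 params = list(mtry = as.integer(mtry),
                               ntree = as.integer(ntree),
                               seed = as.integer(seed)))
}

#' @describeIn RFClassResult-class the 2 x 2 OOB confusion matrix.
#' @export
setMethod("confusionMatrix", "RFClassResult", function(x, ...) x@confusion)

#' @describeIn RFClassResult-class overall OOB error rate (proportion).
#' @export
setMethod("oobError", "RFClassResult", function(x, ...) x@oobError)

#' @describeIn RFClassResult-class named per-gene mean decrease in Gini.
#' @export
setMethod("giniImportance", "RFClassResult", function(x, ...) x@importance)

setMethod("show", "RFClassResult", function(object) {
    cat(sprintf(
        "RFClassResult: OOB error %.2f%% (mtry = %d, ntree = %d)\n",
        100 * object@oobError, object@params$mtry, object@params$ntree))
    print(object@confusion)
})

#' Error rates of a 2 x 2 confusion matrix
#'
#' Per-class error = off-diagonal count / row sum; overall error = total
#' off-diagonal / total samples. Pure arithmetic, rows are the true
#' classes.
#'
#' @param confusion 2 x 2 non-negative integer matrix with positive row
#'   sums.
#' @return list with \code{classErrors} (named numeric) and \code{overall}
#'   (proportion).
#' @examples
#' confusionErrorRates(matrix(c(115, 6, 10, 129), 2,
#'                            dimnames = list(c("H", "L"), c("H", "L"))))
#' @export
confusionErrorRates <- function(confusion) {
    confusion <- as.matrix(confusion)
    if (!all(dim(confusion) == 2L))
        stop("'confusion' must be a 2 x 2 matrix")
    if (any(confusion < 0) || any(confusion != round(confusion)))
        stop("'confusion' must contain non-negative integers")
    rs <- rowSums(confusion)
    if (any(rs == 0)) stop("every true class must have samples")
    off <- rs - diag(confusion)
    lev <- rownames(confusion)
    if (is.null(lev)) lev <- c("H", "L")
    list(classErrors = stats::setNames(off / rs, lev),
         overall = sum(off) / sum(confusion))
}

#' Rank genes by mean decrease in Gini importance
#'
#' @param result an [RFClassResult-class].
#' @param topK number of genes returned; larger than the gene count
#'   truncates with a warning, 0 returns an empty table. Ties are broken
#'   lexicographically by gene name.
#' @return data.frame with columns \code{gene},
#'   \code{mean_decrease_gini}, \code{rank}.
#' @export
importanceRanking <- function(result, topK = 10L) {
    imp <- giniImportance(result)
    if (topK > length(imp)) {
        warning(sprintf("topK (%d) exceeds the gene count (%d); truncated",
                        topK, length(imp)))
        topK <- length(imp)
    }
    ord <- order(-imp, names(imp))
    out <- data.frame(gene = names(imp)[ord],
                      mean_decrease_gini = unname(imp[ord]),
                      rank = seq_along(imp))
    utils::head(out, topK)
}
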