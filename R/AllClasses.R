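#' @import methods
NULL

setOldClass("igraph")
setOldClass("hclust")

#' Interactome: an undirected protein-protein interaction graph
#'
#' Wraps an undirected, simple (no self-loops, no multi-edges) \pkg{igraph}
#' graph whose vertices are gene identifiers. The vertex degree is the
#' gene's connection number used throughout the scoring stages.
#'
#' @slot graph an undirected simple \code{igraph} object with named vertices.
#'
#' @seealso [Interactome()], [simulateInteractome()], [readInteractome()]
#' @exportClass Interactome
setClass("Interactome", representation(graph = "igraph"))

setValidity("Interactome", function(object) {
    g <- object@graph
    msg <- character()
    if (igraph::is_directed(g))
        msg <- c(msg, "graph must be undirected")
    if (any(igraph::which_loop(g)))
        msg <- c(msg, "graph must not contain self-loops")
    if (any(igraph::which_multiple(g)))
        msg <- c(msg, "graph must not contain multiple edges")
    nm <- igraph::V(g)$name
    if (is.null(nm) || anyNA(nm) || anyDuplicated(nm))
        msg <- c(msg, "vertices must carry unique gene identifiers")
    if (length(msg)) msg else TRUE
})

#' SampleCohort: per-sample upregulated-gene profiles
#'
#' Holds one row of metadata per tumor sample (identifier, cancer type,
#' aggressiveness class H or L) together with the set of genes called
#' upregulated in that sample.
#'
#' @slot samples a \code{data.frame} with columns \code{sample_id},
#'   \code{cancer_type} and \code{class} (values \code{"H"} or \code{"L"}).
#' @slot upregulated a list of character vectors, one per sample and named
#'   by \code{sample_id}, each holding that sample's upregulated genes.
#'
#' @seealso [SampleCohort()], [simulateCohort()], [readCohort()]
#' @exportClass SampleCohort
setClass("SampleCohort",
    representation(samples = "data.frame", upregulated = "list"))

setValidity("SampleCohort", function(object) {
    s <- object@samples
    msg <- character()
    need <- c("sample_id", "cancer_type", "class")
    if (!all(need %in% names(s)))
        return(sprintf("samples must have columns %s",
                       paste(need, collapse = ", ")))
    if (anyDuplicated(s$sample_id))
        msg <- c(msg, "sample identifiers must be unique")
    if (!all(s$class %in% c("H", "L")))
        msg <- c(msg, "class labels must be 'H' or 'L'")
    if (!identical(sort(names(object@upregulated)),
                   sort(as.character(s$sample_id))))
        msg <- c(msg, "upregulated list must be named by sample_id")
    if (any(vapply(object@upregulated, anyDuplicated, 0L) > 0L))
        msg <- c(msg, "genes must be unique within a sample")
    if (length(msg)) msg else TRUE
})

#' CohortDesign: ground-truth design of a synthetic upregulation cohort
#'
#' Specifies the groups (cancer type, class, sample count) and the per-gene
#' class-specific Bernoulli upregulation frequencies from which a
#' [SampleCohort] is drawn. The design, recorded before any sampling, is the
#' ground truth against which downstream recovery is measured.
#'
#' @slot groups \code{data.frame} with columns \code{cancer_type},
#'   \code{class} (H/L) and \code{n} (positive sample counts).
#' @slot freqH,freqL named numeric vectors in \[0, 1\]: each gene's
#'   upregulation probability in H-class and L-class samples.
#' @slot seed integer seed used when sampling the cohort.
#' @slot truth list of ground-truth annotations (planted hub genes,
#'   class-exclusive genes), recorded before sampling.
#'
#' @seealso [cohortDesign()], [defaultCohortDesign()], [simulateCohort()]
#' @exportClass CohortDesign
setClass("CohortDesign",
    representation(groups = "data.frame", freqH = "numeric",
                   freqL = "numeric", seed = "integer", truth = "list"))

setValidity("CohortDesign", function(object) {
    msg <- character()
    g <- object@groups
    if (!all(c("cancer_type", "class", "n") %in% names(g)))
        return("groups must have columns cancer_type, class, n")
    if (!all(g$class %in% c("H", "L")))
        msg <- c(msg, "class labels must be 'H' or 'L'")
    if (any(g$n <= 0))
        msg <- c(msg, "sample counts must be positive")
    fr <- c(object@freqH, object@freqL)
    if (anyNA(fr) || any(fr < 0) || any(fr > 1))
        msg <- c(msg, "all frequencies must lie in [0, 1]")
    if (!identical(names(object@freqH), names(object@freqL)))
        msg <- c(msg, "freqH and freqL must be named over the same genes")
    if (length(msg)) msg else TRUE
})

#' HubBoundary: an exclusive hub boundary in (connections, frequency) space
#'
#' The result of [hubBoundarySearch()]: thresholds on normalized connections
#' and normalized counts such that the genes at or above both thresholds in
#' the H class are exclusive hubs (no L-class gene qualifies).
#'
#' @slot connThreshold numeric, normalized-connection threshold (inclusive).
#' @slot freqThreshold numeric in \[0, 1\], normalized-count threshold
#'   (inclusive).
#' @slot genes character, the qualifying H-class genes.
#' @slot objective numeric, the objective value (number of exclusive hubs).
#'
#' @exportClass HubBoundary
setClass("HubBoundary",
    representation(connThreshold = "numeric", freqThreshold = "numeric",
                   genes = "character", objective = "numeric"))

#' PCADecomposition: principal components of a cancer-type x gene matrix
#'
#' Output of [runPCA()]: singular-value-decomposition based components with
#' a fixed sign convention (largest-magnitude loading of each component is
#' positive), variance proportions and row coordinates.
#'
#' @slot sdev numeric, component standard deviations.
#' @slot rotation gene x component loading matrix.
#' @slot x row-coordinate matrix (cancer types x components).
#' @slot proportions numeric, per-component proportion of variance.
#' @slot cumulative numeric, cumulative proportions.
#' @slot center numeric, the column centers applied (or 0s).
#' @slot rowClass named character, class annotation (H/L) of each row,
#'   possibly empty.
#'
#' @exportClass PCADecomposition
setClass("PCADecomposition",
    representation(sdev = "numeric", rotation = "matrix", x = "matrix",
                   proportions = "numeric", cumulative = "numeric",
                   center = "numeric", rowClass = "character"))

setValidity("PCADecomposition", function(object) {
    msg <- character()
    if (ncol(object@rotation) != length(object@sdev))
        msg <- c(msg, "rotation must have one column per component")
    if (length(object@proportions) &&
        any(diff(object@cumulative) < -1e-12))
        msg <- c(msg, "cumulative proportions must be non-decreasing")
    if (length(msg)) msg else TRUE
})

#' RFClassResult: random-forest classification of samples into H/L
#'
#' Output of [trainRFC()]: out-of-bag (OOB) confusion matrix and error
#' rates plus the per-gene mean decrease in Gini impurity.
#'
#' @slot confusion 2 x 2 integer matrix, rows = true class (H, L),
#'   columns = OOB-predicted class.
#' @slot classErrors named numeric, per-class OOB error rates.
#' @slot oobError numeric, overall OOB error rate (proportion).
#' @slot importance named numeric, per-gene mean decrease in Gini.
#' @slot params list of forest parameters (\code{mtry}, \code{ntree},
#'   \code{seed}).
#'
#' @exportClass RFClassResult
setClass("RFClassResult",
    representation(confusion = "matrix", classErrors = "numeric",
                   oobError = "numeric", importance = "numeric",
                   params = "list"))

#' SubNetwork: induced sub-interactome of a selected gene list
#'
#' Output of [extractSubnetwork()]: the subgraph of the interactome induced
#' by a gene list, with connected-component labels, the major component, and
#' per-gene annotations (origin of the gene, full- and sub-graph degrees).
#'
#' @slot graph undirected \code{igraph} induced subgraph.
#' @slot nodeInfo \code{data.frame} with columns \code{gene}, \code{source},
#'   \code{degree_full}, \code{degree_sub}, \code{component}.
#' @slot majorComponent character, the genes of the largest component
#'   (ties broken by the lexicographically smallest sorted member set).
#'
#' @exportClass SubNetwork
setClass("SubNetwork",
    representation(graph = "igraph", nodeInfo = "data.frame",
                   majorComponent = "character"))

setValidity("SubNetwork", function(object) {
    msg <- character()
    nm <- igraph::V(object@graph)$name
    if (!setequal(nm, object@nodeInfo$gene))
        msg <- c(msg, "nodeInfo must describe exactly the graph's vertices")
    if (!all(object@majorComponent %in% c(nm, character())))
        msg <- c(msg, "majorComponent genes must be graph vertices")
    if (length(msg)) msg else TRUE
})
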