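#' @include rfclass.R
NULL

.majorComponent <- function(graph) {
    if (igraph::vcount(graph) == 0L) return(character())
    comp <- igraph::components(graph)
    sizes <- comp$csize
    cands <- which(sizes == max(sizes))
    members <- lapply(cands, function(k)
        sort(igraph::V(graph)$name[comp$membership == k]))
    keys <- vapply(members, paste, "", collapse = "\r")
    members[[order(keys)[1L]]]
}

.makeSubNetwork <- function(interactome, genes, source) {
    sub <- igraph::induced_subgraph(interactome@graph, genes)
    comp <- if (length(genes)) igraph::components(sub)
            else list(membership = integer())
    nm <- igraph::V(sub)$name
    info <- data.frame(
        gene = nm,
        source = if (length(nm)) unname(source[nm]) else character(),
        degree_full = as.integer(igraph::degree(interactome@graph)[nm]),
        degree_sub = as.integer(igraph::degree(sub)),
        component = as.integer(comp$membership))
    info <- info[order(info$gene), , drop = FALSE]
    rownames(info) <- NULL
    methods::new("SubNetwork", graph = sub, nodeInfo = info,
                 majorComponent = .majorComponent(sub))
}

#' Extract the sub-interactome induced by a gene list
#'
#' Induced subgraph of the full interactome on the listed genes, with
#' connected components labeled and the major component identified (the
#' largest; ties resolved toward the lexicographically smallest sorted
#' member set, deterministically).
#'
#' @param genes non-empty character vector of genes (e.g. the union of the
#'   ordination and classification gene lists).
#' @param interactome an [Interactome-class].
#' @param source optional named character vector annotating each gene's
#'   origin (e.g. \code{"pca"}, \code{"rfc"}, \code{"both"}); defaults to
#'   \code{"listed"}.
#' @return a [SubNetwork-class]. Genes absent from the interactome are
#'   dropped with a warning; an error is raised if none remain.
#' @export
extractSubnetwork <- function(genes, interactome, source = NULL) {
    if (!length(genes)) stop("empty gene list")
    genes <- unique(genes)
    present <- intersect(genes, interactomeGenes(interactome))
    if (!length(present))
        stop("none of the listed genes is in the interactome")
    if (length(present) < length(genes))
        warning(sprintf("%d listed gene(s) absent from the interactome",
                        length(genes) - length(present)))
    if (is.null(source))
        source <- stats::setNames(rep("listed", length(present)), present)
    .makeSubNetwork(interactome, present, source)
}

#' @describeIn SubNetwork-class the genes of the subnetwork.
#' @export
setMethod("networkGenes", "SubNetwork", function(x, ...)
    sort(igraph::V(x@graph)$name))

#' @describeIn SubNetwork-class genes of the major connected component.
#' @export
setMethod("majorComponent", "SubNetwork", function(x, ...)
    x@majorComponent)

#' @describeIn SubNetwork-class sizes of the connected components.
#' @export
setMethod("componentSizes", "SubNetwork", function(x, ...) {
    if (!nrow(x@nodeInfo)) return(integer())
    sort(as.integer(table(x@nodeInfo$component)), decreasing = TRUE)
})

#' @describeIn SubNetwork-class the per-gene annotation table.
#' @export
setMethod("nodeInfo", "SubNetwork", function(x, ...) x@nodeInfo)

setMethod("show", "SubNetwork", function(object) {
    cat(sprintf(
        "SubNetwork: %d genes, %d edges, %d component(s); major component %d gene(s)\n",
        igraph::vcount(object@graph), igraph::ecount(object@graph),
        length(unique(object@nodeInfo$component)),
        length(object@majorComponent)))
})

#' Drop low-connectivity genes from a subnetwork
#'
#' Removes genes whose connection number in the \emph{full} interactome is
#' below \code{minDegreeFull} (poorly connected genes have little chance
#' of joining the major component) and relabels the components.
#'
#' @param network a [SubNetwork-class].
#' @param interactome the [Interactome-class] the network was extracted
#'   from.
#' @param minDegreeFull inclusive full-interactome degree threshold
#'   (default 10); 0 is the identity.
#' @return a [SubNetwork-class], possibly empty.
#' @export
excludeLowConnectivity <- function(network, interactome,
                                   minDegreeFull = 10L) {
    info <- network@nodeInfo
    keep <- info$gene[info$degree_full >= minDegreeFull]
    source <- stats::setNames(info$source, info$gene)
    .makeSubNetwork(interactome, keep, source)
}

#' Bridging paths from an isolated gene to the major component
#'
#' Searches the full interactome for paths connecting a gene outside the
#' subnetwork's major component to any gene of that component through
#' intermediary proteins. Intermediaries are interactome genes outside the
#' listed gene set: other listed genes not in the major component are
#' excluded from the search interior. The default policy returns all
#' shortest such paths; \code{policy = "all"} returns every simple path
#' with at most \code{maxIntermediaries} intermediaries.
#'
#' @param origin gene identifier; must be in the interactome and not in
#'   the major component.
#' @param network a [SubNetwork-class].
#' @param interactome the full [Interactome-class].
#' @param maxIntermediaries maximum number of intermediary genes allowed.
#' @param policy \code{"shortest"} (default) or \code{"all"}.
#' @return list of paths, each a list with \code{origin},
#'   \code{terminal}, \code{intermediaries} (character, possibly empty)
#'   and \code{length} (edge count); empty when no path fits the bound.
#' @export
bridgePaths <- function(origin, network, interactome,
                        maxIntermediaries = 6L,
                        policy = c("shortest", "all")) {
    policy <- match.arg(policy)
    g <- interactome@graph
    if (!origin %in% igraph::V(g)$name)
        stop("origin gene not in the interactome")
    major <- network@majorComponent
    if (origin %in% major)
        stop("origin gene already belongs to the major component")
    if (!length(major)) return(list())
    excluded <- setdiff(networkGenes(network), c(major, origin))
    g2 <- igraph::delete_vertices(g, intersect(excluded,
                                               igraph::V(g)$name))
    nm <- igraph::V(g2)$name
    targets <- intersect(major, nm)
    if (!origin %in% nm || !length(targets)) return(list())
    asPath <- function(v) {
        p <- igraph::V(g2)$name[as.integer(v)]
        list(origin = p[1L], terminal = p[length(p)],
             intermediaries = p[-c(1L, length(p))],
             length = length(p) - 1L)
    }
    if (policy == "shortest") {
        d <- suppressWarnings(igraph::distances(g2, v = origin,
                                                to = targets))
        dmin <- min(d)
        if (!is.finite(dmin) || dmin - 1L > maxIntermediaries)
            return(list())
        near <- targets[d[1L, ] == dmin]
        paths <- igraph::all_shortest_paths(g2, from = origin,
                                            to = near)$res
        out <- lapply(paths, asPath)
    } else {
        paths <- igraph::all_simple_paths(
            g2, from = origin, to = targets,
            cutoff = maxIntermediaries + 1L)
        out <- lapply(paths, asPath)
        # keep only paths that first touch the component at their terminal
        out <- Filter(function(p)
            !any(p$intermediaries %in% targets), out)
    }
    out[order(vapply(out, `[[`, 0L, "length"),
              vapply(out, `[[`, "", "terminal"))]
}

#' Export a subnetwork for Cytoscape
#'
#' GraphML export carries the node annotations (source, full and subgraph
#' degrees, component) and round-trips exactly through
#' [readSubnetworkGraphml()]; SIF export writes one \code{"a pp b"} line
#' per interaction and a bare line per isolated gene.
#'
#' @param network a [SubNetwork-class].
#' @param file output path.
#' @param format \code{"graphml"} or \code{"sif"}.
#' @export
exportNetwork <- function(network, file, format = c("graphml", "sif")) {
    format <- match.arg(format)
    g <- network@graph
    if (format == "graphml") {
        info <- network@nodeInfo
        idx <- match(igraph::V(g)$name, info$gene)
        igraph::V(g)$source <- info$source[idx]
        igraph::V(g)$degree_full <- info$degree_full[idx]
        igraph::V(g)$degree_sub <- info$degree_sub[idx]
        igraph::V(g)$component <- info$component[idx]
        igraph::write_graph(g, file, format = "graphml")
    } else {
        el <- igraph::as_edgelist(g)
        lines <- if (nrow(el)) paste(el[, 1L], "pp", el[, 2L])
                 else character()
        isolated <- igraph::V(g)$name[igraph::degree(g) == 0L]
        writeLines(c(lines, isolated), file)
    }
    invisible(file)
}

#' @rdname exportNetwork
#' @return [readSubnetworkGraphml()] reconstructs the
#'   [SubNetwork-class] (graph, annotations, major component) from a
#'   GraphML file written by [exportNetwork()].
#' @export
readSubnetworkGraphml <- function(file) {
    g <- igraph::read_graph(file, format = "graphml")
    nm <- igraph::V(g)$name
    info <- data.frame(gene = nm,
                       source = igraph::V(g)$source,
                       degree_full = as.integer(igraph::V(g)$degree_full),
                       degree_sub = as.integer(igraph::V(g)$degree_sub),
                       component = as.integer(igraph::V(g)$component))
    info <- info[order(info$gene), , drop = FALSE]
    rownames(info) <- NULL
    methods::new("SubNetwork", graph = g, nodeInfo = info,
                 majorComponent = .majorComponent(g))
}
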