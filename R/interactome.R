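#' @include AllGenerics.R
NULL

#' Construct an Interactome from an edge list
#'
#' Builds an undirected, simple interaction graph from unordered gene
#' pairs. Duplicate edges (in either orientation) and self-loops are
#' rejected rather than silently collapsed so that degree bookkeeping is
#' explicit.
#'
#' @param edges a two-column character matrix or data.frame of gene pairs.
#' @param nodes optional character vector of additional (possibly isolated)
#'   genes to include as vertices.
#' @return an [Interactome-class] object.
#' @examples
#' ppi <- Interactome(cbind(c("TP53", "TP53"), c("MDM2", "EP300")))
#' geneDegree(ppi)
#' @export
Interactome <- function(edges, nodes = NULL) {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L)
        stop("'edges' must have exactly two columns")
    mode(edges) <- "character"
    if (any(edges[, 1L] == edges[, 2L]))
        stop("self-loops are not allowed in an interactome")
    key <- paste(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]))
    if (anyDuplicated(key))
        stop("duplicate interactions found; provide each unordered pair once")
    vs <- unique(c(as.vector(t(edges)), nodes))
    g <- igraph::graph_from_data_frame(
        as.data.frame(edges, stringsAsFactors = FALSE),
        directed = FALSE, vertices = vs)
    methods::new("Interactome", graph = g)
}

#' @describeIn Interactome-class gene identifiers (vertex names).
#' @export
setMethod("interactomeGenes", "Interactome", function(x, ...)
    igraph::V(x@graph)$name)

#' @describeIn Interactome-class named integer vector of connection numbers;
#'   \code{genes} restricts (and orders) the result.
#' @param genes optional character vector of genes to report.
#' @export
setMethod("geneDegree", "Interactome", function(x, genes = NULL, ...) {
    d <- igraph::degree(x@graph)
    if (is.null(genes)) return(d)
    missing <- setdiff(genes, names(d))
    if (length(missing))
        stop(sprintf("%d gene(s) absent from the interactome: %s",
                     length(missing),
                     paste(utils::head(missing, 5L), collapse = ", ")))
    d[genes]
})

#' @describeIn Interactome-class number of interactions (edges).
#' @export
setMethod("numInteractions", "Interactome", function(x)
    igraph::ecount(x@graph))

setMethod("show", "Interactome", function(object) {
    d <- igraph::degree(object@graph)
    cat(sprintf(
        "Interactome: %d genes, %d interactions (max degree %d, median %g)\n",
        length(d), igraph::ecount(object@graph),
        if (length(d)) max(d) else 0L,
        if (length(d)) stats::median(d) else 0))
})

#' Read / write an interactome edge list
#'
#' Plain two-column tab-separated edge lists (no header by default) are the
#' interchange format for the interaction graph.
#'
#' @param file path to a TSV file.
#' @param header logical, whether the file carries a header line.
#' @return [Interactome-class] for the reader; invisibly `file` for the
#'   writer.
#' @export
readInteractome <- function(file, header = FALSE) {
    df <- utils::read.table(file, header = header, sep = "\t",
                            colClasses = "character", quote = "")
    Interactome(df[, 1:2])
}

#' @rdname readInteractome
#' @param x an [Interactome-class].
#' @export
writeInteractome <- function(x, file) {
    el <- igraph::as_edgelist(x@graph)
    utils::write.table(el, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(file)
}

#' Read a MITAB-flavored interaction file
#'
#' Minimal reader for PSI-MI tab-delimited interaction files: takes the
#' interactor alias columns (5 and 6), extracts the \code{"(gene name)"}
#' alias when present and falls back to the primary identifier otherwise.
#' Self-interactions and duplicate pairs are dropped.
#'
#' @param file path to a MITAB 2.5+ file (with or without a `#` header).
#' @return an [Interactome-class] object.
#' @export
readMitab <- function(file) {
    lines <- readLines(file)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (!length(lines)) stop("no interaction records in ", file)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    pick <- function(rec, aliasCol, idCol) {
        alias <- if (length(rec) >= aliasCol) rec[[aliasCol]] else "-"
        m <- regmatches(alias,
                        regexpr("[^|:]+(?=\\(gene name\\))", alias,
                                perl = TRUE))
        if (length(m) && nzchar(m)) return(m)
        sub("^[^:]*:", "", strsplit(rec[[idCol]], "|", fixed = TRUE)[[1L]][1L])
    }
    a <- vapply(fields, pick, "", aliasCol = 5L, idCol = 1L)
    b <- vapply(fields, pick, "", aliasCol = 6L, idCol = 2L)
    keep <- a != b
    key <- paste(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]))
    first <- !duplicated(key)
    Interactome(cbind(a[keep][first], b[keep][first]))
}
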