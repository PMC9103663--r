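# Shared in-code fixtures: tiny graphs, hand-built stats tables, and
# brute-force oracles used across test files.

# path graph a-b-c-d plus a hub x connected to a,b,c
toyInteractome <- function() {
    Interactome(rbind(c("a", "b"), c("b", "c"), c("c", "d"),
                      c("x", "a"), c("x", "b"), c("x", "c")))
}

# class-grouped stats table built directly from per-class counts
makeStats <- function(gene, nH, nL, degree, sizeH = 125L, sizeL = 135L) {
    df <- rbind(
        data.frame(gene = gene, group = "H", n = nH, group_size = sizeH),
        data.frame(gene = gene, group = "L", n = nL, group_size = sizeL))
    df$norm_count <- df$n / df$group_size
    df$degree <- rep(degree, 2L)
    df$norm_connections <- df$norm_count * df$degree
    df
}

# random class-grouped stats for oracle comparisons
randomStats <- function(nGenes, seed) {
    set.seed(seed)
    gene <- sprintf("g%03d", seq_len(nGenes))
    makeStats(gene,
              nH = stats::rbinom(nGenes, 125, stats::runif(nGenes)),
              nL = stats::rbinom(nGenes, 135, stats::runif(nGenes)),
              degree = sample(1:500, nGenes, replace = TRUE))
}

# exhaustive (c, f) grid search: the oracle for hubBoundarySearch()
bruteBoundary <- function(stats) {
    H <- stats[stats$group == "H" & stats$n > 0, , drop = FALSE]
    L <- stats[stats$group == "L" & stats$n > 0, , drop = FALSE]
    best <- list(count = 0L, c = NA_real_, f = NA_real_,
                 genes = character())
    for (c0 in unique(H$norm_connections)) {
        for (f0 in unique(H$norm_count)) {
            if (any(L$norm_connections >= c0 & L$norm_count >= f0)) next
            qual <- H$norm_connections >= c0 & H$norm_count >= f0
            count <- sum(qual)
            if (!count) next
            ct <- min(H$norm_connections[qual])
            ft <- min(H$norm_count[qual])
            if (count > best$count ||
                (count == best$count &&
                 (ct > best$c || (ct == best$c && ft > best$f))))
                best <- list(count = count, c = ct, f = ft,
                             genes = sort(H$gene[qual]))
        }
    }
    best
}

# cohort with prescribed per-gene upregulation counts per class
countsToCohort <- function(gene, nH, nL, sizeH = 125L, sizeL = 135L) {
    ids <- c(sprintf("H_%03d", seq_len(sizeH)),
             sprintf("L_%03d", seq_len(sizeL)))
    samples <- data.frame(sample_id = ids,
                          cancer_type = rep(c("TH", "TL"),
                                            c(sizeH, sizeL)),
                          class = rep(c("H", "L"), c(sizeH, sizeL)))
    ups <- c(lapply(seq_len(sizeH), function(i) gene[nH >= i]),
             lapply(seq_len(sizeL), function(i) gene[nL >= i]))
    names(ups) <- ids
    SampleCohort(samples, ups)
}

# all simple paths origin -> targets by DFS; oracle for bridgePaths()
bruteSimplePaths <- function(graph, origin, targets, maxLen) {
    adj <- igraph::as_adj_list(graph)
    nm <- igraph::V(graph)$name
    adj <- lapply(adj, function(v) nm[as.integer(v)])
    names(adj) <- nm
    out <- list()
    walk <- function(path) {
        last <- path[length(path)]
        if (last %in% targets && length(path) > 1L) {
            out[[length(out) + 1L]] <<- path
            return()
        }
        if (length(path) - 1L >= maxLen) return()
        for (nxt in setdiff(adj[[last]], path)) walk(c(path, nxt))
    }
    walk(origin)
    out
}
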