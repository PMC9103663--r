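test_that("induced subgraphs keep exactly the interactome's internal edges", {
    ppi <- toyInteractome()
    net <- extractSubnetwork(c("a", "b", "x", "d"), ppi)
    g <- net@graph
    nm <- networkGenes(net)
    full <- ppi@graph
    for (i in seq_along(nm)) for (j in seq_len(i - 1L))
        expect_equal(igraph::are_adjacent(g, nm[i], nm[j]),
                     igraph::are_adjacent(full, nm[i], nm[j]))
    info <- nodeInfo(net)
    expect_equal(info$degree_full[info$gene == "x"], 3L)
    expect_equal(info$degree_sub[info$gene == "d"], 0L)
    # component labels partition the nodes
    expect_equal(sum(componentSizes(net)), length(nm))
    expect_setequal(majorComponent(net), c("a", "b", "x"))
})

test_that("two planted cliques yield two components with the larger major", {
    edges <- rbind(t(utils::combn(c("c1", "c2", "c3", "c4"), 2)),
                   t(utils::combn(c("d1", "d2", "d3"), 2)))
    ppi <- Interactome(edges)
    net <- extractSubnetwork(igraph::V(ppi@graph)$name, ppi)
    expect_equal(componentSizes(net), c(4L, 3L))
    expect_setequal(majorComponent(net), c("c1", "c2", "c3", "c4"))
    # equal-size tie resolves to the lexicographically smallest member set
    tie <- Interactome(rbind(c("m1", "m2"), c("a1", "a2")))
    netTie <- extractSubnetwork(c("m1", "m2", "a1", "a2"), tie)
    expect_setequal(majorComponent(netTie), c("a1", "a2"))
    solo <- extractSubnetwork("c1", ppi)
    expect_equal(networkGenes(solo), "c1")
    expect_equal(igraph::ecount(solo@graph), 0)
    expect_warning(extractSubnetwork(c("c1", "zz"), ppi), "absent")
    expect_error(extractSubnetwork("zz", ppi), "none of the listed")
})

test_that("low-connectivity exclusion filters on full-interactome degree", {
    ppi <- toyInteractome()
    net <- extractSubnetwork(c("a", "d", "x"), ppi)
    # identity at threshold 0
    same <- excludeLowConnectivity(net, ppi, 0)
    expect_setequal(networkGenes(same), networkGenes(net))
    # 'd' has full degree 1 < 2 -> removed
    pruned <- excludeLowConnectivity(net, ppi, 2)
    expect_false("d" %in% networkGenes(pruned))
    # threshold above the maximum degree empties the network
    empty <- excludeLowConnectivity(net, ppi, 99)
    expect_length(networkGenes(empty), 0)
})

test_that("bridge paths find planted chains and respect the bound", {
    # origin o - i1 - i2 - c1, plus major clique c1..c3 and direct o2-c2
    ppi <- Interactome(rbind(
        t(utils::combn(c("c1", "c2", "c3"), 2)),
        c("o", "i1"), c("i1", "i2"), c("i2", "c1"), c("o2", "c2")))
    net <- extractSubnetwork(c("c1", "c2", "c3", "o"), ppi)
    expect_setequal(majorComponent(net), c("c1", "c2", "c3"))
    bp <- bridgePaths("o", net, ppi, maxIntermediaries = 6)
    expect_length(bp, 1)
    expect_equal(bp[[1]]$intermediaries, c("i1", "i2"))
    expect_equal(bp[[1]]$terminal, "c1")
    expect_equal(bp[[1]]$length, 3L)
    # adjacent origin: zero intermediaries
    bp2 <- bridgePaths("o2", net, ppi)
    expect_equal(bp2[[1]]$intermediaries, character())
    expect_equal(bp2[[1]]$length, 1L)
    # tight bound excludes the chain
    expect_length(bridgePaths("o", net, ppi, maxIntermediaries = 1), 0)
    expect_length(bridgePaths("o", net, ppi, maxIntermediaries = 0), 0)
    expect_error(bridgePaths("c1", net, ppi), "already belongs")
    expect_error(bridgePaths("zz", net, ppi), "not in the interactome")
})

test_that("other isolated listed genes cannot serve as intermediaries", {
    # two equally short routes exist; the one through the listed (but
    # component-isolated) gene 'iso' is barred from the search interior
    ppi <- Interactome(rbind(
        t(utils::combn(c("c1", "c2", "c3"), 2)),
        c("o", "x"), c("x", "iso"), c("iso", "y"), c("y", "c1"),
        c("o", "u1"), c("u1", "u2"), c("u2", "u3"), c("u3", "c2")))
    net <- extractSubnetwork(c("c1", "c2", "c3", "o", "iso"), ppi)
    expect_setequal(majorComponent(net), c("c1", "c2", "c3"))
    bp <- bridgePaths("o", net, ppi, maxIntermediaries = 4)
    expect_length(bp, 1)
    expect_equal(bp[[1]]$intermediaries, c("u1", "u2", "u3"))
})

test_that("shortest bridge paths agree with brute-force enumeration", {
    for (s in c(2, 17)) {
        set.seed(s)
        ppi <- simulateInteractome(40, 2, seed = s)
        genes <- interactomeGenes(ppi)
        listed <- sample(genes, 8)
        net <- extractSubnetwork(listed, ppi)
        outside <- setdiff(networkGenes(net), majorComponent(net))
        for (o in outside) {
            bp <- bridgePaths(o, net, ppi, maxIntermediaries = 4)
            # oracle: all simple paths in the pruned graph, keep shortest
            excl <- setdiff(networkGenes(net),
                            c(majorComponent(net), o))
            g2 <- igraph::delete_vertices(ppi@graph, excl)
            brute <- bruteSimplePaths(g2, o, majorComponent(net),
                                      maxLen = 5)
            brute <- Filter(function(p)
                !any(p[-c(1, length(p))] %in% majorComponent(net)),
                brute)
            if (!length(brute)) {
                expect_length(bp, 0)
                next
            }
            lens <- lengths(brute) - 1L
            shortest <- brute[lens == min(lens)]
            expect_equal(length(bp), length(shortest))
            key <- function(p) paste(p, collapse = ">")
            expect_setequal(
                vapply(bp, function(p)
                    key(c(p$origin, p$intermediaries, p$terminal)), ""),
                vapply(shortest, key, ""))
        }
    }
})

test_that("the all-simple-paths policy honors the intermediary bound", {
    ppi <- Interactome(rbind(
        t(utils::combn(c("c1", "c2", "c3"), 2)),
        c("o", "i1"), c("i1", "c1"), c("o", "j1"), c("j1", "j2"),
        c("j2", "c2")))
    net <- extractSubnetwork(c("c1", "c2", "c3", "o"), ppi)
    all2 <- bridgePaths("o", net, ppi, maxIntermediaries = 2,
                        policy = "all")
    expect_equal(sort(vapply(all2, `[[`, 0L, "length")), c(2L, 3L))
    all1 <- bridgePaths("o", net, ppi, maxIntermediaries = 1,
                        policy = "all")
    expect_length(all1, 1)
})

test_that("network export round-trips GraphML and writes SIF lines", {
    ppi <- Interactome(rbind(c("p", "q"), c("q", "r")), nodes = "lone")
    net <- extractSubnetwork(c("p", "q", "r", "lone"), ppi,
                             source = c(p = "pca", q = "rfc", r = "both",
                                        lone = "pca"))
    f <- withr::local_tempfile(fileext = ".graphml")
    exportNetwork(net, f, "graphml")
    back <- readSubnetworkGraphml(f)
    expect_equal(nodeInfo(back), nodeInfo(net))
    expect_setequal(majorComponent(back), majorComponent(net))
    expect_true(igraph::isomorphic(back@graph, net@graph))
    # SIF: one interaction line per edge plus one bare line per isolate
    s <- withr::local_tempfile(fileext = ".sif")
    exportNetwork(net, s, "sif")
    lines <- readLines(s)
    expect_length(lines, 3)
    expect_equal(sum(grepl(" pp ", lines)), 2)
    expect_true("lone" %in% lines)
    # empty network still writes a valid (empty) file
    emptyNet <- excludeLowConnectivity(net, ppi, 99)
    e <- withr::local_tempfile(fileext = ".sif")
    exportNetwork(emptyNet, e, "sif")
    expect_length(readLines(e), 0)
    eg <- withr::local_tempfile(fileext = ".graphml")
    exportNetwork(emptyNet, eg, "graphml")
    expect_equal(igraph::vcount(
        igraph::read_graph(eg, format = "graphml")), 0)
})

test_that("MITAB records map to gene symbols with identifier fallback", {
    lines <- c(
        "#ID(A)\tID(B)\talt A\talt B\talias A\talias B",
        paste("uniprotkb:P1", "uniprotkb:P2", "-", "-",
              "uniprotkb:TP53(gene name)|x:foo(other)",
              "uniprotkb:MDM2(gene name)", sep = "\t"),
        paste("uniprotkb:P1", "uniprotkb:P3", "-", "-",
              "uniprotkb:TP53(gene name)", "-", sep = "\t"),
        # duplicate of the first pair, reversed -> dropped
        paste("uniprotkb:P2", "uniprotkb:P1", "-", "-",
              "uniprotkb:MDM2(gene name)",
              "uniprotkb:TP53(gene name)", sep = "\t"))
    f <- withr::local_tempfile(fileext = ".mitab")
    writeLines(lines, f)
    ppi <- readMitab(f)
    expect_setequal(interactomeGenes(ppi), c("TP53", "MDM2", "P3"))
    expect_equal(numInteractions(ppi), 2L)
    expect_equal(unname(geneDegree(ppi, "TP53")), 2L)
})
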