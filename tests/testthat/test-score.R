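test_that("pathway filtering partitions retained genes by class occurrence", {
    samples <- data.frame(sample_id = c("s1", "s2"),
                          cancer_type = c("A", "B"),
                          class = c("H", "L"))
    cohort <- SampleCohort(samples,
                           list(s1 = c("g1", "g3", "zz"),
                                s2 = c("g2", "g3")))
    filt <- filterToPathways(cohort, list(P = c("g1", "g2", "g3")))
    expect_equal(filt$summary$total, 3L)
    expect_equal(filt$summary$hOnly, 1L)
    expect_equal(filt$summary$lOnly, 1L)
    expect_equal(filt$summary$shared, 1L)
    expect_equal(filt$summary$shared + filt$summary$hOnly +
                 filt$summary$lOnly, filt$summary$total)
    expect_setequal(upregulatedGenes(filt$cohort, "s1"), c("g1", "g3"))
    # identity pathways leave the profiles unchanged
    all <- filterToPathways(cohort, list(U = c("g1", "g2", "g3", "zz")))
    expect_setequal(upregulatedGenes(all$cohort, "s1"),
                    upregulatedGenes(cohort, "s1"))
    # pathways covering no profiled gene empty every profile
    none <- filterToPathways(cohort, list(P = "unrelated"))
    expect_equal(none$summary$total, 0L)
    expect_length(upregulatedGenes(none$cohort, "s1"), 0)
    expect_error(filterToPathways(cohort, list()), "empty pathway union")
})

test_that("normalized counts follow n / group size with null imputation", {
    cohort <- countsToCohort(c("abl1", "ubiq", "honly"),
                             nH = c(1L, 125L, 10L), nL = c(5L, 135L, 0L))
    stats <- classNormCounts(cohort, "class")
    get <- function(g, cl)
        stats$norm_count[stats$gene == g & stats$group == cl]
    expect_equal(get("abl1", "H"), 0.008)
    expect_equal(get("ubiq", "H"), 1.0)
    expect_equal(get("ubiq", "L"), 1.0)
    expect_equal(get("honly", "L"), 0.0)  # never seen in L
    expect_true(all(stats$norm_count >= 0 & stats$norm_count <= 1))
})

test_that("norm counts are invariant under duplicating every sample", {
    ppi <- simulateInteractome(100, 2, seed = 4)
    design <- defaultCohortDesign(
        ppi, groups = data.frame(cancer_type = c("A", "B"),
                                 class = c("H", "L"), n = c(9L, 7L)),
        seed = 5)
    sim <- simulateCohort(design, ppi)
    s <- sampleInfo(sim$cohort)
    s2 <- rbind(s, transform(s, sample_id = paste0(sample_id, "_dup")))
    ups <- sim$cohort@upregulated
    ups2 <- c(ups, stats::setNames(ups, paste0(names(ups), "_dup")))
    doubled <- SampleCohort(s2, ups2)
    a <- classNormCounts(sim$cohort, "class")
    b <- classNormCounts(doubled, "class")
    expect_equal(b$norm_count, a$norm_count)
    expect_equal(b$n, 2L * a$n)
})

test_that("normalized connections multiply frequency by degree", {
    stats <- makeStats(c("CTNNB1", "GRB2", "zero"),
                       nH = c(81L, 54L, 10L), nL = c(62L, 36L, 5L),
                       degree = c(444L, 753L, 0L))
    nc <- function(g, cl)
        stats$norm_connections[stats$gene == g & stats$group == cl]
    expect_equal(round(nc("CTNNB1", "H"), 1), 287.7)
    expect_equal(round(nc("GRB2", "H"), 1), 325.3)
    expect_equal(nc("zero", "H"), 0)
    expect_true(all(stats$norm_connections <= stats$degree))
    # the package path reproduces the hand-built table from raw profiles
    cohort <- countsToCohort(c("CTNNB1", "GRB2", "zero"),
                             nH = c(81L, 54L, 10L), nL = c(62L, 36L, 5L))
    viaPkg <- normConnections(classNormCounts(cohort, "class"),
                              c(CTNNB1 = 444, GRB2 = 753, zero = 0))
    merged <- merge(viaPkg, stats, by = c("gene", "group"))
    expect_equal(merged$norm_connections.x, merged$norm_connections.y)
    # unknown genes are excluded with a warning
    expect_warning(
        dropped <- normConnections(classNormCounts(cohort, "class"),
                                   c(CTNNB1 = 444, GRB2 = 753)),
        "absent from the interactome")
    expect_false("zero" %in% dropped$gene)
})

test_that("variance filter keeps high-variance and class-exclusive genes", {
    stats <- makeStats(c("flat", "vary", "honly", "lonly"),
                       nH = c(50L, 60L, 12L, 0L),
                       nL = c(54L, 10L, 0L, 30L),
                       degree = c(10L, 10L, 10L, 10L),
                       sizeH = 100L, sizeL = 108L)
    # 'flat' has identical norm counts (0.5) in both classes
    vf <- varianceFilter(stats, threshold = 0.005)
    expect_false("flat" %in% vf$genes)
    expect_true(all(c("vary", "honly", "lonly") %in% vf$genes))
    d <- vf$detail
    expect_equal(d$variance[d$gene == "flat"], 0)
    # two-class values (0.1, 0.3): unbiased sample variance 0.02
    s2 <- makeStats("g", nH = 10L, nL = 30L, degree = 1L,
                    sizeH = 100L, sizeL = 100L)
    vf2 <- varianceFilter(s2, threshold = 0.005)
    expect_equal(vf2$detail$variance, 0.02)
    expect_true("g" %in% vf2$genes)
    # selection is on strict inequality
    expect_false("g" %in% varianceFilter(s2, threshold = 0.02)$genes)
})

test_that("raising the variance threshold never adds genes", {
    stats <- randomStats(80, seed = 31)
    prev <- varianceFilter(stats, threshold = 0)$genes
    for (th in c(0.001, 0.005, 0.02, 0.1)) {
        cur <- varianceFilter(stats, threshold = th)$genes
        expect_true(all(cur %in% prev))
        prev <- cur
    }
    # connection-weighted mode filters on norm_connections
    vfc <- varianceFilter(stats, threshold = 100,
                          on = "norm_connections")
    d <- vfc$detail[vfc$detail$status == "both", ]
    expect_equal(d$selected, d$variance > 100)
})

test_that("hub boundary search recovers a planted exclusive optimum", {
    set.seed(77)
    nBg <- 60
    bg <- data.frame(gene = sprintf("bg%02d", 1:nBg),
                     nc = stats::runif(nBg, 0, 200),
                     f = stats::runif(nBg, 0.01, 0.6))
    planted <- data.frame(gene = sprintf("hub%d", 1:9),
                          nc = c(27, stats::runif(8, 28, 400)),
                          f = c(0.73, stats::runif(8, 0.74, 1)))
    mk <- function(d, cl) data.frame(gene = d$gene, group = cl, n = 1L,
                                     group_size = 10L, norm_count = d$f,
                                     degree = 1, norm_connections = d$nc)
    stats <- rbind(mk(rbind(bg, planted), "H"), mk(bg, "L"))
    hb <- hubBoundarySearch(stats)
    expect_equal(hb@connThreshold, 27)
    expect_equal(hb@freqThreshold, 0.73)
    expect_setequal(boundaryGenes(hb), planted$gene)
    expect_equal(hb@objective, 9)
})

test_that("identical class tables admit no exclusive boundary", {
    stats <- randomStats(40, seed = 8)
    sym <- stats
    sym[sym$group == "L", c("n", "norm_count", "norm_connections")] <-
        sym[sym$group == "H", c("n", "norm_count", "norm_connections")]
    hb <- hubBoundarySearch(sym)
    expect_length(boundaryGenes(hb), 0)
    expect_equal(hb@objective, 0)
})

test_that("hub boundary grid search equals exhaustive brute force", {
    for (s in c(14, 57, 203)) {
        stats <- randomStats(60, seed = s)
        fast <- hubBoundarySearch(stats)
        slow <- bruteBoundary(stats)
        expect_equal(fast@objective, as.numeric(slow$count))
        if (slow$count > 0) {
            expect_equal(fast@connThreshold, slow$c)
            expect_equal(fast@freqThreshold, slow$f)
            expect_identical(boundaryGenes(fast), slow$genes)
        }
    }
})

test_that("class scores are additive and tolerate absent genes", {
    stats <- randomStats(50, seed = 12)
    genes <- unique(stats$gene)
    a <- genes[1:20]; b <- genes[21:50]
    sAB <- classScore(stats, c(a, b))
    expect_equal(sAB$totals,
                 classScore(stats, a)$totals + classScore(stats, b)$totals)
    # a gene absent from L contributes 0 there
    one <- makeStats("solo", nH = 10L, nL = 0L, degree = 50L)
    sc <- classScore(one, "solo")
    expect_equal(unname(sc$totals["L"]), 0)
    expect_equal(classScore(stats, character())$totals, c(H = 0, L = 0))
})
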