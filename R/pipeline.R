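#' @include netx.R
NULL

#' Default pipeline configuration
#'
#' All stage parameters with their standard defaults: upregulation calling
#' at alpha 0.025, variance threshold 0.005, 8 candidate features per
#' split and 50 trees for the classifier, 3 retained components, bridging
#' search up to 6 intermediaries, low-connectivity exclusion at full
#' degree 10. Every stochastic stage derives its own seed from the single
#' top-level seed.
#'
#' @param outDir output directory for all stage artifacts.
#' @param seed master integer seed.
#' @return nested list, suitable for [runPipeline()] after optional
#'   overriding.
#' @export
defaultRunConfig <- function(outDir = tempfile("hubsig_run_"), seed = 1L) {
    list(
        seed = as.integer(seed),
        out_dir = outDir,
        interactome = list(n_genes = 1500L, edges_per_node = 2L),
        pathways = list(genes_per_pathway = 60L, overlap_fraction = 0.2),
        cohort = list(),  # defaults of defaultCohortDesign()
        upcall = list(enabled = TRUE, n_genes = 1000L, n_pairs = 4L,
                      dispersion = 0.1, planted_up_fraction = 0.1,
                      fold_change = 4, alpha = 0.025, pseudocount = 0.5,
                      rule = "normal"),
        score = list(variance_threshold = 0.005, variance_on = "norm_count"),
        pca = list(retained = 3L, center = TRUE, scale = FALSE,
                   hc_distance = "manhattan", hc_linkage = "complete"),
        rfc = list(mtry = 8L, ntree = 50L, top_k = 10L),
        network = list(min_degree_full = 10L, max_intermediaries = 6L,
                       pca_min_total_variance = 1))
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it (recursively) over
#' [defaultRunConfig()], so a config file only needs to state the
#' parameters it overrides.
#'
#' @param file path to a YAML configuration file.
#' @return the merged configuration list.
#' @export
readRunConfig <- function(file) {
    user <- yaml::read_yaml(file)
    base <- defaultRunConfig(
        outDir = if (!is.null(user$out_dir)) user$out_dir
                 else tempfile("hubsig_run_"),
        seed = if (!is.null(user$seed)) user$seed else 1L)
    merge2 <- function(a, b) {
        for (nm in names(b)) {
            a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
                merge2(a[[nm]], b[[nm]]) else b[[nm]]
        }
        a
    }
    merge2(base, user)
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE))
}

#' Run the full synthetic-to-network pipeline
#'
#' Executes every stage in dependency order — simulate (interactome,
#' pathways, cohort), upregulation-calling demonstration on paired counts,
#' pathway filtering, normalized counts/connections, variance filter, hub
#' boundary, class scores, cross-type rank tests, PCA with gene
#' contributions, hierarchical clustering, random-forest classification,
#' and sub-interactome extraction with bridging paths — writing each
#' stage's tables under \code{config$out_dir} plus a JSON manifest of all
#' parameters, seeds, record counts and file digests. Re-running an
#' identical configuration reproduces byte-identical tabular outputs.
#'
#' @param config a configuration list from [defaultRunConfig()] /
#'   [readRunConfig()], or a path to a YAML file.
#' @return invisibly, a list with the in-memory stage results and
#'   \code{manifest}.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
    if (is.character(config)) config <- readRunConfig(config)
    out <- config$out_dir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    seed <- as.integer(config$seed) %% 100000L
    funnel <- list()

    sim <- .stage("simulate", {
        ppi <- simulateInteractome(config$interactome$n_genes,
                                   config$interactome$edges_per_node,
                                   seed = seed + 1L)
        pws <- simulatePathways(
            ppi, genesPerPathway = config$pathways$genes_per_pathway,
            overlapFraction = config$pathways$overlap_fraction,
            seed = seed + 2L)
        design <- do.call(defaultCohortDesign,
                          c(list(interactome = ppi, seed = seed + 3L),
                            config$cohort))
        sim <- simulateCohort(design, ppi)
        writeInteractome(ppi, file.path(out, "interactome.tsv"))
        writePathways(pws, file.path(out, "pathways.tsv"))
        writeCohort(sim$cohort, file.path(out, "profiles.tsv"))
        list(ppi = ppi, pathways = pws, design = design,
             cohort = sim$cohort, truth = sim$truth)
    })
    funnel$genes_observed <-
        length(unique(unlist(sim$cohort@upregulated, use.names = FALSE)))

    upcall <- NULL
    if (isTRUE(config$upcall$enabled)) {
        upcall <- .stage("upcall", {
            pc <- simulatePairedCounts(
                nGenes = config$upcall$n_genes,
                nPairs = config$upcall$n_pairs,
                dispersion = config$upcall$dispersion,
                plantedUpFraction = config$upcall$planted_up_fraction,
                foldChange = config$upcall$fold_change,
                seed = seed + 4L)
            calls <- lapply(colnames(pc$tumor), function(p)
                callUpregulated(pc$tumor[, p], pc$control[, p],
                                pc$lengths,
                                alpha = config$upcall$alpha,
                                pseudocount = config$upcall$pseudocount,
                                rule = config$upcall$rule, pairId = p))
            writeCalls(calls, file.path(out, "upcall.tsv"))
            called <- lapply(calls, `[[`, "upregulated")
            sens <- mean(vapply(called, function(g)
                mean(pc$truth$planted %in% g), 0))
            list(calls = calls, truth = pc$truth,
                 meanSensitivity = sens)
        })
    }

    score <- .stage("score", {
        filt <- filterToPathways(sim$cohort, sim$pathways)
        stats <- normConnections(classNormCounts(filt$cohort, "class"),
                                 sim$ppi)
        vf <- varianceFilter(stats,
                             threshold = config$score$variance_threshold,
                             on = config$score$variance_on)
        boundary <- hubBoundarySearch(stats)
        scores <- classScore(stats, vf$genes)
        writeStats(stats, file.path(out, "class_stats.tsv"))
        jsonlite::write_json(
            list(conn_threshold = boundary@connThreshold,
                 freq_threshold = boundary@freqThreshold,
                 genes = boundary@genes,
                 objective = boundary@objective,
                 class_scores = as.list(scores$totals),
                 relative_difference_pct = scores$relativeDifference),
            file.path(out, "hub_boundary.json"), auto_unbox = TRUE,
            digits = NA)
        list(filtered = filt, stats = stats, selection = vf,
             boundary = boundary, scores = scores)
    })
    funnel$genes_in_pathways <- score$filtered$summary$total
    funnel$genes_selected <- length(score$selection$genes)

    groupstats <- .stage("groupstats", {
        obs <- connectionObservations(score$filtered$cohort, sim$ppi,
                                      pathways = sim$pathways)
        kw <- kruskalByPathway(obs)
        pw <- pairwiseWilcoxon(obs)
        writeStats(kw, file.path(out, "kruskal.tsv"))
        writeStats(pw, file.path(out, "pairwise_wilcoxon.tsv"))
        list(kruskal = kw, pairwise = pw)
    })

    pca <- .stage("pca", {
        typeStats <- normConnections(
            classNormCounts(score$filtered$cohort, "cancer_type"),
            sim$ppi)
        classOf <- stats::setNames(sim$design@groups$class,
                                   sim$design@groups$cancer_type)
        mat <- buildFeatureMatrix(typeStats, score$selection$genes,
                                  classOf = classOf)
        dec <- runPCA(mat, center = config$pca$center,
                      scale = config$pca$scale)
        contrib <- geneContributions(dec, retained = config$pca$retained)
        hc <- hierarchicalCluster(mat,
                                  distance = config$pca$hc_distance,
                                  linkage = config$pca$hc_linkage)
        utils::write.csv(contrib,
                         file.path(out, "gene_contributions.csv"),
                         row.names = FALSE)
        writeNewick(hc$tree, file.path(out, "dendrogram.nwk"))
        jsonlite::write_json(
            list(proportions = dec@proportions,
                 cumulative = dec@cumulative,
                 hc_purity = hc$purity),
            file.path(out, "pca_summary.json"), digits = NA)
        list(matrix = mat, decomposition = dec, contributions = contrib,
             hc = hc)
    })

    rfc <- .stage("rfc", {
        sf <- buildSampleFeatures(score$filtered$cohort, sim$ppi,
                                  score$selection$genes)
        fit <- trainRFC(sf$features, sf$labels,
                        mtry = config$rfc$mtry, ntree = config$rfc$ntree,
                        seed = seed + 5L)
        rank <- importanceRanking(fit, topK = config$rfc$top_k)
        writeStats(rank, file.path(out, "rfc_importance.tsv"))
        jsonlite::write_json(
            list(confusion = unclass(confusionMatrix(fit)),
                 class_errors = as.list(fit@classErrors),
                 oob_error = oobError(fit), params = fit@params),
            file.path(out, "rfc_result.json"), auto_unbox = TRUE,
            digits = NA, matrix = "rowmajor")
        list(features = sf, fit = fit, ranking = rank)
    })

    network <- .stage("network", {
        pcaGenes <- pca$contributions$gene[
            pca$contributions$pct_total_variance >=
                config$network$pca_min_total_variance]
        rfcGenes <- rfc$ranking$gene
        genes <- union(pcaGenes, rfcGenes)
        src <- stats::setNames(
            ifelse(genes %in% pcaGenes & genes %in% rfcGenes, "both",
                   ifelse(genes %in% pcaGenes, "pca", "rfc")), genes)
        net <- extractSubnetwork(genes, sim$ppi, source = src)
        net <- excludeLowConnectivity(net, sim$ppi,
                                      config$network$min_degree_full)
        outside <- setdiff(networkGenes(net), majorComponent(net))
        bridges <- stats::setNames(lapply(outside, function(g)
            bridgePaths(g, net, sim$ppi,
                        config$network$max_intermediaries)), outside)
        exportNetwork(net, file.path(out, "subnetwork.graphml"),
                      "graphml")
        exportNetwork(net, file.path(out, "subnetwork.sif"), "sif")
        jsonlite::write_json(
            list(genes = networkGenes(net),
                 component_sizes = componentSizes(net),
                 major_component = majorComponent(net),
                 bridges = lapply(bridges, function(b)
                     lapply(b, function(p) p[c("origin", "terminal",
                                               "intermediaries",
                                               "length")]))),
            file.path(out, "network_report.json"), auto_unbox = TRUE,
            digits = NA)
        list(subnetwork = net, bridges = bridges)
    })

    tabular <- list.files(out, pattern = "\\.(tsv|csv|nwk|sif)$",
                          full.names = TRUE)
    manifest <- list(
        package = "hubsig",
        version = as.character(utils::packageVersion("hubsig")),
        r_version = paste(R.version$major, R.version$minor, sep = "."),
        timestamp = format(Sys.time(), tz = "UTC"),
        config = config[setdiff(names(config), "out_dir")],
        stage_seeds = list(interactome = seed + 1L, pathways = seed + 2L,
                           cohort = seed + 3L, paired_counts = seed + 4L,
                           rfc = seed + 5L),
        funnel = funnel,
        digests = as.list(stats::setNames(
            unname(tools::md5sum(tabular)), basename(tabular))))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(simulate = sim, upcall = upcall, score = score,
                   groupstats = groupstats, pca = pca, rfc = rfc,
                   network = network, manifest = manifest,
                   out_dir = out))
}
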