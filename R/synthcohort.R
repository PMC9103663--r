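#' @include interactome.R
NULL

.padGenes <- function(n) {
    sprintf(paste0("G%0", max(4L, nchar(n)), "d"), seq_len(n))
}

#' Simulate a scale-free interactome by preferential attachment
#'
#' Grows an undirected graph one gene at a time: starting from a complete
#' graph on \code{edgesPerNode + 1} genes, every new gene attaches to
#' \code{edgesPerNode} distinct existing genes sampled with probability
#' proportional to their current degree. The result is connected with a
#' heavy-tailed degree distribution: few high-degree hubs and many
#' low-degree genes, as in real signaling networks.
#'
#' @param nGenes total number of genes; must exceed \code{edgesPerNode}.
#' @param edgesPerNode edges added per new gene (attachment parameter).
#' @param seed integer seed; identical arguments reproduce identical edge
#'   sets.
#' @return an [Interactome-class] with genes named \code{"G0001"}, ...
#' @examples
#' ppi <- simulateInteractome(200, 2, seed = 1)
#' max(geneDegree(ppi))
#' @export
simulateInteractome <- function(nGenes, edgesPerNode = 2L, seed = 1L) {
    nGenes <- as.integer(nGenes)
    m <- as.integer(edgesPerNode)
    if (m < 1L) stop("'edgesPerNode' must be a positive integer")
    if (nGenes <= m)
        stop("'nGenes' must be strictly greater than 'edgesPerNode'")
    el <- withr::with_seed(seed, {
        n0 <- m + 1L
        seedEdges <- t(utils::combn(seq_len(n0), 2L))
        deg <- integer(nGenes)
        deg[seq_len(n0)] <- n0 - 1L
        grown <- vector("list", max(0L, nGenes - n0))
        if (nGenes > n0) {
            for (i in (n0 + 1L):nGenes) {
                existing <- seq_len(i - 1L)
                targets <- sample(existing, size = m,
                                  prob = deg[existing], replace = FALSE)
                deg[targets] <- deg[targets] + 1L
                deg[i] <- m
                grown[[i - n0]] <- cbind(rep.int(i, m), targets)
            }
        }
        rbind(seedEdges, do.call(rbind, grown))
    })
    genes <- .padGenes(nGenes)
    Interactome(cbind(genes[el[, 1L]], genes[el[, 2L]]))
}

#' Simulate overlapping pathway annotations
#'
#' Assigns genes to named pathways so that every unordered pathway pair
#' shares the same core of genes: each pathway is the union of a common
#' core of size \code{round(overlapFraction * genesPerPathway)} and its own
#' private genes, so the pairwise overlap fraction equals
#' \code{overlapFraction} exactly (up to the rounding of the core size).
#'
#' @param interactome an [Interactome-class] providing the gene universe.
#' @param pathwayNames character vector of pathway names; defaults to the
#'   WNT pathway and its seven cross-linked signaling pathways.
#' @param genesPerPathway genes in every pathway.
#' @param overlapFraction in \[0, 1\]: shared fraction of each pathway.
#' @param seed integer seed.
#' @return named list of character vectors (pathway -> member genes).
#' @export
simulatePathways <- function(interactome,
                             pathwayNames = c("WNT", "EGF", "FGF",
                                              "HEDGEHOG", "mTOR", "NFKB",
                                              "NOTCH", "TGFB"),
                             genesPerPathway = 60L,
                             overlapFraction = 0.2,
                             seed = 1L) {
    stopifnot(overlapFraction >= 0, overlapFraction <= 1,
              genesPerPathway >= 1)
    universe <- interactomeGenes(interactome)
    nP <- length(pathwayNames)
    core <- round(overlapFraction * genesPerPathway)
    private <- genesPerPathway - core
    need <- core + nP * private
    if (need > length(universe))
        stop(sprintf(
            "impossible size/overlap combination: %d genes needed, %d available",
            need, length(universe)))
    withr::with_seed(seed, {
        pool <- sample(universe, need)
        coreGenes <- pool[seq_len(core)]
        rest <- pool[-seq_len(core)]
        out <- vector("list", nP)
        for (i in seq_len(nP)) {
            own <- if (private > 0)
                rest[((i - 1L) * private + 1L):(i * private)]
            else character()
            out[[i]] <- sort(c(coreGenes, own))
        }
        names(out) <- pathwayNames
        out
    })
}

#' Construct a cohort design
#'
#' @param groups data.frame with columns \code{cancer_type}, \code{class}
#'   (H/L) and \code{n}.
#' @param freqH,freqL named per-gene upregulation probabilities for the H
#'   and L classes (same gene names, values in \[0, 1\]).
#' @param seed integer seed used by [simulateCohort()].
#' @param truth optional list of ground-truth annotations.
#' @return a [CohortDesign-class].
#' @export
cohortDesign <- function(groups, freqH, freqL, seed = 1L, truth = list()) {
    methods::new("CohortDesign",
                 groups = as.data.frame(groups), freqH = freqH,
                 freqL = freqL, seed = as.integer(seed), truth = truth)
}

#' Default six-type cohort design with planted hub enrichment
#'
#' Builds the study-condition design used throughout the package's tests
#' and examples: six cancer types split into H (STAD 27, LUSC 48, LIHC 50)
#' and L (KIRP 31, THCA 56, PRAD 48), a baseline per-gene upregulation
#' frequency shared by both classes, hub genes (degree at or above the
#' \code{hubQuantile} quantile) enriched in the H class, and class-exclusive
#' genes whose frequency in the other class is exactly zero.
#'
#' @param interactome an [Interactome-class].
#' @param groups group table; defaults to the six-type design above
#'   (125 H / 135 L samples in total).
#' @param hubQuantile degree quantile above which genes are planted as
#'   H-enriched hubs.
#' @param hubFreqH,hubFreqL ranges (min, max) of hub upregulation
#'   frequencies in H and L; the ranges must not overlap so planted hubs are
#'   strictly H-enriched.
#' @param baseFreq range of baseline frequencies for unplanted genes.
#' @param hOnlyFraction,lOnlyFraction fractions of non-hub genes made
#'   exclusive to H (frequency 0 in L) or to L.
#' @param exclusiveFreq frequency range of class-exclusive genes in their
#'   own class.
#' @param seed integer seed (drives both the frequency draws and, through
#'   the design, the cohort sampling).
#' @return a [CohortDesign-class] whose \code{truth} records
#'   \code{hubGenes}, \code{hOnly}, \code{lOnly} and the frequency vectors.
#' @export
defaultCohortDesign <- function(interactome,
                                groups = data.frame(
                                    cancer_type = c("STAD", "LUSC", "LIHC",
                                                    "KIRP", "THCA", "PRAD"),
                                    class = c("H", "H", "H", "L", "L", "L"),
                                    n = c(27L, 48L, 50L, 31L, 56L, 48L)),
                                hubQuantile = 0.9,
                                hubFreqH = c(0.6, 0.95),
                                hubFreqL = c(0.05, 0.3),
                                baseFreq = c(0.02, 0.35),
                                hOnlyFraction = 0.06,
                                lOnlyFraction = 0.025,
                                exclusiveFreq = c(0.1, 0.5),
                                seed = 1L) {
    stopifnot(max(hubFreqL) < min(hubFreqH))
    deg <- geneDegree(interactome)
    genes <- names(deg)
    nG <- length(genes)
    withr::with_seed(seed, {
        base <- stats::runif(nG, baseFreq[1L], baseFreq[2L])
        freqH <- freqL <- stats::setNames(base, genes)
        hub <- genes[deg >= stats::quantile(deg, hubQuantile)]
        freqH[hub] <- stats::runif(length(hub), hubFreqH[1L], hubFreqH[2L])
        freqL[hub] <- stats::runif(length(hub), hubFreqL[1L], hubFreqL[2L])
        nonHub <- setdiff(genes, hub)
        nH <- round(hOnlyFraction * nG)
        nL <- round(lOnlyFraction * nG)
        excl <- sample(nonHub, min(nH + nL, length(nonHub)))
        hOnly <- utils::head(excl, nH)
        lOnly <- utils::tail(excl, length(excl) - length(hOnly))
        freqH[hOnly] <- stats::runif(length(hOnly),
                                     exclusiveFreq[1L], exclusiveFreq[2L])
        freqL[hOnly] <- 0
        freqL[lOnly] <- stats::runif(length(lOnly),
                                     exclusiveFreq[1L], exclusiveFreq[2L])
        freqH[lOnly] <- 0
        cohortDesign(groups, freqH, freqL, seed = seed,
                     truth = list(hubGenes = hub, hOnly = hOnly,
                                  lOnly = lOnly, freqH = freqH,
                                  freqL = freqL))
    })
}

#' Construct a SampleCohort
#'
#' @param samples data.frame with columns \code{sample_id},
#'   \code{cancer_type}, \code{class}.
#' @param upregulated list of character vectors named by \code{sample_id}.
#' @return a [SampleCohort-class].
#' @export
SampleCohort <- function(samples, upregulated) {
    samples <- as.data.frame(samples)
    samples$sample_id <- as.character(samples$sample_id)
    methods::new("SampleCohort", samples = samples,
                 upregulated = upregulated[samples$sample_id])
}

#' @describeIn SampleCohort-class the per-sample metadata table.
#' @export
setMethod("sampleInfo", "SampleCohort", function(x, ...) x@samples)

#' @describeIn SampleCohort-class upregulated genes of one sample
#'   (\code{sample} given) or the full named list.
#' @param sample optional sample identifier.
#' @export
setMethod("upregulatedGenes", "SampleCohort", function(x, sample = NULL, ...) {
    if (is.null(sample)) return(x@upregulated)
    if (!sample %in% names(x@upregulated))
        stop("unknown sample: ", sample)
    x@upregulated[[sample]]
})

#' @describeIn SampleCohort-class number of samples.
#' @export
setMethod("nSamples", "SampleCohort", function(x) nrow(x@samples))

setMethod("show", "SampleCohort", function(object) {
    s <- object@samples
    cat(sprintf("SampleCohort: %d samples (%d H, %d L) over %d cancer types\n",
                nrow(s), sum(s$class == "H"), sum(s$class == "L"),
                length(unique(s$cancer_type))))
    cat(sprintf("  upregulated genes per sample: median %g\n",
                stats::median(lengths(object@upregulated))))
})

#' Simulate a class-structured upregulation cohort
#'
#' Draws, for every sample of every group in the design, each gene's
#' upregulation as an independent Bernoulli event at the gene's
#' class-specific frequency. The empirical class frequency of any gene
#' therefore converges to its design frequency as sample count grows.
#'
#' @param design a [CohortDesign-class].
#' @param interactome an [Interactome-class]; every designed gene must be
#'   one of its genes.
#' @return list with elements \code{cohort} (a [SampleCohort-class]) and
#'   \code{truth} (the design's ground-truth list, augmented with the
#'   frequency vectors).
#' @export
simulateCohort <- function(design, interactome) {
    stopifnot(methods::is(design, "CohortDesign"))
    genes <- names(design@freqH)
    unknown <- setdiff(genes, interactomeGenes(interactome))
    if (length(unknown))
        stop(sprintf("%d designed gene(s) not in the interactome: %s",
                     length(unknown),
                     paste(utils::head(unknown, 5L), collapse = ", ")))
    g <- design@groups
    withr::with_seed(design@seed, {
        meta <- list(); ups <- list()
        for (i in seq_len(nrow(g))) {
            n <- g$n[i]
            freq <- if (g$class[i] == "H") design@freqH else design@freqL
            ids <- sprintf("%s_%s_%03d", g$cancer_type[i], g$class[i],
                           seq_len(n))
            draw <- matrix(stats::runif(n * length(genes)), nrow = n) <
                matrix(freq, nrow = n, ncol = length(genes), byrow = TRUE)
            ups <- c(ups, stats::setNames(
                lapply(seq_len(n), function(j) genes[draw[j, ]]), ids))
            meta[[i]] <- data.frame(sample_id = ids,
                                    cancer_type = g$cancer_type[i],
                                    class = g$class[i])
        }
        cohort <- SampleCohort(do.call(rbind, meta), ups)
        truth <- design@truth
        truth$freqH <- design@freqH
        truth$freqL <- design@freqL
        list(cohort = cohort, truth = truth)
    })
}

#' Simulate paired tumor/control count tables
#'
#' Negative-binomial paired counts for an upregulation-calling stage:
#' per-gene expected expression is drawn log-normally and scaled by the
#' gene's coding-sequence length; a planted fraction of genes has its tumor
#' mean multiplied by \code{foldChange}.
#'
#' @param nGenes,nPairs table dimensions.
#' @param dispersion negative-binomial dispersion (\code{size = 1 /
#'   dispersion}); must be positive.
#' @param plantedUpFraction fraction of genes planted as upregulated.
#' @param foldChange tumor/control mean ratio of planted genes; must
#'   exceed 1.
#' @param meanLog,sdLog log-normal parameters of per-gene baseline
#'   expression (per kilobase of coding sequence).
#' @param seed integer seed.
#' @return list with \code{tumor} and \code{control} (gene x pair integer
#'   matrices), \code{lengths} (named CDS lengths, bp) and \code{truth}
#'   (planted gene names, fold change).
#' @export
simulatePairedCounts <- function(nGenes = 2000L, nPairs = 30L,
                                 dispersion = 0.1,
                                 plantedUpFraction = 0.1,
                                 foldChange = 4,
                                 meanLog = log(300), sdLog = 1,
                                 seed = 1L) {
    if (dispersion <= 0) stop("'dispersion' must be positive")
    if (foldChange <= 1) stop("'foldChange' must be greater than 1")
    stopifnot(plantedUpFraction >= 0, plantedUpFraction <= 1)
    genes <- .padGenes(nGenes)
    withr::with_seed(seed, {
        lengths <- stats::setNames(round(stats::runif(nGenes, 500, 5000)),
                                   genes)
        baseMu <- stats::rlnorm(nGenes, meanLog, sdLog) * lengths / 1000
        planted <- sort(sample(genes, round(plantedUpFraction * nGenes)))
        muT <- baseMu
        muT[genes %in% planted] <- muT[genes %in% planted] * foldChange
        size <- 1 / dispersion
        draw <- function(mu) {
            m <- matrix(stats::rnbinom(nGenes * nPairs,
                                       mu = rep(mu, nPairs), size = size),
                        nrow = nGenes,
                        dimnames = list(genes,
                                        sprintf("pair%02d", seq_len(nPairs))))
            m
        }
        list(tumor = draw(muT), control = draw(baseMu), lengths = lengths,
             truth = list(planted = planted, foldChange = foldChange,
                          plantedUpFraction = plantedUpFraction))
    })
}

#' Read / write cohort profile tables
#'
#' The interchange format is a long TSV with one row per (sample, gene):
#' columns \code{sample_id}, \code{cancer_type}, \code{class}, \code{gene}.
#' Samples with no upregulated genes are preserved with an empty gene field.
#'
#' @param x a [SampleCohort-class].
#' @param file path to a TSV file.
#' @return the reader returns a [SampleCohort-class]; the writer invisibly
#'   returns \code{file}.
#' @export
writeCohort <- function(x, file) {
    s <- sampleInfo(x)
    rows <- lapply(seq_len(nrow(s)), function(i) {
        genes <- x@upregulated[[s$sample_id[i]]]
        if (!length(genes)) genes <- ""
        data.frame(sample_id = s$sample_id[i],
                   cancer_type = s$cancer_type[i],
                   class = s$class[i], gene = genes)
    })
    utils::write.table(do.call(rbind, rows), file, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' @rdname writeCohort
#' @export
readCohort <- function(file) {
    df <- utils::read.table(file, header = TRUE, sep = "\t",
                            colClasses = "character", quote = "")
    samples <- unique(df[, c("sample_id", "cancer_type", "class")])
    rownames(samples) <- NULL
    ups <- lapply(split(df$gene, df$sample_id),
                  function(g) unique(g[nzchar(g)]))
    SampleCohort(samples, ups[samples$sample_id])
}

#' Write pathway membership as a two-column TSV
#'
#' @param pathways named list of character vectors.
#' @param file path to a TSV file.
#' @export
writePathways <- function(pathways, file) {
    df <- data.frame(pathway = rep(names(pathways), lengths(pathways)),
                     gene = unlist(pathways, use.names = FALSE))
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' @rdname writePathways
#' @export
readPathways <- function(file) {
    df <- utils::read.table(file, header = TRUE, sep = "\t",
                            colClasses = "character", quote = "")
    lapply(split(df$gene, df$pathway), unique)
}
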