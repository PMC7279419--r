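# File interfaces: delimited expression matrices, label files, statistics and
# frequency tables mirroring the reference table layouts, and the end-to-end
# pipeline driver.

#' Read an expression matrix and sample labels
#'
#' The expression file is delimited text with a header row of sample ids and
#' probes as rows (first column = probe id). The label file has two columns:
#' sample id, class. Parse errors (ragged rows, duplicate ids, non-numeric
#' cells) are reported with their location.
#'
#' @param exprPath path to the expression table (TSV by default).
#' @param labelPath path to the two-column label table.
#' @param scale \code{"raw"} or \code{"log2"}.
#' @param classLevels optional length-2 class order (control-like first).
#' @param sep field separator (default tab).
#' @return A [PhenotypeExperiment-class].
#' @export
readExpression <- function(exprPath, labelPath, scale = c("raw", "log2"),
                           classLevels = NULL, sep = "\t") {
  scale <- match.arg(scale)
  nf <- utils::count.fields(exprPath, sep = sep, quote = "")
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop("ragged expression file: line ", bad, " has ", nf[bad],
         " fields, expected ", nf[1L])
  }
  raw <- utils::read.delim(exprPath, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character")
  probes <- raw[[1L]]
  if (anyDuplicated(probes)) {
    stop("duplicate probe id at row ",
         which(duplicated(probes))[1L], ": ", probes[duplicated(probes)][1L])
  }
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicate sample id: ", samples[duplicated(samples)][1L])
  }
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at row %d (probe '%s'), column '%s'",
                 bad[1L], probes[bad[1L]], samples[bad[2L]]))
  }
  vals <- matrix(vals, nrow = nrow(raw), dimnames = list(probes, samples))
  labels <- utils::read.delim(labelPath, sep = sep, header = FALSE,
                              colClasses = "character")
  if (ncol(labels) < 2L) stop("label file needs two columns: sample id, class")
  cls <- stats::setNames(labels[[2L]], labels[[1L]])
  if (!all(samples %in% names(cls))) {
    stop("samples without labels: ",
         paste(utils::head(setdiff(samples, names(cls)), 3L), collapse = ", "))
  }
  PhenotypeExperiment(vals, cls[samples], scale = scale,
                      classLevels = classLevels)
}

#' Write an expression matrix and sample labels
#'
#' Inverse of [readExpression()]: values round-trip bit-identically through
#' full-precision formatting.
#'
#' @param pe a [PhenotypeExperiment-class].
#' @param exprPath,labelPath output paths.
#' @param sep field separator (default tab).
#' @return \code{exprPath}, invisibly.
#' @export
writeExpression <- function(pe, exprPath, labelPath, sep = "\t") {
  x <- exprValues(pe)
  df <- data.frame(probeId = rownames(x),
                   format(x, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, exprPath, sep = sep, quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(x), class = as.character(phenoClasses(pe))),
    labelPath, sep = sep, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(exprPath)
}

#' Write per-gene statistics as a TSV
#'
#' Mirrors the reference layout (Gene, Mean-A, Std-A, Mean-B, Std-B, FC, FR);
#' full precision by default, 2 decimals with \code{round2 = TRUE}.
#'
#' @param stats data.frame from [geneStatistics()].
#' @param path output path.
#' @param round2 round FC/FR and moments to 2 decimals for display.
#' @return \code{path}, invisibly.
#' @export
writeGeneStatistics <- function(stats, path, round2 = FALSE) {
  out <- stats
  if (round2) out[-1L] <- lapply(out[-1L], round, digits = 2L)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a frequency table as a TSV
#'
#' Joins the posterior sampling-frequency ranking with the per-gene group
#' means, FC and FR (when \code{stats} is supplied), mirroring the reference
#' frequency-table layout.
#'
#' @param ft a [FrequencyTable-class].
#' @param path output path.
#' @param stats optional data.frame from [geneStatistics()].
#' @return \code{path}, invisibly.
#' @export
writeFrequencyTable <- function(ft, path, stats = NULL) {
  df <- frequencyData(ft)
  if (!is.null(stats)) {
    i <- match(df$probeId, stats$probeId)
    df <- cbind(df[1L], meanA = stats$meanA[i], meanB = stats$meanB[i],
                fc = stats$fc[i], fr = stats$fr[i], df[-1L])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Keys (all optional, defaults in parentheses): \code{comparison}
#' ("control_vs_case"), \code{frCutoff} (0.5), \code{nBags} (1000),
#' \code{trainFraction} (0.75), \code{accuracyThreshold} (80), \code{k} (1),
#' \code{maxPrefix} (200), \code{seed} (1), \code{samplers}
#' (c("holdout")), \code{topN} (10), \code{expression}/\code{labels} input
#' paths, \code{geneSets} GMT path, \code{scale} ("raw").
#'
#' @param path YAML file path.
#' @return Named list merged over the defaults.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  defaults <- list(comparison = "control_vs_case", frCutoff = 0.5,
                   nBags = 1000L, trainFraction = 0.75,
                   accuracyThreshold = 80, k = 1L, maxPrefix = 200L,
                   seed = 1L, samplers = "holdout", topN = 10L,
                   scale = "raw")
  utils::modifyList(defaults, user)
}

#' Run the full analysis pipeline
#'
#' Executes transform -> statistics -> sampler(s) -> frequency tables ->
#' network (-> enrichment when a gene-set collection is given) on an
#' experiment and writes the report bundle to \code{outDir}: per-gene
#' statistics, one frequency table per sampler, a sampler-comparison summary
#' when several samplers ran, the bag-level log, the correlation-network edge
#' list over the top-ranked genes, the enrichment table, a 2-decimal report
#' table, and a manifest (seed, parameters, versions) sufficient to reproduce
#' the run. On a stage failure the partial outputs are removed and the stage
#' is named in the error.
#'
#' @param pe a [PhenotypeExperiment-class] (raw or log2 scale). Alternatively
#'   NULL to read from \code{config$expression}/\code{config$labels}.
#' @param outDir output directory (created if needed).
#' @param config named list of parameters (see [readPipelineConfig()]).
#' @return Invisibly, a list with the in-memory results (\code{stats},
#'   \code{bags}, \code{accepted}, \code{frequency}, \code{tables},
#'   \code{comparison}, \code{network}, \code{enrichment}, \code{files}).
#' @export
runPipeline <- function(pe = NULL, outDir, config = list()) {
  cfg <- utils::modifyList(
    list(comparison = "control_vs_case", frCutoff = 0.5, nBags = 1000L,
         trainFraction = 0.75, accuracyThreshold = 80, k = 1L,
         maxPrefix = 200L, seed = 1L, samplers = "holdout", topN = 10L,
         scale = "raw"),
    config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(writer, file, ...) {
    path <- file.path(outDir, file)
    writer(..., path)
    written <<- c(written, path)
    path
  }
  stage <- "input"
  tryCatch({
    if (is.null(pe)) {
      pe <- readExpression(cfg$expression, cfg$labels, scale = cfg$scale)
    }
    stage <- "transform"
    if (exprScale(pe) == "raw") pe <- log2Transform(pe)
    stage <- "statistics"
    stats <- geneStatistics(pe)
    emit(function(s, p) writeGeneStatistics(s, p), "gene_statistics.tsv", stats)
    stage <- "sampling"
    tables <- list()
    bags <- accepted <- NULL
    if ("holdout" %in% cfg$samplers) {
      bags <- runHoldoutSampler(pe, frCutoff = cfg$frCutoff,
                                nBags = cfg$nBags, k = cfg$k,
                                maxPrefix = cfg$maxPrefix,
                                trainFraction = cfg$trainFraction,
                                seed = cfg$seed)
      bagLog <- data.frame(
        bagId = vapply(bags, function(b) b@bagId, integer(1L)),
        signatureLength = vapply(bags, function(b)
          length(b@signature@genes), integer(1L)),
        learnAccuracy = vapply(bags, function(b)
          b@signature@accuracy, numeric(1L)),
        validationAccuracy = vapply(bags, function(b)
          b@validationAccuracy, numeric(1L)))
      emit(function(d, p) utils::write.csv(d, p, row.names = FALSE),
           "bag_log.csv", bagLog)
      accepted <- filterByAccuracy(bags, cfg$accuracyThreshold)
      if (length(accepted)) {
        tables$holdout <- frequencyTable(accepted)
      }
    }
    if ("fisher" %in% cfg$samplers) {
      tables$fisher <- runFisherSampler(pe, nDraws = cfg$nBags,
                                        frCutoff = cfg$frCutoff,
                                        acceptThreshold = cfg$accuracyThreshold,
                                        k = cfg$k, seed = cfg$seed)
    }
    if ("rf" %in% cfg$samplers) {
      tables$rf <- runForestSampler(pe, seed = cfg$seed)
    }
    stage <- "frequency tables"
    for (nm in names(tables)) {
      emit(function(ft, p) writeFrequencyTable(ft, p, stats = stats),
           paste0("frequency_", nm, ".tsv"), tables[[nm]])
    }
    comparison <- NULL
    if (length(tables) >= 2L) {
      comparison <- compareSamplers(tables, topN = cfg$topN)
      emit(function(d, p) utils::write.table(d, p, sep = "\t", quote = FALSE,
                                             row.names = FALSE),
           "sampler_comparison.tsv", comparison)
    }
    stage <- "network"
    network <- NULL
    if (length(tables)) {
      top <- utils::head(frequencyData(tables[[1L]])$probeId, cfg$topN)
      if (length(top) >= 2L) {
        network <- correlationNetwork(pe, top)
        emit(function(g, p) writeEdgeList(g, p), "network_edges.tsv", network)
      }
    }
    stage <- "enrichment"
    enrichment <- NULL
    if (!is.null(cfg$geneSets) && length(tables)) {
      sets <- readGeneSets(cfg$geneSets)
      universe <- unique(rankGenes(stats, cfg$frCutoff))
      top <- intersect(utils::head(frequencyData(tables[[1L]])$probeId,
                                   cfg$topN), universe)
      if (length(top)) {
        enrichment <- overrepresentation(top, sets, universe)
        emit(function(d, p) utils::write.table(d, p, sep = "\t", quote = FALSE,
                                               row.names = FALSE),
             "enrichment.tsv", enrichment)
      }
    }
    stage <- "report"
    emit(function(s, p) writeGeneStatistics(s, p, round2 = TRUE),
         "gene_statistics_report.tsv",
         utils::head(stats[order(stats$fr, decreasing = TRUE), ], 50L))
    manifest <- list(comparison = cfg$comparison, seed = cfg$seed,
                     parameters = cfg[c("frCutoff", "nBags", "trainFraction",
                                        "accuracyThreshold", "k", "maxPrefix",
                                        "samplers", "topN")],
                     nProbes = nrow(pe), nSamples = ncol(pe),
                     classes = levels(phenoClasses(pe)),
                     packageVersion =
                       as.character(utils::packageVersion("phenoSampler")),
                     rVersion = R.version.string)
    emit(function(m, p) yaml::write_yaml(m, p), "manifest.yaml", manifest)
    invisible(list(stats = stats, bags = bags, accepted = accepted,
                   frequency = tables[[1L]], tables = tables,
                   comparison = comparison, network = network,
                   enrichment = enrichment, files = written))
  }, error = function(e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}
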