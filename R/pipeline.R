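#' Assemble a pipeline run configuration
#'
#' All stage thresholds with their standard defaults (DE alpha 0.01;
#' network |r| > 0.8, p < 0.01; QC 200 / 3 / 5000 / 0.30; enrichment FDR
#' 0.05; integration hop limit 1), the synthetic-data parameters used when
#' no input files are given, and the master seed. The configuration is
#' serialized verbatim into the output directory so a run can be reproduced
#' exactly.
#'
#' @param seed master seed for every stochastic stage.
#' @param alpha DE significance level (raw p).
#' @param rThreshold,pThreshold network retention thresholds.
#' @param minGenes,minCells,maxGenes,maxMito single-cell QC thresholds.
#' @param fdrThreshold enrichment significance threshold.
#' @param hops integration neighborhood radius.
#' @param bulk named list of [simulateBulk()] arguments (less the seed).
#' @param sc `NULL` to skip the single-cell stage, otherwise a named list of
#'   [simulateSC()] arguments (less the seed).
#' @param matrixPath,groupPath optional expression TSV and two-column sample
#'   metadata TSV (sample, group) to analyze instead of simulating; requires
#'   `biotypePath`.
#' @param biotypePath optional two-column gene annotation TSV (gene,
#'   biotype).
#' @param caseGroup,controlGroup group labels compared.
#' @param gmtPath optional GMT file for enrichment; when absent, a
#'   simulated collection over the matrix universe is used.
#' @param ppiPath,tfPath optional edge-list TSVs for the integration stage.
#' @param excludedSets set ids excluded from enrichment (disease-specific
#'   pathways).
#' @return a named list (class `lncnetConfig`).
#' @export
pipelineConfig <- function(seed = 1, alpha = 0.01, rThreshold = 0.8,
                           pThreshold = 0.01, minGenes = 200, minCells = 3,
                           maxGenes = 5000, maxMito = 0.30,
                           fdrThreshold = 0.05, hops = 1,
                           bulk = list(), sc = NULL,
                           matrixPath = NULL, groupPath = NULL,
                           biotypePath = NULL,
                           caseGroup = "IPF", controlGroup = "normal",
                           gmtPath = NULL, ppiPath = NULL, tfPath = NULL,
                           excludedSets = character()) {
  cfg <- list(seed = seed, alpha = alpha, rThreshold = rThreshold,
              pThreshold = pThreshold, minGenes = minGenes,
              minCells = minCells, maxGenes = maxGenes, maxMito = maxMito,
              fdrThreshold = fdrThreshold, hops = hops, bulk = bulk, sc = sc,
              matrixPath = matrixPath, groupPath = groupPath,
              biotypePath = biotypePath, caseGroup = caseGroup,
              controlGroup = controlGroup, gmtPath = gmtPath,
              ppiPath = ppiPath, tfPath = tfPath,
              excludedSets = excludedSets)
  class(cfg) <- "lncnetConfig"
  cfg
}

#' Run the full co-expression analysis pipeline
#'
#' Orchestrates simulate (or load) -> differential expression ->
#' intersection -> bipartite network -> degree ranking and hub subnetwork ->
#' gene-set crosstalk and enrichment -> optional single-cell QC -> optional
#' layer integration, writing every stage's table plus a machine-readable
#' `summary.json` and the serialized configuration (`config.yaml`) to
#' `outDir`. Structured messages report each filter's before/after counts.
#' Re-running from the serialized configuration reproduces all outputs.
#'
#' @param config a configuration from [pipelineConfig()], or a path to a
#'   serialized `config.yaml`.
#' @param outDir output directory (created if needed).
#' @return invisibly, the summary list written to `summary.json`.
#' @examples
#' cfg <- pipelineConfig(seed = 1,
#'                       bulk = list(nGenes = 120, nLnc = 12, hubDegree = 8))
#' res <- runPipeline(cfg, tempfile("run"))
#' res$hub
#' @export
runPipeline <- function(config, outDir) {
  # named atomic vectors survive YAML only as maps: convert on the way out,
  # restore on the way in
  vecToMap <- function(l) lapply(l, function(e)
    if (is.atomic(e) && !is.null(names(e))) as.list(e) else e)
  mapToVec <- function(l) lapply(l, function(e)
    if (is.list(e) && length(e) && !is.null(names(e)) &&
        all(vapply(e, function(v) is.atomic(v) && length(v) == 1L,
                   logical(1)))) unlist(e) else e)
  if (is.character(config)) {
    cfg <- yaml::read_yaml(config)
    for (f in c("bulk", "sc"))
      if (!is.null(cfg[[f]])) cfg[[f]] <- mapToVec(cfg[[f]])
    class(cfg) <- "lncnetConfig"
  } else cfg <- config
  stopifnot(inherits(cfg, "lncnetConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ser <- unclass(cfg)
  for (f in c("bulk", "sc"))
    if (!is.null(ser[[f]])) ser[[f]] <- vecToMap(ser[[f]])
  yaml::write_yaml(ser, file.path(outDir, "config.yaml"))
  summary <- list(seed = cfg$seed)

  # --- expression matrix: load or simulate -------------------------------
  truth <- NULL
  if (!is.null(cfg$matrixPath)) {
    for (p in c(cfg$matrixPath, cfg$groupPath, cfg$biotypePath))
      if (is.null(p) || !file.exists(p))
        stop("pipeline stage 'input': missing input file: ",
             if (is.null(p)) "(unset path)" else p)
    mat <- readExprTSV(cfg$matrixPath)
    meta <- utils::read.delim(cfg$groupPath)
    anno <- utils::read.delim(cfg$biotypePath)
    expr <- makeBulkExperiment(mat, setNames(meta[[2]], meta[[1]]),
                               setNames(anno[[2]], anno[[1]]))
  } else {
    sim <- do.call(simulateBulk, c(cfg$bulk, list(seed = cfg$seed)))
    expr <- sim$expr
    truth <- sim$truth
    writeExprTSV(assay(expr, 1L), file.path(outDir, "matrix.tsv"))
  }
  message("expression matrix: ", nrow(expr), " genes x ", ncol(expr),
          " samples")

  # --- differential expression -------------------------------------------
  deg <- runComparison(expr, cfg$caseGroup, cfg$controlGroup,
                       alpha = cfg$alpha)
  utils::write.table(as.data.frame(deg), file.path(outDir, "deg.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ipf <- intersectComparisons(list(deg))
  message("DE at p < ", cfg$alpha, ": ", length(ipf$lnc), " lncRNAs and ",
          length(ipf$mrna), " mRNAs of ", nrow(expr), " genes")
  summary$n_de_lnc <- length(ipf$lnc)
  summary$n_de_mrna <- length(ipf$mrna)

  # --- co-expression network ---------------------------------------------
  net <- buildNetwork(expr, ipf$lnc, ipf$mrna, list(deg),
                      rThreshold = cfg$rThreshold,
                      pThreshold = cfg$pThreshold)
  writeNetworkSIF(net, file.path(outDir, "network"))
  dt <- degreeTable(net)
  utils::write.table(as.data.frame(dt), file.path(outDir, "degree.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary$n_edges <- length(net)
  summary$n_nodes <- nrow(netNodes(net))
  hubs <- hubGenes(net, biotype = "lncRNA")
  summary$hub <- hubs
  message("network: ", summary$n_nodes, " nodes, ", summary$n_edges,
          " edges; top-degree lncRNA(s): ",
          paste(hubs, collapse = ", "))
  if (!is.null(truth)) summary$planted_hub <- names(truth@hubLncs)

  neighbors <- character()
  if (length(hubs) >= 1L) {
    sub <- hubSubnetwork(net, hubs[[1L]])
    writeNetworkSIF(sub, file.path(outDir, "hub_subnetwork"))
    summary$hub_subnetwork_genes <- nrow(netNodes(sub))
    ed <- netEdges(sub)
    neighbors <- setdiff(unique(c(ed$lnc, ed$mrna)), hubs[[1L]])
  }

  # --- gene sets: crosstalk + enrichment ---------------------------------
  universe <- rownames(expr)
  sets <- if (!is.null(cfg$gmtPath)) readGMT(cfg$gmtPath)
          else geneSets(simulateGeneSets(universe, seed = cfg$seed))
  coll <- GeneSetCollection(sets, universe, excludedIds = cfg$excludedSets)
  if (length(neighbors)) {
    ct <- crosstalkTable(neighbors, coll)
    utils::write.table(ct, file.path(outDir, "crosstalk.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    enr <- enrichGeneSets(neighbors, coll, fdrThreshold = cfg$fdrThreshold)
    utils::write.table(as.data.frame(enr),
                       file.path(outDir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$n_crosstalk_links <- nrow(ct)
    summary$n_enriched_sets <- sum(enr$significant)
  }

  # --- optional single-cell QC -------------------------------------------
  if (!is.null(cfg$sc)) {
    scSim <- do.call(simulateSC, c(cfg$sc, list(seed = cfg$seed)))
    th <- scSim$truth@thresholds
    qc <- qcFilter(scSim$sce, th$minGenes, th$minCells, th$maxGenes,
                   th$maxMito)
    rep <- qc$report
    jsonlite::write_json(
      list(n_cells_in = rep@nCellsIn, n_genes_in = rep@nGenesIn,
           removed_cells_min_genes = rep@removedCellsMinGenes,
           removed_genes_min_cells = rep@removedGenesMinCells,
           removed_cells_max_genes_or_mito = rep@removedCellsMaxGenesOrMito,
           n_cells_out = rep@nCellsOut, n_genes_out = rep@nGenesOut,
           thresholds = rep@thresholds),
      file.path(outDir, "qc_report.json"), auto_unbox = TRUE)
    summary$sc_cells_out <- rep@nCellsOut
    summary$sc_genes_out <- rep@nGenesOut
    message("single-cell QC: ", rep@nCellsIn, " -> ", rep@nCellsOut,
            " cells, ", rep@nGenesIn, " -> ", rep@nGenesOut, " genes")
  }

  # --- optional integration ----------------------------------------------
  if ((!is.null(cfg$ppiPath) || !is.null(cfg$tfPath)) && length(hubs)) {
    ppi <- if (!is.null(cfg$ppiPath)) readEdgeList(cfg$ppiPath)
    tf <- if (!is.null(cfg$tfPath)) readEdgeList(cfg$tfPath)
    merged <- mergeNetworks(net, ppi, tf, focal = hubs[[1L]],
                            hops = cfg$hops)
    utils::write.table(merged, file.path(outDir, "integrated.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$integrated_layer_counts <-
      as.list(attr(merged, "layer_counts"))
  }

  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
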