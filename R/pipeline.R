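# End-to-end orchestration: simulate -> normalize -> DE -> separability
# -> enrichment -> network -> topology -> qPCR, with per-stage artifacts
# and a machine-readable run report.

#' Pipeline configuration
#'
#' Collects stage parameters, toggles and paths for [runPipeline()]. The
#' single `seed` fans out deterministically to the per-stage generators.
#' When the `simulate` stage is disabled, paths to a counts TSV, sample
#' sheet, interaction TSV, GMT file and (optionally) a qPCR well table
#' must be supplied.
#'
#' @param outdir directory for all artifacts (created if absent).
#' @param seed global RNG seed.
#' @param sim named list of [simConfig()] overrides for the simulate
#'   stage.
#' @param alpha,lfc_min DE thresholds (raw p and |log2FC|).
#' @param filter_min_fpkm,filter_min_samples optional expression filter;
#'   `NULL` disables filtering (the default).
#' @param r_min,sign_mode,min_shared network thresholds.
#' @param k top-k cutoff for pivotal-node calling (default 10, suited to
#'   desk-scale networks; the study-scale convention is 100).
#' @param posterior_threshold GMM confident-assignment threshold.
#' @param reference_gene qPCR endogenous control id.
#' @param stages named logical list toggling
#'   simulate/normalize/de/evaluate/enrich/network/topology/qpcr.
#' @param counts_path,samples_path,interactions_path,gmt_path,wells_path
#'   input files used when `simulate` is disabled.
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(outdir = tempfile("cerna_run_"), seed = 1,
                           sim = list(), alpha = 0.05, lfc_min = 1,
                           filter_min_fpkm = NULL, filter_min_samples = 2,
                           r_min = 0.6, sign_mode = "positive",
                           min_shared = 1, k = 10,
                           posterior_threshold = 0.8,
                           reference_gene = "REF1",
                           stages = list(), counts_path = NULL,
                           samples_path = NULL, interactions_path = NULL,
                           gmt_path = NULL, wells_path = NULL) {
  default_stages <- list(simulate = TRUE, normalize = TRUE, de = TRUE,
                         evaluate = TRUE, enrich = TRUE, network = TRUE,
                         topology = TRUE, qpcr = TRUE)
  default_stages[names(stages)] <- stages
  cfg <- list(outdir = outdir, seed = seed, sim = sim, alpha = alpha,
              lfc_min = lfc_min, filter_min_fpkm = filter_min_fpkm,
              filter_min_samples = filter_min_samples, r_min = r_min,
              sign_mode = sign_mode, min_shared = min_shared, k = k,
              posterior_threshold = posterior_threshold,
              reference_gene = reference_gene, stages = default_stages,
              counts_path = counts_path, samples_path = samples_path,
              interactions_path = interactions_path, gmt_path = gmt_path,
              wells_path = wells_path)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys match the arguments of [pipelineConfig()]; unknown
#' keys are rejected.
#'
#' @param path YAML file.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipelineConfig, y)
}

stageLog <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

stageStop <- function(stage, e) {
  stop(sprintf("pipeline stage '%s' failed: %s", stage,
               conditionMessage(e)), call. = FALSE)
}

#' Run the ceRNA-network pipeline end to end
#'
#' Executes the enabled stages in order, writes every intermediate
#' artifact under `config$outdir` and returns (and writes as
#' `report.json`) a run report listing the counts at each stage together
#' with all parameters and the seed, so a run can be reproduced from its
#' report alone. Any stage error aborts with the stage name; artifacts
#' already written are retained.
#'
#' @param config a `PipelineConfig` ([pipelineConfig()] /
#'   [readPipelineConfig()]) or the path of a YAML config.
#' @return the run report, invisibly a list (also written to
#'   `<outdir>/report.json`).
#' @export
runPipeline <- function(config = pipelineConfig()) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "PipelineConfig"))
  st <- config$stages
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(config$outdir, f)
  report <- list(parameters = config[setdiff(names(config), "outdir")],
                 counts = list(), artifacts = list())

  truth <- NULL; interactions <- NULL; collection <- NULL; wells <- NULL
  if (isTRUE(st$simulate)) {
    tryCatch({
      scfg <- do.call(simConfig, c(list(seed = config$seed), config$sim))
      sim <- simulateExpression(scfg)
      counts <- sim$matrix; truth <- sim$truth
      interactions <- simulateInteractionTable(scfg, truth)
      gs <- simulateGeneSets(scfg, truth)
      collection <- gs$collection; truth <- gs$truth
      wells <- simulateQPCR(truth, scfg)
      writeExpression(counts, pth("counts.tsv"))
      writeInteractions(interactions, pth("interactions.tsv"))
      writeGMT(collection, pth("gene_sets.gmt"))
      writeWells(wells, pth("qpcr_wells.tsv"))
      jsonlite::write_json(truth[c("de_genes", "hub_lncrna_id",
                                   "module_mrna_ids",
                                   "enriched_term_id")],
                           pth("truth.json"), auto_unbox = TRUE,
                           pretty = TRUE)
      stageLog("simulate", "%d genes x %d samples, %d planted DE",
               nrow(counts), ncol(counts), nrow(truth$de_genes))
    }, error = function(e) stageStop("simulate", e))
  } else {
    tryCatch({
      if (is.null(config$counts_path))
        stop("simulate disabled and no counts_path given")
      counts <- readExpression(config$counts_path, config$samples_path)
      if (!is.null(config$interactions_path))
        interactions <- readInteractions(config$interactions_path)
      if (!is.null(config$gmt_path))
        collection <- readGMT(config$gmt_path)
      if (!is.null(config$wells_path))
        wells <- readWells(config$wells_path)
      stageLog("load", "%d genes x %d samples", nrow(counts),
               ncol(counts))
    }, error = function(e) stageStop("load", e))
  }
  report$counts$genes_in <- nrow(counts)
  report$counts$samples <- ncol(counts)

  if (!isTRUE(st$normalize))
    stop("the normalize stage is required by all downstream stages")
  fpkm <- tryCatch({
    f <- computeFPKM(counts)
    if (!is.null(config$filter_min_fpkm))
      f <- filterExpressed(f, config$filter_min_fpkm,
                           config$filter_min_samples)
    writeExpression(f, pth("fpkm.tsv"))
    stageLog("normalize", "%d genes after filtering", nrow(f))
    f
  }, error = function(e) stageStop("normalize", e))
  report$counts$genes_normalized <- nrow(fpkm)

  de <- NULL
  if (isTRUE(st$de)) {
    de <- tryCatch({
      res <- classifyDE(testDifferential(fpkm), config$alpha,
                        config$lfc_min)
      writeDEResults(res, pth("de_results.tsv"))
      res
    }, error = function(e) stageStop("de", e))
    de_m <- de$gene_id[de$status != "ns" & de$biotype == "mRNA"]
    de_l <- de$gene_id[de$status != "ns" & de$biotype == "lncRNA"]
    report$counts$de_mrna <- length(de_m)
    report$counts$de_lncrna <- length(de_l)
    stageLog("de", "%d DE mRNAs, %d DE lncRNAs", length(de_m),
             length(de_l))
  }

  if (isTRUE(st$evaluate)) {
    if (is.null(de)) stop("the evaluate stage requires the de stage")
    tryCatch({
      sep <- evaluateSeparation(fpkm, de_m, k = 2,
                                posteriorThreshold =
                                  config$posterior_threshold,
                                seed = config$seed)
      utils::write.table(
        data.frame(sample_id = rownames(sep$pca$coords),
                   sep$pca$coords,
                   kmeans = sep$kmeans$cluster,
                   posterior = sep$gmm$assigned_posterior),
        pth("separation_coords.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      jsonlite::write_json(
        list(concordance = sep$concordance,
             explained_var = sep$pca$explained_var[1:2],
             high_posterior_fraction =
               as.list(sep$high_posterior_fraction)),
        pth("separation_report.json"), auto_unbox = TRUE, pretty = TRUE)
      report$counts$separation_concordance <- sep$concordance
      stageLog("evaluate", "concordance %.3f", sep$concordance)
    }, error = function(e) stageStop("evaluate", e))
  }

  if (isTRUE(st$enrich)) {
    if (is.null(de)) stop("the enrich stage requires the de stage")
    if (is.null(collection)) stop("the enrich stage needs gene sets")
    tryCatch({
      universe <- de$gene_id[de$biotype == "mRNA"]
      enr <- enrichCollection(de[de$biotype == "mRNA", ], collection,
                              universe)
      utils::write.table(enr, pth("enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      report$counts$enriched_terms_raw_p <- sum(enr$p_value < 0.05)
      stageLog("enrich", "%d terms tested, %d at raw p < 0.05",
               nrow(enr), sum(enr$p_value < 0.05))
    }, error = function(e) stageStop("enrich", e))
  }

  network <- NULL
  if (isTRUE(st$network)) {
    if (is.null(de)) stop("the network stage requires the de stage")
    if (is.null(interactions))
      stop("the network stage needs an interaction table")
    tryCatch({
      edges <- correlationEdges(fpkm, de_l, de_m)
      kept <- filterCorrelation(edges, config$alpha, config$r_min,
                                config$sign_mode)
      xref <- crossReference(kept, interactions, config$min_shared)
      network <- buildCeRNA(xref)
      utils::write.table(xref, pth("correlation_edges.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      writeNetworkSIF(network, pth("network.sif"))
      writeNetworkTables(network, pth("network_edges.tsv"),
                         pth("network_nodes.tsv"))
      report$counts$pairs_tested <- nrow(edges)
      report$counts$edges_correlation_filter <- nrow(kept)
      report$counts$edges_crossref <- nrow(xref)
      nt <- table(factor(networkNodes(network)$type,
                         levels = NODE_TYPES))
      ek <- table(factor(networkEdges(network)$kind,
                         levels = EDGE_KINDS))
      report$counts$network_nodes <- as.list(nt)
      report$counts$network_edges <- as.list(ek)
      stageLog("network",
               "%d pairs -> %d after correlation -> %d after crossref",
               nrow(edges), nrow(kept), nrow(xref))
    }, error = function(e) stageStop("network", e))
  }

  if (isTRUE(st$topology)) {
    if (is.null(network))
      stop("the topology stage requires the network stage")
    tryCatch({
      cent <- centralities(network)
      piv <- pivotalNodes(cent, config$k)
      writeCentralities(cent, pth("centralities.tsv"))
      writePivotalSet(piv, pth("pivotal.json"))
      report$counts$pivotal_nodes <- length(piv$intersection)
      report$counts$pivotal_by_type <- lapply(piv$by_type, length)
      report$pivotal <- piv$intersection
      stageLog("topology", "%d pivotal nodes at k = %d",
               length(piv$intersection), config$k)
    }, error = function(e) stageStop("topology", e))
  }

  if (isTRUE(st$qpcr)) {
    if (is.null(wells)) stop("the qpcr stage needs a well table")
    tryCatch({
      rel <- relativeExpression(wells, config$reference_gene)
      utils::write.table(rel, pth("qpcr_relative.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      targets <- unique(rel$target)
      cmp <- do.call(rbind, lapply(targets, function(tg) {
        g <- compareGroups(rel, tg)
        data.frame(target = tg, fold_ratio = g$fold_ratio,
                   p_value = g$p_value, stringsAsFactors = FALSE)
      }))
      utils::write.table(cmp, pth("qpcr_groups.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      report$counts$qpcr_targets <- length(targets)
      stageLog("qpcr", "%d targets quantified", length(targets))
    }, error = function(e) stageStop("qpcr", e))
  }

  if (!is.null(truth)) {
    report$truth <- list(hub_lncrna_id = truth$hub_lncrna_id,
                         module_mrna_ids = truth$module_mrna_ids,
                         enriched_term_id = truth$enriched_term_id)
    if (!is.null(report$pivotal))
      report$hub_in_pivotal <-
        truth$hub_lncrna_id %in% report$pivotal
  }
  jsonlite::write_json(report, pth("report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(report)
}
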