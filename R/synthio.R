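# Synthetic data with planted ground truth: negative-binomial expression,
# a co-regulated hub-lncRNA module, matched miRNA-target tables, gene-set
# collections and qPCR plates. Every generator is a pure function of
# (config, seed).

#' Simulation configuration
#'
#' Collects the parameters of the synthetic study. The defaults describe
#' a desk-scale paired case-control bulk RNA-seq design: 6 tumor/normal
#' pairs, log-normal baseline means, negative-binomial counts
#' (var = mu + phi mu^2), a planted differentially expressed fraction, a
#' hub lncRNA co-regulating a module of mRNAs through a shared per-sample
#' latent factor, and miRNA-target tables in which hub and module share
#' miRNAs.
#'
#' @param n_pairs tumor/normal pairs (samples = 2 * n_pairs).
#' @param n_mrna,n_lncrna,n_mirna feature counts per biotype.
#' @param nb_mean_log_mu,nb_mean_log_sd meanlog/sdlog of the log-normal
#'   distribution baseline NB means are drawn from.
#' @param nb_dispersion NB dispersion phi in var = mu + phi mu^2;
#'   0 gives Poisson counts.
#' @param de_fraction fraction of genes with planted differential
#'   expression.
#' @param de_log2fc magnitude of the planted log2 fold change.
#' @param module_size number of mRNAs co-regulated by the hub lncRNA.
#' @param module_rho target log-scale correlation between hub and module
#'   members (in \[0, 1); 0 disables the latent factor).
#' @param shared_mirna_count miRNAs targeting both the hub and each
#'   module member.
#' @param geneset_count,geneset_size shape of the gene-set collection.
#' @param pair_log2_sd sd (log2 scale) of a per-pair baseline offset
#'   shared by the tumor and normal sample of a pair; 0 (default) keeps
#'   samples independent, matching the unpaired downstream analysis.
#' @param background_pairs random background miRNA-target rows.
#' @param seed RNG seed; all generators are deterministic given it.
#' @return a `SimulationConfig` (a validated named list).
#' @export
simConfig <- function(n_pairs = 6, n_mrna = 400, n_lncrna = 180,
                      n_mirna = 120, nb_mean_log_mu = 5,
                      nb_mean_log_sd = 1.5, nb_dispersion = 0.08,
                      de_fraction = 0.1, de_log2fc = 3, module_size = 8,
                      module_rho = 0.8, shared_mirna_count = 3,
                      geneset_count = 50, geneset_size = 25,
                      pair_log2_sd = 0, background_pairs = 4 * n_mirna,
                      seed = 1) {
  cfg <- list(n_pairs = n_pairs, n_mrna = n_mrna, n_lncrna = n_lncrna,
              n_mirna = n_mirna, nb_mean_log_mu = nb_mean_log_mu,
              nb_mean_log_sd = nb_mean_log_sd,
              nb_dispersion = nb_dispersion, de_fraction = de_fraction,
              de_log2fc = de_log2fc, module_size = module_size,
              module_rho = module_rho,
              shared_mirna_count = shared_mirna_count,
              geneset_count = geneset_count, geneset_size = geneset_size,
              pair_log2_sd = pair_log2_sd,
              background_pairs = background_pairs, seed = seed)
  for (f in c("n_pairs", "n_mrna", "n_lncrna", "n_mirna", "module_size",
              "geneset_count", "geneset_size"))
    stopifnot_scalar_number(cfg[[f]], f, lo = 1)
  stopifnot_scalar_number(cfg$de_fraction, "de_fraction", 0, 1)
  stopifnot_scalar_number(cfg$nb_dispersion, "nb_dispersion", 0)
  stopifnot_scalar_number(cfg$module_rho, "module_rho", 0, 1 - 1e-12)
  stopifnot_scalar_number(cfg$shared_mirna_count, "shared_mirna_count", 0)
  stopifnot_scalar_number(cfg$pair_log2_sd, "pair_log2_sd", 0)
  if (cfg$module_size > cfg$n_mrna)
    stop("module_size exceeds n_mrna")
  if (cfg$shared_mirna_count > cfg$n_mirna)
    stop("shared_mirna_count exceeds n_mirna")
  if (cfg$geneset_size > cfg$n_mrna)
    stop("geneset_size exceeds n_mrna")
  class(cfg) <- "SimulationConfig"
  cfg
}

# Total log2 biological sd given to module genes; split between the
# shared latent factor and an independent component so the latent share
# of variance equals module_rho.
MODULE_LOG2_SD <- 1.0

#' Simulate a case-control expression matrix with planted truth
#'
#' Counts are negative-binomial (var = mu + phi mu^2) around log-normal
#' baseline means. A `de_fraction` of genes receives a group-mean shift of
#' `2^de_log2fc` in tumor samples (random sign; the hub lncRNA and its
#' module mRNAs are always planted, downregulated). Hub and module share
#' a per-sample latent log2-scale factor whose variance share equals
#' `module_rho`, so their pairwise sample correlation approaches
#' `module_rho` (dilution by counting noise means the target is
#' approached, not matched exactly). Gene lengths are drawn uniformly in
#' \[200, 10000\] bp, independent of expression.
#'
#' @param config a [simConfig()] object.
#' @return a list with elements `matrix` (an [ExpressionMatrix-class] of
#'   counts) and `truth` (a `PlantedTruth` list: `de_genes` data.frame
#'   with `gene_id`, `direction`, `log2fc`; `hub_lncrna_id`;
#'   `module_mrna_ids`; `true_log2fc` named over all genes;
#'   `mrna_ids`/`lncrna_ids`/`mirna_ids`; `enriched_term_id`, filled by
#'   [simulateGeneSets()]).
#' @export
simulateExpression <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  n_genes <- config$n_mrna + config$n_lncrna
  n_de <- round(config$de_fraction * n_genes)
  if (config$de_fraction > 0 && n_de < 1)
    stop("de_fraction is positive but selects no genes")
  withSeed(config$seed, {
    mrna_ids <- sprintf("MRNA%04d", seq_len(config$n_mrna))
    lnc_ids <- sprintf("LNC%04d", seq_len(config$n_lncrna))
    mirna_ids <- sprintf("MIR%04d", seq_len(config$n_mirna))
    gene_ids <- c(mrna_ids, lnc_ids)
    biotype <- rep(c("mRNA", "lncRNA"), c(config$n_mrna, config$n_lncrna))
    lengths <- sample(200:10000, n_genes, replace = TRUE)
    base_mu <- stats::rlnorm(n_genes, config$nb_mean_log_mu,
                             config$nb_mean_log_sd)
    names(base_mu) <- gene_ids

    hub <- sample(lnc_ids, 1L)
    module <- sample(mrna_ids, config$module_size)
    # Anchor hub/module baseline one sdlog above the median so the
    # planted structure is comfortably expressed.
    base_mu[c(hub, module)] <-
      exp(config$nb_mean_log_mu + config$nb_mean_log_sd) *
      stats::rlnorm(config$module_size + 1L, 0, 0.2)

    true_lfc <- stats::setNames(rep(0, n_genes), gene_ids)
    de_ids <- character(0)
    if (n_de >= 1) {
      planted <- c(hub, module)
      extra <- max(n_de - length(planted), 0L)
      others <- setdiff(gene_ids, planted)
      de_ids <- c(planted, sample(others, min(extra, length(others))))
      dirs <- stats::setNames(sample(c(-1, 1), length(de_ids),
                                     replace = TRUE), de_ids)
      dirs[planted] <- -1  # hub and module planted downregulated
      true_lfc[de_ids] <- dirs * config$de_log2fc
    }

    n_samp <- 2L * config$n_pairs
    sample_ids <- c(sprintf("T%02d", seq_len(config$n_pairs)),
                    sprintf("N%02d", seq_len(config$n_pairs)))
    condition <- rep(c("tumor", "control"), each = config$n_pairs)
    pair_id <- rep(sprintf("P%02d", seq_len(config$n_pairs)), 2L)

    log2mu <- matrix(log2(base_mu), n_genes, n_samp,
                     dimnames = list(gene_ids, sample_ids))
    log2mu[, condition == "tumor"] <-
      log2mu[, condition == "tumor"] + true_lfc
    if (config$pair_log2_sd > 0) {
      poff <- stats::rnorm(config$n_pairs, 0, config$pair_log2_sd)
      log2mu <- sweep(log2mu, 2, poff[rep(seq_len(config$n_pairs), 2L)],
                      "+")
    }
    if (config$module_rho > 0) {
      a <- MODULE_LOG2_SD * sqrt(config$module_rho)
      b <- MODULE_LOG2_SD * sqrt(1 - config$module_rho)
      z <- stats::rnorm(n_samp)
      mem <- c(hub, module)
      eps <- matrix(stats::rnorm(length(mem) * n_samp), length(mem))
      log2mu[mem, ] <- log2mu[mem, ] +
        a * matrix(z, length(mem), n_samp, byrow = TRUE) + b * eps
    }
    mu <- 2^log2mu
    counts <- if (config$nb_dispersion > 0) {
      matrix(stats::rnbinom(length(mu), mu = mu,
                            size = 1 / config$nb_dispersion),
             n_genes, dimnames = dimnames(mu))
    } else {
      matrix(stats::rpois(length(mu), mu), n_genes,
             dimnames = dimnames(mu))
    }

    ss <- data.frame(sample_id = sample_ids, condition = condition,
                     pair_id = pair_id, stringsAsFactors = FALSE)
    em <- ExpressionMatrix(counts, lengths, biotype, ss, unit = "counts")
    truth <- structure(list(
      de_genes = data.frame(
        gene_id = de_ids,
        direction = if (length(de_ids)) ifelse(true_lfc[de_ids] > 0,
                                               "up", "down")
                    else character(0),
        log2fc = unname(true_lfc[de_ids]),
        stringsAsFactors = FALSE),
      hub_lncrna_id = hub,
      module_mrna_ids = module,
      true_log2fc = true_lfc,
      mrna_ids = mrna_ids, lncrna_ids = lnc_ids, mirna_ids = mirna_ids,
      enriched_term_id = NA_character_), class = "PlantedTruth")
    list(matrix = em, truth = truth)
  })
}

#' Simulate a miRNA-target interaction table
#'
#' Emulates a database export of predicted miRNA-RNA interactions: a
#' pool of miRNAs targets the hub lncRNA, each module mRNA is targeted by
#' `shared_mirna_count` miRNAs from that pool (so every hub/module pair
#' shares at least that many miRNAs), and `background_pairs` random
#' (miRNA, gene) rows are added over the remaining genes. Duplicate rows
#' are removed.
#'
#' @param config a [simConfig()].
#' @param truth the `PlantedTruth` from [simulateExpression()] under the
#'   same config.
#' @return data.frame with columns `mirna_id`, `target_id`,
#'   `target_biotype`.
#' @export
simulateInteractionTable <- function(config, truth) {
  stopifnot(inherits(config, "SimulationConfig"),
            inherits(truth, "PlantedTruth"))
  if (config$shared_mirna_count > config$n_mirna)
    stop("shared_mirna_count exceeds n_mirna")
  withSeed(config$seed + 101L, {
    rows <- list()
    sh <- config$shared_mirna_count
    if (sh > 0) {
      pool <- sample(truth$mirna_ids,
                     min(config$n_mirna, max(2L * sh, sh)))
      rows[[1]] <- data.frame(mirna_id = pool,
                              target_id = truth$hub_lncrna_id,
                              target_biotype = "lncRNA",
                              stringsAsFactors = FALSE)
      mem_rows <- lapply(truth$module_mrna_ids, function(m) {
        data.frame(mirna_id = pool[sample.int(length(pool), sh)],
                   target_id = m, target_biotype = "mRNA",
                   stringsAsFactors = FALSE)
      })
      rows <- c(rows, mem_rows)
    }
    others <- setdiff(c(truth$mrna_ids, truth$lncrna_ids),
                      c(truth$hub_lncrna_id, truth$module_mrna_ids))
    if (config$background_pairs > 0 && length(others)) {
      tg <- sample(others, config$background_pairs, replace = TRUE)
      bg <- data.frame(
        mirna_id = sample(truth$mirna_ids, config$background_pairs,
                          replace = TRUE),
        target_id = tg,
        target_biotype = ifelse(tg %in% truth$mrna_ids, "mRNA", "lncRNA"),
        stringsAsFactors = FALSE)
      rows <- c(rows, list(bg))
    }
    tab <- do.call(rbind, rows) %||%
      data.frame(mirna_id = character(0), target_id = character(0),
                 target_biotype = character(0))
    tab <- unique(tab)
    rownames(tab) <- NULL
    tab
  })
}

#' Simulate a gene-set collection with one planted enriched term
#'
#' Generates `geneset_count` sets of size `geneset_size` over the mRNA
#' universe. When planted DE mRNAs exist, the first term (`GS0001`) draws
#' at least 80% of its members from them, so downstream
#' over-representation analysis should rank it first; all other terms
#' are uniform background draws.
#'
#' @inheritParams simulateInteractionTable
#' @return list with `collection` (a `GeneSetCollection`: `sets` named
#'   list of gene-id vectors, `descriptions` named character) and
#'   `truth`, the input truth with `enriched_term_id` filled (`NA` when
#'   no DE mRNAs were planted).
#' @export
simulateGeneSets <- function(config, truth) {
  stopifnot(inherits(config, "SimulationConfig"),
            inherits(truth, "PlantedTruth"))
  if (config$geneset_size > config$n_mrna)
    stop("geneset_size exceeds n_mrna")
  withSeed(config$seed + 202L, {
    universe <- truth$mrna_ids
    ids <- sprintf("GS%04d", seq_len(config$geneset_count))
    sets <- lapply(ids, function(i) sample(universe, config$geneset_size))
    names(sets) <- ids
    descriptions <- stats::setNames(
      sprintf("background set %s", ids), ids)
    de_mrna <- intersect(truth$de_genes$gene_id, universe)
    enriched <- NA_character_
    if (length(de_mrna)) {
      enriched <- ids[1L]
      k <- min(ceiling(0.8 * config$geneset_size), length(de_mrna))
      core <- sample(de_mrna, k)
      rest <- sample(setdiff(universe, core), config$geneset_size - k)
      sets[[enriched]] <- c(core, rest)
      descriptions[enriched] <- "planted enriched set"
    }
    collection <- structure(list(sets = sets, descriptions = descriptions),
                            class = "GeneSetCollection")
    truth$enriched_term_id <- enriched
    list(collection = collection, truth = truth)
  })
}

#' Simulate a qPCR well table
#'
#' Builds a triplicate-well plate for chosen target genes plus one
#' reference gene across `nPerGroup` tumor and control samples. The
#' tumor-vs-control shift in delta-Ct equals minus the planted log2 fold
#' change; independent Gaussian replicate noise (sd `noiseSd` cycles) is
#' added to every well. With `noiseSd = 0` the downstream 2^-ddCt fold is
#' exact.
#'
#' @param truth a `PlantedTruth`.
#' @param config a [simConfig()].
#' @param targets gene ids to assay; default the hub lncRNA and the
#'   first three module mRNAs.
#' @param nPerGroup samples per group (default 10, a typical validation
#'   cohort).
#' @param noiseSd replicate noise sd in cycles.
#' @param replicates wells per (sample, target); must be >= 1.
#' @param referenceGene id of the endogenous control.
#' @return data.frame with columns `sample_id`, `group`, `target`,
#'   `replicate`, `ct`.
#' @export
simulateQPCR <- function(truth, config, targets = NULL, nPerGroup = 10,
                         noiseSd = 0.2, replicates = 3,
                         referenceGene = "REF1") {
  stopifnot(inherits(config, "SimulationConfig"),
            inherits(truth, "PlantedTruth"))
  if (replicates < 1) stop("at least one replicate is required")
  targets <- targets %||%
    c(truth$hub_lncrna_id,
      utils::head(truth$module_mrna_ids, 3L))
  withSeed(config$seed + 303L, {
    samples <- data.frame(
      sample_id = c(sprintf("VT%02d", seq_len(nPerGroup)),
                    sprintf("VN%02d", seq_len(nPerGroup))),
      group = rep(c("tumor", "control"), each = nPerGroup),
      stringsAsFactors = FALSE)
    base_ct <- stats::setNames(stats::runif(length(targets), 22, 28),
                               targets)
    ref_ct <- 18
    grid <- expand.grid(sample_idx = seq_len(nrow(samples)),
                        target = c(targets, referenceGene),
                        replicate = seq_len(replicates),
                        stringsAsFactors = FALSE)
    ct <- numeric(nrow(grid))
    for (i in seq_len(nrow(grid))) {
      g <- grid[i, ]
      smp <- samples[g$sample_idx, ]
      ct[i] <- if (g$target == referenceGene) ref_ct else {
        lfc <- if (g$target %in% names(truth$true_log2fc))
          truth$true_log2fc[[g$target]] else 0
        base_ct[[g$target]] +
          if (smp$group == "tumor") -lfc else 0
      }
    }
    if (noiseSd > 0) ct <- ct + stats::rnorm(length(ct), 0, noiseSd)
    data.frame(sample_id = samples$sample_id[grid$sample_idx],
               group = samples$group[grid$sample_idx],
               target = grid$target, replicate = grid$replicate,
               ct = ct, stringsAsFactors = FALSE)
  })
}

#' Write / read an interaction table TSV
#' @param table data.frame with `mirna_id`, `target_id`,
#'   `target_biotype`.
#' @param path TSV path.
#' @return `readInteractions` returns the data.frame; `writeInteractions`
#'   returns `path` invisibly.
#' @export
writeInteractions <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeInteractions
#' @export
readInteractions <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna_id", "target_id", "target_biotype")
  if (!all(need %in% colnames(tab)))
    stop("interaction table needs columns ", paste(need, collapse = ", "))
  tab
}

#' Write / read a qPCR well table TSV
#' @param wells data.frame as produced by [simulateQPCR()].
#' @param path TSV path.
#' @export
writeWells <- function(wells, path) {
  utils::write.table(wells, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeWells
#' @export
readWells <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
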