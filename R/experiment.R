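# Experiment orchestration: multi-chain, multi-proposal sweeps with
# reproducible manifests, tying the generator, sampler and diagnostics
# together the way the convergence studies are designed (independent
# random-start chains per proposal mixture, pooled samples, pairwise SSD
# tables, and an optional dataset-size sweep of MAP scores).

#' Read an experiment configuration
#'
#' YAML or JSON with fields: `data`/`mask` (file paths) or `generator`
#' (list: `nodes`, `density`, `arity`, `concentration`, `samples`,
#' `interventions`), `proposals` (list of mixture vectors), `chains`,
#' `burnIn`, `sampleSize`, `thin`, `fanin`, `ess`, `seed`, optional
#' `subsampleSizes`.
#'
#' @param path configuration file.
#' @return a named list.
#' @export
readExperimentConfig <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

.experimentDataset <- function(config) {
  if (!is.null(config$data)) {
    readDiscreteDataset(config$data, maskPath = config$mask,
                        arities = config$arities)
  } else if (!is.null(config$generator)) {
    g <- config$generator
    dag <- randomDag(g$nodes, edgeDensity = g$density %||% 0.3,
                     maxFanin = g$maxFanin %||% Inf)
    bn <- randomCpts(dag, arities = g$arity %||% 3,
                     concentration = g$concentration %||% 0.5)
    if ((g$interventions %||% 0) > 0)
      interventionalSample(bn, g$samples, g$interventions)
    else forwardSample(bn, g$samples)
  } else stop("config must name a data file or a generator")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.chainSeed <- function(base, i, j) as.integer((base + 7919L * i + 104729L * j) %% .Machine$integer.max)

#' Write the standard per-chain outputs
#'
#' `trace.csv` (index, logScore), `dags.txt` (one flattened row-major 0/1
#' adjacency string per retained state), `edge_posteriors.csv`, and
#' `acceptance.csv` (per transition length).
#'
#' @param sample a [ChainSample-class].
#' @param dir output directory (created if needed).
#' @export
writeChainOutputs <- function(sample, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(scoreTrace(sample), file.path(dir, "trace.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  s01 <- matrix(as.integer(sample@states != as.raw(0)),
                nrow(sample@states), ncol(sample@states))
  writeLines(apply(s01, 1, paste, collapse = ""), file.path(dir, "dags.txt"))
  ep <- edgePosteriors(sample)
  write.table(as.matrix(ep), file.path(dir, "edge_posteriors.csv"), sep = ",",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(acceptanceRates(sample), file.path(dir, "acceptance.csv"),
              sep = ",", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Run a multi-proposal, multi-chain experiment
#'
#' For every proposal mixture, runs `chains` independent random-start
#' chains, writes per-chain outputs and a pairwise SSD table, pools the
#' chains, and reports the pooled MAP score. When `subsampleSizes` is
#' given, the whole design is additionally repeated on seeded row
#' subsamples of each size and the pooled MAP score recorded per size. A
#' manifest (config, seeds, input digests, output inventory) sufficient to
#' re-run the experiment is written to `manifest.json`.
#'
#' @param config list (see [readExperimentConfig()]) or a path to one.
#' @param outDir output directory.
#' @return (invisibly) a list with `ssd` (data.frame), `map` (data.frame),
#'   `samples` (list of lists of [ChainSample-class]).
#' @export
runExperiment <- function(config, outDir) {
  if (is.character(config)) config <- readExperimentConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  set.seed(seed)
  dataset <- .experimentDataset(config)
  proposals <- config$proposals
  if (is.null(proposals)) stop("config$proposals is required")
  if (!is.list(proposals)) proposals <- list(proposals)
  nChains <- config$chains %||% 3L
  fanin <- config$fanin %||% Inf
  settings <- scoreSettings(ess = config$ess %||% 1)

  runSet <- function(ds, pIdx, tag) {
    spec <- proposalSpec(as.numeric(proposals[[pIdx]]), maxFanin = fanin)
    configs <- lapply(seq_len(nChains), function(j)
      chainConfig(sampleSize = config$sampleSize, burnIn = config$burnIn %||% 0,
                  thin = config$thin %||% 1,
                  seed = .chainSeed(seed, pIdx, j),
                  initialDag = "random", proposal = spec, score = settings))
    samples <- runChainEnsemble(configs, ds)
    for (j in seq_along(samples))
      writeChainOutputs(samples[[j]],
                        file.path(outDir, tag, sprintf("chain-%d", j)))
    samples
  }

  ssdRows <- list(); mapRows <- list(); allSamples <- list()
  for (p in seq_along(proposals)) {
    tag <- sprintf("proposal-%d", p)
    samples <- runSet(dataset, p, tag)
    allSamples[[tag]] <- samples
    pooled <- poolChains(samples)
    mp <- mapDag(pooled)
    bc <- bestConvergedPair(samples)
    tab <- bc$ssdTable
    write.table(tab, file.path(outDir, tag, "ssd_pairs.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
    ssdRows[[p]] <- data.frame(proposal = tag, meanSSD = mean(tab$ssd),
                               minSSD = min(tab$ssd))
    mapRows[[p]] <- data.frame(proposal = tag, size = nSamples(dataset),
                               mapLogScore = mp$logScore)
    writeDagEdgeList(mp$dag, file.path(outDir, tag, "map_dag.tsv"))
  }

  for (s in config$subsampleSizes %||% integer(0)) {
    set.seed(.chainSeed(seed, 0L, s))
    rows <- sample.int(nSamples(dataset), s)
    sub <- discreteDataset(dataset@values[rows, , drop = FALSE],
                           arities = dataset@arities,
                           mask = if (hasInterventions(dataset))
                             dataset@mask[rows, , drop = FALSE] else NULL)
    for (p in seq_along(proposals)) {
      tag <- sprintf("proposal-%d-size-%d", p, s)
      samples <- runSet(sub, p, tag)
      mp <- mapDag(poolChains(samples))
      mapRows[[length(mapRows) + 1L]] <-
        data.frame(proposal = sprintf("proposal-%d", p), size = s,
                   mapLogScore = mp$logScore)
    }
  }

  ssd <- do.call(rbind, ssdRows)
  map <- do.call(rbind, mapRows)
  write.table(ssd, file.path(outDir, "ssd_summary.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  write.table(map, file.path(outDir, "map_scores.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)

  digests <- list()
  for (f in c(config$data, config$mask))
    if (!is.null(f) && file.exists(f))
      digests[[f]] <- unname(tools::md5sum(f))
  manifest <- list(package = "mcmcDag",
                   version = as.character(packageVersion("mcmcDag")),
                   seed = seed, config = config,
                   chainSeeds = lapply(seq_along(proposals), function(p)
                     vapply(seq_len(nChains), function(j)
                       .chainSeed(seed, p, j), integer(1))),
                   inputDigests = digests,
                   outputs = list.files(outDir, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(ssd = ssd, map = map, samples = allSamples))
}

#' Re-run an experiment from its manifest
#'
#' Reconstructs the configuration (including per-chain seeds) stored in a
#' `manifest.json` and re-executes the experiment into `outDir`; retained
#' DAG sequences reproduce exactly on the same platform.
#'
#' @param manifestPath path to a manifest written by [runExperiment()].
#' @param outDir output directory for the re-run.
#' @export
replayExperiment <- function(manifestPath, outDir) {
  manifest <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
  cfg <- manifest$config
  if (!is.null(cfg$proposals) && !is.list(cfg$proposals))
    cfg$proposals <- as.list(as.data.frame(t(cfg$proposals)))
  runExperiment(cfg, outDir)
}
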