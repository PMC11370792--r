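#' Default pipeline configuration
#'
#' Returns the bundled demo configuration: a complete synthetic study with
#' three TDP subtypes at sizes small enough for an interactive run. Every
#' stochastic stage derives its own seed from the global seed via
#' [deriveSeed()], so adding stages never perturbs existing ones.
#'
#' @param seed global integer seed.
#' @return a named list (the run configuration).
#' @export
defaultConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    geometry = list(nRegions = 60L, layout = "sphere"),
    expression = list(nGenes = 150L, autocorrScale = 0.5, nDonors = 1L,
                      donorNoiseSd = 0.2),
    geneLists = list(fracHar = 0.15, fracCs = 0.08, overlapEnrichment = 2),
    subtypes = c("TDP-A", "TDP-B", "TDP-C"),
    atrophy = list(plantedPerSubtype = 3L, weight = 1, noiseSd = 0.5),
    cohort = list(nControls = 40L, nPatients = 6L, noiseSd = 0.1,
                  severity = 1,
                  covariates = list(age = list(mean = 70, sd = 8, beta = -0.005),
                                    sex = list(levels = c("F", "M"), beta = 0.02))),
    association = list(B = 60L, q = 0.05, tau = 0.2),
    sweep = list(tauGrid = seq(0, 0.5, 0.05)),
    sequences = list(lengthRange = c(300L, 900L), guLow = 0.01, guHigh = 0.06),
    connectivity = list(nSeeds = 20L, kernelScale = 0.5, noiseSd = 0.05),
    graph = list(theta = 0.3, maxGenes = 25L)
  )
}

#' Validate a pipeline configuration
#'
#' Fails fast (before any output is written) on schema violations.
#'
#' @param config a configuration list, see [defaultConfig()].
#' @return the config, invisibly, if valid.
#' @export
validateConfig <- function(config) {
  need <- c("seed", "geometry", "expression", "geneLists", "subtypes",
            "atrophy", "cohort", "association", "sequences", "connectivity",
            "graph")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config error: missing section(s): ", paste(miss, collapse = ", "))
  if (config$association$B < 1) stop("config error: B must be >= 1")
  if (config$geometry$nRegions < 4) stop("config error: nRegions must be >= 4")
  q <- config$association$q
  if (q <= 0 || q >= 1) stop("config error: q must be in (0, 1)")
  if (config$association$tau < 0) stop("config error: tau must be >= 0")
  if (length(config$subtypes) < 2) stop("config error: need >= 2 subtypes")
  invisible(config)
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file.
#' @return the configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$subtypes <- as.character(cfg$subtypes)
  validateConfig(cfg)
}

#' @rdname readRunConfig
#' @param config a configuration list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes every stage in dependency order on synthetic data: geometry and
#' expression generation, gene-list and sequence simulation, per-subtype
#' cohorts, the normative W-score model, group-averaged atrophy maps,
#' surrogate-corrected spatial association, the uniqueness-index threshold
#' sweep, gene-set overlap statistics, GU-repeat scoring, the co-expression
#' graph, and epicentre assignment. All outputs are plain-text files in
#' `outDir`; a manifest records every artifact with its MD5 checksum and
#' the config hash. Reruns with the same config and seed reproduce
#' identical outputs.
#'
#' @param config configuration list (see [defaultConfig()]) or path to a
#'   YAML file.
#' @param outDir output directory (created; must be empty or absent).
#' @return invisibly, the manifest as a list.
#' @export
runPipeline <- function(config = defaultConfig(), outDir) {
  if (is.character(config)) config <- readRunConfig(config)
  validateConfig(config)
  if (dir.exists(outDir) && length(list.files(outDir)))
    stop("config error: output directory not empty")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  gseed <- function(stage) deriveSeed(config$seed, stage)
  outputs <- character(0)
  emit <- function(name, writer) {
    path <- file.path(outDir, name)
    writer(path)
    outputs <<- c(outputs, name)
    path
  }

  ## geometry + expression
  geom <- makeGeometry(config$geometry$nRegions, config$geometry$layout,
                       seed = gseed("geometry"))
  expr <- makeExpression(geom, config$expression$nGenes,
                         config$expression$autocorrScale,
                         nDonors = config$expression$nDonors,
                         donorNoiseSd = config$expression$donorNoiseSd,
                         seed = gseed("expression"))
  emit("expression.tsv", function(p) writeExpressionTSV(expr, p))
  genes <- rownames(SummarizedExperiment::assay(expr, "expr"))

  ## gene lists
  catalog <- makeGeneLists(genes, config$geneLists$fracHar,
                           config$geneLists$fracCs,
                           config$geneLists$overlapEnrichment,
                           seed = gseed("geneLists"))
  emit("har_genes.txt", function(p) writeGeneList(geneSet(catalog, "HAR"), p))
  emit("cs_genes.txt", function(p) writeGeneList(geneSet(catalog, "CS"), p))

  ## per-subtype atrophy truth, cohorts, W-maps
  truth <- list()
  groupMaps <- list()
  patientMaps <- list()
  for (st in config$subtypes) {
    sseed <- gseed(paste0("atrophy_", st))
    planted <- withSeed(sseed, sample(genes, config$atrophy$plantedPerSubtype))
    pw <- setNames(rep(config$atrophy$weight, length(planted)), planted)
    atr <- makeAtrophy(geom, expr, pw, noiseSd = config$atrophy$noiseSd,
                       autocorrScale = config$expression$autocorrScale,
                       seed = sseed, label = st)
    coh <- makeCohort(geom, config$cohort$nControls, config$cohort$nPatients,
                      config$cohort$covariates, atrophy = atr$wmap,
                      severity = config$cohort$severity,
                      noiseSd = config$cohort$noiseSd,
                      seed = gseed(paste0("cohort_", st)))
    ctrl <- coh$subjects[coh$subjects$group == "control", ]
    pats <- coh$subjects[coh$subjects$group == "patient", ]
    model <- fitControlModel(ctrl, names(config$cohort$covariates))
    wm <- computeWMaps(pats, model)
    patientMaps[[st]] <- wm
    gm <- groupAverage(wm, label = st)
    groupMaps[[st]] <- gm
    truth[[st]] <- list(plantedGenes = atr$truth$plantedGenes,
                        realizedR = as.list(atr$truth$realizedR))
    emit(paste0("wmap_", st, ".tsv"), function(p) writeWMapTSV(gm, p))
  }

  ## spatial association per subtype
  tables <- list()
  for (st in config$subtypes) {
    sa <- spatialAssociation(groupMaps[[st]], expr, geom,
                             B = config$association$B,
                             q = config$association$q,
                             tau = config$association$tau,
                             seed = gseed(paste0("surrogates_", st)))
    tables[[st]] <- sa$table
    emit(paste0("correlations_", st, ".tsv"), function(p)
      write.table(sa$table, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  ## threshold sweep + uniqueness index
  sweep <- thresholdSweep(tables, config$sweep$tauGrid,
                          alpha = config$association$q)
  tauStar <- attr(sweep, "tauStar")
  emit("sweep.tsv", function(p)
    write.table(sweep, p, sep = "\t", quote = FALSE, row.names = FALSE))

  ## set statistics
  selected <- lapply(tables, function(tb) tb$gene[tb$selected])
  corrUnion <- unique(unlist(selected))
  setStats <- list(tauStar = tauStar)
  if (length(corrUnion) && length(geneSet(catalog, "HAR"))) {
    f <- fisherOverlap(geneSet(catalog, "HAR"), corrUnion, genes)
    setStats$harOverlap <- list(overlap = f$overlap, p = f$p)
  }
  if (length(corrUnion) && length(geneSet(catalog, "CS"))) {
    f <- fisherOverlap(geneSet(catalog, "CS"), corrUnion, genes)
    setStats$csOverlap <- list(overlap = f$overlap, p = f$p)
    ora <- oraCollections(corrUnion, geneSets(catalog), genes)
    emit("ora.tsv", function(p)
      write.table(ora, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  ## GU repeats: CS genes get elevated GT-run probability
  gw <- setNames(rep(config$sequences$guLow, length(genes)), genes)
  gw[geneSet(catalog, "CS")] <- config$sequences$guHigh
  seqs <- makeSequences(genes, config$sequences$lengthRange, gw,
                        seed = gseed("sequences"))
  emit("sequences.fasta", function(p) writeFasta(seqs, p))
  prof <- guProfile(seqs)
  emit("gu_profile.tsv", function(p)
    write.table(prof, p, sep = "\t", quote = FALSE, row.names = FALSE))
  highGu <- classifyHighGu(prof)
  emit("high_gu_genes.txt", function(p) writeGeneList(highGu, p))
  if (length(highGu)) {
    f <- fisherOverlap(highGu, geneSet(catalog, "CS"), genes)
    setStats$highGuCsOverlap <- list(overlap = f$overlap, p = f$p)
  }

  ## co-expression graph over top correlated genes
  graphGenes <- head(corrUnion, config$graph$maxGenes)
  if (length(graphGenes) >= 3) {
    R <- coexpressionMatrix(expr, graphGenes)
    gph <- binarizeAndDegree(R, theta = config$graph$theta)
    emit("graph_nodes.tsv", function(p)
      write.table(data.frame(gene = gph@genes, degree = gph@degree),
                  p, sep = "\t", quote = FALSE, row.names = FALSE))
    emit("graph_edges.tsv", function(p)
      write.table(graphEdges(gph), p, sep = "\t", quote = FALSE,
                  row.names = FALSE))
  }

  ## epicentres
  lib <- makeConnectivityLibrary(geom, config$connectivity$nSeeds,
                                 config$connectivity$kernelScale,
                                 noiseSd = config$connectivity$noiseSd,
                                 seed = gseed("connectivity"))
  emit("connectivity.tsv", function(p) writeConnectivityTSV(lib, p))
  assign <- do.call(rbind, lapply(config$subtypes, function(st)
    findEpicentres(patientMaps[[st]], lib, st)))
  emit("epicentres.tsv", function(p)
    write.table(assign, p, sep = "\t", quote = FALSE, row.names = FALSE))
  freq <- epicentreFrequency(assign)
  emit("epicentre_frequency.tsv", function(p)
    write.table(freq$frequency, p, sep = "\t", quote = FALSE,
                row.names = FALSE))

  ## truth + summary stats + manifest
  emit("truth.json", function(p)
    jsonlite::write_json(truth, p, auto_unbox = TRUE, digits = NA))
  emit("set_statistics.json", function(p)
    jsonlite::write_json(setStats, p, auto_unbox = TRUE, digits = NA,
                         na = "null"))
  cfgJson <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "atrogex",
    version = as.character(utils::packageVersion("atrogex")),
    seed = config$seed,
    configHash = unname(digestString(cfgJson)),
    outputs = lapply(setNames(outputs, outputs), function(f)
      unname(tools::md5sum(file.path(outDir, f)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# MD5 of a string via a temp file (tools::md5sum is file-based).
digestString <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(x), tf)
  unname(tools::md5sum(tf))
}

#' Summarize a completed pipeline run
#'
#' Reads the manifest of a run directory, verifies every artifact's
#' checksum (a mismatch raises an integrity warning), and assembles a
#' one-row-per-analysis summary from the stage outputs without any
#' recomputation. Stages whose outputs are absent from the manifest are
#' marked absent rather than treated as errors.
#'
#' @param runDir directory written by [runPipeline()].
#' @return data.frame: analysis, status, detail.
#' @export
reportRun <- function(runDir) {
  mpath <- file.path(runDir, "manifest.json")
  if (!file.exists(mpath)) stop("incomplete run: no manifest")
  manifest <- jsonlite::read_json(mpath)
  for (f in names(manifest$outputs)) {
    path <- file.path(runDir, f)
    if (!file.exists(path)) stop("incomplete run: missing artifact ", f)
    if (!identical(unname(tools::md5sum(path)),
                   unname(unlist(manifest$outputs[[f]]))))
      warning("integrity warning: checksum mismatch for ", f)
  }
  has <- function(f) f %in% names(manifest$outputs)
  rows <- list()
  add <- function(analysis, status, detail = "")
    rows[[length(rows) + 1]] <<- data.frame(analysis = analysis,
                                            status = status, detail = detail,
                                            stringsAsFactors = FALSE)
  if (has("expression.tsv")) add("expression", "present", "")
  corr <- grep("^correlations_", names(manifest$outputs), value = TRUE)
  for (f in corr) {
    tb <- read.delim(file.path(runDir, f))
    add(sub("\\.tsv$", "", f), "present",
        sprintf("%d selected of %d genes", sum(tb$selected), nrow(tb)))
  }
  if (has("sweep.tsv")) {
    sw <- read.delim(file.path(runDir, "sweep.tsv"))
    add("sweep", "present", sprintf("%d thresholds", nrow(sw)))
  } else add("sweep", "absent")
  if (has("set_statistics.json")) {
    ss <- jsonlite::read_json(file.path(runDir, "set_statistics.json"))
    add("set_statistics", "present",
        paste(names(ss), collapse = ", "))
  } else add("set_statistics", "absent")
  if (has("high_gu_genes.txt"))
    add("gu_repeats", "present",
        sprintf("%d high-GU genes",
                length(readGeneList(file.path(runDir, "high_gu_genes.txt")))))
  else add("gu_repeats", "absent")
  if (has("graph_nodes.tsv")) {
    nd <- read.delim(file.path(runDir, "graph_nodes.tsv"))
    add("graph", "present", sprintf("%d nodes, max degree %d",
                                    nrow(nd), max(nd$degree)))
  } else add("graph", "absent")
  if (has("epicentres.tsv")) {
    ep <- read.delim(file.path(runDir, "epicentres.tsv"))
    add("epicentres", "present", sprintf("%d patients", nrow(ep)))
  } else add("epicentres", "absent")
  do.call(rbind, rows)
}
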