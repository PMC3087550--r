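# Pipeline orchestration: harvest -> align -> tree -> root -> PoGO ->
# ancestry, as one reproducible run with config validation, structured
# logging and a run manifest.
#
# Each stage writes its outputs under `out_dir` and the manifest records
# per-stage paths, row counts and md5 hashes; re-running with an
# identical config and seed reproduces identical hashes for every
# deterministic stage.

.pipeline_defaults <- function() list(
  manifest = NULL, queries = NULL, est_fasta = NULL,
  outgroup_fasta = NULL, out_dir = NULL,
  evalue = 1e-4, min_coverage = 0.40, collapse_identity = 0.99,
  distance = "pdist", bootstrap = 1000L, seed = 1L,
  min_support = 50, refs = c("At", "Os"), focal_nodes = NULL,
  prefix_ids = FALSE)

#' Validate a pipeline configuration
#'
#' Fills defaults and checks every parameter before any stage runs.
#'
#' @param config Named list, or path to a YAML file mirroring the flags
#'   (`manifest`, `queries`, `est_fasta`, `outgroup_fasta`, `out_dir`,
#'   `evalue`, `min_coverage`, `distance`, `bootstrap`, `seed`,
#'   `min_support`, `refs`, `focal_nodes`).
#' @return The completed config list.
#' @export
validatePipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(.pipeline_defaults()))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ","),
         call. = FALSE)
  cfg <- utils::modifyList(.pipeline_defaults(), config)
  if (is.null(cfg$manifest) || is.null(cfg$queries) ||
      is.null(cfg$out_dir))
    stop("config requires 'manifest', 'queries' and 'out_dir'",
         call. = FALSE)
  if (!is.numeric(cfg$min_coverage) || cfg$min_coverage < 0 ||
      cfg$min_coverage > 1)
    stop("min_coverage must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(cfg$evalue) || cfg$evalue <= 0)
    stop("evalue must be positive", call. = FALSE)
  if (!cfg$distance %in% c("pdist", "pam001"))
    stop("distance must be 'pdist' or 'pam001'", call. = FALSE)
  if (!is.numeric(cfg$bootstrap) || cfg$bootstrap < 1)
    stop("bootstrap must be a positive integer", call. = FALSE)
  if (!is.numeric(cfg$min_support) || cfg$min_support < 0 ||
      cfg$min_support > 100)
    stop("min_support must lie in [0, 100]", call. = FALSE)
  cfg
}

.plog <- function(state, stage, level, msg, ...) {
  line <- sprintf("[%s] %s %s: %s", stage, level,
                  format(Sys.time(), "%H:%M:%S"), sprintf(msg, ...))
  message(line)
  if (!is.null(state$logfile))
    cat(line, "\n", file = state$logfile, append = TRUE)
  invisible(NULL)
}

.stage_record <- function(state, stage, outputs, counts) {
  state$manifest$stages[[stage]] <- list(
    outputs = as.list(outputs),
    md5 = as.list(unname(tools::md5sum(unlist(outputs)))),
    counts = as.list(counts),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  invisible(NULL)
}

#' Run the full family-profiling pipeline
#'
#' Executes harvest (proteome search, EST search, aligned-block
#' extraction, coverage filter, redundancy collapse), multiple alignment,
#' tree building with bootstrap, outgroup rooting, PoGO calling and
#' ancestry reporting, writing all artifacts plus a run manifest under
#' `out_dir`.  Any stage error aborts with the stage name.
#'
#' @param config See [validatePipelineConfig()].
#' @return The run manifest (list), invisibly; also written as
#'   `run_manifest.yaml`.
#' @export
runPipeline <- function(config) {
  cfg <- validatePipelineConfig(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- new.env(parent = emptyenv())
  state$logfile <- file.path(cfg$out_dir, "run.log")
  cat("", file = state$logfile)
  cfg_echo <- cfg
  yaml::write_yaml(cfg_echo, file.path(cfg$out_dir, "config_echo.yaml"))
  state$manifest <- list(
    tool = "PoGOfam",
    version = as.character(utils::packageVersion("PoGOfam")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(
      file.path(cfg$out_dir, "config_echo.yaml"))),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    stages = list())
  run_stage <- function(stage, fn) {
    .plog(state, stage, "INFO", "start")
    tryCatch(fn(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  scfg <- scoringConfig(evalue_max = cfg$evalue)

  registry <- readSpeciesRegistry(cfg$manifest)
  tb <- registryTable(registry)
  queries <- Biostrings::readAAStringSet(cfg$queries)
  names(queries) <- vapply(strsplit(names(queries), "[ \t]+"), `[`,
                           character(1), 1L)
  # ---- harvest ----
  family_path <- file.path(cfg$out_dir, "family.faa")
  run_stage("harvest", function() {
    if (is.null(tb$fasta_path))
      stop("manifest lacks a fasta_path column")
    prots <- Biostrings::AAStringSet()
    for (i in seq_len(nrow(tb))) {
      p <- readProteinFasta(tb$fasta_path[i], tb$species_code[i],
                            prefix_species = cfg$prefix_ids)
      prots <- c(prots, p)
    }
    ests <- if (!is.null(cfg$est_fasta))
      Biostrings::readDNAStringSet(cfg$est_fasta)
    else Biostrings::DNAStringSet()
    if (length(ests))
      names(ests) <- vapply(strsplit(names(ests), "[ \t]+"), `[`,
                            character(1), 1L)
    phits <- list(); ehits <- list()
    for (q in seq_along(queries)) {
      phits[[q]] <- searchProtein(queries[q], prots, scfg)
      if (length(ests))
        ehits[[q]] <- searchTranslated(queries[q], ests, scfg)
    }
    phits <- do.call(rbind, phits)
    ehits <- if (length(ehits)) do.call(rbind, ehits) else .empty_hsps()
    .plog(state, "harvest", "INFO",
          "%d protein hits, %d translated-EST hits",
          nrow(phits), nrow(ehits))
    fam <- hitsToFasta(phits, prots)
    qlen <- setNames(Biostrings::nchar(queries), names(queries))
    blocks <- Biostrings::AAStringSet()
    if (nrow(ehits)) {
      cov <- coverageFilter(ehits, qlen, cfg$min_coverage)
      .plog(state, "harvest", "INFO",
            "coverage filter kept %d / %d EST subjects",
            length(cov$kept), length(cov$kept) + length(cov$discarded))
      for (sid in cov$kept) {
        b <- extractAlignedBlocks(ehits[ehits$subject_id == sid, ],
                                  ests[[sid]])
        names(b) <- paste0(sid, "_blocks")
        blocks <- c(blocks, b)
      }
    }
    fam_all <- c(fam, blocks)
    n_before <- length(fam_all)
    fam_all <- collapseRedundant(fam_all, cfg$collapse_identity, scfg)
    .plog(state, "harvest", "INFO",
          "redundancy collapse: %d -> %d records", n_before,
          length(fam_all))
    writeFasta(fam_all, family_path)
    .stage_record(state, "harvest", c(family = family_path),
                  c(records = length(fam_all)))
  })

  # ---- msa ----
  aln_path <- file.path(cfg$out_dir, "family_aligned.faa")
  outgroup_ids <- character(0)
  run_stage("msa", function() {
    fam <- Biostrings::readAAStringSet(family_path)
    S4Vectors::mcols(fam) <- NULL
    if (!is.null(cfg$outgroup_fasta)) {
      og <- Biostrings::readAAStringSet(cfg$outgroup_fasta)
      names(og) <- vapply(strsplit(names(og), "[ \t]+"), `[`,
                          character(1), 1L)
      outgroup_ids <<- names(og)
      fam <- fam[setdiff(names(fam), names(og))]  # avoid double entries
      fam <- c(fam, og)
    }
    aln <- progressiveMsa(fam, scfg)
    writeAlignedFasta(aln, aln_path)
    .stage_record(state, "msa", c(alignment = aln_path),
                  c(rows = length(aln), columns = Biostrings::nchar(aln)[1]))
  })

  # ---- tree ----
  tree_path <- file.path(cfg$out_dir, "gene_tree.nwk")
  run_stage("tree", function() {
    aln <- readAlignedFasta(aln_path)
    tr <- bootstrapSupport(aln, n_replicates = as.integer(cfg$bootstrap),
                           seed = cfg$seed, model = cfg$distance)
    writeNewick(tr, tree_path)
    .stage_record(state, "tree", c(tree = tree_path),
                  c(leaves = ape::Ntip(tr)))
  })

  # ---- root ----
  rooted_path <- file.path(cfg$out_dir, "gene_tree_rooted.nwk")
  run_stage("root", function() {
    tr <- readNewick(tree_path)
    if (length(outgroup_ids) == 0L)
      stop("no outgroup supplied (outgroup_fasta)")
    rooted <- rootWithOutgroup(tr, outgroup_ids)
    writeNewick(rooted, rooted_path)
    .stage_record(state, "root", c(tree = rooted_path),
                  c(outgroup = length(outgroup_ids)))
  })

  # ---- pogo ----
  pogo_path <- file.path(cfg$out_dir, "pogo_report.tsv")
  pogos <- NULL
  run_stage("pogo", function() {
    rooted <- readNewick(rooted_path)
    pogos <<- callPogos(rooted, registry,
                        reference_species = cfg$refs,
                        min_support = cfg$min_support,
                        outgroup_ids = outgroup_ids)
    writePogoReport(pogos, pogo_path)
    .plog(state, "pogo", "INFO", "%d PoGOs, %d paralog groups",
          length(pogoGroups(pogos)), length(paralogGroups(pogos)))
    .stage_record(state, "pogo", c(report = pogo_path),
                  c(pogos = length(pogoGroups(pogos))))
  })

  # ---- ancestry ----
  founders_path <- file.path(cfg$out_dir, "founders.tsv")
  events_path <- file.path(cfg$out_dir, "events.tsv")
  run_stage("ancestry", function() {
    focal <- cfg$focal_nodes
    if (is.null(focal)) focal <- lineageNodes(registry)
    writeAncestryReports(pogos, registry, focal,
                         founders_path = founders_path,
                         events_path = events_path)
    .stage_record(state, "ancestry",
                  c(founders = founders_path, events = events_path),
                  c(focal_nodes = length(focal)))
  })

  state$manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  yaml::write_yaml(state$manifest,
                   file.path(cfg$out_dir, "run_manifest.yaml"))
  invisible(state$manifest)
}
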