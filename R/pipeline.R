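#' Read and validate a run configuration
#'
#' Plain YAML configuration driving the pipeline commands. Recognized keys:
#' \code{proteins} (FASTA path), \code{peptides} (peptide TSV path),
#' \code{bioactive_table} (TSV path; default the bundled fixture),
#' \code{enzymes} (list of labels), \code{time_grid}, \code{out_dir},
#' \code{include_ambiguous} (logical, default FALSE), \code{mask_below}
#' (report masking threshold), \code{csv} (logical: peptide table is
#' comma-separated) and an optional \code{simulator} block (\code{seed},
#' \code{base_hazard}, \code{n_molecules}, \code{p1_weights},
#' \code{p1prime_weights}, \code{detect_min_len}, \code{detect_max_len},
#' \code{detect_prob}, \code{protein_id}, \code{enzyme}).
#'
#' All referenced paths must exist; enzyme labels must be distinct.
#'
#' @param path YAML file path.
#' @return a named list (class \code{cep_config}).
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) cepStop("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  for (key in c("proteins", "peptides", "bioactive_table")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      cepStop("config '%s': path does not exist: %s", key, cfg[[key]])
  }
  if (!is.null(cfg$enzymes) && anyDuplicated(cfg$enzymes))
    cepStop("config: enzyme labels must be distinct")
  if (is.null(cfg$out_dir)) cfg$out_dir <- "."
  if (is.null(cfg$include_ambiguous)) cfg$include_ambiguous <- FALSE
  if (is.null(cfg$mask_below)) cfg$mask_below <- 0L
  cfg$config_path <- path
  class(cfg) <- c("cep_config", "list")
  cfg
}

# Internal: write a small run log (version, config hash, input digests) next
# to the outputs, and echo it to stderr.
writeRunLog <- function(cfg, command, inputs) {
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  digests <- vapply(unlist(inputs, use.names = TRUE),
                    function(p) unname(tools::md5sum(p)), character(1))
  info <- list(
    tool = "CEPspec",
    version = as.character(utils::packageVersion("CEPspec")),
    command = command,
    config = cfg$config_path,
    config_md5 = if (!is.null(cfg$config_path))
      unname(tools::md5sum(cfg$config_path)) else NA,
    input_md5 = as.list(digests),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(cfg$out_dir, paste0("run_", command, ".json"))
  jsonlite::write_json(info, path, auto_unbox = TRUE, null = "null")
  message(sprintf("[CEPspec %s] %s: inputs %s", info$version, command,
                  paste(names(digests), collapse = ", ")))
  invisible(info)
}

# Internal: load shared inputs for a config.
loadConfigInputs <- function(cfg, needPeptides = TRUE) {
  proteins <- if (!is.null(cfg$proteins)) loadFasta(cfg$proteins)
              else caseinReferences()
  obs <- NULL
  if (needPeptides) {
    if (is.null(cfg$peptides))
      cepStop("config: 'peptides' path is required for this command",
              class = "cep_schema_error")
    sep <- if (isTRUE(cfg$csv)) "," else "\t"
    obs <- readPeptideTable(cfg$peptides, sep = sep)
  }
  list(proteins = proteins, observations = obs)
}

#' Pipeline command: map peptides to proteins
#'
#' Maps the configured peptide table onto the protein references and writes
#' \code{mapped_peptides.tsv} plus \code{unmapped_peptides.tsv} under the
#' configured output directory. Unmapped observations are reported, never
#' dropped.
#'
#' @param cfg a configuration from [readRunConfig()] (or an equivalent
#'   list).
#' @return invisibly, the [mapObservations()] result.
#' @export
runMapping <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- loadConfigInputs(cfg)
  res <- mapObservations(inp$observations, inp$proteins)
  writeMappedPeptides(res$mapped, file.path(cfg$out_dir, "mapped_peptides.tsv"))
  utils::write.table(res$unmapped,
                     file.path(cfg$out_dir, "unmapped_peptides.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(res$unmapped))
    warning(nrow(res$unmapped), " observation(s) could not be mapped")
  if (nrow(inp$observations) == 0L)
    warning("peptide table is empty; outputs are empty")
  writeRunLog(cfg, "map", list(proteins = cfg$proteins,
                               peptides = cfg$peptides))
  invisible(res)
}

#' Pipeline command: full specificity analysis
#'
#' Runs the complete chain for each configured enzyme and substrate:
#' mapping, cleavage-site inference over the time course, subsite
#' specificity table (TSV report + JSON with unrounded values and means),
#' site count and bond coverage; when exactly two enzymes are configured,
#' the inter-enzyme site-overlap and peptide-overlap reports are included.
#' Outputs are deterministic given the config.
#'
#' @param cfg a configuration from [readRunConfig()].
#' @return invisibly, a list: per-substrate, per-enzyme results plus
#'   overlap summaries.
#' @export
runSpecificity <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- loadConfigInputs(cfg)
  obs <- inp$observations
  enzymes <- cfg$enzymes
  if (is.null(enzymes)) enzymes <- sort(unique(obs$enzyme))
  out <- list()
  for (pid in sort(unique(obs$protein_id))) {
    protein <- inp$proteins[[pid]]
    perEnzyme <- list()
    for (enz in enzymes) {
      sel <- obs[obs$protein_id == pid & obs$enzyme == enz, , drop = FALSE]
      if (!nrow(sel)) next
      mapping <- mapObservations(sel, inp$proteins)
      tc <- buildTimeCourse(mapping$mapped, protein, enzyme = enz,
                            includeAmbiguous = isTRUE(cfg$include_ambiguous))
      sites <- if (length(tc@times)) cumulativeSites(tc) else integer()
      spec <- buildSpecificityTable(sites, protein, enzyme = enz)
      stem <- file.path(cfg$out_dir, sprintf("specificity_%s_%s", pid, enz))
      writeSpecificityTable(spec, paste0(stem, ".tsv"),
                            maskBelow = cfg$mask_below)
      writeSpecificityJson(spec, paste0(stem, ".json"))
      writeSiteTable(tc, protein, file.path(cfg$out_dir,
                     sprintf("sites_%s_%s.tsv", pid, enz)))
      perEnzyme[[enz]] <- list(
        sites = sites, nSites = length(sites),
        bondCoverage = bondCoverage(sites, protein),
        peptides = unique(mapping$mapped$peptide),
        specificity = spec, timeCourse = tc)
    }
    summary <- list(enzymes = perEnzyme)
    if (length(perEnzyme) == 2L) {
      labs <- names(perEnzyme)
      summary$siteOverlap <- siteOverlap(perEnzyme[[1]]$sites,
                                         perEnzyme[[2]]$sites)
      summary$peptideOverlap <- peptideOverlap(perEnzyme[[1]]$peptides,
                                               perEnzyme[[2]]$peptides)
      ov <- summary$siteOverlap
      jsonlite::write_json(
        list(protein_id = pid, enzymes = labs,
             n_sites = list(ov$nA, ov$nB), n_shared = ov$nShared,
             pct_shared_of_A = ov$pctA, pct_shared_of_B = ov$pctB,
             pct_peptides_shared_of_union =
               summary$peptideOverlap$pctSharedOfUnion),
        file.path(cfg$out_dir, sprintf("overlap_%s.json", pid)),
        auto_unbox = TRUE, digits = NA)
    }
    out[[pid]] <- summary
  }
  writeRunLog(cfg, "specificity", list(proteins = cfg$proteins,
                                       peptides = cfg$peptides))
  invisible(out)
}

#' Pipeline command: bioactive-peptide matching
#'
#' Matches each enzyme's observed peptide set against the bioactive
#' reference table and writes a match report plus a per-substrate,
#' per-enzyme summary (counts, shared, exclusive).
#'
#' @param cfg a configuration from [readRunConfig()].
#' @return invisibly, a list: per-substrate summaries.
#' @export
runBioactive <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- loadConfigInputs(cfg)
  obs <- inp$observations
  tablePath <- if (!is.null(cfg$bioactive_table)) cfg$bioactive_table
               else system.file("extdata", "bioactive_peptides.tsv",
                                package = "CEPspec")
  ref <- loadBioactiveTable(tablePath)
  enzymes <- cfg$enzymes
  if (is.null(enzymes)) enzymes <- sort(unique(obs$enzyme))
  out <- list()
  for (pid in sort(unique(obs$protein_id))) {
    byEnzyme <- lapply(enzymes, function(enz)
      unique(obs$sequence[obs$protein_id == pid & obs$enzyme == enz]))
    names(byEnzyme) <- enzymes
    matches <- lapply(byEnzyme, matchBioactive, table = ref)
    writeBioactiveReport(matches,
                         file.path(cfg$out_dir,
                                   sprintf("bioactive_%s.tsv", pid)))
    if (length(enzymes) == 2L) {
      out[[pid]] <- summarizeBioactive(byEnzyme[[1]], byEnzyme[[2]], ref,
                                       labels = enzymes)
      jsonlite::write_json(
        list(protein_id = pid,
             counts = as.list(out[[pid]]$counts),
             shared = out[[pid]]$nShared),
        file.path(cfg$out_dir, sprintf("bioactive_summary_%s.json", pid)),
        auto_unbox = TRUE, digits = NA)
    } else {
      out[[pid]] <- list(matches = matches)
    }
  }
  writeRunLog(cfg, "bioactive", list(peptides = cfg$peptides,
                                     bioactive_table = tablePath))
  invisible(out)
}

#' Pipeline command: simulate a synthetic peptide dataset
#'
#' Builds a \linkS4class{DigestionModel} from the config's
#' \code{simulator} block and writes the simulated observation table as
#' \code{simulated_peptides.tsv}. A seed is mandatory: identical configs
#' yield byte-identical tables.
#'
#' @param cfg a configuration from [readRunConfig()].
#' @return invisibly, the simulated observation data.frame.
#' @export
runSimulation <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- cfg$simulator
  if (is.null(sim)) cepStop("config: 'simulator' block is required")
  if (is.null(sim$seed))
    cepStop("config: simulator.seed is required for reproducible output")
  proteins <- if (!is.null(cfg$proteins)) loadFasta(cfg$proteins)
              else caseinReferences()
  pid <- if (!is.null(sim$protein_id)) sim$protein_id else names(proteins)[1]
  if (!pid %in% names(proteins))
    cepStop("simulator.protein_id '%s' not among loaded proteins", pid,
            class = "cep_lookup_error")
  toNum <- function(x, default) if (is.null(x)) default else as.numeric(x)
  model <- digestionModel(
    baseHazard = toNum(sim$base_hazard, 5e-5),
    p1Weights = unlist(sim$p1_weights),
    p1primeWeights = unlist(sim$p1prime_weights),
    nMolecules = toNum(sim$n_molecules, 500),
    detectMinLen = toNum(sim$detect_min_len, 3),
    detectMaxLen = toNum(sim$detect_max_len, 40),
    detectProb = toNum(sim$detect_prob, 0.8),
    seed = as.integer(sim$seed))
  times <- if (!is.null(cfg$time_grid)) as.numeric(cfg$time_grid)
           else c(0, 8, 24, 30, 48, 56)
  enzyme <- if (!is.null(sim$enzyme)) sim$enzyme else "sim"
  obs <- simulateDataset(proteins[[pid]], model, times = times,
                         enzyme = enzyme)
  writePeptideTable(obs, file.path(cfg$out_dir, "simulated_peptides.tsv"))
  writeRunLog(cfg, "simulate", list(proteins = cfg$proteins))
  invisible(obs)
}
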