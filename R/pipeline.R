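# End-to-end orchestration: flat-file run configuration and the four
# pipeline commands (scan, events, test, simulate). A thin subcommand CLI
# over these functions ships in inst/scripts/codonloss.R.

#' Read a flat key=value run configuration
#'
#' One \code{key = value} (or \code{key<TAB>value}) pair per line; blank
#' lines and lines starting with \code{#} are ignored. Recognized keys:
#' \code{alignment}, \code{tree}, \code{reference}, \code{frame_offset},
#' \code{foreground} (comma-separated tips), \code{mask} (intervals such
#' as \code{"120-180,400-460"}), \code{freq} (equal/f1x4/f3x4),
#' \code{stop_frame} (query/reference), \code{seed}, \code{out_dir}.
#' All referenced paths are validated at once.
#'
#' @param path Path to the config file.
#' @return A named list with parsed, validated fields.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_]+)\\s*[=\t]\\s*(.*?)\\s*$",
                                  lines))
  bad <- lines[vapply(kv, length, integer(1)) != 3L]
  if (length(bad))
    stop("unparseable config lines: ", paste(bad, collapse = " | "))
  cfg <- setNames(lapply(kv, `[`, 3L), vapply(kv, `[`, character(1), 2L))
  problems <- character()
  for (key in c("alignment", "tree"))
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      problems <- c(problems, sprintf("%s path does not exist: %s",
                                      key, cfg[[key]]))
  if (!is.null(cfg$freq) &&
      !tolower(cfg$freq) %in% c("equal", "f1x4", "f3x4"))
    problems <- c(problems, paste("unknown freq scheme:", cfg$freq))
  if (!is.null(cfg$stop_frame) &&
      !cfg$stop_frame %in% c("query", "reference"))
    problems <- c(problems, paste("unknown stop_frame:", cfg$stop_frame))
  if (!is.null(cfg$seed) && is.na(suppressWarnings(as.integer(cfg$seed))))
    problems <- c(problems, paste("seed is not an integer:", cfg$seed))
  if (length(problems))
    stop("invalid run configuration:\n  ",
         paste(problems, collapse = "\n  "))
  if (!is.null(cfg$foreground))
    cfg$foreground <- trimws(strsplit(cfg$foreground, ",")[[1]])
  if (!is.null(cfg$frame_offset))
    cfg$frame_offset <- as.integer(cfg$frame_offset)
  if (!is.null(cfg$seed)) cfg$seed <- as.integer(cfg$seed)
  if (!is.null(cfg$freq))
    cfg$freq <- c(equal = "equal", f1x4 = "F1x4",
                  f3x4 = "F3x4")[[tolower(cfg$freq)]]
  if (!is.null(cfg$mask)) {
    iv <- strsplit(trimws(strsplit(cfg$mask, ",")[[1]]), "-")
    cfg$mask <- lapply(iv, function(x) as.integer(x))
    if (any(vapply(cfg$mask, function(x)
      length(x) != 2L || anyNA(x) || x[1] > x[2], logical(1))))
      stop("invalid mask interval specification")
  }
  cfg
}

.loadInputs <- function(config) {
  seqs <- readCodonFasta(config$alignment)
  ref <- config$reference %||% names(seqs)[1]
  aln <- codonAlignment(seqs, ref, config$frame_offset %||% 0L)
  for (iv in config$mask %||% list())
    aln <- maskRegion(aln, iv[1], iv[2])
  tree <- readSpeciesTree(config$tree)
  if (!is.null(config$foreground))
    tree <- speciesTree(tree@tree, foreground = config$foreground)
  list(alignment = aln, tree = tree)
}

#' Pipeline command: scan for ORF disruptions
#'
#' Runs the scanner over every non-reference sequence present in the tree
#' (or all sequences when no tree is configured) and writes the disruption
#' report and functional calls to \code{out_dir}.
#'
#' @param config A list from \code{\link{readRunConfig}} (or built
#'   directly).
#' @return Invisibly, a list with \code{records}, \code{calls} and the
#'   report path.
#' @export
pipelineScan <- function(config) {
  inp <- .loadInputs(config)
  aln <- inp$alignment
  frame <- config$stop_frame %||% "query"
  records <- scanDisruptions(aln, frame = frame)
  calls <- classifyFunctional(records,
                              setdiff(speciesIds(aln), referenceId(aln)))
  outDir <- config$out_dir %||% "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(outDir, "disruptions.tsv")
  writeDisruptionReport(records, calls, path)
  callsPath <- file.path(outDir, "functional_calls.tsv")
  write.table(calls, callsPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(records = records, calls = calls,
                 paths = c(path, callsPath)))
}

#' Pipeline command: infer loss events
#'
#' Scans, groups shared disruptions and infers the minimum set of
#' independent loss events on the configured tree.
#'
#' @inheritParams pipelineScan
#' @return Invisibly, a list with \code{shared}, \code{events} and the
#'   report path.
#' @export
pipelineEvents <- function(config) {
  inp <- .loadInputs(config)
  aln <- inp$alignment
  tree <- inp$tree
  species <- intersect(setdiff(speciesIds(aln), referenceId(aln)),
                       tree@tree$tip.label)
  records <- scanDisruptions(aln, species = species,
                             frame = config$stop_frame %||% "query")
  calls <- classifyFunctional(records, species)
  shared <- collectShared(records)
  events <- inferLossEvents(shared, calls, tree)
  outDir <- config$out_dir %||% "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(outDir, "loss_events.tsv")
  writeLossReport(events, path)
  invisible(list(shared = shared, events = events, path = path))
}

#' Pipeline command: branch-model battery for the configured foreground
#'
#' Scans, classifies, prunes to the configured foreground lineage and runs
#' the one-ratio / two-ratio / fixed-omega-1 model battery with LRTs.
#'
#' @inheritParams pipelineScan
#' @return Invisibly, the \code{\link{runBattery}} result plus the report
#'   path.
#' @export
pipelineTest <- function(config) {
  if (is.null(config$foreground))
    stop("a foreground lineage is required for the model battery")
  inp <- .loadInputs(config)
  aln <- inp$alignment
  tree <- inp$tree
  species <- intersect(setdiff(speciesIds(aln), referenceId(aln)),
                       tree@tree$tip.label)
  records <- scanDisruptions(aln, species = species,
                             frame = config$stop_frame %||% "query")
  calls <- classifyFunctional(records, species)
  battery <- runBattery(aln, calls, tree, config$foreground,
                        freq = config$freq %||% "F3x4")
  outDir <- config$out_dir %||% "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(outDir, "battery.tsv")
  writeBatteryReport(battery, paste(config$foreground, collapse = ","),
                     path)
  battery$path <- path
  invisible(battery)
}

#' Pipeline command: simulate a fixture bundle
#'
#' Simulates a codon alignment under the configured tree and omega regime,
#' plants the configured loss events and writes FASTA + Newick + truth TSV.
#'
#' @param config A list with at least \code{tree} (path) and \code{seed};
#'   optional \code{foreground}, \code{n_codons}, \code{out_dir}.
#' @return Invisibly, the simulation result with output paths.
#' @export
pipelineSimulate <- function(config) {
  if (is.null(config$seed)) stop("simulation requires a seed")
  tree <- readSpeciesTree(config$tree)
  if (!is.null(config$foreground))
    tree <- speciesTree(tree@tree, foreground = config$foreground)
  lossClades <- if (!is.null(config$loss))
    lapply(strsplit(trimws(strsplit(config$loss, ";")[[1]]), ","), trimws)
    else list()
  cfg <- simConfig(tree,
                   nCodons = as.integer(config$n_codons %||% 300L),
                   lossClades = lossClades, seed = config$seed)
  sim <- simulateAlignment(cfg)
  sim <- plantPseudogenization(sim$alignment, sim$truth, cfg)
  outDir <- config$out_dir %||% "."
  paths <- writeSimBundle(sim, cfg, outDir)
  sim$paths <- paths
  invisible(sim)
}
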