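#' Write fluorescence traces to delimited text
#'
#' One TSV file per trace with header comment lines carrying the
#' protocol (as JSON), the seed and other metadata, followed by
#' `time_s` and `dF` columns. Round-trips exactly through
#' [readTraces()].
#'
#' @param traces a [FluorescenceTrace-class] or a list of them.
#' @param path output file (single trace) or directory (list).
#' @return The written file path(s), invisibly.
#' @export
writeTraces <- function(traces, path) {
  if (is(traces, "FluorescenceTrace")) {
    .writeTrace(traces, path)
    return(invisible(path))
  }
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  files <- vapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    id <- tr@meta$cell_id
    if (is.null(id)) id <- sprintf("trace%03d", i)
    f <- file.path(path, sprintf("%s_%03d.tsv", id, i))
    .writeTrace(tr, f)
    f
  }, character(1))
  invisible(files)
}

.writeTrace <- function(trace, file) {
  p <- trace@protocol
  proto_json <- jsonlite::toJSON(list(
    bursts = p@bursts, temperature = p@temperature, ca_mM = p@ca_mM,
    condition = p@condition, trace_duration = p@trace_duration,
    sample_interval = p@sample_interval), auto_unbox = TRUE, digits = NA)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# protocol=", proto_json),
    paste0("# seed=", if (is.null(trace@meta$seed)) "NA" else trace@meta$seed),
    paste0("# cell_id=", if (is.null(trace@meta$cell_id)) "NA" else trace@meta$cell_id),
    paste0("# genotype=", if (is.null(trace@meta$genotype)) "NA" else trace@meta$genotype),
    "time_s\tdF"), con)
  writeLines(sprintf("%.17g\t%.17g", trace@t, trace@dF), con)
}

#' Read fluorescence traces from delimited text
#'
#' Reads one trace file, or every `*.tsv` file in a directory, in the
#' format written by [writeTraces()]. Malformed rows and files are
#' rejected with informative errors (including line numbers); an empty
#' file is an explicit error, not an empty result.
#'
#' @param path a file or directory.
#' @return A [FluorescenceTrace-class] (single file) or a list of them
#'   (directory).
#' @export
readTraces <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tsv$", full.names = TRUE))
    if (!length(files)) stop("no .tsv trace files in ", path)
    return(lapply(files, .readTrace))
  }
  .readTrace(path)
}

.readTrace <- function(file) {
  lines <- readLines(file)
  if (!length(lines)) stop("empty trace file: ", file)
  hdr <- grep("^#", lines, value = TRUE)
  proto_line <- grep("^# protocol=", hdr, value = TRUE)
  if (!length(proto_line))
    stop("missing '# protocol=' header comment in ", file)
  pj <- jsonlite::fromJSON(sub("^# protocol=", "", proto_line[1]))
  bursts <- as.data.frame(pj$bursts)
  bursts[] <- lapply(bursts, as.numeric)
  proto <- new("StimulusProtocol",
    bursts = bursts, temperature = pj$temperature,
    ca_mM = pj$ca_mM, condition = pj$condition,
    trace_duration = pj$trace_duration,
    sample_interval = pj$sample_interval)

  seed_line <- grep("^# seed=", hdr, value = TRUE)
  seed <- if (length(seed_line)) {
    s <- sub("^# seed=", "", seed_line[1])
    if (s == "NA") NA else as.integer(s)
  } else NA
  getm <- function(key) {
    l <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(l)) sub(paste0("^# ", key, "="), "", l[1]) else NA_character_
  }

  body <- lines[!grepl("^#", lines)]
  if (!length(body)) stop("no data rows in ", file)
  if (body[1] != "time_s\tdF")
    stop("missing 'time_s\\tdF' header row in ", file)
  body <- body[-1]
  if (!length(body)) stop("no data rows in ", file)
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2)
  if (length(bad))
    stop("malformed row(s) in ", file, " at data line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  t <- as.numeric(vapply(parts, `[[`, character(1), 1))
  dF <- as.numeric(vapply(parts, `[[`, character(1), 2))
  if (anyNA(t) || anyNA(dF)) {
    bad <- which(is.na(t) | is.na(dF))
    stop("non-numeric value(s) in ", file, " at data line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (length(t) > 1 && any(diff(t) <= 0))
    stop("non-monotone time column in ", file)
  new("FluorescenceTrace", t = t, dF = dF, protocol = proto,
      meta = list(cell_id = getm("cell_id"), genotype = getm("genotype"),
                  seed = seed))
}

#' Write a run manifest
#'
#' Records the provenance of a set of output files: the resolved
#' configuration (as a hash of its serialised form), the seeds used,
#' the package version and one line per output file. Re-running the
#' same command with the same config and seed regenerates the manifest
#' verbatim.
#'
#' @param file manifest path.
#' @param command the command or function name that produced the run.
#' @param config a list (or `NULL`) of resolved configuration values.
#' @param seed integer seed used.
#' @param outputs character vector of files produced.
#' @return The manifest path, invisibly.
#' @export
writeRunManifest <- function(file, command, config = NULL, seed = NA,
                             outputs = character(0)) {
  cfg_hash <- sprintf("%08x",
    sum(utf8ToInt(paste(deparse(config), collapse = "")) *
          seq_along(utf8ToInt(paste(deparse(config), collapse = "")))) %%
      .Machine$integer.max)
  lines <- c(
    paste0("command: ", command),
    paste0("package: pHendo ",
           as.character(utils::packageVersion("pHendo"))),
    paste0("seed: ", seed),
    paste0("config_hash: ", cfg_hash),
    paste0("output: ", outputs))
  writeLines(lines, file)
  invisible(file)
}

#' Generate the canonical small fixture dataset
#'
#' Emits 3 cells probed at 5, 25 and 100 AP (10 Hz, 37C defaults), each
#' as a noiseless expected reference trace and one noisy stochastic
#' trace, plus a single noise-free bafilomycin trace (1000 AP 10 Hz),
#' with a sidecar TSV recording every cell's true `tau1` and `slope_m`.
#' The noiseless reference cells are pure linear-slowing cells
#' (`alpha_max = 0`, `tau_reacid = 0`) so that an offset-free
#' exponential fit and the tuning-curve regression recover the sidecar
#' parameters exactly; the noisy traces use the full default kinetics.
#' Byte-identical across runs for a fixed seed.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @return List with `files` (written paths) and `params` (the sidecar
#'   data.frame), invisibly.
#' @export
makeFixtures <- function(dir, seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- defaultKinetics("37C")
  spec <- defaultPopulation(3, "37C", rng_seed = seed)
  cells <- drawCellKinetics(spec)
  ref_cells <- lapply(cells, function(cl) {
    cl@alpha_max <- 0; cl@tau_reacid <- 0; cl@noise_sd <- 0
    cl
  })
  stimuli <- c(5, 25, 100)
  files <- character(0)
  for (ci in seq_along(cells)) {
    for (si in seq_along(stimuli)) {
      proto <- StimulusProtocol(stimuli[si], temperature = "37C")
      exp_tr <- expectedTrace(ref_cells[[ci]], proto)
      exp_tr@meta$cell_id <- sprintf("cell%d_%dAP_noiseless", ci, stimuli[si])
      noisy <- simulateTrace(cells[[ci]], proto,
                             seed = .deriveSeed(seed, ci, si, 1))
      noisy@meta$cell_id <- sprintf("cell%d_%dAP_noisy", ci, stimuli[si])
      for (tr in list(exp_tr, noisy)) {
        f <- file.path(dir, paste0(tr@meta$cell_id, ".tsv"))
        .writeTrace(tr, f)
        files <- c(files, f)
      }
    }
  }
  baf_cell <- base
  baf_cell@noise_sd <- 0
  baf_proto <- StimulusProtocol(1000, temperature = "37C",
                                condition = "bafilomycin", post_window = 30)
  # a 1000 AP train without requenching exhausts the pool by design
  baf <- suppressWarnings(
    simulateTrace(baf_cell, baf_proto, seed = .deriveSeed(seed, 9, 9, 9)))
  baf@meta$cell_id <- "bafilomycin_1000AP"
  fb <- file.path(dir, "bafilomycin_1000AP.tsv")
  .writeTrace(baf, fb)
  files <- c(files, fb)

  params <- data.frame(
    cell = sprintf("cell%d", seq_along(cells)),
    tau1 = vapply(cells, function(c) c@tau1, numeric(1)),
    slope_m = vapply(cells, function(c) c@slope_m, numeric(1)))
  fp <- file.path(dir, "cell_params.tsv")
  utils::write.table(format(params, digits = 17), fp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(files = c(files, fp), params = params))
}
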