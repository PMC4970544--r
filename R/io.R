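# Readers/writers for the package's plain-text artifacts (trace TSV +
# JSON sidecar, event CSV, summary JSON, YAML run configs) and the run
# manifest. All writers are locale-independent (dot decimal, UTF-8, comma
# CSV with a header and no index column).

#' Write force-distance traces as TSV + JSON sidecars
#'
#' Each trace `i` becomes `trace_i.tsv` (columns `distance_nm`,
#' `force_pN`) and `trace_i.json` (velocity, cantilever spring constant
#' and, for synthetic traces, the ground-truth event metadata).
#'
#' @param traces list of [fdc_trace] objects.
#' @param dir output directory (created if needed).
#' @return invisibly, the TSV paths.
#' @export
write_fdc_traces <- function(traces, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    stub <- file.path(dir, sprintf("trace_%04d", i))
    df <- data.frame(distance_nm = tr$distance, force_pN = tr$force)
    write.table(df, paste0(stub, ".tsv"), sep = "\t", row.names = FALSE,
                quote = FALSE)
    meta <- list(velocity_nm_s = tr$velocity,
                 cantilever_k_pN_nm = tr$cantilever_k,
                 ground_truth = tr$ground_truth)
    jsonlite::write_json(meta, paste0(stub, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
    paths[i] <- paste0(stub, ".tsv")
  }
  invisible(paths)
}

#' Read force-distance traces from a directory
#'
#' @param dir directory containing `*.tsv` traces with matching `*.json`
#'   sidecars (as written by [write_fdc_traces]).
#' @return list of [fdc_trace] objects.
#' @export
read_fdc_traces <- function(dir) {
  tsvs <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(tsvs) == 0) {
    stop("no .tsv traces found in ", dir, call. = FALSE)
  }
  lapply(tsvs, function(p) {
    df <- read.delim(p, check.names = FALSE)
    need <- c("distance_nm", "force_pN")
    if (!all(need %in% names(df))) {
      stop("trace file ", basename(p), " lacks required columns ",
           paste(setdiff(need, names(df)), collapse = ", "),
           " (expected distance_nm, force_pN)", call. = FALSE)
    }
    side <- sub("\\.tsv$", ".json", p)
    if (!file.exists(side)) {
      stop("missing JSON sidecar for ", basename(p),
           " (expected ", basename(side), ")", call. = FALSE)
    }
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    fdc_trace(df$distance_nm, df$force_pN,
              velocity = meta$velocity_nm_s,
              cantilever_k = meta$cantilever_k_pN_nm,
              ground_truth = meta$ground_truth)
  })
}

#' Write / read rupture-event tables
#'
#' CSV with columns `force_pN`, `keff_pN_nm`, `velocity_nm_s`,
#' `loading_rate_pN_s`.
#'
#' @param events a [rupture_events] data frame.
#' @param path CSV path.
#' @return `write_events`: the path, invisibly. `read_events`: a
#'   [rupture_events] data frame.
#' @export
write_events <- function(events, path) {
  df <- data.frame(force_pN = events$force, keff_pN_nm = events$keff,
                   velocity_nm_s = events$velocity,
                   loading_rate_pN_s = events$loading_rate)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("no such events file: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE)
  need <- c("force_pN", "keff_pN_nm", "velocity_nm_s")
  if (!all(need %in% names(df))) {
    stop("events file lacks required columns ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  rupture_events(df$force_pN, df$keff_pN_nm, df$velocity_nm_s)
}

#' Run manifest
#'
#' Every pipeline run writes exactly one `manifest.json` capturing the
#' package version, the full config, the root seed, digests of the input
#' files and the output file list, so a run can be reproduced
#' bit-for-bit for its deterministic stages.
#'
#' @param out_dir run output directory.
#' @param config the config list used.
#' @param seed the root seed.
#' @param inputs character vector of input file paths (digested).
#' @param outputs character vector of output file paths.
#' @return invisibly, the manifest path.
#' @export
write_manifest <- function(out_dir, config, seed, inputs = character(),
                           outputs = character()) {
  man <- list(
    tool = "vwforce",
    version = as.character(utils::packageVersion("vwforce")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    input_digests = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = basename(outputs))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path, call. = FALSE)
  yaml::read_yaml(path)
}
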