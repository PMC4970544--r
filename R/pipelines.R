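# End-to-end pipelines tying the stages together:
#   SMFS: traces -> events -> binding stats -> first-peak fits ->
#         Bell-Evans LRD fit -> optional BSK fit
#   BD:   shear sweep -> tensile profiles -> Bell-Evans lifetimes

#' Run the SMFS analysis pipeline
#'
#' Chains trace analysis and kinetic fitting. Input is either a directory
#' of traces (`config$traces`) or an existing events CSV
#' (`config$events`; detection is then bypassed). Per velocity, the
#' first-peak Gaussian is fitted and forces inside mu +/- sigma are kept
#' for the Bell-Evans loading-rate-dependence fit; the LRD scatter
#' (force vs log10 loading rate) is written for plotting. When
#' `config$bsk` is truthy, a BSK fit of the per-velocity Gaussian
#' summaries (optionally combined with MD forces from `config$md_forces`)
#' is added.
#'
#' @param config named list (or YAML path) with entries: one of `traces`
#'   (dir) or `events` (CSV); optional `snr` (default 4), `fit_window`
#'   (nm, default 10), `temperature` (K, default 298), `min_peak_n`
#'   (default 50), `bsk` (logical), `md_forces` (CSV with `force_pN`,
#'   `loading_rate_pN_s`), `exclude_max_md` (logical), `seed`.
#' @param out_dir output directory.
#' @return invisibly, a list with `events`, `binding_stats`, `peaks`,
#'   `bell_evans`, and (optionally) `bsk` / `bsk_band`.
#' @export
run_smfs_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  set.seed(seed)
  temperature <- config$temperature %||% 298
  inputs <- character()
  outputs <- character()

  if (!is.null(config$events)) {
    events <- read_events(config$events)
    inputs <- config$events
    binding <- NULL
  } else if (!is.null(config$traces)) {
    traces <- read_fdc_traces(config$traces)
    inputs <- list.files(config$traces, full.names = TRUE)
    an <- analyze_traces(traces, snr_threshold = config$snr %||% 4,
                         fit_window = config$fit_window %||% 10)
    events <- an$events
    binding <- an$binding_stats
    jsonlite::write_json(unclass(binding),
                         file.path(out_dir, "binding_stats.json"),
                         auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, "binding_stats.json")
  } else {
    stop("config must provide `traces` (directory) or `events` (CSV); ",
         "got neither", call. = FALSE)
  }
  if (nrow(events) == 0) stop("no rupture events to fit", call. = FALSE)
  write_events(events, file.path(out_dir, "events.csv"))
  outputs <- c(outputs, "events.csv")

  # per-velocity first-peak fits and mu +/- sigma selection
  min_n <- config$min_peak_n %||% 50
  peaks <- list()
  selected <- list()
  for (v in sort(unique(events$velocity))) {
    ev <- events[events$velocity == v, ]
    if (nrow(ev) < min_n) {
      selected[[as.character(v)]] <- ev
      next
    }
    pk <- fit_first_peak(ev$force, n_bins = config$n_bins %||% NULL,
                         min_n = min_n)
    peaks[[as.character(v)]] <- pk
    keep <- ev$force >= pk$mu - pk$sigma & ev$force <= pk$mu + pk$sigma
    selected[[as.character(v)]] <- ev[keep, ]
  }
  sel_events <- do.call(rbind, selected)
  class(sel_events) <- c("rupture_events", "data.frame")

  be <- fit_bell_evans(sel_events, temperature = temperature)
  jsonlite::write_json(
    list(koff_per_s = be$koff, x_beta_nm = be$x_beta,
         se_koff = be$se_koff, se_x_beta = be$se_x_beta,
         temperature_K = be$temperature, log_likelihood = be$log_likelihood,
         n_events = be$n_events),
    file.path(out_dir, "bell_evans_fit.json"), auto_unbox = TRUE,
    digits = NA)
  lrd <- data.frame(log10_loading_rate = log10(sel_events$loading_rate),
                    force_pN = sel_events$force)
  write.csv(lrd, file.path(out_dir, "lrd_scatter.csv"), row.names = FALSE,
            quote = FALSE)
  outputs <- c(outputs, "bell_evans_fit.json", "lrd_scatter.csv")

  res <- list(events = events, binding_stats = binding, peaks = peaks,
              bell_evans = be)
  if (isTRUE(config$bsk)) {
    afm <- summarize_velocities(events, min_n = min_n)
    md <- NULL
    if (!is.null(config$md_forces)) {
      mdf <- read.csv(config$md_forces)
      md <- data.frame(force = mdf$force_pN, LR = mdf$loading_rate_pN_s)
      inputs <- c(inputs, config$md_forces)
    }
    bf <- fit_bsk(afm, md = md, temperature = temperature,
                  exclude_max_md = isTRUE(config$exclude_max_md),
                  seed = seed)
    band <- bsk_confidence_band(bf, n_boot = config$n_boot %||% 200,
                                seed = seed)
    jsonlite::write_json(
      list(E_kBT = bf$params$E, x_b_nm = bf$params$x_b,
           D_nm2_s = bf$params$D, k0_per_s = bf$params$k0,
           log_likelihood = bf$log_likelihood),
      file.path(out_dir, "bsk_fit.json"), auto_unbox = TRUE, digits = NA)
    write.csv(data.frame(LR = band$LR, mean_force = band$mean_force,
                         lo95 = band$lo, hi95 = band$hi),
              file.path(out_dir, "bsk_band.csv"), row.names = FALSE,
              quote = FALSE)
    outputs <- c(outputs, "bsk_fit.json", "bsk_band.csv")
    res$bsk <- bf
    res$bsk_band <- band
  }
  write_manifest(out_dir, config, seed, inputs,
                 file.path(out_dir, outputs))
  invisible(res)
}

# shear rates of the tensile-profile sweep, 1/s
#' Default shear-rate sweep
#'
#' @return the eight shear rates 5.5, 18, 55, 182, 545, 1818, 5453 and
#'   18175 1/s used for the tensile-profile sweep.
#' @export
sweep_shear_rates <- function() c(5.5, 18, 55, 182, 545, 1818, 5453, 18175)

#' Run the BD shear-sweep pipeline
#'
#' Runs one BD simulation per shear rate, writes one tensile-profile CSV
#' per rate (`bond_index`, `mean_length_nm`, `force_pN`, `se_pN`) and a
#' summary JSON with the grafted-end tension and the Bell-Evans lifetime
#' at each rate.
#'
#' @param config named list (or YAML path). Chain entries under `chain`
#'   (passed to [chain_config]; in YAML spell the bead count `n_beads` --
#'   a bare `N` key is a YAML 1.1 boolean), engine entries under `engine`
#'   (passed to [engine_config]); further: `shear_rates` (default
#'   [sweep_shear_rates]), `tau0` (s, default 100), `x_beta` (nm, default
#'   0.3), `seed`.
#' @param out_dir output directory.
#' @return invisibly, list of [bd_run] objects (one per shear rate) plus
#'   the summary data frame.
#' @export
run_bd_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  chain_args <- config$chain %||% list()
  # YAML 1.1 resolves a bare `N` key as a boolean, so configs spell the
  # bead count `n_beads`
  if (!is.null(chain_args$n_beads)) {
    chain_args$N <- chain_args$n_beads
    chain_args$n_beads <- NULL
  }
  cfg <- do.call(chain_config, chain_args)
  rates <- config$shear_rates %||% sweep_shear_rates()
  tau0 <- config$tau0 %||% 100
  x_beta <- config$x_beta %||% 0.3
  outputs <- character()
  runs <- list()
  summary <- NULL
  for (i in seq_along(rates)) {
    eng_args <- modifyList(config$engine %||% list(),
                           list(shear_rate = rates[i],
                                seed = seed + i - 1L))
    eng <- do.call(engine_config, eng_args)
    run <- bd_run(cfg, eng)
    runs[[i]] <- run
    prof <- run$profile
    fn <- sprintf("profile_shear_%g.csv", rates[i])
    write.csv(data.frame(bond_index = seq_along(prof$tensile_force),
                         mean_length_nm = prof$mean_bond_length,
                         force_pN = prof$tensile_force,
                         se_pN = prof$se),
              file.path(out_dir, fn), row.names = FALSE, quote = FALSE)
    outputs <- c(outputs, fn)
    summary <- rbind(summary, data.frame(
      shear_rate = rates[i], f0_pN = prof$tensile_force[1],
      f0_se_pN = prof$se[1],
      lifetime_s = lifetime_under_shear(prof, tau0, x_beta,
                                        cfg$temperature)))
  }
  jsonlite::write_json(summary, file.path(out_dir, "bd_summary.json"),
                       digits = NA, dataframe = "rows")
  outputs <- c(outputs, "bd_summary.json")
  write_manifest(out_dir, config, seed, character(),
                 file.path(out_dir, outputs))
  invisible(list(runs = runs, summary = summary))
}
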