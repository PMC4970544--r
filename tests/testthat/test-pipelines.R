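# IO round trips, manifests, and the two end-to-end pipelines

test_that("trace and event files round-trip and reject malformed input", {
  dir <- withr::local_tempdir()
  p <- synthetic_fdc_params(n_cycles = 5, seed = 1)
  traces <- gen_fdc_traces(p)
  write_fdc_traces(traces, dir)
  back <- read_fdc_traces(dir)
  expect_length(back, 5)
  expect_equal(back[[1]]$force, traces[[1]]$force)
  expect_equal(back[[1]]$velocity, traces[[1]]$velocity)

  ev <- gen_rupture_dataset(0.01, 0.3, n_per_velocity = 10, seed = 2)
  path <- file.path(dir, "ev.csv")
  write_events(ev, path)
  ev2 <- read_events(path)
  expect_equal(ev2$force, ev$force)
  expect_equal(ev2$loading_rate, ev$loading_rate)

  bad <- file.path(dir, "bad.csv")
  write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_events(bad), "required columns")
  expect_error(read_events(file.path(dir, "nope.csv")), "no such")
  expect_error(read_fdc_traces(withr::local_tempdir()), "no .tsv")
})

test_that("SMFS pipeline runs end-to-end on synthetic traces and shows the blocking drop", {
  root <- withr::local_tempdir()
  vels <- c(200, 800, 3000)
  tr_dir <- file.path(root, "traces")
  for (v in vels) {
    p <- synthetic_fdc_params(velocity = v, specific_fraction = 0.7,
                              n_cycles = 120, seed = 100 + v)
    write_fdc_traces(gen_fdc_traces(p), tr_dir)
  }
  out <- file.path(root, "out")
  res <- run_smfs_pipeline(list(traces = tr_dir, seed = 3), out)
  expect_true(file.exists(file.path(out, "events.csv")))
  expect_true(file.exists(file.path(out, "bell_evans_fit.json")))
  expect_true(file.exists(file.path(out, "lrd_scatter.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_s3_class(res$bell_evans, "bell_evans_fit")
  expect_gt(res$binding_stats$bp, 0.5)

  # blocked condition: BP collapses
  bl_dir <- file.path(root, "blocked")
  for (v in vels) {
    p <- synthetic_fdc_params(velocity = v, specific_fraction = 0.05,
                              n_cycles = 120, seed = 200 + v)
    write_fdc_traces(gen_fdc_traces(p), bl_dir)
  }
  bl_traces <- read_fdc_traces(bl_dir)
  bp_blocked <- binding_probability(lapply(bl_traces, detect_rupture))$bp
  expect_lt(bp_blocked, res$binding_stats$bp / 4)

  # events-only input bypasses detection and reproduces deterministically
  out2 <- file.path(root, "out2")
  res2 <- run_smfs_pipeline(list(events = file.path(out, "events.csv"),
                                 seed = 3), out2)
  expect_null(res2$binding_stats)
  expect_equal(res2$bell_evans$koff, res$bell_evans$koff, tolerance = 1e-9)
  out3 <- file.path(root, "out3")
  run_smfs_pipeline(list(events = file.path(out, "events.csv"), seed = 3),
                    out3)
  expect_identical(unname(tools::md5sum(file.path(out2, "events.csv"))),
                   unname(tools::md5sum(file.path(out3, "events.csv"))))
  expect_error(run_smfs_pipeline(list(seed = 1), file.path(root, "x")),
               "traces.*events|events.*traces")
})

test_that("BD pipeline writes one profile per shear rate plus a lifetime summary", {
  root <- withr::local_tempdir()
  cfgl <- list(chain = list(N = 8),
               engine = list(n_steps = 3000, n_equil = 500),
               shear_rates = c(545, 18175), tau0 = 100, x_beta = 0.3,
               seed = 7)
  res <- suppressWarnings(run_bd_pipeline(cfgl, root))
  profs <- list.files(root, pattern = "^profile_shear_.*csv$")
  expect_length(profs, 2)
  df <- read.csv(file.path(root, profs[1]))
  expect_equal(nrow(df), 7)            # N - 1 bonds
  expect_named(df, c("bond_index", "mean_length_nm", "force_pN", "se_pN"))
  expect_true(file.exists(file.path(root, "bd_summary.json")))
  expect_equal(nrow(res$summary), 2)
  expect_true(all(res$summary$lifetime_s <= 100))

  # a single-rate run reproduces the corresponding sweep member
  root2 <- withr::local_tempdir()
  cfg1 <- cfgl; cfg1$shear_rates <- 545
  res1 <- suppressWarnings(run_bd_pipeline(cfg1, root2))
  expect_equal(res1$summary$f0_pN[1], res$summary$f0_pN[1],
               tolerance = 1e-12)
})

test_that("YAML configs load and missing files give actionable errors", {
  dir <- withr::local_tempdir()
  cfg_path <- file.path(dir, "run.yaml")
  writeLines(c("seed: 5", "chain:", "  n_beads: 6", "  epsilon: 3"),
             cfg_path)
  cfg <- read_run_config(cfg_path)
  expect_equal(cfg$seed, 5)
  expect_equal(cfg$chain$n_beads, 6)
  expect_equal(cfg$chain$epsilon, 3)
  # the n_beads alias reaches chain_config as N
  out <- withr::local_tempdir()
  cfg$engine <- list(n_steps = 500, n_equil = 100)
  cfg$shear_rates <- 545
  res <- suppressWarnings(run_bd_pipeline(cfg, out))
  expect_length(res$runs[[1]]$profile$tensile_force, 5)
  expect_error(read_run_config(file.path(dir, "none.yaml")), "no such")
})
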