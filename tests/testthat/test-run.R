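write_kinome_inputs <- function(dir) {
  gen <- generate_kinome_table(kinome_scenario(seed = 1))
  aff <- file.path(dir, "affinities.csv")
  exps <- file.path(dir, "exposures.csv")
  write_result_csv(gen$affinities, aff)
  write_result_csv(dplyr::rename(gen$exposures, cpuss_uM = cpuss), exps)
  list(affinities = aff, exposures = exps, truth = gen$truth)
}

test_that("parameter files round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  p <- jitter_params(gsh_params(), 0.1, seed = 6)
  write_params(p, path)
  expect_equal(read_params(path), p)
  expect_error(read_params(withr::local_tempfile()), "not found")
})

test_that("shipped reference parameter fixtures match the constructors", {
  for (spec in list(c("glycogen_reference.yaml", "glycogen_params"),
                    c("ppp_reference.yaml", "ppp_params"),
                    c("gsh_reference.yaml", "gsh_params"))) {
    path <- system.file("extdata", spec[1], package = "tandemtox")
    expect_true(nzchar(path))
    expect_equal(read_params(path), do.call(spec[2], list()))
  }
})

test_that("result CSVs are byte-stable across repeated writes", {
  df <- tibble::tibble(x = c(pi, exp(1), 1 / 3), label = c("a", "b", "c"))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_result_csv(df, f1)
  write_result_csv(df, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_result_csv(f1)
  expect_equal(back$x, df$x, tolerance = 1e-8)
})

test_that("invalid configurations fail before any output is written", {
  out <- withr::local_tempdir()
  expect_error(run_config(list(stage = "nope", out_dir = out)),
               class = "tandemtox_config_error")
  expect_error(run_config(list(stage = "candidates", out_dir = out,
                               affinities = "/no/such/file.csv")),
               class = "tandemtox_config_error")
  expect_error(run_config(list(stage = "simulate", out_dir = out,
                               horizon = -5)),
               class = "tandemtox_config_error")
  expect_identical(list.files(out), character(0))
})

test_that("the candidates stage writes checksummed outputs and a run record", {
  dir <- withr::local_tempdir()
  inputs <- write_kinome_inputs(dir)
  out <- file.path(dir, "out")
  rec <- run_config(list(
    stage = "candidates", out_dir = out,
    affinities = inputs$affinities, exposures = inputs$exposures,
    drug_a = "drug_a", drug_b = "drug_b"
  ))
  expect_identical(rec$status, "ok")
  expect_true(file.exists(file.path(out, "candidates.csv")))
  expect_true(file.exists(file.path(out, "run_record.json")))
  # manifest checksums match the files on disk
  expect_identical(unname(tools::md5sum(file.path(out, rec$outputs$file))),
                   rec$outputs$md5)
  hits <- read_result_csv(file.path(out, "candidates.csv"))
  expect_setequal(hits$kinase_id, inputs$truth$offtarget_ids)
})

test_that("identical configs produce byte-identical CSV outputs", {
  dir <- withr::local_tempdir()
  cfg <- function(out) list(stage = "scan", which = "glycogen-dose",
                            grid = c(0, 1, 10), horizon = 300, out_dir = out)
  r1 <- run_config(cfg(file.path(dir, "a")))
  r2 <- run_config(cfg(file.path(dir, "b")))
  f1 <- file.path(dir, "a", "scan_glycogen-dose.csv")
  f2 <- file.path(dir, "b", "scan_glycogen-dose.csv")
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("synth and ic50fit stages chain through the file interface", {
  dir <- withr::local_tempdir()
  syn <- file.path(dir, "syn")
  run_config(list(stage = "synth", what = "assay", seed = 7,
                  noise_cv = 0.05, out_dir = syn))
  rec <- run_config(list(stage = "ic50fit",
                         assay = file.path(syn, "synthetic_assay.csv"),
                         out_dir = file.path(dir, "fit")))
  expect_identical(rec$status, "ok")
  gl <- jsonlite::read_json(file.path(dir, "fit", "ic50_summary.json"))
  expect_lt(abs(gl$ic50 - 5.5) / 5.5, 0.2)
})

test_that("a YAML config file is accepted directly", {
  dir <- withr::local_tempdir()
  cfg_path <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(list(stage = "synth", what = "kinome", seed = 2,
                        out_dir = file.path(dir, "out")), cfg_path)
  rec <- run_config(cfg_path)
  expect_identical(rec$status, "ok")
  expect_true(file.exists(file.path(dir, "out",
                                    "synthetic_kinome_truth.json")))
})
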