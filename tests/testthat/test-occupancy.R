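test_that("occupancy follows the binding isotherm and its limits", {
  expect_identical(compute_occupancy(5.5, 5.5), 0.5)
  expect_identical(compute_occupancy(123, 0), 0)
  expect_equal(compute_occupancy(1, 9), 0.9)
  expect_identical(compute_occupancy(NA_real_, 3), 0)

  withr::with_seed(11, {
    kd <- 10^runif(500, -3, 4)
    cp <- 10^runif(500, -3, 2)
    occ <- compute_occupancy(kd, cp)
    expect_true(all(occ > 0 & occ < 1))
    # strictly increasing in exposure, strictly decreasing in kd
    expect_true(all(compute_occupancy(kd, cp * 2) > occ))
    expect_true(all(compute_occupancy(kd * 2, cp) < occ))
  })

  expect_error(compute_occupancy(0, 1), "positive")
  expect_error(compute_occupancy(-1, 1), "positive")
  expect_error(compute_occupancy(1, -0.1), "non-negative")
})

test_that("a drug profile is the element-wise isotherm over its panel", {
  aff <- tibble::tibble(kinase_id = c("K1", "K2", "K3"), drug_id = "a",
                        kd = c(1, 9, NA))
  exps <- tibble::tibble(drug_id = "a", cpuss = 1)
  prof <- occupancy_profile(aff, exps, "a")
  expect_equal(prof$occupancy, c(0.5, 0.1, 0))

  # zero exposure: all-zero profile
  prof0 <- occupancy_profile(aff, tibble::tibble(drug_id = "a", cpuss = 0), "a")
  expect_true(all(prof0$occupancy == 0))

  gen <- generate_kinome_table(kinome_scenario(seed = 42))
  for (d in unique(gen$affinities$drug_id)) {
    p <- occupancy_profile(gen$affinities, gen$exposures, d)
    cp <- gen$exposures$cpuss[gen$exposures$drug_id == d]
    expect_equal(p$occupancy, compute_occupancy(p$kd, cp))
  }

  expect_error(occupancy_profile(aff, exps, "missing"), "no entries")
})

test_that("differential shortlist equals a brute-force filter and ignores row order", {
  gen <- generate_kinome_table(kinome_scenario(seed = 3))
  drugs <- unique(gen$affinities$drug_id)
  pa <- occupancy_profile(gen$affinities, gen$exposures, drugs[1])
  pb <- occupancy_profile(gen$affinities, gen$exposures, drugs[2])

  for (thr in list(c(0.5, 0.1), c(0.3, 0.3), c(0, 1))) {
    hits <- differential_candidates(pa, pb, thr[1], thr[2])
    ref <- brute_force_candidates(pa, pb, thr[1], thr[2])
    if (is.null(ref)) {
      expect_identical(nrow(hits), 0L)
    } else {
      expect_equal(hits$kinase_id, ref$kinase_id)
      expect_equal(hits$delta, ref$delta)
    }
  }

  # shuffled input rows give the identical ranked output
  shuf <- withr::with_seed(9, pa[sample(nrow(pa)), ])
  expect_equal(differential_candidates(shuf, pb), differential_candidates(pa, pb))

  # identical profiles: empty whenever thresholds are incompatible
  expect_identical(nrow(differential_candidates(pa, pa, 0.5, 0.1)), 0L)
  # fully permissive thresholds return every kinase, delta-sorted
  all_hits <- differential_candidates(pa, pb, 0, 1)
  expect_identical(nrow(all_hits), length(union(pa$kinase_id, pb$kinase_id)))
  expect_true(all(diff(all_hits$delta) <= 0))
  expect_equal(all_hits$delta, all_hits$occupancy_a - all_hits$occupancy_b)

  expect_error(differential_candidates(pa, pb, -0.1, 0.5), "thresholds")
  expect_error(differential_candidates(pa, pb, 0.5, 1.5), "thresholds")
})

test_that("profiles align on the kinase union with missing kinases at zero", {
  pa <- tibble::tibble(kinase_id = c("K1", "K2"), occupancy = c(0.8, 0.6))
  pb <- tibble::tibble(kinase_id = c("K2", "K3"), occupancy = c(0.05, 0.9))
  hits <- differential_candidates(pa, pb, 0.5, 0.1)
  expect_equal(hits$kinase_id, c("K1", "K2"))
  expect_equal(hits$occupancy_b, c(0, 0.05))
})

test_that("affinity and exposure readers handle units and censoring", {
  aff_path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "kinase_id,drug_id,kd,unit",
    "K1,a,500,nM",
    "K2,a,2,uM",
    "K3,a,,uM"
  ), aff_path)
  aff <- read_affinity_table(aff_path)
  expect_equal(aff$kd, c(0.5, 2, NA))

  exp_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("drug_id\tcpuss_uM", "a\t0.25"), exp_path)
  exps <- read_exposure_table(exp_path)
  expect_equal(exps$cpuss, 0.25)

  dup_path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("kinase_id,drug_id,kd", "K1,a,1", "K1,a,2"), dup_path)
  expect_error(read_affinity_table(dup_path), "unique")
})
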