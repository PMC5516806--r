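ref <- glycogen_params()

test_that("competitive inhibition only raises the apparent Km", {
  # no inhibitor: plain Michaelis-Menten
  s <- c(0.5, 5, 50)
  expect_equal(phk_rate(s, 0, ref),
               ref$vmax_phk * s / (ref$km_phk + s))
  # S << Km, I = Ki: halved rate, exactly (Km+S)/(2Km+S) of the free rate
  s_small <- 0.01 * ref$km_phk
  ratio <- phk_rate(s_small, ref$ki_drug, ref) / phk_rate(s_small, 0, ref)
  expect_equal(ratio, (ref$km_phk + s_small) / (2 * ref$km_phk + s_small),
               tolerance = 1e-12)
  # competitive limit: enormous inhibitor excess abolishes the flux
  expect_lt(phk_rate(5, 1e6 * ref$ki_drug, ref), 1e-3 * ref$vmax_phk)
  expect_error(phk_rate(-1, 0, ref), ">= 0")
  expect_error(phk_rate(1, -1, ref), ">= 0")
})

test_that("enzyme pools are conserved along trajectories", {
  for (dose in c(0, 5.5, 100)) {
    traj <- simulate_glycogen(ref, drug_conc = dose, horizon = 1000)
    expect_lt(conservation_drift(traj, function(r) r[["gpa"]] + r[["gpb"]]),
              1e-6)
    expect_lt(conservation_drift(traj, function(r) r[["gsa"]] + r[["gsb"]]),
              1e-6)
    expect_true(all(as.matrix(traj[-1]) >= 0))
  }
})

test_that("the drug-free reference state is a fixed point", {
  init <- glycogen_initial_state(ref)
  traj <- simulate_glycogen(ref, drug_conc = 0, horizon = 1000)
  fin <- unlist(traj[nrow(traj), -1])
  expect_relative_equal(fin[names(init)], init, 1e-3)
  # and endpoints at horizon H and 2H agree once relaxed
  ep1 <- endpoint_summary(simulate_glycogen(ref, 0, horizon = 1000))
  ep2 <- endpoint_summary(simulate_glycogen(ref, 0, horizon = 2000))
  expect_relative_equal(unlist(ep2), unlist(ep1), 1e-3)
})

test_that("a constant trajectory has the same endpoint everywhere", {
  traj <- simulate_glycogen(ref, drug_conc = 0, horizon = 500)
  interior <- traj[ceiling(nrow(traj) / 2), ]
  ep <- endpoint_summary(traj)
  expect_relative_equal(ep$glycogen, interior$gly, 1e-3)
  expect_relative_equal(ep$g6p, interior$g6p, 1e-3)
})

test_that("dose endpoints move in the cascade's expected directions", {
  scan <- glycogen_dose_scan(ref, drug_grid = c(0, 10^seq(-2, 2, length.out = 7)),
                             horizon = 1000)
  expect_true(all(diff(scan$phk_activity) <= 0))
  expect_true(all(diff(scan$gp_activity) <= 0))
  expect_true(all(diff(scan$gs_activity) >= 0))
  expect_true(all(diff(scan$glycogen) >= 0))
  expect_true(all(diff(scan$g6p) <= 0))
  # strong inhibition flips the two enzymes relative to drug-free
  hi <- scan[nrow(scan), ]
  expect_lt(hi$gp_activity, scan$gp_activity[1])
  expect_gt(hi$gs_activity, scan$gs_activity[1])
})

test_that("endpoints are insensitive to tightening solver tolerances", {
  ep_loose <- endpoint_summary(simulate_glycogen(ref, 10, horizon = 1000,
                                                 rtol = 1e-6, atol = 1e-8))
  ep_tight <- endpoint_summary(simulate_glycogen(ref, 10, horizon = 1000,
                                                 rtol = 1e-9, atol = 1e-11))
  expect_relative_equal(unlist(ep_tight), unlist(ep_loose), 1e-3)
})

test_that("integrated steady states match independent root-solving", {
  for (dose in c(0, 5.5)) {
    root <- oracle_root_glycogen(ref, dose)
    ss <- steady_glycogen(ref, dose)
    expect_true(ss$converged)
    expect_relative_equal(ss$state[names(root)], root, 1e-3)
  }
  pj <- jitter_params(ref, 0.2, seed = 21)
  root <- oracle_root_glycogen(pj, 5.5)
  ss <- steady_glycogen(pj, 5.5)
  expect_relative_equal(ss$state[names(root)], root, 1e-3)
})

test_that("initial states violating the conserved pools are rejected", {
  bad <- glycogen_initial_state(ref)
  bad[["gpa"]] <- bad[["gpa"]] + 1
  expect_error(simulate_glycogen(ref, initial = bad), "conserved")
})
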