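test_that("fold-changes are 1 under the null perturbation and track the model", {
  fc0 <- fold_changes("glycogen", glycogen_params(), list(),
                      quantities = c("g6p", "glycogen"))
  expect_equal(fc0$ratio, c(1, 1))
  fc <- fold_changes("glycogen", glycogen_params(),
                     list(drug_conc = 100 * 5.5),
                     quantities = c("g6p", "glycogen"))
  expect_lt(fc$ratio[fc$quantity == "g6p"], 1)
  expect_gt(fc$ratio[fc$quantity == "glycogen"], 1)
  expect_equal(fc$ratio * fc$baseline, fc$perturbed)
})

test_that("fold-changes are invariant to the model's concentration unit", {
  pert <- list(drug_conc = 20)
  q <- c("g6p", "glycogen", "gs_activity")
  fc1 <- fold_changes("glycogen", glycogen_params(), pert, q)
  fc10 <- fold_changes("glycogen", rescale_params(glycogen_params(), 10),
                       pert, q)
  expect_relative_equal(fc10$ratio, fc1$ratio, 1e-6)
  # concentration-dimensioned baselines scale with the unit; the active
  # fraction is dimensionless and must not
  conc_q <- fc1$quantity %in% c("g6p", "glycogen")
  expect_relative_equal(fc10$baseline[conc_q], 10 * fc1$baseline[conc_q], 1e-6)
  expect_relative_equal(fc10$baseline[!conc_q], fc1$baseline[!conc_q], 1e-6)
})

test_that("propagate applies ratios to the mapped downstream inputs", {
  fc <- tibble::tibble(quantity = "g6p", baseline = 100, perturbed = 50,
                       ratio = 0.5)
  spec <- interface_spec("glycogen", "ppp", c(g6p = "g6p_initial"))
  cfg <- propagate(fc, spec, list(params = ppp_params(), g6p_initial = 100))
  expect_identical(cfg$g6p_initial, 50)

  # ratio 1 leaves the configuration unchanged
  fc1 <- tibble::tibble(quantity = "g6p", baseline = 100, perturbed = 100,
                        ratio = 1)
  cfg1 <- propagate(fc1, spec, list(params = ppp_params(), g6p_initial = 100))
  expect_identical(cfg1$g6p_initial, 100)

  # absolute mode overwrites instead of scaling
  spec_abs <- interface_spec("glycogen", "ppp", c(g6p = "g6p_initial"),
                             mode = "absolute")
  cfg_abs <- propagate(fc, spec_abs, list(params = ppp_params(),
                                          g6p_initial = 999))
  expect_identical(cfg_abs$g6p_initial, 50)

  # parameters inside $params are reachable too
  spec2 <- interface_spec("ppp", "gsh", c(nadph_ratio = "k_nadph_supply"))
  fc2 <- tibble::tibble(quantity = "nadph_ratio", baseline = 0.6,
                        perturbed = 0.3, ratio = 0.5)
  cfg2 <- propagate(fc2, spec2, list(params = gsh_params()))
  expect_identical(cfg2$params$k_nadph_supply, gsh_params()$k_nadph_supply / 2)

  expect_error(propagate(fc, spec2, list(params = gsh_params())), "missing")
  expect_error(
    propagate(fc, interface_spec("a", "b", c(g6p = "nope")), list(params = ppp_params())),
    "no input")
})

chain <- tandem_chain()
scan <- run_tandem(chain, drug_grid = c(0, 0.1, 1, 10, 100))

test_that("the unperturbed chain reproduces each standalone baseline", {
  d0 <- scan[scan$drug_conc == 0, ]
  expect_true(d0$converged)
  expect_equal(d0$g6p_fold, 1, tolerance = 1e-6)
  expect_equal(d0$nadph_ratio_fold, 1, tolerance = 1e-6)
  expect_equal(d0$gsh_fold, 1, tolerance = 1e-6)
  # standalone endpoints
  ep <- endpoint_summary(simulate_glycogen(chain$glycogen, 0, horizon = 1000))
  expect_relative_equal(d0$g6p, ep$g6p, 1e-3)
  ss_ppp <- steady_ppp(chain$ppp, g6p_initial = chain$g6p_initial)
  expect_relative_equal(d0$nadph_ratio, ss_ppp$nadph_ratio, 1e-3)
  ss_gsh <- steady_gsh(chain$gsh)
  expect_relative_equal(d0$gsh, ss_gsh$state[["gsh"]], 1e-3)
})

test_that("end-to-end endpoints are monotone along the dose grid", {
  expect_true(all(scan$converged))
  expect_true(all(diff(scan$glycogen) >= 0))
  expect_true(all(diff(scan$g6p) <= 0))
  expect_true(all(diff(scan$nadph_ratio) <= 0))
  expect_true(all(diff(scan$gsh) <= 0))
})

test_that("chain fold-changes survive rescaling any single model by 10x", {
  grid <- c(0, 10, 100)
  base <- run_tandem(chain, grid)
  variants <- list(
    tandem_chain(glycogen = rescale_params(glycogen_params(), 10)),
    tandem_chain(ppp = rescale_params(ppp_params(), 10), g6p_initial = 1000),
    tandem_chain(gsh = rescale_params(gsh_params(), 10))
  )
  for (v in variants) {
    alt <- run_tandem(v, grid)
    expect_relative_equal(alt$g6p_fold, base$g6p_fold, 1e-6)
    expect_relative_equal(alt$nadph_ratio_fold, base$nadph_ratio_fold, 1e-6)
    expect_relative_equal(alt$gsh_fold, base$gsh_fold, 1e-6)
  }
})

test_that("a saturating vitamin-E load rescues the high-dose GSH endpoint", {
  with_vite <- run_tandem(tandem_chain(vite_pool = 1e6), c(0, 100))
  rescued <- with_vite$gsh[with_vite$drug_conc == 100]
  # back to the vitamin-E chain's own drug-free level, and at least the
  # plain chain's drug-free GSH (quenching overshoots the redox set point)
  expect_relative_equal(rescued, with_vite$gsh[with_vite$drug_conc == 0], 0.05)
  expect_gte(rescued, scan$gsh[scan$drug_conc == 0] * (1 - 1e-6))
})

test_that("chains must connect the models in pathway order", {
  expect_error(
    tandem_chain(interfaces = list(
      interface_spec("ppp", "gsh", c(nadph_ratio = "k_nadph_supply")),
      interface_spec("glycogen", "ppp", c(g6p = "g6p_initial"))
    )),
    "interfaces must connect")
  expect_error(interface_spec("a", "b", character()), "non-empty")
})
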