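# Independent steady-state oracles: multidimensional root-finding on the
# model RHS (pracma::fsolve in log-space so iterates stay positive),
# started from neutral interior guesses, never from an integrated answer.

solve_positive_root <- function(fn, x0) {
  res <- pracma::fsolve(function(u) fn(exp(u)), log(x0), tol = 1e-12)
  exp(res$x)
}

# glycogen cascade: unknowns (gpa, gsa, gly, g6p); gpb/gsb by conservation
oracle_root_glycogen <- function(params, drug_conc) {
  p <- params
  fn <- function(x) {
    gpa <- x[1]; gsa <- x[2]; gly <- x[3]; g6p <- x[4]
    v_phk <- p$vmax_phk * (p$gp_total - gpa) /
      (p$km_phk * (1 + drug_conc / p$ki_drug) + p$gp_total - gpa)
    v_pp1_gp <- p$vmax_pp1 * gpa / (p$km_pp1 + gpa)
    v_pp1_gs <- p$vmax_pp1 * (p$gs_total - gsa) / (p$km_pp1 + p$gs_total - gsa)
    v_gp <- p$vmax_gp * gpa * gly / (p$km_gp_gly + gly)
    v_gs <- p$vmax_gs * gsa * (g6p / (p$km_gs_g6p + g6p)) * (1 - gly / p$gly_cap)
    c(v_phk - v_pp1_gp,
      v_pp1_gs - p$k_gs_inact * (v_phk / p$vmax_phk) * gsa,
      v_gs - v_gp,
      p$k_g6p_in + v_gp - v_gs - p$k_g6p_out * g6p)
  }
  x <- solve_positive_root(fn, c(p$gp_total / 2, p$gs_total / 2,
                                 p$gly_cap / 4, p$k_g6p_in / p$k_g6p_out))
  c(gpa = x[1], gpb = p$gp_total - x[1], gsa = x[2],
    gsb = p$gs_total - x[2], gly = x[3], g6p = x[4])
}

# oxidative PPP: unknowns (g6p, pg6, nadph); nadp by conservation, ru5p is
# a terminal sink with no steady value
oracle_root_ppp <- function(params, g6p_initial) {
  p <- params
  fn <- function(x) {
    g6p <- x[1]; pg6 <- x[2]; nadph <- x[3]
    nadp <- p$nadp_total - nadph
    v1 <- p$vmax_g6pd * (g6p / (p$km_g6pd_g6p + g6p)) *
      (nadp / (p$km_g6pd_nadp + nadp))
    v2 <- p$vmax_6pgd * (pg6 / (p$km_6pgd_6pg + pg6)) *
      (nadp / (p$km_6pgd_nadp + nadp))
    c(p$k_g6p_refresh * (g6p_initial - g6p) - v1,
      v1 - v2,
      v1 + v2 - p$k_nadph_drain * nadph)
  }
  x <- solve_positive_root(fn, c(g6p_initial / 2, p$km_6pgd_6pg,
                                 p$nadp_total / 2))
  c(g6p = x[1], pg6 = x[2], nadp = p$nadp_total - x[3], nadph = x[3])
}

# glutathione cycle with synthesis/efflux off: unknowns (gssg, h2o2,
# nadph); gsh and nadp by moiety conservation
oracle_root_gsh <- function(params) {
  p <- params
  stopifnot(p$k_synth == 0, p$k_efflux == 0)
  fn <- function(x) {
    gssg <- x[1]; h2o2 <- x[2]; nadph <- x[3]
    gsh <- p$gsh_total_init - 2 * gssg
    nadp <- p$nadp_total - nadph
    v_gpx <- p$vmax_gpx * (gsh / (p$km_gpx_gsh + gsh)) *
      (h2o2 / (p$km_gpx_h2o2 + h2o2))
    v_gr <- p$vmax_gr * (gssg / (p$km_gr_gssg + gssg)) *
      (nadph / (p$km_gr_nadph + nadph))
    c(p$k_h2o2_prod - v_gpx - p$k_vite_quench * p$vite_pool * h2o2,
      v_gpx - v_gr,
      p$k_nadph_supply * (nadp / p$nadp_total) - v_gr)
  }
  x <- solve_positive_root(fn, c(p$gsh_total_init / 8, p$km_gpx_h2o2 / 10,
                                 p$nadp_total / 2))
  c(gsh = p$gsh_total_init - 2 * x[1], gssg = x[1], h2o2 = x[2],
    nadph = x[3], nadp = p$nadp_total - x[3])
}

# brute-force differential shortlist over the kinase union
brute_force_candidates <- function(profile_a, profile_b, min_occ_a, max_occ_b) {
  ids <- sort(union(profile_a$kinase_id, profile_b$kinase_id))
  occ <- function(prof, id) {
    i <- match(id, prof$kinase_id)
    if (is.na(i)) 0 else prof$occupancy[i]
  }
  rows <- lapply(ids, function(id) {
    oa <- occ(profile_a, id); ob <- occ(profile_b, id)
    if (oa >= min_occ_a && ob <= max_occ_b) {
      data.frame(kinase_id = id, occupancy_a = oa, occupancy_b = ob,
                 delta = oa - ob)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out[order(-out$delta, out$kinase_id), , drop = FALSE]
}

# largest relative drift of a conserved quantity along a trajectory
conservation_drift <- function(traj, value_fn) {
  vals <- apply(traj, 1, value_fn)
  max(abs(vals - vals[1])) / abs(vals[1])
}

expect_relative_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol * pmax(abs(expected), 1e-12)),
              label = sprintf("max rel err %.3g vs tol %.3g",
                              max(abs(actual - expected) /
                                    pmax(abs(expected), 1e-12)), tol))
}
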