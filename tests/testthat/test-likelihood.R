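nu03 <- nuisance_model("hwe_rm_fixed_af", a2 = 0.3)

test_that("nuisance models validate their regimes", {
  expect_error(nuisance_model("hwe_rm_free_af"), "a2")
  expect_error(nuisance_model("mating_symmetry", mu = rep(1, 5)), "six")
  expect_error(nuisance_model("pae", mu = c(1, 1, 1, 2, 1, 1)),
               "mu3 = mu4")
  expect_error(nuisance_model("hwe_rm_fixed_af", a2 = 0.3,
                              mu = rep(1, 6)), "not both")
})

test_that("HWE-implied mating-type parameters match the closed form", {
  for (a2 in c(0.1, 0.3, 0.5, 0.77)) {
    p <- a2; q <- 1 - a2
    expect_equal(mu_from_a2(a2),
                 c(p^4, p^3 * q, p^2 * q^2, p^2 * q^2, p * q^3, q^4))
    ## PAE holds under HWE
    expect_identical(mu_from_a2(a2)[3], mu_from_a2(a2)[4])
    ## ordered-pair frequencies sum to one
    mu <- mu_from_a2(a2)
    expect_equal(mu[1] + 4 * mu[2] + 2 * mu[3] + 4 * mu[4] + 4 * mu[5] +
                   mu[6], 1)
  }
})

test_that("null trio and duo tables match the enumeration oracle", {
  tt <- trio_cell_table(risk_parameters(), nu03)
  expect_equal(tt$cells$probability, oracle_trio_probs(risk_parameters(),
                                                       0.3),
               tolerance = 1e-12)
  ## spot values: all-11 trio and the double-heterozygote cell
  expect_equal(tt$cells$probability[15], 0.7^4)
  expect_equal(tt$cells$probability[9], 2 * 0.3^2 * 0.7^2)
  dt <- duo_cell_table(risk_parameters(), nu03)
  expect_equal(dt$cells$probability, oracle_duo_probs(risk_parameters(),
                                                      0.3),
               tolerance = 1e-12)
  expect_equal(dt$cells$probability[7], 0.7^3)
})

test_that("cell tables match the oracle for random parameters", {
  set.seed(11)
  for (i in 1:20) {
    rp <- rand_rp()
    a2 <- runif(1, 0.05, 0.95)
    nu <- nuisance_model("hwe_rm_fixed_af", a2 = a2)
    expect_equal(trio_cell_table(rp, nu)$cells$probability,
                 oracle_trio_probs(rp, a2), tolerance = 1e-10)
    expect_equal(duo_cell_table(rp, nu)$cells$probability,
                 oracle_duo_probs(rp, a2), tolerance = 1e-10)
  }
})

test_that("all cell tables normalise and collapse consistently", {
  set.seed(12)
  for (i in 1:250) {
    rp <- rand_rp()
    nu <- if (i %% 2)
      nuisance_model("hwe_rm_fixed_af", a2 = runif(1, 0.05, 0.95))
    else nuisance_model("mating_symmetry", mu = rand_mu())
    tt <- trio_cell_table(rp, nu)
    expect_lt(abs(sum(tt$cells$probability) - 1), 1e-12)
    for (kind in c("case_mother_duo", "case_father_duo", "case_only",
                   "mother_of_case", "parents_of_case")) {
      ct <- cell_table(kind, rp, nu)
      expect_lt(abs(sum(ct$cells$probability) - 1), 1e-12)
      expect_equal(collapse_structure(tt, kind)$cells$probability,
                   ct$cells$probability, tolerance = 1e-12)
    }
  }
})

test_that("imprinting symmetry equates the ambiguous-origin halves", {
  ## when im = ip the two origin-specific halves of the ambiguous trio
  ## cell are equal: the merged cell is twice either half
  rp_sym <- risk_parameters(r1 = 1.5, r2 = 2, s1 = 1.3, im = 1.7,
                            ip = 1.7)
  rp_mat <- risk_parameters(r1 = 1.5, r2 = 2, s1 = 1.3, im = 1.7)
  half <- function(rp, gc) {
    w <- famlik:::trio_raw_weights(famlik:::log_factors(rp),
                                   mu_from_a2(0.3))
    en <- famlik:::TRIO_ENUM
    w[en$gm == "12" & en$gf == "12" & en$gc == gc]
  }
  expect_equal(half(rp_sym, "12"), half(rp_sym, "21"))
  expect_gt(half(rp_mat, "21"), half(rp_mat, "12"))
})

test_that("HWE regime equals the mu regime at the HWE values", {
  set.seed(13)
  for (a2 in c(0.2, 0.3, 0.6)) {
    rp <- rand_rp()
    t1 <- trio_cell_table(rp, nuisance_model("hwe_rm_fixed_af", a2 = a2))
    t2 <- trio_cell_table(rp, nuisance_model("mating_symmetry",
                                             mu = mu_from_a2(a2)))
    expect_equal(t1$cells$probability, t2$cells$probability,
                 tolerance = 1e-12)
  }
})

test_that("control tables are the null-population distributions", {
  expect_equal(control_cell_table("control", nu03)$cells$probability,
               c(0.49, 0.42, 0.09))
  expect_equal(
    control_cell_table("parents_of_control", nu03)$cells$probability,
    c(0.0081, 0.0756, 0.0882, 0.1764, 0.4116, 0.2401))
  ## mu-regime proportional to HWE gives the same mating-type table
  nu_mu <- nuisance_model("mating_symmetry", mu = 7 * mu_from_a2(0.3))
  expect_equal(
    control_cell_table("parents_of_control", nu_mu)$cells$probability,
    c(0.0081, 0.0756, 0.0882, 0.1764, 0.4116, 0.2401))
  ## control duos ignore the risk parameters entirely
  expect_equal(
    control_cell_table("control_mother_duo", nu03)$cells$probability,
    duo_cell_table(risk_parameters(), nu03)$cells$probability)
  expect_equal(
    cell_table("control_mother_duo", risk_parameters(r1 = 4, s2 = 3),
               nu03)$cells$probability,
    duo_cell_table(risk_parameters(), nu03)$cells$probability)
})

test_that("prevalence agrees with the enumeration oracle", {
  expect_equal(prevalence(risk_parameters(alpha = 0.1), nu03), 0.1)
  set.seed(14)
  for (i in 1:10) {
    rp <- rand_rp(0.2)
    rp[["alpha"]] <- 0.05
    a2 <- runif(1, 0.1, 0.9)
    e <- oracle_enum(rp, a2)
    K <- 0.05 * sum(e$prob * e$risk)
    expect_equal(prevalence(rp, nuisance_model("hwe_rm_fixed_af",
                                               a2 = a2)), K,
                 tolerance = 1e-12)
    expect_gt(K, 0); expect_lt(K, 1)
  }
})

test_that("joint log-likelihood is additive and handles edge cases", {
  rp <- risk_parameters(r1 = 1.5, r2 = 2.25)
  tab <- duo_cell_table(rp, nu03)
  n <- 1000
  d <- structure_counts("case_mother_duo", n * tab$cells$probability)
  ll1 <- joint_loglik(d, rp, nu03)
  expect_equal(ll1, n * sum(tab$cells$probability *
                              log(tab$cells$probability)))
  expect_equal(joint_loglik(list(d, d), rp, nu03), 2 * ll1)
  expect_equal(joint_loglik(list(), rp, nu03), 0)
  expect_error(structure_counts("case_mother_duo", 1:3), "7 cells")
  expect_error(structure_counts("case_mother_duo", c(-1, rep(1, 6))),
               "nonnegative")
})
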