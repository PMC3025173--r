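test_that("the built-in scenario table holds the canonical rows", {
  tab <- scenario_table()
  expect_equal(nrow(tab), 10L)
  expect_true(all(tab$a2 == 0.3) && all(tab$alpha == 0.1))
  a <- tab[tab$scenario == "A", ]
  expect_equal(c(a$r1, a$r2), c(1.5, 2.25))
  expect_true(all(unlist(a[c("s1", "s2", "im", "ip", "g11", "g22")]) ==
                    1))
  b <- tab[tab$scenario == "B", ]
  expect_equal(c(b$r1, b$r2, b$s1, b$s2), c(1, 1, 1.5, 2.25))
  h <- tab[tab$scenario == "H", ]
  expect_equal(c(h$g11, h$g22), c(0.5, 0.5))
  expect_equal(tab$im[tab$scenario %in% c("D", "F", "I")], rep(1.8, 3))
  expect_equal(tab$ip[tab$scenario %in% c("E", "G", "J")], rep(1.8, 3))
  ## every scenario's penetrance ceiling is feasible (validation passes)
  for (s in tab$scenario) expect_s3_class(scenario_table(s), "scenario")
  ## the binding case: the largest cell of scenario F
  f <- scenario_table("F")
  ptF <- build_penetrance_table(f$params, weight_maternal = 0.7)
  expect_equal(max(ptF$ordered$penetrance), 0.1 * 2.25 * 2.25 * 1.8)
  expect_lte(max(ptF$ordered$penetrance), 1)
})

test_that("identical seeds reproduce counts; different seeds differ", {
  scen <- scenario_table("C")
  a <- simulate_structure("case_mother_duo", scen, 300, seed = 9)
  b <- simulate_structure("case_mother_duo", scen, 300, seed = 9)
  c_ <- simulate_structure("case_mother_duo", scen, 300, seed = 10)
  expect_identical(a$counts, b$counts)
  expect_false(identical(a$counts, c_$counts))
  expect_equal(sum(a$counts), 300)
  ## the caller's RNG stream is untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_structure("control", scen, 10,
                                            seed = 3))
  expect_identical(runif(1), before)
})

test_that("rejection sampling reproduces the model cell frequencies", {
  n <- 1e5
  ## null trios against the 15-cell table
  nullscen <- scenario(name = "null", a2 = 0.3, alpha = 0.1)
  d <- simulate_structure("case_parent_trio", nullscen, n, seed = 101)
  p <- trio_cell_table(risk_parameters(),
                       nuisance_model("hwe_rm_fixed_af",
                                      a2 = 0.3))$cells$probability
  expect_gt(chisq.test(d$counts, p = p)$p.value, 0.001)

  ## scenario C duos against the 7-cell table
  scen <- scenario_table("C")
  d <- simulate_structure("case_mother_duo", scen, n, seed = 102)
  p <- duo_cell_table(scen$params,
                      nuisance_model("hwe_rm_fixed_af",
                                     a2 = 0.3))$cells$probability
  expect_gt(chisq.test(d$counts, p = p)$p.value, 0.001)

  ## scenario I trios (imprinting + interaction) against the full table
  scen <- scenario_table("I")
  d <- simulate_structure("case_parent_trio", scen, n, seed = 103)
  p <- trio_cell_table(scen$params,
                       nuisance_model("hwe_rm_fixed_af",
                                      a2 = 0.3))$cells$probability
  expect_gt(chisq.test(d$counts, p = p)$p.value, 0.001)

  ## control-side structures come from the null population
  d <- simulate_structure("parents_of_control", scen, n, seed = 104)
  p <- control_cell_table("parents_of_control",
                          nuisance_model("hwe_rm_fixed_af",
                                         a2 = 0.3))$cells$probability
  expect_gt(chisq.test(d$counts, p = p)$p.value, 0.001)
})

test_that("stratified sampling mixes sub-populations correctly", {
  ## degenerate stratification equals the unstratified draw
  s1 <- scenario(name = "x", a2 = 0.3, alpha = 0.1, r1 = 1.5, r2 = 2.25)
  s2 <- scenario(name = "x", a2 = 0.3, alpha = 0.1, r1 = 1.5, r2 = 2.25,
                 strata = data.frame(prop = c(0.5, 0.5), a2 = 0.3,
                                     alpha = 0.1))
  a <- simulate_structure("case_mother_duo", s1, 400, seed = 21)
  b <- simulate_stratified("case_mother_duo", s2, 400, seed = 21)
  ## same marginal distribution (not the same draws: the stratum draw
  ## consumes random numbers); compare against the model table
  p <- duo_cell_table(s1$params, nuisance_model("hwe_rm_fixed_af",
                                                a2 = 0.3))$cells$probability
  expect_gt(chisq.test(b$counts, p = p)$p.value, 0.001)
  expect_error(simulate_stratified("control", s1, 10), "no stratification")

  ## pooled control genotype frequencies equal the closed-form mixture
  strat <- stratified_null_scenario()
  n <- 4e4
  d <- simulate_structure("control", strat, n, seed = 22)
  mix <- 0.5 * c(0.7^2, 2 * 0.3 * 0.7, 0.3^2) +
    0.5 * c(0.85^2, 2 * 0.15 * 0.85, 0.15^2)
  expect_gt(chisq.test(d$counts, p = mix)$p.value, 0.001)

  ## confounding direction: cases are enriched for the risk allele
  ## relative to controls because the high-risk stratum carries more of
  ## it (closed form: compare allele frequencies)
  dc <- simulate_structure("case_only", strat, n, seed = 23)
  f_case <- sum(dc$counts * 0:2) / (2 * n)
  f_ctl <- sum(d$counts * 0:2) / (2 * n)
  expect_gt(f_case, f_ctl + 0.01)
})

test_that("invalid scenarios are rejected", {
  expect_error(scenario(a2 = 0.3, alpha = 0.9, r2 = 2), "overflow")
  expect_error(scenario(strata = data.frame(prop = c(0.6, 0.6),
                                            a2 = c(0.3, 0.2),
                                            alpha = 0.1)), "sum to 1")
})
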