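nu03 <- nuisance_model("hwe_rm_fixed_af", a2 = 0.3)

expected_counts <- function(kind, rp, nu, n = 1e5)
  structure_counts(kind, n * cell_table(kind, rp, nu)$cells$probability)

test_that("fitting exact expected counts recovers the generating values", {
  rp <- risk_parameters(r1 = 1.5, r2 = 2.25, s1 = 1.5, s2 = 2.25)
  d <- list(expected_counts("case_mother_duo", rp, nu03),
            expected_counts("parents_of_control", rp, nu03))
  f <- fit_model(d, model_spec(c("r1", "r2", "s1", "s2"),
                               "hwe_rm_free_af"))
  expect_true(f$converged)
  expect_true(f$identifiable)
  expect_equal(f$estimates$estimate, c(1.5, 2.25, 1.5, 2.25),
               tolerance = 1e-4)
  expect_equal(f$nuisance$a2, 0.3, tolerance = 1e-5)
  expect_gte(f$max_loglik, f$null_loglik - 1e-8)

  ## trio data identify all seven canonical parameters without controls
  rp7 <- risk_parameters(r1 = 1.5, r2 = 2.25, s1 = 1.3, s2 = 1.7,
                         im = 1.8, g11 = 0.6, g22 = 1.4)
  d7 <- expected_counts("case_parent_trio", rp7, nu03)
  f7 <- fit_model(d7, model_spec(c("r1", "r2", "s1", "s2", "im", "g11",
                                   "g22"), "mating_symmetry"),
                  compute_null = FALSE)
  expect_true(f7$identifiable)
  expect_equal(f7$estimates$estimate,
               unname(unclass(rp7)[c("r1", "r2", "s1", "s2", "im", "g11",
                                     "g22")]),
               tolerance = 1e-3)
})

test_that("free allele frequency is flagged unidentifiable on duos alone", {
  scen <- scenario_table("F")
  d <- simulate_structure("case_mother_duo", scen, 2000, seed = 5)
  f <- fit_model(d, model_spec(c("r1", "r2", "s1", "s2", "im"),
                               "hwe_rm_free_af"), compute_null = FALSE)
  expect_false(f$identifiable)
  expect_true(all(is.na(f$estimates$se)))
})

test_that("likelihood-ratio test arithmetic and nesting checks", {
  rp <- risk_parameters(r1 = 1.5, r2 = 2.25)
  d <- expected_counts("case_mother_duo", rp, nu03, n = 500)
  full <- fit_model(d, model_spec(c("r1", "r2"), "hwe_rm_fixed_af",
                                  a2 = 0.3), compute_null = FALSE)
  lrt0 <- likelihood_ratio_test(full, full)
  expect_equal(lrt0$statistic, 0)
  expect_equal(lrt0$p_value, 1)
  nullf <- fit_model(d, model_spec(character(), "hwe_rm_fixed_af",
                                   a2 = 0.3), compute_null = FALSE)
  lrt <- likelihood_ratio_test(full, nullf)
  expect_equal(lrt$df, 2L)
  expect_equal(lrt$p_value,
               pchisq(lrt$statistic, 2, lower.tail = FALSE))
  ## the canonical chi-square quantile check
  expect_equal(pchisq(3.84, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)
  other <- fit_model(d, model_spec(c("s1", "s2"), "hwe_rm_fixed_af",
                                   a2 = 0.3), compute_null = FALSE)
  expect_error(likelihood_ratio_test(full, other), "subset")
})

test_that("maximised log-likelihood is monotone in the free set", {
  scen <- scenario_table("C")
  d <- list(simulate_structure("case_mother_duo", scen, 500, seed = 31),
            simulate_structure("parents_of_control", scen, 500,
                               seed = 32))
  lls <- vapply(list(character(0), "r1", c("r1", "r2"),
                     c("r1", "r2", "s1"), c("r1", "r2", "s1", "s2")),
                function(fr) fit_model(d, model_spec(fr, "hwe_rm_free_af"),
                                       compute_null = FALSE)$max_loglik,
                0)
  expect_true(all(diff(lls) >= -1e-6))
})

test_that("imprinting designation does not change the LRT", {
  scen <- scenario_table("F")
  tr <- simulate_structure("case_parent_trio", scen, 500, seed = 7)
  f_im <- fit_model(tr, model_spec(c("r1", "r2", "s1", "s2", "im"),
                                   "mating_symmetry"))
  f_ip <- fit_model(tr, model_spec(c("r1", "r2", "s1", "s2", "ip"),
                                   "mating_symmetry"))
  expect_equal(f_im$max_loglik, f_ip$max_loglik, tolerance = 1e-6)
  expect_equal(f_im$null_loglik, f_ip$null_loglik, tolerance = 1e-6)
})

test_that("method presets configure regimes and required controls", {
  scen <- scenario_table("C")
  duo <- simulate_structure("case_mother_duo", scen, 400, seed = 61)
  poc <- simulate_structure("parents_of_control", scen, 400, seed = 62)
  cmd <- simulate_structure("control_mother_duo", scen, 400, seed = 63)

  expect_error(fit_method(4, duo, NULL), "parents_of_control")
  expect_error(fit_method(7, duo, list(poc)), "control_mother_duo")
  expect_error(fit_method(1, duo), "allele frequency")

  f5 <- fit_method(5, duo, poc, compute_null = FALSE)
  expect_equal(f5$spec$regime, "pae")
  mu5 <- f5$nuisance$mu
  expect_equal(mu5[3], mu5[4])
  f6 <- fit_method(6, duo, poc, compute_null = FALSE)
  expect_equal(f6$spec$regime, "mating_symmetry")
  f9 <- fit_method(9, duo, cmd, compute_null = FALSE)
  expect_equal(f9$spec$regime, "mating_symmetry")
  ## data generated under HWE: the PAE fit agrees with the HWE fit
  ## within Monte-Carlo error
  f4 <- fit_method(4, duo, poc, compute_null = FALSE)
  expect_equal(f5$estimates$log_estimate, f4$estimates$log_estimate,
               tolerance = 0.12)
})

test_that("fixing the allele frequency at the wrong value inflates the test", {
  nullscen <- scenario(name = "null", a2 = 0.3, alpha = 0.1)
  bad <- run_study(nullscen, 1, 500, 150, free = c("r1", "r2", "im"),
                   base_seed = 21, a2 = 0.4)
  good <- run_study(nullscen, 1, 500, 150, free = c("r1", "r2", "im"),
                    base_seed = 21, a2 = 0.3)
  r_bad <- bad$tests$rejection[bad$tests$level == 0.05]
  r_good <- good$tests$rejection[good$tests$level == 0.05]
  se <- sqrt(0.05 * 0.95 / 150)
  expect_gt(r_bad, 0.05 + 3 * se)     # strongly anticonservative
  expect_lt(abs(r_good - 0.05), 3 * se)
})

test_that("p-values are uniform under the null with the correct model", {
  nullscen <- scenario(name = "null", a2 = 0.3, alpha = 0.1)
  n_reps <- 300
  pv <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    dat <- famlik:::simulate_method_data(nullscen, 4, "case_mother_duo",
                                         500, 77 + r)
    f <- fit_method(4, dat$case, dat$control,
                    free = c("r1", "r2", "s1", "s2"))
    stat <- max(0, 2 * (f$max_loglik - f$null_loglik))
    pv[r] <- pchisq(stat, df = 4, lower.tail = FALSE)
  }
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
  expect_lt(abs(mean(pv < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / n_reps))
})

test_that("model sequences rank by AIC with first-wins ties", {
  scen <- scenario_table("B")
  d <- list(simulate_structure("case_mother_duo", scen, 500, seed = 91),
            simulate_structure("parents_of_control", scen, 500,
                               seed = 92))
  sA <- model_spec(c("r1", "r2"), "hwe_rm_free_af")
  sB <- model_spec(c("s1", "s2"), "hwe_rm_free_af")
  seq1 <- model_sequence(d, list(sA, sB))
  expect_equal(nrow(seq1), 2L)
  ## data generated under maternal effects: the maternal model wins
  expect_true(seq1$best[seq1$model == "s1+s2"])
  seq2 <- model_sequence(d, list(sA, sA))
  expect_equal(which(seq2$best), 1L)   # tie broken by user order
  expect_equal(seq2$aic[1], seq2$aic[2], tolerance = 1e-6)
  expect_error(model_sequence(d, list(sA)), "at least two")
})

test_that("fit results serialise to the flat TSV layout", {
  rp <- risk_parameters(r1 = 1.5, r2 = 2.25)
  d <- expected_counts("case_mother_duo", rp, nu03, n = 500)
  f <- fit_model(d, model_spec(c("r1", "r2"), "hwe_rm_fixed_af",
                               a2 = 0.3))
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_fit_results(f, path, snp_id = "rs1", model_name = "m1")
  out <- read.delim(path)
  expect_equal(names(out),
               c("snp_id", "model_name", "parameter", "estimate", "se",
                 "loglik_null", "loglik_max", "lrt", "df", "p", "flags"))
  expect_equal(out$parameter, c("r1", "r2"))
  expect_equal(out$flags, c("ok", "ok"))
  expect_equal(out$lrt[1], 2 * (f$max_loglik - f$null_loglik),
               tolerance = 1e-8)
})
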