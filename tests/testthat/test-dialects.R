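## Cell-by-cell table equality is the oracle for every conversion: a
## dialect map is correct exactly when the two parameter sets induce the
## same penetrance table.

dialect_table_of <- function(rp) {
  famlik:::risk_product(rp, famlik:::ORDERED_COMBOS$gm,
                        famlik:::ORDERED_COMBOS$gc)
}

test_that("dialect parameter sets are validated", {
  expect_error(dialect_parameters("mfg_1b", c(rho1 = 1)), "requires")
  expect_error(dialect_parameters("mfg_1a",
                                  c(rho1 = 1, rho2 = 1, eta1 = 1,
                                    eta2 = 1, mu0 = 1, bogus = 2)),
               "requires")
  expect_error(dialect_parameters("default", c(zeta = 1)), "unknown")
  expect_error(dialect_parameters("matching",
                                  c(rho1 = -1, rho2 = 1, eta1 = 1,
                                    eta2 = 1, mu = 1)), "positive")
})

test_that("identity parameter sets map to the null model", {
  dp <- dialect_parameters("mfg_1b", c(rho1 = 1, rho2 = 1, eta1 = 1,
                                       eta2 = 1, mu0 = 1, mu2 = 1))
  rp <- to_default_dialect(dp)
  expect_equal(unname(unclass(rp)[-1]), rep(1, 10))

  dp <- dialect_parameters("parimi_li", c(mu = 0, a0 = 0, d0 = 0, am = 0,
                                          dm = 0, i_m = 0, i_c = 0))
  rp <- to_default_dialect(dp)
  expect_equal(unname(unclass(rp)[-1]), rep(1, 10))
  expect_equal(unclass(rp)[["alpha"]], 1)  # exp(0 - 0 - 0)
})

test_that("the MFG incompatibility map inverts as printed", {
  ## a pure mu0 = 4 incompatibility model: solving against the default
  ## dialect gives g11 = 1/4 and R1 = 4 (and the table matches cell by
  ## cell, which is the real check)
  dp <- dialect_parameters("mfg_1b", c(rho1 = 1, rho2 = 1, eta1 = 1,
                                       eta2 = 1, mu0 = 4, mu2 = 1))
  rp <- to_default_dialect(dp)
  expect_equal(unclass(rp)[["g11"]], 0.25)
  expect_equal(unclass(rp)[["r1"]], 4)
  expect_equal(dialect_table_of(rp),
               unname(famlik:::dialect_ordered_table(dp)),
               tolerance = 1e-12)
})

test_that("round trips through every dialect preserve the table", {
  set.seed(42)
  ## imprinting-capable dialects: exact on the ordered-origin table
  for (d in c("weinberg_original_im", "weinberg_original_ip",
              "weinberg_later_im", "weinberg_later_ip")) {
    for (i in 1:10) {
      v <- exp(rnorm(5, 0, 0.4))
      rp <- risk_parameters(r1 = v[1], r2 = v[2], s1 = v[3], s2 = v[4],
                            im = if (endsWith(d, "im")) v[5] else 1,
                            ip = if (endsWith(d, "ip")) v[5] else 1)
      back <- to_default_dialect(to_dialect(rp, d))
      expect_equal(dialect_table_of(back), dialect_table_of(rp),
                   tolerance = 1e-10)
    }
  }
  ## interaction dialects (no imprinting in the source table)
  for (i in 1:10) {
    v <- exp(rnorm(6, 0, 0.4))
    rp <- risk_parameters(r1 = v[1], r2 = v[2], s1 = v[3], s2 = v[4],
                          g11 = v[5], g22 = v[6])
    back <- to_default_dialect(to_dialect(rp, "mfg_1b"))
    expect_equal(dialect_table_of(back), dialect_table_of(rp),
                 tolerance = 1e-10)
  }
  ## the log-scale saturated dialect handles imprinting too
  for (i in 1:10) {
    v <- exp(rnorm(6, 0, 0.4))
    rp <- risk_parameters(r1 = v[1], r2 = v[2], s1 = v[3], s2 = v[4],
                          ip = v[5], g11 = v[6], alpha = 0.01)
    back <- to_default_dialect(to_dialect(rp, "parimi_li"), fix = "im")
    expect_equal(dialect_table_of(back), dialect_table_of(rp),
                 tolerance = 1e-8)
  }
})

test_that("MFG 1B and the default two-interaction family coincide", {
  ## both are 7-parameter families over the origin-symmetric tables:
  ## any table from one is exactly representable in the other
  set.seed(43)
  for (i in 1:10) {
    v <- exp(rnorm(6, 0, 0.5))
    rp <- risk_parameters(r1 = v[1], r2 = v[2], s1 = v[3], s2 = v[4],
                          g11 = v[5], g22 = v[6])
    dd <- to_dialect(rp, "mfg_1b")
    expect_s3_class(dd, "dialect_parameters")
    ## and back: random MFG tables are representable in the default set
    dp <- dialect_parameters("mfg_1b", exp(rnorm(6, 0, 0.5)) |>
                               stats::setNames(c("rho1", "rho2", "eta1",
                                                 "eta2", "mu0", "mu2")))
    expect_s3_class(to_default_dialect(dp), "risk_parameters")
  }
})

test_that("the saturated dialect represents any observable 7-cell table", {
  set.seed(44)
  for (i in 1:10) {
    rp <- rand_rp(0.3)
    rp[["alpha"]] <- 0.02
    wm <- runif(1)
    dd <- to_dialect(rp, "saturated_delta", weight_maternal = wm)
    expect_equal(unname(dd$values),
                 build_penetrance_table(rp, wm)$collapsed$penetrance,
                 tolerance = 1e-12)
  }
})

test_that("origin-dependent tables are rejected by origin-blind dialects", {
  rp <- risk_parameters(im = 2)   # genuine parent-of-origin dependence
  expect_error(to_dialect(rp, "mfg_1b"), "not representable")
  expect_error(to_dialect(rp, "matching"), "not representable")
})

test_that("the two main-effects baselines give one table (worked example)", {
  a <- build_penetrance_table(
    risk_parameters(r1 = 2, r2 = 4, s1 = 3, s2 = 4, alpha = 0.05))
  ## baseline-(22,22) parameters, written as a saturated table the long
  ## way round: alpha' * r'_{2-j} * s'_{2-i}
  rr <- c(1, 0.5, 0.25); ss <- c(1, 0.75, 0.25)
  cnt <- function(g) nchar(gsub("[^2]", "", g))
  b <- 0.8 * rr[3 - cnt(a$collapsed$gc)] * ss[3 - cnt(a$collapsed$gm)]
  expect_equal(a$collapsed$penetrance, b, tolerance = 1e-12)
})
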