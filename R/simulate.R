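## Synthetic nuclear-family data generator.  Families are drawn from
## HWE + random mating (optionally a mixture of sub-populations), the
## child's alleles are transmitted Mendelianly with parental origin
## recorded, and case-side structures are produced by rejection sampling:
## a family is kept as a case family with probability equal to the
## ordered-origin penetrance of its configuration.  This mechanism is
## deliberately independent of the cell-probability algebra, so empirical
## cell frequencies provide an external check on the likelihood tables.

#' Simulation scenario
#'
#' @param name scenario label.
#' @param a2 risk-allele frequency.
#' @param alpha baseline penetrance.
#' @param r1,r2,s1,s2,im,ip,g11,g12,g21,g22 risk factors (see
#'   [risk_parameters()]).
#' @param strata optional data frame with columns `prop`, `a2`, `alpha`
#'   describing sub-populations with differing allele frequencies and
#'   baseline risks; `prop` must sum to 1.  Risk factors are shared
#'   across strata.
#' @return An object of class `scenario`.
#' @export
scenario <- function(name = "custom", a2 = 0.3, alpha = 0.1,
                     r1 = 1, r2 = 1, s1 = 1, s2 = 1, im = 1, ip = 1,
                     g11 = 1, g12 = 1, g21 = 1, g22 = 1, strata = NULL) {
  params <- risk_parameters(r1 = r1, r2 = r2, s1 = s1, s2 = s2, im = im,
                            ip = ip, g11 = g11, g12 = g12, g21 = g21,
                            g22 = g22, alpha = alpha)
  if (is.null(strata)) {
    strata <- data.frame(prop = 1, a2 = a2, alpha = alpha)
  } else {
    stopifnot(is.data.frame(strata),
              all(c("prop", "a2", "alpha") %in% names(strata)))
    if (abs(sum(strata$prop) - 1) > 1e-8)
      stop("stratum mixing proportions must sum to 1")
  }
  ## validate the penetrance ceiling in every stratum
  for (i in seq_len(nrow(strata))) {
    pi <- params
    pi[["alpha"]] <- strata$alpha[i]
    invisible(build_penetrance_table(pi,
                                     weight_maternal = 1 - strata$a2[i]))
  }
  structure(list(name = name, a2 = a2, alpha = alpha, params = params,
                 strata = strata), class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("Simulation scenario", x$name, "\n")
  cat("  a2 =", x$a2, " alpha =", x$alpha, "\n")
  fac <- unclass(x$params)[RISK_FACTOR_NAMES]
  cat("  ", paste(names(fac), fac, sep = "=", collapse = " "), "\n")
  if (nrow(x$strata) > 1L) {
    cat("  stratified population:\n")
    print(x$strata, row.names = FALSE)
  }
  invisible(x)
}

#' Built-in simulation scenarios A-J
#'
#' The ten canonical simulation scenarios: all share risk-allele
#' frequency 0.3 and baseline penetrance 0.1; A carries child-genotype
#' effects only (1.5, 2.25), B maternal effects only, C both, D/E add a
#' maternal/paternal imprinting factor 1.8 to A, F/G add it to C, H adds
#' interactions `g11 = g22 = 0.5` to C, and I/J combine interactions with
#' maternal/paternal imprinting.
#'
#' @param name optional scenario letter; when supplied, the
#'   corresponding [scenario()] object is returned instead of the table.
#' @return A data frame with one row per scenario (when `name` is
#'   `NULL`), otherwise a `scenario` object.
#' @examples
#' scenario_table()
#' scenario_table("C")
#' @export
scenario_table <- function(name = NULL) {
  tab <- data.frame(
    scenario = LETTERS[1:10],
    a2 = 0.3, alpha = 0.1,
    r1 = c(1.5, 1, 1.5, 1.5, 1.5, 1.5, 1.5, 1.5, 1.5, 1.5),
    r2 = c(2.25, 1, 2.25, 2.25, 2.25, 2.25, 2.25, 2.25, 2.25, 2.25),
    s1 = c(1, 1.5, 1.5, 1, 1, 1.5, 1.5, 1.5, 1.5, 1.5),
    s2 = c(1, 2.25, 2.25, 1, 1, 2.25, 2.25, 2.25, 2.25, 2.25),
    im = c(1, 1, 1, 1.8, 1, 1.8, 1, 1, 1.8, 1),
    ip = c(1, 1, 1, 1, 1.8, 1, 1.8, 1, 1, 1.8),
    g11 = c(1, 1, 1, 1, 1, 1, 1, 0.5, 0.5, 0.5),
    g22 = c(1, 1, 1, 1, 1, 1, 1, 0.5, 1, 1),
    stringsAsFactors = FALSE)
  if (is.null(name)) return(tab)
  name <- match.arg(toupper(name), tab$scenario)
  r <- as.list(tab[tab$scenario == name, ])
  scenario(name = r$scenario, a2 = r$a2, alpha = r$alpha, r1 = r$r1,
           r2 = r$r2, s1 = r$s1, s2 = r$s2, im = r$im, ip = r$ip,
           g11 = r$g11, g22 = r$g22)
}

## with_seed: run code under a given seed without disturbing the
## caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}

GENO_STR <- c("11", "12", "22")

## draw one batch of families; returns data frame of copies/origins
draw_families <- function(n, scen) {
  ns <- nrow(scen$strata)
  stratum <- if (ns == 1L) rep(1L, n)
  else sample.int(ns, n, replace = TRUE, prob = scen$strata$prop)
  a2 <- scen$strata$a2[stratum]
  gm <- stats::rbinom(n, 2L, a2)   # maternal copies of allele 2
  gf <- stats::rbinom(n, 2L, a2)
  mat <- stats::rbinom(n, 1L, gm / 2)  # maternal-origin allele is 2?
  pat <- stats::rbinom(n, 1L, gf / 2)
  list(gm = gm, gf = gf, mat = mat, pat = pat, stratum = stratum)
}

## penetrance of each drawn family
family_penetrance <- function(fam, scen) {
  p <- unclass(scen$params)
  j <- fam$mat + fam$pat
  rfac <- c(1, p[["r1"]], p[["r2"]])
  sfac <- c(1, p[["s1"]], p[["s2"]])
  gam <- matrix(c(1, 1, 1, 1, p[["g11"]], p[["g12"]], 1, p[["g21"]],
                  p[["g22"]]), nrow = 3L, byrow = TRUE)
  alpha <- scen$strata$alpha[fam$stratum]
  alpha * rfac[j + 1L] * sfac[fam$gm + 1L] *
    p[["im"]]^fam$mat * p[["ip"]]^fam$pat *
    gam[cbind(fam$gm + 1L, j + 1L)]
}

## observable cell label of each family under a structure kind
family_labels <- function(fam, structure_kind) {
  gm <- GENO_STR[fam$gm + 1L]
  gf <- GENO_STR[fam$gf + 1L]
  gc <- GENO_STR[fam$mat + fam$pat + 1L]
  mt <- function(a, b) {  # exchangeable mating-type label
    hi <- pmax(fam$gm, fam$gf); lo <- pmin(fam$gm, fam$gf)
    paste0(GENO_STR[hi + 1L], "x", GENO_STR[lo + 1L])
  }
  switch(structure_kind,
    case_parent_trio = paste(gm, gf, gc, sep = "-"),
    case_mother_duo = , control_mother_duo = paste(gm, gc, sep = "-"),
    case_father_duo = , control_father_duo = paste(gf, gc, sep = "-"),
    case_only = , control = gc,
    mother_of_case = gm,
    father_of_case = gf,
    parents_of_case = , parents_of_control = mt())
}

#' Simulate genotype-combination counts for one data structure
#'
#' Case-side structures are generated by rejection sampling: families
#' are drawn from the (possibly stratified) population, the child's
#' alleles are transmitted with parental origin recorded, and a family
#' is retained with probability equal to its penetrance.  Control-side
#' structures are population draws without disease conditioning.
#'
#' @param structure_kind any of [structure_kinds()].
#' @param scen a [scenario()] object.
#' @param n number of family units to generate.
#' @param seed optional integer seed; the same seed reproduces identical
#'   counts and the caller's RNG stream is left untouched.
#' @return A [structure_counts()] object.
#' @examples
#' simulate_structure("case_mother_duo", scenario_table("C"), 500,
#'                    seed = 1)
#' @export
simulate_structure <- function(structure_kind, scen, n, seed = NULL) {
  structure_kind <- match.arg(structure_kind, STRUCTURE_KINDS)
  stopifnot(inherits(scen, "scenario"), n >= 1)
  case_side <- is.na(CONTROL_EQUIVALENT[structure_kind])
  with_seed(seed, {
    labs <- character(0)
    got <- 0L
    guard <- 0L
    while (got < n) {
      guard <- guard + 1L
      if (guard > 10000L)
        stop("rejection sampler failed to accept any families; ",
             "check the scenario's penetrances")
      todo <- n - got
      batch <- if (case_side) as.integer(ceiling(todo / 0.05) + 100L)
               else todo
      fam <- draw_families(batch, scen)
      if (case_side) {
        pen <- family_penetrance(fam, scen)
        keep <- stats::runif(batch) < pen
        if (!any(keep)) next
        fam <- lapply(fam, `[`, keep)
      }
      new <- family_labels(fam, structure_kind)
      take <- min(length(new), todo)
      labs <- c(labs, new[seq_len(take)])
      got <- got + take
    }
    counts <- table(factor(labs, levels = cell_labels(structure_kind)))
    structure_counts(structure_kind, as.numeric(counts),
                     snp_id = paste0("sim_", scen$name))
  })
}

#' @param ... passed on to [simulate_structure()].
#' @rdname simulate_structure
#' @export
simulate_stratified <- function(structure_kind, scen, n, ...) {
  if (nrow(scen$strata) < 2L)
    stop("scenario has no stratification; use simulate_structure()")
  simulate_structure(structure_kind, scen, n, ...)
}

#' Two-subpopulation stratified null scenario
#'
#' Convenience constructor for the population-stratification experiment:
#' two equally mixed sub-populations with differing baseline risks
#' (0.1 and 0.05) and risk-allele frequencies (0.3 and 0.15), and no
#' genetic effects.
#'
#' @param prop1 mixing proportion of the first sub-population.
#' @return A [scenario()] object.
#' @export
stratified_null_scenario <- function(prop1 = 0.5) {
  scenario(name = "stratified_null", a2 = 0.3, alpha = 0.1,
           strata = data.frame(prop = c(prop1, 1 - prop1),
                               a2 = c(0.3, 0.15),
                               alpha = c(0.1, 0.05)))
}
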