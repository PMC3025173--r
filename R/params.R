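#' Multiplicative disease-risk parameters
#'
#' Container for the multiplicative penetrance model used throughout the
#' package.  Disease risk for a child is `alpha` (the baseline probability of
#' disease for an 11 child of an 11 x 11 mating) multiplied by:
#' `r1`/`r2` when the child carries one/two copies of the risk allele
#' (allele 2), `s1`/`s2` when the mother carries one/two copies, `im`/`ip`
#' when the child's copy was inherited maternally/paternally, and the
#' interaction factor `gij` when the mother carries i and the child j copies.
#'
#' `alpha` is only needed when penetrances are reported or data are
#' simulated; it cancels out of all retrospective (case-conditional)
#' likelihoods, so it may be left as `NA` for fitting.
#'
#' @param r1,r2 child-genotype relative risks (one/two copies of allele 2).
#' @param s1,s2 maternal-genotype relative risks.
#' @param im,ip maternal/paternal imprinting (parent-of-origin) factors.
#' @param g11,g12,g21,g22 maternal-fetal interaction factors gamma_ij.
#' @param alpha baseline penetrance in (0, 1], or `NA` when not needed.
#' @return An object of class `risk_parameters`: a named numeric vector with
#'   elements `alpha, r1, r2, s1, s2, im, ip, g11, g12, g21, g22`.
#' @examples
#' risk_parameters(r1 = 1.5, r2 = 2.25, alpha = 0.1)
#' @export
risk_parameters <- function(r1 = 1, r2 = 1, s1 = 1, s2 = 1,
                            im = 1, ip = 1,
                            g11 = 1, g12 = 1, g21 = 1, g22 = 1,
                            alpha = NA_real_) {
  p <- c(alpha = alpha, r1 = r1, r2 = r2, s1 = s1, s2 = s2,
         im = im, ip = ip, g11 = g11, g12 = g12, g21 = g21, g22 = g22)
  if (!is.numeric(p) || length(p) != 11L)
    stop("risk parameters must be single numeric values")
  fac <- p[-1L]
  if (any(!is.finite(fac)) || any(fac <= 0))
    stop("all relative-risk factors must be strictly positive and finite")
  if (!is.na(p[["alpha"]]) && (p[["alpha"]] <= 0 || p[["alpha"]] > 1))
    stop("alpha must lie in (0, 1]")
  structure(p, class = "risk_parameters")
}

#' @export
print.risk_parameters <- function(x, ...) {
  cat("Multiplicative disease-risk parameters\n")
  v <- format(signif(unclass(x), 6))
  cat("  baseline alpha:", v["alpha"], "\n")
  cat("  child   R1, R2:", v["r1"], v["r2"], "\n")
  cat("  mother  S1, S2:", v["s1"], v["s2"], "\n")
  cat("  imprint Im, Ip:", v["im"], v["ip"], "\n")
  cat("  interactions  :", paste0("g", c(11, 12, 21, 22), "=",
                                  v[c("g11", "g12", "g21", "g22")],
                                  collapse = " "), "\n")
  invisible(x)
}

## Relative-risk product for one ordered-origin combination, alpha excluded.
## Vectorised over gm/gc.
risk_product <- function(params, gm, gc) {
  p <- unclass(params)
  i <- nchar(gsub("[^2]", "", gm))          # maternal copies of allele 2
  mat <- substr(gc, 1L, 1L) == "2"          # maternal-origin allele is 2
  pat <- substr(gc, 2L, 2L) == "2"
  j <- mat + pat                            # child copies of allele 2
  r <- rep(1, length(gm))
  r[j == 1L] <- r[j == 1L] * p[["r1"]]
  r[j == 2L] <- r[j == 2L] * p[["r2"]]
  r[i == 1L] <- r[i == 1L] * p[["s1"]]
  r[i == 2L] <- r[i == 2L] * p[["s2"]]
  r[mat] <- r[mat] * p[["im"]]
  r[pat] <- r[pat] * p[["ip"]]
  gam <- matrix(c(1, 1, 1,
                  1, p[["g11"]], p[["g12"]],
                  1, p[["g21"]], p[["g22"]]),
                nrow = 3L, byrow = TRUE)
  r * gam[cbind(i + 1L, j + 1L)]
}

#' Build the penetrance table implied by a set of risk parameters
#'
#' Computes the penetrance (probability of disease) for every
#' Mendelian-compatible combination of maternal genotype and ordered-origin
#' child genotype, together with the seven-cell collapsed view in which the
#' parental origin of a heterozygous child's risk allele is unobserved.  In
#' the collapsed view the double-heterozygote cell (mother 12, child 12) is
#' the mixture `weight_maternal * P(maternal origin) +
#' (1 - weight_maternal) * P(paternal origin)`; under Hardy-Weinberg
#' equilibrium and random mating the maternal weight equals the frequency
#' `A1` of the low-risk allele.
#'
#' @param params a [risk_parameters()] object with non-missing `alpha`.
#' @param weight_maternal mixture weight in `[0, 1]` for the maternal-origin
#'   penetrance in the collapsed double-heterozygote cell.  Use `1 - a2`
#'   under HWE and random mating at risk-allele frequency `a2`; defaults to
#'   0.5 when no allele frequency is in scope.
#' @return An object of class `penetrance_table`: a list with elements
#'   `ordered` (data frame: `gm`, `gc` (ordered), `penetrance`; 8 rows),
#'   `collapsed` (data frame: `gm`, `gc` (unordered), `penetrance`; 7 rows)
#'   and `weight_maternal`.
#' @examples
#' build_penetrance_table(
#'   risk_parameters(r1 = 2, r2 = 4, s1 = 3, s2 = 4, alpha = 0.05))
#' @export
build_penetrance_table <- function(params, weight_maternal = 0.5) {
  stopifnot(inherits(params, "risk_parameters"))
  alpha <- unclass(params)[["alpha"]]
  if (is.na(alpha))
    stop("alpha is required to report penetrances")
  if (!is.numeric(weight_maternal) || length(weight_maternal) != 1L ||
      is.na(weight_maternal) || weight_maternal < 0 || weight_maternal > 1)
    stop("weight_maternal must be a proportion in [0, 1]")
  ord <- ORDERED_COMBOS
  ord$penetrance <- alpha * risk_product(params, ord$gm, ord$gc)
  if (any(ord$penetrance > 1 + 1e-12)) {
    bad <- ord[which.max(ord$penetrance), ]
    stop(sprintf(
      "penetrance overflow: cell (g_m=%s, ordered g_c=%s) has penetrance %.4g > 1",
      bad$gm, bad$gc, bad$penetrance))
  }
  coll <- collapse_penetrance(ord, weight_maternal)
  structure(list(ordered = ord, collapsed = coll,
                 weight_maternal = weight_maternal),
            class = "penetrance_table")
}

## Collapse the 8 ordered-origin entries down to the 7 observable
## (g_m, unordered g_c) cells; only (12,12) needs the origin mixture.
collapse_penetrance <- function(ord, weight_maternal) {
  ent <- function(gm, gc) ord$penetrance[ord$gm == gm & ord$gc == gc]
  data.frame(
    gm = c("11", "11", "12", "12", "12", "22", "22"),
    gc = c("11", "12", "11", "12", "22", "12", "22"),
    penetrance = c(
      ent("11", "11"), ent("11", "12"),
      ent("12", "11"),
      weight_maternal * ent("12", "21") +
        (1 - weight_maternal) * ent("12", "12"),
      ent("12", "22"),
      ent("22", "21"), ent("22", "22")),
    stringsAsFactors = FALSE)
}

#' @export
print.penetrance_table <- function(x, ...) {
  cat("Penetrance table (collapsed 7-cell view, rows g_m, columns g_c)\n")
  m <- matrix(NA_real_, 3, 3, dimnames = list(gm = c("11", "12", "22"),
                                              gc = c("11", "12", "22")))
  m[cbind(x$collapsed$gm, x$collapsed$gc)] <- x$collapsed$penetrance
  print(round(m, 6), na.print = "-")
  cat("double-heterozygote maternal-origin weight:", x$weight_maternal, "\n")
  invisible(x)
}

#' Solve a child-plus-mother main-effects model against a 7-cell table
#'
#' Given the seven observable penetrances (or odds), solves exactly for the
#' five parameters `(alpha, r1, r2, s1, s2)` of the multiplicative
#' main-effects model, expressed relative to either the (g_m, g_c) = (11, 11)
#' baseline or the (22, 22) baseline.  The two conventions describe the same
#' table with different parameter values; this function makes that
#' re-expression explicit.
#'
#' @param collapsed a 7-row data frame with columns `gm`, `gc`, `penetrance`
#'   (as the `collapsed` element of a [build_penetrance_table()] result).
#' @param baseline `"11"` (effects relative to the all-low-risk combination)
#'   or `"22"` (relative to the all-high-risk combination).
#' @param tol relative tolerance used to verify that the table is in fact
#'   representable by the five-parameter model.
#' @return Named numeric vector `c(alpha, r1, r2, s1, s2)`.
#' @examples
#' tab <- build_penetrance_table(
#'   risk_parameters(r1 = 2, r2 = 4, s1 = 3, s2 = 4, alpha = 0.05))
#' solve_main_effects(tab$collapsed, baseline = "22")
#' @export
solve_main_effects <- function(collapsed, baseline = c("11", "22"),
                               tol = 1e-8) {
  baseline <- match.arg(baseline)
  ent <- function(gm, gc)
    collapsed$penetrance[collapsed$gm == gm & collapsed$gc == gc]
  if (baseline == "11") {
    alpha <- ent("11", "11")
    r1 <- ent("11", "12") / alpha
    s1 <- ent("12", "11") / alpha
    r2 <- ent("12", "22") / (alpha * s1)
    s2 <- ent("22", "12") / (alpha * r1)
  } else {
    alpha <- ent("22", "22")
    r1 <- ent("22", "12") / alpha
    s1 <- ent("12", "22") / alpha
    r2 <- ent("12", "11") / (alpha * s1)
    s2 <- ent("11", "12") / (alpha * r1)
  }
  fit <- c(alpha = alpha, r1 = r1, r2 = r2, s1 = s1, s2 = s2)
  chk <- if (baseline == "11")
    build_penetrance_table(risk_parameters(r1 = r1, r2 = r2, s1 = s1,
                                           s2 = s2, alpha = alpha))
  else {
    ## baseline-22 model: cell (gm, gc) = alpha * r_{2 - #child 2s} * s_{2 - #mother 2s}
    tab <- collapsed
    cnt <- function(g) nchar(gsub("[^2]", "", g))
    rr <- c(1, r1, r2); ss <- c(1, s1, s2)
    tab$penetrance <- alpha * rr[3L - cnt(tab$gc)] * ss[3L - cnt(tab$gm)]
    list(collapsed = tab)
  }
  err <- abs(chk$collapsed$penetrance - collapsed$penetrance) /
    pmax(abs(collapsed$penetrance), .Machine$double.eps)
  if (any(err > tol))
    stop("table is not representable by a main-effects model at this tolerance")
  fit
}
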