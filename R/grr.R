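#' Apparent genotype relative risks under a generating penetrance model
#'
#' Computes, by exact enumeration of the joint distribution of maternal
#' genotype, paternal genotype and ordered-origin child genotype under
#' Hardy-Weinberg equilibrium and random mating, the genotype relative
#' risks that a naive comparison would estimate: either cases versus
#' population controls (conditioning on the child's genotype) or mothers
#' of cases versus mothers of population controls (conditioning on the
#' mother's genotype).  These "apparent" risks show how maternal,
#' imprinting and interaction effects masquerade as child-genotype
#' effects and vice versa: a pure maternal-imprinting factor of 2
#' produces apparent child risks (1.5, 2) identical in both analyses,
#' whereas a pure paternal-imprinting effect is invisible in the mothers.
#'
#' @param params a [risk_parameters()] object; `alpha` may be `NA` (it
#'   cancels from every ratio).
#' @param a2 risk-allele frequency in (0, 1).
#' @param analysis `"cases_vs_controls"` or `"mothers_vs_mothers"`.
#' @return Named vector `c(rr12, rr22)`: relative risks of the
#'   heterozygote and risk-homozygote relative to the low-risk
#'   homozygote.
#' @examples
#' apparent_grr(risk_parameters(im = 2), a2 = 0.3)
#' apparent_grr(risk_parameters(s1 = 2, s2 = 4), a2 = 0.3)
#' @export
apparent_grr <- function(params, a2,
                         analysis = c("cases_vs_controls",
                                      "mothers_vs_mothers")) {
  analysis <- match.arg(analysis)
  stopifnot(inherits(params, "risk_parameters"))
  if (a2 <= 0 || a2 >= 1) stop("a2 must lie in (0, 1)")
  alpha <- unclass(params)[["alpha"]]
  if (!is.na(alpha)) {
    pt <- build_penetrance_table(params, weight_maternal = 1 - a2)
    invisible(pt)  # triggers the penetrance-overflow check
  }
  mu <- mu_from_a2(a2)
  ## joint population probability and relative risk of the 16 ordered
  ## trio outcomes
  w_pop <- TRIO_ENUM$mendel * PAIR_MULT[TRIO_ENUM$type] * mu[TRIO_ENUM$type]
  rr <- risk_product(params, TRIO_ENUM$gm, TRIO_ENUM$gc)
  margin <- if (analysis == "cases_vs_controls")
    ifelse(TRIO_ENUM$gc == "21", "12", TRIO_ENUM$gc)
  else TRIO_ENUM$gm
  risk_by_g <- tapply(w_pop * rr, margin, sum) / tapply(w_pop, margin, sum)
  c(rr12 = unname(risk_by_g[["12"]] / risk_by_g[["11"]]),
    rr22 = unname(risk_by_g[["22"]] / risk_by_g[["11"]]))
}

#' Approximate power of the 2-df genotype case-control test
#'
#' Power of the Pearson chi-square test comparing the three genotype
#' frequencies between cases and population controls, via the noncentral
#' chi-square approximation with the noncentrality computed from the
#' expected genotype frequencies.  Case genotype frequencies follow from
#' the control (population, HWE) frequencies re-weighted by the supplied
#' relative risks.  This is an analytic approximation to the usual
#' genetic power-calculator convention for a 2-df genotype test.
#'
#' @param rr12,rr22 genotype relative risks of the heterozygote and
#'   risk-homozygote versus the low-risk homozygote.
#' @param a2 risk-allele frequency in (0, 1).
#' @param prevalence disease prevalence (used to verify the implied
#'   penetrances stay within (0, 1); population controls are assumed, so
#'   it does not otherwise enter).
#' @param n_case,n_control sample sizes.
#' @param alpha_level significance level of the test.
#' @return Estimated power in (0, 1).
#' @examples
#' grr_power(1.5, 2.25, a2 = 0.3, prevalence = 0.1,
#'           n_case = 500, n_control = 500)
#' @export
grr_power <- function(rr12, rr22, a2, prevalence = 0.1,
                      n_case = 500, n_control = 500, alpha_level = 0.05) {
  if (rr12 <= 0 || rr22 <= 0) stop("relative risks must be positive")
  if (a2 <= 0 || a2 >= 1) stop("a2 must lie in (0, 1)")
  if (n_case <= 0 || n_control <= 0) stop("sample sizes must be positive")
  q <- 1 - a2
  p_ctl <- c(q^2, 2 * a2 * q, a2^2)
  rr <- c(1, rr12, rr22)
  denom <- sum(p_ctl * rr)
  f0 <- prevalence / denom  # baseline penetrance implied by the risks
  if (any(f0 * rr >= 1) || f0 <= 0)
    stop("supplied relative risks and prevalence imply penetrances ",
         "outside (0, 1)")
  p_case <- p_ctl * rr / denom
  ## Pearson chi-square noncentrality for a 2 x 3 table of expected
  ## frequencies
  w1 <- n_case / (n_case + n_control)
  p_bar <- w1 * p_case + (1 - w1) * p_ctl
  ncp <- n_case * sum((p_case - p_bar)^2 / p_bar) +
    n_control * sum((p_ctl - p_bar)^2 / p_bar)
  crit <- stats::qchisq(1 - alpha_level, df = 2)
  stats::pchisq(crit, df = 2, ncp = ncp, lower.tail = FALSE)
}
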