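#' Nuisance model for parental mating-type frequencies
#'
#' The retrospective cell probabilities depend on the frequencies of the
#' six exchangeable parental mating types.  These can be parameterised
#' either through the allele-2 frequency `a2` (assuming Hardy-Weinberg
#' equilibrium and random mating, with `a2` fixed externally or freely
#' estimated) or through six mating-type stratification parameters
#' `mu[1..6]`, identified only up to a common scale.  Parental allelic
#' exchangeability (`pae`) is the intermediate assumption `mu3 = mu4`;
#' full HWE and random mating implies `mu = (p^4, p^3 q, p^2 q^2, p^2 q^2,
#' p q^3, q^4)` with `p = a2`, `q = 1 - a2`.
#'
#' Mating types are indexed 1-6 in the order 22x22, 22x12, 22x11, 12x12,
#' 12x11, 11x11; in the row-wise ordered-pair scale used here the
#' unordered mating-type probabilities are `(mu1, 4 mu2, 2 mu3, 4 mu4,
#' 4 mu5, mu6)`.
#'
#' @param regime one of `"hwe_rm_fixed_af"`, `"hwe_rm_free_af"`, `"pae"`,
#'   `"mating_symmetry"`.
#' @param a2 allele-2 (risk allele) frequency in (0, 1); required for the
#'   `hwe_*` regimes.
#' @param mu positive numeric vector of length 6; required for the `pae`
#'   and `mating_symmetry` regimes.  Under `pae`, `mu[3]` must equal
#'   `mu[4]`.
#' @return An object of class `nuisance_model`.
#' @examples
#' nuisance_model("hwe_rm_fixed_af", a2 = 0.3)
#' nuisance_model("mating_symmetry", mu = mu_from_a2(0.3))
#' @export
nuisance_model <- function(regime = c("hwe_rm_fixed_af", "hwe_rm_free_af",
                                      "pae", "mating_symmetry"),
                           a2 = NULL, mu = NULL) {
  regime <- match.arg(regime)
  if (startsWith(regime, "hwe")) {
    if (is.null(a2) || !is.numeric(a2) || length(a2) != 1L ||
        a2 <= 0 || a2 >= 1)
      stop("regime '", regime, "' requires an allele frequency a2 in (0, 1)")
    if (!is.null(mu))
      stop("supply either a2 or mu, not both")
    mu <- NULL
  } else {
    if (is.null(mu) || !is.numeric(mu) || length(mu) != 6L || any(mu <= 0))
      stop("regime '", regime,
           "' requires six strictly positive mating-type parameters mu")
    if (!is.null(a2))
      stop("supply either a2 or mu, not both")
    if (regime == "pae" &&
        abs(mu[3] - mu[4]) > 1e-12 * max(mu[3], mu[4]))
      stop("parental allelic exchangeability requires mu3 = mu4")
    a2 <- NULL
  }
  structure(list(regime = regime, a2 = a2, mu = mu),
            class = "nuisance_model")
}

#' @export
print.nuisance_model <- function(x, ...) {
  cat("Nuisance model:", x$regime, "\n")
  if (!is.null(x$a2)) cat("  allele-2 frequency a2 =", x$a2, "\n")
  if (!is.null(x$mu))
    cat("  mu1..mu6 =", paste(signif(x$mu, 6), collapse = " "), "\n")
  invisible(x)
}

#' Mating-type stratification parameters implied by HWE and random mating
#'
#' @param a2 allele-2 frequency in (0, 1).
#' @return Numeric vector `(p^4, p^3 q, p^2 q^2, p^2 q^2, p q^3, q^4)`
#'   with `p = a2`, `q = 1 - a2` (row-wise ordered-pair scale).
#' @export
mu_from_a2 <- function(a2) {
  p <- a2; q <- 1 - a2
  c(p^4, p^3 * q, p^2 * q^2, p^2 * q^2, p * q^3, q^4)
}

## mu vector on the probability scale for any nuisance model
nuisance_mu <- function(nuisance) {
  if (!is.null(nuisance$a2)) mu_from_a2(nuisance$a2) else nuisance$mu
}
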