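#' Observed multinomial counts for one data structure
#'
#' @param structure_kind any of [structure_kinds()].
#' @param counts nonnegative numeric vector aligned to the frozen cell
#'   ordering of the structure (see [cell_labels()]).
#' @param snp_id identifier string for the variant the counts refer to.
#' @return An object of class `structure_counts`.
#' @examples
#' structure_counts("case_only", c(49, 42, 9))
#' @export
structure_counts <- function(structure_kind, counts, snp_id = "snp1") {
  structure_kind <- match.arg(structure_kind, STRUCTURE_KINDS)
  labels <- cell_labels(structure_kind)
  if (length(counts) != length(labels))
    stop(sprintf("'%s' has %d cells but %d counts were supplied",
                 structure_kind, length(labels), length(counts)))
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be nonnegative")
  structure(list(structure_kind = structure_kind,
                 counts = stats::setNames(as.numeric(counts), labels),
                 snp_id = as.character(snp_id)),
            class = "structure_counts")
}

#' @export
print.structure_counts <- function(x, ...) {
  cat(sprintf("Counts for %s (snp %s), n = %g\n", x$structure_kind,
              x$snp_id, sum(x$counts)))
  print(x$counts)
  invisible(x)
}

## Floor applied to fitted cell probabilities inside logs, solely so the
## optimiser stays finite when a weight underflows; exact structural zeros
## with nonzero counts still produce -Inf through the count * log term.
PROB_FLOOR <- 1e-300

#' Joint multinomial log-likelihood over several data structures
#'
#' Sums, over the supplied datasets, the multinomial log-likelihood
#' `sum(counts * log(p))` of the cell probabilities implied by the risk
#' parameters and nuisance model (control-side structures contribute
#' their population likelihoods, which depend on the nuisance model
#' only).  Multinomial coefficients are omitted; they do not depend on
#' the parameters.
#'
#' @param datasets a list of [structure_counts()] objects (a single
#'   object is accepted).
#' @param params a [risk_parameters()] object.
#' @param nuisance a [nuisance_model()].
#' @return The joint log-likelihood; `-Inf` if any cell with zero
#'   fitted probability has a nonzero count, `0` for an empty dataset
#'   list.
#' @export
joint_loglik <- function(datasets, params, nuisance) {
  if (inherits(datasets, "structure_counts")) datasets <- list(datasets)
  log_fac <- log_factors(params)
  mu <- nuisance_mu(nuisance)
  ll <- 0
  for (d in datasets) {
    if (!inherits(d, "structure_counts"))
      stop("datasets must be structure_counts objects")
    p <- structure_probs(d$structure_kind, log_fac, mu)$prob
    if (any(p == 0 & d$counts > 0)) return(-Inf)
    ll <- ll + sum(d$counts * log(pmax(p, PROB_FLOOR)))
  }
  ll
}
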