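## Genotype-combination cell tables for every supported data structure.
##
## Everything is driven by one frozen enumeration of the 16 ordered-origin
## trio outcomes (the observable 15 cells, with the double-heterozygote
## trio cell split into its maternal- and paternal-origin halves).  All
## collapsed structures are sums over this enumeration, so collapse
## consistency holds by construction.

## Row order follows the canonical trio-cell ordering (cells 1-15, with the
## ambiguous cell split into "9a" maternal-origin-unknown halves).
TRIO_ENUM <- data.frame(
  cell  = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 9L, 10L, 11L, 12L, 13L,
            14L, 15L),
  gm    = c("22", "22", "22", "12", "12", "22", "11", "12", "12", "12",
            "12", "12", "12", "11", "11", "11"),
  gf    = c("22", "12", "12", "22", "22", "11", "22", "12", "12", "12",
            "12", "11", "11", "12", "12", "11"),
  gc    = c("22", "22", "21", "22", "12", "21", "12", "22", "12", "21",
            "11", "21", "11", "12", "11", "11"),
  type  = c(1L, 2L, 2L, 2L, 2L, 3L, 3L, 4L, 4L, 4L, 4L, 5L, 5L, 5L, 5L,
            6L),
  mendel = c(1, 0.5, 0.5, 0.5, 0.5, 1, 1, 0.25, 0.25, 0.25, 0.25, 0.5,
             0.5, 0.5, 0.5, 1),
  stringsAsFactors = FALSE
)

## Ordered parental-pair frequency = PAIR_MULT * mu[type]:
## one ordered pair of type 1/3/6 carries mu1 / mu3 / mu6; types 2 and 5
## carry 2*mu per ordered pair and type 4 carries 4*mu4.
PAIR_MULT <- c(1, 2, 1, 4, 2, 1)

STRUCTURE_KINDS <- c("case_parent_trio", "case_mother_duo",
                     "case_father_duo", "case_only", "mother_of_case",
                     "father_of_case", "parents_of_case",
                     "control", "control_mother_duo",
                     "control_father_duo", "parents_of_control")

CONTROL_EQUIVALENT <- c(control = "case_only",
                        control_mother_duo = "case_mother_duo",
                        control_father_duo = "case_father_duo",
                        parents_of_control = "parents_of_case")

MATING_TYPE_LABELS <- c("22x22", "22x12", "22x11", "12x12", "12x11",
                        "11x11")

## Frozen cell orderings and the trio-row -> cell mapping per structure.
structure_layout <- local({
  unord <- function(g) ifelse(g == "21", "12", g)
  gc_u <- unord(TRIO_ENUM$gc)
  trio_labels <- with(TRIO_ENUM[!duplicated(TRIO_ENUM$cell), ],
                      paste(gm, gf, ifelse(gc == "21", "12", gc), sep = "-"))
  duo_order <- c("22-22", "22-12", "12-22", "12-12", "12-11", "11-12",
                 "11-11")
  geno_order <- c("11", "12", "22")
  list(
    case_parent_trio = list(labels = trio_labels, group = TRIO_ENUM$cell),
    case_mother_duo = list(
      labels = duo_order,
      group = match(paste(TRIO_ENUM$gm, gc_u, sep = "-"), duo_order)),
    case_father_duo = list(
      labels = duo_order,
      group = match(paste(TRIO_ENUM$gf, gc_u, sep = "-"), duo_order)),
    case_only = list(labels = geno_order,
                     group = match(gc_u, geno_order)),
    mother_of_case = list(labels = geno_order,
                          group = match(TRIO_ENUM$gm, geno_order)),
    father_of_case = list(labels = geno_order,
                          group = match(TRIO_ENUM$gf, geno_order)),
    parents_of_case = list(labels = MATING_TYPE_LABELS,
                           group = TRIO_ENUM$type)
  )
})

#' Frozen cell labels for a data structure
#'
#' Cell orderings are frozen package constants: trio cells follow the
#' 15-row canonical ordering (from the 22-22-22 trio down to 11-11-11),
#' duo cells run (22-22, 22-12, 12-22, 12-12, 12-11, 11-12, 11-11),
#' single-genotype structures run (11, 12, 22) and parents-of-X structures
#' use the six exchangeable mating types (22x22, 22x12, 22x11, 12x12,
#' 12x11, 11x11).  Count files must follow these orderings.
#'
#' @param structure_kind one of the structure kinds listed in
#'   [structure_kinds()].
#' @return Character vector of cell labels in the frozen order.
#' @export
cell_labels <- function(structure_kind) {
  structure_kind <- match.arg(structure_kind, STRUCTURE_KINDS)
  eq <- CONTROL_EQUIVALENT[structure_kind]
  if (!is.na(eq)) structure_kind <- eq
  structure_layout[[structure_kind]]$labels
}

#' Supported data-structure kinds
#' @return Character vector of all structure kinds the package models.
#' @export
structure_kinds <- function() STRUCTURE_KINDS

## ---- fast numeric core -----------------------------------------------

## Exponent matrix of the 16 trio weights in the 10 risk factors, derived
## once from risk_product() so the table algebra has a single source.
cell_core <- local({
  core <- NULL
  function() {
    if (!is.null(core)) return(core)
    n <- nrow(TRIO_ENUM)
    E <- matrix(0, n, length(RISK_FACTOR_NAMES),
                dimnames = list(NULL, RISK_FACTOR_NAMES))
    for (f in RISK_FACTOR_NAMES) {
      v <- stats::setNames(as.list(rep(1, length(RISK_FACTOR_NAMES))),
                           RISK_FACTOR_NAMES)
      v[[f]] <- exp(1)
      rp <- do.call(risk_parameters, v)
      E[, f] <- log(risk_product(rp, TRIO_ENUM$gm, TRIO_ENUM$gc))
    }
    E <- round(E)  # exponents are small integers
    core <<- list(E = E,
                  base = TRIO_ENUM$mendel * PAIR_MULT[TRIO_ENUM$type],
                  type = TRIO_ENUM$type)
    core
  }
})

## Unnormalised weights of the 16 ordered trio outcomes (alpha removed).
## `log_fac` is log of the 10 risk factors in RISK_FACTOR_NAMES order.
trio_raw_weights <- function(log_fac, mu) {
  cc <- cell_core()
  as.vector(exp(cc$E %*% log_fac)) * cc$base * mu[cc$type]
}

log_factors <- function(params) {
  log(unclass(params)[RISK_FACTOR_NAMES])
}

## Probabilities over the cells of one structure.  Control-side structures
## use the null (all factors 1) weights.  Returns list(prob, sigma, raw).
structure_probs <- function(structure_kind, log_fac, mu) {
  eq <- CONTROL_EQUIVALENT[structure_kind]
  if (!is.na(eq)) {
    structure_kind <- eq
    log_fac <- numeric(length(RISK_FACTOR_NAMES))
  }
  raw <- trio_raw_weights(log_fac, mu)
  sigma <- sum(raw)
  lay <- structure_layout[[structure_kind]]
  w <- rowsum(raw, lay$group)[, 1L]
  list(prob = unname(w / sigma), weights = unname(w), sigma = sigma)
}

## ---- user-facing constructors ----------------------------------------

new_cell_table <- function(structure_kind, labels, prob, weights, sigma) {
  structure(list(structure_kind = structure_kind,
                 cells = data.frame(label = labels, probability = prob,
                                    stringsAsFactors = FALSE),
                 weights = stats::setNames(weights, labels),
                 sigma = sigma),
            class = "cell_table")
}

#' @export
print.cell_table <- function(x, digits = 6, ...) {
  cat("Cell probabilities:", x$structure_kind, "\n")
  df <- x$cells
  df$probability <- round(df$probability, digits)
  print(df, row.names = FALSE)
  cat("normalising divisor Sigma =", signif(x$sigma, digits), "\n")
  invisible(x)
}

#' Multinomial cell probabilities for a data structure
#'
#' Computes the retrospective (case-conditional) probabilities of the
#' observable genotype-combination cells of any supported case-side
#' structure, or the population probabilities of a control-side structure,
#' under a multiplicative penetrance model and a mating-type nuisance
#' model.  Each unnormalised cell weight is the relative-risk product for
#' the cell (baseline penetrance divided out), times the Mendelian
#' transmission factor, times the ordered parental-pair frequency; the
#' normalising divisor `Sigma` is the sum of all sixteen ordered trio
#' weights.  Control-side structures use the null (all factors 1) weights
#' and assume a random population sample of unknown disease status.
#'
#' @param structure_kind any of [structure_kinds()].
#' @param params a [risk_parameters()] object (ignored for control-side
#'   structures; defaults to the null model).
#' @param nuisance a [nuisance_model()].
#' @return A `cell_table` object whose `cells` element holds the labelled
#'   probabilities in the frozen ordering; probabilities sum to 1.
#' @examples
#' cell_table("case_parent_trio", risk_parameters(r1 = 1.5, r2 = 2.25),
#'            nuisance_model("hwe_rm_fixed_af", a2 = 0.3))
#' @export
cell_table <- function(structure_kind, params = risk_parameters(),
                       nuisance = nuisance_model("hwe_rm_fixed_af",
                                                 a2 = 0.5)) {
  structure_kind <- match.arg(structure_kind, STRUCTURE_KINDS)
  stopifnot(inherits(params, "risk_parameters"),
            inherits(nuisance, "nuisance_model"))
  sp <- structure_probs(structure_kind, log_factors(params),
                        nuisance_mu(nuisance))
  new_cell_table(structure_kind, cell_labels(structure_kind),
                 sp$prob, sp$weights, sp$sigma)
}

#' @rdname cell_table
#' @export
trio_cell_table <- function(params, nuisance)
  cell_table("case_parent_trio", params, nuisance)

#' @rdname cell_table
#' @export
duo_cell_table <- function(params, nuisance)
  cell_table("case_mother_duo", params, nuisance)

#' @param nuisance a [nuisance_model()].
#' @rdname collapse_structure
#' @export
control_cell_table <- function(structure_kind = c("control",
                                                  "parents_of_control",
                                                  "control_mother_duo",
                                                  "control_father_duo"),
                               nuisance) {
  structure_kind <- match.arg(structure_kind)
  cell_table(structure_kind, risk_parameters(), nuisance)
}

#' Collapse a trio cell table to a partially observed structure
#'
#' Sums the cells of a case/parent-trio table over the unobserved margin
#' (father's genotype, child's genotype, one or both parents) to obtain
#' the cell table of the corresponding partial structure.  Collapsing the
#' full table this way is exactly how the package defines every partial
#' structure, so this function is primarily useful for making that
#' consistency explicit.
#'
#' @param trio_table a `cell_table` of kind `case_parent_trio` carrying
#'   the generating parameters (see [cell_table()]); the collapse operates
#'   on its unnormalised weights.
#' @param structure_kind the case-side target structure.
#' @return A `cell_table` for the target structure.
#' @export
collapse_structure <- function(trio_table,
                               structure_kind = c("case_mother_duo",
                                                  "case_father_duo",
                                                  "case_only",
                                                  "mother_of_case",
                                                  "father_of_case",
                                                  "parents_of_case")) {
  stopifnot(inherits(trio_table, "cell_table"),
            trio_table$structure_kind == "case_parent_trio")
  structure_kind <- match.arg(structure_kind)
  ## re-expand the 15 trio weights to the 16 ordered rows: the ambiguous
  ## double-heterozygote cell is the only merged one, and its two halves
  ## collapse into the same cell of every partial structure, so the merged
  ## weight can be carried by either half.
  w16 <- trio_table$weights[TRIO_ENUM$cell]
  dup9 <- which(TRIO_ENUM$cell == 9L)
  w16[dup9[2L]] <- 0
  lay <- structure_layout[[structure_kind]]
  w <- rowsum(w16, lay$group)[, 1L]
  new_cell_table(structure_kind, lay$labels, unname(w / sum(w)),
                 unname(w), trio_table$sigma)
}

#' Population disease prevalence implied by a penetrance model
#'
#' @param params a [risk_parameters()] object with non-missing `alpha`.
#' @param nuisance a [nuisance_model()]; for `mu` regimes the mating-type
#'   parameters must be on the probability scale (summing over ordered
#'   pairs to 1) for the result to be a prevalence.
#' @return `K = alpha * Sigma`, the marginal probability that a child is
#'   affected.
#' @export
prevalence <- function(params, nuisance) {
  alpha <- unclass(params)[["alpha"]]
  if (is.na(alpha)) stop("alpha is required to compute a prevalence")
  sigma <- sum(trio_raw_weights(log_factors(params), nuisance_mu(nuisance)))
  alpha * sigma
}
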