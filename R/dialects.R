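## Published penetrance parameterisations ("dialects") and exact
## conversions between them.  Every dialect is defined by the ordered-origin
## penetrance table it induces; conversions solve one table against the
## other parameter set and are verified cell-by-cell, so the algebra can
## never drift from the table definitions.

DIALECTS <- list(
  default             = RISK_FACTOR_NAMES,
  weinberg_original_im = c("r1", "r2", "s1", "s2", "im"),
  weinberg_original_ip = c("r1", "r2", "s1", "s2", "ip"),
  weinberg_later_im   = c("r1", "r2", "s1", "s2", "im"),
  weinberg_later_ip   = c("r1", "r2", "s1", "s2", "ip"),
  mfg_1a              = c("rho1", "rho2", "eta1", "eta2", "mu0"),
  mfg_1b              = c("rho1", "rho2", "eta1", "eta2", "mu0", "mu2"),
  matching            = c("rho1", "rho2", "eta1", "eta2", "mu"),
  parimi_li           = c("mu", "a0", "d0", "am", "dm", "i_m", "i_c"),
  saturated_delta     = c("d00", "d01", "d10", "d11", "d12", "d21", "d22"),
  rm_rp               = c("rm", "rp", "r2")
)

## parimi_li values live on the log scale and may be negative;
## saturated_delta values are penetrances; all others are positive factors.

#' Parameters of a published penetrance parameterisation
#'
#' Constructs a parameter set in one of the alternative "dialects" in which
#' family-based penetrance models have been published: the original and
#' later parent-of-origin (imprinting) parameterisations, the two
#' maternal-fetal genotype incompatibility (MFG) parameterisations, the
#' genotype "matching" model, the additive/dominance log-scale
#' parameterisation, the saturated seven-cell model, and the
#' maternal/paternal transmission-factor form.
#'
#' @param dialect one of `"default"`, `"weinberg_original_im"`,
#'   `"weinberg_original_ip"`, `"weinberg_later_im"`, `"weinberg_later_ip"`,
#'   `"mfg_1a"`, `"mfg_1b"`, `"matching"`, `"parimi_li"`,
#'   `"saturated_delta"`, `"rm_rp"`.
#' @param values named numeric vector or list giving every parameter of the
#'   dialect (see Details); unknown names are rejected.  `parimi_li` values
#'   are on the log scale and may be negative; all other dialects take
#'   strictly positive values.
#' @param alpha optional baseline penetrance; ignored by `parimi_li`
#'   (whose baseline is `exp(mu - am - a0)`) and `saturated_delta`
#'   (whose values are already penetrances).
#' @return An object of class `dialect_parameters`.
#' @examples
#' dialect_parameters("mfg_1b",
#'   c(rho1 = 1, rho2 = 1, eta1 = 1, eta2 = 1, mu0 = 4, mu2 = 1))
#' @export
dialect_parameters <- function(dialect, values, alpha = NA_real_) {
  dialect <- match.arg(dialect, names(DIALECTS))
  values <- unlist(values)
  need <- DIALECTS[[dialect]]
  if (dialect == "default") {
    miss <- setdiff(names(values), need)
    if (length(miss)) stop("unknown parameter name(s): ",
                           paste(miss, collapse = ", "))
    full <- stats::setNames(rep(1, length(need)), need)
    full[names(values)] <- values
    values <- full
  }
  if (!setequal(names(values), need))
    stop(sprintf("dialect '%s' requires exactly the parameters: %s",
                 dialect, paste(need, collapse = ", ")))
  values <- values[need]
  if (dialect != "parimi_li" && any(values <= 0))
    stop("dialect parameter values must be strictly positive")
  if (dialect == "saturated_delta" && any(values > 1))
    stop("saturated-model penetrances must lie in (0, 1]")
  structure(list(dialect = dialect, values = values, alpha = alpha),
            class = "dialect_parameters")
}

#' @export
print.dialect_parameters <- function(x, ...) {
  cat("Penetrance parameterisation:", x$dialect, "\n")
  print(signif(x$values, 6))
  if (!is.na(x$alpha)) cat("baseline alpha:", x$alpha, "\n")
  invisible(x)
}

## Ordered-origin table induced by a dialect, on the relative-risk scale
## (baseline penetrance divided out unless the dialect encodes it itself).
## Returns a named 8-vector keyed by ORDERED_KEYS.
dialect_ordered_table <- function(dp) {
  v <- as.list(dp$values)
  a <- if (!is.na(dp$alpha)) dp$alpha else 1
  tab <- switch(dp$dialect,
    default = {
      rp <- do.call(risk_parameters, v)
      a * risk_product(rp, ORDERED_COMBOS$gm, ORDERED_COMBOS$gc)
    },
    weinberg_original_im = with(v, a * c(
      1, r1, s1, r1 * s1, r1 * s1 * im, r2 * s1 * im, r1 * s2 * im,
      r2 * s2 * im)),
    weinberg_original_ip = with(v, a * c(
      1, r1 * ip, s1, r1 * s1 * ip, r1 * s1, r2 * s1 * ip, r1 * s2,
      r2 * s2 * ip)),
    weinberg_later_im = with(v, a * c(
      1, r1, s1, r1 * s1, r1 * s1 * im, r2 * s1, r1 * s2 * im, r2 * s2)),
    weinberg_later_ip = with(v, a * c(
      1, r1 * ip, s1, r1 * s1 * ip, r1 * s1, r2 * s1, r1 * s2, r2 * s2)),
    mfg_1a = with(v, a * c(
      1, rho1 * mu0, eta1, rho1 * eta1, rho1 * eta1, rho2 * eta1,
      rho1 * eta2, rho2 * eta2)),
    mfg_1b = with(v, a * c(
      1, rho1 * mu0, eta1, rho1 * eta1, rho1 * eta1, rho2 * eta1,
      rho1 * eta2 * mu2, rho2 * eta2)),
    matching = with(v, a * c(
      mu, rho1, eta1 * mu, rho1 * eta1 * mu, rho1 * eta1 * mu,
      rho2 * eta1 * mu, rho1 * eta2, rho2 * eta2 * mu)),
    parimi_li = with(v, {
      alpha <- exp(mu - am - a0)
      r1 <- exp(a0 + d0); r2 <- exp(2 * a0)
      s1 <- exp(am + dm); s2 <- exp(2 * am)
      jm <- exp(i_m); jc <- exp(i_c)
      alpha * c(1, r1 * jm * jc, s1 * jc, r1 * s1 * jm, r1 * s1,
                r2 * s1 * jc, r1 * s2 * jc, r2 * s2)
    }),
    saturated_delta = with(v, c(d00, d01, d10, d11, d11, d12, d21, d22)),
    rm_rp = with(v, a * c(1, rp, 1, rp, rm, r2, rm, r2))
  )
  stats::setNames(tab, ORDERED_KEYS)
}

## Solve the canonical default-dialect parameters from an ordered table,
## under the identification Ip = g12 = g21 = 1 (or Im = g12 = g21 = 1
## when fix = "im").
solve_default_from_table <- function(tab, fix = c("ip", "im")) {
  fix <- match.arg(fix)
  a <- tab[["11.11"]]
  s1 <- tab[["12.11"]] / a
  if (fix == "ip") {
    r1 <- tab[["11.12"]] / a
    g11 <- tab[["12.12"]] / (a * r1 * s1)
    im <- tab[["12.21"]] / tab[["12.12"]]
    r2 <- tab[["12.22"]] / (a * s1 * im)
    s2 <- tab[["22.21"]] / (a * r1 * im)
    g22 <- tab[["22.22"]] / (a * r2 * s2 * im)
    list(r1 = r1, r2 = r2, s1 = s1, s2 = s2, im = im, ip = 1,
         g11 = g11, g22 = g22, alpha = a)
  } else {
    im <- 1
    ## mirror convention: estimate Ip, fix Im
    ip <- tab[["12.12"]] / tab[["12.21"]]
    r1 <- tab[["11.12"]] / (a * ip)
    g11 <- tab[["12.21"]] / (a * r1 * s1)
    r2 <- tab[["12.22"]] / (a * s1 * ip)
    s2 <- tab[["22.21"]] / (a * r1)
    g22 <- tab[["22.22"]] / (a * r2 * s2 * ip)
    list(r1 = r1, r2 = r2, s1 = s1, s2 = s2, im = 1, ip = ip,
         g11 = g11, g22 = g22, alpha = a)
  }
}

#' Convert a dialect parameter set to the canonical parameterisation
#'
#' Finds the canonical (default-dialect) risk parameters whose induced
#' ordered-origin penetrance table is identical, cell by cell, to the table
#' induced by `dp`.  Where the map is many-to-one the canonical
#' identification fixes `ip = g12 = g21 = 1` (or, with `fix = "im"`, fixes
#' `im = g12 = g21 = 1` and estimates `ip`), so returned parameters should
#' be read as the composites listed by [identifiable_set()] when that
#' fixing assumption fails.
#'
#' @param dp a [dialect_parameters()] object.
#' @param fix which imprinting factor to fix at 1 (`"ip"`, the default
#'   convention, or the mirror convention `"im"`).
#' @return A [risk_parameters()] object, with attribute `"notes"` listing
#'   the fixing convention used.
#' @examples
#' to_default_dialect(dialect_parameters("mfg_1b",
#'   c(rho1 = 1, rho2 = 1, eta1 = 1, eta2 = 1, mu0 = 4, mu2 = 1)))
#' @export
to_default_dialect <- function(dp, fix = c("ip", "im")) {
  stopifnot(inherits(dp, "dialect_parameters"))
  fix <- match.arg(fix)
  tab <- dialect_ordered_table(dp)
  sol <- solve_default_from_table(tab, fix = fix)
  base <- sol$alpha                     # table value in the (11, 11) cell
  sol$alpha <- NULL
  ## report alpha only when the dialect pins down an absolute penetrance scale
  has_scale <- !is.na(dp$alpha) ||
    dp$dialect %in% c("parimi_li", "saturated_delta")
  alpha_out <- if (has_scale && base > 0 && base <= 1) base else NA_real_
  rp <- do.call(risk_parameters, c(sol, list(alpha = alpha_out)))
  back <- base * risk_product(rp, ORDERED_COMBOS$gm, ORDERED_COMBOS$gc)
  rel_err <- abs(back - tab) / pmax(abs(tab), .Machine$double.eps)
  if (any(rel_err > 1e-10))
    stop(sprintf(
      "dialect '%s' has no default-dialect representation under the %s-fixed identification",
      dp$dialect, toupper(fix)))
  attr(rp, "notes") <- sprintf(
    "canonical identification: %s = g12 = g21 = 1; parameters are composites if that fails",
    fix)
  rp
}

#' Express canonical risk parameters in another dialect
#'
#' Solves the target dialect's parameters against the penetrance table
#' induced by `params` and verifies the round trip cell by cell: dialects
#' able to represent parent-of-origin differences are matched on the full
#' ordered-origin table, dialects without imprinting terms require the
#' source table to be origin-symmetric, and the saturated dialect is
#' matched on the seven observable (collapsed) cells.
#'
#' @param params a [risk_parameters()] object.
#' @param dialect target dialect name (see [dialect_parameters()]).
#' @param weight_maternal maternal-origin mixture weight, used only when
#'   collapsing for the saturated dialect.
#' @param tol relative tolerance for the round-trip verification.
#' @return A [dialect_parameters()] object.
#' @examples
#' to_dialect(risk_parameters(r1 = 1.5, r2 = 2.25, im = 1.8),
#'            "weinberg_later_im")
#' @export
to_dialect <- function(params, dialect, weight_maternal = 0.5, tol = 1e-10) {
  stopifnot(inherits(params, "risk_parameters"))
  dialect <- match.arg(dialect, names(DIALECTS))
  alpha <- unclass(params)[["alpha"]]
  a <- if (is.na(alpha)) 1 else alpha
  tab <- stats::setNames(
    a * risk_product(params, ORDERED_COMBOS$gm, ORDERED_COMBOS$gc),
    ORDERED_KEYS)
  t_ <- function(k) tab[[k]]
  vals <- switch(dialect,
    default = {
      sol <- solve_default_from_table(tab)
      sol[c("alpha")] <- NULL
      unlist(sol)
    },
    weinberg_original_im = {
      r1 <- t_("11.12") / a; s1 <- t_("12.11") / a
      im <- t_("12.21") / t_("12.12")
      c(r1 = r1, r2 = t_("12.22") / (a * s1 * im), s1 = s1,
        s2 = t_("22.21") / (a * r1 * im), im = im)
    },
    weinberg_original_ip = {
      s1 <- t_("12.11") / a
      ip <- t_("12.12") / t_("12.21")
      r1 <- t_("11.12") / (a * ip)
      c(r1 = r1, r2 = t_("12.22") / (a * s1 * ip), s1 = s1,
        s2 = t_("22.21") / (a * r1), ip = ip)
    },
    weinberg_later_im = {
      r1 <- t_("11.12") / a; s1 <- t_("12.11") / a
      im <- t_("12.21") / t_("12.12")
      c(r1 = r1, r2 = t_("12.22") / (a * s1), s1 = s1,
        s2 = t_("22.21") / (a * r1 * im), im = im)
    },
    weinberg_later_ip = {
      s1 <- t_("12.11") / a
      ip <- t_("12.12") / t_("12.21")
      r1 <- t_("11.12") / (a * ip)
      c(r1 = r1, r2 = t_("12.22") / (a * s1), s1 = s1,
        s2 = t_("22.21") / (a * r1), ip = ip)
    },
    mfg_1a = ,
    mfg_1b = {
      eta1 <- t_("12.11") / a
      rho1 <- t_("12.12") / (a * eta1)
      rho2 <- t_("12.22") / (a * eta1)
      eta2 <- t_("22.22") / (a * rho2)
      v <- c(rho1 = rho1, rho2 = rho2, eta1 = eta1, eta2 = eta2,
             mu0 = t_("11.12") / (a * rho1))
      if (dialect == "mfg_1b")
        v <- c(v, mu2 = t_("22.21") / (a * rho1 * eta2))
      v
    },
    matching = {
      eta1 <- t_("12.11") / a
      rho1 <- t_("12.12") / (a * eta1)
      mu <- a * rho1 / t_("11.12")
      rho2 <- t_("12.22") / (a * eta1)
      eta2 <- t_("22.21") * mu / (a * rho1)
      c(rho1 = rho1, rho2 = rho2, eta1 = eta1, eta2 = eta2, mu = mu)
    },
    parimi_li = {
      jm <- t_("12.12") / t_("12.21")
      jc2 <- t_("11.12") * t_("12.11") / (a * t_("12.21") * jm)
      jc <- sqrt(jc2)
      s1 <- t_("12.11") / (a * jc)
      r1 <- t_("12.21") / (a * s1)
      r2 <- t_("12.22") / (a * s1 * jc)
      s2 <- t_("22.21") / (a * r1 * jc)
      a0 <- log(r2) / 2; am <- log(s2) / 2
      c(mu = log(a) + am + a0, a0 = a0, d0 = log(r1) - a0,
        am = am, dm = log(s1) - am, i_m = log(jm), i_c = log(jc))
    },
    saturated_delta = {
      if (is.na(alpha))
        stop("the saturated dialect requires alpha (its values are penetrances)")
      coll <- collapse_penetrance(
        data.frame(ORDERED_COMBOS, penetrance = tab), weight_maternal)
      stats::setNames(coll$penetrance,
                      c("d00", "d01", "d10", "d11", "d12", "d21", "d22"))
    },
    rm_rp = {
      c(rm = t_("22.21") / a, rp = t_("11.12") / a, r2 = t_("22.22") / a)
    })
  dp_alpha <- if (dialect %in% c("parimi_li", "saturated_delta"))
    NA_real_
  else if (dialect == "matching")
    a / vals[["mu"]]   # the matching baseline is alpha' = alpha / mu
  else alpha
  dp <- dialect_parameters(dialect, vals, alpha = dp_alpha)
  back <- dialect_ordered_table(dp)
  if (dialect == "saturated_delta") {
    src <- collapse_penetrance(
      data.frame(ORDERED_COMBOS, penetrance = tab), weight_maternal)
    bk <- collapse_penetrance(
      data.frame(ORDERED_COMBOS, penetrance = back), weight_maternal)
    rel_err <- abs(bk$penetrance - src$penetrance) /
      pmax(abs(src$penetrance), .Machine$double.eps)
  } else {
    rel_err <- abs(back - tab) / pmax(abs(tab), .Machine$double.eps)
  }
  if (any(rel_err > tol))
    stop(sprintf(
      "penetrance table is not representable in dialect '%s' (max relative error %.3g)",
      dialect, max(rel_err)))
  dp
}

#' Identifiable relative-risk parameters for a set of data structures
#'
#' Reports the canonical free parameter set for the data structures in
#' hand, together with the composite each returned parameter represents if
#' the canonical fixing assumption (`ip = g12 = g21 = 1`) fails.  With
#' case/parent trios seven relative-risk parameters are identifiable; with
#' case/mother duos alone the seven observable cells support at most six
#' free parameters in total (including any freely estimated nuisance such
#' as the allele frequency).
#'
#' @param structure_kinds character vector of structure kinds present
#'   (e.g. `"case_parent_trio"`, `"case_mother_duo"`).
#' @param regime nuisance regime, as in [nuisance_model()].
#' @param requested optional character vector of requested free risk
#'   parameters (plus `"a2"`); when the request may exceed what the data
#'   identify, the result carries a `joint_identifiability_warning`
#'   attribute and the fit-level information-matrix check should be
#'   consulted.
#' @param fix which imprinting factor the canonical convention fixes.
#' @return Data frame with columns `parameter` and `composite`.
#' @export
identifiable_set <- function(structure_kinds, regime = "mating_symmetry",
                             requested = NULL, fix = c("ip", "im")) {
  fix <- match.arg(fix)
  if (length(structure_kinds) == 0L)
    stop("structure_kinds must be nonempty")
  comp <- if (fix == "ip")
    c(r1 = "R1*Ip", r2 = "R2*Ip^2*g12", s1 = "S1", s2 = "S2*g21",
      im = "Im/Ip", g11 = "g11", g22 = "g22/(g12*g21)")
  else
    c(r1 = "R1*Im", r2 = "R2*Im^2*g12", s1 = "S1", s2 = "S2*g21",
      ip = "Ip/Im", g11 = "g11", g22 = "g22/(g12*g21)")
  out <- data.frame(parameter = names(comp), composite = unname(comp),
                    stringsAsFactors = FALSE)
  duo_only <- !any(structure_kinds %in% "case_parent_trio")
  if (duo_only) {
    ## seven observable duo cells minus one normalisation
    free_n <- if (regime == "hwe_rm_free_af") 5L else 6L
    out <- out[seq_len(min(nrow(out), free_n)), ]
    if (regime == "hwe_rm_free_af")
      out <- rbind(out, data.frame(parameter = "a2",
                                   composite = "allele-2 frequency"))
  }
  if (!is.null(requested) && duo_only) {
    ## 7 duo cells - 1 normalisation = at most 6 jointly estimable
    ## parameters; requests at (or beyond) that bound need the fit-level
    ## information-matrix check
    n_risk <- length(setdiff(requested, "a2"))
    if (length(requested) > 6L ||
        ("a2" %in% requested && n_risk >= 5L))
      attr(out, "joint_identifiability_warning") <- TRUE
  }
  out
}
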