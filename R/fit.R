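#' Model specification for a multinomial family-likelihood fit
#'
#' @param free character vector of freely estimated risk parameters, named
#'   in the chosen dialect (for the default dialect a subset of
#'   `r1, r2, s1, s2, im, ip, g11, g12, g21, g22`).  May be empty (null
#'   model).
#' @param regime nuisance regime, as in [nuisance_model()].
#' @param a2 allele-2 frequency: the fixed value under
#'   `"hwe_rm_fixed_af"`, otherwise an optional starting value.
#' @param fixed named list of fixed values for non-free dialect
#'   parameters (defaults: 1, or 0 for the log-scale dialect).
#' @param dialect penetrance parameterisation to estimate in (see
#'   [dialect_parameters()]); inference is invariant to this choice
#'   whenever the dialects span the same table family, but the meaning of
#'   the estimates is not.
#' @return An object of class `model_spec`.
#' @examples
#' model_spec(c("r1", "r2", "s1", "s2"), regime = "hwe_rm_free_af")
#' @export
model_spec <- function(free = character(),
                       regime = c("hwe_rm_fixed_af", "hwe_rm_free_af",
                                  "pae", "mating_symmetry"),
                       a2 = NULL, fixed = list(), dialect = "default") {
  regime <- match.arg(regime)
  dialect <- match.arg(dialect, names(DIALECTS))
  all_names <- DIALECTS[[dialect]]
  free <- as.character(free)
  bad <- setdiff(free, all_names)
  if (length(bad))
    stop(sprintf("unknown free parameter(s) for dialect '%s': %s",
                 dialect, paste(bad, collapse = ", ")))
  bad <- setdiff(names(fixed), all_names)
  if (length(bad))
    stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "))
  if (regime == "hwe_rm_fixed_af") {
    if (is.null(a2)) stop("regime 'hwe_rm_fixed_af' requires a fixed a2")
    if (a2 <= 0 || a2 >= 1) stop("fixed a2 must lie in (0, 1)")
  }
  structure(list(free = free, regime = regime, a2 = a2,
                 fixed = fixed, dialect = dialect),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model specification (dialect:", x$dialect, ")\n")
  cat("  free risk parameters:",
      if (length(x$free)) paste(x$free, collapse = ", ") else "(none)", "\n")
  if (length(x$fixed))
    cat("  fixed:", paste(names(x$fixed), unlist(x$fixed), sep = "=",
                          collapse = ", "), "\n")
  cat("  nuisance regime:", x$regime,
      if (!is.null(x$a2)) paste0("(a2 ", if (x$regime == "hwe_rm_fixed_af")
        "fixed at " else "start ", x$a2, ")") else "", "\n")
  invisible(x)
}

## number of freely estimated nuisance parameters per regime
n_free_nuisance <- function(regime)
  switch(regime, hwe_rm_fixed_af = 0L, hwe_rm_free_af = 1L, pae = 4L,
         mating_symmetry = 5L)

## Full dialect value vector from free values theta + fixed values.
## Free values enter on the log scale except for the log-scale dialect.
dialect_values <- function(spec, theta_free) {
  all_names <- DIALECTS[[spec$dialect]]
  base <- if (spec$dialect == "parimi_li") 0 else 1
  v <- stats::setNames(rep(base, length(all_names)), all_names)
  if (length(spec$fixed)) v[names(spec$fixed)] <- unlist(spec$fixed)
  if (length(spec$free))
    v[spec$free] <- if (spec$dialect == "parimi_li") theta_free
                    else exp(theta_free)
  v
}

## log risk factors (canonical scale) implied by a dialect value vector
dialect_log_factors <- function(spec, values) {
  if (spec$dialect == "default") {
    lf <- numeric(length(RISK_FACTOR_NAMES))
    names(lf) <- RISK_FACTOR_NAMES
    lf[names(values)] <- log(values)
    return(lf)
  }
  dp <- list(dialect = spec$dialect, values = values, alpha = NA_real_)
  tab <- dialect_ordered_table(dp)
  sol <- solve_default_from_table(tab)
  lf <- log(unlist(sol[RISK_FACTOR_NAMES[1:7]]))
  lf <- c(lf, g12 = 0, g21 = 0, g22 = log(sol$g22))
  lf[RISK_FACTOR_NAMES] - log(sol$alpha)  # rescale so baseline term is 0
}

## mu vector from the nuisance block of theta
theta_to_mu <- function(spec, theta_nuis) {
  switch(spec$regime,
    hwe_rm_fixed_af = mu_from_a2(spec$a2),
    hwe_rm_free_af = mu_from_a2(stats::plogis(theta_nuis[1L])),
    pae = {
      m <- exp(theta_nuis)
      c(m[1L], m[2L], m[3L], m[3L], m[4L], 1)
    },
    mating_symmetry = c(exp(theta_nuis), 1))
}

## rescale a fitted mu vector so the implied null table is a distribution
rescale_mu <- function(mu) {
  tot <- mu[1L] + 4 * mu[2L] + 2 * mu[3L] + 4 * mu[4L] + 4 * mu[5L] + mu[6L]
  mu / tot
}

## Pre-digest datasets for the optimiser
digest_datasets <- function(datasets) {
  if (inherits(datasets, "structure_counts")) datasets <- list(datasets)
  if (!length(datasets)) stop("at least one dataset is required")
  lapply(datasets, function(d) {
    stopifnot(inherits(d, "structure_counts"))
    kind <- d$structure_kind
    eq <- CONTROL_EQUIVALENT[kind]
    list(kind = kind,
         layout_kind = if (is.na(eq)) kind else eq,
         is_control = !is.na(eq),
         group = structure_layout[[if (is.na(eq)) kind else eq]]$group,
         counts = unname(d$counts),
         n = sum(d$counts))
  })
}

## joint log-likelihood evaluated from pre-digested datasets
digested_loglik <- function(dig, log_fac, mu) {
  raw <- trio_raw_weights(log_fac, mu)
  raw0 <- NULL
  ll <- 0
  for (d in dig) {
    if (d$is_control) {
      if (is.null(raw0))
        raw0 <- trio_raw_weights(numeric(length(RISK_FACTOR_NAMES)), mu)
      w <- rowsum(raw0, d$group)[, 1L]
    } else {
      w <- rowsum(raw, d$group)[, 1L]
    }
    p <- w / sum(w)
    ll <- ll + sum(d$counts * log(pmax(p, PROB_FLOOR)))
  }
  ll
}

#' Fit a multinomial family-likelihood model
#'
#' Maximises the joint multinomial log-likelihood of the supplied
#' datasets over the log-transformed free risk parameters and the
#' nuisance parameters of the chosen regime (logit allele frequency, or
#' log mating-type parameters with `mu6` fixed at 1 to absorb the free
#' scale).  Standard errors come from the inverse observed information on
#' the working (log) scale; a condition number of the information matrix
#' above `1e10` raises the non-identifiability flag and suppresses the
#' standard errors.  Quasi-Newton maximisation (`nlminb`) is retried from
#' deterministically perturbed starting points on non-convergence, so
#' results do not depend on the random-number generator state.
#'
#' @param datasets a [structure_counts()] object or list of them.
#' @param spec a [model_spec()].
#' @param compute_null also fit the nested null model with every risk
#'   factor fixed at 1 and the nuisance profiled (default `TRUE`).
#' @param start optional named starting values for the free risk
#'   parameters (natural scale).
#' @param restarts number of perturbed restarts after a failed attempt.
#' @return An object of class `fit_result` with elements `estimates`
#'   (data frame: parameter, estimate, se, log_estimate, se_log),
#'   `max_loglik`, `null_loglik`, `nuisance` (fitted [nuisance_model()]),
#'   `converged`, `identifiable`, `condition_number`, `iterations`,
#'   `spec`, `n_free`.
#' @examples
#' nu <- nuisance_model("hwe_rm_fixed_af", a2 = 0.3)
#' tab <- duo_cell_table(risk_parameters(r1 = 1.5, r2 = 2.25), nu)
#' d <- structure_counts("case_mother_duo", round(500 * tab$cells$probability))
#' fit_model(d, model_spec(c("r1", "r2"), "hwe_rm_fixed_af", a2 = 0.3))
#' @export
fit_model <- function(datasets, spec, compute_null = TRUE, start = NULL,
                      restarts = 3L) {
  stopifnot(inherits(spec, "model_spec"))
  dig <- digest_datasets(datasets)
  if (all(vapply(dig, function(d) d$n, 0) == 0))
    stop("all datasets have zero total count")
  k_risk <- length(spec$free)
  k_nuis <- n_free_nuisance(spec$regime)
  k <- k_risk + k_nuis

  negll <- function(theta) {
    lf <- dialect_log_factors(
      spec, dialect_values(spec, theta[seq_len(k_risk)]))
    mu <- theta_to_mu(spec, theta[k_risk + seq_len(k_nuis)])
    v <- -digested_loglik(dig, lf, mu)
    if (!is.finite(v)) v <- 1e12
    v
  }

  ## starting point: identity risk factors; allele frequency from a crude
  ## pooled allele count; mu at the HWE values of that frequency
  a2_start <- spec$a2
  if (is.null(a2_start)) a2_start <- crude_allele_freq(datasets)
  theta0 <- numeric(k)
  if (k_risk && !is.null(start)) {
    st <- rep(0, k_risk)
    hit <- match(names(start), spec$free)
    st[hit[!is.na(hit)]] <- log(unlist(start)[!is.na(hit)])
    theta0[seq_len(k_risk)] <- st
  }
  if (k_nuis) {
    theta0[k_risk + seq_len(k_nuis)] <- switch(spec$regime,
      hwe_rm_free_af = stats::qlogis(a2_start),
      pae = log(mu_from_a2(a2_start)[c(1, 2, 3, 5)] /
                  mu_from_a2(a2_start)[6]),
      mating_symmetry = log(mu_from_a2(a2_start)[1:5] /
                              mu_from_a2(a2_start)[6]))
  }

  best <- NULL
  iterations <- 0L
  for (attempt in 0:restarts) {
    th <- theta0
    if (attempt > 0 && k > 0)
      th <- theta0 + 0.5 * attempt * sin(seq_len(k) * attempt * 1.7)
    if (k == 0L) {
      best <- list(par = numeric(0), objective = negll(numeric(0)),
                   convergence = 0L, iterations = 0L)
      break
    }
    opt <- tryCatch(
      stats::nlminb(th, negll,
                    control = list(rel.tol = 1e-10, iter.max = 500L)),
      error = function(e) NULL)
    if (!is.null(opt)) {
      iterations <- iterations + opt$iterations
      if (is.null(best) || opt$objective < best$objective - 1e-9)
        best <- opt
      if (opt$convergence == 0L && attempt >= 0) break
    }
  }
  if (is.null(best))
    stop("optimiser failed on every attempt")
  converged <- best$convergence == 0L
  theta_hat <- best$par
  max_ll <- -best$objective

  ## observed information on the working scale
  se_log <- rep(NA_real_, k_risk)
  identifiable <- TRUE
  cond <- NA_real_
  if (k > 0L) {
    H <- tryCatch(stats::optimHess(theta_hat, negll), error = function(e) NULL)
    V <- NULL
    if (!is.null(H)) {
      ev <- tryCatch(eigen(H, symmetric = TRUE,
                           only.values = TRUE)$values,
                     error = function(e) NULL)
      cond <- if (!is.null(ev) && min(ev) > 0) max(ev) / min(ev) else Inf
      if (is.finite(cond) && cond <= 1e10)
        V <- tryCatch(solve(H), error = function(e) NULL)
    }
    if (is.null(V)) {
      identifiable <- FALSE
    } else if (k_risk > 0L) {
      se_log <- sqrt(pmax(diag(V)[seq_len(k_risk)], 0))
    }
  }

  est_nat <- if (k_risk) {
    v <- dialect_values(spec, theta_hat[seq_len(k_risk)])[spec$free]
    unname(v)
  } else numeric(0)
  log_est <- if (spec$dialect == "parimi_li") est_nat else log(est_nat)
  estimates <- data.frame(
    parameter = spec$free,
    estimate = est_nat,
    se = if (spec$dialect == "parimi_li") se_log else est_nat * se_log,
    log_estimate = log_est,
    se_log = se_log,
    stringsAsFactors = FALSE)

  mu_hat <- theta_to_mu(spec, theta_hat[k_risk + seq_len(k_nuis)])
  nuis_hat <- if (startsWith(spec$regime, "hwe"))
    nuisance_model(spec$regime,
                   a2 = if (spec$regime == "hwe_rm_fixed_af") spec$a2
                        else stats::plogis(theta_hat[k_risk + 1L]))
  else nuisance_model(spec$regime, mu = rescale_mu(mu_hat))

  null_ll <- NA_real_
  if (compute_null) {
    if (k_risk == 0L) null_ll <- max_ll
    else {
      null_spec <- spec
      null_spec$free <- character(0)
      null_spec$fixed <- list()
      nf <- fit_model(datasets, null_spec, compute_null = FALSE,
                      restarts = restarts)
      null_ll <- nf$max_loglik
    }
  }

  structure(list(estimates = estimates, max_loglik = max_ll,
                 null_loglik = null_ll, nuisance = nuis_hat,
                 converged = converged, identifiable = identifiable,
                 condition_number = cond, iterations = iterations,
                 spec = spec,
                 n_free = c(risk = k_risk, nuisance = k_nuis)),
            class = "fit_result")
}

## crude pooled allele-2 frequency over all structures, used only as a
## starting value
crude_allele_freq <- function(datasets) {
  if (inherits(datasets, "structure_counts")) datasets <- list(datasets)
  two <- 0; tot <- 0
  for (d in datasets) {
    labs <- names(d$counts)
    n2 <- vapply(strsplit(gsub("[x-]", "", labs), ""),
                 function(a) sum(a == "2"), 0)
    n_alleles <- nchar(gsub("[x-]", "", labs))
    two <- two + sum(d$counts * n2)
    tot <- tot + sum(d$counts * n_alleles)
  }
  if (tot == 0) return(0.5)
  min(max(two / tot, 0.02), 0.98)
}

#' @export
print.fit_result <- function(x, digits = 4, ...) {
  cat("Multinomial family-likelihood fit (dialect:", x$spec$dialect, ")\n")
  cat(sprintf("  max log-likelihood %.4f (null %.4f), regime %s\n",
              x$max_loglik, x$null_loglik, x$spec$regime))
  if (nrow(x$estimates)) {
    df <- x$estimates
    df$estimate <- signif(df$estimate, digits)
    df$se <- signif(df$se, digits)
    print(df[, c("parameter", "estimate", "se")], row.names = FALSE)
  } else cat("  (no free risk parameters)\n")
  if (!x$converged) cat("  WARNING: optimiser did not converge\n")
  if (!x$identifiable)
    cat("  WARNING: information matrix singular or ill-conditioned;",
        "parameters may not be jointly identifiable\n")
  invisible(x)
}

#' Likelihood-ratio test between two nested fits
#'
#' @param full,null `fit_result` objects; the null's free risk-parameter
#'   set must be a subset of the full's (a null with no free risk
#'   parameters is nested in any model).  Nuisance parameters are profiled
#'   under both hypotheses and do not contribute degrees of freedom.
#' @return List with `statistic` (twice the log-likelihood difference,
#'   clipped at zero), `df` and `p_value`.
#' @export
likelihood_ratio_test <- function(full, null) {
  stopifnot(inherits(full, "fit_result"), inherits(null, "fit_result"))
  nested <- length(null$spec$free) == 0L ||
    (identical(null$spec$dialect, full$spec$dialect) &&
       all(null$spec$free %in% full$spec$free))
  if (!nested)
    stop("the null model's free parameters are not a subset of the full model's")
  df <- full$n_free[["risk"]] - null$n_free[["risk"]]
  if (df <= 0L) df <- max(df, 0L)
  stat <- max(0, 2 * (full$max_loglik - null$max_loglik))
  list(statistic = stat, df = df,
       p_value = if (df == 0L) 1 else stats::pchisq(stat, df,
                                                    lower.tail = FALSE))
}

#' Fit one of the preset analysis methods
#'
#' Configures the nuisance regime and control likelihoods of the numbered
#' method presets and runs [fit_model()]:
#' method 0 is the logistic-regression comparator for case/mother vs
#' control/mother duos; 1 assumes HWE and random mating with the allele
#' frequency fixed; 2 (equivalently 2a) estimates the allele frequency
#' under HWE and random mating from the family data alone, while 2b
#' estimates the six mating-type parameters instead; 3, 4 and 7 estimate
#' the allele frequency with the help of unrelated controls, parents of
#' controls, or control/mother duos respectively; 5 and 8 assume only
#' parental allelic exchangeability (`mu3 = mu4`); 6 and 9 assume only
#' mating symmetry.
#'
#' @param method_id one of `"0","1","2","2a","2b","3","4","5","6","7",
#'   "8","9"` (numeric accepted).
#' @param case_datasets list of case-side [structure_counts()].
#' @param control_datasets list of control-side [structure_counts()]
#'   (required for methods 3-9; must contain the method's control
#'   structure).
#' @param free free risk parameters passed to [model_spec()].
#' @param a2 fixed allele frequency (required for method 1).
#' @param ... further arguments to [fit_model()] (or, for method 0, to
#'   [logistic_duo_comparator()]).
#' @return A `fit_result`.
#' @export
fit_method <- function(method_id, case_datasets, control_datasets = NULL,
                       free = c("r1", "r2", "s1", "s2"), a2 = NULL, ...) {
  method_id <- as.character(method_id)
  method_id <- match.arg(method_id,
                         c("0", "1", "2", "2a", "2b", "3", "4", "5", "6",
                           "7", "8", "9"))
  if (inherits(case_datasets, "structure_counts"))
    case_datasets <- list(case_datasets)
  if (inherits(control_datasets, "structure_counts"))
    control_datasets <- list(control_datasets)
  kinds <- function(ds) vapply(ds, function(d) d$structure_kind, "")

  if (method_id == "0") {
    ccase <- case_datasets[kinds(case_datasets) == "case_mother_duo"]
    cctl <- control_datasets[kinds(control_datasets) ==
                               "control_mother_duo"]
    if (!length(ccase) || !length(cctl))
      stop("method 0 requires case/mother and control/mother duos")
    return(logistic_duo_comparator(ccase[[1L]], cctl[[1L]], free = free,
                                   ...))
  }

  need_ctl <- switch(method_id, "3" = "control",
                     "4" = , "5" = , "6" = "parents_of_control",
                     "7" = , "8" = , "9" = "control_mother_duo",
                     NULL)
  if (!is.null(need_ctl)) {
    have <- kinds(control_datasets)
    if (!need_ctl %in% have)
      stop(sprintf("method %s requires a '%s' control sample", method_id,
                   need_ctl))
    control_datasets <- control_datasets[have == need_ctl]
  } else control_datasets <- NULL

  regime <- switch(method_id,
    "1" = "hwe_rm_fixed_af",
    "2" = , "2a" = , "3" = , "4" = , "7" = "hwe_rm_free_af",
    "5" = , "8" = "pae",
    "2b" = , "6" = , "9" = "mating_symmetry")
  if (regime == "hwe_rm_fixed_af" && is.null(a2))
    stop("method 1 requires a fixed allele frequency a2")
  spec <- model_spec(free = free, regime = regime, a2 = a2)
  fit_model(c(case_datasets, control_datasets), spec, ...)
}

#' Fit a sequence of candidate models and compare them by AIC
#'
#' @param datasets as in [fit_model()].
#' @param specs ordered list of at least two [model_spec()] objects.
#' @param ... passed to [fit_model()].
#' @return Data frame with one row per model (`model`, `k_risk`,
#'   `k_nuisance`, `max_loglik`, `aic`, `best`), with the fits attached
#'   as the `"fits"` attribute.  Ties are broken in favour of the model
#'   listed first.
#' @export
model_sequence <- function(datasets, specs, ...) {
  if (length(specs) < 2L) stop("at least two model specifications required")
  fits <- lapply(specs, function(s) fit_model(datasets, s,
                                              compute_null = FALSE, ...))
  k_risk <- vapply(fits, function(f) f$n_free[["risk"]], 0L)
  k_nuis <- vapply(fits, function(f) f$n_free[["nuisance"]], 0L)
  ll <- vapply(fits, function(f) f$max_loglik, 0)
  aic <- 2 * (k_risk + k_nuis) - 2 * ll
  best <- which(aic <= min(aic) + 1e-9)[1L]  # first wins on ties
  out <- data.frame(
    model = vapply(seq_along(specs), function(i)
      if (length(specs[[i]]$free))
        paste(specs[[i]]$free, collapse = "+") else "(null)", ""),
    k_risk = k_risk, k_nuisance = k_nuis, max_loglik = ll, aic = aic,
    best = seq_along(specs) == best,
    stringsAsFactors = FALSE)
  attr(out, "fits") <- fits
  out
}
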