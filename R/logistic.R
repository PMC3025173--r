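## Prospective logistic comparator: case/mother duos vs control/mother
## duos with cell-level covariates coded from the multiplicative risk
## model.  Fitted by Newton-Raphson on the aggregated binomial
## likelihood; implemented here directly so the comparator is
## self-contained and its likelihood is available exactly.

## covariate column for one risk parameter over the 7 duo cells
## (frozen duo order 22-22, 22-12, 12-22, 12-12, 12-11, 11-12, 11-11);
## the ambiguous (12,12) cell carries fractional imprinting exposure
## wm (maternal) / 1 - wm (paternal)
duo_design_column <- function(par, wm) {
  switch(par,
    r1  = c(0, 1, 0, 1, 0, 1, 0),
    r2  = c(1, 0, 1, 0, 0, 0, 0),
    s1  = c(0, 0, 1, 1, 1, 0, 0),
    s2  = c(1, 1, 0, 0, 0, 0, 0),
    im  = c(1, 1, 1, wm, 0, 0, 0),
    ip  = c(1, 0, 1, 1 - wm, 0, 1, 0),
    g11 = c(0, 0, 0, 1, 0, 0, 0),
    g12 = c(0, 0, 1, 0, 0, 0, 0),
    g21 = c(0, 1, 0, 0, 0, 0, 0),
    g22 = c(1, 0, 0, 0, 0, 0, 0),
    stop("no logistic covariate coding for parameter '", par, "'"))
}

## allele-2 frequency among the genotypes of a duo count vector
duo_allele_freq <- function(counts) {
  labs <- names(counts)
  n2 <- vapply(strsplit(gsub("-", "", labs), ""),
               function(a) sum(a == "2"), 0)
  sum(counts * n2) / (4 * sum(counts))
}

#' Logistic regression of case/mother vs control/mother duos
#'
#' The standard prospective comparator: disease status is regressed on
#' cell-level covariates coded from the chosen risk parameterisation over
#' the seven observable mother/child genotype combinations.  Imprinting
#' covariates are ambiguous in the double-heterozygote cell; there they
#' take the fractional value `weight_maternal`, which by default is the
#' low-risk allele frequency `A1` estimated (plug-in) from the control
#' duos.  The model is fitted by Newton-Raphson iteration on the
#' aggregated binomial log-likelihood.
#'
#' @param case_duos a `case_mother_duo` [structure_counts()].
#' @param control_duos a `control_mother_duo` [structure_counts()].
#' @param free risk parameters to include as covariates (subset of
#'   `r1, r2, s1, s2, im, ip, g11, g12, g21, g22`), or `"saturated"` for
#'   one indicator per non-baseline cell.
#' @param weight_maternal optional override for the fractional maternal
#'   weight in the double-heterozygote cell.
#' @param tol convergence tolerance on the score norm.
#' @param max_iter maximum Newton iterations.
#' @return A `fit_result`; `estimates` hold odds ratios (`estimate`) and
#'   log odds ratios (`log_estimate`), `max_loglik`/`null_loglik` are the
#'   binomial log-likelihoods of the fitted and intercept-only models.
#' @export
logistic_duo_comparator <- function(case_duos, control_duos,
                                    free = c("r1", "r2", "s1", "s2"),
                                    weight_maternal = NULL,
                                    tol = 1e-10, max_iter = 50L) {
  stopifnot(inherits(case_duos, "structure_counts"),
            inherits(control_duos, "structure_counts"))
  if (case_duos$structure_kind != "case_mother_duo" ||
      control_duos$structure_kind != "control_mother_duo")
    stop("expected one case_mother_duo and one control_mother_duo dataset")
  if (is.null(weight_maternal))
    weight_maternal <- 1 - duo_allele_freq(control_duos$counts)
  if (identical(free, "saturated")) {
    X <- cbind(1, diag(7)[, 1:6])
    colnames(X) <- c("(intercept)", paste0("cell", 1:6))
  } else {
    X <- cbind(1, vapply(free,
                         function(p) duo_design_column(p, weight_maternal),
                         numeric(7)))
    colnames(X) <- c("(intercept)", free)
  }
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient logistic design: requested parameters are not ",
         "jointly identifiable from the seven duo cells")
  y <- unname(case_duos$counts)        # successes (cases) per cell
  n <- y + unname(control_duos$counts) # binomial totals per cell
  keep <- n > 0
  Xk <- X[keep, , drop = FALSE]; yk <- y[keep]; nk <- n[keep]

  newton <- function(Xm) {
    beta <- numeric(ncol(Xm))
    for (it in seq_len(max_iter)) {
      eta <- as.vector(Xm %*% beta)
      p <- stats::plogis(eta)
      score <- crossprod(Xm, yk - nk * p)
      W <- nk * p * (1 - p)
      info <- crossprod(Xm, Xm * W)
      step <- tryCatch(solve(info, score), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      beta <- beta + as.vector(step)
      if (sqrt(sum(score^2)) < tol) break
    }
    p <- stats::plogis(as.vector(Xm %*% beta))
    p <- pmin(pmax(p, PROB_FLOOR), 1 - 1e-16)
    list(beta = beta, info = info,
         loglik = sum(yk * log(p) + (nk - yk) * log(1 - p)),
         iterations = it)
  }
  fit <- newton(Xk)
  if (is.null(fit))
    stop("logistic information matrix is singular")
  nul <- newton(Xk[, 1L, drop = FALSE])

  V <- tryCatch(solve(fit$info), error = function(e) NULL)
  se <- if (is.null(V)) rep(NA_real_, ncol(Xk)) else sqrt(diag(V))
  idx <- seq_len(ncol(Xk))[-1L]
  estimates <- data.frame(
    parameter = colnames(Xk)[idx],
    estimate = exp(fit$beta[idx]),
    se = exp(fit$beta[idx]) * se[idx],
    log_estimate = fit$beta[idx],
    se_log = se[idx],
    stringsAsFactors = FALSE)
  spec <- structure(list(free = colnames(Xk)[idx],
                         regime = "logistic", a2 = NULL, fixed = list(),
                         dialect = "default"),
                    class = "model_spec")
  structure(list(estimates = estimates, max_loglik = fit$loglik,
                 null_loglik = nul$loglik, nuisance = NULL,
                 converged = TRUE, identifiable = !is.null(V),
                 condition_number = NA_real_,
                 iterations = fit$iterations, spec = spec,
                 n_free = c(risk = length(idx), nuisance = 0L),
                 weight_maternal = weight_maternal),
            class = "fit_result")
}
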