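## Replicated simulation harness: bias, standard-error and power/type-I
## summaries for any scenario x method combination, and a
## model-misspecification study with a deterministic expected-value
## reference.

## control structure required by each method preset
method_control_structure <- function(method_id) {
  switch(as.character(method_id),
    "0" = "control_mother_duo",
    "3" = "control",
    "4" = , "5" = , "6" = "parents_of_control",
    "7" = , "8" = , "9" = "control_mother_duo",
    NULL)
}

simulate_method_data <- function(scen, method_id, case_structure, n, seed) {
  case <- simulate_structure(case_structure, scen, n, seed = seed)
  ctl_kind <- method_control_structure(method_id)
  ctl <- if (!is.null(ctl_kind))
    list(simulate_structure(ctl_kind, scen, n, seed = seed + 500000L))
  else NULL
  list(case = list(case), control = ctl)
}

#' Replicated simulation study of one analysis method
#'
#' Simulates `n_reps` replicates of a scenario, fits the requested model
#' with one of the method presets per replicate, and summarises parameter
#' estimation (mean and SD of the log estimates, mean estimated standard
#' error), the total estimated standard error, and the rejection
#' proportions of likelihood-ratio tests at the 0.05, 0.01 and 0.001
#' levels with binomial Monte-Carlo standard errors.  Replicates whose
#' fit fails to converge or is flagged non-identifiable are reported,
#' not dropped.
#'
#' @param scen a [scenario()] object.
#' @param method_id method preset (see [fit_method()]).
#' @param n_per_structure units simulated per data structure.
#' @param n_reps number of replicates (at least 2).
#' @param free free risk parameters of the full model.
#' @param tests list of tests; each element is a list with elements
#'   `full` and `null`, character vectors of free risk parameters (the
#'   null must be a subset of the full).  Defaults to the joint test of
#'   `free` against the global null.
#' @param base_seed integer; replicate `r` uses seed `base_seed + r`.
#' @param case_structure `"case_mother_duo"` or `"case_parent_trio"`.
#' @param a2 fixed allele frequency (method 1 only).
#' @return List of class `study_summary` with elements `params` (per
#'   parameter summary), `tests` (per test rejection proportions),
#'   `total_se` (mean/median of the per-replicate sum of standard
#'   errors), `n_reps`, `n_failed`.
#' @export
run_study <- function(scen, method_id, n_per_structure = 500,
                      n_reps = 100, free = c("r1", "r2", "s1", "s2"),
                      tests = NULL, base_seed = 1,
                      case_structure = c("case_mother_duo",
                                         "case_parent_trio"),
                      a2 = NULL) {
  case_structure <- match.arg(case_structure)
  if (n_reps < 2L) stop("n_reps must be at least 2")
  if (is.null(tests))
    tests <- list(list(full = free, null = character(0)))
  for (tst in tests)
    if (!all(tst$null %in% tst$full))
      stop("test null parameters must be a subset of the full parameters")

  fit_one <- function(fr, dat) {
    if (as.character(method_id) == "0")
      fit_method("0", dat$case, dat$control, free = fr)
    else fit_method(method_id, dat$case, dat$control, free = fr, a2 = a2,
                    compute_null = FALSE)
  }

  log_est <- matrix(NA_real_, n_reps, length(free),
                    dimnames = list(NULL, free))
  se_log <- matrix(NA_real_, n_reps, length(free),
                   dimnames = list(NULL, free))
  pvals <- matrix(NA_real_, n_reps, length(tests))
  flagged <- logical(n_reps)
  failed <- logical(n_reps)

  for (r in seq_len(n_reps)) {
    dat <- simulate_method_data(scen, method_id, case_structure,
                                n_per_structure, base_seed + r)
    rep_fits <- new.env(parent = emptyenv())
    get_fit <- function(fr) {
      key <- paste0("k_", paste(sort(fr), collapse = ","))
      if (is.null(rep_fits[[key]]))
        rep_fits[[key]] <- tryCatch(fit_one(fr, dat),
                                    error = function(e) NULL)
      rep_fits[[key]]
    }
    f <- get_fit(free)
    if (is.null(f)) { failed[r] <- TRUE; next }
    flagged[r] <- !f$converged || !f$identifiable
    idx <- match(f$estimates$parameter, free)
    log_est[r, idx] <- f$estimates$log_estimate
    se_log[r, idx] <- f$estimates$se_log
    for (ti in seq_along(tests)) {
      ffull <- get_fit(tests[[ti]]$full)
      fnull <- get_fit(tests[[ti]]$null)
      if (!is.null(ffull) && !is.null(fnull))
        pvals[r, ti] <- likelihood_ratio_test(ffull, fnull)$p_value
    }
  }

  params <- data.frame(
    parameter = free,
    true_log = log(unclass(scen$params)[free]),
    mean_log_estimate = colMeans(log_est, na.rm = TRUE),
    sd_log_estimate = apply(log_est, 2, stats::sd, na.rm = TRUE),
    mc_se = apply(log_est, 2, stats::sd, na.rm = TRUE) /
      sqrt(colSums(!is.na(log_est))),
    mean_se = colMeans(se_log, na.rm = TRUE),
    stringsAsFactors = FALSE)
  lv <- c(0.05, 0.01, 0.001)
  tests_df <- do.call(rbind, lapply(seq_along(tests), function(ti) {
    p <- pvals[, ti]
    ok <- sum(!is.na(p))
    rej <- vapply(lv, function(a) mean(p < a, na.rm = TRUE), 0)
    data.frame(
      test = paste(paste(tests[[ti]]$full, collapse = "+"), "vs",
                   if (length(tests[[ti]]$null))
                     paste(tests[[ti]]$null, collapse = "+") else "null"),
      df = length(tests[[ti]]$full) - length(tests[[ti]]$null),
      level = lv, rejection = rej,
      mc_se = sqrt(rej * (1 - rej) / max(ok, 1)),
      n_eval = ok, stringsAsFactors = FALSE)
  }))
  tot <- rowSums(se_log)
  structure(list(params = params, tests = tests_df,
                 total_se = data.frame(mean = mean(tot, na.rm = TRUE),
                                       median = stats::median(tot,
                                                              na.rm = TRUE),
                                       n = sum(!is.na(tot))),
                 n_reps = n_reps, n_failed = sum(failed),
                 n_flagged = sum(flagged),
                 method = as.character(method_id),
                 scenario = scen$name),
            class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf("Simulation study: scenario %s, method %s, %d replicates (%d failed, %d flagged)\n",
              x$scenario, x$method, x$n_reps, x$n_failed, x$n_flagged))
  cat("\nParameter estimation (log scale):\n")
  print(transform(x$params,
                  mean_log_estimate = round(mean_log_estimate, 4),
                  sd_log_estimate = round(sd_log_estimate, 4),
                  mc_se = round(mc_se, 4),
                  mean_se = round(mean_se, 4),
                  true_log = round(true_log, 4)), row.names = FALSE)
  cat("\nLikelihood-ratio tests:\n")
  print(transform(x$tests, rejection = round(rejection, 4),
                  mc_se = round(mc_se, 4)), row.names = FALSE)
  cat(sprintf("\nTotal estimated SE: mean %.4f, median %.4f\n",
              x$total_se$mean, x$total_se$median))
  invisible(x)
}

#' Model-misspecification study
#'
#' Generates data under one scenario but analyses them under a
#' (possibly non-nested) different parameter set, summarising the
#' apparent estimates.  Alongside the Monte-Carlo summary it reports a
#' deterministic reference: the analysis model fitted to the exact
#' expected cell counts (scenario cell probabilities times the sample
#' size), which is the expected large-sample value of the misspecified
#' estimates.
#'
#' @inheritParams run_study
#' @param analysis_free free risk parameters of the analysis model.
#' @return List of class `misspec_summary` with elements `params`
#'   (Monte-Carlo summary including the `pseudo_log` reference column),
#'   `n_reps`, `n_failed`.
#' @export
misspecification_study <- function(scen, analysis_free, method_id,
                                   n_per_structure = 500, n_reps = 100,
                                   base_seed = 1,
                                   case_structure = c("case_mother_duo",
                                                      "case_parent_trio"),
                                   a2 = NULL) {
  case_structure <- match.arg(case_structure)
  st <- run_study(scen, method_id, n_per_structure, n_reps,
                  free = analysis_free, base_seed = base_seed,
                  case_structure = case_structure, a2 = a2)

  ## expected-cell-probability pseudo-fit (deterministic reference)
  nu <- nuisance_model("hwe_rm_fixed_af", a2 = scen$a2)
  exp_case <- structure_counts(
    case_structure,
    n_per_structure * cell_table(case_structure, scen$params, nu)$cells$probability)
  ctl_kind <- method_control_structure(method_id)
  datasets <- list(exp_case)
  ctl <- NULL
  if (!is.null(ctl_kind)) {
    ctl <- structure_counts(
      ctl_kind,
      n_per_structure * cell_table(ctl_kind, scen$params, nu)$cells$probability)
    datasets <- c(datasets, list(ctl))
  }
  pseudo <- if (as.character(method_id) == "0")
    logistic_duo_comparator(exp_case, ctl, free = analysis_free)
  else fit_method(method_id, list(exp_case),
                  if (is.null(ctl)) NULL else list(ctl),
                  free = analysis_free, a2 = a2, compute_null = FALSE)
  params <- st$params
  params$true_log <- NULL  # the generating model is not the analysis model
  params$pseudo_log <- pseudo$estimates$log_estimate[
    match(params$parameter, pseudo$estimates$parameter)]
  structure(list(params = params, n_reps = n_reps,
                 n_failed = st$n_failed, method = as.character(method_id),
                 scenario = scen$name),
            class = "misspec_summary")
}

#' @export
print.misspec_summary <- function(x, ...) {
  cat(sprintf(
    "Misspecification study: generated under %s, analysed with method %s (%d replicates)\n",
    x$scenario, x$method, x$n_reps))
  print(transform(x$params,
                  mean_log_estimate = round(mean_log_estimate, 4),
                  sd_log_estimate = round(sd_log_estimate, 4),
                  mc_se = round(mc_se, 4),
                  mean_se = round(mean_se, 4),
                  pseudo_log = round(pseudo_log, 4)), row.names = FALSE)
  invisible(x)
}
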