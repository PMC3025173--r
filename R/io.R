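## Count-table interchange format, pedigree tabulation, and results
## output.  The canonical interchange is a TSV with columns
## snp_id / structure / cell / count, using the frozen cell labels.

#' Read and write genotype-combination count tables
#'
#' The canonical interchange format is a tab-separated file with header
#' `snp_id  structure  cell  count`; `structure` is any of
#' [structure_kinds()] and `cell` must use that structure's frozen
#' labels (see [cell_labels()]).  Cells may appear in any order within a
#' (snp, structure) block; cells absent from a block are taken as zero.
#' `write_counts()` followed by `read_counts()` round-trips exactly.
#'
#' @param path file path.
#' @return `read_counts()`: a list of [structure_counts()] objects, one
#'   per (snp, structure) block, in order of first appearance;
#'   `write_counts()`: `path`, invisibly.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty counts file: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, c("snp_id", "structure", "cell", "count")))
    stop("line 1: expected header 'snp_id\\tstructure\\tcell\\tcount'")
  body <- lines[-1L]
  body_no <- which(nzchar(trimws(body))) # keep line numbers for messages
  recs <- list()
  seen <- character(0)
  for (i in body_no) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    lineno <- i + 1L
    if (length(f) != 4L)
      stop(sprintf("line %d: expected 4 tab-separated fields", lineno))
    if (!f[2L] %in% STRUCTURE_KINDS)
      stop(sprintf("line %d: unknown structure '%s'", lineno, f[2L]))
    labs <- cell_labels(f[2L])
    if (!f[3L] %in% labs)
      stop(sprintf("line %d: unknown cell label '%s' for structure '%s'",
                   lineno, f[3L], f[2L]))
    cnt <- suppressWarnings(as.numeric(f[4L]))
    if (is.na(cnt) || cnt < 0)
      stop(sprintf("line %d: count must be a nonnegative number", lineno))
    key <- paste(f[1L], f[2L], sep = "\r")
    dupkey <- paste(key, f[3L], sep = "\r")
    if (dupkey %in% seen)
      stop(sprintf("line %d: duplicate cell '%s' for snp '%s', structure '%s'",
                   lineno, f[3L], f[1L], f[2L]))
    seen <- c(seen, dupkey)
    if (is.null(recs[[key]]))
      recs[[key]] <- stats::setNames(numeric(length(labs)), labs)
    recs[[key]][f[3L]] <- cnt
  }
  lapply(names(recs), function(key) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    structure_counts(parts[2L], recs[[key]], snp_id = parts[1L])
  })
}

#' @param data a [structure_counts()] object or list of them.
#' @rdname read_counts
#' @export
write_counts <- function(data, path) {
  if (inherits(data, "structure_counts")) data <- list(data)
  rows <- lapply(data, function(d) {
    stopifnot(inherits(d, "structure_counts"))
    data.frame(snp_id = d$snp_id, structure = d$structure_kind,
               cell = names(d$counts),
               count = format(unname(d$counts), scientific = FALSE,
                              trim = TRUE),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## --- pedigree ingestion ------------------------------------------------

## copies of allele 2 from two allele codes; NA when untyped
geno_copies <- function(a1, a2) {
  ifelse(a1 == "0" | a2 == "0", NA_integer_,
         (a1 == "2") + (a2 == "2"))
}

## is child genotype jc Mendelian-consistent with parental genotypes?
## NA parents are unconstrained
mendel_ok <- function(gm, gf, jc) {
  if (is.na(jc)) return(TRUE)
  mat_poss <- if (is.na(gm)) 0:1 else unique(c(gm > 0, gm == 2) * 1L)
  pat_poss <- if (is.na(gf)) 0:1 else unique(c(gf > 0, gf == 2) * 1L)
  any(outer(mat_poss, pat_poss, `+`) == jc)
}

mating_label <- function(gm, gf) {
  hi <- max(gm, gf); lo <- min(gm, gf)
  paste0(GENO_STR[hi + 1L], "x", GENO_STR[lo + 1L])
}

#' Tabulate a PED/MAP pedigree file into structure counts
#'
#' Reads a whitespace-separated pedigree file (family id, individual id,
#' father id, mother id, sex, phenotype, then two allele columns per
#' variant in the accompanying MAP file; allele code 0 = missing,
#' phenotype 2 = affected, 1/0/-9 = control or unknown, treated as
#' population controls) and assigns each nuclear family to the data
#' structure determined by which members are genotyped and the
#' offspring's phenotype.  Families with several offspring contribute
#' only their first offspring (with a warning); Mendelian-inconsistent
#' families are excluded with a warning.
#'
#' @param ped_path,map_path file paths.
#' @param snp_id variant to tabulate (must appear in the MAP file).
#' @return A list of [structure_counts()] objects (one per structure
#'   kind observed).
#' @export
tabulate_pedigree <- function(ped_path, map_path, snp_id) {
  map <- utils::read.table(map_path, header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(map) < 2L) stop("malformed MAP file: fewer than 2 columns")
  snp_idx <- match(snp_id, map[[2L]])
  if (is.na(snp_idx)) stop("snp '", snp_id, "' not found in MAP file")
  ped <- utils::read.table(ped_path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  need <- 6L + 2L * nrow(map)
  if (ncol(ped) != need)
    stop(sprintf("malformed PED file: expected %d columns (6 + 2 per MAP snp), found %d",
                 need, ncol(ped)))
  a_col <- 6L + 2L * snp_idx - 1L
  ped$g <- geno_copies(ped[[a_col]], ped[[a_col + 1L]])

  tallies <- list()
  add <- function(kind, label) {
    if (is.null(tallies[[kind]]))
      tallies[[kind]] <<- stats::setNames(numeric(length(cell_labels(kind))),
                                          cell_labels(kind))
    tallies[[kind]][label] <<- tallies[[kind]][label] + 1
  }

  for (fid in unique(ped[[1L]])) {
    fam <- ped[ped[[1L]] == fid, ]
    offs <- fam[fam[[3L]] != "0" | fam[[4L]] != "0", ]
    if (nrow(offs) == 0L) next
    if (nrow(offs) > 1L)
      warning("family ", fid, ": multiple offspring; using the first")
    off <- offs[1L, ]
    mo <- fam[fam[[2L]] == off[[4L]], ]
    fa <- fam[fam[[2L]] == off[[3L]], ]
    gm <- if (nrow(mo)) mo$g[1L] else NA_integer_
    gf <- if (nrow(fa)) fa$g[1L] else NA_integer_
    gc <- off$g[1L]
    affected <- off[[6L]] == "2"
    if (!mendel_ok(gm, gf, gc)) {
      warning("family ", fid, ": Mendelian inconsistency; excluded")
      next
    }
    has <- c(child = !is.na(gc), mother = !is.na(gm), father = !is.na(gf))
    kind <- if (affected) {
      if (all(has)) "case_parent_trio"
      else if (has["child"] && has["mother"]) "case_mother_duo"
      else if (has["child"] && has["father"]) "case_father_duo"
      else if (has["child"]) "case_only"
      else if (has["mother"] && has["father"]) "parents_of_case"
      else if (has["mother"]) "mother_of_case"
      else if (has["father"]) "father_of_case"
      else NA_character_
    } else {
      if (has["child"] && has["mother"]) "control_mother_duo"
      else if (has["child"] && has["father"]) "control_father_duo"
      else if (has["child"]) "control"
      else if (has["mother"] && has["father"]) "parents_of_control"
      else NA_character_
    }
    if (is.na(kind)) next
    label <- switch(kind,
      case_parent_trio = paste(GENO_STR[gm + 1L], GENO_STR[gf + 1L],
                               GENO_STR[gc + 1L], sep = "-"),
      case_mother_duo = , control_mother_duo =
        paste(GENO_STR[gm + 1L], GENO_STR[gc + 1L], sep = "-"),
      case_father_duo = , control_father_duo =
        paste(GENO_STR[gf + 1L], GENO_STR[gc + 1L], sep = "-"),
      case_only = , control = GENO_STR[gc + 1L],
      mother_of_case = GENO_STR[gm + 1L],
      father_of_case = GENO_STR[gf + 1L],
      parents_of_case = , parents_of_control = mating_label(gm, gf))
    if (!label %in% cell_labels(kind)) {
      warning("family ", fid, ": Mendelian inconsistency; excluded")
      next
    }
    add(kind, label)
  }
  lapply(names(tallies), function(kind)
    structure_counts(kind, tallies[[kind]], snp_id = snp_id))
}

#' Serialise fit results as a flat TSV
#'
#' One row per parameter, with columns `snp_id`, `model_name`,
#' `parameter`, `estimate`, `se`, `loglik_null`, `loglik_max`, `lrt`,
#' `df`, `p`, `flags`.
#'
#' @param fit a `fit_result`.
#' @param path output file.
#' @param snp_id,model_name identifiers written on every row.
#' @return `path`, invisibly.
#' @export
write_fit_results <- function(fit, path, snp_id = "snp1",
                              model_name = "model") {
  stopifnot(inherits(fit, "fit_result"))
  df <- fit$n_free[["risk"]]
  lrt <- if (is.na(fit$null_loglik)) NA_real_
  else max(0, 2 * (fit$max_loglik - fit$null_loglik))
  p <- if (is.na(lrt) || df == 0L) NA_real_
  else stats::pchisq(lrt, df, lower.tail = FALSE)
  flags <- paste(c(if (!fit$converged) "nonconverged",
                   if (!fit$identifiable) "nonidentifiable"),
                 collapse = ";")
  if (!nzchar(flags)) flags <- "ok"
  est <- fit$estimates
  if (!nrow(est))
    est <- data.frame(parameter = "(none)", estimate = NA_real_,
                      se = NA_real_)
  out <- data.frame(snp_id = snp_id, model_name = model_name,
                    parameter = est$parameter,
                    estimate = est$estimate, se = est$se,
                    loglik_null = fit$null_loglik,
                    loglik_max = fit$max_loglik,
                    lrt = lrt, df = df, p = p, flags = flags,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
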