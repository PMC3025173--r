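## Independent brute-force enumeration oracle.  Deliberately written from
## first principles (explicit loops over parental genotypes and Mendelian
## transmissions), sharing no code with the package internals, so that it
## can serve as an external check on the cell-table algebra.

## risk multiplier for (mother copies i, maternal-origin allele m,
## paternal-origin allele p), given a plain named list of factors
oracle_risk <- function(v, i, m, p) {
  j <- m + p
  r <- 1
  if (j == 1) r <- r * v$r1 else if (j == 2) r <- r * v$r2
  if (i == 1) r <- r * v$s1 else if (i == 2) r <- r * v$s2
  if (m == 1) r <- r * v$im
  if (p == 1) r <- r * v$ip
  gam <- rbind(c(1, 1, 1), c(1, v$g11, v$g12), c(1, v$g21, v$g22))
  r * gam[i + 1, j + 1]
}

## enumerate the joint population distribution of
## (gm, gf, maternal allele, paternal allele) under HWE + random mating
oracle_enum <- function(params, a2) {
  v <- as.list(unclass(params))
  q <- 1 - a2
  gfreq <- c(q^2, 2 * a2 * q, a2^2)  # genotypes with 0, 1, 2 copies
  out <- NULL
  for (gm in 0:2) for (gf in 0:2) for (m in 0:1) for (p in 0:1) {
    pm <- if (gm == 0) c(1, 0) else if (gm == 1) c(0.5, 0.5) else c(0, 1)
    pp <- if (gf == 0) c(1, 0) else if (gf == 1) c(0.5, 0.5) else c(0, 1)
    prob <- gfreq[gm + 1] * gfreq[gf + 1] * pm[m + 1] * pp[p + 1]
    if (prob == 0) next
    out <- rbind(out, data.frame(gm = gm, gf = gf, m = m, p = p,
                                 prob = prob,
                                 risk = oracle_risk(v, gm, m, p)))
  }
  out
}

GSTR <- c("11", "12", "22")

## 15-cell trio probabilities in the frozen ordering, by enumeration
oracle_trio_probs <- function(params, a2) {
  e <- oracle_enum(params, a2)
  e$w <- e$prob * e$risk
  lab <- paste(GSTR[e$gm + 1], GSTR[e$gf + 1], GSTR[e$m + e$p + 1],
               sep = "-")
  w <- tapply(e$w, lab, sum)
  w <- w[cell_labels("case_parent_trio")]
  as.vector(w / sum(w))
}

oracle_duo_probs <- function(params, a2) {
  e <- oracle_enum(params, a2)
  e$w <- e$prob * e$risk
  lab <- paste(GSTR[e$gm + 1], GSTR[e$m + e$p + 1], sep = "-")
  w <- tapply(e$w, lab, sum)
  w <- w[cell_labels("case_mother_duo")]
  as.vector(w / sum(w))
}

## P(disease | margin genotype) by enumeration; margin "child" or "mother"
oracle_risk_by_genotype <- function(params, a2, margin = "child") {
  e <- oracle_enum(params, a2)
  g <- if (margin == "child") e$m + e$p else e$gm
  as.vector(tapply(e$prob * e$risk, g, sum) / tapply(e$prob, g, sum))
}

## random positive risk-parameter draws around the null
rand_rp <- function(sd = 0.4) {
  v <- exp(stats::rnorm(10, 0, sd))
  names(v) <- c("r1", "r2", "s1", "s2", "im", "ip", "g11", "g12", "g21",
                "g22")
  do.call(risk_parameters, as.list(v))
}

rand_mu <- function() exp(stats::rnorm(6, 0, 1))
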