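## Shared constants used across modules (loaded first by collation order).

## Names of the free relative-risk factors (alpha excluded).
RISK_FACTOR_NAMES <- c("r1", "r2", "s1", "s2", "im", "ip",
                       "g11", "g12", "g21", "g22")

## Mendelian-compatible (g_m, ordered g_c) combinations.  Ordered child
## genotypes are written maternal-then-paternal: "21" means the maternal
## allele is 2 and the paternal allele is 1.
ORDERED_COMBOS <- data.frame(
  gm = c("11", "11", "12", "12", "12", "12", "22", "22"),
  gc = c("11", "12", "11", "12", "21", "22", "21", "22"),
  stringsAsFactors = FALSE
)

## Keys for the 8 ordered-origin cells, "gm.gc" with gc maternal-paternal.
ORDERED_KEYS <- paste(ORDERED_COMBOS$gm, ORDERED_COMBOS$gc, sep = ".")
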