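# Round to the nearest integer, ties away from zero ("half-up" for the
# positive quantities used here).  base::round() rounds half to even, which
# does not match how the published 1-in-N figures were derived
# (e.g. 10000.5 -> 10001, 1250.5 -> 1251).
round_half_up <- function(x) floor(x + 0.5)

# Truncate a percentage at `digits` decimal places (no rounding).  Computed on
# an integer grid to keep values like 0.148 exactly reproducible.
truncate_percent <- function(pct, digits = 3L) {
  floor(pct * 10^digits) / 10^digits
}

variant_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

`%||%` <- rlang::`%||%`
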