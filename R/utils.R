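# Small shared helpers.

# Derive a reproducible sub-seed from a master seed. Each generator
# component (panel, dosages, covariates, noise, eyes) draws from its own
# substream so e.g. adding subjects never perturbs the panel. Kept below
# 2^31 - 1 (R seeds are 32-bit integers); arithmetic stays exact in doubles.
derive_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647)
  as.integer((s * 69069 + as.double(k) * 10007) %% 2147483647)
}

# format a double so that read-back reproduces it bit-exactly
format_exact <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}
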