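#' @importFrom stats coef cor integrate kruskal.test p.adjust pf pt ptukey
#' @importFrom stats aov rnbinom rnorm runif sd setNames TukeyHSD var ks.test
#' @importFrom utils read.csv read.delim write.csv packageVersion
NULL

# run `code` under a fixed RNG seed, restoring global RNG state afterwards
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# derive a reproducible per-stage sub-seed from one global seed; kept below
# .Machine$integer.max so it is always a valid 32-bit seed
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset * 7919) %% 2147483647L)
}

stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}
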