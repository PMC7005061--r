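# Internal helpers shared across modules.

# Canonical vertical compartments, stump to small branches.
COMPARTMENTS <- c("Stu", "Ste_b", "Ste", "LB", "MB", "SB")

GUILDS <- c("P", "NPLD", "ST")

#' @noRd
stop_if_not <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(..., call. = call.)
}

# Derive a reproducible sub-seed (< 2^31) from a base seed and a label.
# Keeps independent RNG substreams per stage / per tree without consuming
# the global stream.
derive_seed <- function(seed, ...) {
  lab <- paste(c(seed, ...), collapse = "/")
  h <- utils::head(strtoi(charToRaw(digest_label(lab)), 16L), 6L)
  as.integer(sum(h * c(1L, 7L, 31L, 127L, 511L, 2047L)) %% 2147483587L)
}

# Cheap deterministic label hash (hex of a simple polynomial rolling hash).
digest_label <- function(x) {
  bytes <- as.integer(charToRaw(x))
  acc <- 5381
  for (b in bytes) acc <- (acc * 33 + b) %% 2147483647
  format(as.hexmode(as.integer(acc)), width = 8)
}

# Dirichlet draw via independent gammas.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1
  g / sum(g)
}

# Significance codes used for correlation / test tables.
signif_code <- function(p) {
  ifelse(is.na(p), "na",
         ifelse(p <= 0.001, "***",
                ifelse(p <= 0.01, "**",
                       ifelse(p <= 0.05, "*", "ns"))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
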