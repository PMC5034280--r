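# Internal helpers. All genomic coordinates in this package are 0-based,
# half-open (BED convention): a 147 bp footprint starting at s is [s, s+147)
# and its dyad is s + 73. Track vectors map index i to coordinate i - 1.

HALF_CORE <- 73L   # dyad offset within a 147 bp core: [dyad-73, dyad+74)
CORE_BP   <- 147L

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
footprint_of <- function(dyad) {
  cbind(start = dyad - HALF_CORE, end = dyad + HALF_CORE + 1L)
}

# Deterministic sub-seed derivation: keeps every derived seed in [0, 2^31).
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# condition label -> safe file fragment ("Gln-Pro" -> "Gln-Pro" is fine for
# filenames; only path separators are replaced)
cond_slug <- function(x) gsub("[/\\\\]", "_", x)

msg <- function(verbose, ...) if (isTRUE(verbose)) message(sprintf(...))
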