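## Internal helpers shared across modules.

## Canonical species key: trimmed, case-folded binomial. No synonym resolution.
speciesKey <- function(x) tolower(trimws(as.character(x)))

## Draw a deterministic child seed from a base seed and a label, keeping the
## result inside the 32-bit integer range.
deriveSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

## Evaluate code under a temporary RNG state seeded with `seed`, restoring the
## caller's RNG afterwards so library code does not disturb user randomness.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

## stopifnot with a formatted message
assertThat <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

clip01 <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }

## Sample SD that is 0 (not NA) for a single observation.
sampleSD <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
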