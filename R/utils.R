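## Small internal helpers shared across modules.

## Evaluate `code` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG state afterwards.  `code` is a promise and is
## evaluated in the caller's frame.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

## Deterministic 31-bit hash of a character string (polynomial rolling hash);
## used to derive independent per-cell seeds that do not depend on row or
## loop order.
str_hash <- function(s) {
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

## Combine a base seed with cell identifiers into one seed below 2^31.
cell_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (s in list(...)) h <- (h * 131 + str_hash(as.character(s))) %% 2147483647
  as.integer(h)
}

fmt_num <- function(x, digits = 5) formatC(x, format = "f", digits = digits)
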