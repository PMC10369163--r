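#' @keywords internal
"_PACKAGE"

## Classed error helper so callers can distinguish failure modes.
lcs_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "lcsmediate_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
## seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

## Derive a sub-stream seed from a trial-level seed by a fixed offset.
## Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, offset) {
  as.integer(((as.double(seed) %% 65011) * 31859 + as.double(offset) * 7919) %%
               2147483629) + 1L
}

## Largest-remainder apportionment of an integer total across weights.
## Ties on the fractional part go to the earliest index, so the split is
## deterministic. Returns integer counts summing exactly to `total`.
largest_remainder <- function(total, weights) {
  if (total < 0) lcs_stop("total must be non-negative", "lcs_config_error")
  if (any(weights < 0) || sum(weights) <= 0)
    lcs_stop("weights must be non-negative with positive sum", "lcs_config_error")
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  short <- as.integer(round(total - sum(base)))
  out <- base
  if (short > 0) {
    frac <- quota - base
    give <- order(-frac, seq_along(frac))[seq_len(short)]
    out[give] <- out[give] + 1
  }
  as.integer(out)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
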