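# internal helpers shared across modules

# Deterministic 32-bit sub-seed derived from a master seed and indices, so
# per-unit / per-trial streams do not depend on how much randomness earlier
# units consumed.
derive_seed <- function(master, index, salt = 0L) {
  v <- (as.double(master) %% 2147483647) * 48271 +
    as.double(index) * 7919 + as.double(salt) * 104729
  as.integer(v %% 2147483629) + 1L
}

# Run code under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# cosine distance 1 - u.v/(|u||v|), in [0, 2]; zero vectors give NA
cosine_distance <- function(u, v) {
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  1 - sum(u * v) / (nu * nv)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# classed condition so callers (and the CLI) can tell validation errors
# from computation errors
stop_contract <- function(...) {
  stop(structure(class = c("rgcclust_contract_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

# numbers written to CSV must round-trip at double precision
format_double <- function(x) sprintf("%.17g", x)
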