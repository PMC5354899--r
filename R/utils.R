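# Small shared helpers (internal).

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# The caller's .Random.seed is restored on exit, so seeded package
# functions never disturb the user's random stream.
with_rng_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Column products of a numeric matrix; entries assumed non-negative.
colprods <- function(x) {
  if (nrow(x) == 1L) {
    x[1L, ]
  } else {
    apply(x, 2L, prod)
  }
}

# round-half-up, unlike base round()'s round-half-to-even
round_half_up <- function(x) floor(x + 0.5)

# Stable MD5 of an R object via its deparsed source form.
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(deparse(x, control = c("keepNA", "keepInteger", "showAttributes")),
             tmp)
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
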