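#' @keywords internal
"_PACKAGE"

## Run `expr` under a fixed RNG seed without disturbing the caller's RNG
## stream. All stochastic entry points funnel through this, which is what
## makes outputs a pure function of (inputs, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single non-missing number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

check_fraction <- function(x, name, lo = 0, hi = 1,
                           lo_open = FALSE, hi_open = FALSE) {
  bad <- !is.numeric(x) | is.na(x) |
    (if (lo_open) x <= lo else x < lo) |
    (if (hi_open) x >= hi else x > hi)
  if (any(bad)) {
    stop(sprintf("'%s' must lie in %s%g, %g%s", name,
                 if (lo_open) "(" else "[", lo, hi,
                 if (hi_open) ")" else "]"), call. = FALSE)
  }
  invisible(x)
}

check_p <- function(p, name = "p") {
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stop(sprintf("'%s' must be a p-value in (0, 1]", name), call. = FALSE)
  }
  invisible(p)
}

## sign() that returns integer, used for effect-direction products
sign_int <- function(x) as.integer(sign(x))

## log(sum(exp(lx))) without overflow, for tail-mass accumulation
logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

## 32-bit FNV-1a over a character scalar; used to stamp run manifests.
## Arithmetic stays on doubles split into 16-bit halves: h can reach 2^32-1,
## which overflows both R's integer type and exact double multiplication.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    lo <- bitwXor(as.integer(h %% 65536), b)
    hi <- h %/% 65536
    h <- ((hi * m) %% 65536) * 65536 + lo * m
    h <- h %% 4294967296
  }
  sprintf("%08x", h)
}
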