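#' @keywords internal
"_PACKAGE"

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# stable log(exp(a) - exp(b)) for a >= b; round-off below b is clamped to -Inf
logdiffexp <- function(a, b) {
  if (b == -Inf) return(a)
  d <- b - a
  if (d >= 0) return(-Inf)   # clamp negative round-off mass
  a + log1p(-exp(d))
}

# evaluate expr under a local RNG state: the global .Random.seed is restored
# afterwards, so generators never leak state into each other
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# DNA complement for strand-flip resolution; non-ACGT strings returned as-is
complement_allele <- function(a) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- comp[a]
  out[is.na(out)] <- a[is.na(out)]
  unname(out)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}
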