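# internal helpers

# run expr with a local RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# round half away from zero (deterministic composition counts)
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# largest-remainder apportionment of n into shares proportional to w
largestRemainder <- function(n, w) {
  q <- n * w / sum(w)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(q - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# most frequent value among the 8 corners of a volume (background estimate)
cornerBackground <- function(vol) {
  d <- dim(vol)
  ix <- c(1L, d[1]); iy <- c(1L, d[2]); iz <- c(1L, d[3])
  v <- as.vector(vol[ix, iy, iz])
  tb <- table(v)
  as.numeric(names(tb)[which.max(tb)])
}

stopifnotShape <- function(a, b, what = "inputs") {
  if (!identical(dim(a)[1:3], dim(b)[1:3]))
    stop(what, " must share the same grid: ",
         paste(dim(a)[1:3], collapse = "x"), " vs ",
         paste(dim(b)[1:3], collapse = "x"))
  invisible(TRUE)
}

# elementwise map over two parallel nested lists of numeric arrays
treeMap2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(treeMap2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else f(a, b)
}

treeMap <- function(a, f) {
  if (is.list(a)) {
    out <- lapply(a, treeMap, f = f)
    names(out) <- names(a)
    out
  } else f(a)
}
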