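## shared small fixtures, generated in code; cached per test run
.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, force(expr), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

smallGrid <- function(n = 6L, cell = 0.25) {
  savGrid(latRange = c(-12, -12 + n * cell),
          lonRange = c(22, 22 + n * cell), cellSize = cell)
}

## 36-pixel, 24-year default-condition simulation shared across test files
smallSim <- function() cached("smallSim", {
  simulateSavanna(smallGrid(6L), seed = 4242L, years = 1990:2013)
})

smallClim <- function() cached("smallClim", computeClimatology(smallSim()$rain))
smallVeg <- function() cached("smallVeg",
  computeVegetation(smallSim()$lai, smallSim()$vod))

## independent brute-force oracles (deliberately naive double loops)
bruteTheilSen <- function(t, y) {
  sl <- c()
  n <- length(y)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (t[j] != t[i]) sl <- c(sl, (y[j] - y[i]) / (t[j] - t[i]))
  sl <- sort(sl)
  m <- length(sl)
  if (m %% 2 == 1) sl[(m + 1) / 2] else (sl[m / 2] + sl[m / 2 + 1]) / 2
}

bruteMkS <- function(y) {
  s <- 0L
  n <- length(y)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    s <- s + sign(y[j] - y[i])
  s
}

## factorial-enumeration LMG oracle: average sequential R^2 gains over all
## orderings, each subset R^2 obtained from lm()
bruteLmg <- function(X, y) {
  p <- ncol(X)
  subs <- lapply(0:(2^p - 1), function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
  r2 <- vapply(subs, function(S) {
    if (!length(S)) return(0)
    summary(lm(y ~ X[, S, drop = FALSE]))$r.squared
  }, numeric(1))
  key <- vapply(subs, function(S) sum(2^(S - 1)), numeric(1))
  r2of <- function(S) r2[match(sum(2^(S - 1)), key)]
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  contrib <- numeric(p)
  pp <- perms(seq_len(p))
  for (ord in pp) {
    prev <- integer(0)
    for (k in ord) {
      contrib[k] <- contrib[k] + r2of(sort(c(prev, k))) -
        (if (length(prev)) r2of(sort(prev)) else 0)
      prev <- c(prev, k)
    }
  }
  raw <- contrib / length(pp)
  100 * raw / r2of(seq_len(p))
}
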