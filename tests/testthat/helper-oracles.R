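# Independent loop-based oracles for every disparity quantity, coded as
# plain element-by-element summations so they share no code path with the
# package's vectorized implementations.

o_weighted_mean <- function(le, pop) {
  num <- 0
  den <- 0
  for (i in seq_along(le)) {
    num <- num + pop[i] * le[i]
    den <- den + pop[i]
  }
  num / den
}

o_led <- function(le) {
  best <- le[1]; worst <- le[1]
  for (x in le) {
    if (x > best) best <- x
    if (x < worst) worst <- x
  }
  best - worst
}

o_ler <- function(le) {
  best <- le[1]; worst <- le[1]
  for (x in le) {
    if (x > best) best <- x
    if (x < worst) worst <- x
  }
  best / worst
}

o_md <- function(le, exclude_reference = FALSE) {
  best <- le[1]
  for (x in le) if (x > best) best <- x
  s <- 0
  for (x in le) s <- s + (best - x)
  n <- length(le) - if (exclude_reference && length(le) > 1) 1 else 0
  s / n
}

o_id <- function(le, exclude_reference = FALSE) {
  best <- le[1]
  for (x in le) if (x > best) best <- x
  100 * o_md(le, exclude_reference) / best
}

o_bgv <- function(le, pop) {
  mu <- o_weighted_mean(le, pop)
  total <- 0
  for (p in pop) total <- total + p
  s <- 0
  for (i in seq_along(le)) s <- s + (pop[i] / total) * (le[i] - mu)^2
  s
}

# unweighted-expansion cross-check: replicate each country pop_i times
# (integer populations only) and take the plain variance about the mean
o_bgv_expand <- function(le, pop) {
  expanded <- rep(le, times = pop)
  mu <- mean(expanded)
  mean((expanded - mu)^2)
}

o_theil <- function(le, pop) {
  mu <- o_weighted_mean(le, pop)
  total <- sum(pop)
  s <- 0
  for (i in seq_along(le)) {
    s <- s + (pop[i] / total) * (le[i] / mu) * log(le[i] / mu)
  }
  s
}

o_mld <- function(le, pop) {
  mu <- o_weighted_mean(le, pop)
  total <- sum(pop)
  s <- 0
  for (i in seq_along(le)) s <- s + (pop[i] / total) * log(mu / le[i])
  s
}

o_sti <- function(le, pop, scale = 1000) {
  scale * (o_theil(le, pop) + o_mld(le, pop)) / 2
}

# random region slice for property tests
random_slice <- function(n = NULL) {
  n <- n %||% sample(2:8, 1)
  list(le = stats::runif(n, 40, 85),
       pop = stats::rlnorm(n, log(1e5), 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_panel <- function(le, pop = rep(1, length(le)), period = "1965-1970",
                      sex = "both", ids = sprintf("C%02d", seq_along(le))) {
  panel(tibble::tibble(country = ids, period = period, sex = sex,
                       le = le, population = pop))
}

fmt2 <- function(x) formatC(x, format = "f", digits = 2)
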