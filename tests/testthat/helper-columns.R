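# toy specimen columns built in code

# n-vertebra column with arbitrary values and a simple flag plan:
# ribs on 1..rib_end (double-headed up to rib_double), chevrons from
# chevron_start to n - fluke_n, fluke on the last fluke_n vertebrae
toy_column <- function(values, rib_end = 3, chevron_start = NULL,
                       fluke_n = 0, rib_double = 1, status = NULL,
                       species = "spA", specimen = "spA_1") {
  n <- nrow(values)
  if (is.null(chevron_start)) chevron_start <- n + 1
  x <- seq_len(n)
  flags <- data.frame(
    rib_bearing = x <= rib_end,
    rib_head = ifelse(x <= rib_double, "double",
                      ifelse(x <= rib_end, "single", "none")),
    chevron_bearing = x >= chevron_start & x <= n - fluke_n,
    fluke = x > n - fluke_n)
  specimen_column(species, specimen, values, flags, status = status)
}

# smooth 16-measurement value matrix with no planted structure
toy_values <- function(n, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * 16, mean = 10, sd = 2), n, 16)
}

# brute-force Gower oracle: double loop over pairs and variables
gower_oracle <- function(x) {
  n <- nrow(x)
  rng <- apply(x, 2, function(v) diff(range(v)))
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    terms <- numeric(ncol(x))
    for (v in seq_len(ncol(x)))
      terms[v] <- if (rng[v] > 0) abs(x[i, v] - x[j, v]) / rng[v] else 0
    d[i, j] <- mean(terms)
  }
  d
}

# constrained least-squares oracle for the continuous segmented fit:
# per-segment intercept/slope pairs with explicit equality constraints at
# each knot, solved through the KKT system
segmented_oracle_rss <- function(y, x, breakpoints) {
  r <- length(breakpoints) + 1
  region <- findInterval(x, breakpoints + 0.5) + 1
  X <- matrix(0, length(x), 2 * r)
  for (j in seq_len(r)) {
    rows <- region == j
    X[rows, 2 * j - 1] <- 1
    X[rows, 2 * j] <- x[rows]
  }
  C <- matrix(0, r - 1, 2 * r)
  for (j in seq_len(r - 1)) {
    t <- breakpoints[j]
    C[j, (2 * j - 1):(2 * j)] <- c(1, t)
    C[j, (2 * j + 1):(2 * j + 2)] <- c(-1, -t)
  }
  if (r == 1) {
    theta <- qr.coef(qr(X), y)
    return(sum((y - X %*% theta)^2))
  }
  kkt <- rbind(cbind(2 * crossprod(X), t(C)),
               cbind(C, matrix(0, r - 1, r - 1)))
  rhs <- c(2 * crossprod(X, y), rep(0, r - 1))
  sol <- solve(kkt, rhs)
  theta <- sol[seq_len(2 * r)]
  sum((y - X %*% theta)^2)
}

# per-segment unconstrained (discontinuous) fit used as a comparator
discontinuous_rss <- function(y, x, breakpoints) {
  region <- findInterval(x, breakpoints + 0.5) + 1
  sum(vapply(unique(region), function(g) {
    rows <- region == g
    sum(resid(lm(y[rows] ~ x[rows]))^2)
  }, numeric(1)))
}
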