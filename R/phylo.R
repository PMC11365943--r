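#' Prune a phylogeny to the analysis taxa
#'
#' Returns the induced subtree on the requested taxa, with degree-2 nodes
#' suppressed and branch lengths summed, so patristic distances among
#' survivors are preserved. Taxa absent from the tree are reported with a
#' warning and must be dropped from the trait table too.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param taxa character vector of tip labels to keep.
#' @return The pruned `phylo` tree, with attribute `dropped` listing
#'   requested taxa that were not in the tree.
#' @export
prune_tree <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing) > 0)
    warning("taxa not in tree, dropped: ", paste(missing, collapse = ", "))
  keep <- intersect(taxa, tree$tip.label)
  if (length(keep) < 3) stop("fewer than 3 taxa remain after pruning")
  out <- ape::keep.tip(tree, keep)
  attr(out, "dropped") <- missing
  out
}

# lambda-scaled Brownian covariance: off-diagonals multiplied by lambda
.pagel_cov <- function(V, lambda) {
  Vl <- lambda * V
  diag(Vl) <- diag(V)
  Vl
}

# GLS machinery under a fixed covariance structure (up to sigma2)
.gls_core <- function(X, y, Vl) {
  n <- length(y)
  U <- chol(Vl)
  Xi <- backsolve(U, X, transpose = TRUE)
  yi <- backsolve(U, y, transpose = TRUE)
  qr_ <- qr(Xi)
  beta <- qr.coef(qr_, yi)
  res <- y - X %*% beta
  rss <- sum(qr.resid(qr_, yi)^2)   # e' V^-1 e
  sig2_ml <- rss / n
  logdet <- 2 * sum(log(diag(U)))
  ll <- -0.5 * (n * log(2 * pi) + n * log(sig2_ml) + logdet + n)
  XtViX_inv <- chol2inv(qr.R(qr_))
  list(beta = drop(beta), rss = rss, sig2_ml = sig2_ml, loglik = ll,
       cov_unscaled = XtViX_inv, residuals = drop(res), n = n,
       k = ncol(X))
}

# ML estimate of Pagel's lambda on [0, 1]: 21-point grid then
# golden-section refinement around the grid optimum; ties -> smaller lambda
.lambda_ml <- function(X, y, V, grid_n = 21L) {
  f <- function(l) .gls_core(X, y, .pagel_cov(V, l))$loglik
  grid <- seq(0, 1, length.out = grid_n)
  ll <- vapply(grid, f, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(grid_n, i + 1L)]
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  if (opt$objective > ll[i] + 1e-10) opt$maximum else grid[i]
}

# phylogeny-aware prediction errors (conditional expectation of each tip
# given all others under the fitted covariance)
.pred_errors <- function(X, beta, y, Vl, sig2) {
  n <- length(y)
  res <- y - X %*% beta
  vapply(seq_len(n), function(i) {
    cond <- Vl[i, -i, drop = FALSE] %*% solve(Vl[-i, -i], res[-i])
    y[i] - (sum(X[i, ] * beta) + cond)
  }, numeric(1))
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits a linear model by generalized least squares with residual
#' covariance proportional to the lambda-scaled Brownian-motion correlation
#' of the tree (off-diagonal elements multiplied by lambda, in `[0, 1]`).
#' Lambda is estimated by maximum likelihood (21-point grid plus
#' golden-section refinement) unless fixed. At lambda 0 the fit equals
#' ordinary least squares. Goodness of fit is the partial predictive R2:
#' one minus the ratio of summed squared phylogeny-aware prediction errors
#' of the full model over the intercept-only phylogenetic null.
#'
#' @param formula model formula; variables looked up in `data`.
#' @param data data frame with row names matching tree tip labels.
#' @param tree an [ape::phylo] tree with branch lengths covering the data
#'   species.
#' @param lambda `"ML"` (default) or a fixed value in `[0, 1]`.
#' @param compute_r2 compute the predictive R2 (default TRUE).
#' @return Object of class `phylo_fit`: coefficient table with SEs, t and
#'   p values, `lambda`, `loglik`, `sigma2`, `r2_pred`, `n`, residuals.
#' @export
pgls <- function(formula, data, tree, lambda = "ML", compute_r2 = TRUE) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  taxa <- rownames(mf)
  if (length(taxa) == 0 || !all(taxa %in% tree$tip.label))
    stop("data row names must match tree tip labels")
  tr <- if (length(taxa) < length(tree$tip.label))
    prune_tree(tree, taxa) else tree
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  ord <- match(tr$tip.label, taxa)
  y <- y[ord]
  X <- X[ord, , drop = FALSE]
  n <- length(y)
  if (n < ncol(X) + 2) stop("too few species for the model")
  if (qr(X)$rank < ncol(X)) stop("singular design matrix")
  V <- ape::vcv(tr)
  degenerate <- stats::sd(y) == 0
  lam <- if (identical(lambda, "ML")) {
    if (degenerate) 0 else .lambda_ml(X, y, V)
  } else {
    stopifnot(is.numeric(lambda), lambda >= 0, lambda <= 1)
    lambda
  }
  Vl <- .pagel_cov(V, lam)
  fit <- .gls_core(X, y, Vl)
  df <- n - fit$k
  sig2 <- fit$rss / df
  se <- sqrt(diag(fit$cov_unscaled) * sig2)
  tval <- fit$beta / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  if (degenerate) {
    tval[] <- NA
    pval[] <- NA
  }
  r2 <- NA_real_
  if (compute_r2 && ncol(X) > 1 && !degenerate) {
    e1 <- .pred_errors(X, fit$beta, y, Vl, sig2)
    X0 <- X[, 1, drop = FALSE]
    lam0 <- .lambda_ml(X0, y, V)
    fit0 <- .gls_core(X0, y, .pagel_cov(V, lam0))
    e0 <- .pred_errors(X0, fit0$beta, y, .pagel_cov(V, lam0), fit0$sig2_ml)
    r2 <- 1 - sum(e1^2) / sum(e0^2)
  }
  structure(list(
    coefficients = data.frame(estimate = fit$beta, se = se, t = tval,
                              p = pval,
                              row.names = colnames(X)),
    lambda = lam, loglik = fit$loglik, sigma2 = sig2, rss = fit$rss,
    r2_pred = r2, n = n, df_residual = df, residuals = fit$residuals,
    tree = tr, V = V, Vl = Vl, X = X, y = y, degenerate = degenerate,
    formula = formula),
    class = "phylo_fit")
}

#' @export
print.phylo_fit <- function(x, ...) {
  cat(sprintf("<phylo_fit> n=%d, lambda=%.3f, logLik=%.3f", x$n, x$lambda,
              x$loglik))
  if (!is.na(x$r2_pred)) cat(sprintf(", R2_pred=%.3f", x$r2_pred))
  if (!is.null(x$F)) cat(sprintf(", F=%.3f (p=%.4g)", x$F, x$F_p))
  cat("\n")
  print(format(x$coefficients, digits = 4))
  invisible(x)
}

#' Phylogenetically corrected ANOVA
#'
#' Lambda-GLS fit of a response on a category factor, compared with the
#' intercept-only model by the generalized extra-sum-of-squares F test.
#' Lambda is estimated by maximum likelihood under the full model and held
#' fixed for the null, so the two residual sums of squares are computed
#' under the same covariance.
#'
#' @param formula `response ~ category`.
#' @param data data frame with row names matching tip labels; the category
#'   column is coerced to factor.
#' @param tree an [ape::phylo] tree.
#' @return A [pgls()] `phylo_fit` with extra elements `F`, `F_p`, `df1`,
#'   `df2`.
#' @export
phylo_anova <- function(formula, data, tree) {
  fac <- all.vars(formula)[2]
  data[[fac]] <- factor(data[[fac]])
  sizes <- table(data[[fac]])
  if (length(sizes) < 2) stop("need at least 2 categories")
  if (any(sizes < 2))
    warning("category with a single species: ",
            paste(names(sizes)[sizes < 2], collapse = ", "))
  fit <- pgls(formula, data, tree, lambda = "ML", compute_r2 = FALSE)
  X0 <- fit$X[, 1, drop = FALSE]
  fit0 <- .gls_core(X0, fit$y, fit$Vl)
  q <- ncol(fit$X) - 1L
  df2 <- fit$n - ncol(fit$X)
  Fstat <- ((fit0$rss - fit$rss) / q) / (fit$rss / df2)
  fit$F <- Fstat
  fit$F_p <- stats::pf(Fstat, q, df2, lower.tail = FALSE)
  fit$df1 <- q
  fit$df2 <- df2
  fit
}

#' Ancestral states of a continuous trait under Brownian motion
#'
#' Maximum-likelihood (GLS) estimates of the trait at every internal node:
#' the BM root state is the GLS mean over tips, and each node estimate is
#' the conditional expectation given the tips under the Brownian
#' covariance implied by shared branch lengths. Estimate variances include
#' the uncertainty in the root mean.
#'
#' @param tree an [ape::phylo] tree with positive branch lengths.
#' @param x named numeric vector of tip values (names = tip labels),
#'   complete.
#' @return Data frame with one row per internal node: `node`, `estimate`,
#'   `variance`.
#' @export
bm_asr <- function(tree, x) {
  stopifnot(inherits(tree, "phylo"))
  if (!all(tree$tip.label %in% names(x))) stop("tip values incomplete")
  x <- x[tree$tip.label]
  ntip <- length(tree$tip.label)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  D <- ape::dist.nodes(tree)
  root <- ntip + 1L
  depth <- D[root, ]
  covfun <- function(a, b)
    (outer(depth[a], depth[b], `+`) - D[a, b, drop = FALSE]) / 2
  tips <- seq_len(ntip)
  Ctt <- covfun(tips, tips)
  Cat <- covfun(nodes, tips)
  if (any(diag(Ctt) <= 0))
    stop("zero-length terminal branches make tip states conflict")
  Cinv <- solve(Ctt)
  one <- rep(1, ntip)
  denom <- sum(Cinv %*% one)
  mu <- sum(Cinv %*% x) / denom
  sig2 <- drop(t(x - mu) %*% Cinv %*% (x - mu)) / ntip
  w <- Cat %*% Cinv
  est <- drop(mu + w %*% (x - mu))
  caa <- depth[nodes]
  condv <- caa - rowSums(w * Cat)
  muv <- (1 - drop(w %*% one))^2 / denom
  data.frame(node = nodes, estimate = est,
             variance = pmax(sig2 * (condv + muv), 0))
}

#' Size-corrected swimming speed
#'
#' Speed divided by body size, in body lengths per unit time. Missing
#' speeds propagate as `NA`.
#'
#' @param speed swimming speed (e.g. m/s); may be `NA`.
#' @param size body size in the same length unit; must be positive.
#' @return `speed / size`.
#' @export
size_correct_speed <- function(speed, size) {
  if (any(!is.na(size) & size <= 0)) stop("body size must be positive")
  if (any(!is.na(speed) & speed <= 0)) stop("speed must be positive")
  speed / size
}
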