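## Gaussian marginal model (GEE) with identity link, exchangeable or
## independence working correlation, and bias-reduced (Mancl-DeRouen)
## cluster-robust sandwich covariance.  Written for the small-cluster
## regime of this design (10 athletes, 16 observations each); inference
## downstream uses a t reference with (clusters - 1) degrees of freedom.

gee_gaussian <- function(y, X, id, corstr = c("exchangeable",
                                              "independence"),
                         maxit = 25L, tol = 1e-10) {
  corstr <- match.arg(corstr)
  stopifnot(length(y) == nrow(X), length(id) == length(y))
  id <- as.character(id)
  clusters <- unique(id)
  n_clu <- length(clusters)
  p <- ncol(X)

  ## drop aliased columns so the bread is invertible
  qrX <- qr(X)
  aliased <- rep(FALSE, p)
  if (qrX$rank < p) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    aliased[-keep] <- TRUE
    X <- X[, keep, drop = FALSE]
    p <- ncol(X)
  }
  idx <- split(seq_along(y), id)[clusters]

  beta <- qr.coef(qr(X), y)
  rho <- 0
  converged <- FALSE
  for (it in seq_len(maxit)) {
    r <- y - drop(X %*% beta)
    ## floor keeps degenerate (zero-residual) fits well defined
    sigma2 <- max(sum(r^2) / (length(y) - p), 1e-300)
    if (corstr == "exchangeable") {
      num <- 0; den <- 0
      for (ii in idx) {
        ri <- r[ii]; ni <- length(ri)
        if (ni < 2) next
        num <- num + (sum(ri)^2 - sum(ri^2)) / 2
        den <- den + ni * (ni - 1) / 2
      }
      rho <- if (den > 0) num / (den * sigma2) else 0
      max_ni <- max(lengths(idx))
      rho <- min(max(rho, -1 / (max_ni - 1) + 1e-6), 0.99)
    }
    A <- matrix(0, p, p)
    b <- numeric(p)
    for (ii in idx) {
      Xi <- X[ii, , drop = FALSE]
      yi <- y[ii]
      WX <- winv_mult(Xi, sigma2, rho)
      A <- A + crossprod(WX, Xi)
      b <- b + crossprod(WX, yi)
    }
    beta_new <- solve(A, b)
    delta <- max(abs(beta_new - beta))
    beta <- drop(beta_new)
    if (delta < tol) { converged <- TRUE; break }
    if (corstr == "independence" && it >= 2L) { converged <- TRUE; break }
  }

  ## Mancl-DeRouen bias-reduced sandwich: inflate each cluster's residual
  ## by (I - H_i)^{-1} before forming the meat
  bread <- solve(A)
  r <- y - drop(X %*% beta)
  meat <- matrix(0, p, p)
  for (ii in idx) {
    Xi <- X[ii, , drop = FALSE]
    ri <- r[ii]
    WXi <- winv_mult(Xi, sigma2, rho)
    Hi <- Xi %*% bread %*% t(WXi)
    ri_adj <- solve(diag(length(ri)) - Hi, ri)
    gi <- crossprod(WXi, ri_adj)
    meat <- meat + tcrossprod(gi)
  }
  vcov_full <- matrix(NA_real_, length(aliased), length(aliased))
  beta_full <- rep(NA_real_, length(aliased))
  beta_full[!aliased] <- beta
  vcov_full[!aliased, !aliased] <- bread %*% meat %*% bread

  list(beta = beta_full, vcov = vcov_full, aliased = aliased,
       sigma2 = sigma2, rho = rho, df = n_clu - 1L,
       n_clusters = n_clu, converged = converged)
}

## (sigma2 * ((1-rho) I + rho J))^{-1} %*% M, via Sherman-Morrison
winv_mult <- function(M, sigma2, rho) {
  ni <- nrow(M)
  if (rho == 0) return(M / sigma2)
  a <- 1 / (sigma2 * (1 - rho))
  b <- -rho / (sigma2 * (1 - rho) * (1 + (ni - 1) * rho))
  a * M + b * matrix(colSums(M), ni, ncol(M), byrow = TRUE)
}
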