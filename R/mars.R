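# Compact multivariate adaptive regression splines.
#
# Forward pass: starting from the intercept, repeatedly add the reflected pair
# of hinge functions max(x - t, 0) / max(t - x, 0) (optionally multiplied into
# an existing basis term, up to `degree`) that most reduces the residual sum of
# squares. Knots are restricted to a quantile grid of each predictor. Backward
# pass: prune terms one at a time, keeping the subset with the best GCV, where
# the effective number of parameters is n_terms + penalty * n_knots.
# The final model is an ordinary least-squares fit on the selected basis, so
# coefficient uncertainty is the classical lm covariance.

mars_fit <- function(x, y, degree = 2, nk = 21, penalty = 3, n_knots = 20) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  stopifnot(n == length(y), p >= 1)

  knots <- lapply(seq_len(p), function(j) {
    q <- unique(quantile(x[, j], probs = seq(0.05, 0.95, length.out = n_knots),
                         type = 1, names = FALSE))
    q[q > min(x[, j]) & q < max(x[, j])]
  })

  # basis bookkeeping: each term is a list of (var, knot, sign) factors
  terms <- list(list())                 # intercept
  B <- matrix(1, n, 1)
  sst <- sum((y - mean(y))^2)
  if (sst == 0 || all(lengths(knots) == 0)) {
    return(mars_finalize(B, terms, x, y, penalty))
  }

  qrB <- qr(B)
  rss <- sum(qr.resid(qrB, y)^2)
  while (ncol(B) + 2 <= nk) {
    best <- NULL
    res <- qr.resid(qrB, y)
    for (m in seq_along(terms)) {
      parent <- terms[[m]]
      if (length(parent) >= degree) next
      used_vars <- vapply(parent, function(f) f$var, 0L)
      pb <- B[, m]
      for (j in setdiff(seq_len(p), used_vars)) {
        for (t in knots[[j]]) {
          h1 <- pb * pmax(x[, j] - t, 0)
          h2 <- pb * pmax(t - x[, j], 0)
          cand <- cbind(h1, h2)
          # score: RSS reduction of adding the pair to the current fit
          z <- qr.resid(qrB, cand)
          znorm <- sqrt(colSums(z^2))
          ok <- znorm > 1e-8 * sqrt(n)
          if (!any(ok)) next
          z <- z[, ok, drop = FALSE]
          qz <- qr(z)
          dz <- qr.resid(qz, res)
          red <- sum(res^2) - sum(dz^2)
          if (is.null(best) || red > best$red + 1e-12) {
            best <- list(red = red, j = j, t = t, m = m, cand = cand[, ok, drop = FALSE],
                         signs = c(1, -1)[ok])
          }
        }
      }
    }
    if (is.null(best) || best$red <= 1e-10 * sst) break
    for (i in seq_along(best$signs)) {
      terms[[length(terms) + 1]] <- c(terms[[best$m]],
                                      list(list(var = best$j, knot = best$t, sign = best$signs[i])))
    }
    B <- cbind(B, best$cand)
    qrB <- qr(B)
    new_rss <- sum(qr.resid(qrB, y)^2)
    if (rss - new_rss <= 1e-10 * sst) {  # numerically useless pair: drop and stop
      drop_idx <- (ncol(B) - length(best$signs) + 1):ncol(B)
      B <- B[, -drop_idx, drop = FALSE]
      terms <- terms[seq_len(ncol(B))]
      break
    }
    rss <- new_rss
  }

  # backward pruning by GCV
  sel <- seq_len(ncol(B))
  best_sel <- sel
  best_gcv <- mars_gcv(B[, sel, drop = FALSE], y, penalty)
  while (length(sel) > 1) {
    gcvs <- vapply(seq_along(sel)[-1], function(i) {
      mars_gcv(B[, sel[-i], drop = FALSE], y, penalty)
    }, 0)
    i_drop <- which.min(gcvs) + 1L
    sel <- sel[-i_drop]
    g <- mars_gcv(B[, sel, drop = FALSE], y, penalty)
    if (g < best_gcv) {
      best_gcv <- g
      best_sel <- sel
    }
  }
  mars_finalize(B[, best_sel, drop = FALSE], terms[best_sel], x, y, penalty)
}

mars_gcv <- function(B, y, penalty) {
  n <- nrow(B)
  rss <- sum(qr.resid(qr(B), y)^2)
  nterm <- ncol(B)
  ck <- nterm + penalty * (nterm - 1) / 2  # each reflected pair shares one knot
  denom <- (1 - min(ck, n - 1) / n)^2
  rss / (n * denom)
}

mars_finalize <- function(B, terms, x, y, penalty) {
  qrB <- qr(B)
  rank <- qrB$rank
  if (rank < ncol(B)) {
    keep <- qrB$pivot[seq_len(rank)]
    keep <- sort(keep)
    B <- B[, keep, drop = FALSE]
    terms <- terms[keep]
    qrB <- qr(B)
  }
  cf <- qr.coef(qrB, y)
  fitted <- as.numeric(B %*% cf)
  res <- y - fitted
  n <- nrow(B)
  dfree <- max(n - ncol(B), 1)
  sigma2 <- sum(res^2) / dfree
  xtx_inv <- chol2inv(qr.R(qrB))
  # undo the QR pivot ordering for the covariance
  piv <- qrB$pivot
  cov_unpiv <- matrix(0, ncol(B), ncol(B))
  cov_unpiv[piv, piv] <- xtx_inv
  list(
    fitted = fitted,
    coef = cf,
    coef_cov = sigma2 * cov_unpiv,
    basis_matrix = B,
    terms = terms,
    gcv = mars_gcv(B, y, penalty)
  )
}

# evaluate a fitted mars basis on new data (used by tests)
mars_basis <- function(terms, x) {
  x <- as.matrix(x)
  vapply(terms, function(term) {
    b <- rep(1, nrow(x))
    for (f in term) {
      b <- b * pmax(f$sign * (x[, f$var] - f$knot), 0)
    }
    b
  }, numeric(nrow(x)))
}
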