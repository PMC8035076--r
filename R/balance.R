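# Matrix balancing. Both methods scale the valid submatrix so that every row
# of b_i * b_j * count(i,j) sums to 1; masked rows/columns are left NA.
# For fully supported symmetric matrices the row-sum-1 scaling is unique, so
# the two methods agree to numerical tolerance.

#' Knight-Ruiz matrix balancing
#'
#' Inner-outer Newton iteration with a conjugate-gradient inner solver
#' (Knight & Ruiz 2013). The balanced value is `b_i * b_j * count(i, j)`;
#' every valid row sums to 1 within `tol`.
#'
#' @param cm A filtered `contact_matrix`.
#' @param tol Convergence tolerance on the row-sum residual.
#' @param max_iter Maximum outer iterations.
#' @return `cm` with `biases`, `normalized` and `norm_method = "kr"` set.
#' @export
kr_balance <- function(cm, tol = 1e-10, max_iter = 100L) {
  finish_balance(cm, kr_solve, tol, max_iter, "kr")
}

#' Iterative-correction matrix balancing
#'
#' Imakaev-style iterative correction: per-bin biases are repeatedly divided
#' by the (mean-scaled) marginals until the marginals are flat, then rescaled
#' so each valid row sums to 1.
#'
#' @inheritParams kr_balance
#' @return `cm` with `biases`, `normalized` and `norm_method = "ice"` set.
#' @export
ice_balance <- function(cm, tol = 1e-10, max_iter = 2000L) {
  finish_balance(cm, ice_solve, tol, max_iter, "ice")
}

finish_balance <- function(cm, solver, tol, max_iter, method) {
  idx <- which(cm$valid)
  if (!length(idx)) stop("no valid bins to balance")
  a <- cm$counts[idx, idx, drop = FALSE]
  if (any(rowSums(a) == 0))
    stop("matrix is structurally unbalanceable: valid bin with zero marginal")
  b <- solver(a, tol, max_iter)
  n <- length(cm$bins)
  biases <- rep(NA_real_, n)
  biases[idx] <- b
  norm <- matrix(NA_real_, n, n)
  norm[idx, idx] <- a * tcrossprod(b)
  cm$biases <- biases
  cm$normalized <- norm
  cm$norm_method <- method
  cm
}

# Knight-Ruiz bnewt: solve diag(x) A x = e on a fully supported symmetric
# nonnegative matrix. Returns the bias vector x.
kr_solve <- function(a, tol = 1e-10, max_iter = 100L, delta = 0.1, Delta = 3) {
  n <- nrow(a)
  e <- rep(1, n)
  x <- e
  g <- 0.9; etamax <- 0.1
  eta <- etamax
  stop_tol <- tol * 0.5
  rt <- tol^2
  v <- x * as.vector(a %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1; rold <- rout
  i <- 0L
  while (rout > rt) {
    i <- i + 1L
    if (i > max_iter)
      stop(sprintf(
        "KR balancing did not converge in %d iterations (residual %.3g)",
        max_iter, sqrt(rout)))
    k <- 0L; y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    Z <- p <- w <- NULL
    while (rho_km1 > innertol) {  # inner CG
      k <- k + 1L
      if (k == 1L) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * as.vector(a %*% (x * p)) + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        if (delta == 0) break
        ind <- which(ap < 0)
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- which(ynew > Delta)
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
      if (k > 200L) break
    }
    x <- x * y
    v <- x * as.vector(a %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    rat <- rout / rold
    rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), stop_tol / res_norm)
  }
  x
}

# Iterative correction: returns bias vector with row sums of b_i b_j a_ij = 1.
ice_solve <- function(a, tol = 1e-10, max_iter = 2000L) {
  n <- nrow(a)
  b <- rep(1, n)
  w <- a
  for (it in seq_len(max_iter)) {
    m <- rowSums(w)
    if (any(m == 0))
      stop("matrix is structurally unbalanceable: zero marginal during ICE")
    db <- m / mean(m)
    b <- b * db
    w <- w / tcrossprod(db)
    if (max(abs(db - 1)) < tol) {
      # w = a / (b_i b_j) with flat row sums s; rescale to row sums 1
      s <- mean(rowSums(w))
      return(1 / (b * sqrt(s)))
    }
  }
  stop(sprintf(
    "ICE balancing did not converge in %d iterations (residual %.3g)",
    max_iter, max(abs(rowSums(w) / mean(rowSums(w)) - 1))))
}
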