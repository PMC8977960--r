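# Numerical helpers shared by the synthetic-data generator.

#' Truncated-normal moments and quantiles
#'
#' Closed-form mean/sd and quantile function of a normal distribution
#' truncated to `[lower, upper]`. Used to draw physiologically bounded
#' covariates (notably BMI, which is truncated at the obesity cut-off so that
#' stratum membership and the BMI rule agree by construction).
#'
#' @param mean,sd parent-normal parameters.
#' @param lower,upper truncation bounds (may be infinite).
#' @return `tnorm_moments()` a list with elements `mean` and `sd`;
#'   `qtnorm()` quantiles of the truncated distribution.
#' @keywords internal
#' @noRd
tnorm_moments <- function(mean, sd, lower = -Inf, upper = Inf) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  za <- pnorm(a)
  zb <- pnorm(b)
  z <- zb - za
  if (z <= 0) stop("empty truncation interval", call. = FALSE)
  da <- dnorm(a)
  db <- dnorm(b)
  m <- mean + sd * (da - db) / z
  # standard second-moment identity for the doubly truncated normal
  amul <- if (is.finite(a)) a * da else 0
  bmul <- if (is.finite(b)) b * db else 0
  v <- sd^2 * (1 + (amul - bmul) / z - ((da - db) / z)^2)
  list(mean = m, sd = sqrt(v))
}

qtnorm <- function(p, mean, sd, lower = -Inf, upper = Inf) {
  za <- pnorm(lower, mean, sd)
  zb <- pnorm(upper, mean, sd)
  qnorm(za + p * (zb - za), mean, sd)
}

#' Solve parent-normal parameters for target truncated moments
#'
#' Finds `(mean, sd)` of the parent normal such that the one-sided truncated
#' distribution has the requested mean and sd. Deterministic Nelder-Mead on
#' the squared relative moment error.
#' @keywords internal
#' @noRd
solve_tnorm_parent <- function(target_mean, target_sd, lower = -Inf, upper = Inf) {
  obj <- function(par) {
    mom <- tnorm_moments(par[1], exp(par[2]), lower, upper)
    (mom$mean / target_mean - 1)^2 + (mom$sd / target_sd - 1)^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj,
               control = list(reltol = 1e-14, maxit = 2000))
  if (fit$value > 1e-8) {
    stop("could not match truncated-normal moments (mean ", target_mean,
         ", sd ", target_sd, ")", call. = FALSE)
  }
  list(mean = fit$par[1], sd = exp(fit$par[2]))
}

#' Project a symmetric matrix to the nearest positive semi-definite
#' correlation matrix by eigenvalue clipping
#' @keywords internal
#' @noRd
project_psd <- function(mat, eps = 1e-8) {
  if (!isSymmetric(unname(mat), tol = 1e-10)) {
    stop("correlation matrix must be symmetric", call. = FALSE)
  }
  eig <- eigen(mat, symmetric = TRUE)
  if (min(eig$values) >= eps) return(mat)
  vals <- pmax(eig$values, eps)
  out <- eig$vectors %*% diag(vals, nrow = length(vals)) %*% t(eig$vectors)
  # restore unit diagonal after clipping
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  dimnames(out) <- dimnames(mat)
  out
}

#' Largest-remainder integer allocation of `total` across weights
#' @keywords internal
#' @noRd
allocate_counts <- function(total, weights) {
  raw <- total * weights / sum(weights)
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

# abort helper with consistent class for user-facing contract violations
mm_abort <- function(msg, class = "musclemap_error") {
  rlang::abort(msg, class = class)
}
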