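# Positive-definite smoothing of indefinite correlation matrices.  All three
# smoothers leave matrices that are already positive definite (smallest
# eigenvalue > pd_tol) untouched.

check_unit_diagonal <- function(r, arg = "R") {
  if (!is.matrix(r) || nrow(r) != ncol(r)) abort(sprintf("`%s` must be square.", arg))
  if (max(abs(r - t(r))) > 1e-8) abort(sprintf("`%s` must be symmetric.", arg))
  if (max(abs(diag(r) - 1)) > 1e-8) abort(sprintf("`%s` must have a unit diagonal.", arg))
  (r + t(r)) / 2
}

new_smooth_result <- function(matrix, input, algorithm, iterations = 0L,
                              delta = NULL, delta_i = NULL) {
  out_eig <- min(eigen(matrix, symmetric = TRUE, only.values = TRUE)$values)
  in_eig <- min(eigen(input, symmetric = TRUE, only.values = TRUE)$values)
  structure(
    list(
      matrix = matrix,
      report = list(
        algorithm = algorithm,
        input_min_eigenvalue = in_eig,
        output_min_eigenvalue = out_eig,
        max_abs_change = max(abs(matrix - input)),
        iterations = as.integer(iterations),
        delta = delta,
        delta_i = delta_i
      )
    ),
    class = "smooth_result"
  )
}

#' @export
print.smooth_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "%s smoothing: min eigenvalue %.4g -> %.4g, max |change| %.4g\n",
    r$algorithm, r$input_min_eigenvalue, r$output_min_eigenvalue, r$max_abs_change
  ))
  invisible(x)
}

#' @export
tidy.smooth_result <- function(x, ...) {
  r <- x$report
  tibble(
    algorithm = r$algorithm,
    input_min_eigenvalue = r$input_min_eigenvalue,
    output_min_eigenvalue = r$output_min_eigenvalue,
    max_abs_change = r$max_abs_change,
    iterations = r$iterations,
    delta = r$delta %||% NA_real_
  )
}

project_psd <- function(m, floor = 0) {
  e <- eigen(m, symmetric = TRUE)
  v <- pmax(e$values, floor)
  out <- e$vectors %*% (v * t(e$vectors))
  (out + t(out)) / 2
}

#' Nearest-correlation-matrix smoothing (alternating projections)
#'
#' Computes the correlation matrix nearest to `R` in the Frobenius norm by
#' Dykstra-corrected alternating projections between the positive semidefinite
#' cone and the unit-diagonal affine set, followed by a small eigenvalue floor
#' that moves the limit from semidefinite to strictly positive definite.
#' Positive definite inputs are returned unchanged.
#'
#' @param R Symmetric matrix with unit diagonal.
#' @param max_iter Maximum number of projection sweeps.
#' @param tol Convergence tolerance on the Frobenius norm of successive
#'   iterates.
#' @param eig_floor Eigenvalue floor applied after convergence.
#' @param pd_tol Positive definiteness tolerance for the short-circuit.
#' @return A `smooth_result`: the smoothed matrix plus a report (input/output
#'   smallest eigenvalues, largest elementwise change, iterations used).
#' @examples
#' r <- matrix(c(1, .9, .9, .9, 1, -.9, .9, -.9, 1), 3, 3)
#' smooth_higham(r)
#' @export
smooth_higham <- function(R, max_iter = 1000L, tol = 1e-9, eig_floor = 1e-8,
                          pd_tol = 1e-8) {
  r <- check_unit_diagonal(R)
  pd <- is_positive_definite(r, tol = pd_tol)
  if (pd$is_pd) {
    return(new_smooth_result(r, r, "higham", iterations = 0L))
  }
  y <- r
  ds <- matrix(0, nrow(r), ncol(r))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    y_old <- y
    rr <- y - ds
    x <- project_psd(rr)
    ds <- x - rr
    y <- x
    diag(y) <- 1
    if (norm(y - y_old, "F") < tol) break
    if (iter >= max_iter) {
      abort(sprintf("Alternating projections did not converge in %d iterations.", max_iter))
    }
  }
  out <- project_psd(y, floor = eig_floor)
  d <- 1 / sqrt(diag(out))
  out <- out * tcrossprod(d)
  diag(out) <- 1
  new_smooth_result(out, r, "higham", iterations = iter)
}

#' Eigenvalue-clipping smoothing
#'
#' Replaces eigenvalues of `R` below the floor `delta` with `delta` and
#' rescales the reconstruction back to unit diagonal:
#' `R(delta) = Diag(K D+ K')^{-1/2} (K D+ K') Diag(K D+ K')^{-1/2}`, where
#' `K D K'` is the eigendecomposition of `R` and `D+` clips eigenvalues below
#' `delta` up to `delta`.  Positive definite inputs are returned unchanged.
#'
#' @inheritParams smooth_higham
#' @param delta Eigenvalue floor (default 0.1).
#' @return A `smooth_result`.
#' @examples
#' r <- matrix(c(1, .9, .9, .9, 1, -.9, .9, -.9, 1), 3, 3)
#' smooth_knol_berger(r)$report$output_min_eigenvalue
#' @export
smooth_knol_berger <- function(R, delta = 0.1, pd_tol = 1e-8) {
  stopifnot(delta > 0)
  r <- check_unit_diagonal(R)
  pd <- is_positive_definite(r, tol = pd_tol)
  if (pd$is_pd) {
    return(new_smooth_result(r, r, "knol_berger", delta = delta))
  }
  e <- eigen(r, symmetric = TRUE)
  if (all(e$values >= delta)) {
    return(new_smooth_result(r, r, "knol_berger", delta = delta))
  }
  m <- e$vectors %*% (pmax(e$values, delta) * t(e$vectors))
  d <- 1 / sqrt(diag(m))
  out <- m * tcrossprod(d)
  out <- (out + t(out)) / 2
  diag(out) <- 1
  new_smooth_result(out, r, "knol_berger", delta = delta)
}

#' Minimum trace factor analysis decomposition
#'
#' Finds the diagonal matrix `D` maximizing `sum(diag(D))` subject to `R - D`
#' being positive semidefinite, so that `R - D` is the PSD "common" part with
#' minimal trace and `D` the (possibly negative) "unique" part.  For
#' indefinite `R` some entries of `D` are necessarily negative; these mark
#' Heywood-type variables.
#'
#' The semidefinite program is solved by a log-barrier interior-point method:
#' for a decreasing barrier weight `mu`, Newton's method maximizes
#' `sum(d) + mu * log det(R - diag(d))` (gradient `1 - mu * diag(S)`, Hessian
#' `-mu * S * S` elementwise with `S = (R - diag(d))^{-1}`), starting from the
#' strictly feasible `d = lambda_min(R) - 0.5`.  The duality gap at barrier
#' weight `mu` is `J * mu`; iteration continues until it is below `gap_tol`.
#'
#' @param R Symmetric matrix.
#' @param gap_tol Bound on the final duality gap (absolute, on the trace).
#' @return A list: `d` (diagonal entries), `trace_common`
#'   (`trace(R) - sum(d)`), `min_eigenvalue_common` of `R - D`, `iterations`.
#' @examples
#' minimum_trace_decomposition(diag(3))$d  # all ones
#' @export
minimum_trace_decomposition <- function(R, gap_tol = 1e-8) {
  if (!is.matrix(R) || nrow(R) != ncol(R)) abort("`R` must be square.")
  if (max(abs(R - t(R))) > 1e-8) abort("`R` must be symmetric.")
  r <- (R + t(R)) / 2
  j <- nrow(r)
  lam_min <- min(eigen(r, symmetric = TRUE, only.values = TRUE)$values)
  d <- rep(lam_min - 0.5, j)
  mu <- 1
  total_iter <- 0L
  while (mu * j > gap_tol) {
    for (it in 1:50) {
      m <- r - diag(d, j)
      s <- tryCatch(chol2inv(chol(m)), error = function(e) NULL)
      if (is.null(s)) abort("Interior-point iterate left the feasible cone.")
      grad <- 1 - mu * diag(s)
      hess <- mu * (s * s)
      step <- tryCatch(solve(hess, grad), error = function(e) grad / diag(hess))
      # Backtrack until R - diag(d + t * step) stays positive definite.
      t_ <- 1
      repeat {
        ok <- tryCatch(
          {
            chol(r - diag(d + t_ * step, j))
            TRUE
          },
          error = function(e) FALSE
        )
        if (ok) break
        t_ <- t_ / 2
        if (t_ < 1e-14) break
      }
      d <- d + t_ * step
      total_iter <- total_iter + 1L
      if (sqrt(sum(grad^2)) < 1e-10) break
    }
    mu <- mu * 0.2
  }
  common <- r - diag(d, j)
  list(
    d = d,
    trace_common = sum(diag(common)),
    min_eigenvalue_common = min(eigen(common, symmetric = TRUE, only.values = TRUE)$values),
    iterations = total_iter
  )
}

#' Heywood-variable rescaling smoothing
#'
#' Produces `R* = Delta R0 Delta + D_R`, where `R0` is `R` with a zeroed
#' diagonal, `D_R` the diagonal of `R`, and `Delta` a diagonal matrix with
#' entries `delta_i` in `(0, 1]`.  Variables implicated as Heywood-type by the
#' minimum trace decomposition ([minimum_trace_decomposition()]: negative
#' unique variance `d_i`) get a common shrink factor found by bisection — the
#' largest value in `(0, 1]` for which the smallest eigenvalue of the result
#' exceeds `pd_tol`; all other variables keep `delta_i = 1`, so only rows and
#' columns of implicated variables change.  Off-diagonal `(i, j)` of the
#' output equals `delta_i * delta_j * R[i, j]`; the diagonal is preserved
#' exactly.  Positive definite inputs are returned unchanged with all
#' `delta_i = 1`.
#'
#' @inheritParams smooth_higham
#' @param bisect_iter Number of bisection steps for the shrink factor.
#' @return A `smooth_result`; the report carries the rescaling factors
#'   `delta_i`.
#' @examples
#' r <- matrix(c(1, .9, .9, .9, 1, -.9, .9, -.9, 1), 3, 3)
#' smooth_bentler_yuan(r)$report$delta_i
#' @export
smooth_bentler_yuan <- function(R, pd_tol = 1e-8, bisect_iter = 60L) {
  r <- check_unit_diagonal(R)
  j <- nrow(r)
  pd <- is_positive_definite(r, tol = pd_tol)
  if (pd$is_pd) {
    return(new_smooth_result(r, r, "bentler_yuan", delta_i = rep(1, j)))
  }
  mtfa <- minimum_trace_decomposition(r)
  heywood <- mtfa$d < 0
  if (!any(heywood)) {
    abort("Minimum trace decomposition found no Heywood-type variable for an indefinite matrix.")
  }
  r0 <- r
  diag(r0) <- 0
  d_r <- diag(r)

  min_eig_for <- function(s) {
    delta_i <- ifelse(heywood, s, 1)
    m <- (delta_i %o% delta_i) * r0 + diag(d_r, j)
    min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  }
  if (min_eig_for(1e-8) <= pd_tol) {
    abort("Rescaling cannot reach positive definiteness: the unimplicated block is singular.")
  }
  lo <- 1e-8
  hi <- 1
  for (i in seq_len(bisect_iter)) {
    mid <- (lo + hi) / 2
    if (min_eig_for(mid) > pd_tol) lo <- mid else hi <- mid
  }
  s <- lo
  delta_i <- ifelse(heywood, s, 1)
  out <- (delta_i %o% delta_i) * r0 + diag(d_r, j)
  out <- (out + t(out)) / 2
  new_smooth_result(out, r, "bentler_yuan", iterations = bisect_iter, delta_i = delta_i)
}

smoother_for <- function(smoothing, delta = 0.1) {
  switch(smoothing,
    none = NULL,
    higham = function(r) smooth_higham(r),
    knol_berger = function(r) smooth_knol_berger(r, delta = delta),
    bentler_yuan = function(r) smooth_bentler_yuan(r),
    abort(sprintf("Unknown smoothing algorithm '%s'.", smoothing))
  )
}
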