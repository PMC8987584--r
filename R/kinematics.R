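#' Kinematic quantities of a deformation gradient
#'
#' Computes the left and right Cauchy-Green tensors `B = F F^T`,
#' `C = F^T F`, the principal invariants `I1 = tr B`,
#' `I2 = ((tr B)^2 - tr B^2)/2`, `I3 = det B`, the volume ratio
#' `J = det F`, and, when a reference fiber direction `a0` is given, the
#' fiber pseudo-invariant `I4 = a0 . (C a0)` and fiber stretch
#' `lambda = sqrt(I4)`.
#'
#' @param F 3x3 deformation gradient with `det F > 0`.
#' @param a0 optional unit reference fiber direction.
#' @return object of class `deformation_state`.
#' @examples
#' st <- kinematics(diag(c(1.1, 1/sqrt(1.1), 1/sqrt(1.1))), a0 = c(1, 0, 0))
#' st$J; st$lam_fiber
#' @export
kinematics <- function(F, a0 = NULL) {
  F <- as.matrix(F)
  stopifnot(is.numeric(F), all(dim(F) == c(3L, 3L)), all(is.finite(F)))
  J <- det(F)
  if (J <= 0)
    stop("invalid deformation: det(F) = ", signif(J, 4), " <= 0")
  B <- F %*% t(F)
  C <- t(F) %*% F
  I1 <- sum(diag(B))
  I2 <- 0.5 * (I1^2 - sum(B * B))  # tr(B^2) = sum of squared entries (B symmetric)
  I3 <- J^2
  st <- list(F = F, B = B, C = C, I1 = I1, I2 = I2, I3 = I3, J = J,
             a0 = NULL, I4 = NA_real_, lam_fiber = NA_real_)
  if (!is.null(a0)) {
    a0 <- as.numeric(a0)
    stopifnot(length(a0) == 3L)
    a0 <- a0 / sqrt(sum(a0^2))
    I4 <- as.numeric(t(a0) %*% C %*% a0)
    st$a0 <- a0
    st$I4 <- I4
    st$lam_fiber <- sqrt(I4)
  }
  structure(st, class = "deformation_state")
}

#' @export
print.deformation_state <- function(x, ...) {
  cat("<deformation_state>\n")
  cat(sprintf("  J = %.6g;  I1 = %.6g, I2 = %.6g, I3 = %.6g\n",
              x$J, x$I1, x$I2, x$I3))
  if (!is.null(x$a0))
    cat(sprintf("  fiber: I4 = %.6g, lambda = %.6g\n", x$I4, x$lam_fiber))
  invisible(x)
}
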