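#' @importFrom rlang %||%
#' @importFrom ggplot2 autoplot
NULL

#' Finite-strain kinematics from a deformation gradient
#'
#' Computes the volume ratio J, right/left Cauchy-Green tensors, their
#' modified (unimodular) counterparts from the isochoric-volumetric split
#' `F = (J^(1/3) I) F_bar`, the modified first invariant `I1_bar = tr(C_bar)`,
#' and the modified fourth invariants `I4_bar = a0i . C_bar . a0i` (squared
#' isochoric fiber stretches) for each fiber family.
#'
#' @param F A 3 x 3 deformation gradient with `det(F) > 0`.
#' @param fibers A [fiber_set()].
#' @return An object of class `deformation`: list with `F`, `J`, `C`, `B`,
#'   `C_bar`, `B_bar`, `I1_bar`, `I4_bar` (named over `a01`..`a04`), `fibers`.
#' @examples
#' d <- deformation(diag(c(1.2, 1.2, 1 / 1.44)))
#' d$J        # 1
#' d$I4_bar   # all 1.44 at alpha = 30
#' @export
deformation <- function(F, fibers = fiber_set()) {
  if (!is.matrix(F) || !all(dim(F) == c(3, 3)) || any(!is.finite(F))) {
    stop("`F` must be a finite 3 x 3 matrix.", call. = FALSE)
  }
  J <- det(F)
  if (J <= 0) stop("`det(F)` must be > 0 (no reflections or collapse).", call. = FALSE)
  C <- crossprod(F)          # t(F) %*% F
  B <- tcrossprod(F)         # F %*% t(F)
  C_bar <- J^(-2 / 3) * C
  B_bar <- J^(-2 / 3) * B
  I1_bar <- sum(diag(C_bar))
  dirs <- fibers$directions
  I4_bar <- vapply(rownames(dirs), function(nm) {
    a <- dirs[nm, ]
    drop(a %*% C_bar %*% a)
  }, numeric(1))
  structure(
    list(F = F, J = J, C = C, B = B, C_bar = C_bar, B_bar = B_bar,
         I1_bar = I1_bar, I4_bar = I4_bar, fibers = fibers),
    class = "deformation"
  )
}

#' @export
print.deformation <- function(x, ...) {
  cat(sprintf("<deformation> J = %.6g, I1_bar = %.6g\n", x$J, x$I1_bar))
  cat("I4_bar:", paste(sprintf("%s = %.6g", names(x$I4_bar), x$I4_bar),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Stretch from Green-Lagrange strain
#'
#' `lambda = sqrt(2 E + 1)`, the conversion used when strains are measured by
#' digital image correlation.
#'
#' @param E Green-Lagrange strain(s), `E >= -0.5`.
#' @return Stretch(es) lambda.
#' @examples
#' stretch_from_green_lagrange(c(0, 1.5))  # 1, 2
#' @export
stretch_from_green_lagrange <- function(E) {
  if (any(!is.finite(E)) || any(E < -0.5)) {
    stop("Green-Lagrange strain must be finite and >= -0.5.", call. = FALSE)
  }
  sqrt(2 * E + 1)
}

#' @rdname stretch_from_green_lagrange
#' @param lambda Stretch(es), > 0.
#' @export
green_lagrange_from_stretch <- function(lambda) {
  if (any(!is.finite(lambda)) || any(lambda <= 0)) {
    stop("Stretch must be finite and > 0.", call. = FALSE)
  }
  (lambda^2 - 1) / 2
}

#' Membrane true (Cauchy) stress from axial force
#'
#' Under incompressibility the current cross-section of a square membrane
#' specimen loaded in-plane is `L * T / lambda`, so the true stress is
#' `sigma = P * lambda / (L * T)`.
#'
#' @param P Axial force (N).
#' @param lambda Stretch in the loading direction.
#' @param L Specimen edge length (mm).
#' @param T Specimen thickness (mm).
#' @return True stress in MPa.
#' @examples
#' membrane_true_stress(10, 1.3, 40, 1.188)  # ~0.2736 MPa
#' @export
membrane_true_stress <- function(P, lambda, L, T) {
  if (any(L <= 0) || any(T <= 0)) stop("`L` and `T` must be > 0.", call. = FALSE)
  if (any(lambda <= 0)) stop("`lambda` must be > 0.", call. = FALSE)
  P * lambda / (L * T)
}

#' @rdname membrane_true_stress
#' @param sigma True stress (MPa).
#' @export
membrane_force <- function(sigma, lambda, L, T) {
  if (any(L <= 0) || any(T <= 0)) stop("`L` and `T` must be > 0.", call. = FALSE)
  if (any(lambda <= 0)) stop("`lambda` must be > 0.", call. = FALSE)
  sigma * L * T / lambda
}
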