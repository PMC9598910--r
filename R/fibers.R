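#' Collagen fiber family directions
#'
#' Builds the reference directions of the four collagen fiber families of the
#' intestinal wall: `a01` along the longitudinal axis (e1, longitudinal
#' muscular layer), `a02` along the circumferential axis (e2, circumferential
#' muscular layer), and the crosswise submucosal pair `a03`, `a04` at
#' `+alpha_deg` / `-alpha_deg` to e1 in the e1-e2 plane.
#'
#' @param alpha_deg Submucosal fiber half-angle in degrees, in `[0, 90)`.
#'   Defaults to 30, the histologically measured crosswise arrangement.
#'
#' @return An object of class `fiber_set`: a list with `directions` (a 4 x 3
#'   matrix of unit row vectors named `a01`..`a04`) and `alpha_deg`.
#' @examples
#' fs <- fiber_set(30)
#' fs$directions["a03", ]  # (sqrt(3)/2, 1/2, 0)
#' @export
fiber_set <- function(alpha_deg = 30) {
  if (!is.numeric(alpha_deg) || length(alpha_deg) != 1 || !is.finite(alpha_deg)) {
    stop("`alpha_deg` must be a single finite number.", call. = FALSE)
  }
  if (alpha_deg < 0 || alpha_deg >= 90) {
    stop("`alpha_deg` must lie in [0, 90).", call. = FALSE)
  }
  a <- alpha_deg * pi / 180
  directions <- rbind(
    a01 = c(1, 0, 0),
    a02 = c(0, 1, 0),
    a03 = c(cos(a), sin(a), 0),
    a04 = c(cos(a), -sin(a), 0)
  )
  colnames(directions) <- c("e1", "e2", "e3")
  structure(list(directions = directions, alpha_deg = alpha_deg),
            class = "fiber_set")
}

#' @export
print.fiber_set <- function(x, ...) {
  cat("<fiber_set> alpha =", x$alpha_deg, "deg\n")
  print(round(x$directions, 6))
  invisible(x)
}
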