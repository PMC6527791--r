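#' Velocity-gradient tensor with derived strain and vorticity parts
#'
#' Wraps a 3x3 velocity-gradient matrix `g[i, j] = du_i/dx_j` (units 1/s) and
#' exposes its symmetric (strain `S`) and antisymmetric (vorticity `W`) parts.
#' Planar (2-D) gradients are embedded with a zero third row and column, so
#' every downstream operator works on the full 3x3 tensor.
#'
#' @param g numeric 3x3 matrix (or 2x2, which is zero-embedded) of velocity
#'   derivatives, `g[i, j] = du_i/dx_j` in 1/s.
#' @return An object of class `gradient_tensor`: a list with elements `g`,
#'   `S = (g + t(g))/2` and `W = (g - t(g))/2`.
#' @examples
#' G <- gradient_tensor(pure_shear_gradient(10))
#' G$S[1, 2]  # 5
#' @export
gradient_tensor <- function(g) {
  g <- as.matrix(g)
  if (all(dim(g) == c(2L, 2L))) {
    g3 <- matrix(0, 3, 3)
    g3[1:2, 1:2] <- g
    g <- g3
  }
  if (!all(dim(g) == c(3L, 3L)))
    stop("gradient_tensor: 'g' must be a 3x3 (or 2x2) matrix", call. = FALSE)
  if (!all(is.finite(g)))
    stop("gradient_tensor: non-finite entries in the velocity gradient",
         call. = FALSE)
  structure(list(g = g, S = (g + t(g)) / 2, W = (g - t(g)) / 2),
            class = "gradient_tensor")
}

as_gradient_tensor <- function(G) {
  if (inherits(G, "gradient_tensor")) G else gradient_tensor(G)
}

#' @export
print.gradient_tensor <- function(x, ...) {
  cat("<gradient_tensor> |S| =",
      format(smagorinsky_dm(x), digits = 4), "1/s\n")
  print(x$g)
  invisible(x)
}

#' Canonical velocity-gradient building blocks
#'
#' Convenience constructors for the flow archetypes used throughout the
#' closure tests: simple shear `du/dy = gamma`, solid-body rotation at rate
#' `omega` and a diagonal (pure straining) gradient.
#'
#' @param gamma shear rate du/dy (1/s).
#' @param omega rotation rate (1/s).
#' @param d numeric length-3 vector of diagonal entries (1/s).
#' @return A 3x3 numeric matrix.
#' @name canonical-gradient-matrices
NULL

#' @rdname canonical-gradient-matrices
#' @export
pure_shear_gradient <- function(gamma) {
  g <- matrix(0, 3, 3); g[1, 2] <- gamma; g
}

#' @rdname canonical-gradient-matrices
#' @export
rotation_gradient <- function(omega) {
  g <- matrix(0, 3, 3); g[1, 2] <- -omega; g[2, 1] <- omega; g
}

#' @rdname canonical-gradient-matrices
#' @export
diagonal_gradient <- function(d) diag(as.numeric(d), 3, 3)

#' Q-criterion vortex indicator
#'
#' `Q = (|W|^2 - |S|^2) / 2` with Frobenius norms of the vorticity and strain
#' tensors; positive where rotation dominates strain, which is the standard
#' criterion for extracting coherent vortex cores from a resolved velocity
#' field.
#'
#' @param G a [gradient_tensor()] (or a raw 3x3/2x2 matrix).
#' @return Scalar Q in 1/s^2.
#' @examples
#' q_criterion(rotation_gradient(2))   # 4: rotation-dominated
#' q_criterion(pure_shear_gradient(5)) # 0: shear is strain/rotation balanced
#' @export
q_criterion <- function(G) {
  G <- as_gradient_tensor(G)
  (sum(G$W^2) - sum(G$S^2)) / 2
}
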