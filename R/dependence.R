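#' Admissible range of the third pairwise correlation
#'
#' With three latent detection processes there are three pairwise Pearson
#' correlations. Fixing two of them, the third cannot vary freely over
#' \[-1, 1\]: positive semidefiniteness of the 3x3 correlation matrix
#' restricts it to
#' \deqn{r_{xy} r_{xz} \pm \sqrt{(1 - r_{xy}^2)(1 - r_{xz}^2)}.}
#'
#' @param r_xy,r_xz Correlations in \[-1, 1\]; vectors are recycled.
#'
#' @return A tibble with columns `r_xy`, `r_xz`, `lower`, `upper`.
#' @examples
#' admissible_range(0, 0)       # (-1, 1)
#' admissible_range(-0.5, -0.5) # (-0.5, 1): -0.5 sits exactly on the boundary
#' @export
admissible_range <- function(r_xy, r_xz) {
  if (any(abs(r_xy) > 1, na.rm = TRUE) || any(abs(r_xz) > 1, na.rm = TRUE)) {
    abort("Correlations must lie in [-1, 1].")
  }
  half <- sqrt(pmax((1 - r_xy^2) * (1 - r_xz^2), 0))
  tibble::tibble(
    r_xy = r_xy, r_xz = r_xz,
    lower = pmax(r_xy * r_xz - half, -1),
    upper = pmin(r_xy * r_xz + half, 1)
  )
}

# Smallest eigenvalue of the unit-diagonal symmetric 3x3 correlation matrix
# with off-diagonals (a, b, c) = (r_xy, r_xz, r_yz), by the closed-form
# trigonometric solution for symmetric 3x3 eigenvalues. Vectorized; used for
# dense admissibility grids. base::eigen is the cross-check in the tests.
smallest_eigenvalue3 <- function(r_xy, r_xz, r_yz) {
  p2 <- 2 * (r_xy^2 + r_xz^2 + r_yz^2)
  p <- sqrt(p2 / 6)
  # det((M - I)/p) for unit-diagonal M is 2*r_xy*r_xz*r_yz / p^3
  r <- ifelse(p > 0, pmin(pmax(r_xy * r_xz * r_yz / p^3, -1), 1), 0)
  phi <- acos(r) / 3
  ifelse(p > 0, 1 + 2 * p * cos(phi + 2 * pi / 3), 1)
}

#' Is a trivariate correlation matrix admissible?
#'
#' A triple (r_xy, r_xz, r_yz) is admissible iff the implied unit-diagonal
#' 3x3 matrix is positive semidefinite (smallest eigenvalue >= `-tol`); this
#' is equivalent to r_yz lying in [admissible_range()]. Exact-boundary
#' matrices (e.g. the equicorrelated triple at -0.5, smallest eigenvalue 0)
#' are admissible; the fully countermonotone triple (-1, -1, -1) is not.
#'
#' @param r_xy,r_xz,r_yz Correlations in \[-1, 1\]; vectors are recycled.
#' @param tol Non-negative slack on the smallest eigenvalue, default 1e-10,
#'   so that exact-boundary (singular) matrices are admitted.
#'
#' @return A tibble with columns `r_xy`, `r_xz`, `r_yz`, `min_eigenvalue`,
#'   `admissible`.
#' @examples
#' is_admissible(-0.5, -0.5, -0.5) # admissible, eigenvalue 0
#' is_admissible(-1, -1, -1)       # not constructible
#' @export
is_admissible <- function(r_xy, r_xz, r_yz, tol = 1e-10) {
  if (any(abs(c(r_xy, r_xz, r_yz)) > 1, na.rm = TRUE)) {
    abort("Correlations must lie in [-1, 1].")
  }
  lam <- smallest_eigenvalue3(r_xy, r_xz, r_yz)
  tibble::tibble(
    r_xy = r_xy, r_xz = r_xz, r_yz = r_yz,
    min_eigenvalue = lam,
    admissible = lam >= -tol
  )
}

# Build the 3x3 correlation matrix for modalities (A, V, S) from a triple.
correlation_matrix <- function(r_AV, r_AS, r_VS) {
  m <- diag(3)
  dimnames(m) <- list(MODALITIES, MODALITIES)
  m["A", "V"] <- m["V", "A"] <- r_AV
  m["A", "S"] <- m["S", "A"] <- r_AS
  m["V", "S"] <- m["S", "V"] <- r_VS
  m
}

# Validate a correlation matrix: symmetric, unit diagonal, entries in [-1,1].
check_correlation_matrix <- function(m) {
  if (!is.matrix(m) || !identical(dim(m), c(3L, 3L))) {
    abort("`correlation` must be a 3x3 matrix.")
  }
  if (max(abs(m - t(m))) > 1e-12) abort("`correlation` must be symmetric.")
  if (max(abs(diag(m) - 1)) > 1e-12) abort("`correlation` must have unit diagonal.")
  if (any(abs(m) > 1 + 1e-12)) abort("Correlations must lie in [-1, 1].")
  invisible(m)
}
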