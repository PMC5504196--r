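# Gaussian-copula machinery for correlated Erlang channel latencies.
#
# Draws are built by mapping trivariate standard normals through pnorm and the
# Erlang quantile function. The Pearson correlation of the gamma margins is an
# attenuated, strictly increasing function of the latent normal correlation;
# because all three channels share the integer shape and correlation is
# scale-free, the map depends on the shape only. It is computed once per shape
# by 2-D Gauss-Hermite quadrature and inverted by monotone interpolation.

.copula_cache <- new.env(parent = emptyenv())

# Tail-safe Erlang quantile of Phi(z): works for |z| far into the tails.
erlang_qnorm_transform <- function(z, shape) {
  qgamma(pnorm(z, lower.tail = FALSE), shape = shape, rate = 1,
         lower.tail = FALSE)
}

# Pearson correlation of two unit-rate Erlang(shape) margins coupled by a
# Gaussian copula with latent correlation rho. Vectorized over rho.
pearson_from_latent <- function(rho, shape, nodes = 48) {
  gh <- pracma::gaussHermite(nodes)
  z <- sqrt(2) * gh$x
  w <- gh$w / sqrt(pi)
  g <- erlang_qnorm_transform(z, shape)
  mu <- sum(w * g)
  v <- sum(w * g^2) - mu^2
  vapply(rho, function(r) {
    if (r >= 1) return(1)
    if (r <= -1) r <- -1
    g2 <- erlang_qnorm_transform(outer(r * z, sqrt(1 - r^2) * z, "+"), shape)
    as.numeric((crossprod(w * g, g2) %*% w - mu^2) / v)
  }, numeric(1))
}

copula_map <- function(shape) {
  key <- as.character(shape)
  if (!is.null(.copula_cache[[key]])) return(.copula_cache[[key]])
  latent <- sort(unique(c(seq(-1, 1, by = 0.02), c(-0.999, -0.99, 0.99, 0.999))))
  achieved <- pearson_from_latent(latent, shape)
  achieved[latent == 0] <- 0
  achieved[latent == 1] <- 1
  map <- list(latent = latent, achieved = achieved, floor = achieved[1])
  .copula_cache[[key]] <- map
  map
}

#' Latent copula correlation for a target Pearson correlation
#'
#' Inverts the shape-specific map from latent Gaussian-copula correlation to
#' the Pearson correlation of Erlang(shape) margins. The attainable Pearson
#' range is `[countermonotone floor, 1]`; the floor is above -1 for skewed
#' margins (about -0.80 at shape 2).
#'
#' @param r Target Pearson correlation(s) of the latencies.
#' @param shape Common integer shape of the channel Erlang distributions.
#'
#' @return Numeric vector of latent normal correlations.
#' @examples
#' latent_from_pearson(-0.42, shape = 2)
#' @export
latent_from_pearson <- function(r, shape) {
  map <- copula_map(shape)
  if (any(r < map$floor - 1e-6 | r > 1)) {
    abort(sprintf(
      "Target Pearson correlation outside the attainable range [%.4f, 1] for shape %d margins under a Gaussian copula.",
      map$floor, as.integer(shape)))
  }
  out <- stats::approx(map$achieved, map$latent, xout = pmax(r, map$floor),
                       rule = 2, ties = "ordered")$y
  out[r == 0] <- 0
  out
}

# Symmetric PSD square root; negative eigenvalues (numerical or from
# projection) floored at zero.
psd_sqrt <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors)
}

# Project a symmetric matrix to the nearest unit-diagonal PSD matrix by
# eigenvalue clipping followed by diagonal renormalization.
project_psd_correlation <- function(m, tol = 1e-10) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= -tol) return(m)
  m2 <- e$vectors %*% diag(pmax(e$values, 0)) %*% t(e$vectors)
  d <- sqrt(diag(m2))
  m2 <- m2 / tcrossprod(d)
  dimnames(m2) <- dimnames(m)
  (m2 + t(m2)) / 2
}

# Resolve a requested Pearson correlation matrix for the latencies into a
# latent copula matrix, clamping to the attainable/PSD set if necessary.
# Returns list(latent, achieved, clamped).
resolve_copula_correlation <- function(target, shape) {
  check_correlation_matrix(target)
  off <- c(target["A", "V"], target["A", "S"], target["V", "S"])
  adm <- is_admissible(off[1], off[2], off[3])
  if (!adm$admissible) {
    abort(sprintf(
      paste0("Requested correlations (r_AV = %.3f, r_AS = %.3f, r_VS = %.3f) do not form a ",
             "positive-semidefinite matrix: smallest eigenvalue %.4g. ",
             "Each coefficient must lie in the Stanley-Wang range implied by the other two ",
             "(see admissible_range())."),
      off[1], off[2], off[3], adm$min_eigenvalue))
  }
  map <- copula_map(shape)
  clamped <- any(off < map$floor - 1e-6)
  off_target <- pmax(off, map$floor)
  lat <- latent_from_pearson(off_target, shape)
  latent <- correlation_matrix(lat[1], lat[2], lat[3])
  lat_min <- smallest_eigenvalue3(lat[1], lat[2], lat[3])
  if (lat_min < -1e-10) {
    latent <- project_psd_correlation(latent)
    clamped <- TRUE
  }
  ach <- pearson_from_latent(
    c(latent["A", "V"], latent["A", "S"], latent["V", "S"]), shape)
  achieved <- correlation_matrix(ach[1], ach[2], ach[3])
  if (clamped) {
    warn(sprintf(
      paste0("Requested latency correlations are not exactly attainable with a Gaussian ",
             "copula on Erlang(shape = %d) margins; the latent matrix was clamped to the ",
             "admissible set. Achieved Pearson correlations: r_AV = %.3f, r_AS = %.3f, ",
             "r_VS = %.3f."),
      as.integer(shape), ach[1], ach[2], ach[3]))
  } else if (max(abs(ach - off)) > 0.02) {
    warn("Copula calibration residual exceeds 0.02; inspect achieved correlations.")
  }
  list(latent = latent, achieved = achieved, clamped = clamped)
}
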