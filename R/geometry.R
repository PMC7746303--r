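# Low-level 3D geometry: rigid transforms, quaternion least-squares
# superposition, and the ideal L-alanine template used to reconstruct
# glycine's virtual C-beta.

#' @keywords internal
.vnorm <- function(v) sqrt(sum(v * v))

#' @keywords internal
.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' @keywords internal
.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-9) stop("degenerate geometry: zero-length vector")
  v / n
}

# Ideal L-alanine fragment (N, CA, C, O, CB), CA at the origin, N-CA-C in the
# xy-plane. Bond lengths/angles follow standard peptide geometry
# (N-CA 1.458 A, CA-C 1.525 A, N-CA-C 111.2 deg); CB is placed by the
# standard tetrahedral construction and sits ~1.53 A from CA.
#' @keywords internal
.idealAlanine <- local({
  n  <- c(1.458, 0, 0)
  ca <- c(0, 0, 0)
  ang <- 111.2 * pi / 180
  cc <- 1.525 * c(cos(ang), sin(ang), 0)
  # virtual C-beta: tetrahedral placement from the backbone frame
  b <- ca - n
  k <- cc - ca
  a <- .cross3(b, k)
  cb <- -0.58273431 * a + 0.56802827 * b - 0.54067466 * k + ca
  # carbonyl O in the backbone plane, CA-C-O ~ 120.8 deg, C-O 1.231 A
  u <- .unit(cc - ca)
  w <- .unit(.cross3(c(0, 0, 1), u))
  oang <- (180 - 120.8) * pi / 180
  o <- cc + 1.231 * (cos(oang) * u + sin(oang) * w)
  m <- rbind(N = n, CA = ca, C = cc, O = o, CB = cb)
  colnames(m) <- c("x", "y", "z")
  m
})

#' Ideal alanine template coordinates
#'
#' The prototypic L-alanine fragment (atoms N, CA, C, O, CB; CA at the
#' origin) used both to reconstruct glycine's virtual C-beta and to emit
#' backbone atoms in the synthetic structure generator.
#'
#' @return A 5 x 3 numeric matrix with rownames N, CA, C, O, CB.
#' @export
idealAlanine <- function() .idealAlanine

# Quaternion (Horn) least-squares superposition of paired point sets.
# Returns the proper rotation R and translation t minimising
# sum | R x_i + t - y_i |^2, plus the minimised RMSD.
#' @keywords internal
.quaternionSuperpose <- function(x, y) {
  stopifnot(is.matrix(x), is.matrix(y), nrow(x) == nrow(y), ncol(x) == 3L)
  n <- nrow(x)
  if (n < 3L) stop("degenerate superposition: need at least 3 point pairs")
  cx <- colMeans(x)
  cy <- colMeans(y)
  xc <- sweep(x, 2L, cx)
  yc <- sweep(y, 2L, cy)
  S <- crossprod(xc, yc)  # S[a, b] = sum_i x_a * y_b
  K <- matrix(0, 4L, 4L)
  K[1L, 1L] <- S[1L, 1L] + S[2L, 2L] + S[3L, 3L]
  K[1L, 2L] <- K[2L, 1L] <- S[2L, 3L] - S[3L, 2L]
  K[1L, 3L] <- K[3L, 1L] <- S[3L, 1L] - S[1L, 3L]
  K[1L, 4L] <- K[4L, 1L] <- S[1L, 2L] - S[2L, 1L]
  K[2L, 2L] <- S[1L, 1L] - S[2L, 2L] - S[3L, 3L]
  K[2L, 3L] <- K[3L, 2L] <- S[1L, 2L] + S[2L, 1L]
  K[2L, 4L] <- K[4L, 2L] <- S[3L, 1L] + S[1L, 3L]
  K[3L, 3L] <- -S[1L, 1L] + S[2L, 2L] - S[3L, 3L]
  K[3L, 4L] <- K[4L, 3L] <- S[2L, 3L] + S[3L, 2L]
  K[4L, 4L] <- -S[1L, 1L] - S[2L, 2L] + S[3L, 3L]
  e <- eigen(K, symmetric = TRUE)
  q <- e$vectors[, 1L]
  R <- .quatToRot(q)
  # evaluate the minimised RMSD from the residuals under the optimal
  # rotation rather than from sqrt(g - 2*lambda_max), which cancels
  # catastrophically for near-identical sets
  resid <- yc - xc %*% t(R)
  rmsd <- sqrt(sum(resid * resid) / n)
  t <- cy - as.vector(R %*% cx)
  list(rotation = R, translation = t, rmsd = rmsd)
}

#' @keywords internal
.quatToRot <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    w * w + x * x - y * y - z * z, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w * w - x * x + y * y - z * z, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w * w - x * x - y * y + z * z),
    3L, 3L, byrow = TRUE)
}

#' @keywords internal
.applyRigid <- function(coords, rotation, translation = c(0, 0, 0)) {
  sweep(coords %*% t(rotation), 2L, translation, `+`)
}

#' @keywords internal
.randomRotation <- function() {
  # uniform random rotation from a normalised Gaussian quaternion
  q <- stats::rnorm(4L)
  .quatToRot(q / .vnorm(q))
}

#' Reconstruct glycine's virtual C-beta
#'
#' Glycine has no C-beta atom, yet the sidechain representative point of
#' every amino acid is its C-beta. The virtual position is obtained by
#' least-squares superposition of a prototypic L-alanine (its N, CA, C
#' atoms) onto the glycine backbone and transplanting the alanine C-beta.
#' The construction is equivariant under rigid motion of the inputs.
#'
#' @param n,ca,c Numeric length-3 coordinates (Angstrom) of the backbone
#'   N, C-alpha and C atoms.
#' @return Numeric length-3 coordinate of the virtual C-beta.
#' @export
#' @examples
#' tmpl <- idealAlanine()
#' cb <- reconstructGlyCb(tmpl["N", ], tmpl["CA", ], tmpl["C", ])
#' sqrt(sum((cb - tmpl["CB", ])^2))  # ~0: identity superposition
reconstructGlyCb <- function(n, ca, c) {
  pts <- rbind(n, ca, c)
  if (any(!is.finite(pts))) stop("degenerate geometry: non-finite backbone coordinates")
  v1 <- n - ca
  v2 <- c - ca
  if (.vnorm(.cross3(v1, v2)) < 1e-6)
    stop("degenerate geometry: collinear N/CA/C backbone")
  tmpl <- .idealAlanine
  fit <- .quaternionSuperpose(tmpl[c("N", "CA", "C"), ], pts)
  as.vector(fit$rotation %*% tmpl["CB", ] + fit$translation)
}
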