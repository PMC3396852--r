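#' Similarity transforms between scan spaces
#'
#' A `similarity_transform` maps coordinates from one scan space into
#' another as `y = s * R %*% x + t`: a proper rotation `R` (3 x 3,
#' det = +1), a translation `t` (mm) and a positive isotropic scale `s`.
#' With `s = 1` this is a rigid-body motion, the expected case for pre/post
#' scan pairs acquired on the same scanner.
#'
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation numeric length-3 translation vector (mm).
#' @param scale positive scalar scale factor.
#' @return An object of class `similarity_transform` with elements
#'   `rotation`, `translation`, `scale`.
#' @seealso [horn_register()], [apply_transform()]
#' @export
similarity_transform <- function(rotation = diag(3),
                                 translation = c(0, 0, 0),
                                 scale = 1) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  scale <- as.numeric(scale)
  stopifnot(length(translation) == 3L, length(scale) == 1L)
  if (!all(is.finite(rotation)) || !all(is.finite(translation)) ||
      !is.finite(scale)) {
    stop("transform components must be finite", call. = FALSE)
  }
  if (scale <= 0) stop("scale factor must be positive", call. = FALSE)
  assert_rotation(rotation)
  structure(list(rotation = rotation, translation = translation,
                 scale = scale),
            class = "similarity_transform")
}

# Orthonormality and handedness check shared by constructors and IO.
assert_rotation <- function(r, tol = 1e-9) {
  if (max(abs(crossprod(r) - diag(3))) > tol || abs(det(r) - 1) > tol) {
    stop("rotation matrix must be orthonormal with determinant +1",
         call. = FALSE)
  }
  invisible(r)
}

#' @export
print.similarity_transform <- function(x, ...) {
  ang <- decompose_rotation(x$rotation)
  cat("<similarity_transform>\n")
  cat(sprintf("  scale       : %.9g\n", x$scale))
  cat(sprintf("  translation : (%.4f, %.4f, %.4f) mm\n",
              x$translation[1], x$translation[2], x$translation[3]))
  cat(sprintf("  rotation    : alpha=%.6f beta=%.6f gamma=%.6f rad (%s)\n",
              ang["alpha"], ang["beta"], ang["gamma"], euler_convention()))
  invisible(x)
}

#' Apply a similarity transform to a point set
#'
#' Maps every point `p` to `s * R %*% p + t`, preserving labels and order.
#' This is the forward map from pre-operative to post-operative space once
#' the transform has been estimated with [horn_register()].
#'
#' @param transform a [similarity_transform()].
#' @param points a [point_set()], or a numeric n x 3 matrix / length-3
#'   vector of raw coordinates.
#' @return The transformed points, of the same type as the input.
#' @examples
#' tr <- similarity_transform(translation = c(1, 2, 3))
#' apply_transform(tr, c(0, 0, 0))
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "similarity_transform"))
  if (inherits(points, "point_set")) {
    out <- points
    out$coords <- transform_coords(transform, points$coords)
    return(out)
  }
  if (is.null(dim(points))) {
    stopifnot(length(points) == 3L)
    return(drop(transform_coords(transform, matrix(points, 1, 3))))
  }
  transform_coords(transform, points)
}

transform_coords <- function(transform, m) {
  out <- transform$scale * (m %*% t(transform$rotation))
  out <- sweep(out, 2L, transform$translation, "+")
  colnames(out) <- c("x", "y", "z")
  out
}

#' Euler-angle composition and decomposition
#'
#' The package's fixed Euler convention is intrinsic rotations applied in
#' the order `R = Rx(alpha) %*% Ry(beta) %*% Rz(gamma)` about the sagittal
#' (x), coronal (y) and axial (z) axes respectively, angles in radians.
#' `compose_euler_rotation()` builds the rotation matrix;
#' `decompose_rotation()` inverts it. Away from gimbal lock
#' (`|beta| = pi/2`) the round trip is exact to numerical precision; at
#' gimbal lock the decomposition returns the canonical representative with
#' `alpha = 0`.
#'
#' @param alpha,beta,gamma rotation angles in radians about x, y, z.
#' @return `compose_euler_rotation()`: a 3 x 3 rotation matrix.
#'   `decompose_rotation()`: a named numeric vector
#'   `c(alpha=, beta=, gamma=)`.
#' @examples
#' r <- compose_euler_rotation(0.3, -0.2, 0.1)
#' decompose_rotation(r)
#' @export
compose_euler_rotation <- function(alpha, beta, gamma) {
  stopifnot(is.finite(alpha), is.finite(beta), is.finite(gamma))
  ca <- cos(alpha); sa <- sin(alpha)
  cb <- cos(beta);  sb <- sin(beta)
  cg <- cos(gamma); sg <- sin(gamma)
  rx <- matrix(c(1, 0, 0,  0, ca, -sa,  0, sa, ca), 3, 3, byrow = TRUE)
  ry <- matrix(c(cb, 0, sb,  0, 1, 0,  -sb, 0, cb), 3, 3, byrow = TRUE)
  rz <- matrix(c(cg, -sg, 0,  sg, cg, 0,  0, 0, 1), 3, 3, byrow = TRUE)
  rx %*% ry %*% rz
}

#' @rdname compose_euler_rotation
#' @param rotation a 3 x 3 rotation matrix.
#' @export
decompose_rotation <- function(rotation) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  assert_rotation(rotation)
  # R[1,3] = sin(beta); R[1,1] = cos(beta)cos(gamma); R[2,3] = -sin(alpha)cos(beta)
  sb <- max(-1, min(1, rotation[1, 3]))
  if (abs(sb) > 1 - 1e-12) {
    # gimbal lock: only alpha +/- gamma is determined; pick alpha = 0
    beta <- if (sb > 0) pi / 2 else -pi / 2
    alpha <- 0
    gamma <- atan2(rotation[2, 1], rotation[2, 2])
  } else {
    beta <- asin(sb)
    gamma <- atan2(-rotation[1, 2], rotation[1, 1])
    alpha <- atan2(-rotation[2, 3], rotation[3, 3])
  }
  c(alpha = alpha, beta = beta, gamma = gamma)
}

euler_convention <- function() "intrinsic Rx(alpha)*Ry(beta)*Rz(gamma), x=sagittal y=coronal z=axial"

#' Read and write transform JSON files
#'
#' Transforms (optionally with their registration residuals) are exchanged
#' as JSON with keys `rotation` (row-major 3 x 3), `translation_mm`,
#' `scale`, `residual_e_mm`, `per_point_residuals_mm` and `convention`
#' (a fixed string documenting the Euler axis order).
#'
#' @param x a `similarity_transform` or a `registration_result`.
#' @param path file path.
#' @return `read_transform()` returns a `similarity_transform` (with
#'   attributes `residual_e` and `per_point_residuals` if present in the
#'   file); `write_transform()` returns `path` invisibly.
#' @export
write_transform <- function(x, path) {
  res_e <- NULL; res_pp <- NULL
  if (inherits(x, "registration_result")) {
    res_e <- x$residual_e
    res_pp <- x$per_point_residuals
    x <- x$transform
  }
  stopifnot(inherits(x, "similarity_transform"))
  obj <- list(
    rotation = as.numeric(t(x$rotation)),   # row-major
    translation_mm = x$translation,
    scale = x$scale,
    residual_e_mm = res_e,
    per_point_residuals_mm = res_pp,
    convention = euler_convention()
  )
  obj <- obj[!vapply(obj, is.null, logical(1))]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- similarity_transform(
    rotation = matrix(as.numeric(obj$rotation), 3, 3, byrow = TRUE),
    translation = as.numeric(obj$translation_mm),
    scale = as.numeric(obj$scale)
  )
  if (!is.null(obj$residual_e_mm)) {
    attr(tr, "residual_e") <- as.numeric(obj$residual_e_mm)
  }
  if (!is.null(obj$per_point_residuals_mm)) {
    attr(tr, "per_point_residuals") <- as.numeric(obj$per_point_residuals_mm)
  }
  tr
}
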