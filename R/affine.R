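#' Rotation + anisotropic scale + translation in the image plane
#'
#' The transform acts on 0-based pixel-centre coordinates `(x, y)` (x along
#' columns, y along rows) as `T(p) = R(rotation) %*% diag(scale_x, scale_y)
#' %*% p + t`. The object also stores the exact linear matrix so that
#' inverses and compositions (which need not lie in the
#' rotation-times-diagonal-scale family when scaling is anisotropic) remain
#' exact; the named parameters are then the nearest decomposition.
#'
#' Convention (as in ITK-style registration): the transform returned by
#' [fit_affine()] and consumed by [apply_affine()] maps points of the *fixed*
#' image domain into the *moving* image domain, i.e. it is the resampling
#' transform that, pulled back through [apply_affine()], registers the moving
#' image onto the fixed one. With the ~0.9x extra magnification of the Fluo-4
#' detection path this is a transform with `scale_x = scale_y = 0.9`, matching
#' the conventional description "the Fluo-4 channel is demagnified by 0.9x".
#'
#' @param rotation_deg Rotation angle, degrees (counter-clockwise in x-y).
#' @param scale_x,scale_y Scale factors along x and y; must be positive.
#' @param tx_px,ty_px Translation in pixels.
#' @return An object of class `affine_params`.
#' @export
affine_params <- function(rotation_deg = 0, scale_x = 1, scale_y = 1,
                          tx_px = 0, ty_px = 0) {
  stopifnot(is.finite(rotation_deg), scale_x > 0, scale_y > 0,
            is.finite(tx_px), is.finite(ty_px))
  th <- rotation_deg * pi / 180
  M <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2) %*%
    diag(c(scale_x, scale_y))
  new_affine(M, c(tx_px, ty_px))
}

# internal constructor from an exact matrix + offset; named fields are the
# nearest rotation-scale decomposition (exact when M is of that form)
new_affine <- function(M, t) {
  sx <- sqrt(M[1, 1]^2 + M[2, 1]^2)
  sy <- sqrt(M[1, 2]^2 + M[2, 2]^2)
  th1 <- atan2(M[2, 1], M[1, 1])
  th2 <- atan2(-M[1, 2], M[2, 2])
  th <- atan2(sin(th1) + sin(th2), cos(th1) + cos(th2))
  structure(list(rotation_deg = th * 180 / pi, scale_x = sx, scale_y = sy,
                 tx_px = t[1], ty_px = t[2], matrix = M,
                 offset = c(t[1], t[2])),
            class = "affine_params")
}

#' @export
print.affine_params <- function(x, ...) {
  cat(sprintf(
    "affine_params: rot=%.4f deg, scale=(%.4f, %.4f), t=(%.3f, %.3f) px\n",
    x$rotation_deg, x$scale_x, x$scale_y, x$tx_px, x$ty_px))
  invisible(x)
}

#' Apply an affine transform to point coordinates
#'
#' @param params An [affine_params()] object.
#' @param pts N x 2 matrix of `(x, y)` coordinates (0-based pixel centres),
#'   or a length-2 vector for a single point.
#' @return N x 2 matrix of transformed coordinates.
#' @export
transform_points <- function(params, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  pts <- as.matrix(pts)
  stopifnot(ncol(pts) == 2)
  sweep(pts %*% t(params$matrix), 2, params$offset, "+")
}

#' Invert an affine transform
#'
#' Exact matrix inverse; `compose_affine(params, invert_affine(params))` is
#' the identity to machine precision.
#'
#' @param params An [affine_params()] object.
#' @return The inverse transform as `affine_params`.
#' @export
invert_affine <- function(params) {
  Minv <- solve(params$matrix)
  new_affine(Minv, -as.vector(Minv %*% params$offset))
}

#' Compose two affine transforms
#'
#' `compose_affine(a, b)` returns the transform `T(p) = a(b(p))`.
#'
#' @param a,b [affine_params()] objects.
#' @return An `affine_params` object.
#' @export
compose_affine <- function(a, b) {
  M <- a$matrix %*% b$matrix
  t_ab <- as.vector(a$matrix %*% b$offset) + a$offset
  new_affine(M, t_ab)
}

#' Fit a rotation + scale + translation transform to corresponding points
#'
#' Estimates the resampling transform `T` minimising
#' `sum || points_moving - T(points_fixed) ||^2` by linear least squares on
#' the full affine model followed by projection onto the
#' rotation-times-anisotropic-scale family (exact when the correspondence is
#' generated by such a transform). At least three non-collinear
#' correspondences are required.
#'
#' @param points_moving N x 2 `(x, y)` coordinates in the moving image (the
#'   channel that will be resampled, e.g. Fluo-4).
#' @param points_fixed N x 2 coordinates of the same features in the fixed
#'   (reference) image, e.g. the CMO channel.
#' @return An `affine_params` object with attribute `residual_rms` (pixels).
#' @export
fit_affine <- function(points_moving, points_fixed) {
  pm <- as.matrix(points_moving); pf <- as.matrix(points_fixed)
  stopifnot(ncol(pm) == 2, ncol(pf) == 2, nrow(pm) == nrow(pf))
  if (nrow(pm) < 3) stop("affine fit needs at least 3 corresponding points")
  cf <- sweep(pf, 2, colMeans(pf))
  sv <- svd(cf)$d
  if (sv[2] < 1e-8 * max(sv[1], 1)) {
    stop("affine fit is degenerate: fixed points are collinear")
  }
  X <- cbind(pf, 1)
  beta <- qr.solve(X, pm)           # 3 x 2: full affine, moving ~ M pf + t
  M <- t(beta[1:2, ])
  params0 <- new_affine(M, beta[3, ])
  # rebuild the linear part from the projected parameters, then re-estimate
  # the translation under that constrained linear part
  params <- affine_params(params0$rotation_deg, params0$scale_x,
                          params0$scale_y, 0, 0)
  tvec <- colMeans(pm) - colMeans(pf %*% t(params$matrix))
  params$tx_px <- tvec[1]; params$ty_px <- tvec[2]
  params$offset <- tvec
  res <- pm - transform_points(params, pf)
  attr(params, "residual_rms") <- sqrt(mean(res^2))
  params
}

# Vectorized bilinear sampling of a matrix at 0-based (x, y) positions;
# outside the image the value is 0.
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  gather <- function(xi, yi) {
    ok <- xi >= 0 & xi <= nc - 1 & yi >= 0 & yi <= nr - 1
    v <- numeric(length(xi))
    v[ok] <- img[cbind(yi[ok] + 1, xi[ok] + 1)]
    v
  }
  gather(x0, y0) * (1 - fx) * (1 - fy) +
    gather(x0 + 1, y0) * fx * (1 - fy) +
    gather(x0, y0 + 1) * (1 - fx) * fy +
    gather(x0 + 1, y0 + 1) * fx * fy
}

nearest_sample <- function(img, x, y) {
  xi <- round(x); yi <- round(y)
  ok <- xi >= 0 & xi <= ncol(img) - 1 & yi >= 0 & yi <= nrow(img) - 1
  v <- numeric(length(xi))
  v[ok] <- img[cbind(yi[ok] + 1, xi[ok] + 1)]
  v
}

#' Resample an image through an affine transform
#'
#' Pull-back resampling: output pixel at 0-based position `p` takes the value
#' of the input image at `T(p)`. With `params` fitted by [fit_affine()]
#' (moving = this image), the output is the moving image registered onto the
#' fixed image's grid. The output has the same shape as the input;
#' out-of-bounds samples are 0.
#'
#' @param image Numeric matrix.
#' @param params An [affine_params()] object.
#' @param interpolation `"bilinear"` (default) or `"nearest"`.
#' @return Resampled matrix of the same shape.
#' @export
apply_affine <- function(image, params,
                         interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(is.matrix(image))
  nr <- nrow(image); nc <- ncol(image)
  g <- expand.grid(y = 0:(nr - 1), x = 0:(nc - 1))
  p <- transform_points(params, cbind(g$x, g$y))
  v <- switch(interpolation,
              bilinear = bilinear_sample(image, p[, 1], p[, 2]),
              nearest = nearest_sample(image, p[, 1], p[, 2]))
  matrix(v, nr, nc)
}

#' Write affine parameters to JSON
#'
#' @param params An [affine_params()] object.
#' @param path Output file path.
#' @export
write_affine_json <- function(params, path) {
  x <- unclass(params)[c("rotation_deg", "scale_x", "scale_y",
                         "tx_px", "ty_px")]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read affine parameters from JSON
#'
#' @param path File written by [write_affine_json()].
#' @return An `affine_params` object.
#' @export
read_affine_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  affine_params(x$rotation_deg, x$scale_x, x$scale_y, x$tx_px, x$ty_px)
}
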