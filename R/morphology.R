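#' Spherical structuring element
#'
#' The digital Euclidean ball of radius `R`: all integer offsets within
#' `[-R, R]^3` whose Euclidean norm is at most `R`. `Sphere(1)` is the
#' 7-voxel cross (centre plus the 6 face neighbours), which is also the
#' neighbourhood the wavefront advances by at each iteration.
#'
#' @param R Integer radius >= 1.
#' @return Logical 3D array of side `2R + 1`, `TRUE` inside the ball.
#' @export
sphere_element <- function(R) {
  R <- as.integer(R)
  if (is.na(R) || R < 1L) stop("sphere_element: R must be an integer >= 1")
  ax <- -R:R
  g <- expand.grid(x = ax, y = ax, z = ax)
  inside <- g$x^2 + g$y^2 + g$z^2 <= R^2
  array(inside, dim = rep(2L * R + 1L, 3L))
}

# n x 3 integer offset matrix of a sphere element (for the C++ kernels)
sphere_offsets <- function(R) {
  el <- sphere_element(R)
  idx <- which(el, arr.ind = TRUE)
  matrix(as.integer(idx - (R + 1L)), ncol = 3L)
}

as_mask <- function(x) {
  if (is.logical(x)) return(x)
  array(x != 0L, dim = dim(x))
}

#' Binary dilation, erosion and closing with a spherical element
#'
#' 3D binary morphology on logical masks. Out-of-bounds voxels are treated
#' as background, so erosion (and hence closing) is computed with zero
#' padding.
#'
#' @param mask Logical 3D array.
#' @param R Radius of the spherical structuring element (integer >= 1), or
#'   an explicit n x 3 integer offset matrix via `offsets`.
#' @param offsets Optional n x 3 offset matrix overriding `R`.
#' @return Logical 3D array of the same shape.
#' @export
dilate_mask <- function(mask, R = 1L, offsets = NULL) {
  if (is.null(offsets)) offsets <- sphere_offsets(R)
  out <- cpp_dilate(as_mask(mask), as.integer(dim(mask)), offsets)
  array(out, dim = dim(mask))
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(mask, R = 1L, offsets = NULL) {
  if (is.null(offsets)) offsets <- sphere_offsets(R)
  out <- cpp_erode(as_mask(mask), as.integer(dim(mask)), offsets)
  array(out, dim = dim(mask))
}

#' @rdname dilate_mask
#' @export
close_mask <- function(mask, R = 1L, offsets = NULL) {
  if (is.null(offsets)) offsets <- sphere_offsets(R)
  erode_mask(dilate_mask(mask, offsets = offsets), offsets = offsets)
}

#' Label connected components of a binary mask
#'
#' Deterministic labelling: components are numbered 1..n in column-major
#' scan order of their first voxel.
#'
#' @param mask Logical 3D array.
#' @param connectivity 6 (face) or 26 (face, edge and corner).
#' @return Integer 3D array of labels; 0 is background.
#' @export
label_components <- function(mask, connectivity = 26L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L))
    stop("label_components: connectivity must be 6 or 26")
  out <- cpp_label(as_mask(mask), as.integer(dim(mask)), connectivity)
  array(out, dim = dim(mask))
}

#' Fill interior holes of a binary mask
#'
#' Sets to foreground every 6-connected background component that does not
#' reach the array border; background connected to the border is left
#' unchanged, so open-ended structures (e.g. the lumen of a tube crossing
#' the crop) are not filled.
#'
#' @param X Logical 3D array.
#' @return Logical 3D array containing `X`.
#' @export
fill_holes <- function(X) {
  m <- as_mask(X)
  reach <- array(cpp_border_background(m, as.integer(dim(m))), dim = dim(m))
  m | (!m & !reach)
}
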