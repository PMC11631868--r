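#' Affine subject-to-composite transform
#'
#' A 4x4 homogeneous affine mapping subject voxel coordinates (0-based)
#' into the composite/atlas grid. The inverse is precomputed and the
#' round trip checked.
#'
#' @param mat 4x4 numeric matrix; last row `(0, 0, 0, 1)`.
#' @param subject subject identifier (used in error messages).
#' @return an object of class `subject_transform` with `mat` and `inv`.
#' @export
subject_transform <- function(mat = diag(4), subject = "s1") {
  mat <- as.matrix(mat)
  if (!identical(dim(mat), c(4L, 4L)))
    stop_validation("transform for subject %s must be 4x4", subject)
  det_ <- det(mat)
  if (!is.finite(det_) || abs(det_) < 1e-12)
    stop_validation("singular transform for subject %s", subject)
  inv <- solve(mat)
  if (max(abs(mat %*% inv - diag(4))) > 1e-8)
    stop_validation("transform for subject %s does not invert cleanly", subject)
  structure(list(mat = mat, inv = inv, subject = subject),
            class = "subject_transform")
}

# trilinear interpolation of 3D array `vol` at fractional 0-based
# coordinates (n x 3 matrix); outside the grid -> NA
trilinear <- function(vol, coords) {
  d <- dim(vol)
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  # clamp the upper corner so points exactly on the last plane still work
  x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
  z1 <- pmin(z0 + 1, d[3] - 1)
  inside <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 &
    z >= 0 & z <= d[3] - 1
  at <- function(i, j, k) vol[cbind(i + 1, j + 1, k + 1)]
  out <- rep(NA_real_, nrow(coords))
  if (any(inside)) {
    i <- inside
    c000 <- at(x0[i], y0[i], z0[i]); c100 <- at(x1[i], y0[i], z0[i])
    c010 <- at(x0[i], y1[i], z0[i]); c110 <- at(x1[i], y1[i], z0[i])
    c001 <- at(x0[i], y0[i], z1[i]); c101 <- at(x1[i], y0[i], z1[i])
    c011 <- at(x0[i], y1[i], z1[i]); c111 <- at(x1[i], y1[i], z1[i])
    w <- function(a, b, f) a * (1 - f) + b * f
    cz0 <- w(w(c000, c100, fx[i]), w(c010, c110, fx[i]), fy[i])
    cz1 <- w(w(c001, c101, fx[i]), w(c011, c111, fx[i]), fy[i])
    out[i] <- w(cz0, cz1, fz[i])
  }
  out
}

#' Group composite percent-change map
#'
#' Each composite voxel location is mapped into every subject's native
#' grid through the inverse of that subject's transform, the subject's
#' percent-change value is sampled there by trilinear interpolation, and
#' the composite value is the mean of the available contributions.
#' Locations falling outside a subject's grid (or on invalid voxels)
#' simply contribute nothing for that subject.
#'
#' @param maps list of 3D percent-change arrays (one per subject).
#' @param transforms list of [subject_transform()] objects (subject to
#'   composite), same length as `maps`.
#' @param dim_out integer dimensions of the composite grid; default the
#'   first map's grid.
#' @return 3D numeric array; voxels with no contribution are `NA`.
#' @export
composite_map <- function(maps, transforms = NULL, dim_out = NULL) {
  if (!length(maps)) stop_validation("no subject maps supplied")
  if (is.null(transforms))
    transforms <- replicate(length(maps),
                            subject_transform(diag(4)), simplify = FALSE)
  if (length(transforms) != length(maps))
    stop_validation("need one transform per subject map")
  if (is.null(dim_out)) dim_out <- dim(maps[[1]])
  grid <- as.matrix(expand.grid(x = 0:(dim_out[1] - 1),
                                y = 0:(dim_out[2] - 1),
                                z = 0:(dim_out[3] - 1)))
  acc <- numeric(nrow(grid))
  n <- numeric(nrow(grid))
  hom <- cbind(grid, 1)
  for (j in seq_along(maps)) {
    subj_xyz <- hom %*% t(transforms[[j]]$inv)
    vals <- trilinear(maps[[j]], subj_xyz[, 1:3, drop = FALSE])
    ok <- !is.na(vals)
    acc[ok] <- acc[ok] + vals[ok]
    n[ok] <- n[ok] + 1
  }
  out <- ifelse(n > 0, acc / n, NA_real_)
  array(out, dim = dim_out)
}
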