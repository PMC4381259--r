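#' Voxel grid specification
#'
#' Defines the sampling grid of a PET volume: array dimensions and isotropic
#' or anisotropic voxel spacing in millimetres. Voxel `(i, j, k)` has its
#' centre at `((i, j, k) - 0.5) * spacing` so the volume occupies
#' `[0, dim * spacing]` in each axis.
#'
#' @param dim integer length-3 array dimensions (voxels).
#' @param spacing numeric length-3 voxel spacing in mm, all positive.
#' @return A list of class `pet_grid` with elements `dim` and `spacing`.
#' @examples
#' pet_grid(c(64, 64, 80), c(4, 4, 4))
#' @export
pet_grid <- function(dim = c(128L, 128L, 160L), spacing = c(4, 4, 4)) {
  dim <- as.integer(dim)
  spacing <- as.numeric(spacing)
  if (length(dim) != 3L || any(dim < 1L)) {
    abort("`dim` must be three positive integers.")
  }
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three positive voxel sizes in mm.")
  }
  structure(list(dim = dim, spacing = spacing), class = "pet_grid")
}

#' @export
print.pet_grid <- function(x, ...) {
  cat(sprintf(
    "<pet_grid> %d x %d x %d voxels @ %.4g x %.4g x %.4g mm\n",
    x$dim[1], x$dim[2], x$dim[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  invisible(x)
}

voxel_volume_ml <- function(spacing) prod(spacing) / 1000

# Physical coordinates (mm) of voxel centres along one axis.
axis_centers <- function(n, sp) (seq_len(n) - 0.5) * sp

# Inclusive index range of voxel centres falling in [lo, hi] along one axis.
axis_range <- function(n, sp, lo, hi) {
  i0 <- max(1L, as.integer(ceiling(lo / sp + 0.5 - 1e-9)))
  i1 <- min(n, as.integer(floor(hi / sp + 0.5 + 1e-9)))
  if (i0 > i1) integer(0) else i0:i1
}

# Voxels (linear indices) whose centres satisfy a geometric predicate, with
# the predicate only evaluated inside the shape's bounding box. Returns an
# integer vector; optionally also a per-voxel field (used for lesion
# profiles via the normalised ellipsoidal radius).
geometry_voxels <- function(dim, spacing, shape, center_mm, size_mm,
                            with_rho2 = FALSE) {
  shape <- match.arg(shape, c("sphere", "box", "cylinder", "ellipsoid"))
  if (any(!is.finite(center_mm)) || length(center_mm) != 3L) {
    abort("`center_mm` must be a finite 3-vector.")
  }
  if (any(!is.finite(size_mm)) || any(size_mm <= 0)) {
    abort("shape dimensions must be positive and finite.")
  }
  half <- switch(shape,
    sphere = rep(size_mm[1] / 2, 3),
    box = size_mm / 2,
    cylinder = c(size_mm[1] / 2, size_mm[1] / 2, size_mm[2] / 2),
    ellipsoid = size_mm
  )
  rng <- lapply(1:3, function(a) {
    axis_range(dim[a], spacing[a], center_mm[a] - half[a], center_mm[a] + half[a])
  })
  if (any(lengths(rng) == 0L)) {
    return(if (with_rho2) list(idx = integer(0), rho2 = numeric(0)) else integer(0))
  }
  ax <- lapply(1:3, function(a) axis_centers(dim[a], spacing[a])[rng[[a]]] - center_mm[a])
  keep_field <- switch(shape,
    sphere = {
      r2 <- (size_mm[1] / 2)^2
      d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
      list(keep = d2 <= r2, rho2 = d2 / r2)
    },
    ellipsoid = {
      rho2 <- outer(
        outer((ax[[1]] / size_mm[1])^2, (ax[[2]] / size_mm[2])^2, "+"),
        (ax[[3]] / size_mm[3])^2, "+"
      )
      list(keep = rho2 <= 1, rho2 = rho2)
    },
    box = {
      keep <- outer(
        outer(abs(ax[[1]]) <= half[1], abs(ax[[2]]) <= half[2], "&"),
        abs(ax[[3]]) <= half[3], "&"
      )
      list(keep = keep, rho2 = NULL)
    },
    cylinder = {
      r2 <- (size_mm[1] / 2)^2
      inplane <- outer(ax[[1]]^2, ax[[2]]^2, "+") <= r2
      keep <- outer(inplane, abs(ax[[3]]) <= half[3], "&")
      list(keep = keep, rho2 = NULL)
    }
  )
  loc <- which(keep_field$keep, arr.ind = TRUE)
  if (nrow(loc) == 0L) {
    return(if (with_rho2) list(idx = integer(0), rho2 = numeric(0)) else integer(0))
  }
  nx <- dim[1]; nxy <- dim[1] * dim[2]
  gi <- (rng[[1]][1] - 1L) + loc[, 1]
  gj <- (rng[[2]][1] - 1L) + loc[, 2]
  gk <- (rng[[3]][1] - 1L) + loc[, 3]
  idx <- gi + (gj - 1L) * nx + (gk - 1L) * nxy
  if (with_rho2) {
    list(idx = idx, rho2 = keep_field$rho2[keep_field$keep])
  } else {
    idx
  }
}

# Does a sphere lie entirely inside the physical volume?
sphere_inside <- function(dim, spacing, center_mm, radius_mm) {
  extent <- dim * spacing
  all(center_mm - radius_mm >= 0) && all(center_mm + radius_mm <= extent)
}

grid_of <- function(x) pet_grid(dim(x$voxels %||% x$activity), x$spacing)

same_geometry <- function(a, b) {
  identical(dim(a$voxels %||% a$activity), dim(b$voxels %||% b$activity)) &&
    isTRUE(all.equal(a$spacing, b$spacing))
}
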