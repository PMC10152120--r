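#' Voxel-phantom specification
#'
#' Defines a simple 3-D digital phantom: ellipsoidal or spherical hot
#' objects on a low uniform background, used to exercise the threshold
#' segmentation and SUV conversion stages without real SPECT data.
#'
#' @param grid_shape Integer vector of 3 voxel counts.
#' @param voxel_size_mm Isotropic voxel spacing in mm.
#' @param objects List of objects, each a list with `shape` (`"sphere"` or
#'   `"ellipsoid"`), `center` (voxel coordinates, may be fractional),
#'   `radii` (one radius in voxels for a sphere, three for an ellipsoid)
#'   and `concentration` (activity concentration, kBq/ml, >= 0). Objects
#'   must lie fully inside the grid.
#' @param background_concentration Uniform background level, kBq/ml.
#' @param body_weight_kg,injected_activity_MBq Patient-level quantities for
#'   SUV conversion of phantom voxel values.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(grid_shape, voxel_size_mm, objects = list(),
                         background_concentration = 0,
                         body_weight_kg = 80, injected_activity_MBq = 6000) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1),
            voxel_size_mm > 0, background_concentration >= 0,
            body_weight_kg > 0, injected_activity_MBq > 0)
  for (ob in objects) {
    shape <- match.arg(ob$shape, c("sphere", "ellipsoid"))
    radii <- if (shape == "sphere") rep(ob$radii[1], 3) else ob$radii
    stopifnot(length(ob$center) == 3, length(radii) == 3,
              all(radii > 0), ob$concentration >= 0)
    if (any(ob$center - radii < 1) || any(ob$center + radii > grid_shape))
      stop("object extends outside the grid", call. = FALSE)
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm, objects = objects,
                 background_concentration = background_concentration,
                 body_weight_kg = body_weight_kg,
                 injected_activity_MBq = injected_activity_MBq),
            class = "phantom_spec")
}

object_mask <- function(spec, ob) {
  d <- spec$grid_shape
  radii <- if (ob$shape == "sphere") rep(ob$radii[1], 3) else ob$radii
  cx <- (seq_len(d[1]) - ob$center[1]) / radii[1]
  cy <- (seq_len(d[2]) - ob$center[2]) / radii[2]
  cz <- (seq_len(d[3]) - ob$center[3]) / radii[3]
  outer(outer(cx^2, cy^2, `+`), cz^2, `+`) <= 1
}

#' Build decayed 3-D activity grids from a phantom specification
#'
#' Paints each object into the grid (later objects overwrite earlier ones
#' where they overlap, with a warning) and decays each voxel to the
#' requested times with its object's half-life.
#'
#' @param spec A [phantom_spec()].
#' @param half_life_h Effective half-life in hours per object (recycled if
#'   scalar).
#' @param times_h Times post injection at which grids are produced.
#' @param background_half_life_h Half-life applied to background voxels
#'   (default `Inf`, i.e. constant background).
#' @return Named list (one element per time, names `"t<hours>"`) of 3-D
#'   arrays of activity concentration.
#' @export
build_phantom <- function(spec, half_life_h, times_h,
                          background_half_life_h = Inf) {
  stopifnot(inherits(spec, "phantom_spec"), all(times_h >= 0),
            all(half_life_h > 0))
  nob <- length(spec$objects)
  half_life_h <- rep_len(half_life_h, max(nob, 1L))
  conc0 <- array(spec$background_concentration, spec$grid_shape)
  which_obj <- array(0L, spec$grid_shape)
  for (i in seq_len(nob)) {
    m <- object_mask(spec, spec$objects[[i]])
    if (any(which_obj[m] > 0))
      warning("objects overlap; later object wins", call. = FALSE)
    conc0[m] <- spec$objects[[i]]$concentration
    which_obj[m] <- i
  }
  hl <- array(background_half_life_h, spec$grid_shape)
  for (i in seq_len(nob)) hl[which_obj == i] <- half_life_h[i]
  out <- lapply(times_h, function(t) conc0 * 2^(-t / hl))
  names(out) <- paste0("t", times_h)
  out
}

#' Fixed-threshold segmentation with 26-connectivity
#'
#' Thresholds the grid at `fraction` of the maximum voxel value found inside
#' `seed_region`, then keeps the 26-connected component that contains that
#' maximum voxel. This is the fixed-threshold VOI segmentation used for
#' kidneys (20% of maximum by default).
#'
#' @param grid 3-D numeric array.
#' @param seed_region Optional logical array of the same shape restricting
#'   where the maximum is sought (default: whole grid).
#' @param fraction Threshold as a fraction of the regional maximum, in
#'   `[0, 1]`. `fraction = 0` selects the whole connected non-zero region;
#'   `fraction = 1` selects only the maximal voxel(s).
#' @return Logical 3-D mask.
#' @export
segment_fixed_threshold <- function(grid, seed_region = NULL,
                                    fraction = 0.20) {
  stopifnot(is.array(grid), length(dim(grid)) == 3,
            fraction >= 0, fraction <= 1)
  dims <- dim(grid)
  if (is.null(seed_region)) seed_region <- array(TRUE, dims)
  stopifnot(identical(dim(seed_region), dims))
  vals <- ifelse(seed_region, grid, -Inf)
  mx <- max(vals)
  if (!is.finite(mx) || mx <= 0)
    stop("seed region contains no positive voxels", call. = FALSE)
  cand <- grid >= fraction * mx & grid > 0
  seed_idx <- which(vals == mx)[1]
  # breadth-first flood fill over the 26-neighborhood
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  mask <- array(FALSE, dims)
  mask[seed_idx] <- TRUE
  frontier <- arrayInd(seed_idx, dims)
  while (nrow(frontier) > 0) {
    nb <- frontier[rep(seq_len(nrow(frontier)), each = nrow(offs)), ,
                   drop = FALSE] +
      offs[rep(seq_len(nrow(offs)), nrow(frontier)), , drop = FALSE]
    keep <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nb <- nb[keep, , drop = FALSE]
    lin <- unique((nb[, 3] - 1) * dims[1] * dims[2] +
                    (nb[, 2] - 1) * dims[1] + nb[, 1])
    lin <- lin[cand[lin] & !mask[lin]]
    mask[lin] <- TRUE
    frontier <- arrayInd(lin, dims)
  }
  mask
}

#' Total activity inside a voxel mask
#'
#' @param grid 3-D array of activity concentration in kBq/ml.
#' @param mask Logical mask of the same shape.
#' @param voxel_size_mm Isotropic voxel spacing, mm.
#' @return Activity in kBq: sum of masked voxel values times voxel volume
#'   in ml (1 ml = 1000 mm^3).
#' @export
mask_activity_kBq <- function(grid, mask, voxel_size_mm) {
  stopifnot(identical(dim(grid), dim(mask)), voxel_size_mm > 0)
  sum(grid[mask]) * voxel_size_mm^3 / 1000
}

#' Convert activity concentration to SUV
#'
#' Body-weight standardized uptake value with unit-density tissue
#' (1 g/ml), so SUV = C[kBq/ml] * BW[g] / A_inj[kBq].
#'
#' @param concentration_kBq_per_ml Activity concentration, kBq/ml.
#' @param injected_activity_MBq Injected activity, MBq, > 0.
#' @param body_weight_kg Body weight, kg, > 0.
#' @return Dimensionless SUV (vectorized over the concentration).
#' @export
concentration_to_suv <- function(concentration_kBq_per_ml,
                                 injected_activity_MBq, body_weight_kg) {
  if (any(concentration_kBq_per_ml < 0) || injected_activity_MBq <= 0 ||
      body_weight_kg <= 0)
    stop("inputs must be positive (concentration non-negative)",
         call. = FALSE)
  concentration_kBq_per_ml * body_weight_kg / injected_activity_MBq
}

#' Write / read phantom grids as NIfTI volumes
#'
#' Thin wrappers over RNifti preserving the voxel spacing, so phantom
#' volumes can be exchanged with external imaging software.
#'
#' @param grid 3-D array.
#' @param path Output `.nii` / `.nii.gz` path.
#' @param voxel_size_mm Isotropic voxel spacing, mm.
#' @return `write_phantom_nifti` returns `path` invisibly;
#'   `read_phantom_nifti` returns a plain 3-D array with attribute
#'   `voxel_size_mm`.
#' @export
write_phantom_nifti <- function(grid, path, voxel_size_mm) {
  img <- RNifti::asNifti(grid)
  RNifti::pixdim(img) <- rep(voxel_size_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_phantom_nifti
#' @export
read_phantom_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "voxel_size_mm") <- RNifti::pixdim(img)[1]
  out
}
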