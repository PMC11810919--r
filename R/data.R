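#' Patient-grouped dataset splitting
#'
#' Partitions samples into train/validation/test sets at the patient level
#' (never splitting a patient's slices across partitions), with patient
#' counts given by largest-remainder rounding of the requested fractions.
#' Ties in the remainders are broken in partition order train > val > test.
#' The split is invariant to sample order: patients are sorted before the
#' seeded shuffle.
#'
#' @param samples List of \code{\link{new_sample}} objects.
#' @param fractions Numeric length-3 vector (train, val, test); must be
#'   positive and sum to 1. The default is the 54/6/40 split.
#' @param seed Integer seed for the patient shuffle.
#' @return A named list of sample lists: \code{train}, \code{val},
#'   \code{test}.
#' @export
split_by_patient <- function(samples, fractions = c(0.54, 0.06, 0.40),
                             seed = 1L) {
  if (length(fractions) != 3 || any(fractions <= 0))
    stop("fractions must be three positive numbers", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1", call. = FALSE)
  ids <- sort(unique(vapply(samples, function(s) s$patient_id, character(1))))
  if (length(ids) < 3)
    stop("need at least 3 distinct patients to split", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  ids <- sample(ids)
  counts <- largest_remainder(length(ids), fractions)
  part_of <- stats::setNames(
    rep(c("train", "val", "test"), counts), ids)
  out <- list(train = list(), val = list(), test = list())
  for (s in samples) out[[part_of[[s$patient_id]]]] <-
      c(out[[part_of[[s$patient_id]]]], list(s))
  out
}

# Largest-remainder apportionment of n units over fractions; ties broken by
# position (train > val > test).
largest_remainder <- function(n, fractions) {
  exact <- n * fractions
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(-(exact - base), seq_along(fractions))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Geometric augmentation settings
#'
#' Symmetric ranges for the four augmentation operations applied to
#' training pairs: rotation, shifting, shearing and zooming. Each draw
#' composes one transform from all four; the identical transform is applied
#' to the image (bilinear resampling) and to the mask (nearest-neighbour
#' resampling, so the mask stays strictly binary). Out-of-bounds regions are
#' filled with 0 in both.
#'
#' @param rotation_deg Maximum absolute rotation (degrees).
#' @param shift_frac Maximum absolute shift as a fraction of the side length.
#' @param shear_deg Maximum absolute horizontal shear (degrees).
#' @param zoom_frac Maximum absolute zoom deviation (scale in
#'   \code{1 +/- zoom_frac}); must be > -1.
#' @return An object of class \code{gb_augment_spec}.
#' @export
augment_spec <- function(rotation_deg = 15, shift_frac = 0.10,
                         shear_deg = 10, zoom_frac = 0.10) {
  stopifnot(is.finite(rotation_deg), is.finite(shift_frac),
            is.finite(shear_deg), is.finite(zoom_frac), zoom_frac > -1)
  structure(list(rotation_deg = rotation_deg, shift_frac = shift_frac,
                 shear_deg = shear_deg, zoom_frac = zoom_frac),
            class = "gb_augment_spec")
}

#' Augment one image/mask pair
#'
#' Draws a rotation, shift, shear and zoom from the spec's ranges (using the
#' caller's random stream), composes them into one affine transform about
#' the image centre, and applies it to the pair. The mask is re-binarized at
#' 0.5 after resampling (a no-op for nearest-neighbour sampling, kept as a
#' guarantee).
#'
#' @param s A \code{\link{new_sample}}.
#' @param spec An \code{\link{augment_spec}}.
#' @param rotation_deg,shift_r,shift_c,shear_deg,zoom Optional fixed values
#'   overriding the random draws (used for deterministic transforms).
#' @return An augmented \code{gb_sample} of identical shape.
#' @export
augment_pair <- function(s, spec = augment_spec(),
                         rotation_deg = NULL, shift_r = NULL, shift_c = NULL,
                         shear_deg = NULL, zoom = NULL) {
  stopifnot(inherits(s, "gb_sample"))
  h <- nrow(s$image); w <- ncol(s$image)
  th <- if (is.null(rotation_deg))
    stats::runif(1, -spec$rotation_deg, spec$rotation_deg) else rotation_deg
  sr <- if (is.null(shift_r))
    stats::runif(1, -spec$shift_frac, spec$shift_frac) * h else shift_r
  sc <- if (is.null(shift_c))
    stats::runif(1, -spec$shift_frac, spec$shift_frac) * w else shift_c
  sh <- if (is.null(shear_deg))
    stats::runif(1, -spec$shear_deg, spec$shear_deg) else shear_deg
  zm <- if (is.null(zoom))
    1 + stats::runif(1, -spec$zoom_frac, spec$zoom_frac) else zoom

  th <- th * pi / 180
  sh <- tan(sh * pi / 180)
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  shear <- matrix(c(1, 0, sh, 1), 2, 2)
  fwd <- rot %*% shear %*% diag(c(zm, zm))
  inv <- solve(fwd)
  shift <- -inv %*% c(sr, sc)

  img <- warp_affine_cpp(s$image, inv, as.numeric(shift), TRUE, 0)
  msk <- warp_affine_cpp(s$mask, inv, as.numeric(shift), FALSE, 0)
  msk <- (msk >= 0.5) + 0
  new_sample(img, msk, s$patient_id)
}

#' Expand a training set with augmented copies
#'
#' Keeps every original sample and appends \code{copies_per_sample}
#' independently augmented copies of each; reproducible given the seed.
#'
#' @param samples List of \code{gb_sample}s.
#' @param spec An \code{\link{augment_spec}}.
#' @param copies_per_sample Non-negative integer.
#' @param seed Integer seed.
#' @return A list of length \code{length(samples) * (1 + copies_per_sample)}.
#' @export
expand_training_set <- function(samples, spec = augment_spec(),
                                copies_per_sample = 1L, seed = 1L) {
  stopifnot(copies_per_sample >= 0)
  if (copies_per_sample == 0) return(samples)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  extra <- list()
  for (s in samples)
    for (k in seq_len(copies_per_sample))
      extra <- c(extra, list(augment_pair(s, spec)))
  c(samples, extra)
}
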