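#' Image/mask sample
#'
#' A single training or evaluation unit: a normalized grayscale slice, its
#' binary foreground mask, and the identifier of the patient the slice
#' belongs to (splits are patient-grouped).
#'
#' @param image Numeric matrix in \code{[0,1]}.
#' @param mask Binary matrix (0/1) of the same shape.
#' @param patient_id Opaque identifier (character).
#' @return An object of class \code{gb_sample}.
#' @export
new_sample <- function(image, mask, patient_id) {
  stopifnot(is.matrix(image), is.matrix(mask),
            identical(dim(image), dim(mask)))
  if (!all(mask %in% c(0, 1)))
    stop("mask must be strictly binary", call. = FALSE)
  structure(list(image = image, mask = mask,
                 patient_id = as.character(patient_id)),
            class = "gb_sample")
}

#' @export
print.gb_sample <- function(x, ...) {
  cat(sprintf("<gb_sample %s: %dx%d, foreground %.3f%%>\n", x$patient_id,
              nrow(x$image), ncol(x$image), 100 * mean(x$mask)))
  invisible(x)
}

#' Phantom generator settings
#'
#' Parameters of the synthetic gallbladder phantom: a textured "liver-like"
#' bright region on a darker abdominal background, a single hypodense
#' elliptical gallbladder inside the liver whose area targets the extreme
#' class imbalance of clinical gallbladder CT (foreground about 0.55% of
#' pixels), plus hypodense distractor structures — one of them deliberately
#' matched to the gallbladder's intensity — and additive Gaussian noise.
#'
#' @param size Integer pair, image size in pixels (at least 32x32).
#' @param fg_fraction_target Target foreground pixel fraction in (0, 0.5);
#'   default 0.0055, the imbalance the generator is required to emulate.
#' @param contrast Intensity gap between liver parenchyma and the
#'   gallbladder interior (the gallbladder is hypodense on CT).
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param n_background_structures Number of distractor ellipses.
#' @param seed Integer seed; together with a phantom index it fully
#'   determines each phantom.
#' @return An object of class \code{gb_phantom_spec}.
#' @export
phantom_spec <- function(size = c(256L, 256L), fg_fraction_target = 0.0055,
                         contrast = 0.25, noise_sd = 0.05,
                         n_background_structures = 3L, seed = 42L) {
  size <- as.integer(size)
  if (length(size) == 1) size <- c(size, size)
  if (any(size < 32)) stop("size must be at least 32x32", call. = FALSE)
  if (fg_fraction_target <= 0 || fg_fraction_target >= 0.5)
    stop("fg_fraction_target must be in (0, 0.5)", call. = FALSE)
  if (fg_fraction_target * prod(size) < 8)
    stop("fg_fraction_target is unreachable at this size ",
         "(fewer than 8 foreground pixels)", call. = FALSE)
  structure(list(size = size, fg_fraction_target = fg_fraction_target,
                 contrast = contrast, noise_sd = noise_sd,
                 n_background_structures = as.integer(n_background_structures),
                 seed = as.integer(seed)),
            class = "gb_phantom_spec")
}

# Smooth low-frequency texture: bilinear upsampling of a coarse noise grid.
smooth_texture <- function(h, w, coarse = 9L) {
  g <- matrix(stats::rnorm(coarse * coarse), coarse, coarse)
  ri <- seq(1, coarse, length.out = h)
  ci <- seq(1, coarse, length.out = w)
  r0 <- pmin(floor(ri), coarse - 1); fr <- ri - r0
  c0 <- pmin(floor(ci), coarse - 1); fc <- ci - c0
  top <- g[r0, c0] * outer(1 - fr, 1 - fc) + g[r0, c0 + 1] * outer(1 - fr, fc)
  bot <- g[r0 + 1, c0] * outer(fr, 1 - fc) + g[r0 + 1, c0 + 1] * outer(fr, fc)
  top + bot
}

# Logical raster of a filled ellipse (pixel-centre inclusion).
ellipse_mask <- function(h, w, cr, cc, a, b, theta) {
  dr <- outer(seq_len(h) - cr, rep(1, w))
  dc <- outer(rep(1, h), seq_len(w) - cc)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate one synthetic phantom
#'
#' Fully determined by \code{(spec$seed, index)}: the same pair always
#' yields the same sample, and the caller's random stream is left untouched.
#' Phantoms are grouped into synthetic "patients" of
#' \code{slices_per_patient} consecutive indices so that patient-grouped
#' splitting is exercised.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @param index Positive integer phantom index.
#' @param slices_per_patient Phantoms per synthetic patient (default 5).
#' @return A \code{\link{new_sample}} object.
#' @export
make_phantom <- function(spec, index, slices_per_patient = 5L) {
  stopifnot(inherits(spec, "gb_phantom_spec"), index >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed((spec$seed %% 65011) * 32749L + (as.integer(index) %% 32719L) + 11L)

  h <- spec$size[1]; w <- spec$size[2]
  liver_base <- 0.60
  bg_base <- 0.25

  img <- bg_base + 0.06 * smooth_texture(h, w)

  # liver-like bright region
  lcr <- h * stats::runif(1, 0.45, 0.55)
  lcc <- w * stats::runif(1, 0.45, 0.55)
  la <- h * stats::runif(1, 0.30, 0.40)
  lb <- w * stats::runif(1, 0.26, 0.36)
  lth <- stats::runif(1, 0, pi)
  liver <- ellipse_mask(h, w, lcr, lcc, la, lb, lth)
  liver_tex <- liver_base + 0.07 * smooth_texture(h, w)
  img[liver] <- liver_tex[liver]

  gb_value <- liver_base - spec$contrast

  # distractor structures, hypodense, outside the liver where possible;
  # the first one is matched to the gallbladder's intensity to exercise the
  # similar-structure failure mode
  area <- spec$fg_fraction_target * h * w
  for (k in seq_len(spec$n_background_structures)) {
    da <- sqrt(area * stats::runif(1, 1, 3) / pi)
    ratio <- stats::runif(1, 1.1, 2)
    for (try in 1:20) {
      dcr <- stats::runif(1, da * ratio + 2, h - da * ratio - 2)
      dcc <- stats::runif(1, da * ratio + 2, w - da * ratio - 2)
      inside <- ((dcr - lcr) * cos(lth) + (dcc - lcc) * sin(lth))^2 / la^2 +
        (-(dcr - lcr) * sin(lth) + (dcc - lcc) * cos(lth))^2 / lb^2 <= 1
      if (!inside) break
    }
    dm <- ellipse_mask(h, w, dcr, dcc, da * sqrt(ratio), da / sqrt(ratio),
                       stats::runif(1, 0, pi))
    dval <- if (k == 1) gb_value else stats::runif(1, 0.30, 0.45)
    img[dm] <- dval
  }

  # gallbladder: single hypodense ellipse inside the liver, area targeting
  # the imbalance statistic
  ratio <- stats::runif(1, 1.1, 2.2)
  ga <- sqrt(area * ratio / pi)
  gb <- sqrt(area / (pi * ratio))
  gth <- stats::runif(1, 0, pi)
  for (try in 1:50) {
    ang <- stats::runif(1, 0, 2 * pi)
    t <- stats::runif(1, 0.15, 0.65)
    gcr <- lcr + t * la * cos(ang) * cos(lth) - t * lb * sin(ang) * sin(lth)
    gcc <- lcc + t * la * cos(ang) * sin(lth) + t * lb * sin(ang) * cos(lth)
    if (gcr > ga + 2 && gcr < h - ga - 2 && gcc > ga + 2 && gcc < w - ga - 2) break
  }
  gmask <- ellipse_mask(h, w, gcr, gcc, ga, gb, gth)
  img[gmask] <- gb_value + 0.02 * smooth_texture(h, w)[gmask]

  img <- img + stats::rnorm(h * w, 0, spec$noise_sd)
  img <- pmin(pmax(img, 0), 1)

  pid <- sprintf("SYN%04d", 1L + (as.integer(index) - 1L) %/% as.integer(slices_per_patient))
  new_sample(img, gmask + 0, pid)
}

#' Generate a set of phantoms
#'
#' @param n Number of phantoms.
#' @param spec A \code{\link{phantom_spec}}.
#' @param indices Optional explicit phantom indices (default \code{1:n}).
#' @param slices_per_patient Phantoms per synthetic patient.
#' @return A list of \code{gb_sample} objects.
#' @export
phantom_dataset <- function(n, spec = phantom_spec(), indices = seq_len(n),
                            slices_per_patient = 5L) {
  lapply(indices, function(i) make_phantom(spec, i, slices_per_patient))
}

#' Write a phantom set to disk
#'
#' Writes paired image/mask PNGs, a CSV manifest (columns \code{patient_id},
#' \code{image_path}, \code{mask_path}, \code{partition}) and a JSON echo of
#' the generator parameters.
#'
#' @param samples List of \code{gb_sample}s.
#' @param dir Output directory.
#' @param partitions Optional character vector (one entry per sample); the
#'   default marks everything \code{"train"}.
#' @param spec Optional \code{\link{phantom_spec}} echoed to JSON.
#' @return Invisibly, the manifest tibble.
#' @export
write_phantom_set <- function(samples, dir, partitions = NULL, spec = NULL) {
  dir.create(file.path(dir, "images"), showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE, recursive = TRUE)
  if (is.null(partitions)) partitions <- rep("train", length(samples))
  rows <- purrr::imap(samples, function(s, i) {
    ip <- file.path("images", sprintf("slice_%04d.png", i))
    mp <- file.path("masks", sprintf("mask_%04d.png", i))
    write_slice_png(s$image, file.path(dir, ip))
    write_slice_png(s$mask, file.path(dir, mp))
    tibble::tibble(patient_id = s$patient_id, image_path = ip,
                   mask_path = mp, partition = partitions[i])
  })
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (!is.null(spec))
    jsonlite::write_json(unclass(spec), file.path(dir, "phantom_params.json"),
                         auto_unbox = TRUE)
  invisible(manifest)
}

#' Read a manifest of image/mask pairs
#'
#' @param path Path to a manifest CSV with columns \code{patient_id},
#'   \code{image_path}, \code{mask_path}, \code{partition} (paths relative
#'   to the manifest's directory).
#' @return A list of \code{gb_sample}s with a \code{partition} attribute
#'   column accessible via \code{attr(, "manifest")}.
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  base <- dirname(path)
  samples <- lapply(seq_len(nrow(man)), function(i) {
    img <- read_slice_png(file.path(base, man$image_path[i]))
    msk <- round(read_slice_png(file.path(base, man$mask_path[i])))
    new_sample(img, msk, man$patient_id[i])
  })
  attr(samples, "manifest") <- tibble::as_tibble(man)
  samples
}
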