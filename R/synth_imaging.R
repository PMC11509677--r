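#' Elliptical cell mask
#'
#' Labelled mask (single cell, label 1) of an ellipse with the given centre,
#' semi-axes and orientation. Coordinates are row-major with origin top-left
#' and pixel centres at integer coordinates.
#'
#' @param shape c(rows, cols) of the image.
#' @param center c(row, col) of the ellipse centre (default image centre).
#' @param semiaxes c(major, minor) semi-axis lengths in pixels.
#' @param angle orientation of the major axis in radians (0 = along columns).
#' @return Integer matrix mask (0 outside, 1 inside).
#' @export
ellipse_mask <- function(shape = c(256L, 256L), center = shape / 2,
                         semiaxes = c(90, 40), angle = 0) {
  if (2 * max(semiaxes) > min(shape))
    stop("ellipse_mask: mask larger than image")
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  dr <- rr - center[1]; dc <- cc - center[2]
  u <- dr * sin(angle) + dc * cos(angle)   # along major axis
  v <- -dr * cos(angle) + dc * sin(angle)  # along minor axis
  mask <- (u / semiaxes[1])^2 + (v / semiaxes[2])^2 <= 1
  matrix(as.integer(mask), shape[1], shape[2])
}

#' Simulate a polarised cell image with a planted rear/front intensity fold
#'
#' Builds an elliptical cell whose intensity varies along the major axis so
#' that, before noise, the rear-half mean divided by the front-half mean
#' equals \code{rear_fold} exactly. The rear is the half at negative
#' projections along the axis direction. \code{profile = "step"} uses two
#' intensity levels; \code{"ramp"} a linear gradient with the same half-mean
#' ratio.
#'
#' @param shape image size c(rows, cols).
#' @param center,semiaxes,angle ellipse geometry (see
#'   \code{\link{ellipse_mask}}).
#' @param rear_fold planted rear/front mean intensity ratio (> 0).
#' @param base_intensity front-level intensity in arbitrary units.
#' @param background additive background level outside and inside the cell.
#' @param profile \code{"step"} or \code{"ramp"}.
#' @param noise \code{"none"}, \code{"poisson"} (counts) or
#'   \code{"gaussian"}.
#' @param gaussian_sd sd for gaussian noise.
#' @param seed integer RNG seed.
#' @return List: \code{image} (numeric matrix), \code{mask} (labelled
#'   matrix), \code{truth} (list: \code{rear_fold}, \code{axis_angle},
#'   \code{rear_pole} c(row, col), \code{background}).
#' @export
simulate_polarized_cell_image <- function(shape = c(256L, 256L),
                                          center = shape / 2 + 0.5,
                                          semiaxes = c(90, 40),
                                          angle = 0,
                                          rear_fold = 8,
                                          base_intensity = 100,
                                          background = 0,
                                          profile = c("step", "ramp"),
                                          noise = c("none", "poisson", "gaussian"),
                                          gaussian_sd = 5,
                                          seed = 1L) {
  profile <- match.arg(profile)
  noise <- match.arg(noise)
  if (rear_fold <= 0) stop("simulate_polarized_cell_image: rear_fold must be > 0")
  set.seed(seed)
  mask <- ellipse_mask(shape, center, semiaxes, angle)
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  s <- (rr - center[1]) * sin(angle) + (cc - center[2]) * cos(angle)

  img <- matrix(background, shape[1], shape[2])
  inside <- mask == 1
  if (profile == "step") {
    lev <- ifelse(s < 0, base_intensity * rear_fold, base_intensity)
    # guard the exact-centre column so halves stay equal-sized
    lev[s == 0] <- base_intensity * (1 + rear_fold) / 2
  } else {
    # linear ramp a + b*s whose half means are in the planted ratio:
    # halves of the symmetric ellipse have mean projection -+ sbar
    sb <- mean(abs(s[inside]))
    a <- base_intensity * (1 + rear_fold) / 2
    b <- base_intensity * (1 - rear_fold) / (2 * sb)
    lev <- a + b * s
    if (min(lev[inside]) < 0)
      stop("simulate_polarized_cell_image: rear_fold too large for a linear ",
           "ramp (front tip would go negative); use profile = 'step'")
  }
  img[inside] <- img[inside] + lev[inside]

  if (noise == "poisson") {
    img[] <- stats::rpois(length(img), pmax(img, 0))
  } else if (noise == "gaussian") {
    img <- img + stats::rnorm(length(img), 0, gaussian_sd)
  }
  rear_dir <- c(-sin(angle), -cos(angle))
  rear_pole <- center + rear_dir * semiaxes[1]
  list(image = img, mask = mask,
       truth = list(rear_fold = rear_fold, axis_angle = angle,
                    rear_pole = rear_pole, background = background))
}

#' Simulate a proximity-ligation-assay image with planted dots
#'
#' Places \code{n_dots} isotropic Gaussian-profile dots inside an elliptical
#' cell by rejection sampling subject to a minimum pairwise separation
#' (10,000-attempt cap), over a noisy background.
#'
#' @param shape image size c(rows, cols).
#' @param center,semiaxes,angle ellipse geometry.
#' @param n_dots number of dots to plant (>= 0).
#' @param dot_radius Gaussian sigma of each dot, pixels.
#' @param min_separation minimum pairwise centre distance, pixels.
#' @param amplitude peak dot intensity above background.
#' @param background mean background level.
#' @param noise_sd gaussian background noise sd.
#' @param seed integer RNG seed.
#' @return List: \code{image}, \code{mask}, \code{truth} (list:
#'   \code{dot_centres} n x 2 matrix (row, col), \code{dot_count},
#'   \code{background}).
#' @export
simulate_pla_image <- function(shape = c(256L, 256L), center = shape / 2,
                               semiaxes = c(90, 60), angle = 0,
                               n_dots = 12, dot_radius = 2,
                               min_separation = 10, amplitude = 60,
                               background = 10, noise_sd = 2, seed = 1L) {
  set.seed(seed)
  mask <- ellipse_mask(shape, center, semiaxes, angle)
  inside_idx <- which(mask == 1, arr.ind = TRUE)
  centres <- matrix(numeric(0), 0, 2)
  attempts <- 0L
  while (nrow(centres) < n_dots) {
    if (attempts >= 10000L)
      stop("simulate_pla_image: could not place ", n_dots,
           " dots at min_separation ", min_separation,
           " within the attempt cap")
    attempts <- attempts + 1L
    cand <- inside_idx[sample.int(nrow(inside_idx), 1L), ]
    if (nrow(centres) == 0 ||
        all(sqrt(rowSums(sweep(centres, 2, cand)^2)) >= min_separation))
      centres <- rbind(centres, cand)
  }
  img <- background + matrix(stats::rnorm(prod(shape), 0, noise_sd),
                             shape[1], shape[2])
  if (n_dots > 0) {
    rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
    cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    for (i in seq_len(nrow(centres))) {
      d2 <- (rr - centres[i, 1])^2 + (cc - centres[i, 2])^2
      img <- img + amplitude * exp(-d2 / (2 * dot_radius^2))
    }
  }
  dimnames(centres) <- list(NULL, c("row", "col"))
  list(image = img, mask = mask,
       truth = list(dot_centres = centres, dot_count = n_dots,
                    background = background))
}

#' Write a single-channel image as TIFF
#'
#' Intensities are stored as 16-bit samples after scaling by \code{scale}
#' (choose a scale that keeps values within 0..65535). Masks can be written
#' directly with \code{scale = 1}.
#'
#' @param image numeric or integer matrix.
#' @param path output path.
#' @param scale divisor applied before writing (default 65535, i.e. values
#'   are treated as already 16-bit).
#' @return \code{path}, invisibly.
#' @export
write_image_tiff <- function(image, path, scale = 65535) {
  x <- pmin(pmax(image / scale, 0), 1)
  tiff::writeTIFF(x, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a single-channel TIFF written by \code{\link{write_image_tiff}}
#' @param path TIFF path.
#' @param scale multiplier restoring the original intensity scale.
#' @return Numeric matrix.
#' @export
read_image_tiff <- function(path, scale = 65535) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x * scale
}
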