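#' Estimate the front-rear polarity axis of a cell
#'
#' The axis is the principal axis of the second moments of the cell's mask
#' pixels ("the longest cell axis"). The rear pole is the axis end whose half
#' of the cell has the higher mean intensity — the caveolin-enriched pole —
#' unless a manual \code{rear_hint} is given. Near-isotropic masks (axis
#' ratio < 1.05) without a hint are ambiguous and raise an error.
#'
#' @param mask labelled mask; the cell with label \code{label} is analysed.
#' @param image intensity matrix used to pick the rear pole.
#' @param rear_hint optional c(row, col) near the rear; overrides the
#'   intensity rule.
#' @param label cell label in the mask (default 1).
#' @return A list of class \code{"polarity_axis"}: \code{vector} unit c(dr,
#'   dc) pointing rear -> front, \code{centroid}, \code{rear_pole},
#'   \code{front_pole} (mask pixels of extreme projection), \code{length}
#'   (extent along the axis, px), \code{axis_ratio}.
#' @export
estimate_polarity_axis <- function(mask, image, rear_hint = NULL, label = 1L) {
  px <- which(mask == label, arr.ind = TRUE)
  if (nrow(px) < 100)
    stop("estimate_polarity_axis: cell region has fewer than 100 pixels")
  centroid <- colMeans(px)
  cv <- stats::cov(px)
  eig <- eigen(cv, symmetric = TRUE)
  axis_ratio <- sqrt(eig$values[1] / max(eig$values[2], .Machine$double.eps))
  v <- eig$vectors[, 1]
  if (axis_ratio < 1.05 && is.null(rear_hint))
    stop("estimate_polarity_axis: near-isotropic mask (axis ratio ",
         round(axis_ratio, 3), ") is ambiguous; supply rear_hint")
  s <- as.vector((px[, 1] - centroid[1]) * v[1] + (px[, 2] - centroid[2]) * v[2])
  if (!is.null(rear_hint)) {
    sh <- (rear_hint[1] - centroid[1]) * v[1] + (rear_hint[2] - centroid[2]) * v[2]
    if (sh > 0) { v <- -v; s <- -s }
  } else {
    vals <- image[px]
    mean_neg <- mean(vals[s < 0]); mean_pos <- mean(vals[s > 0])
    if (mean_pos > mean_neg) { v <- -v; s <- -s }  # rear = brighter half
  }
  rear_pole <- px[which.min(s), ]
  front_pole <- px[which.max(s), ]
  structure(list(vector = v, centroid = centroid,
                 rear_pole = as.numeric(rear_pole),
                 front_pole = as.numeric(front_pole),
                 length = max(s) - min(s), axis_ratio = axis_ratio),
            class = "polarity_axis")
}

#' Split a cell mask into equal-sized rear and front regions
#'
#' Orders the cell's pixels by their projection on the polarity axis and
#' assigns the rear-most floor(n/2) to the rear region and the front-most
#' floor(n/2) to the front region (the middle pixel of an odd count is
#' dropped), guaranteeing equal pixel counts.
#'
#' @param mask labelled mask.
#' @param axis a \code{polarity_axis}.
#' @param label cell label (default 1).
#' @return List of two logical matrices \code{rear} and \code{front}.
#' @export
split_mask_halves <- function(mask, axis, label = 1L) {
  px <- which(mask == label, arr.ind = TRUE)
  s <- (px[, 1] - axis$centroid[1]) * axis$vector[1] +
    (px[, 2] - axis$centroid[2]) * axis$vector[2]
  ord <- order(s)
  half <- floor(nrow(px) / 2)
  rear <- front <- matrix(FALSE, nrow(mask), ncol(mask))
  rear[px[ord[seq_len(half)], , drop = FALSE]] <- TRUE
  front[px[ord[seq(nrow(px) - half + 1, nrow(px))], , drop = FALSE]] <- TRUE
  list(rear = rear, front = front)
}

#' Rear localisation index
#'
#' Background-subtracted mean intensity of the rear region divided by that of
#' an equal-sized front region — the fold enrichment of signal at the cell
#' rear. If regions are not supplied they are derived by splitting the cell
#' in half along the polarity axis.
#'
#' @param image intensity matrix.
#' @param mask labelled mask.
#' @param rear_region,front_region logical matrices of equal pixel count
#'   (+-1), both inside the cell; derived from \code{axis} when NULL.
#' @param axis optional \code{polarity_axis} (estimated from mask + image if
#'   needed).
#' @param background scalar background level subtracted before the ratio
#'   (subtracted means floor at 0).
#' @param label cell label (default 1).
#' @return The rear/front intensity ratio (scalar).
#' @export
rear_localization_index <- function(image, mask, rear_region = NULL,
                                    front_region = NULL, axis = NULL,
                                    background = 0, label = 1L) {
  if (is.null(rear_region) || is.null(front_region)) {
    if (is.null(axis)) axis <- estimate_polarity_axis(mask, image, label = label)
    halves <- split_mask_halves(mask, axis, label)
    rear_region <- halves$rear; front_region <- halves$front
  }
  n_rear <- sum(rear_region); n_front <- sum(front_region)
  if (abs(n_rear - n_front) > 1)
    stop("rear_localization_index: regions differ by more than one pixel (",
         n_rear, " vs ", n_front, ")")
  if (any(rear_region & mask != label) || any(front_region & mask != label))
    stop("rear_localization_index: regions must lie inside the cell")
  rear_mean <- max(mean(image[rear_region]) - background, 0)
  front_mean <- max(mean(image[front_region]) - background, 0)
  if (front_mean == 0)
    stop("rear_localization_index: front mean is 0; index undefined")
  rear_mean / front_mean
}

#' Line-scan profile and quadrant means along the polarity axis
#'
#' Emulates a wide line drawn from the rear towards the front along the
#' longest cell axis: cell pixels within \code{line_width_px / 2} of the axis
#' line are projected onto the axis, averaged per unit position to give the
#' line profile, and averaged within four equal-length segments ordered
#' rear, centre rear, centre front, front.
#'
#' @param image intensity matrix.
#' @param mask labelled mask.
#' @param axis a \code{polarity_axis}.
#' @param line_width_px width of the scan line in pixels (default 50).
#' @param background scalar background subtracted from intensities.
#' @param label cell label (default 1).
#' @return List: \code{profile} data.frame (position from the rear pole, px;
#'   mean intensity; n_pixels) and \code{quadrant_means} named numeric
#'   (rear, centre_rear, centre_front, front).
#' @export
quadrant_profile <- function(image, mask, axis, line_width_px = 50,
                             background = 0, label = 1L) {
  px <- which(mask == label, arr.ind = TRUE)
  v <- axis$vector
  s <- (px[, 1] - axis$centroid[1]) * v[1] + (px[, 2] - axis$centroid[2]) * v[2]
  d_perp <- abs(-(px[, 1] - axis$centroid[1]) * v[2] +
                  (px[, 2] - axis$centroid[2]) * v[1])
  in_line <- d_perp <= line_width_px / 2
  s <- s[in_line]
  vals <- pmax(image[px[in_line, , drop = FALSE]] - background, 0)
  L <- max(s) - min(s)
  if (L < 4) stop("quadrant_profile: axis extent shorter than 4 px")
  pos <- s - min(s)
  bin <- floor(pos)
  prof <- tapply(vals, bin, mean)
  profile <- data.frame(position = as.numeric(names(prof)) + 0.5,
                        mean_intensity = as.numeric(prof),
                        n_pixels = as.integer(table(bin)))
  quad <- pmin(floor(pos / (L / 4)), 3)
  qm <- tapply(vals, factor(quad, levels = 0:3), mean)
  quadrant_means <- as.numeric(qm)
  names(quadrant_means) <- c("rear", "centre_rear", "centre_front", "front")
  list(profile = profile, quadrant_means = quadrant_means)
}

#' Count proximity-ligation-assay dots per cell
#'
#' Gaussian-smooths the image, thresholds at mean + k * sd of the in-mask
#' pixels, labels 8-connected components, filters them by area, and assigns
#' each dot to the cell containing its centroid. Dots whose centroid falls
#' outside every cell are excluded from the per-cell counts.
#'
#' @param image intensity matrix.
#' @param mask labelled cell mask (any number of cells).
#' @param sigma Gaussian smoothing sigma, px (default 1; 0 disables).
#' @param threshold_k threshold is in-mask mean + threshold_k * sd of the
#'   smoothed image (default 5, conservative enough that pure background
#'   yields no components).
#' @param min_area,max_area component area bounds in pixels.
#' @param threshold optional absolute threshold overriding the rule.
#' @return List of class \code{"pla_counts"}: \code{counts} (named integer
#'   per cell label, zero-filled), \code{n_total} components after area
#'   filtering, \code{centroids} (n x 2), \code{dot_mask} (logical matrix),
#'   \code{threshold}.
#' @export
count_pla_dots <- function(image, mask, sigma = 1, threshold_k = 5,
                           min_area = 2, max_area = Inf, threshold = NULL) {
  sm <- if (sigma > 0) gaussian_smooth(image, sigma) else image
  inmask <- mask > 0
  if (is.null(threshold))
    threshold <- mean(sm[inmask]) + threshold_k * stats::sd(sm[inmask])
  bw <- sm > threshold
  lab <- label_components(bw)
  labels <- sort(unique(mask[mask > 0]))
  counts <- stats::setNames(integer(length(labels)), labels)
  centroids <- matrix(numeric(0), 0, 2,
                      dimnames = list(NULL, c("row", "col")))
  n_total <- 0L
  if (max(lab) > 0) {
    px <- which(lab > 0, arr.ind = TRUE)
    comp <- lab[px]
    areas <- tabulate(comp)
    keep <- which(areas >= min_area & areas <= max_area)
    n_total <- length(keep)
    if (n_total > 0) {
      cr <- tapply(px[, 1], comp, mean)[as.character(keep)]
      cc <- tapply(px[, 2], comp, mean)[as.character(keep)]
      centroids <- cbind(row = as.numeric(cr), col = as.numeric(cc))
      cell <- mask[cbind(pmin(pmax(round(centroids[, 1]), 1), nrow(mask)),
                         pmin(pmax(round(centroids[, 2]), 1), ncol(mask)))]
      tab <- table(cell[cell > 0])
      counts[names(tab)] <- as.integer(tab)
    }
  }
  structure(list(counts = counts, n_total = n_total, centroids = centroids,
                 dot_mask = lab > 0, threshold = threshold),
            class = "pla_counts")
}

gaussian_smooth <- function(image, sigma) {
  # gblur needs a margin; pad by reflection to avoid edge darkening
  pad <- ceiling(4 * sigma)
  padded <- image[c(pmin(pad:1, nrow(image)), seq_len(nrow(image)),
                    nrow(image) - seq_len(pad) + 1),
                  c(pmin(pad:1, ncol(image)), seq_len(ncol(image)),
                    ncol(image) - seq_len(pad) + 1)]
  sm <- EBImage::gblur(padded, sigma = sigma)
  sm[pad + seq_len(nrow(image)), pad + seq_len(ncol(image))]
}

label_components <- function(bw) {
  # 8-connected components via EBImage (which labels across diagonals when
  # the kernel-closed neighbourhood touches); bwlabel is 4-connected, so
  # bridge diagonals explicitly before labelling and restrict afterwards
  lab4 <- EBImage::bwlabel(bw)
  # merge labels that touch diagonally
  merge_pairs <- diag_touches(lab4)
  if (nrow(merge_pairs)) {
    parent <- seq_len(max(lab4))
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (r in seq_len(nrow(merge_pairs))) {
      a <- find(merge_pairs[r, 1]); b <- find(merge_pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    root <- vapply(seq_along(parent), find, 1L)
    relab <- match(root, sort(unique(root)))
    lab4[lab4 > 0] <- relab[lab4[lab4 > 0]]
  }
  storage.mode(lab4) <- "integer"
  lab4
}

diag_touches <- function(lab) {
  n <- nrow(lab); m <- ncol(lab)
  a1 <- lab[-n, -m]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-n, -1]; b2 <- lab[-1, -m]    # down-left diagonal
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  unique(pairs)
}

#' Fraction of PLA dots in the rear of the cell
#'
#' Projects dot centroids onto the polarity axis and reports the fraction
#' falling rear-ward of the stated boundary: the rear quarter of the axis
#' extent (default, matching the line-scan quadrants) or the rear half.
#'
#' @param centroids n x 2 matrix (row, col) of dot centroids.
#' @param axis a \code{polarity_axis}.
#' @param mask labelled mask defining the axis extent.
#' @param boundary \code{"quadrant"} or \code{"half"}.
#' @param label cell label (default 1).
#' @return List: \code{fraction} (NA when no dots), \code{n_dots},
#'   \code{n_rear}, \code{undefined} flag.
#' @export
rear_fraction_of_dots <- function(centroids, axis, mask,
                                  boundary = c("quadrant", "half"),
                                  label = 1L) {
  boundary <- match.arg(boundary)
  if (is.null(centroids) || nrow(centroids) == 0)
    return(list(fraction = NA_real_, n_dots = 0L, n_rear = 0L,
                undefined = TRUE))
  px <- which(mask == label, arr.ind = TRUE)
  v <- axis$vector
  s_mask <- (px[, 1] - axis$centroid[1]) * v[1] +
    (px[, 2] - axis$centroid[2]) * v[2]
  s <- (centroids[, 1] - axis$centroid[1]) * v[1] +
    (centroids[, 2] - axis$centroid[2]) * v[2]
  L <- max(s_mask) - min(s_mask)
  cut <- if (boundary == "quadrant") min(s_mask) + L / 4 else min(s_mask) + L / 2
  n_rear <- sum(s < cut)
  list(fraction = n_rear / nrow(centroids), n_dots = nrow(centroids),
       n_rear = as.integer(n_rear), undefined = FALSE)
}

#' Pearson colocalisation of two channels within a mask
#'
#' @param image_a,image_b intensity matrices of identical shape.
#' @param mask logical or labelled mask; pixels > 0 are used.
#' @return Pearson correlation coefficient over in-mask pixels.
#' @export
pearson_colocalization <- function(image_a, image_b, mask) {
  if (!identical(dim(image_a), dim(image_b)) ||
      !identical(dim(image_a), dim(mask)))
    stop("pearson_colocalization: shapes differ")
  sel <- mask > 0
  a <- image_a[sel]; b <- image_b[sel]
  if (length(a) < 2)
    stop("pearson_colocalization: fewer than 2 in-mask pixels")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("pearson_colocalization: zero-variance channel within the mask")
  stats::cor(a, b)
}
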