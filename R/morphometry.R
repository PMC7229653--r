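## Segmentation-based morphometry: nucleus segmentation, focus counting,
## region intensities, EdU-positive fractions, sprout lengths, gel
## contraction, and cell shape.

asMatrix <- function(x) {
  if (is(x, "Image")) x <- EBImage::imageData(x)
  if (is.array(x) && length(dim(x)) == 3 && dim(x)[3] == 1)
    x <- x[, , 1, drop = TRUE]
  x
}

#' Segment nuclei in a fluorescence channel
#'
#' Global Otsu threshold, hole filling, and a distance-transform watershed to
#' split touching nuclei, followed by removal of regions below a minimum
#' area.
#'
#' @param image 2D nonnegative nucleus-channel matrix.
#' @param minAreaPx smallest region kept (pixels).
#' @return Integer label matrix (0 = background); all zeros when the frame has
#'   no foreground.
#' @export
segmentNuclei <- function(image, minAreaPx = 50) {
  image <- asMatrix(image)
  stopifnot(is.matrix(image), all(image >= 0))
  rng <- range(image)
  if (rng[2] <= rng[1])
    return(matrix(0L, nrow(image), ncol(image)))
  norm <- (image - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(norm))
  bw <- norm > th
  if (!any(bw))
    return(matrix(0L, nrow(image), ncol(image)))
  bw <- asMatrix(EBImage::fillHull(EBImage::Image(bw * 1)))
  dm <- EBImage::distmap(EBImage::Image(bw))
  labels <- asMatrix(EBImage::watershed(dm, tolerance = 1, ext = 1))
  labels <- as.matrix(labels)
  tab <- tabulate(labels[labels > 0])
  drop <- which(tab < minAreaPx)
  if (length(drop)) labels[labels %in% drop] <- 0L
  # relabel 1..n
  kept <- sort(unique(labels[labels > 0]))
  out <- matrix(0L, nrow(labels), ncol(labels))
  for (i in seq_along(kept)) out[labels == kept[i]] <- i
  out
}

# Scale-normalized Laplacian-of-Gaussian kernel (negative at the centre for a
# bright spot, so -LoG response peaks on spots of width ~ sigma).
logKernel <- function(sigmaPx) {
  w <- max(2L, ceiling(3 * sigmaPx))
  xs <- -w:w
  g <- exp(-outer(xs^2, xs^2, "+") / (2 * sigmaPx^2))
  r2 <- outer(xs^2, xs^2, "+")
  k <- (r2 / sigmaPx^2 - 2) * g
  k - mean(k)  # zero-sum: flat regions give zero response
}

#' Count bright foci per nucleus
#'
#' Band-passes the focus channel with a Laplacian-of-Gaussian filter matched
#' to the expected spot width, finds local maxima of the response, and keeps
#' maxima whose response exceeds `prominenceFactor` times the median absolute
#' deviation of the response inside the nucleus (its background level).
#' Foci closer than the resolution of the filter merge into one detection.
#' Detection is background subtracted, so adding a constant to the channel
#' does not change counts.
#'
#' @param fociChannel 2D matrix, aligned with `labels`.
#' @param labels integer label matrix from [segmentNuclei()].
#' @param spotSigmaUm expected focus width (Gaussian sigma, micrometres);
#'   must be positive.
#' @param prominenceFactor multiple of the in-nucleus MAD a maximum must
#'   exceed (default 8).
#' @param pixelSizeUm pixel size (micrometres).
#' @return data.frame `nucleus_id`, `foci_count`.
#' @export
countFoci <- function(fociChannel, labels, spotSigmaUm = 0.25,
                      prominenceFactor = 8, pixelSizeUm = 0.21) {
  if (spotSigmaUm <= 0) stop("spotSigmaUm must be positive")
  fociChannel <- asMatrix(fociChannel)
  stopifnot(identical(dim(fociChannel), dim(labels)))
  sigmaPx <- spotSigmaUm / pixelSizeUm
  resp <- -asMatrix(EBImage::filter2(EBImage::Image(fociChannel),
                                     logKernel(sigmaPx),
                                     boundary = "replicate"))
  r <- max(1L, round(1.5 * sigmaPx))
  isMax <- resp == maxFilter(resp, r) & resp > 0
  ids <- sort(unique(labels[labels > 0]))
  counts <- integer(length(ids))
  for (i in seq_along(ids)) {
    inside <- labels == ids[i]
    noise <- stats::mad(resp[inside])
    cutoff <- prominenceFactor * max(noise, 1e-12)
    hits <- isMax & inside & resp >= cutoff
    if (!any(hits)) { counts[i] <- 0L; next }
    # merge plateau maxima: count connected components of the hit mask
    comp <- asMatrix(EBImage::bwlabel(EBImage::Image(hits * 1)))
    counts[i] <- max(comp)
  }
  data.frame(nucleus_id = ids, foci_count = counts)
}

#' Per-region intensity measurements
#'
#' Computes mean, total, and (for calibrated z-stacks) total-per-volume
#' intensity for every labelled region in one channel. For a z-stack the 2D
#' labels are applied to every plane, totals are summed over planes, and the
#' volume is `voxels * pixel_area * z_step`.
#'
#' @param channel 2D matrix or 3D array `[y, x, z]`.
#' @param labels integer label matrix.
#' @param pixelSizeUm pixel size (micrometres).
#' @param zStepUm z step (micrometres); required for `total_per_volume` on
#'   stacks.
#' @return data.frame with `region_id`, `area_px`, `area_um2`,
#'   `mean_intensity`, `total_intensity` and, when computable,
#'   `total_per_volume_um3` (plus `volume_um3`).
#' @export
regionIntensities <- function(channel, labels, pixelSizeUm = 1,
                              zStepUm = NA_real_) {
  channel <- if (is(channel, "ImageFrameSeries")) channel@data else
    asMatrix(channel)
  is3d <- length(dim(channel)) == 3
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) {
    warning("no labelled regions")
    return(data.frame(region_id = integer(0)))
  }
  out <- lapply(ids, function(id) {
    sel <- labels == id
    npx <- sum(sel)
    vals <- if (is3d) {
      as.vector(apply(channel, 3, function(pl) pl[sel]))
    } else channel[sel]
    nvox <- length(vals)
    row <- data.frame(region_id = id, area_px = npx,
                      area_um2 = npx * pixelSizeUm^2,
                      mean_intensity = mean(vals),
                      total_intensity = sum(vals))
    if (is3d && !is.na(zStepUm)) {
      vol <- nvox * pixelSizeUm^2 * zStepUm
      row$volume_um3 <- vol
      row$total_per_volume_um3 <- sum(vals) / vol
    }
    row
  })
  do.call(rbind, out)
}

#' Normalize per-nucleus intensities to a control condition
#'
#' Divides every value by the mean of the control-condition values, the
#' normalization used for per-nucleus marker intensities reported relative to
#' a control population.
#'
#' @param values numeric intensities to normalize.
#' @param controlValues intensities of the control condition (>= 1 value,
#'   nonzero mean).
#' @return Normalized values (control mean maps to 1).
#' @export
normalizedNuclearIntensity <- function(values, controlValues) {
  if (!length(controlValues)) stop("control condition has no nuclei")
  m <- mean(controlValues)
  if (m == 0) stop("control mean is zero; cannot normalize")
  values / m
}

# 1D Otsu threshold on a numeric vector (maximizes between-class variance).
otsuSplit <- function(x) {
  xs <- sort(unique(x))
  if (length(xs) < 2) stop("cannot Otsu-split fewer than 2 distinct values")
  cuts <- (xs[-1] + xs[-length(xs)]) / 2
  bcv <- vapply(cuts, function(cc) {
    lo <- x[x <= cc]; hi <- x[x > cc]
    length(lo) * length(hi) * (mean(hi) - mean(lo))^2
  }, numeric(1))
  cuts[which.max(bcv)]
}

#' EdU-positive fraction per field of view
#'
#' Computes the mean EdU intensity inside every nucleus and classifies nuclei
#' as positive above a threshold: either a fixed value or (default) an Otsu
#' split of the per-nucleus means, which requires at least two nuclei with
#' distinct means.
#'
#' @param eduChannel 2D matrix aligned with `labels`.
#' @param labels integer label matrix with at least one nucleus.
#' @param threshold numeric fixed threshold, or `NULL` for the Otsu rule.
#' @return A list with `percent_positive`, `n_positive`, `n_total`,
#'   `threshold` and the per-nucleus table.
#' @export
eduPositiveFraction <- function(eduChannel, labels, threshold = NULL) {
  eduChannel <- asMatrix(eduChannel)
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) stop("need at least one nucleus")
  means <- vapply(ids, function(id) mean(eduChannel[labels == id]),
                  numeric(1))
  if (is.null(threshold)) {
    if (length(ids) < 2)
      stop("Otsu rule needs >= 2 nuclei; supply a fixed threshold")
    threshold <- otsuSplit(means)
  }
  pos <- means > threshold
  list(percent_positive = 100 * sum(pos) / length(pos),
       n_positive = sum(pos), n_total = length(pos),
       threshold = threshold,
       table = data.frame(nucleus_id = ids, mean_intensity = means,
                          positive = pos))
}

#' Sprout metrics of an embedded spheroid
#'
#' Quantifies outgrowth from a spheroid: the image is thresholded, the
#' largest connected component (spheroid plus sprouts) kept, the core removed
#' by a morphological opening at `coreRemovalRadiusUm`, and the remaining
#' sprouts skeletonized. Each connected skeleton piece is rooted at its pixel
#' closest to the core; a sprout is the path from a skeleton endpoint back to
#' that root. Its length is measured on the path resampled every 5 pixels
#' (summing pixel steps on an 8-connected skeleton overestimates oblique
#' lines by up to 8%, the chamfer bias; the resampled polyline does not),
#' plus the root-to-core gap and half the estimated sprout width (the
#' thinning retracts each tip by about half the width). Paths shorter than
#' `minSproutLengthUm` (opening debris near the core boundary) are discarded.
#'
#' @param image calibrated 2D actin image.
#' @param pixelSizeUm pixel size (micrometres).
#' @param coreRemovalRadiusUm radius of the opening that removes the core;
#'   should be larger than the sprout half-width and smaller than the core.
#' @param threshold fixed intensity threshold, or `NULL` for Otsu.
#' @param minSproutLengthUm shortest path kept as a sprout (micrometres).
#' @return A list with `n_sprouts`, `avg_sprout_length_um`,
#'   `total_skeleton_length_um` and `per_sprout_lengths_um`.
#' @export
sproutMetrics <- function(image, pixelSizeUm, coreRemovalRadiusUm = 8,
                          threshold = NULL, minSproutLengthUm = 10) {
  image <- asMatrix(image)
  zero <- list(n_sprouts = 0L, avg_sprout_length_um = 0,
               total_skeleton_length_um = 0,
               per_sprout_lengths_um = numeric(0))
  rng <- range(image)
  if (rng[2] <= rng[1]) return(zero)
  if (is.null(threshold)) {
    norm <- (image - rng[1]) / (rng[2] - rng[1])
    threshold <- rng[1] + EBImage::otsu(EBImage::Image(norm)) *
      (rng[2] - rng[1])
  }
  bw <- image > threshold
  if (!any(bw)) return(zero)
  comp <- asMatrix(EBImage::bwlabel(EBImage::Image(bw * 1)))
  main <- which.max(tabulate(comp[comp > 0]))
  blob <- comp == main
  rPx <- max(2L, round(coreRemovalRadiusUm / pixelSizeUm))
  brush <- EBImage::makeBrush(2 * rPx + 1, shape = "disc")
  core <- asMatrix(EBImage::opening(EBImage::Image(blob * 1), brush)) > 0.5
  sprouts <- blob & !core
  if (!any(sprouts) || !any(core)) return(zero)
  skel <- thinSkeleton(sprouts)
  sg <- skeletonGraph(skel)
  if (is.null(sg$graph)) return(zero)
  deg <- igraph::degree(sg$graph)
  # distance of every skeleton pixel to the core
  dmap <- asMatrix(EBImage::distmap(EBImage::Image((!core) * 1)))
  dCore <- dmap[cbind(sg$row, sg$col)]
  widthPx <- sum(sprouts) /
    max(1, sum(igraph::E(igraph::mst(sg$graph))$weight))
  memb <- igraph::components(sg$graph)$membership
  lens <- numeric(0)
  for (cm in unique(memb)) {
    vs <- which(memb == cm)
    root <- vs[which.min(dCore[vs])]
    tips <- vs[deg[vs] <= 1 & vs != root]
    for (tp in tips) {
      vp <- igraph::shortest_paths(sg$graph, from = tp,
                                   to = root)$vpath[[1]]
      ii <- as.integer(vp)
      if (length(ii) < 2) next
      k <- unique(c(seq(1, length(ii), by = 5), length(ii)))
      poly <- sum(sqrt(diff(sg$row[ii[k]])^2 + diff(sg$col[ii[k]])^2))
      lens <- c(lens, (poly + dCore[root] + widthPx / 2) * pixelSizeUm)
    }
  }
  lens <- lens[lens >= minSproutLengthUm]
  if (!length(lens)) return(zero)
  totalUm <- sum(igraph::E(igraph::mst(sg$graph))$weight) * pixelSizeUm
  list(n_sprouts = length(lens),
       avg_sprout_length_um = mean(lens),
       total_skeleton_length_um = max(totalUm, sum(lens)),
       per_sprout_lengths_um = unname(lens))
}

#' Gel-contraction series from silhouette images
#'
#' Measures the gel area in every frame (threshold, largest connected
#' component, hole fill) and reports areas normalized to frame 1 and the
#' percent contraction `100 (1 - normalized)`.
#'
#' @param frames list of 2D matrices (>= 2), or an [ImageFrameSeries-class].
#' @param timesDays acquisition times (days); default `0, 1, 2, ...`.
#' @param gelBright is the gel brighter than the background (default `TRUE`)?
#' @return data.frame `time_days`, `area_px`, `normalized_area`,
#'   `percent_contraction`, `flagged_small` (area below 1% of the frame).
#' @export
gelContraction <- function(frames, timesDays = NULL, gelBright = TRUE) {
  if (is(frames, "ImageFrameSeries"))
    frames <- lapply(seq_len(nFrames(frames)), getFrame, x = frames)
  if (length(frames) < 2) stop("need at least 2 frames")
  if (is.null(timesDays)) timesDays <- seq_along(frames) - 1
  areas <- vapply(frames, function(fr) {
    fr <- asMatrix(fr)
    rng <- range(fr)
    if (rng[2] <= rng[1]) return(0)
    norm <- (fr - rng[1]) / (rng[2] - rng[1])
    bw <- norm > EBImage::otsu(EBImage::Image(norm))
    if (!gelBright) bw <- !bw
    comp <- asMatrix(EBImage::bwlabel(EBImage::Image(bw * 1)))
    if (!any(comp > 0)) return(0)
    main <- comp == which.max(tabulate(comp[comp > 0]))
    main <- asMatrix(EBImage::fillHull(EBImage::Image(main * 1))) > 0.5
    sum(main)
  }, numeric(1))
  if (areas[1] <= 0) stop("no gel found in the first frame")
  data.frame(time_days = timesDays, area_px = areas,
             normalized_area = areas / areas[1],
             percent_contraction = 100 * (1 - areas / areas[1]),
             flagged_small = areas < 0.01 * length(asMatrix(frames[[1]])))
}

#' Area and aspect ratio of a single region
#'
#' Area from the pixel count and aspect ratio from the best-fit ellipse
#' (square root of the ratio of the second-moment eigenvalues).
#'
#' @param mask logical matrix with a single region of at least 5 pixels.
#' @param pixelSizeUm pixel size (micrometres).
#' @return A list with `area_um2`, `area_px` and `aspect_ratio` (>= 1).
#' @export
cellShape <- function(mask, pixelSizeUm = 1) {
  stopifnot(is.logical(mask))
  npx <- sum(mask)
  if (npx < 5) stop("region smaller than 5 pixels")
  idx <- which(mask, arr.ind = TRUE)
  cov <- stats::cov(idx)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 1e-12)
  list(area_um2 = npx * pixelSizeUm^2, area_px = npx,
       aspect_ratio = sqrt(ev[1] / ev[2]))
}
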