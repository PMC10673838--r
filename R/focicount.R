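# Immunofluorescence foci counting: the classic macro pipeline
# (background subtraction, contrast rescale, Gaussian blur, fixed
# threshold, particle counting per nucleus) on single-channel images
# represented as numeric matrices.

disk_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
}

shift_mat <- function(img, dy, dx, fill) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(fill, nr, nc)
  ri <- max(1L, 1L - dy):min(nr, nr - dy)
  ci <- max(1L, 1L - dx):min(nc, nc - dx)
  if (length(ri) > 0L && length(ci) > 0L)
    out[ri, ci] <- img[ri + dy, ci + dx]
  out
}

morph_erode <- function(img, offs) {
  out <- matrix(Inf, nrow(img), ncol(img))
  for (k in seq_len(nrow(offs)))
    out <- pmin(out, shift_mat(img, offs$dy[k], offs$dx[k], Inf))
  out
}

morph_dilate <- function(img, offs) {
  out <- matrix(-Inf, nrow(img), ncol(img))
  for (k in seq_len(nrow(offs)))
    out <- pmax(out, shift_mat(img, offs$dy[k], offs$dx[k], -Inf))
  out
}

# Grayscale opening with a disk: idempotent background estimate that
# removes structures smaller than the disk (stands in for rolling-ball
# background subtraction).
morph_open <- function(img, radius) {
  offs <- disk_offsets(radius)
  morph_dilate(morph_erode(img, offs), offs)
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with replicated borders.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  conv_dim <- function(m, along_rows) {
    n <- if (along_rows) nrow(m) else ncol(m)
    out <- 0
    for (t in -r:r) {
      idx <- pmin(pmax(seq_len(n) + t, 1L), n)  # replicate border
      out <- out + k[t + r + 1L] *
        (if (along_rows) m[idx, , drop = FALSE] else m[, idx, drop = FALSE])
    }
    out
  }
  conv_dim(conv_dim(img, TRUE), FALSE)
}

# Run-based two-pass connected-component labelling, 4-connectivity.
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "logical"
  nr <- nrow(mask)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  runs <- vector("list", nr)   # per row: matrix cols start,end,label
  for (i in seq_len(nr)) {
    r <- rle(mask[i, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- which(r$values)
    if (length(sel) == 0L) { runs[i] <- list(NULL); next }
    row_runs <- cbind(start = starts[sel], end = ends[sel], label = 0L)
    prev <- if (i > 1L) runs[[i - 1L]] else NULL
    for (q in seq_len(nrow(row_runs))) {
      lab <- 0L
      if (!is.null(prev)) {
        ov <- prev[, "start"] <= row_runs[q, "end"] &
              prev[, "end"] >= row_runs[q, "start"]
        for (p in which(ov)) {
          plab <- find(prev[p, "label"])
          if (lab == 0L) lab <- plab
          else if (plab != lab) parent[plab] <- lab
        }
      }
      if (lab == 0L) {
        parent[length(parent) + 1L] <- length(parent) + 1L
        lab <- length(parent)
      }
      row_runs[q, "label"] <- lab
    }
    runs[[i]] <- row_runs
  }
  # resolve roots and renumber compactly
  roots <- vapply(seq_along(parent), find, integer(1))
  remap <- integer(length(parent))
  remap[sort(unique(roots))] <- seq_along(unique(roots))
  labels <- matrix(0L, nr, ncol(mask))
  for (i in seq_len(nr)) {
    rr <- runs[[i]]
    if (is.null(rr)) next
    for (q in seq_len(nrow(rr)))
      labels[i, rr[q, "start"]:rr[q, "end"]] <- remap[roots[rr[q, "label"]]]
  }
  labels
}

otsu_threshold <- function(img, nbins = 256L) {
  rng <- range(img)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- as.numeric(tabulate(findInterval(img, br, all.inside = TRUE), nbins))
  mids <- (br[-1] + br[-length(br)]) / 2
  w1 <- cumsum(h); w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / pmax(w1, 1)
  m2 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w2, 1)
  between <- w1 * w2 * (m1 - m2)^2
  mids[which.max(between[-nbins])]
}

#' Segment nuclei by thresholding and size gating
#'
#' Connected components (4-connectivity) of `image > nucleus_threshold`
#' with at least `min_nucleus_area` pixels, labelled 1..n. Touching nuclei
#' are not split (the generator places nuclei without overlap).
#'
#' @param image Numeric matrix (single channel).
#' @param nucleus_threshold Intensity threshold; `NULL` (default) uses
#'   Otsu's method.
#' @param min_nucleus_area Minimum component area in px (default 50).
#' @return Integer label matrix; 0 is background. Warns if no nucleus is
#'   found.
#' @export
segment_nuclei <- function(image, nucleus_threshold = NULL,
                           min_nucleus_area = 50L) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (is.null(nucleus_threshold)) nucleus_threshold <- otsu_threshold(image)
  labels <- label_components(image > nucleus_threshold)
  if (max(labels) > 0L) {
    areas <- tabulate(labels[labels > 0L], max(labels))
    keep <- which(areas >= min_nucleus_area)
    remap <- integer(max(labels))
    remap[keep] <- seq_along(keep)
    labels[labels > 0L] <- remap[labels[labels > 0L]]
  }
  if (max(labels) == 0L) warnf("no nucleus found above threshold")
  labels
}

#' Foci-counting pipeline parameters
#'
#' Defaults are calibration choices (documented in the methods vignette):
#' the macro they reimplement applies experiment-specific, manually
#' confirmed thresholds.
#'
#' @param background_radius_px Disk radius for the opening-based
#'   background estimate (default 8; must exceed the spot radius).
#' @param background_smooth_sigma Gaussian sigma applied to the copy of
#'   the image from which the background is estimated (default 1);
#'   without it the morphological opening tracks noise minima and the
#'   background estimate is biased low, as in rolling-ball
#'   implementations that pre-smooth.
#' @param saturation_fraction Fraction of pixels saturated at each tail by
#'   the linear contrast rescale (default 0.0035, the ImageJ default).
#' @param blur_sigma_px Gaussian blur sigma (default 1).
#' @param threshold Absolute intensity threshold after preprocessing
#'   (rescaled images lie in [0, 1]; default 0.35).
#' @param min_area_px,max_area_px Particle size gate (defaults 4 and 400).
#' @param positivity_k Focus-count cutoff for calling a nucleus positive
#'   (default 5).
#' @param positivity_rule `"ge"` (counts >= k, default) or `"gt"`
#'   (counts > k); captions use both conventions.
#' @return Validated list of class `foci_params`.
#' @export
foci_params <- function(background_radius_px = 8,
                        background_smooth_sigma = 1,
                        saturation_fraction = 0.0035,
                        blur_sigma_px = 1, threshold = 0.35,
                        min_area_px = 4L, max_area_px = 400L,
                        positivity_k = 5L, positivity_rule = c("ge", "gt")) {
  check_pos(background_radius_px, "background_radius_px")
  check_prob(saturation_fraction, "saturation_fraction")
  if (saturation_fraction >= 0.5) stopf("saturation_fraction must be < 0.5")
  check_pos(blur_sigma_px, "blur_sigma_px")
  if (!is.numeric(threshold) || length(threshold) != 1L)
    stopf("threshold must be a single number")
  min_area_px <- check_count(min_area_px, "min_area_px")
  max_area_px <- check_count(max_area_px, "max_area_px")
  if (min_area_px > max_area_px) stopf("min_area_px must be <= max_area_px")
  positivity_k <- check_count(positivity_k, "positivity_k")
  if (background_smooth_sigma < 0) stopf("background_smooth_sigma must be >= 0")
  structure(list(background_radius_px = background_radius_px,
                 background_smooth_sigma = background_smooth_sigma,
                 saturation_fraction = saturation_fraction,
                 blur_sigma_px = blur_sigma_px, threshold = threshold,
                 min_area_px = min_area_px, max_area_px = max_area_px,
                 positivity_k = positivity_k,
                 positivity_rule = match.arg(positivity_rule)),
            class = "foci_params")
}

#' Count foci per nucleus
#'
#' Pipeline: (a) background subtraction — grayscale opening (disk radius
#' `background_radius_px`) of a lightly pre-smoothed copy is subtracted
#' from the image (clipped at 0); (b) linear contrast rescale to [0, 1] saturating
#' `saturation_fraction` of pixels at each tail; (c) Gaussian blur;
#' (d) binary mask at `threshold`; (e) connected components within each
#' nucleus label, gated by `[min_area_px, max_area_px]`.
#'
#' @param image Numeric matrix.
#' @param labels Integer nucleus label matrix (from [segment_nuclei()] or
#'   a generator ground-truth mask), same dimensions as `image`.
#' @param params A [foci_params()].
#' @return A `foci_result`: list with `per_nucleus` (data.frame `nucleus,
#'   count, area`) and `mask` (the binary focus mask).
#' @export
count_foci <- function(image, labels, params = foci_params()) {
  stopifnot(inherits(params, "foci_params"),
            is.matrix(image), is.matrix(labels),
            all(dim(image) == dim(labels)))
  bg_src <- gaussian_blur(image, params$background_smooth_sigma)
  sub <- pmax(image - morph_open(bg_src, params$background_radius_px), 0)
  qs <- quantile(sub, c(params$saturation_fraction,
                        1 - params$saturation_fraction), names = FALSE)
  rescaled <- if (qs[2] > qs[1])
    pmin(pmax((sub - qs[1]) / (qs[2] - qs[1]), 0), 1)
  else matrix(0, nrow(sub), ncol(sub))
  blurred <- gaussian_blur(rescaled, params$blur_sigma_px)
  mask <- blurred >= params$threshold
  comp <- label_components(mask)
  nlab <- max(labels)
  counts <- integer(nlab)
  if (max(comp) > 0L) {
    for (cid in seq_len(max(comp))) {
      px <- comp == cid
      area <- sum(px)
      if (area < params$min_area_px || area > params$max_area_px) next
      # assign the particle to the nucleus holding most of its pixels
      owner <- labels[px]
      owner <- owner[owner > 0L]
      if (length(owner) == 0L) next
      win <- as.integer(names(which.max(table(owner))))
      counts[win] <- counts[win] + 1L
    }
  }
  areas <- if (nlab > 0L) tabulate(labels[labels > 0L], nlab) else integer(0)
  structure(list(per_nucleus = data.frame(nucleus = seq_len(nlab),
                                          count = counts, area = areas),
                 mask = mask),
            class = "foci_result")
}

#' Percentage of focus-positive nuclei
#'
#' @param result A `foci_result` or a numeric vector of per-nucleus focus
#'   counts.
#' @param k Focus-count cutoff.
#' @param rule `"ge"` (count >= k) or `"gt"` (count > k); figure captions
#'   use both ("5 or more foci", "more than 5 foci"), hence the switch.
#' @return Percent of nuclei positive, in `[0, 100]`.
#' @examples
#' percent_positive(c(5, 4), 5, "ge")  # 50
#' percent_positive(c(5, 4), 5, "gt")  # 0
#' @export
percent_positive <- function(result, k = 5L, rule = c("ge", "gt")) {
  rule <- match.arg(rule)
  counts <- if (inherits(result, "foci_result")) result$per_nucleus$count
            else result
  if (!is.numeric(counts) || length(counts) == 0L)
    stopf("need at least one nucleus")
  pos <- if (rule == "ge") counts >= k else counts > k
  100 * mean(pos)
}
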