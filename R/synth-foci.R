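# Seeded generator for immunofluorescence-style images: bright disk
# nuclei on a dark background, Gaussian foci inside nuclei, optional
# Poisson noise on intensity, with a per-nucleus ground-truth count table
# and the true nucleus label mask.

#' Generate synthetic nucleus/foci images with ground truth
#'
#' Nuclei are non-overlapping bright disks placed on a jittered grid;
#' each receives a number of foci drawn from `foci_count_dist` (a single
#' number for a point mass, an integer vector recycled per nucleus, or
#' `list(name = "poisson", lambda = )`). Foci are Gaussian spots of
#' amplitude `snr * sqrt(nucleus_intensity)` (peak signal-to-noise ratio
#' against Poisson shot noise at nucleus intensity) placed inside the
#' nucleus with a minimum pairwise separation. With
#' `noise_model = "poisson"` every pixel is replaced by a Poisson draw
#' with its intensity as mean.
#'
#' @param n_nuclei Number of nuclei.
#' @param foci_count_dist Per-nucleus focus count distribution (see
#'   above); default Poisson with mean 5.
#' @param spot_sigma_px Gaussian spot sigma (default 1.5).
#' @param noise_model `"none"` or `"poisson"`.
#' @param nucleus_radius_px Disk radius (default 18).
#' @param nucleus_intensity,background_intensity Mean intensities
#'   (defaults 100 and 5).
#' @param snr Spot peak amplitude in units of nucleus shot-noise sd
#'   (default 5).
#' @param min_separation_px Minimum focus-to-focus separation
#'   (default `5 * spot_sigma_px`; closer spots merge under the analysis blur).
#' @param seed Integer seed.
#' @return List with `image` (numeric matrix), `nucleus_mask` (integer
#'   label matrix, ground truth), and `truth` (data.frame
#'   `nucleus, n_foci`). Errors if the requested foci cannot be placed at
#'   the minimum separation (density exceeds nucleus capacity).
#' @export
gen_foci_images <- function(n_nuclei, foci_count_dist = list(name = "poisson",
                                                             lambda = 5),
                            spot_sigma_px = 1.5, noise_model = c("none",
                                                               "poisson"),
                            nucleus_radius_px = 18,
                            nucleus_intensity = 100,
                            background_intensity = 5,
                            snr = 5,
                            min_separation_px = NULL, seed = 1L) {
  n_nuclei <- check_count(n_nuclei, "n_nuclei", min = 1L)
  noise_model <- match.arg(noise_model)
  check_pos(spot_sigma_px, "spot_sigma_px")
  check_pos(nucleus_radius_px, "nucleus_radius_px")
  seed <- check_count(seed, "seed")
  if (is.null(min_separation_px)) min_separation_px <- 5 * spot_sigma_px
  cell <- ceiling(2.5 * nucleus_radius_px)       # grid cell per nucleus
  ncol_g <- ceiling(sqrt(n_nuclei))
  nrow_g <- ceiling(n_nuclei / ncol_g)
  H <- nrow_g * cell; W <- ncol_g * cell
  with_substream(seed, "foci_images", {
    img <- matrix(background_intensity, H, W)
    labels <- matrix(0L, H, W)
    truth_n <- integer(n_nuclei)
    amp <- snr * sqrt(nucleus_intensity)
    for (i in seq_len(n_nuclei)) {
      gr <- (i - 1L) %/% ncol_g
      gc <- (i - 1L) %% ncol_g
      jit <- round(runif(2, -0.1, 0.1) * cell)
      cy <- gr * cell + cell / 2 + jit[1]
      cx <- gc * cell + cell / 2 + jit[2]
      yy <- pmax(1, floor(cy - nucleus_radius_px)):
            pmin(H, ceiling(cy + nucleus_radius_px))
      xx <- pmax(1, floor(cx - nucleus_radius_px)):
            pmin(W, ceiling(cx + nucleus_radius_px))
      d2 <- outer((yy - cy)^2, (xx - cx)^2, `+`)
      inside <- d2 <= nucleus_radius_px^2
      img[yy, xx][inside] <- nucleus_intensity
      labels[yy, xx][inside] <- i
      nf <- if (is.numeric(foci_count_dist)) {
        as.integer(rep_len(foci_count_dist, n_nuclei)[i])
      } else if (identical(foci_count_dist$name, "poisson")) {
        rpois(1, foci_count_dist$lambda)
      } else stopf("unknown foci_count_dist")
      truth_n[i] <- nf
      if (nf == 0L) next
      # rejection-sample focus centres inside the nucleus with a minimum
      # pairwise separation; error if capacity is exceeded
      margin <- nucleus_radius_px - 2 * spot_sigma_px
      if (margin <= 0) stopf("spot sigma too large for the nucleus radius")
      pts <- matrix(numeric(0), 0, 2)
      tries <- 0L
      while (nrow(pts) < nf) {
        tries <- tries + 1L
        if (tries > 200L * nf)
          stopf("cannot place %d foci at separation %.1f px in a nucleus of radius %.1f px",
                nf, min_separation_px, nucleus_radius_px)
        ang <- runif(1, 0, 2 * pi); rad <- margin * sqrt(runif(1))
        cand <- c(cy + rad * sin(ang), cx + rad * cos(ang))
        if (nrow(pts) == 0L ||
            all((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2 >=
                min_separation_px^2))
          pts <- rbind(pts, cand)
      }
      ext <- ceiling(4 * spot_sigma_px)
      for (q in seq_len(nrow(pts))) {
        sy <- pts[q, 1]; sx <- pts[q, 2]
        yy2 <- pmax(1, floor(sy - ext)):pmin(H, ceiling(sy + ext))
        xx2 <- pmax(1, floor(sx - ext)):pmin(W, ceiling(sx + ext))
        g <- amp * exp(-outer((yy2 - sy)^2, (xx2 - sx)^2, `+`) /
                         (2 * spot_sigma_px^2))
        img[yy2, xx2] <- img[yy2, xx2] + g
      }
    }
    if (noise_model == "poisson")
      img <- matrix(rpois(length(img), img), H, W)
    list(image = img, nucleus_mask = labels,
         truth = data.frame(nucleus = seq_len(n_nuclei), n_foci = truth_n))
  })
}
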