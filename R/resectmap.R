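# END-seq resection quantification: motif scanning, signal binning around
# sites, cut-site calling, peak-width resection distances, ranking, and
# heatmap matrices. Coverage tracks are named lists of per-base numeric
# vectors (one per chromosome); coordinates are 0-based half-open.

#' Find exact motif occurrences in a genome
#'
#' Scans the forward strand for exact matches. The default AsiSI
#' recognition site `GCGATCGC` is its own reverse complement, so the
#' forward-strand scan already covers both strands and each locus is
#' reported once.
#'
#' @param genome Named character vector of uppercase chromosome sequences.
#' @param motif Motif string (default `"GCGATCGC"`).
#' @return Data.frame `chrom, pos, site_center` (0-based; center is
#'   `pos + floor(len/2)`), sorted by `(chrom, pos)`.
#' @export
find_motif_sites <- function(genome, motif = "GCGATCGC") {
  if (!is.character(genome) || is.null(names(genome)))
    stopf("genome must be a named character vector of sequences")
  valid_dna(motif, "motif", allow_empty = FALSE)
  hits <- lapply(names(genome), function(chrom) {
    m <- Biostrings::matchPattern(motif, Biostrings::DNAString(genome[[chrom]]))
    pos <- Biostrings::start(m) - 1L
    if (length(pos)) data.frame(chrom = chrom, pos = pos) else NULL
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) out <- data.frame(chrom = character(0), pos = integer(0))
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  out$site_center <- out$pos + nchar(motif) %/% 2L
  rownames(out) <- NULL
  out
}

check_track <- function(track) {
  if (is.list(track) && !is.null(track$track)) track <- track$track
  if (!is.list(track) || is.null(names(track)) ||
      !all(vapply(track, is.numeric, logical(1))))
    stopf("track must be a named list of per-base numeric vectors")
  track
}

#' Scale an end-count track to reads per million
#'
#' @param track Named list of per-base numeric vectors (or a
#'   `gen_endseq_track()` result).
#' @param library_size Total reads to normalize by; defaults to the sum of
#'   the track itself.
#' @return The scaled track (attribute `normalized = TRUE`).
#' @export
normalize_track <- function(track, library_size = NULL) {
  track <- check_track(track)
  if (is.null(library_size))
    library_size <- sum(vapply(track, sum, numeric(1)))
  if (!is.numeric(library_size) || length(library_size) != 1L ||
      library_size <= 0)
    stopf("library_size must be a single positive number")
  out <- lapply(track, function(v) v * 1e6 / library_size)
  attr(out, "normalized") <- TRUE
  out
}

#' Bin signal around each site
#'
#' Each site profile covers `[center - window, center + window)` split
#' into `2 * window / bin_size` bins; a bin's value is the sum of track
#' signal over its half-open genomic interval. Bins falling off the contig
#' are zero-filled and the profile flagged `edge_clipped`.
#'
#' @param track Coverage track (named list of per-base vectors).
#' @param sites Data.frame with `chrom`, `pos`, and optionally
#'   `site_center` (defaults to `pos + 4`, the AsiSI center).
#' @param window Bases on each side of the center (default 20000).
#' @param bin_size Bin width in bp (default 250); must divide `window`.
#' @return List of `site_profile` objects (fields `chrom, pos, center,
#'   window, bin_size, bins, edge_clipped, normalized`).
#' @export
bin_signal <- function(track, sites, window = 20000L, bin_size = 250L) {
  track <- check_track(track)
  window <- check_count(window, "window", min = 1L)
  bin_size <- check_count(bin_size, "bin_size", min = 1L)
  if (window %% bin_size != 0L) stopf("window must be divisible by bin_size")
  normalized <- isTRUE(attr(track, "normalized"))
  centers <- if ("site_center" %in% names(sites)) sites$site_center
             else sites$pos + 4L
  nb <- 2L * window %/% bin_size
  lapply(seq_len(nrow(sites)), function(i) {
    chrom <- sites$chrom[i]
    if (!chrom %in% names(track)) stopf("chromosome '%s' not in track", chrom)
    v <- track[[chrom]]
    center <- centers[i]
    start <- center - window          # 0-based start of the profile
    clipped <- start < 0 || center + window > length(v)
    if (clipped)
      warnf("site %s:%d window exits the contig; edge bins zero-filled",
            chrom, sites$pos[i])
    bins <- numeric(nb)
    for (b in seq_len(nb)) {
      b0 <- start + (b - 1L) * bin_size
      lo <- max(b0, 0L); hi <- min(b0 + bin_size, length(v))
      if (lo < hi) bins[b] <- sum(v[(lo + 1L):hi])
    }
    structure(list(chrom = chrom, pos = sites$pos[i], center = center,
                   window = window, bin_size = bin_size, bins = bins,
                   edge_clipped = clipped, normalized = normalized,
                   is_cut = NA),
              class = "site_profile")
  })
}

#' Call cut sites by central enrichment over flanking background
#'
#' A site is called cut when the mean signal within `center_span` of the
#' center is at least `min_enrichment` times the median signal of the
#' outermost `flank_span` on each side (pooled, floored at `pseudocount`
#' per bin so zero-background profiles with real central signal are still
#' callable).
#'
#' @param profiles List of `site_profile` (from [bin_signal()]).
#' @param min_enrichment Fold-enrichment threshold (default 5).
#' @param center_span,flank_span Spans in bp (defaults 1000 and 5000).
#' @param pseudocount Background floor, in signal units per bin
#'   (default 0.25, suited to raw end counts).
#' @return The profiles with `is_cut` (logical) and `enrichment` set.
#' @export
call_cut_sites <- function(profiles, min_enrichment = 5,
                           center_span = 1000L, flank_span = 5000L,
                           pseudocount = 0.25) {
  lapply(profiles, function(pr) {
    stopifnot(inherits(pr, "site_profile"))
    nb <- length(pr$bins)
    bpb <- pr$bin_size
    if (center_span > pr$window || flank_span > pr$window)
      stopf("spans must lie within the profile window")
    cs <- max(1L, center_span %/% bpb)
    fs <- max(1L, flank_span %/% bpb)
    mid <- nb %/% 2L
    center_mean <- mean(pr$bins[(mid - cs + 1L):(mid + cs)])
    flank_med <- median(c(pr$bins[1:fs], pr$bins[(nb - fs + 1L):nb]))
    pr$enrichment <- center_mean / max(flank_med, pseudocount)
    pr$is_cut <- pr$enrichment >= min_enrichment
    pr
  })
}

moving_avg <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  half <- (k - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Resection distance from peak width
#'
#' After moving-average smoothing, the per-side resection distance is the
#' distance from the site center to the outer edge of the farthest bin of
#' the contiguous run (starting at the center) whose smoothed signal is at
#' least `height_fraction` of the peak height. `combined_bp` summarizes
#' the two sides (`max` by default: resection can be asymmetric and the
#' max tracks the measurable tract).
#'
#' Strand-resolved tracks are supported by passing per-strand profiles:
#' the left distance is then measured on the minus-strand profile and the
#' right on the plus-strand profile.
#'
#' @param profile A called `site_profile` (see [call_cut_sites()]).
#' @param height_fraction Fraction of peak height defining the width
#'   (default 0.1).
#' @param smooth_bins Moving-average window in bins (default 3; use 1 to
#'   disable).
#' @param combine `"max"` (default), `"mean"`, or `"sum"`.
#' @param minus_profile,plus_profile Optional strand-resolved profiles of
#'   the same geometry.
#' @param require_cut Error if the profile was not called cut
#'   (default TRUE).
#' @return A `resection_call`: list `chrom, pos, is_cut, peak_height,
#'   left_bp, right_bp, combined_bp`.
#' @export
resection_distance <- function(profile, height_fraction = 0.1,
                               smooth_bins = 3L,
                               combine = c("max", "mean", "sum"),
                               minus_profile = NULL, plus_profile = NULL,
                               require_cut = TRUE) {
  combine <- match.arg(combine)
  stopifnot(inherits(profile, "site_profile"))
  if (require_cut && !isTRUE(profile$is_cut))
    stopf("profile is not a called cut site; run call_cut_sites() first")
  check_prob(height_fraction, "height_fraction")
  side_dist <- function(bins, side) {
    sm <- moving_avg(bins, smooth_bins)
    peak <- max(sm)
    thr <- height_fraction * peak
    nb <- length(sm)
    mid <- nb %/% 2L
    idx <- if (side == "right") (mid + 1L):nb else mid:1L
    run <- 0L
    for (i in idx) {
      if (sm[i] >= thr) run <- run + 1L else break
    }
    list(dist = run * profile$bin_size, peak = peak)
  }
  left_src <- if (!is.null(minus_profile)) minus_profile$bins else profile$bins
  right_src <- if (!is.null(plus_profile)) plus_profile$bins else profile$bins
  l <- side_dist(left_src, "left")
  r <- side_dist(right_src, "right")
  combined <- switch(combine, max = max(l$dist, r$dist),
                     mean = mean(c(l$dist, r$dist)), sum = l$dist + r$dist)
  structure(list(chrom = profile$chrom, pos = profile$pos,
                 is_cut = isTRUE(profile$is_cut),
                 peak_height = max(moving_avg(profile$bins, smooth_bins)),
                 left_bp = l$dist, right_bp = r$dist,
                 combined_bp = combined),
            class = "resection_call")
}

#' @rdname resection_distance
#' @param profiles List of called `site_profile`s.
#' @param ... Passed to [resection_distance()].
#' @return `resection_distances()` returns a data.frame, one row per
#'   profile.
#' @export
resection_distances <- function(profiles, ...) {
  rows <- lapply(profiles, function(pr) {
    rc <- resection_distance(pr, ...)
    data.frame(chrom = rc$chrom, pos = rc$pos, is_cut = rc$is_cut,
               peak_height = rc$peak_height, left_bp = rc$left_bp,
               right_bp = rc$right_bp, combined_bp = rc$combined_bp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Top-n sites by resection distance
#'
#' @param calls Data.frame from [resection_distances()].
#' @param n Number of sites to keep (default 20, the per-sample
#'   convention for resection summaries).
#' @return The first `n` rows after sorting by `combined_bp` descending
#'   (ties broken by chrom, pos); all rows with a warning if fewer than
#'   `n` are available.
#' @export
top_sites <- function(calls, n = 20L) {
  n <- check_count(n, "n", min = 1L)
  stopifnot(is.data.frame(calls))
  calls <- calls[order(-calls$combined_bp, calls$chrom, calls$pos), ,
                 drop = FALSE]
  if (nrow(calls) < n) {
    warnf("only %d call(s) available; returning all", nrow(calls))
    n <- nrow(calls)
  }
  out <- head(calls, n)
  rownames(out) <- NULL
  out
}

#' Site-by-bin signal matrix for heatmaps
#'
#' Rows are sites ordered by decreasing resection distance (recomputed
#' with [resection_distance()] defaults unless `order_by` is supplied),
#' columns are bins labelled by their start offset relative to the site
#' center.
#'
#' @param profiles List of `site_profile`s sharing window and bin size.
#' @param order_by Optional numeric vector (one per profile) to sort rows
#'   by, descending; defaults to each profile's combined resection
#'   distance.
#' @return Numeric matrix with `chrom:pos` rownames and relative-offset
#'   colnames; attribute `order_by` carries the sort key in row order.
#' @export
heatmap_matrix <- function(profiles, order_by = NULL) {
  stopifnot(length(profiles) >= 1L)
  geom <- vapply(profiles, function(p) c(p$window, p$bin_size), numeric(2))
  if (nrow(unique(t(geom))) != 1L)
    stopf("profiles have mixed window/bin_size geometry")
  if (is.null(order_by))
    order_by <- vapply(profiles, function(p)
      resection_distance(p, require_cut = FALSE)$combined_bp, numeric(1))
  ord <- order(-order_by,
               vapply(profiles, `[[`, character(1), "chrom"),
               vapply(profiles, `[[`, numeric(1), "pos"))
  mat <- t(vapply(profiles[ord], `[[`, numeric(length(profiles[[1]]$bins)),
                  "bins"))
  rownames(mat) <- vapply(profiles[ord], function(p)
    sprintf("%s:%d", p$chrom, p$pos), character(1))
  colnames(mat) <- seq(-profiles[[1]]$window,
                       profiles[[1]]$window - profiles[[1]]$bin_size,
                       by = profiles[[1]]$bin_size)
  attr(mat, "order_by") <- order_by[ord]
  mat
}

#' Read/write coverage tracks as bedGraph
#'
#' Converts between the package's dense per-base track representation and
#' 4-column bedGraph (0-based half-open), via rtracklayer.
#'
#' @param track Named list of per-base numeric vectors.
#' @param path bedGraph file path.
#' @return `track_from_bedgraph()` returns a track; lengths are taken
#'   from `seqlengths` (named vector) or the furthest covered base.
#' @export
track_to_bedgraph <- function(track, path) {
  track <- check_track(track)
  si <- GenomeInfoDb::Seqinfo(names(track), lengths(track))
  grl <- lapply(names(track), function(chrom) {
    r <- rle(track[[chrom]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0
    if (!any(keep)) return(NULL)
    GenomicRanges::GRanges(chrom,
      IRanges::IRanges(starts[keep], ends[keep]), score = r$values[keep],
      seqinfo = si)
  })
  keep <- grl[!vapply(grl, is.null, logical(1))]
  gr <- if (length(keep) > 0L) do.call(c, keep) else {
    g0 <- GenomicRanges::GRanges(seqinfo = si)
    S4Vectors::mcols(g0)$score <- numeric(0)
    g0
  }
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname track_to_bedgraph
#' @param seqlengths Optional named vector of chromosome lengths.
#' @export
track_from_bedgraph <- function(path, seqlengths = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  chroms <- as.character(GenomeInfoDb::seqlevels(gr))
  lens <- if (!is.null(seqlengths)) seqlengths
          else setNames(vapply(chroms, function(ch)
            max(GenomicRanges::end(gr[GenomicRanges::seqnames(gr) == ch])),
            numeric(1)), chroms)
  track <- empty_track(lens)
  for (i in seq_along(gr)) {
    ch <- as.character(GenomicRanges::seqnames(gr)[i])
    idx <- GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]
    track[[ch]][idx] <- track[[ch]][idx] + gr$score[i]
  }
  track
}
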