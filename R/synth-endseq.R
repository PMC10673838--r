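# Seeded generator for END-seq-style coverage around restriction motif
# sites. Signal is a pile of single-base resection endpoints: per cut site
# and per side, endpoint distances from the cut are drawn from an
# exponential (optionally gamma) distribution and deposited moving outward,
# on top of a uniform Poisson background.

#' Parameters for the END-seq track simulator
#'
#' @param sites Data.frame with `chrom` and `pos` (0-based motif start);
#'   the site center is `pos + 4` for the 8-bp AsiSI motif.
#' @param mean_resection_bp True mean resection tract length in bp: a
#'   single value or one per site.
#' @param reads_per_site Endpoints drawn per site *per side*.
#' @param background_rate Background reads per kb, deposited uniformly
#'   (Poisson per base).
#' @param strand_model If `TRUE`, endpoints left of the cut are returned
#'   on a minus-strand track and right endpoints on a plus-strand track,
#'   in addition to the combined track.
#' @param endpoint_dist `"exponential"` (default; single-parameter, heavy
#'   right tail) or `"gamma"`.
#' @param gamma_shape Shape when `endpoint_dist = "gamma"` (mean is held
#'   at `mean_resection_bp`).
#' @param seed Integer seed.
#' @return Parameter list of class `endseq_sim_params`.
#' @export
endseq_sim_params <- function(sites, mean_resection_bp = 1000,
                              reads_per_site = 2000L,
                              background_rate = 0,
                              strand_model = FALSE,
                              endpoint_dist = c("exponential", "gamma"),
                              gamma_shape = 2, seed = 1L) {
  stopifnot(is.data.frame(sites), all(c("chrom", "pos") %in% names(sites)))
  check_pos(mean_resection_bp, "mean_resection_bp")
  if (!length(mean_resection_bp) %in% c(1L, nrow(sites)))
    stopf("mean_resection_bp must have length 1 or one value per site")
  reads_per_site <- check_count(reads_per_site, "reads_per_site")
  if (background_rate < 0) stopf("background_rate must be >= 0")
  seed <- check_count(seed, "seed")
  structure(list(sites = sites,
                 mean_resection_bp = rep_len(mean_resection_bp, nrow(sites)),
                 reads_per_site = reads_per_site,
                 background_rate = background_rate,
                 strand_model = isTRUE(strand_model),
                 endpoint_dist = match.arg(endpoint_dist),
                 gamma_shape = gamma_shape, seed = seed),
            class = "endseq_sim_params")
}

genome_lengths <- function(genome) {
  if (is.character(genome)) setNames(nchar(genome), names(genome))
  else if (is.numeric(genome)) genome
  else stopf("genome must be named sequences or named lengths")
}

empty_track <- function(lens) lapply(lens, function(l) numeric(l))

deposit <- function(vec, pos0) {
  # pos0: 0-based positions, already clamped to [0, len)
  tab <- tabulate(pos0 + 1L, nbins = length(vec))
  vec + tab
}

#' Generate a synthetic END-seq end-count track with truth
#'
#' For each site, `reads_per_site` resection endpoints are drawn per side
#' with distance from the cut distributed exponentially (mean
#' `mean_resection_bp`), rounded to whole bases (minimum 1) and deposited
#' as single-base end counts moving outward from the site center. Uniform
#' Poisson background is added genome-wide. Endpoints falling off a contig
#' are truncated at the edge with a warning.
#'
#' @param genome Named character vector of chromosome sequences, or named
#'   numeric vector of chromosome lengths.
#' @param params An [endseq_sim_params()].
#' @return List with `track` (named list of per-base numeric vectors),
#'   `plus`/`minus` (strand tracks, `NULL` unless `strand_model`), and
#'   `truth` (data.frame: `chrom, pos, center, mean_resection_bp,
#'   reads_per_site`).
#' @export
gen_endseq_track <- function(genome, params) {
  stopifnot(inherits(params, "endseq_sim_params"))
  lens <- genome_lengths(genome)
  sites <- params$sites
  bad <- !(sites$chrom %in% names(lens)) |
    sites$pos < 0 | sites$pos + 8 > lens[sites$chrom]
  if (any(bad)) stopf("%d site(s) fall outside the genome", sum(bad))
  with_substream(params$seed, "endseq_track", {
    plus <- empty_track(lens)
    minus <- empty_track(lens)
    n <- params$reads_per_site
    for (i in seq_len(nrow(sites))) {
      chrom <- sites$chrom[i]
      center <- sites$pos[i] + 4L
      mu <- params$mean_resection_bp[i]
      len <- lens[[chrom]]
      for (side in c("left", "right")) {
        dist <- switch(params$endpoint_dist,
          exponential = rexp(n, rate = 1 / mu),
          gamma = rgamma(n, shape = params$gamma_shape,
                         rate = params$gamma_shape / mu))
        bp <- pmax(1, round(dist))
        pos <- if (side == "left") center - bp else center + bp - 1
        clipped <- pos < 0 | pos >= len
        if (any(clipped)) {
          warnf("site %s:%d within resection range of a contig edge; %d endpoint(s) truncated",
                chrom, sites$pos[i], sum(clipped))
          pos <- pmin(pmax(pos, 0), len - 1)
        }
        if (side == "left") minus[[chrom]] <- deposit(minus[[chrom]], pos)
        else plus[[chrom]] <- deposit(plus[[chrom]], pos)
      }
    }
    if (params$background_rate > 0) {
      for (chrom in names(lens)) {
        bg <- rpois(lens[[chrom]], params$background_rate / 1000)
        half <- rbinom(lens[[chrom]], bg, 0.5)
        plus[[chrom]] <- plus[[chrom]] + half
        minus[[chrom]] <- minus[[chrom]] + (bg - half)
      }
    }
    combined <- mapply(`+`, plus, minus, SIMPLIFY = FALSE)
    truth <- data.frame(chrom = sites$chrom, pos = sites$pos,
                        center = sites$pos + 4L,
                        mean_resection_bp = params$mean_resection_bp,
                        reads_per_site = n)
    list(track = combined,
         plus = if (params$strand_model) plus else NULL,
         minus = if (params$strand_model) minus else NULL,
         truth = truth)
  })
}

#' Generate a random genome with motif sites planted at known positions
#'
#' Builds seeded random ACGT chromosomes and writes the motif at the
#' requested 0-based positions, giving a ground-truth site set for motif
#' scanning and resection recovery tests. Random background can contain
#' additional chance motif occurrences (~L/4^8 expected); these carry no
#' cut signal.
#'
#' @param site_positions Named list: chromosome -> integer vector of
#'   0-based motif start positions.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param motif Motif to plant (default the AsiSI site, `GCGATCGC`).
#' @param seed Integer seed.
#' @return List with `genome` (named character vector) and `sites`
#'   (data.frame `chrom, pos`).
#' @export
gen_motif_genome <- function(site_positions, chrom_lengths,
                             motif = "GCGATCGC", seed = 1L) {
  stopifnot(is.list(site_positions),
            all(names(site_positions) %in% names(chrom_lengths)))
  seed <- check_count(seed, "seed")
  with_substream(seed, "motif_genome", {
    genome <- vapply(names(chrom_lengths), function(chrom) {
      s <- random_dna(chrom_lengths[[chrom]])
      for (pos in site_positions[[chrom]]) {
        if (pos < 0 || pos + nchar(motif) > nchar(s))
          stopf("site position %d outside chromosome %s", pos, chrom)
        substr(s, pos + 1L, pos + nchar(motif)) <- motif
      }
      s
    }, character(1))
    sites <- data.frame(
      chrom = rep(names(site_positions),
                  lengths(site_positions)),
      pos = unlist(site_positions, use.names = FALSE))
    sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
    rownames(sites) <- NULL
    list(genome = genome, sites = sites)
  })
}
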