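make_profile <- function(bins, bin_size = 250L, window = 20000L,
                         is_cut = TRUE) {
  structure(list(chrom = "chr1", pos = 0L, center = 4L, window = window,
                 bin_size = bin_size, bins = bins, edge_clipped = FALSE,
                 normalized = FALSE, is_cut = is_cut),
            class = "site_profile")
}

test_that("motif scanning is exact and palindrome-complete", {
  g <- c(chr1 = "NNGCGATCGCNN")
  hits <- find_motif_sites(g)
  expect_equal(hits$pos, 2)
  expect_equal(hits$site_center, 6)

  # the AsiSI site is its own reverse complement: a forward scan is the
  # full both-strand site set
  expect_equal(oracle_revcomp("GCGATCGC"), "GCGATCGC")

  withr::with_seed(31, {
    seq <- random_dna(100000)
  })
  hits2 <- find_motif_sites(c(chrA = seq), "ACGT")
  expect_equal(hits2$pos, oracle_motif_scan(seq, "ACGT"))

  expect_equal(nrow(find_motif_sites(c(chr1 = "AAAA"), "GCGATCGC")), 0)
})

test_that("track normalization is linear RPM scaling", {
  tr <- list(chr1 = c(0, 10, 0, 5), chr2 = c(0, 0))
  n <- normalize_track(tr, 1e6)
  expect_equal(n$chr1, c(0, 10, 0, 5))
  z <- normalize_track(list(chr1 = rep(0, 4)), 100)
  expect_true(all(z$chr1 == 0))
  # scaling then summing equals summing then scaling
  expect_equal(sum(unlist(normalize_track(tr, 3e5))),
               sum(unlist(tr)) * 1e6 / 3e5)
  expect_error(normalize_track(tr, 0), "positive")
  # default library size is the track total
  expect_equal(sum(unlist(normalize_track(tr))), 1e6)
})

test_that("binning matches a brute-force per-base recount", {
  withr::with_seed(41, {
    v <- rpois(80000, 0.2)
  })
  track <- list(chr1 = v)
  sites <- data.frame(chrom = "chr1", pos = 40000L)
  prof <- bin_signal(track, sites, window = 4000, bin_size = 200)[[1]]
  expect_length(prof$bins, 40)
  expect_equal(prof$bins, oracle_bin(v, 40004, 4000, 200))

  # uniform track: every bin = c * bin_size
  u <- bin_signal(list(chr1 = rep(2, 80000)), sites,
                  window = 4000, bin_size = 200)[[1]]
  expect_true(all(u$bins == 400))

  # delta at the center lands in the first right-of-center bin
  dvec <- numeric(80000); dvec[40005] <- 7   # 0-based 40004 = center
  d <- bin_signal(list(chr1 = dvec), sites, window = 4000, bin_size = 200)[[1]]
  expect_equal(d$bins[21], 7)
  expect_equal(sum(d$bins), 7)

  expect_error(bin_signal(track, sites, window = 4000, bin_size = 300),
               "divisible")
  edge <- data.frame(chrom = "chr1", pos = 100L)
  expect_warning(pe <- bin_signal(track, edge, window = 4000,
                                  bin_size = 200), "contig")
  expect_true(pe[[1]]$edge_clipped)
})

test_that("cut-site calling separates peaks from flat background", {
  flat <- make_profile(rep(1, 160), is_cut = NA)
  called <- call_cut_sites(list(flat))[[1]]
  expect_false(called$is_cut)

  peaked <- rep(1, 160)
  peaked[77:84] <- 20   # 20x center enrichment over background 1
  expect_true(call_cut_sites(list(make_profile(peaked, is_cut = NA)))[[1]]$is_cut)

  zero <- make_profile(rep(0, 160), is_cut = NA)
  expect_false(call_cut_sites(list(zero))[[1]]$is_cut)
})

test_that("resection distance: box, one-sided, and exponential closed form", {
  nb <- 160L
  # rectangle spanning exactly +/-3000 bp (12 bins of 250 each side)
  box <- numeric(nb); box[(80 - 11):(80 + 12)] <- 10
  rc <- resection_distance(make_profile(box), smooth_bins = 1)
  expect_equal(rc$left_bp, 3000)
  expect_equal(rc$right_bp, 3000)
  expect_equal(rc$combined_bp, 3000)

  # one-sided signal
  right_only <- numeric(nb); right_only[81:92] <- 10
  rc1 <- resection_distance(make_profile(right_only), smooth_bins = 1)
  expect_equal(rc1$left_bp, 0)
  expect_equal(rc1$combined_bp, rc1$right_bp)

  # exponential decay with length lambda: threshold crossing at -lambda ln f
  lambda <- 1000
  x <- (seq_len(nb) - 0.5 - 80) * 250       # signed bin-center offsets
  expo <- exp(-abs(x) / lambda)
  rc2 <- resection_distance(make_profile(expo), smooth_bins = 1)
  expect_lt(abs(rc2$right_bp - lambda * log(10)), 250)
  expect_lt(abs(rc2$left_bp - lambda * log(10)), 250)

  # combine rules
  asym <- numeric(nb); asym[81:88] <- 10; asym[77:80] <- 10
  rca <- resection_distance(make_profile(asym), smooth_bins = 1)
  expect_equal(rca$combined_bp, max(rca$left_bp, rca$right_bp))
  rcs <- resection_distance(make_profile(asym), smooth_bins = 1,
                            combine = "sum")
  expect_equal(rcs$combined_bp, rca$left_bp + rca$right_bp)

  expect_error(resection_distance(make_profile(box, is_cut = FALSE)),
               "call_cut_sites")
})

test_that("strand-resolved profiles drive their respective sides", {
  nb <- 160L
  minus <- numeric(nb); minus[(80 - 11):80] <- 10
  plus <- numeric(nb); plus[81:(80 + 4)] <- 10
  comb <- minus + plus
  rc <- resection_distance(make_profile(comb), smooth_bins = 1,
                           minus_profile = make_profile(minus),
                           plus_profile = make_profile(plus))
  expect_equal(rc$left_bp, 3000)
  expect_equal(rc$right_bp, 1000)
})

test_that("top_sites ranks by combined distance with deterministic ties", {
  calls <- data.frame(chrom = "chr1", pos = c(1, 2, 3),
                      is_cut = TRUE, peak_height = 1,
                      left_bp = 0, right_bp = 0,
                      combined_bp = c(1, 5, 3))
  expect_equal(top_sites(calls, 2)$combined_bp, c(5, 3))
  expect_warning(all5 <- top_sites(calls, 20), "returning all")
  expect_equal(nrow(all5), 3)
})

test_that("heatmap matrix conserves bins and follows ranking order", {
  p1 <- make_profile(c(rep(0, 70), rep(5, 20), rep(0, 70)))
  p2 <- make_profile(c(rep(0, 76), rep(9, 8), rep(0, 76)))
  p2$pos <- 100L
  mat <- heatmap_matrix(list(p2, p1))
  expect_equal(dim(mat), c(2, 160))
  expect_equal(unname(rowSums(mat)[rownames(mat) == "chr1:0"]), sum(p1$bins))
  # wider profile resects farther -> first row
  expect_equal(rownames(mat)[1], "chr1:0")
  expect_equal(heatmap_matrix(list(p1)), heatmap_matrix(list(p1)))
  bad <- make_profile(rep(1, 80), bin_size = 500L)
  expect_error(heatmap_matrix(list(p1, bad)), "geometry")
})

test_that("estimated distances are monotone in true mean resection", {
  # scaled-down version of the recovery experiment (full scale runs in
  # the acceptance suite)
  gm <- gen_motif_genome(list(chr1 = c(60000L, 200000L, 340000L)),
                         c(chr1 = 400000L), seed = 61)
  med_for <- function(mu, seed) {
    pr <- endseq_sim_params(gm$sites, mu, reads_per_site = 500,
                            background_rate = 1, seed = seed)
    sim <- gen_endseq_track(c(chr1 = 400000L), pr)
    prof <- call_cut_sites(bin_signal(sim$track, gm$sites))
    median(resection_distances(prof)$combined_bp)
  }
  meds <- c(med_for(500, 71), med_for(1000, 72), med_for(2000, 73),
            med_for(4000, 74))
  expect_true(all(diff(meds) >= 0))
})

test_that("bedGraph round trip preserves the dense track", {
  tr <- list(chr1 = c(0, 0, 3, 3, 0, 1.5, 0, 0), chr2 = c(2, 0, 0, 1))
  path <- withr::local_tempfile(fileext = ".bedGraph")
  track_to_bedgraph(tr, path)
  back <- track_from_bedgraph(path, seqlengths = c(chr1 = 8, chr2 = 4))
  expect_equal(back$chr1, tr$chr1)
  expect_equal(back$chr2, tr$chr2)
})
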