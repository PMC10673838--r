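# Seeded generator for translocation-junction read populations.
#
# Emulates the read population recovered by junction PCR: every read is the
# predicted blunt-fusion product carrying one contiguous deletion that
# overlaps or abuts the breakpoint, optionally placed at a flanking
# microhomology, optionally with a non-templated insertion at the junction.
# The paired truth table records the generative scar of each read.

size_dist <- function(x, name) {
  if (is.numeric(x) && length(x) == 1L) x <- list(name = "point", size = x)
  if (!is.list(x) || is.null(x$name))
    stopf("'%s' must be list(name = ..., ...) or a single number", name)
  x$name <- match.arg(x$name, c("point", "geometric", "empirical"))
  x
}

draw_sizes <- function(dist, n, min_size = 0L) {
  switch(dist$name,
    point = rep.int(as.integer(dist$size), n),
    geometric = {
      mu <- dist$mean - min_size
      if (mu < 0) stopf("geometric mean below distribution minimum")
      min_size + if (mu == 0) integer(n) else rgeom(n, 1 / (1 + mu))
    },
    empirical = sample(as.integer(dist$values), n, replace = TRUE,
                       prob = dist$probs))
}

#' Parameters for the junction-read simulator
#'
#' @param n_reads Number of reads to generate.
#' @param deletion_size_dist Deletion size distribution: a single number
#'   (point mass) or `list(name = "geometric", mean = )` /
#'   `list(name = "empirical", values = , probs = )`. Default geometric
#'   with mean 20 bp, the order of magnitude of junction deletion medians
#'   in Polymerase-theta-proficient cells.
#' @param mh_propensity Probability that a deletion is placed at a
#'   flanking microhomology (default 0.5).
#' @param insertion_rate Probability of a non-templated junction insertion
#'   (default 0.1).
#' @param insertion_length_dist Insertion length distribution (lengths
#'   >= 1); default geometric with mean 3 bp.
#' @param read_trim Maximum bases removed from each outer read end
#'   (default 0; the scar classifier expects untrimmed, primer-anchored
#'   reads).
#' @param seed Integer seed.
#' @return Validated parameter list of class `scar_sim_params`.
#' @export
scar_sim_params <- function(n_reads,
                            deletion_size_dist = list(name = "geometric",
                                                      mean = 20),
                            mh_propensity = 0.5,
                            insertion_rate = 0.1,
                            insertion_length_dist = list(name = "geometric",
                                                         mean = 3),
                            read_trim = 0L, seed = 1L) {
  n_reads <- check_count(n_reads, "n_reads")
  check_prob(mh_propensity, "mh_propensity")
  check_prob(insertion_rate, "insertion_rate")
  read_trim <- check_count(read_trim, "read_trim")
  seed <- check_count(seed, "seed")
  structure(list(n_reads = n_reads,
                 deletion_size_dist = size_dist(deletion_size_dist,
                                                "deletion_size_dist"),
                 mh_propensity = mh_propensity,
                 insertion_rate = insertion_rate,
                 insertion_length_dist = size_dist(insertion_length_dist,
                                                   "insertion_length_dist"),
                 read_trim = read_trim, seed = seed),
            class = "scar_sim_params")
}

# Candidate left edges for a d-bp deletion whose interval intersects the
# closed breakpoint window [j-1, j+1] (junction PCR only recovers
# junction-proximal scars).
deletion_placements <- function(d, j, L) {
  if (d < 1L || d > L) return(integer(0))
  lo <- max(0L, j - d)
  hi <- min(j + 1L, L - d)
  if (lo > hi) integer(0) else seq.int(lo, hi)
}

draw_insertion <- function(len, pc, a, d, L) {
  bases <- c("A", "C", "G", "T")
  ins <- sample(bases, len, replace = TRUE)
  # canonicalize: an edge base equal to the flanking product base would be
  # absorbed into an anchor, making the generative scar unrecoverable
  left_ban <- if (a < L) pc[a + 1L] else ""
  right_ban <- if (a + d >= 1L) pc[a + d] else ""
  if (len == 1L) {
    ins[1] <- sample(setdiff(bases, c(left_ban, right_ban)), 1L)
  } else {
    ins[1] <- sample(setdiff(bases, left_ban), 1L)
    ins[len] <- sample(setdiff(bases, right_ban), 1L)
  }
  paste(ins, collapse = "")
}

#' Generate junction reads with a matching scar truth table
#'
#' Each read is the predicted product carrying one contiguous deletion
#' intersecting the closed breakpoint window `[j-1, j+1]`, with the
#' deletion size drawn from `deletion_size_dist`. With probability
#' `mh_propensity` the deletion is placed at a flanking repeat
#' (microhomology >= 1 bp) when one is available; otherwise a slide-free
#' placement is preferred so the generated scar representation is unique.
#' With probability `insertion_rate` a non-templated insertion is added at
#' the junction, with edge bases redrawn so they cannot be absorbed into
#' an anchor (canonical minimal representation).
#'
#' Deletions too large for the product are rejected and redrawn. When an
#' MH placement is requested but no repeat is available the event falls
#' back to a non-MH placement (`mh_event = FALSE` in truth). The truth
#' table always records the re-measurable scar of the emitted read:
#' `del_size`, `del_start` (canonical, rightmost placement), `insertion`,
#' and `mh_len` (junction-shift ambiguity).
#'
#' @param template A [junction_template()].
#' @param params A [scar_sim_params()].
#' @return List with `reads` (named character vector) and `truth`
#'   (data.frame: `read_id, del_size, del_start, insertion, mh_len,
#'   mh_event, trim_left, trim_right`).
#' @export
gen_junction_reads <- function(template, params) {
  stopifnot(inherits(template, "junction_template"),
            inherits(params, "scar_sim_params"))
  prod <- template$product_seq
  L <- nchar(prod)
  j <- template$j
  pc <- strsplit(prod, "")[[1]]
  n <- params$n_reads
  if (n == 0L)
    return(list(reads = setNames(character(0), character(0)),
                truth = data.frame(read_id = character(0),
                                   del_size = integer(0),
                                   del_start = integer(0),
                                   insertion = character(0),
                                   mh_len = integer(0),
                                   mh_event = logical(0),
                                   trim_left = integer(0),
                                   trim_right = integer(0))))
  with_substream(params$seed, "junction_reads", {
    reads <- character(n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      d <- NA_integer_; placements <- integer(0); tries <- 0L
      repeat {
        d <- draw_sizes(params$deletion_size_dist, 1L)
        if (d == 0L) break
        placements <- deletion_placements(d, j, L)
        if (length(placements) > 0L) break
        tries <- tries + 1L
        if (tries > 1000L)
          stopf("could not place a deletion after 1000 draws; product too short")
      }
      mh_event <- FALSE
      if (d == 0L) {
        a <- j
        m <- 0L
      } else {
        mh_per <- vapply(placements, function(a)
          sum(product_mh(pc, a, L - a - d, L)), integer(1))
        want_mh <- runif(1) < params$mh_propensity
        if (want_mh && any(mh_per > 0L)) {
          mh_event <- TRUE
          pool <- placements[mh_per > 0L]
        } else if (any(mh_per == 0L)) {
          pool <- placements[mh_per == 0L]
        } else {
          pool <- placements[mh_per == min(mh_per)]
        }
        a <- if (length(pool) == 1L) pool else sample(pool, 1L)
        m <- sum(product_mh(pc, a, L - a - d, L))
      }
      ins <- ""
      if (runif(1) < params$insertion_rate) {
        ilen <- draw_sizes(params$insertion_length_dist, 1L, min_size = 1L)
        ins <- draw_insertion(ilen, pc, a, d, L)
      }
      read <- paste0(substr(prod, 1L, a), ins,
                     substr(prod, a + d + 1L, L))
      tl <- tr <- 0L
      if (params$read_trim > 0L) {
        tl <- sample.int(params$read_trim + 1L, 1L) - 1L
        tr <- sample.int(params$read_trim + 1L, 1L) - 1L
        read <- substr(read, tl + 1L, nchar(read) - tr)
      }
      reads[i] <- read
      truth[[i]] <- data.frame(read_id = sprintf("read_%d", i),
                               del_size = d, del_start = a,
                               insertion = ins, mh_len = m,
                               mh_event = mh_event,
                               trim_left = tl, trim_right = tr,
                               stringsAsFactors = FALSE)
    }
    names(reads) <- sprintf("read_%d", seq_len(n))
    list(reads = reads, truth = do.call(rbind, truth))
  })
}

#' A synthetic default junction template carrying the Rosa26/H3f3b guides
#'
#' Builds a reproducible pair of synthetic 240-bp parental loci with the
#' Rosa26 and H3f3b protospacers (plus TGG PAMs) embedded at offset 100,
#' and returns the predicted translocation product. The flanking sequence
#' is synthetic (seeded random DNA); only the guide sequences are real.
#'
#' @param flank_seed Seed for the synthetic flanks (default 7421).
#' @return A [junction_template()].
#' @export
default_junction_template <- function(flank_seed = 7421L) {
  guide_a <- "ACTCCAGTCTTTCTAGAAGA"  # Rosa26 protospacer
  guide_b <- "GTTGGCTCGCCGGATACGGG"  # H3f3b protospacer
  withr::with_seed(flank_seed, {
    repeat {
      pa <- paste0(random_dna(100), guide_a, "TGG", random_dna(117))
      pb <- paste0(random_dna(100), guide_b, "TGG", random_dna(117))
      ok <- tryCatch({
        guide_cut_site(pa, guide_a); guide_cut_site(pb, guide_b); TRUE
      }, error = function(e) FALSE)
      if (ok) break  # redraw if a flank duplicated a guide by chance
    }
    build_predicted_junction(pa, pb, guide_a, guide_b)
  })
}

#' Write junction reads to FASTA
#'
#' @param reads Named character vector of reads.
#' @param path Output FASTA path.
#' @return `path`, invisibly. `read_junction_fasta()` returns a named
#'   character vector.
#' @export
write_junction_fasta <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_junction_fasta
#' @param path Input FASTA path.
#' @export
read_junction_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
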