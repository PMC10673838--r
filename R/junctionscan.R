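# Translocation junction construction and scar classification.
#
# A translocation product is modelled as the blunt fusion of the retained
# side of each parental locus: product = parent_a[0, cut_a) + parent_b[cut_b,
# len). Observed junction reads are primer-anchored PCR products that start
# and end exactly like the predicted product; the scar (deletion, insertion,
# microhomology) lives at the fusion point. Coordinates are 0-based,
# half-open throughout; `j = cut_a` is the index of the first parent-B base.

#' Construct a predicted translocation junction from explicit cut positions
#'
#' @param parent_a,parent_b Uppercase ACGTN parental sequences.
#' @param cut_a 0-based offset into `parent_a`; bases `[0, cut_a)` are
#'   retained.
#' @param cut_b 0-based offset into `parent_b`; bases `[cut_b, len)` are
#'   retained.
#' @return A `junction_template`: list with `parent_a_seq`, `parent_b_seq`,
#'   `cut_a`, `cut_b`, `product_seq`, and the junction coordinate `j`
#'   (0-based product coordinate of the first parent-B base).
#' @examples
#' junction_template("AAAA", "CCCC", 4, 0)$product_seq  # "AAAACCCC"
#' @export
junction_template <- function(parent_a, parent_b, cut_a, cut_b) {
  valid_dna(parent_a, "parent_a", allow_empty = FALSE)
  valid_dna(parent_b, "parent_b", allow_empty = FALSE)
  cut_a <- check_count(cut_a, "cut_a")
  cut_b <- check_count(cut_b, "cut_b")
  if (cut_a > nchar(parent_a)) stopf("cut_a beyond end of parent_a")
  if (cut_b > nchar(parent_b)) stopf("cut_b beyond end of parent_b")
  product <- paste0(substr(parent_a, 1L, cut_a),
                    substr(parent_b, cut_b + 1L, nchar(parent_b)))
  structure(list(parent_a_seq = parent_a, parent_b_seq = parent_b,
                 cut_a = cut_a, cut_b = cut_b,
                 product_seq = product, j = cut_a),
            class = "junction_template")
}

#' @export
print.junction_template <- function(x, ...) {
  cat(sprintf("junction_template: product %d bp, junction at %d\n",
              nchar(x$product_seq), x$j))
  invisible(x)
}

# Locate a protospacer in a parent sequence (either strand) and return the
# blunt Cas9 cut coordinate: 3 bp 5' of the PAM, i.e. between protospacer
# positions 17 and 18 for a 20-mer. The PAM (NGG, strand-aware) must be
# present immediately 3' of the protospacer.
guide_cut_site <- function(parent, guide, label = "guide") {
  valid_dna(parent, "parent", allow_empty = FALSE)
  valid_dna(guide, label, allow_empty = FALSE)
  glen <- nchar(guide)
  if (glen < 17L) stopf("'%s' must be at least 17 nt", label)
  subj <- Biostrings::DNAString(parent)
  fwd <- Biostrings::start(Biostrings::matchPattern(guide, subj)) - 1L
  rev <- Biostrings::start(Biostrings::matchPattern(revcomp(guide), subj)) - 1L
  nhit <- length(fwd) + length(rev)
  if (nhit == 0L) stopf("guide '%s' not found in parent on either strand", label)
  if (nhit > 1L) stopf("guide '%s' matches %d times; must be unique", label, nhit)
  plen <- nchar(parent)
  if (length(fwd) == 1L) {
    g <- fwd
    pam <- substr(parent, g + glen + 1L, g + glen + 3L)
    if (nchar(pam) < 3L || substr(pam, 2L, 3L) != "GG")
      stopf("guide '%s': no NGG PAM adjacent to forward-strand match", label)
    g + glen - 3L
  } else {
    g <- rev
    if (g < 3L || substr(parent, g - 2L, g - 1L) != "CC")
      stopf("guide '%s': no NGG PAM adjacent to reverse-strand match", label)
    g + 3L
  }
}

#' Build the predicted translocation product from two guide RNAs
#'
#' Each guide must occur exactly once in its parent (on either strand) with
#' an adjacent NGG PAM. The cut is the blunt Cas9 cut 3 bp 5' of the PAM
#' (between protospacer positions 17 and 18 for a 20-mer), strand-aware.
#' The product joins the PAM-distal upstream piece of parent A to the
#' downstream piece of parent B.
#'
#' @param parent_a,parent_b Parental locus sequences (uppercase ACGTN).
#' @param guide_a,guide_b Protospacer sequences (no PAM).
#' @return A [junction_template()].
#' @export
build_predicted_junction <- function(parent_a, parent_b, guide_a, guide_b) {
  cut_a <- guide_cut_site(parent_a, guide_a, "guide_a")
  cut_b <- guide_cut_site(parent_b, guide_b, "guide_b")
  junction_template(parent_a, parent_b, cut_a, cut_b)
}

# Anchored prefix length of `x` against `y`, allowing up to `mm` internal
# mismatches (anchor must end on a match); N never matches anything.
anchored_prefix <- function(x, y, mm = 0L) {
  n <- min(nchar(x), nchar(y))
  if (n == 0L) return(0L)
  xc <- strsplit(substr(x, 1L, n), "")[[1]]
  yc <- strsplit(substr(y, 1L, n), "")[[1]]
  eq <- xc == yc & xc != "N" & yc != "N"
  ok <- which(eq & cumsum(!eq) <= mm)
  if (length(ok) == 0L) 0L else max(ok)
}

revstr <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")

# Maximal k such that product[a-k, a) == product[b-k, b) (0-based), k <= kmax.
slide_left <- function(prod_chars, a, b, kmax) {
  k <- 0L
  while (k < kmax && prod_chars[a - k] == prod_chars[b - k] &&
         prod_chars[a - k] != "N") k <- k + 1L
  k
}

# Maximal k such that product[a, a+k) == product[b, b+k), k <= kmax.
slide_right <- function(prod_chars, a, b, kmax) {
  k <- 0L
  while (k < kmax && prod_chars[a + 1L + k] == prod_chars[b + 1L + k] &&
         prod_chars[a + 1L + k] != "N") k <- k + 1L
  k
}

# Microhomology (junction-shift ambiguity) of the deletion [p, L-s) in the
# product: how far the deletion can slide left/right leaving the product
# decomposition unchanged. Returns c(m_left, m_right). Degenerate d == 0
# reports 0 (a zero-length deletion has no flank ambiguity).
product_mh <- function(prod_chars, p, s, L) {
  d <- L - p - s
  if (d <= 0L) return(c(0L, 0L))
  ml <- slide_left(prod_chars, p, L - s, min(p, L - s))
  mr <- slide_right(prod_chars, p, L - s, min(s, L - p))
  c(ml, mr)
}

classify_one <- function(read, template, min_anchor, mm) {
  prod <- template$product_seq
  L <- nchar(prod)
  n <- nchar(read)
  P <- anchored_prefix(read, prod, mm)
  S <- anchored_prefix(revstr(read), revstr(prod), mm)
  M <- min(n, L)
  Tt <- min(P + S, M)          # bases explained by anchors
  p <- min(P, Tt)              # overlap excess assigned to the prefix
  s <- Tt - p
  d <- L - Tt
  ins <- substr(read, p + 1L, n - s)
  pc <- strsplit(prod, "")[[1]]
  m2 <- product_mh(pc, p, s, L)
  ml <- m2[1]; mr <- m2[2]
  # junction-proximal read region: 1 base into each anchor + unexplained core
  core <- substr(read, max(1L, p), min(n, n - s + 1L))
  perfect <- d == 0L && nchar(ins) == 0L   # read equals the product
  excluded <- !perfect &&
    (grepl("N", core, fixed = TRUE) || p < min_anchor || s < min_anchor)
  m <- ml + mr
  mh_start <- p - ml
  mh_end <- p + mr
  data.frame(
    p = p, s = s, d = d,
    del_start = p, del_end = L - s,
    insertion = ins,
    mh_len = m,
    mh_seq = if (m > 0L) substr(prod, mh_start + 1L, mh_end) else "",
    mh_start = mh_start, mh_end = mh_end,
    excluded = excluded,
    stringsAsFactors = FALSE)
}

#' Classify junction reads into deletion/insertion/microhomology scars
#'
#' Each read is decomposed against the predicted product by anchored exact
#' matching: `p` = longest common prefix, `s` = longest common suffix,
#' capped so the anchors never over-explain the read (excess assigned to
#' the prefix). The deletion is the unexplained product interval
#' `[p, L - s)` with size `d = L - p - s`; the insertion is the unexplained
#' read core. Microhomology is the junction-shift ambiguity of the deletion
#' within the product: the maximal left/right slide of the deletion interval
#' over identical flanking sequence, reported as length, sequence and
#' half-open span. Reads with `d = 0` and no insertion report `m = 0`.
#'
#' Reads carrying an `N` within 1 bp of the junction, or with an anchor
#' shorter than `min_anchor`, are flagged `excluded = TRUE` (their scar
#' fields are still populated). `N` matches nothing.
#'
#' @param reads Character vector of uppercase ACGTN reads; names become
#'   `read_id` (auto-numbered if unnamed).
#' @param template A [junction_template()].
#' @param min_anchor Minimum anchor length on each side before a read is
#'   flagged excluded (default 10; primer-anchored products comfortably
#'   exceed this).
#' @param max_anchor_mismatch Mismatches tolerated inside each anchor
#'   (default 0; keep 0 for exact oracle equivalence).
#' @return A data.frame of class `junction_calls`, one row per read, with
#'   columns `read_id, p, s, d, del_start, del_end, insertion, mh_len,
#'   mh_seq, mh_start, mh_end, excluded`. Invariants: `p + s + nchar(insertion)
#'   = nchar(read)` and `p + s + d = L`.
#' @examples
#' tpl <- junction_template("TTTGGATC", "GATCCAAA", 8, 0)
#' classify_junction("TTTGGATCCAAA", tpl, min_anchor = 0)
#' @export
classify_junction <- function(reads, template, min_anchor = 10L,
                              max_anchor_mismatch = 0L) {
  stopifnot(inherits(template, "junction_template"))
  if (!is.character(reads) || length(reads) == 0L)
    stopf("'reads' must be a non-empty character vector")
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read_%d", seq_along(reads))
  for (r in reads) valid_dna(r, "read", allow_empty = FALSE)
  rows <- lapply(reads, classify_one, template = template,
                 min_anchor = min_anchor, mm = max_anchor_mismatch)
  calls <- do.call(rbind, rows)
  calls <- cbind(read_id = ids, calls, stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  class(calls) <- c("junction_calls", "data.frame")
  attr(calls, "template") <- template
  calls
}

#' Per-read deletion sizes and their median
#'
#' Excluded reads are dropped first. The median uses the standard
#' midpoint-of-two rule for even counts (half-integer medians are
#' expected for junction deletion spectra).
#'
#' @param calls A `junction_calls` data.frame.
#' @return List with `sizes` (named numeric, one entry per non-excluded
#'   read) and `median`.
#' @export
deletion_sizes <- function(calls) {
  stopifnot(is.data.frame(calls))
  keep <- calls[!calls$excluded, , drop = FALSE]
  if (nrow(keep) == 0L) stopf("all reads are excluded; no deletion sizes")
  list(sizes = setNames(keep$d, keep$read_id), median = median(keep$d))
}

#' Per-coordinate deletion and microhomology frequency profiles
#'
#' For each product coordinate in `[j - window, j + window)`, the fraction
#' of non-excluded reads whose deletion interval (resp. microhomology span)
#' covers it.
#'
#' @param calls A `junction_calls` data.frame.
#' @param template The [junction_template()] the calls were made against.
#' @param window Bases on each side of the junction (>= 1).
#' @return Data.frame with `rel_coord` (coordinate minus `j`), `del_freq`,
#'   `mh_freq`; attribute `n_reads` gives the non-excluded read count.
#' @export
position_profiles <- function(calls, template, window = 50L) {
  window <- check_count(window, "window", min = 1L)
  stopifnot(inherits(template, "junction_template"))
  keep <- calls[!calls$excluded, , drop = FALSE]
  if (nrow(keep) == 0L) stopf("no non-excluded calls to profile")
  rel <- seq.int(-window, window - 1L)
  coord <- template$j + rel
  n <- nrow(keep)
  del_freq <- vapply(coord, function(co)
    sum(keep$del_start <= co & co < keep$del_end) / n, numeric(1))
  mh_freq <- vapply(coord, function(co)
    sum(keep$mh_len > 0L & keep$mh_start <= co & co < keep$mh_end) / n,
    numeric(1))
  out <- data.frame(rel_coord = rel, del_freq = del_freq, mh_freq = mh_freq)
  attr(out, "n_reads") <- n
  out
}

#' Translocation frequency from a well positivity grid
#'
#' Junction PCR is run on pooled wells with technical replicates; the
#' frequency is the percentage of positive wells. Because "positive across
#' both technical replicates" is ambiguous, the positivity rule is
#' configurable: `"any"` (default; detected in >= 1 replicate), `"all"`
#' (every replicate), or `"sum"` (percentage of positive well-replicate
#' reactions).
#'
#' @param grid Logical matrix (wells x replicates) or a data.frame with
#'   columns `well`, `replicate`, `detected`.
#' @param rule Positivity rule, see above.
#' @return Percent positive in `[0, 100]`.
#' @examples
#' g <- rbind(c(TRUE, FALSE), c(FALSE, FALSE), c(TRUE, TRUE),
#'            c(FALSE, FALSE), c(FALSE, TRUE))
#' translocation_frequency(g)          # 60
#' translocation_frequency(g, "all")   # 20
#' @export
translocation_frequency <- function(grid, rule = c("any", "all", "sum")) {
  rule <- match.arg(rule)
  if (is.data.frame(grid)) {
    need <- c("well", "replicate", "detected")
    if (!all(need %in% names(grid)))
      stopf("grid data.frame needs columns: %s", paste(need, collapse = ", "))
    grid <- tapply(as.logical(grid$detected),
                   list(grid$well, grid$replicate), any)
  }
  if (!is.matrix(grid) || nrow(grid) < 1L)
    stopf("grid must be a well x replicate matrix with at least one well")
  storage.mode(grid) <- "logical"
  if (anyNA(grid)) stopf("grid contains missing well/replicate entries")
  switch(rule,
    any = 100 * mean(rowSums(grid) >= 1L),
    all = 100 * mean(rowSums(grid) == ncol(grid)),
    sum = 100 * sum(grid) / length(grid))
}
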