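# Independent oracles used across the suite. These deliberately share no
# code with the package: plain character vectors, explicit loops, and
# exhaustive enumeration.

# Brute-force junction decomposition: enumerate every anchored (p, s) with
# read[0:p] == product[0:p] and matching suffixes, keep the decompositions
# with minimal total unexplained bases, and measure (d, insertion length,
# product-flank MH at the canonical max-p decomposition, and the
# breakpoint-shift range across optimal decompositions).
oracle_classify <- function(read, prod) {
  n <- nchar(read); L <- nchar(prod)
  rc <- strsplit(read, "")[[1]]
  pc <- strsplit(prod, "")[[1]]
  best <- -1L
  opts <- list()
  for (p in 0:min(n, L)) {
    if (p > 0 && !all(rc[1:p] == pc[1:p])) break
    for (s in 0:(min(n, L) - p)) {
      if (s > 0 && !all(rc[(n - s + 1):n] == pc[(L - s + 1):L])) break
      if (p + s > best) { best <- p + s; opts <- list() }
      if (p + s == best) opts[[length(opts) + 1]] <- c(p, s)
    }
  }
  d <- L - best
  ilen <- n - best
  ps <- vapply(opts, `[`, numeric(1), 1)
  p <- max(ps); s <- best - p
  ml <- 0L
  if (d > 0) while (ml < min(p, L - s) && pc[p - ml] == pc[L - s - ml])
    ml <- ml + 1L
  mr <- 0L
  if (d > 0) while (mr < min(s, L - p) && pc[p + 1 + mr] == pc[L - s + 1 + mr])
    mr <- mr + 1L
  list(d = d, ilen = ilen, m = ml + mr, shift_range = max(ps) - min(ps),
       p = p, s = s)
}

oracle_revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Naive sliding-window motif scan.
oracle_motif_scan <- function(seq, motif) {
  L <- nchar(seq); k <- nchar(motif)
  hits <- integer(0)
  for (i in 1:(L - k + 1)) if (substr(seq, i, i + k - 1) == motif)
    hits <- c(hits, i - 1L)
  hits
}

# Exhaustive gamete enumeration for a multi-locus cross: every combination
# of transmitted alleles, each with probability (1/2)^(2 * n_loci), thinned
# by survival and renormalized.
oracle_mendelian <- function(parent1, parent2, loci, lethal = list()) {
  canon <- function(a) {
    a <- a[order(tolower(a), a, method = "radix")]
    paste(a, collapse = if (any(nchar(a) > 1)) "/" else "")
  }
  idx <- expand.grid(rep(list(1:2), 2 * length(loci)))
  tot <- list()
  for (r in seq_len(nrow(idx))) {
    parts <- character(length(loci))
    for (k in seq_along(loci)) {
      a1 <- parent1[[loci[k]]][idx[r, 2 * k - 1]]
      a2 <- parent2[[loci[k]]][idx[r, 2 * k]]
      parts[k] <- canon(c(a1, a2))
    }
    names(parts) <- loci
    surv <- 1
    for (ld in lethal)
      if (all(parts[names(ld$match)] == ld$match)) surv <- surv * ld$survival
    lab <- paste(parts, collapse = ";")
    tot[[lab]] <- (tot[[lab]] %||% 0) + surv / nrow(idx)
  }
  v <- unlist(tot)
  v <- v / sum(v)
  v[order(names(v), method = "radix")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Direct per-base recount of binned signal.
oracle_bin <- function(vec, center, window, bin_size) {
  nb <- 2 * window / bin_size
  out <- numeric(nb)
  for (b in seq_len(nb)) {
    for (pos0 in (center - window + (b - 1) * bin_size):
                 (center - window + b * bin_size - 1)) {
      if (pos0 >= 0 && pos0 < length(vec)) out[b] <- out[b] + vec[pos0 + 1]
    }
  }
  out
}

random_product_template <- function(L) {
  prod <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  # cut_b = 1 on a 1-bp parent_b contributes nothing: product == parent_a
  junction_template(prod, "A", L, 1L)
}
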