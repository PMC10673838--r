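# Mendelian cross expectations with lethality renormalization, chi-square
# goodness of fit, marker-chromosome normalization, and 4-parameter
# log-logistic dose-response (IC50) fitting.

canon_genotype <- function(alleles) {
  # uppercase allele first within a locus ("Aa", never "aA"); multi-char
  # allele names are joined with "/" ("CC/+"); radix = byte order, so the
  # labels do not depend on the session locale
  ord <- order(tolower(alleles), alleles, method = "radix")
  a <- alleles[ord]
  sep <- if (any(nchar(a) > 1L)) "/" else ""
  paste(a, collapse = sep)
}

#' Define a (multi-locus) cross
#'
#' Loci are treated as unlinked (independent assortment); each parent
#' transmits either allele of a locus with probability 1/2. Lethal
#' genotype predicates remove (or thin) matching genotype classes before
#' birth.
#'
#' @param loci Character vector of locus names.
#' @param parent1,parent2 Named lists (one entry per locus) of length-2
#'   allele vectors, e.g. `list(Polq = c("+", "-"))`.
#' @param lethal List of predicates, each
#'   `list(match = c(locus = "genotype"), survival = )`: offspring whose
#'   genotype matches every named locus survive with the given fraction
#'   (0 = fully lethal; fractions multiply across matching predicates).
#' @return Validated list of class `cross_spec`.
#' @examples
#' cross_spec("A", list(A = c("A", "a")), list(A = c("A", "a")),
#'            lethal = list(list(match = c(A = "aa"), survival = 0)))
#' @export
cross_spec <- function(loci, parent1, parent2, lethal = list()) {
  if (length(loci) == 0L) stopf("cross has no loci")
  for (p in list(parent1, parent2)) {
    if (!all(loci %in% names(p)))
      stopf("both parents must specify every locus")
    if (!all(vapply(p[loci], length, integer(1)) == 2L))
      stopf("each locus genotype must be a length-2 allele vector")
  }
  for (ld in lethal) {
    if (is.null(ld$match) || is.null(ld$survival))
      stopf("each lethal entry needs 'match' and 'survival'")
    check_prob(ld$survival, "survival")
  }
  structure(list(loci = loci, parent1 = parent1[loci],
                 parent2 = parent2[loci], lethal = lethal),
            class = "cross_spec")
}

locus_offspring_dist <- function(a1, a2) {
  combos <- expand.grid(g1 = a1, g2 = a2, stringsAsFactors = FALSE)
  labs <- apply(combos, 1, function(x) canon_genotype(x))
  p <- tapply(rep(0.25, 4), labs, sum)
  setNames(as.numeric(p), names(p))
}

survival_of <- function(cross, genotype_parts) {
  # genotype_parts: named character, per-locus canonical genotype
  s <- 1
  for (ld in cross$lethal) {
    if (all(genotype_parts[names(ld$match)] == ld$match))
      s <- s * ld$survival
  }
  s
}

#' Expected offspring genotype proportions for a cross
#'
#' Per-locus transmission probabilities are multiplied across unlinked
#' loci; lethal predicates thin matching genotypes by their survival
#' fraction and the distribution is renormalized to sum to 1.
#'
#' @param cross A [cross_spec()].
#' @param apply_lethality Apply the lethal set (default TRUE).
#' @return Named numeric vector of genotype proportions (names join locus
#'   genotypes with `";"` in locus order).
#' @examples
#' cr <- cross_spec("A", list(A = c("A", "a")), list(A = c("A", "a")))
#' mendelian_expected(cr)  # AA 1/4, Aa 1/2, aa 1/4
#' @export
mendelian_expected <- function(cross, apply_lethality = TRUE) {
  stopifnot(inherits(cross, "cross_spec"))
  per_locus <- lapply(cross$loci, function(l)
    locus_offspring_dist(cross$parent1[[l]], cross$parent2[[l]]))
  grids <- expand.grid(lapply(per_locus, names), stringsAsFactors = FALSE)
  names(grids) <- cross$loci
  probs <- rep(1, nrow(grids))
  for (k in seq_along(per_locus))
    probs <- probs * per_locus[[k]][grids[[k]]]
  if (apply_lethality && length(cross$lethal) > 0L) {
    surv <- vapply(seq_len(nrow(grids)), function(i) {
      parts <- setNames(as.character(grids[i, ]), cross$loci)
      survival_of(cross, parts)
    }, numeric(1))
    probs <- probs * surv
    if (sum(probs) == 0) stopf("all genotypes lethal; expectation undefined")
  }
  labs <- apply(grids, 1, paste, collapse = ";")
  out <- probs / sum(probs)
  names(out) <- labs
  out[order(labs, method = "radix")]
}

#' Chi-square goodness-of-fit test for genotype counts
#'
#' `chi2 = sum (O - E)^2 / E` with `E = proportion * total`,
#' `df = categories - 1`, upper-tail p-value. Categories are aligned by
#' name; expected categories absent from `observed` count as 0.
#'
#' @param observed Named integer vector of observed counts.
#' @param expected Named numeric vector of expected proportions (> 0).
#' @return List `chi2`, `df`, `p`.
#' @export
gof_chisq <- function(observed, expected) {
  if (length(expected) < 2L) stopf("need >= 2 categories")
  if (any(expected <= 0)) stopf("expected proportions must be > 0")
  expected <- expected / sum(expected)
  if (!is.null(names(expected)) && !is.null(names(observed))) {
    extra <- setdiff(names(observed), names(expected))
    if (length(extra) > 0L)
      stopf("observed categories not in expected: %s",
            paste(extra, collapse = ", "))
    obs <- setNames(rep(0, length(expected)), names(expected))
    obs[names(observed)] <- observed
    observed <- obs
  } else if (length(observed) != length(expected)) {
    stopf("observed and expected must align by name or length")
  }
  n <- sum(observed)
  if (n == 0) stopf("total observed count is 0")
  E <- expected * n
  chi2 <- sum((observed - E)^2 / E)
  df <- length(expected) - 1L
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Two-sided binomial genotype test via chi-square goodness of fit
#'
#' Tests a single genotype's observed count against its expected
#' proportion using the two-category chi-square (df = 1, no continuity
#' correction), matching the convention of reporting one test per
#' genotype.
#'
#' @param observed_k Observed count of the genotype.
#' @param n Total offspring.
#' @param p0 Expected proportion in (0, 1).
#' @return List `chi2`, `df`, `p`.
#' @export
binomial_genotype_test <- function(observed_k, n, p0) {
  n <- check_count(n, "n", min = 1L)
  observed_k <- check_count(observed_k, "observed_k")
  if (observed_k > n) stopf("observed_k cannot exceed n")
  if (p0 <= 0 || p0 >= 1) stopf("p0 must be in (0, 1)")
  gof_chisq(c(genotype = observed_k, other = n - observed_k),
            c(genotype = p0, other = 1 - p0))
}

#' Normalize marker-chromosome counts to 40 chromosomes per metaphase
#'
#' Mouse metaphases carry 2n = 40 chromosomes; counting markers per 40
#' chromosomes makes polyploid/aneuploid spreads comparable.
#'
#' @param marker_count Markers observed in a metaphase.
#' @param total_chromosomes Chromosomes counted in the same metaphase.
#' @return `marker_count * 40 / total_chromosomes`.
#' @export
marker_normalize <- function(marker_count, total_chromosomes) {
  if (any(total_chromosomes <= 0)) stopf("total_chromosomes must be > 0")
  marker_count * 40 / total_chromosomes
}

fourpl <- function(d, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (d / ic50)^hill)
}

#' Fit a four-parameter log-logistic dose-response curve
#'
#' `response(d) = bottom + (top - bottom) / (1 + (d / ic50)^hill)`.
#' Responses are first normalized to the mean vehicle (dose 0) response
#' when vehicle wells are present. Least squares via `nls` (port
#' algorithm, bounds `bottom >= 0`, `top <= 1.2 * max response`), with a
#' Nelder-Mead fallback. IC50 is the curve midpoint concentration.
#'
#' @param doses Numeric dose vector (may repeat across replicates; 0 =
#'   vehicle).
#' @param responses Colony counts or survival fractions, same length.
#' @param reference_fit Optional `dose_response_fit`; when given,
#'   `fold_change_vs_reference = ic50 / reference ic50`.
#' @param normalize Normalize to vehicle (default TRUE).
#' @return A `dose_response_fit`: list `top, bottom, hill, ic50,
#'   fold_change_vs_reference, sse`.
#' @export
fit_dose_response <- function(doses, responses, reference_fit = NULL,
                              normalize = TRUE) {
  stopifnot(length(doses) == length(responses))
  if (any(doses < 0) || any(responses < 0))
    stopf("doses and responses must be >= 0")
  if (length(unique(doses[doses > 0])) < 4L)
    stopf("need >= 4 distinct positive doses (plus vehicle)")
  if (normalize && any(doses == 0)) {
    v <- mean(responses[doses == 0])
    if (v <= 0) stopf("vehicle response is 0; cannot normalize")
    responses <- responses / v
  }
  mu <- tapply(responses, doses, mean)
  if (diff(range(mu)) < 1e-9 * max(abs(mu), 1))
    stopf("responses are flat across doses; ic50 unidentifiable")
  dpos <- sort(unique(doses[doses > 0]))
  top0 <- max(mu); bottom0 <- min(mu)
  midresp <- (top0 + bottom0) / 2
  mu_pos <- mu[as.numeric(names(mu)) > 0]
  ic50_0 <- as.numeric(names(mu_pos))[which.min(abs(mu_pos - midresp))]
  dat <- data.frame(d = doses, y = responses)
  lower <- c(top = 0, bottom = 0, ic50 = min(dpos) / 1000, hill = 0.1)
  upper <- c(top = 1.2 * max(responses), bottom = max(responses),
             ic50 = max(dpos) * 1000, hill = 20)
  start <- list(top = top0, bottom = bottom0, ic50 = ic50_0, hill = 1)
  fit <- tryCatch(
    nls(y ~ bottom + (top - bottom) / (1 + (d / ic50)^hill), data = dat,
        start = start, lower = lower, upper = upper, algorithm = "port",
        control = list(maxiter = 500, warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- coef(fit)
    sse <- sum((dat$y - fourpl(dat$d, cf["top"], cf["bottom"], cf["ic50"],
                               cf["hill"]))^2)
  } else {
    obj <- function(par) {
      top <- par[1]; bottom <- par[2]
      ic50 <- exp(par[3]); hill <- exp(par[4])
      if (bottom > top) return(1e12)
      sum((dat$y - fourpl(dat$d, top, bottom, ic50, hill))^2)
    }
    o <- optim(c(top0, bottom0, log(ic50_0), 0), obj,
               control = list(maxit = 5000, reltol = 1e-14))
    if (o$convergence != 0)
      stopf("dose-response fit failed to converge (optim code %d, sse %.3g)",
            o$convergence, o$value)
    cf <- c(top = o$par[1], bottom = o$par[2], ic50 = exp(o$par[3]),
            hill = exp(o$par[4]))
    sse <- o$value
  }
  if (cf[["bottom"]] > cf[["top"]])
    stopf("fit inverted (bottom > top); data do not follow a decreasing curve")
  fc <- if (!is.null(reference_fit)) cf[["ic50"]] / reference_fit$ic50
        else NA_real_
  structure(list(top = cf[["top"]], bottom = cf[["bottom"]],
                 hill = cf[["hill"]], ic50 = cf[["ic50"]],
                 fold_change_vs_reference = fc, sse = sse),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("4PL fit: ic50 = %.4g, hill = %.3g, top = %.3g, bottom = %.3g\n",
              x$ic50, x$hill, x$top, x$bottom))
  if (!is.na(x$fold_change_vs_reference))
    cat(sprintf("  fold change vs reference: %.3g\n",
                x$fold_change_vs_reference))
  invisible(x)
}
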