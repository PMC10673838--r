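# Seeded generators for Mendelian cross tables and dose-response colony
# tables.

#' Simulate offspring genotype counts for a cross
#'
#' Offspring genotypes are drawn from the pre-lethality Mendelian
#' distribution, then thinned per genotype by its survival fraction
#' (from the cross's lethal set, or an explicit override map), and
#' tabulated.
#'
#' @param cross A [cross_spec()].
#' @param n_offspring Number of conceptuses drawn before lethality.
#' @param survival Optional named vector genotype -> survival probability
#'   overriding the cross's lethal set (genotypes absent from the map
#'   survive with probability 1).
#' @param seed Integer seed.
#' @return Named integer vector of surviving counts per genotype (all
#'   pre-lethality genotype labels present, possibly 0).
#' @export
gen_cross_counts <- function(cross, n_offspring, survival = NULL, seed = 1L) {
  stopifnot(inherits(cross, "cross_spec"))
  n_offspring <- check_count(n_offspring, "n_offspring")
  seed <- check_count(seed, "seed")
  pre <- mendelian_expected(cross, apply_lethality = FALSE)
  surv <- if (!is.null(survival)) {
    check_prob(min(survival), "survival"); check_prob(max(survival), "survival")
    s <- setNames(rep(1, length(pre)), names(pre))
    s[intersect(names(survival), names(pre))] <-
      survival[intersect(names(survival), names(pre))]
    s
  } else {
    vapply(names(pre), function(lab) {
      parts <- setNames(strsplit(lab, ";", fixed = TRUE)[[1]], cross$loci)
      survival_of(cross, parts)
    }, numeric(1))
  }
  with_substream(seed, "cross_counts", {
    if (n_offspring == 0L)
      return(setNames(integer(length(pre)), names(pre)))
    born <- as.vector(stats::rmultinom(1, n_offspring, pre))
    kept <- rbinom(length(born), born, surv)
    setNames(kept, names(pre))
  })
}

#' Simulate a dose-response colony table
#'
#' Responses follow the 4-parameter log-logistic curve with multiplicative
#' lognormal noise of the given coefficient of variation.
#'
#' @param fit True curve: list/`dose_response_fit` with `top`, `bottom`,
#'   `hill`, `ic50`.
#' @param doses Dose vector (include 0 for vehicle).
#' @param cv_noise Coefficient of variation of the multiplicative noise
#'   (default 0.1; 0 gives the exact curve).
#' @param n_reps Replicates per dose (default 3).
#' @param seed Integer seed.
#' @return Data.frame `dose, replicate, response`.
#' @export
gen_dose_response <- function(fit, doses, cv_noise = 0.1, n_reps = 3L,
                              seed = 1L) {
  stopifnot(all(c("top", "bottom", "hill", "ic50") %in% names(fit)))
  if (cv_noise < 0) stopf("cv_noise must be >= 0")
  n_reps <- check_count(n_reps, "n_reps", min = 1L)
  seed <- check_count(seed, "seed")
  grid <- expand.grid(dose = doses, replicate = seq_len(n_reps))
  mu <- fourpl(grid$dose, fit$top, fit$bottom, fit$ic50, fit$hill)
  with_substream(seed, "dose_response", {
    noise <- if (cv_noise == 0) rep(1, nrow(grid)) else {
      sdlog <- sqrt(log(1 + cv_noise^2))
      exp(rnorm(nrow(grid), -sdlog^2 / 2, sdlog))  # mean-1 lognormal
    }
    data.frame(dose = grid$dose, replicate = grid$replicate,
               response = mu * noise)
  })
}
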