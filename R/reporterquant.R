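# ddPCR repair-reporter scoring (HR percent, TMEJ score) and CRISPR clone
# genotype binning by frameshift status.

#' Droplet count container
#'
#' @param positives Number of positive droplets.
#' @param total Total accepted droplets.
#' @param droplet_volume_nl Droplet volume in nanolitres (default 0.85,
#'   the industry-standard partition volume).
#' @return Validated list of class `droplet_count`.
#' @export
droplet_count <- function(positives, total, droplet_volume_nl = 0.85) {
  positives <- check_count(positives, "positives")
  total <- check_count(total, "total", min = 1L)
  if (positives > total) stopf("positives cannot exceed total")
  check_pos(droplet_volume_nl, "droplet_volume_nl")
  structure(list(positives = positives, total = total,
                 droplet_volume_nl = droplet_volume_nl),
            class = "droplet_count")
}

#' Absolute concentration from droplet occupancy (Poisson inversion)
#'
#' Copies partition into droplets as Poisson; the mean occupancy is
#' recovered from the positive fraction `f` as `lambda = -ln(1 - f)`
#' copies per droplet, and the concentration is `lambda / volume`.
#'
#' @param d A [droplet_count()].
#' @return Copies per microlitre.
#' @export
ddpcr_concentration <- function(d) {
  stopifnot(inherits(d, "droplet_count"))
  if (d$positives == d$total)
    stopf("all droplets positive: reaction saturated, concentration unbounded")
  lambda <- -log(1 - d$positives / d$total)
  lambda / (d$droplet_volume_nl * 1e-3)   # nl -> ul
}

as_copies <- function(x, name) {
  if (inherits(x, "droplet_count")) return(ddpcr_concentration(x))
  if (!is.numeric(x) || any(x < 0)) stopf("'%s' must be non-negative", name)
  x
}

#' HR reporter score: repair copies per 100 genomic copies
#'
#' @param repair_copies Copies of the templated repair product (number or
#'   [droplet_count()]).
#' @param genomic_control_copies Copies from the genomic control reaction.
#' @return Percent: `100 * repair / control`.
#' @export
hr_score <- function(repair_copies, genomic_control_copies) {
  repair <- as_copies(repair_copies, "repair_copies")
  control <- as_copies(genomic_control_copies, "genomic_control_copies")
  if (control <= 0) stopf("genomic control copies must be > 0")
  100 * repair / control
}

#' TMEJ score: summed signature deletion products, normalized to reference
#'
#' The three validated TMEJ products (`del23bp`, `del39bp`, `del95bp`) are
#' summed and divided by the summed products of the reference (wild-type)
#' sample, so the reference scores 1.
#'
#' @param products Named vector/list with entries `del23bp`, `del39bp`,
#'   `del95bp` (numbers or [droplet_count()]s).
#' @param reference_sum Summed TMEJ copies of the reference sample, or a
#'   products vector of the same shape.
#' @return Dimensionless score `sum(products) / reference_sum`.
#' @export
tmej_score <- function(products, reference_sum) {
  need <- c("del23bp", "del39bp", "del95bp")
  miss <- setdiff(need, names(products))
  if (length(miss) > 0L)
    stopf("missing TMEJ product entries: %s", paste(miss, collapse = ", "))
  tot <- sum(vapply(need, function(k) as_copies(products[[k]], k), numeric(1)))
  if (!is.numeric(reference_sum) || is.list(reference_sum) ||
      !is.null(names(reference_sum)))
    reference_sum <- sum(vapply(need, function(k)
      as_copies(reference_sum[[k]], k), numeric(1)))
  if (reference_sum <= 0) stopf("reference_sum must be > 0")
  tot / reference_sum
}

#' Classify a clone's alleles as knockout / retains_function / unedited
#'
#' An allele is `frameshift` when its net indel length is not a multiple
#' of 3, `in_frame` when nonzero and a multiple of 3, `wildtype` at 0
#' (compound alleles use the summed net length). Alleles below the
#' reporting floor are dropped first. A clone is a knockout only if every
#' reported allele is frameshift; all-wildtype clones are unedited; any
#' surviving wild-type or in-frame allele retains function.
#'
#' @param net_indel_lengths Signed net indel length per allele (bp).
#' @param frequencies Optional allele frequencies in `[0, 1]`.
#' @param floor Reporting floor on frequency (default 0.01; alleles at or
#'   below it are not considered).
#' @return One of `"knockout"`, `"retains_function"`, `"unedited"`.
#' @examples
#' classify_clone(c(1, 1))    # knockout
#' classify_clone(c(3, -1))   # retains_function
#' classify_clone(c(0, -2))   # retains_function
#' @export
classify_clone <- function(net_indel_lengths, frequencies = NULL,
                           floor = 0.01) {
  if (length(net_indel_lengths) == 0L) stopf("empty allele list")
  if (!is.null(frequencies)) {
    stopifnot(length(frequencies) == length(net_indel_lengths))
    net_indel_lengths <- net_indel_lengths[frequencies > floor]
    if (length(net_indel_lengths) == 0L)
      stopf("no allele above the reporting floor")
  }
  cls <- ifelse(net_indel_lengths %% 3 != 0, "frameshift",
                ifelse(net_indel_lengths == 0, "wildtype", "in_frame"))
  if (all(cls == "frameshift")) "knockout"
  else if (all(cls == "wildtype")) "unedited"
  else "retains_function"
}

#' Knockout fraction among edited clones
#'
#' Unedited clones are excluded from the denominator; the fraction is
#' knockouts over (knockouts + clones retaining function).
#'
#' @param classifications Character vector of [classify_clone()] results.
#' @return List with `fraction`, and counts `knockout`,
#'   `retains_function`, `unedited`.
#' @export
ko_fraction <- function(classifications) {
  tab <- table(factor(classifications,
                      levels = c("knockout", "retains_function", "unedited")))
  edited <- tab[["knockout"]] + tab[["retains_function"]]
  if (edited == 0L) stopf("no edited clones; knockout fraction undefined")
  list(fraction = tab[["knockout"]] / edited,
       knockout = tab[["knockout"]],
       retains_function = tab[["retains_function"]],
       unedited = tab[["unedited"]])
}

#' Simulate droplet counts by Poisson occupancy
#'
#' @param true_lambda Mean copies per droplet (>= 0).
#' @param n_droplets Number of droplets.
#' @param seed Integer seed.
#' @param droplet_volume_nl Droplet volume (default 0.85 nl).
#' @return A [droplet_count()] with
#'   `positives ~ Binomial(n, 1 - exp(-lambda))`.
#' @export
gen_droplets <- function(true_lambda, n_droplets, seed = 1L,
                         droplet_volume_nl = 0.85) {
  if (!is.numeric(true_lambda) || true_lambda < 0)
    stopf("true_lambda must be >= 0")
  n_droplets <- check_count(n_droplets, "n_droplets", min = 1L)
  seed <- check_count(seed, "seed")
  pos <- with_substream(seed, "droplets",
                        rbinom(1, n_droplets, 1 - exp(-true_lambda)))
  droplet_count(pos, n_droplets, droplet_volume_nl)
}
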