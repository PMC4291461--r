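#' Dominance SD of a fraction vector
#'
#' The standard deviation of the fractional expression values across a
#' subtype's isoform groups at one stage. It is 0 when all isoforms are
#' expressed evenly and maximal (`sqrt(1/n)` of the one-hot vector with the
#' n-1 denominator) when a single isoform carries the whole population, so
#' its rise over developmental time summarises progressive isoform
#' dominance.
#'
#' @param fractions numeric vector over n >= 2 isoform groups, summing to 1
#'   (tolerance 1e-6).
#' @param denominator `"sample"` (n-1, default) or `"population"` (n).
#' @return the scalar SD.
#' @examples
#' dominance_sd(c(1/3, 1/3, 1/3))  # 0
#' dominance_sd(c(1, 0, 0))        # sqrt(1/3)
#' @export
dominance_sd <- function(fractions, denominator = c("sample", "population")) {
  denominator <- match.arg(denominator)
  n <- length(fractions)
  if (n < 2) stop("dominance_sd needs fractions over at least 2 groups")
  if (abs(sum(fractions) - 1) > 1e-6)
    stop("fractions must sum to 1 (got ", format(sum(fractions)), ")")
  s <- stats::sd(fractions)
  if (denominator == "population") s <- s * sqrt((n - 1) / n)
  s
}

#' Dominance trajectory across ordered developmental stages
#'
#' Computes the per-stage dominance SD on the stage mean fraction vectors
#' (one value per stage), identifies each stage's dominant isoform group,
#' and flags whether the SD is non-decreasing along the stage order — the
#' signature of one isoform progressively taking over the population.
#'
#' @param stage_summaries ordered list of `stage_summary` objects over a
#'   consistent group set.
#' @param family family label carried into the output.
#' @param denominator SD denominator convention, see [dominance_sd()].
#' @return object of class `dominance_trajectory`: list with `family`,
#'   `stages` (data.frame `stage`, `dominance_sd`, `dominant_group`,
#'   `dominant_fraction`) and `trend_monotone` (TRUE iff dominance_sd is
#'   non-decreasing over the stage order; vacuously TRUE for one stage).
#' @export
trajectory <- function(stage_summaries, family = "family",
                       denominator = c("sample", "population")) {
  denominator <- match.arg(denominator)
  if (inherits(stage_summaries, "stage_summary")) stage_summaries <- list(stage_summaries)
  stopifnot(length(stage_summaries) >= 1)
  gsets <- lapply(stage_summaries, function(s) names(s$mean_fraction))
  if (!all(vapply(gsets, identical, logical(1), gsets[[1]])))
    stop("stage summaries have inconsistent group sets")

  rows <- lapply(stage_summaries, function(s) {
    f <- s$mean_fraction
    top <- which(f == max(f))
    if (length(top) > 1) {
      warning("dominant-group tie at stage ", s$stage_label,
              "; broken lexicographically")
      top <- top[order(names(f)[top])][1]
    }
    data.frame(stage = s$stage_label,
               dominance_sd = dominance_sd(f, denominator = denominator),
               dominant_group = names(f)[top],
               dominant_fraction = unname(f[top]),
               stringsAsFactors = FALSE)
  })
  stages <- do.call(rbind, rows)
  structure(list(family = family, stages = stages,
                 trend_monotone = all(diff(stages$dominance_sd) >= -1e-12)),
            class = "dominance_trajectory")
}

#' @export
print.dominance_trajectory <- function(x, ...) {
  cat("Dominance trajectory for", x$family, "(",
      if (x$trend_monotone) "non-decreasing" else "not monotone", ")\n")
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' @export
print.fraction_estimate <- function(x, ...) {
  cat("Fraction estimate for", x$sample_id, "(", x$method, ",",
      x$n_informative_reads, "informative reads )\n")
  print(round(x$fractions, 4))
  invisible(x)
}

#' @export
print.stage_summary <- function(x, ...) {
  cat("Stage", x$stage_label, "- n =", x$n_samples,
      ", dominance SD =", round(x$dominance_sd, 4), "\n")
  tab <- data.frame(group = names(x$mean_fraction),
                    mean = round(unname(x$mean_fraction), 4))
  if (!is.null(x$sd_across_samples)) tab$sd <- round(unname(x$sd_across_samples), 4)
  print(tab, row.names = FALSE)
  invisible(x)
}
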