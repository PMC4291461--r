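#' Build the class design matrix from diagnostic regions
#'
#' `A[c, g]` is the number of valid read starts in group `g` whose k-mer
#' yields match class `c` — the sum of the widths of `g`'s diagnostic
#' regions carrying subset `c`. Under uniform read starts the expected count
#' in class `c` is proportional to `sum_g A[c,g] * s_g`, with `s_g` the
#' per-start read intensity of group `g`; the matrix is therefore the
#' coefficient structure of the linear system that deconvolves ambiguous
#' classes.
#'
#' @param regions a `diagnostic_regions` data.frame.
#' @param groups `isoform_groups` data.frame (or named character vector);
#'   used to verify that the regions partition every group's valid starts.
#' @return object of class `class_design`: list with `A` (classes x groups
#'   integer matrix, dimnames set), `classes`, `groups`, and `valid_starts`
#'   per group.
#' @export
build_design_matrix <- function(regions, groups) {
  seqs <- if (is.data.frame(groups)) stats::setNames(groups$sequence, groups$group_id) else groups
  gids <- names(seqs)
  k <- regions$read_length[1]
  valid <- nchar(seqs) - k + 1L

  # regions must tile each carrier's valid starts without overlap or gap
  for (g in gids) {
    rg <- regions[regions$carrier_group == g, , drop = FALSE]
    rg <- rg[order(rg$start_min_1based), , drop = FALSE]
    has_n <- grepl("N", seqs[[g]], fixed = TRUE)
    if (!has_n) {
      covered_ok <- nrow(rg) > 0 &&
        rg$start_min_1based[1] == 1L &&
        rg$start_max_1based[nrow(rg)] == valid[[g]] &&
        (nrow(rg) == 1 ||
           all(rg$start_min_1based[-1] == rg$start_max_1based[-nrow(rg)] + 1L))
      if (!covered_ok)
        stop("inconsistent regions for group ", g,
             ": starts are not partitioned into disjoint contiguous intervals")
    }
  }

  classes <- unique(regions$group_subset)
  A <- matrix(0L, nrow = length(classes), ncol = length(gids),
              dimnames = list(classes, gids))
  w <- regions$start_max_1based - regions$start_min_1based + 1L
  for (i in seq_len(nrow(regions)))
    A[regions$group_subset[i], regions$carrier_group[i]] <-
      A[regions$group_subset[i], regions$carrier_group[i]] + w[i]
  A <- A[rowSums(A) > 0, , drop = FALSE]
  structure(list(A = A, classes = rownames(A), groups = gids,
                 valid_starts = stats::setNames(as.integer(valid), gids),
                 read_length = k),
            class = "class_design")
}

# group ids of a class key
class_members <- function(cls) strsplit(cls, ";", fixed = TRUE)

#' Estimate isoform-group fractions from class counts
#'
#' Two estimators, mirroring the two situations that arise in snRNA
#' families:
#' \describe{
#'   \item{`"unique"`}{usable when every group owns a singleton match class
#'     (a region of reads unique to it): the per-start intensity is
#'     `count / width` of the singleton class and fractions are its
#'     normalisation. Errors out, pointing at the linear system, when some
#'     group has no unique region.}
#'   \item{`"linear_system"` (default)}{solves the non-negative least-squares
#'     problem `min || A s - counts ||_2`, `s >= 0`, over per-start
#'     intensities `s`, then normalises `s` (optionally length-weighted) to
#'     fractions. Works with ambiguous classes and is the only option for
#'     families where some isoforms lack unique regions.}
#' }
#' Structurally confounded groups — identical columns of `A`, i.e. groups no
#' read class can tell apart — are lumped into a composite group with a
#' concatenated id, with a warning.
#'
#' @param counts a `class_counts` object, or a data.frame with `class` and
#'   `count`.
#' @param design a `class_design` from [build_design_matrix()].
#' @param mode `"linear_system"` (default) or `"unique"`.
#' @param sample_id label for the estimate (defaults to the count table's).
#' @param length_weights optional per-group weights applied when converting
#'   per-start intensities to fractions; default 1 for all groups (snRNA
#'   paralogs have near-identical lengths).
#' @return object of class `fraction_estimate`: list with `sample_id`,
#'   `fractions` (named, non-negative, summing to 1), `n_informative_reads`,
#'   `method`, and `lumped` (character vector of composite ids, if any).
#' @export
estimate_fractions <- function(counts, design,
                               mode = c("linear_system", "unique"),
                               sample_id = NULL, length_weights = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "class_design"))
  if (inherits(counts, "class_counts")) {
    if (is.null(sample_id)) sample_id <- counts$sample_id
    counts <- counts$counts
  }
  if (is.null(sample_id)) sample_id <- "sample"

  unknown <- setdiff(counts$class, design$classes)
  if (length(unknown)) {
    warning("dropping ", length(unknown),
            " class(es) absent from the design: ",
            paste(utils::head(unknown, 3), collapse = ", "))
    counts <- counts[counts$class %in% design$classes, , drop = FALSE]
  }
  b <- stats::setNames(numeric(length(design$classes)), design$classes)
  b[counts$class] <- counts$count
  if (sum(b) <= 0) stop("zero informative reads: no counts fall in any design class")

  A <- design$A
  gids <- design$groups
  if (is.null(length_weights)) length_weights <- stats::setNames(rep(1, length(gids)), gids)
  lumped <- character(0)

  if (mode == "unique") {
    singleton <- design$classes[lengths(class_members(design$classes)) == 1]
    missing <- setdiff(gids, singleton)
    if (length(missing))
      stop("group(s) without a singleton class: ",
           paste(missing, collapse = ", "),
           "; use mode = \"linear_system\"")
    s <- vapply(gids, function(g) b[[g]] / A[g, g], numeric(1))
    n_inf <- sum(b[singleton])
  } else {
    # lump structurally confounded groups (identical design columns)
    key <- apply(A, 2, paste, collapse = ",")
    if (anyDuplicated(key)) {
      cells <- split(seq_along(gids), factor(key, levels = unique(key)))
      new_ids <- vapply(cells, function(ix) make_group_id(gids[ix]), character(1))
      lumped <- new_ids[lengths(cells) > 1]
      warning("structurally confounded groups lumped: ",
              paste(lumped, collapse = "; "))
      A <- A[, vapply(cells, `[`, integer(1), 1), drop = FALSE]
      length_weights <- stats::setNames(
        vapply(cells, function(ix) mean(length_weights[gids[ix]]), numeric(1)),
        new_ids)
      gids <- unname(new_ids)
      colnames(A) <- gids
    }
    s <- stats::setNames(pracma::lsqnonneg(A, unname(b))$x, gids)
    n_inf <- sum(b)
  }

  sw <- s * length_weights[gids]
  if (sum(sw) <= 0) stop("degenerate solution: all estimated intensities are zero")
  structure(list(sample_id = sample_id,
                 fractions = stats::setNames(as.numeric(sw / sum(sw)), gids),
                 n_informative_reads = as.integer(n_inf),
                 method = mode, lumped = lumped),
            class = "fraction_estimate")
}

#' Aggregate per-sample fraction estimates into a stage summary
#'
#' Mean fractions are the arithmetic per-group means across the stage's
#' samples, renormalised to sum to 1; across-replicate standard deviations
#' (n-1 denominator) are reported only when more than one sample is
#' available. The stage's dominance SD (spread of the mean fraction vector
#' across isoform groups) is attached when the family has at least two
#' groups.
#'
#' @param estimates list of `fraction_estimate` objects over the same group
#'   set.
#' @param stage_label the stage these samples belong to.
#' @param sd_denominator passed to [dominance_sd()].
#' @return object of class `stage_summary`: list with `stage_label`,
#'   `n_samples`, `mean_fraction` (named), `sd_across_samples` (named, or
#'   `NULL` when `n_samples == 1`) and `dominance_sd`.
#' @export
aggregate_stage <- function(estimates, stage_label,
                            sd_denominator = c("sample", "population")) {
  if (inherits(estimates, "fraction_estimate")) estimates <- list(estimates)
  stopifnot(length(estimates) >= 1)
  gsets <- lapply(estimates, function(e) names(e$fractions))
  if (!all(vapply(gsets, identical, logical(1), gsets[[1]])))
    stop("estimates have mixed group sets; cannot aggregate stage ", stage_label)
  mat <- do.call(rbind, lapply(estimates, `[[`, "fractions"))
  m <- colMeans(mat)
  m <- m / sum(m)
  n <- nrow(mat)
  structure(list(
    stage_label = stage_label, n_samples = n,
    mean_fraction = m,
    sd_across_samples = if (n > 1) apply(mat, 2, stats::sd) else NULL,
    dominance_sd = if (length(m) >= 2)
      dominance_sd(m, denominator = sd_denominator) else NA_real_
  ), class = "stage_summary")
}
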