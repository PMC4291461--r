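#' Generate a synthetic snRNA paralog family with planted variable sites
#'
#' Emulates the structure of a real snRNA gene family: a handful of
#' near-identical gene copies, some of which share a byte-identical mature
#' sequence (an "isoform group") while distinct groups differ at a small
#' number of planted nucleotide positions.
#'
#' The family is built from one random backbone sequence; every gene carries
#' the backbone except at `n_variable_sites` planted columns, where each cell
#' of `identical_partition` receives its own residue tuple. Tuples are drawn
#' so that (a) every pair of cells differs at one or more planted columns and
#' (b) every planted column actually varies across cells.
#'
#' @param n_genes number of gene copies in the family.
#' @param seq_length length of every gene sequence, in nt.
#' @param n_variable_sites number of planted variable alignment columns.
#' @param identical_partition list of integer vectors partitioning
#'   `1:n_genes`; genes in the same cell share an identical sequence.
#'   Default: all singletons (every gene its own isoform).
#' @param family family label used to construct gene ids (e.g. `"U5"`).
#' @param seed integer seed; the whole construction is deterministic given it.
#' @return An object of class `synthetic_family`: a list with `genes`
#'   (data.frame of `gene_id`, `sequence`), `alignment` (named character
#'   vector; the sequences are equal-length so the alignment is the identity),
#'   `sites` (planted truth: `column_1based` plus one residue column per
#'   partition cell), `partition`, `family` and `seed`.
#' @examples
#' fam <- generate_family(3, 120, 2, identical_partition = list(1:2, 3), seed = 7)
#' fam$genes$sequence[1] == fam$genes$sequence[2]
#' @export
generate_family <- function(n_genes, seq_length, n_variable_sites,
                            identical_partition = NULL,
                            family = "SYN", seed = 1L) {
  if (is.null(identical_partition)) identical_partition <- as.list(seq_len(n_genes))
  identical_partition <- lapply(identical_partition, as.integer)
  idx <- sort(unlist(identical_partition))
  if (!identical(idx, seq_len(n_genes)))
    stop("identical_partition must partition 1:n_genes exactly")
  n_cells <- length(identical_partition)
  if (n_variable_sites < 0 || n_variable_sites >= seq_length)
    stop("n_variable_sites must satisfy 0 <= n_variable_sites < seq_length")
  if (n_cells >= 2 && n_variable_sites < 1)
    stop("infeasible spec: ", n_cells,
         " distinct isoform groups cannot be distinguished with 0 variable sites")
  if (n_cells > 4^n_variable_sites)
    stop("infeasible spec: ", n_variable_sites, " variable sites admit at most ",
         4^n_variable_sites, " distinguishable groups, need ", n_cells)

  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    backbone <- sample(bases, seq_length, replace = TRUE)
    sites <- if (n_variable_sites > 0) sort(sample.int(seq_length, n_variable_sites)) else integer(0)

    # residue tuples: one row per partition cell, one column per planted site
    res <- matrix("", nrow = n_cells, ncol = n_variable_sites)
    if (n_variable_sites > 0 && n_cells >= 2) {
      repeat {
        for (j in seq_len(n_variable_sites)) res[, j] <- sample(bases, n_cells, replace = TRUE)
        tuples <- apply(res, 1, paste0, collapse = "")
        varies <- vapply(seq_len(n_variable_sites),
                         function(j) length(unique(res[, j])) >= 2, logical(1))
        if (!anyDuplicated(tuples) && all(varies)) break
      }
    } else if (n_variable_sites > 0) {
      # single group: planted sites carry the backbone residue (nothing varies)
      res[1, ] <- backbone[sites]
    }

    seqs <- character(n_genes)
    for (ci in seq_along(identical_partition)) {
      s <- backbone
      if (n_variable_sites > 0) s[sites] <- res[ci, ]
      seqs[identical_partition[[ci]]] <- paste0(s, collapse = "")
    }
  })

  ids <- sprintf("%s:g%02d", family, seq_len(n_genes))
  sites_df <- data.frame(column_1based = sites)
  for (ci in seq_len(n_cells))
    sites_df[[paste0("cell_", ci)]] <- if (n_variable_sites > 0) res[ci, ] else character(0)

  structure(list(
    family    = family,
    genes     = data.frame(gene_id = ids, sequence = seqs, stringsAsFactors = FALSE),
    alignment = stats::setNames(seqs, ids),
    sites     = sites_df,
    partition = identical_partition,
    seed      = seed
  ), class = "synthetic_family")
}

#' Generate a developmental mixture trajectory with a rising dominant isoform
#'
#' Draws one fraction vector per developmental stage from a symmetric
#' Dirichlet distribution whose concentration decreases along the stage
#' order, so early stages are heterogeneous and late stages are dominated by
#' one isoform — the developmental switching pattern the pipeline is built
#' to detect. Two constructive guarantees: the per-stage maximum is placed at
#' `dominant_index`, and the stage vectors are ordered so the dominant
#' fraction is non-decreasing over the stage order.
#'
#' @param n_groups number of isoform groups (>= 2).
#' @param stage_labels ordered character vector of developmental stages.
#' @param alpha_schedule per-stage Dirichlet concentration: a numeric vector
#'   (recycled), the string `"uniform"` for exact 1/n fractions, or `NULL`
#'   for the default geometric decay from 5 down to 0.3 across the stages.
#' @param dominant_index group index that dominates late stages.
#' @param seed integer seed.
#' @return An object of class `mixture_truth`: list with `stage_labels` and
#'   `fractions`, a `length(stage_labels) x n_groups` matrix whose rows sum
#'   to 1.
#' @export
generate_mixture_trajectory <- function(n_groups, stage_labels,
                                        alpha_schedule = NULL,
                                        dominant_index = 1L, seed = 1L) {
  if (length(stage_labels) == 0) stop("stage_labels must be non-empty")
  if (n_groups < 2) stop("n_groups must be >= 2")
  if (dominant_index < 1 || dominant_index > n_groups) stop("dominant_index out of range")
  n_stages <- length(stage_labels)

  if (identical(alpha_schedule, "uniform")) {
    frac <- matrix(1 / n_groups, n_stages, n_groups)
  } else {
    if (is.null(alpha_schedule))
      alpha_schedule <- exp(seq(log(5), log(0.3), length.out = max(n_stages, 2)))[seq_len(n_stages)]
    if (any(alpha_schedule <= 0)) stop("alpha_schedule entries must be > 0")
    alpha_schedule <- rep_len(alpha_schedule, n_stages)
    frac <- withr::with_seed(seed, {
      m <- t(vapply(alpha_schedule, function(a) {
        g <- stats::rgamma(n_groups, shape = a)
        if (sum(g) <= 0) rep(1 / n_groups, n_groups) else g / sum(g)
      }, numeric(n_groups)))
      # plant the dominant isoform: swap each stage's max into dominant_index
      for (s in seq_len(n_stages)) {
        j <- which.max(m[s, ])
        m[s, c(dominant_index, j)] <- m[s, c(j, dominant_index)]
      }
      m[order(m[, dominant_index]), , drop = FALSE]
    })
  }
  frac <- frac / rowSums(frac)
  dimnames(frac) <- list(stage_labels, NULL)

  structure(list(stage_labels = stage_labels, fractions = frac,
                 dominant_index = dominant_index),
            class = "mixture_truth")
}

#' Simulate short reads from a mixture of paralog sequences
#'
#' Draws each read's source isoform group from `fractions`, its start
#' position uniformly over the valid starts (1 ... L - read_length + 1,
#' 1-based), and substitutes each base independently with probability
#' `error_rate` (always to a different base; no indels). Constant 'I'
#' qualities are emitted, matching the downstream pipeline which never uses
#' base qualities.
#'
#' @param sequences named character vector of isoform-group sequences
#'   (DNA alphabet).
#' @param fractions numeric vector over the groups, summing to 1.
#' @param reads_per_sample number of reads to emit.
#' @param read_length read length in nt (must not exceed any sequence).
#' @param error_rate per-base substitution probability in `[0, 1)`.
#' @param seed integer seed.
#' @param read_id_prefix prefix for read ids.
#' @return An object of class `simulated_reads`: list with `reads`
#'   (data.frame `read_id`, `sequence`) and `truth` (data.frame `read_id`,
#'   `source_group`, `start_1based`, `n_errors`), plus the configuration.
#' @export
simulate_reads <- function(sequences, fractions, reads_per_sample,
                           read_length, error_rate = 0, seed = 1L,
                           read_id_prefix = "read") {
  if (is.null(names(sequences))) names(sequences) <- paste0("g", seq_along(sequences))
  if (length(fractions) != length(sequences))
    stop("fractions must have one entry per sequence")
  if (abs(sum(fractions) - 1) > 1e-6) stop("fractions must sum to 1")
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  lens <- nchar(sequences)
  if (read_length > min(lens))
    stop("read_length (", read_length, ") exceeds the shortest sequence (", min(lens), ")")

  n <- as.integer(reads_per_sample)
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    src <- sample.int(length(sequences), n, replace = TRUE, prob = fractions)
    valid <- lens[src] - read_length + 1L
    start <- 1L + as.integer(floor(stats::runif(n) * valid))
    reads <- substring(sequences[src], start, start + read_length - 1L)
    n_err <- if (error_rate > 0) stats::rbinom(n, read_length, error_rate) else integer(n)
    for (i in which(n_err > 0)) {
      ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
      pos <- sample.int(read_length, n_err[i])
      for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1)
      reads[i] <- paste0(ch, collapse = "")
    }
  })

  ids <- sprintf("%s_%06d", read_id_prefix, seq_len(n))
  structure(list(
    reads = data.frame(read_id = ids, sequence = unname(reads), stringsAsFactors = FALSE),
    truth = data.frame(read_id = ids, source_group = names(sequences)[src],
                       start_1based = start, n_errors = n_err,
                       stringsAsFactors = FALSE),
    read_length = read_length, error_rate = error_rate, seed = seed
  ), class = "simulated_reads")
}
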