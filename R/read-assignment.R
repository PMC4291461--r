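#' Build an exact-match k-mer index over a family's isoform groups
#'
#' The index maps every read-length-mer occurring in any group's sequence to
#' the set of groups containing it (multiplicity-free). It replaces a
#' no-mismatch short-read aligner at family scale: an exact k-mer lookup is
#' the same decision rule as end-to-end alignment with zero mismatches.
#' K-mers containing `N` are excluded.
#'
#' @param groups an `isoform_groups` data.frame or named character vector of
#'   sequences.
#' @param read_length k.
#' @return object of class `kmer_index`: list with `read_length`, `kmers`
#'   (unique keys), `classes` (parallel vector of group subsets, ids joined
#'   by `;` in family order) and `groups` (family group ids).
#' @export
build_index <- function(groups, read_length) {
  seqs <- if (is.data.frame(groups)) stats::setNames(groups$sequence, groups$group_id) else groups
  if (read_length > min(nchar(seqs)))
    stop("read_length (", read_length, ") exceeds the shortest sequence (",
         min(nchar(seqs)), ")")
  gids <- names(seqs)
  ksets <- group_kmers(seqs, read_length)
  kmers <- unique(unlist(ksets, use.names = FALSE))
  hit <- vapply(ksets, function(ks) kmers %in% ks, logical(length(kmers)))
  if (length(kmers) == 1) hit <- matrix(hit, nrow = 1)
  classes <- apply(hit, 1, function(h) paste(gids[h], collapse = ";"))
  structure(list(read_length = read_length, kmers = kmers,
                 classes = classes, groups = gids),
            class = "kmer_index")
}

#' Assign reads to isoform-group subsets by exact k-mer match
#'
#' Each read is truncated at the 3' end to the index read length and looked
#' up; it is assigned the subset of groups whose sequences contain that
#' k-mer exactly (no mismatches tolerated). Reads shorter than the index
#' k-mer length, and reads whose k-mer is absent from the index, are counted
#' as unmapped. Each read contributes to exactly one match class; fractional
#' apportioning of ambiguous reads is the job of the downstream linear
#' system.
#'
#' @param reads a FASTQ path, a data.frame with `read_id`/`sequence`, or a
#'   character vector of read sequences.
#' @param index a `kmer_index` from [build_index()].
#' @param sample_id label stored in the returned count table.
#' @return object of class `class_counts`: list with `sample_id`, `counts`
#'   (data.frame `class`, `count`), `n_total`, `n_unmapped`, `n_too_short`,
#'   `groups`, and `assignments` (data.frame `read_id`, `matched_groups`,
#'   `NA` when unmapped).
#' @export
assign_reads <- function(reads, index, sample_id = "sample") {
  stopifnot(inherits(index, "kmer_index"))
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- read_fastq(reads)
  if (is.character(reads))
    reads <- data.frame(read_id = sprintf("read_%06d", seq_along(reads)),
                        sequence = reads, stringsAsFactors = FALSE)
  k <- index$read_length
  len <- nchar(reads$sequence)
  trimmed <- substr(reads$sequence, 1L, k)
  cls <- index$classes[match(trimmed, index$kmers)]
  cls[len < k] <- NA_character_
  n_total <- nrow(reads)
  n_too_short <- sum(len < k)
  n_unmapped <- sum(is.na(cls))
  tab <- table(cls[!is.na(cls)])
  counts <- data.frame(class = names(tab), count = as.integer(tab),
                       stringsAsFactors = FALSE, row.names = NULL)
  structure(list(sample_id = sample_id, counts = counts,
                 n_total = n_total, n_unmapped = n_unmapped,
                 n_too_short = n_too_short, groups = index$groups,
                 assignments = data.frame(read_id = reads$read_id,
                                          matched_groups = cls,
                                          stringsAsFactors = FALSE)),
            class = "class_counts")
}

#' Sum class counts over samples
#'
#' Class counts are sufficient for fraction estimation, so pooling samples
#' is exactly the sum of their count tables (used e.g. to add up RIP-seq
#' datasets whose individual IPs are too variable).
#'
#' @param ... `class_counts` objects (or a single list of them).
#' @param sample_id label for the pooled table.
#' @return a pooled `class_counts` object (without per-read assignments).
#' @export
pool_counts <- function(..., sample_id = "pooled") {
  xs <- list(...)
  if (length(xs) == 1 && !inherits(xs[[1]], "class_counts")) xs <- xs[[1]]
  stopifnot(all(vapply(xs, inherits, logical(1), "class_counts")))
  all_counts <- do.call(rbind, lapply(xs, `[[`, "counts"))
  agg <- stats::aggregate(count ~ class, data = all_counts, FUN = sum)
  structure(list(sample_id = sample_id,
                 counts = agg[order(match(agg$class, unique(all_counts$class))), ,
                              drop = FALSE],
                 n_total = sum(vapply(xs, `[[`, numeric(1), "n_total")),
                 n_unmapped = sum(vapply(xs, `[[`, numeric(1), "n_unmapped")),
                 n_too_short = sum(vapply(xs, `[[`, numeric(1), "n_too_short")),
                 groups = xs[[1]]$groups, assignments = NULL),
            class = "class_counts")
}

#' Screen reads for unannotated sequence variants
#'
#' Mismatch-tolerant counterpart of the exact-match assignment: every read
#' is scanned end-to-end against every group sequence at every offset
#' (substitutions only, no indels) and the best placement kept. A high
#' percentage of aligned reads carrying mismatches would indicate expressed
#' sequence variants missing from the catalog.
#'
#' The primary percentage uses aligned reads as denominator; the
#' all-reads-denominator figure is also reported.
#'
#' @param reads FASTQ path, data.frame with `sequence`, or character vector.
#' @param groups `isoform_groups` data.frame or named character vector.
#' @param max_mismatches placements with more substitutions than this are
#'   discarded (read counted unaligned).
#' @return object of class `variant_screen`: list with `n_reads`,
#'   `n_aligned`, `n_with_mismatch`, `percent_with_mismatch` (aligned-read
#'   denominator; `NA` when nothing aligns), `percent_of_all_reads`, and
#'   `max_mismatches`.
#' @export
variant_screen <- function(reads, groups, max_mismatches = 2L) {
  if (max_mismatches < 1) stop("max_mismatches must be >= 1")
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- read_fastq(reads)
  seqs_r <- if (is.data.frame(reads)) reads$sequence else reads
  seqs_g <- if (is.data.frame(groups)) groups$sequence else unname(groups)

  n_reads <- length(seqs_r)
  best <- rep(NA_integer_, n_reads)
  for (rl in unique(nchar(seqs_r))) {
    sel <- which(nchar(seqs_r) == rl)
    rmat <- do.call(rbind, strsplit(seqs_r[sel], "", fixed = TRUE))
    bsel <- rep(rl + 1L, length(sel))  # sentinel: worse than any placement
    for (gs in seqs_g) {
      L <- nchar(gs)
      if (rl > L) next
      gv <- strsplit(gs, "", fixed = TRUE)[[1]]
      for (off in 0:(L - rl)) {
        mm <- rowSums(rmat != matrix(gv[(off + 1):(off + rl)],
                                     nrow = length(sel), ncol = rl, byrow = TRUE))
        bsel <- pmin(bsel, as.integer(mm))
      }
    }
    bsel[bsel > max_mismatches] <- NA_integer_
    best[sel] <- bsel
  }
  n_aligned <- sum(!is.na(best))
  n_with_mm <- sum(best >= 1, na.rm = TRUE)
  structure(list(
    n_reads = n_reads, n_aligned = n_aligned, n_with_mismatch = n_with_mm,
    percent_with_mismatch = if (n_aligned > 0) 100 * n_with_mm / n_aligned else NA_real_,
    percent_of_all_reads = if (n_reads > 0) 100 * n_with_mm / n_reads else NA_real_,
    max_mismatches = max_mismatches
  ), class = "variant_screen")
}
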