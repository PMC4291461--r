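#' Load one snRNA paralog family from a FASTA file
#'
#' Sequences are uppercased and RNA `U` is normalised to DNA `T`; only the
#' alphabet `A/C/G/T/N` is accepted afterwards. Record ids must be unique.
#'
#' @param fasta_path path to a plain FASTA file, one record per gene.
#' @param family family label attached to the genes (e.g. `"U2"`); defaults
#'   to the part of each id before the first `:` when present.
#' @return data.frame with `gene_id`, `sequence` and `family` columns.
#' @export
load_family <- function(fasta_path, family = NULL) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  ss <- Biostrings::readBStringSet(fasta_path)
  if (length(ss) == 0) stop("empty FASTA: ", fasta_path)
  ids <- sub("\\s.*", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate gene_id in ", fasta_path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- chartr("u", "T", chartr("U", "T", toupper(as.character(ss))))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-nucleotide characters in record(s): ", paste(ids[bad], collapse = ", "))
  if (any(nchar(seqs) == 0)) stop("empty sequence in ", fasta_path)
  if (is.null(family)) {
    pref <- unique(sub(":.*", "", ids))
    family <- if (length(pref) == 1) pref else "family"
  }
  data.frame(gene_id = ids, sequence = unname(seqs), family = family,
             stringsAsFactors = FALSE)
}

# "U1:21D" + "U1:95Ca" + "U1:95Cb" -> "U1:21D/95Ca/95Cb"; ids without a
# shared prefix are joined verbatim
make_group_id <- function(member_ids) {
  if (length(member_ids) == 1) return(member_ids)
  pref <- sub(":.*", "", member_ids)
  if (length(unique(pref)) == 1 && all(grepl(":", member_ids, fixed = TRUE)))
    paste(c(member_ids[1], sub(".*:", "", member_ids[-1])), collapse = "/")
  else paste(member_ids, collapse = "/")
}

#' Collapse genes with identical sequences into isoform groups
#'
#' Gene copies sharing a byte-identical sequence are experimentally
#' indistinguishable from RNA-seq reads, so they are measured as one isoform
#' group. Groups are ordered by first appearance of their sequence.
#'
#' @param genes data.frame with `gene_id` and `sequence` (as from
#'   [load_family()]).
#' @return data.frame of class `isoform_groups` with `group_id`, `members`
#'   (list-column of gene ids), `sequence` and `n_members`.
#' @export
collapse_identical <- function(genes) {
  stopifnot(nrow(genes) >= 1)
  key <- factor(genes$sequence, levels = unique(genes$sequence))
  members <- split(genes$gene_id, key)
  out <- data.frame(
    group_id = vapply(members, make_group_id, character(1)),
    sequence = levels(key),
    n_members = lengths(members),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$members <- unname(members)
  out <- out[, c("group_id", "members", "sequence", "n_members")]
  class(out) <- c("isoform_groups", "data.frame")
  out
}

#' Find variable columns of a gapped alignment
#'
#' Returns the alignment columns at which two or more isoform groups carry
#' different residues; a gap (`-`) counts as a distinct residue.
#'
#' @param alignment named character vector of equal-length gapped sequences,
#'   one per isoform group.
#' @return data.frame with `column_1based` and one residue column per group,
#'   sorted by column.
#' @export
find_variable_sites <- function(alignment) {
  if (length(unique(nchar(alignment))) != 1)
    stop("ragged alignment: sequences have unequal lengths")
  if (is.null(names(alignment))) names(alignment) <- paste0("g", seq_along(alignment))
  mat <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  var_cols <- which(apply(mat, 2, function(col) length(unique(col)) >= 2))
  out <- data.frame(column_1based = var_cols)
  for (g in seq_along(alignment))
    out[[names(alignment)[g]]] <- mat[g, var_cols]
  out
}

# Needleman-Wunsch global alignment, match +1 / mismatch -1 / gap -2,
# traceback ties broken toward the diagonal, then up.
nw_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n); S[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(bv == av[i], match, mismatch)
    for (j in seq_len(m))
      S[i + 1, j + 1] <- max(S[i, j] + sub[j], S[i, j + 1] + gap, S[i + 1, j] + gap)
  }
  ra <- character(0); rb <- character(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + (if (av[i] == bv[j]) match else mismatch)) {
      ra <- c(av[i], ra); rb <- c(bv[j], rb); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      ra <- c(av[i], ra); rb <- c("-", rb); i <- i - 1
    } else {
      ra <- c("-", ra); rb <- c(bv[j], rb); j <- j - 1
    }
  }
  c(paste0(ra, collapse = ""), paste0(rb, collapse = ""))
}

#' Build (or accept) a gapped alignment of isoform-group sequences
#'
#' snRNA paralogs within a family have equal or near-equal lengths; when all
#' representative sequences are the same length the alignment is the
#' identity (column i is position i). Otherwise a progressive pairwise
#' scheme (global alignment, match +1 / mismatch -1 / gap -2, ties toward
#' the diagonal) threads each sequence onto the longest one; gaps opened in
#' the reference are propagated to all previously placed rows. A
#' user-supplied aligned FASTA (or named vector of equal-length gapped
#' rows) bypasses computation entirely.
#'
#' @param groups an `isoform_groups` data.frame, or a named character vector
#'   of sequences.
#' @param aligned optional pre-computed alignment: a named character vector
#'   or a path to an aligned FASTA with equal-length rows.
#' @return named character vector of equal-length gapped sequences.
#' @export
build_alignment <- function(groups, aligned = NULL) {
  if (!is.null(aligned)) {
    if (is.character(aligned) && length(aligned) == 1 && file.exists(aligned)) {
      ss <- Biostrings::readBStringSet(aligned)
      aligned <- stats::setNames(toupper(as.character(ss)), sub("\\s.*", "", names(ss)))
    }
    if (length(unique(nchar(aligned))) != 1)
      stop("supplied alignment has unequal row lengths")
    return(aligned)
  }
  seqs <- if (is.data.frame(groups)) stats::setNames(groups$sequence, groups$group_id) else groups
  if (length(seqs) < 2) return(seqs)
  if (length(unique(nchar(seqs))) == 1) return(seqs)

  ord <- order(-nchar(seqs))
  ref <- seqs[[ord[1]]]
  rows <- stats::setNames(character(length(seqs)), names(seqs))
  rows[[ord[1]]] <- ref
  for (k in ord[-1]) {
    pair <- nw_align(gsub("-", "", ref, fixed = TRUE), seqs[[k]])
    # propagate gaps newly opened in the reference into all placed rows
    new_ref <- pair[1]
    if (nchar(new_ref) != nchar(ref)) {
      refchars <- strsplit(ref, "", fixed = TRUE)[[1]]
      newchars <- strsplit(new_ref, "", fixed = TRUE)[[1]]
      expand <- function(row) {
        rv <- strsplit(row, "", fixed = TRUE)[[1]]
        out <- character(length(newchars)); ri <- 1
        for (ci in seq_along(newchars)) {
          if (newchars[ci] == "-" && (ri > length(refchars) || refchars[ri] != "-")) {
            out[ci] <- "-"
          } else {
            out[ci] <- rv[ri]; ri <- ri + 1
          }
        }
        paste0(out, collapse = "")
      }
      done <- names(rows)[nchar(rows) > 0]
      for (nm in done) rows[[nm]] <- expand(rows[[nm]])
      ref <- new_ref
    }
    rows[[names(seqs)[k]]] <- pair[2]
  }
  rows[names(seqs)]
}

# every k-mer of every group, as a list of character vectors (N-containing
# k-mers excluded: they match nothing)
group_kmers <- function(sequences, k) {
  lapply(sequences, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    km <- substring(s, 1:(L - k + 1), k:L)
    km[!grepl("N", km, fixed = TRUE)]
  })
}

#' Compute diagnostic regions: which read starts distinguish which groups
#'
#' For every isoform group and every valid read start (1-based), the
#' read-length-mer beginning there is looked up across all groups' ungapped
#' sequences at all offsets (forward strand). Consecutive starts yielding
#' the same matched-group subset are merged into maximal intervals. Regions
#' whose subset is the whole family are retained but flagged
#' non-informative; k-mers containing `N` match nothing and their starts are
#' excluded.
#'
#' @param groups an `isoform_groups` data.frame (or named character vector
#'   of ungapped sequences).
#' @param read_length k, the read length in nt.
#' @return data.frame of class `diagnostic_regions` with `carrier_group`,
#'   `group_subset` (group ids joined by `;` in family order),
#'   `start_min_1based`, `start_max_1based`, `read_length`, `informative`.
#' @export
diagnostic_regions <- function(groups, read_length) {
  seqs <- if (is.data.frame(groups)) stats::setNames(groups$sequence, groups$group_id) else groups
  if (read_length > min(nchar(seqs)))
    stop("read_length (", read_length, ") exceeds the shortest sequence (",
         min(nchar(seqs)), ")")
  gids <- names(seqs)
  ksets <- group_kmers(seqs, read_length)

  out <- list()
  for (g in seq_along(seqs)) {
    L <- nchar(seqs[[g]])
    starts <- 1:(L - read_length + 1)
    kmers <- substring(seqs[[g]], starts, starts + read_length - 1)
    keep <- !grepl("N", kmers, fixed = TRUE)
    if (!any(keep)) next
    subset_of <- vapply(kmers[keep], function(km) {
      hit <- vapply(ksets, function(ks) km %in% ks, logical(1))
      paste(gids[hit], collapse = ";")
    }, character(1), USE.NAMES = FALSE)
    st <- starts[keep]
    # merge runs of consecutive starts sharing a subset
    brk <- c(TRUE, subset_of[-1] != subset_of[-length(subset_of)] |
                   diff(st) != 1L)
    run <- cumsum(brk)
    out[[g]] <- data.frame(
      carrier_group = gids[g],
      group_subset = tapply(subset_of, run, `[`, 1),
      start_min_1based = as.integer(tapply(st, run, min)),
      start_max_1based = as.integer(tapply(st, run, max)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  res <- do.call(rbind, out)
  res$read_length <- read_length
  all_id <- paste(gids, collapse = ";")
  res$informative <- res$group_subset != all_id
  class(res) <- c("diagnostic_regions", "data.frame")
  res
}

#' Warn about k-mers shared across families
#'
#' Family-level uniqueness is the working approximation to genome-wide
#' unique mapping; this check reports k-mers occurring in more than one
#' family so such collisions are at least visible at catalog build.
#'
#' @param family_groups named list of `isoform_groups` data.frames, one per
#'   family.
#' @param read_length k.
#' @return invisibly, the character vector of colliding k-mers (warns when
#'   non-empty).
#' @export
cross_family_collisions <- function(family_groups, read_length) {
  per_fam <- lapply(family_groups, function(g)
    unique(unlist(group_kmers(stats::setNames(g$sequence, g$group_id), read_length))))
  all_km <- unlist(per_fam)
  coll <- unique(all_km[duplicated(all_km)])
  coll <- coll[vapply(coll, function(km)
    sum(vapply(per_fam, function(ks) km %in% ks, logical(1))) > 1, logical(1))]
  if (length(coll))
    warning(length(coll), " k-mer(s) collide across families; ",
            "within-family uniqueness is not genome-wide uniqueness")
  invisible(coll)
}
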