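# shared fixtures and independent oracles, built in code

toy_genes <- function(sequences, ids = sprintf("FAM:g%02d", seq_along(sequences))) {
  data.frame(gene_id = ids, sequence = sequences, stringsAsFactors = FALSE)
}

# independent oracle: subset of groups whose sequence contains the
# (trimmed) read verbatim; mirrors the documented trim/too-short policy
naive_assign <- function(read, group_seqs, k) {
  if (nchar(read) < k) return(NA_character_)
  r <- substr(read, 1, k)
  hit <- vapply(group_seqs, function(s) grepl(r, s, fixed = TRUE), logical(1))
  if (!any(hit)) NA_character_ else paste(names(group_seqs)[hit], collapse = ";")
}

# a seeded random family + reads for oracle-equivalence style checks
random_family_case <- function(seed, n_genes = NULL, seq_length = NULL,
                               n_sites = NULL) {
  withr::with_seed(seed, {
    if (is.null(n_genes)) n_genes <- sample(2:5, 1)
    if (is.null(seq_length)) seq_length <- sample(120:200, 1)
    if (is.null(n_sites)) n_sites <- sample(2:6, 1)
  })
  generate_family(n_genes, seq_length, n_sites, seed = seed)
}

group_seqs_of <- function(groups) stats::setNames(groups$sequence, groups$group_id)

write_temp_fasta <- function(sequences, ids = names(sequences)) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), sequences)), path)
  path
}
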