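test_that("load_family parses, normalises and validates FASTA input", {
  p <- write_temp_fasta(c("acgu", "ACGT", "NNAC"), c("U9:a", "U9:b", "U9:c"))
  genes <- load_family(p)
  expect_equal(nrow(genes), 3)
  expect_equal(genes$sequence, c("ACGT", "ACGT", "NNAC"))  # uppercased, U -> T
  expect_equal(genes$family, rep("U9", 3))

  dup <- write_temp_fasta(c("ACGT", "ACGT"), c("x", "x"))
  expect_error(load_family(dup), "duplicate")
  bad <- write_temp_fasta("ACXT", "x")
  expect_error(load_family(bad), "non-nucleotide")
  empty <- tempfile(); file.create(empty)
  expect_error(load_family(empty), "empty")
})

test_that("collapse_identical groups byte-identical sequences", {
  g <- collapse_identical(toy_genes(c("ACGT", "ACGT", "ACGA")))
  expect_equal(nrow(g), 2)
  expect_equal(g$members[[1]], c("FAM:g01", "FAM:g02"))
  expect_equal(g$members[[2]], "FAM:g03")

  g4 <- collapse_identical(toy_genes(c("AAAA", "AAAC", "AAAG", "AAAT")))
  expect_equal(nrow(g4), 4)
  expect_equal(g4$n_members, rep(1L, 4))

  # six genes, genes 4 and 5 identical: five distinct isoforms (the U2 case)
  seqs6 <- c("AACGT", "ACCGT", "AGCGT", "ATCGT", "ATCGT", "AACGA")
  g6 <- collapse_identical(toy_genes(seqs6, sprintf("U2:%d", 1:6)))
  expect_equal(nrow(g6), 5)
  expect_equal(g6$group_id[g6$n_members == 2], "U2:4/5")

  # idempotent: collapsing the representatives changes nothing
  again <- collapse_identical(
    data.frame(gene_id = g6$group_id, sequence = g6$sequence))
  expect_equal(again$sequence, g6$sequence)
  expect_equal(nrow(again), nrow(g6))
})

test_that("group ids join members in the field's cytological style", {
  g <- collapse_identical(toy_genes(rep("ACGT", 3),
                                    c("U1:21D", "U1:95Ca", "U1:95Cb")))
  expect_equal(g$group_id, "U1:21D/95Ca/95Cb")
})

test_that("find_variable_sites returns exactly the differing columns", {
  expect_equal(nrow(find_variable_sites(c(a = "AAAA", b = "AAAA"))), 0)

  s <- find_variable_sites(c(a = "AATA", b = "AACA"))
  expect_equal(s$column_1based, 3)
  expect_equal(s$a, "T"); expect_equal(s$b, "C")

  # gaps count as distinct residues
  s <- find_variable_sites(c(a = "AA-A", b = "AACA"))
  expect_equal(s$column_1based, 3)

  expect_error(find_variable_sites(c("AAA", "AAAA")), "ragged")

  # planted differences recovered from a synthetic family
  fam <- generate_family(3, 80, 2, identical_partition = list(1, 2, 3), seed = 21)
  s <- find_variable_sites(fam$alignment[c(1, 2, 3)])
  expect_equal(s$column_1based, fam$sites$column_1based)
})

test_that("build_alignment is identity for equal lengths, NW otherwise", {
  seqs <- c(x = "ACGTACGT", y = "ACGAACGT")
  expect_identical(build_alignment(seqs), seqs)

  al <- build_alignment(c(a = "ACGT", b = "ACGGT"))
  expect_equal(unique(nchar(al)), 5)
  expect_equal(sum(strsplit(al[["a"]], "")[[1]] == "-"), 1)
  expect_equal(al[["b"]], "ACGGT")
  expect_equal(gsub("-", "", al[["a"]]), "ACGT")

  # independent check of the alignment score against Biostrings
  ours <- al
  score_ours <- {
    m <- do.call(rbind, strsplit(ours, "", fixed = TRUE))
    sum(ifelse(m[1, ] == "-" | m[2, ] == "-", -2,
               ifelse(m[1, ] == m[2, ], 1, -1)))
  }
  ref <- Biostrings::pairwiseAlignment(
    "ACGT", "ACGGT", type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1),
    gapOpening = 0, gapExtension = 2)
  expect_equal(score_ours, Biostrings::score(ref))

  # user-supplied alignment is returned verbatim
  given <- c(a = "AC-GT", b = "ACGGT")
  expect_identical(build_alignment(c(a = "ACGT", b = "ACGGT"), aligned = given),
                   given)
  expect_error(build_alignment(seqs, aligned = c("AC", "ACG")), "unequal")
})

test_that("diagnostic regions partition starts around a single variable base", {
  # two length-10 sequences differing only at position 6; k = 4
  # (all 4-mers of each sequence are distinct, so the example is exact)
  a <- "AACCGGTTAC"
  b <- paste0(substr(a, 1, 5), "T", substr(a, 7, 10))
  g <- collapse_identical(toy_genes(c(a, b), c("F:A", "F:B")))
  r <- diagnostic_regions(g, 4)

  for (gid in g$group_id) {
    self <- r[r$carrier_group == gid & r$group_subset == gid, ]
    expect_equal(nrow(self), 1)
    expect_equal(self$start_min_1based, 3)
    expect_equal(self$start_max_1based, 6)
    shared <- r[r$carrier_group == gid & r$group_subset == "F:A;F:B", ]
    expect_equal(sort(shared$start_min_1based), c(1, 7))
    expect_true(all(!shared$informative))
  }
})

test_that("a single-group family yields one full-width region", {
  g <- collapse_identical(toy_genes(rep("ACGTACGTTGCA", 2)))
  r <- diagnostic_regions(g, 5)
  expect_equal(nrow(r), 1)
  expect_equal(r$group_subset, g$group_id)
  expect_equal(r$start_min_1based, 1)
  expect_equal(r$start_max_1based, 12 - 5 + 1)
})

test_that("shared-difference triple produces the ambiguous {A,B} class", {
  base <- withr::with_seed(99, sample(c("A", "C", "G", "T"), 20, replace = TRUE))
  sB <- base; sB[3] <- setdiff(c("A", "C", "G", "T"), base[3])[1]
  sC <- base; sC[10] <- setdiff(c("A", "C", "G", "T"), base[10])[1]
  g <- collapse_identical(toy_genes(
    vapply(list(base, sB, sC), paste0, character(1), collapse = ""),
    c("F:A", "F:B", "F:C")))
  expect_equal(nrow(g), 3)
  r <- diagnostic_regions(g, 6)
  # reads from A covering column 10 but not column 3 match A and B, not C:
  # the "A or B but not C" class the linear system uses
  over <- r[r$carrier_group == "F:A" & r$start_min_1based <= 10 &
            r$start_max_1based >= 10 - 6 + 1 & r$start_min_1based >= 4, ]
  expect_gt(nrow(over), 0)
  expect_true(all(over$group_subset == "F:A;F:B"))
})

test_that("k-mers with N are excluded from regions", {
  g <- collapse_identical(toy_genes(c("ACGTNACGTACG", "ACGTAACGTACG"),
                                    c("F:A", "F:B")))
  r <- diagnostic_regions(g, 4)
  ra <- r[r$carrier_group == "F:A", ]
  covered <- unlist(mapply(seq, ra$start_min_1based, ra$start_max_1based,
                           SIMPLIFY = FALSE))
  # starts 2..5 produce N-containing 4-mers on F:A and must be absent
  expect_true(all(setdiff(1:9, 2:5) %in% covered))
  expect_false(any(2:5 %in% covered))
})

test_that("region widths partition valid starts; longer reads never distinguish fewer groups", {
  for (seed in c(2, 13)) {
    fam <- random_family_case(seed)
    g <- collapse_identical(fam$genes)
    L <- nchar(g$sequence[1])
    unique_capable <- function(k) {
      r <- diagnostic_regions(g, k)
      widths <- tapply(r$start_max_1based - r$start_min_1based + 1,
                       r$carrier_group, sum)
      expect_true(all(widths == L - k + 1))
      unique(r$carrier_group[r$group_subset == r$carrier_group])
    }
    caps <- lapply(c(20, 30, 45), unique_capable)
    expect_true(all(caps[[1]] %in% caps[[2]]))
    expect_true(all(caps[[2]] %in% caps[[3]]))
  }
})

test_that("cross-family k-mer collisions are reported", {
  fa <- collapse_identical(toy_genes("ACGTACGTACGTAAT", "U8:x"))
  fb <- collapse_identical(toy_genes("ACGTACGTACGTCCG", "U9:y"))
  expect_warning(cross_family_collisions(list(U8 = fa, U9 = fb), 10), "collide")
  fc <- collapse_identical(toy_genes("TTTTTGGGGGCCCCC", "U7:z"))
  expect_silent(cross_family_collisions(list(U8 = fa, U7 = fc), 10))
})
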