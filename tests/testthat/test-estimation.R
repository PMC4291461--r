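# hand-built regions with a known width structure; sequences are dummies of
# the right length so the partition check passes (k = 10, L = 16: 7 starts)
two_group_regions <- function() {
  list(
    groups = collapse_identical(toy_genes(
      c("AACCGGTTACGTGCAT", "AACCGGTAACGTGCAT"), c("F:A", "F:B"))),
    regions = structure(data.frame(
      carrier_group = c("F:A", "F:A", "F:B", "F:B"),
      group_subset = c("F:A", "F:A;F:B", "F:B", "F:A;F:B"),
      start_min_1based = c(1L, 5L, 1L, 5L),
      start_max_1based = c(4L, 7L, 4L, 7L),
      read_length = 10L, informative = c(TRUE, FALSE, TRUE, FALSE),
      stringsAsFactors = FALSE), class = c("diagnostic_regions", "data.frame"))
  )
}

test_that("the design matrix sums region widths per class", {
  tg <- two_group_regions()
  des <- build_design_matrix(tg$regions, tg$groups)
  expect_equal(des$A["F:A", ], c("F:A" = 4L, "F:B" = 0L))
  expect_equal(des$A["F:B", ], c("F:A" = 0L, "F:B" = 4L))
  expect_equal(des$A["F:A;F:B", ], c("F:A" = 3L, "F:B" = 3L))
  expect_equal(unname(colSums(des$A)), c(7L, 7L))  # each group's valid starts

  # single group: one cell, L - k + 1
  g1 <- collapse_identical(toy_genes("AACCGGTTACGT"))
  r1 <- diagnostic_regions(g1, 5)
  d1 <- build_design_matrix(r1, g1)
  expect_equal(unname(d1$A[1, 1]), 8L)

  # overlapping / gapped regions are rejected
  broken <- tg$regions
  broken$start_max_1based[1] <- 5L
  expect_error(build_design_matrix(broken, tg$groups), "inconsistent")
})

test_that("a group with no self-unique starts appears only in ambiguous rows", {
  base <- withr::with_seed(41, sample(c("A", "C", "G", "T"), 30, replace = TRUE))
  sB <- base; sB[3] <- setdiff(c("A", "C", "G", "T"), base[3])[1]
  sC <- base; sC[28] <- setdiff(c("A", "C", "G", "T"), base[28])[1]
  g <- collapse_identical(toy_genes(
    vapply(list(base, sB, sC), paste0, character(1), collapse = ""),
    c("F:A", "F:B", "F:C")))
  # with k = 20 no read can cover both column 3 and column 28, so A is never
  # isolated: every A-read matches A;B, A;C or the full family
  des <- build_design_matrix(diagnostic_regions(g, 20), g)
  singleton_rows <- rownames(des$A)[!grepl(";", rownames(des$A))]
  expect_false("F:A" %in% singleton_rows)
  expect_true(all(des$A[singleton_rows, "F:A"] == 0))
  expect_gt(sum(des$A[grepl(";", rownames(des$A)), "F:A"]), 0)
})

test_that("fraction estimation solves the worked linear systems", {
  # two fully distinguishable groups, equal design widths, counts 80/20
  des2 <- structure(list(
    A = matrix(c(4, 0, 0, 4), 2, 2, byrow = TRUE,
               dimnames = list(c("F:A", "F:B"), c("F:A", "F:B"))),
    classes = c("F:A", "F:B"), groups = c("F:A", "F:B"),
    valid_starts = c("F:A" = 4L, "F:B" = 4L), read_length = 10L),
    class = "class_design")
  est <- estimate_fractions(
    data.frame(class = c("F:A", "F:B"), count = c(80, 20)), des2)
  expect_equal(unname(est$fractions), c(0.8, 0.2), tolerance = 1e-9)
  expect_equal(est$n_informative_reads, 100L)

  # triangular 3-group system with unit widths: counts (50, 30, 50) over
  # classes {A},{B},{B,C} give fractions (0.5, 0.3, 0.2)
  des3 <- structure(list(
    A = matrix(c(1, 0, 0,
                 0, 1, 0,
                 0, 1, 1), 3, 3, byrow = TRUE,
               dimnames = list(c("A", "B", "B;C"), c("A", "B", "C"))),
    classes = c("A", "B", "B;C"), groups = c("A", "B", "C"),
    valid_starts = c(A = 1L, B = 2L, C = 1L), read_length = 10L),
    class = "class_design")
  est3 <- estimate_fractions(
    data.frame(class = c("A", "B", "B;C"), count = c(50, 30, 50)), des3)
  expect_equal(unname(est3$fractions), c(0.5, 0.3, 0.2), tolerance = 1e-9)

  expect_error(estimate_fractions(
    data.frame(class = "A", count = 0), des3), "zero informative")
  expect_warning(estimate_fractions(
    data.frame(class = c("A", "nope"), count = c(10, 5)), des3), "dropping")
})

test_that("structurally confounded groups are lumped with a concatenated id", {
  des <- structure(list(
    A = matrix(c(5, 5, 0,
                 3, 3, 4), 2, 3, byrow = TRUE,
               dimnames = list(c("U2:a;U2:b", "U2:a;U2:b;U2:c"),
                               c("U2:a", "U2:b", "U2:c"))),
    classes = c("U2:a;U2:b", "U2:a;U2:b;U2:c"),
    groups = c("U2:a", "U2:b", "U2:c"),
    valid_starts = c("U2:a" = 8L, "U2:b" = 8L, "U2:c" = 4L),
    read_length = 10L), class = "class_design")
  expect_warning(
    est <- estimate_fractions(
      data.frame(class = c("U2:a;U2:b", "U2:a;U2:b;U2:c"), count = c(60, 60)),
      des),
    "lumped")
  expect_named(est$fractions, c("U2:a/b", "U2:c"))
  expect_equal(sum(est$fractions), 1, tolerance = 1e-9)
  expect_equal(est$lumped, "U2:a/b", ignore_attr = TRUE)
})

test_that("unique and linear_system modes agree when unique regions exist", {
  # with counts at their exact expectation (noise-free), the overdetermined
  # NNLS and the singleton-ratio estimator coincide; sampling noise moves
  # them apart, which the recovery tests bound separately
  ran <- 0
  for (seed in c(6, 14)) {
    fam <- random_family_case(seed, n_genes = 4, seq_length = 160, n_sites = 5)
    g <- collapse_identical(fam$genes)
    k <- 33
    des <- build_design_matrix(diagnostic_regions(g, k), g)
    singleton <- rownames(des$A)[!grepl(";", rownames(des$A))]
    if (!all(g$group_id %in% singleton)) next
    ran <- ran + 1
    s_true <- c(0.4, 0.3, 0.2, 0.1) * 1000
    counts <- data.frame(class = rownames(des$A),
                         count = as.vector(des$A %*% s_true))
    eu <- estimate_fractions(counts, des, mode = "unique")
    el <- estimate_fractions(counts, des, mode = "linear_system")
    expect_equal(eu$fractions, el$fractions, tolerance = 1e-6)
  }
  expect_gt(ran, 0)
})

test_that("unique mode refuses families lacking singleton classes", {
  des3 <- structure(list(
    A = matrix(c(1, 0, 0,
                 0, 1, 1), 2, 3, byrow = TRUE,
               dimnames = list(c("A", "B;C"), c("A", "B", "C"))),
    classes = c("A", "B;C"), groups = c("A", "B", "C"),
    valid_starts = c(A = 1L, B = 1L, C = 1L), read_length = 10L),
    class = "class_design")
  expect_error(estimate_fractions(
    data.frame(class = c("A", "B;C"), count = c(5, 5)), des3, mode = "unique"),
    "linear_system")
})

test_that("estimation on pooled counts equals estimation on concatenated reads", {
  fam <- random_family_case(27, n_genes = 3, seq_length = 150, n_sites = 4)
  g <- collapse_identical(fam$genes)
  idx <- build_index(g, 33)
  des <- build_design_matrix(diagnostic_regions(g, 33), g)
  s1 <- simulate_reads(group_seqs_of(g), c(0.6, 0.3, 0.1), 3000, 33, seed = 1)
  s2 <- simulate_reads(group_seqs_of(g), c(0.2, 0.2, 0.6), 3000, 33, seed = 2)
  e_pooled <- estimate_fractions(
    pool_counts(assign_reads(s1$reads, idx), assign_reads(s2$reads, idx)), des)
  e_concat <- estimate_fractions(
    assign_reads(rbind(s1$reads, s2$reads), idx), des)
  expect_equal(e_pooled$fractions, e_concat$fractions, tolerance = 1e-12)
})

test_that("stage aggregation averages, renormalises and reports n-1 SDs", {
  mk <- function(f, id) structure(list(sample_id = id,
                                       fractions = c(A = f[1], B = f[2]),
                                       n_informative_reads = 100L,
                                       method = "linear_system",
                                       lumped = character(0)),
                                  class = "fraction_estimate")
  s <- aggregate_stage(list(mk(c(0.6, 0.4), "a"), mk(c(0.8, 0.2), "b")), "mid")
  expect_equal(unname(s$mean_fraction), c(0.7, 0.3))
  expect_equal(unname(s$sd_across_samples), rep(sqrt(0.02), 2), tolerance = 1e-9)
  expect_equal(s$n_samples, 2)

  one <- aggregate_stage(list(mk(c(0.6, 0.4), "a")), "ovary")
  expect_null(one$sd_across_samples)

  four <- aggregate_stage(rep(list(mk(c(0.5, 0.5), "a")), 4), "late")
  expect_equal(unname(four$sd_across_samples), c(0, 0))

  bad <- structure(list(sample_id = "c", fractions = c(X = 1),
                        n_informative_reads = 1L, method = "unique",
                        lumped = character(0)), class = "fraction_estimate")
  expect_error(aggregate_stage(list(mk(c(0.6, 0.4), "a"), bad), "mid"), "mixed")
})
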