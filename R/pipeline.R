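#' Run the full quantification pipeline for one or more snRNA families
#'
#' Orchestrates catalog building (collapse identical genes, alignment,
#' variable sites, diagnostic regions), exact-match read assignment,
#' fraction estimation, stage aggregation, the dominance trajectory and the
#' optional variant screen, writing every result as a TSV under
#' `config$out_dir`. The run is deterministic given its inputs; re-running
#' with the same config overwrites byte-identical outputs.
#'
#' @param config a named list (or path to a YAML file holding one) with:
#'   \describe{
#'     \item{families}{named list, family label -> FASTA path or a
#'       data.frame of `gene_id`/`sequence` rows.}
#'     \item{aligned}{optional named list, family -> pre-computed aligned
#'       FASTA path (bypasses alignment computation).}
#'     \item{sample_sheet}{data.frame (or TSV path) with `sample_id`,
#'       `fastq`, `stage`, `family`.}
#'     \item{read_length}{k for the k-mer index (>= 10).}
#'     \item{stage_order}{ordered character vector of developmental stages;
#'       must cover every stage in the sheet.}
#'     \item{mode}{`"linear_system"` (default) or `"unique"`.}
#'     \item{sd_denominator}{`"sample"` (default) or `"population"`.}
#'     \item{variant_screen}{logical, default `FALSE`.}
#'     \item{max_mismatches}{for the screen, default 2.}
#'     \item{out_dir}{output directory, created if needed.}
#'     \item{seed}{optional; recorded in the manifest (the quantification
#'       itself is deterministic).}
#'   }
#' @return invisibly, a named list per family with the catalog, per-sample
#'   estimates, stage summaries and trajectory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_config(config)
  sheet <- cfg$sample_sheet
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  results <- list()
  groups_rows <- sites_rows <- region_rows <- count_rows <- sample_rows <-
    frac_rows <- stage_rows <- traj_rows <- screen_rows <- list()

  fams <- unique(sheet$family)
  catalogs <- list()
  for (fam in fams) {
    genes <- cfg$families[[fam]]
    if (is.character(genes)) genes <- load_family(genes, family = fam)
    groups <- collapse_identical(genes)
    aln <- build_alignment(groups, aligned = cfg$aligned[[fam]])
    sites <- find_variable_sites(aln)
    regions <- diagnostic_regions(groups, cfg$read_length)
    index <- build_index(groups, cfg$read_length)
    design <- build_design_matrix(regions, groups)
    catalogs[[fam]] <- list(genes = genes, groups = groups, alignment = aln,
                            sites = sites, regions = regions,
                            index = index, design = design)

    groups_rows[[fam]] <- data.frame(
      family = fam, group_id = groups$group_id,
      members = vapply(groups$members, paste, character(1), collapse = ";"),
      length = nchar(groups$sequence), n_members = groups$n_members)
    if (nrow(sites)) {
      long <- utils::stack(sites[-1])
      sites_rows[[fam]] <- data.frame(
        family = fam, column_1based = rep(sites$column_1based, ncol(sites) - 1),
        group = as.character(long$ind), residue = long$values)
    }
    region_rows[[fam]] <- cbind(family = fam, as.data.frame(regions))
  }
  if (length(fams) > 1)
    cross_family_collisions(lapply(catalogs, `[[`, "groups"), cfg$read_length)

  for (fam in fams) {
    cat_f <- catalogs[[fam]]
    rows <- sheet[sheet$family == fam, , drop = FALSE]
    estimates <- list()
    for (i in seq_len(nrow(rows))) {
      sid <- rows$sample_id[i]
      cc <- assign_reads(rows$fastq[i], cat_f$index, sample_id = sid)
      est <- estimate_fractions(cc, cat_f$design, mode = cfg$mode)
      estimates[[sid]] <- est
      count_rows[[paste(fam, sid)]] <- data.frame(
        family = fam, sample_id = sid, class = cc$counts$class,
        count = cc$counts$count)
      sample_rows[[paste(fam, sid)]] <- data.frame(
        family = fam, sample_id = sid, stage = rows$stage[i],
        n_total = cc$n_total, n_unmapped = cc$n_unmapped,
        n_too_short = cc$n_too_short)
      frac_rows[[paste(fam, sid)]] <- data.frame(
        family = fam, sample_id = sid, stage = rows$stage[i],
        group_id = names(est$fractions), fraction = unname(est$fractions),
        n_informative_reads = est$n_informative_reads, method = est$method)
      if (isTRUE(cfg$variant_screen)) {
        sc <- variant_screen(rows$fastq[i], cat_f$groups,
                             max_mismatches = cfg$max_mismatches)
        screen_rows[[paste(fam, sid)]] <- data.frame(
          family = fam, sample_id = sid, n_reads = sc$n_reads,
          n_aligned = sc$n_aligned, n_with_mismatch = sc$n_with_mismatch,
          percent_with_mismatch = sc$percent_with_mismatch,
          percent_of_all_reads = sc$percent_of_all_reads)
      }
    }

    stages_here <- cfg$stage_order[cfg$stage_order %in% rows$stage]
    summaries <- lapply(stages_here, function(stg) {
      aggregate_stage(estimates[rows$sample_id[rows$stage == stg]], stg,
                      sd_denominator = cfg$sd_denominator)
    })
    traj <- trajectory(summaries, family = fam, denominator = cfg$sd_denominator)

    for (s in summaries)
      stage_rows[[paste(fam, s$stage_label)]] <- data.frame(
        family = fam, stage = s$stage_label, group_id = names(s$mean_fraction),
        mean_fraction = unname(s$mean_fraction),
        sd_across_samples = if (is.null(s$sd_across_samples)) NA_real_
                            else unname(s$sd_across_samples),
        n_samples = s$n_samples)
    traj_rows[[fam]] <- cbind(family = fam, traj$stages,
                              trend_monotone = traj$trend_monotone)

    results[[fam]] <- list(catalog = cat_f, estimates = estimates,
                           stage_summaries = summaries, trajectory = traj)
  }

  od <- cfg$out_dir
  write_tsv(do.call(rbind, unname(groups_rows)), file.path(od, "catalog_groups.tsv"))
  if (length(sites_rows))
    write_tsv(do.call(rbind, unname(sites_rows)), file.path(od, "variable_sites.tsv"))
  write_tsv(do.call(rbind, unname(region_rows)), file.path(od, "diagnostic_regions.tsv"))
  write_tsv(do.call(rbind, unname(count_rows)), file.path(od, "class_counts.tsv"))
  write_tsv(do.call(rbind, unname(sample_rows)), file.path(od, "sample_mapping.tsv"))
  write_tsv(do.call(rbind, unname(frac_rows)), file.path(od, "fractions.tsv"))
  write_tsv(do.call(rbind, unname(stage_rows)), file.path(od, "stage_summary.tsv"))
  write_tsv(do.call(rbind, unname(traj_rows)), file.path(od, "dominance_trajectory.tsv"))
  if (length(screen_rows))
    write_tsv(do.call(rbind, unname(screen_rows)), file.path(od, "screen_report.tsv"))
  write_tsv(run_manifest(cfg), file.path(od, "run_manifest.tsv"))

  invisible(results)
}

validate_config <- function(config) {
  defaults <- list(aligned = list(), mode = "linear_system",
                   sd_denominator = "sample", variant_screen = FALSE,
                   max_mismatches = 2L, seed = NA_integer_)
  cfg <- utils::modifyList(defaults, config)
  for (key in c("families", "sample_sheet", "read_length", "stage_order", "out_dir"))
    if (is.null(cfg[[key]])) stop("config is missing required key '", key, "'")
  if (cfg$read_length < 10) stop("read_length must be >= 10")
  sheet <- cfg$sample_sheet
  if (is.character(sheet)) sheet <- read_tsv(sheet)
  need <- c("sample_id", "fastq", "stage", "family")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]), collapse = ", "))
  bad_stage <- setdiff(sheet$stage, cfg$stage_order)
  if (length(bad_stage))
    stop("sample sheet stage(s) not in stage_order: ",
         paste(bad_stage, collapse = ", "))
  missing_fam <- setdiff(sheet$family, names(cfg$families))
  if (length(missing_fam))
    stop("sample sheet family(ies) without sequences: ",
         paste(missing_fam, collapse = ", "))
  missing_fq <- !file.exists(sheet$fastq)
  if (any(missing_fq))
    stop("FASTQ file missing for sample sheet row(s) ",
         paste(which(missing_fq), collapse = ", "), " (",
         paste(sheet$sample_id[missing_fq], collapse = ", "), ")")
  cfg$sample_sheet <- sheet
  cfg
}

run_manifest <- function(cfg) {
  # hash the analysis-relevant config with paths reduced to basenames, so
  # the same run in a different directory is recognised as the same config
  h <- cfg
  h$out_dir <- NULL
  h$sample_sheet$fastq <- basename(h$sample_sheet$fastq)
  h$families <- lapply(h$families, function(f)
    if (is.character(f)) basename(f) else f)
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(h[order(names(h))], tf)
  data.frame(
    key = c("package", "version", "config_md5", "read_length", "mode",
            "sd_denominator", "seed"),
    value = c("snquant", as.character(utils::packageVersion("snquant")),
              unname(tools::md5sum(tf)), cfg$read_length, cfg$mode,
              cfg$sd_denominator, cfg$seed))
}

#' Generate a synthetic study and run the pipeline end-to-end
#'
#' The acceptance harness: plants a paralog family and a developmental
#' mixture trajectory, simulates reads for every sample of a stage plan,
#' runs [run_pipeline()] on the written FASTA/FASTQ/sample sheet, and
#' compares the estimated fractions and dominance trend against the planted
#' truth.
#'
#' @param n_genes,seq_length,n_variable_sites,identical_partition family
#'   spec, see [generate_family()].
#' @param stage_plan named integer vector: ordered stage labels ->
#'   replicates per stage.
#' @param reads_per_sample,read_length,error_rate read simulation, see
#'   [simulate_reads()].
#' @param alpha_schedule,dominant_index mixture trajectory, see
#'   [generate_mixture_trajectory()].
#' @param out_dir output directory (data under `data/`, results at top
#'   level).
#' @param seed master seed; family, mixture and each sample derive their
#'   own sub-seed from it.
#' @param mode,variant_screen,max_mismatches passed to the pipeline config.
#' @return list with `pipeline` (the [run_pipeline()] result), `truth`
#'   (stage x group fraction matrix, columns named by isoform group) and
#'   `recovery` (per-sample data.frame of `sample_id`, `stage`,
#'   `max_abs_error`, plus attributes `trend_truth`, `trend_estimated`,
#'   `trend_agreement`). The recovery table is also written to
#'   `recovery_report.tsv`.
#' @export
simulate_and_run <- function(n_genes = 7, seq_length = 165,
                             n_variable_sites = 6,
                             identical_partition = NULL,
                             stage_plan = c(early_emb = 4, mid_emb = 4,
                                            late_emb = 4, L3 = 2, pharate = 4),
                             reads_per_sample = 50000, read_length = 48,
                             error_rate = 0, alpha_schedule = NULL,
                             dominant_index = 1L, out_dir = tempfile("snquant_run_"),
                             seed = 1L, mode = "linear_system",
                             variant_screen = FALSE, max_mismatches = 2L) {
  fam <- generate_family(n_genes, seq_length, n_variable_sites,
                         identical_partition = identical_partition,
                         family = "SYN", seed = sub_seed(seed, 1))
  groups <- collapse_identical(fam$genes)
  n_groups <- nrow(groups)
  # map partition cells (truth) to collapsed group ids
  cell_gid <- vapply(fam$partition, function(cell) {
    gid <- groups$group_id[vapply(groups$members, function(m)
      fam$genes$gene_id[cell[1]] %in% m, logical(1))]
    gid[1]
  }, character(1))

  mix <- generate_mixture_trajectory(n_groups, names(stage_plan),
                                     alpha_schedule = alpha_schedule,
                                     dominant_index = dominant_index,
                                     seed = sub_seed(seed, 2))
  truth <- mix$fractions
  colnames(truth) <- cell_gid

  data_dir <- file.path(out_dir, "data")
  dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(data_dir, "family.fasta")
  write_fasta(stats::setNames(fam$genes$sequence, fam$genes$gene_id), fasta)

  sheet <- list(); si <- 0
  group_seqs <- stats::setNames(groups$sequence, groups$group_id)
  for (stg in names(stage_plan)) {
    for (rep_i in seq_len(stage_plan[[stg]])) {
      si <- si + 1
      sid <- sprintf("%s_rep%d", stg, rep_i)
      sim <- simulate_reads(group_seqs, truth[stg, groups$group_id],
                            reads_per_sample, read_length,
                            error_rate = error_rate,
                            seed = sub_seed(seed, 100 + si),
                            read_id_prefix = sid)
      fq <- file.path(data_dir, paste0(sid, ".fastq"))
      write_fastq(sim, fq)
      sheet[[si]] <- data.frame(sample_id = sid, fastq = fq, stage = stg,
                                family = "SYN", stringsAsFactors = FALSE)
    }
  }
  sheet <- do.call(rbind, sheet)
  write_tsv(data.frame(stage = rep(rownames(truth), each = ncol(truth)),
                       group = rep(colnames(truth), nrow(truth)),
                       fraction = as.vector(t(truth))),
            file.path(data_dir, "mixture_truth.tsv"))

  res <- run_pipeline(list(
    families = stats::setNames(list(fasta), "SYN"),
    sample_sheet = sheet, read_length = read_length,
    stage_order = names(stage_plan), mode = mode,
    variant_screen = variant_screen, max_mismatches = max_mismatches,
    out_dir = out_dir, seed = seed))

  est <- res$SYN$estimates
  rec <- do.call(rbind, lapply(seq_len(nrow(sheet)), function(i) {
    f <- est[[sheet$sample_id[i]]]$fractions
    tr <- truth[sheet$stage[i], ]
    data.frame(sample_id = sheet$sample_id[i], stage = sheet$stage[i],
               max_abs_error = max(abs(f[names(tr)] - tr)),
               stringsAsFactors = FALSE)
  }))
  truth_sd <- apply(truth, 1, dominance_sd)
  attr(rec, "trend_truth") <- all(diff(truth_sd) >= -1e-12)
  attr(rec, "trend_estimated") <- res$SYN$trajectory$trend_monotone
  attr(rec, "trend_agreement") <-
    attr(rec, "trend_truth") == attr(rec, "trend_estimated")
  write_tsv(rec, file.path(out_dir, "recovery_report.tsv"))

  list(pipeline = res, truth = truth, recovery = rec)
}

# bounded derived seed (R integers are 32-bit)
sub_seed <- function(seed, i) as.integer((as.numeric(seed) * 1009 + i) %% 2147483629)
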