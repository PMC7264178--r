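#' Pipeline configuration
#'
#' Collects the inputs, thresholds, and method switches for
#' [run_pipeline()]. Either `sim` is given (a [sim_config()]; the
#' `simulate` stage then generates the fixture files) or `input_dir` points
#' at an existing fixture directory in the formats of [write_fixtures()].
#'
#' @param sim Optional [sim_config()] driving the `simulate` stage.
#' @param input_dir Directory with input files (used when `simulate` is not
#'   among the stages). Defaults to the pipeline's own `fixtures/`
#'   subdirectory of the output.
#' @param deg_strict_padj,deg_relaxed_p DEG thresholds (0.1 / 0.005).
#' @param dmr_strict_padj,dmr_relaxed_p DMR thresholds (0.05 / 0.05).
#' @param driver_rna,driver_chip `c(t_single_dm, t_dm_wt)` rescue-driver
#'   thresholds per domain (RNA 2, 0.7; ChIP integration 1, 0.7).
#' @param deg_relaxed_for Genotypes whose DEG/DMR calls use the relaxed
#'   threshold (default the writer heterozygote `A_HET`, whose single
#'   remaining allele produces only mild misregulation).
#' @param qc_threshold Spike-in target-dominance threshold (default 0.8).
#' @param nominal_p Nominal p for direction cross-classification.
#' @param slope_method `"ols_origin"` or `"sma_origin"`.
#' @param dispersion_method `"common"` or `"feature"`.
#' @param target_modification Spike-in target mark (default `"H3K4me3"`).
#' @param seed Integer seed for the run.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, input_dir = NULL,
                            deg_strict_padj = 0.1, deg_relaxed_p = 0.005,
                            dmr_strict_padj = 0.05, dmr_relaxed_p = 0.05,
                            driver_rna = c(2, 0.7), driver_chip = c(1, 0.7),
                            deg_relaxed_for = "A_HET", qc_threshold = 0.8,
                            nominal_p = 0.05, slope_method = "ols_origin",
                            dispersion_method = "feature",
                            target_modification = "H3K4me3", seed = 1L) {
  thr <- c(deg_strict_padj, deg_relaxed_p, dmr_strict_padj, dmr_relaxed_p,
           driver_rna, driver_chip, qc_threshold, nominal_p)
  if (any(thr <= 0)) abort("all thresholds must be positive")
  if (!slope_method %in% c("ols_origin", "sma_origin"))
    abort("unknown slope method: ", slope_method)
  structure(list(sim = sim, input_dir = input_dir,
                 deg_strict_padj = deg_strict_padj,
                 deg_relaxed_p = deg_relaxed_p,
                 dmr_strict_padj = dmr_strict_padj,
                 dmr_relaxed_p = dmr_relaxed_p,
                 driver_rna = driver_rna, driver_chip = driver_chip,
                 deg_relaxed_for = deg_relaxed_for,
                 qc_threshold = qc_threshold, nominal_p = nominal_p,
                 slope_method = slope_method,
                 dispersion_method = dispersion_method,
                 target_modification = target_modification,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys map to [pipeline_config()] arguments; a `sim` block maps
#' to [sim_config()] arguments.
#'
#' @param path Path to the YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  do.call(pipeline_config, y)
}

pipeline_stages <- function() c("simulate", "de", "chip", "rescue",
                                "integrate")

mutant_contrasts <- function() {
  list(A_vs_WT = c("A_HET", "WT"), B_vs_WT = c("B_KO", "WT"),
       DM_vs_WT = c("DM", "WT"), DM_vs_A = c("DM", "A_HET"),
       DM_vs_B = c("DM", "B_KO"))
}

read_de_result <- function(path, contrast) {
  r <- read.delim(path, stringsAsFactors = FALSE)
  r$tested <- !is.na(r$pvalue)
  attr(r, "contrast") <- contrast
  class(r) <- c("de_result", "data.frame")
  r
}

#' Run the rescue-quantification pipeline
#'
#' Orchestrates the stages `simulate` (generate and write synthetic
#' fixtures), `de` (five RNA Wald contrasts and DEG calls), `chip`
#' (spike-in QC, normalization, five DMR contrasts and calls), `rescue`
#' (fold-change tables, direction classes, group shift tests, slopes,
#' rescue drivers for RNA and chromatin), and `integrate` (peak
#' annotation, mRNA-by-chromatin quadrants, gene-set enrichment).
#' Later stages read the files written by earlier ones, so a stage subset
#' can resume from a previous run in the same `out_dir`; a missing
#' prerequisite produces an error naming the stage that would provide it.
#' Given a fixed seed and configuration, reruns are checksum-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of `simulate, de, chip, rescue, integrate`,
#'   executed in canonical order.
#' @return The run report (list): configuration echo, per-stage record
#'   counts, and an output manifest with MD5 checksums. Also written to
#'   `run_report.json`.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = pipeline_stages()) {
  stopifnot(inherits(config, "pipeline_config"))
  bad <- setdiff(stages, pipeline_stages())
  if (length(bad)) abort("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- intersect(pipeline_stages(), stages)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fixtures <- if (!is.null(config$input_dir) &&
                  !"simulate" %in% stages) config$input_dir
              else file.path(out_dir, "fixtures")
  counts_report <- list()
  outputs <- character(0)
  p <- function(f) file.path(out_dir, f)
  need <- function(f, stage) {
    if (!file.exists(f))
      abort("missing input `", basename(f), "`: run stage `", stage,
            "` first (or point `input_dir` at existing fixtures)")
    f
  }

  if ("simulate" %in% stages) {
    sim_cfg <- config$sim
    if (is.null(sim_cfg)) abort("`simulate` stage needs `config$sim`")
    rna <- simulate_rnaseq(sim_cfg)
    chip <- simulate_chipseq(sim_cfg, rna_truth = rna$truth$features)
    rescued <- rna$truth$features$feature[rna$truth$features$rescued]
    sets <- simulate_gene_sets(rna$truth$features$feature,
                               enriched_genes = rescued,
                               seed = sim_cfg$seed)
    files <- write_fixtures(list(rna = rna, chip = chip, config = sim_cfg,
                                 gene_sets = sets), fixtures)
    outputs <- c(outputs, unname(files))
    counts_report$simulate <- list(n_genes = nrow(rna$counts$counts),
                                   n_regions = nrow(chip$counts$counts),
                                   n_rna_samples = ncol(rna$counts$counts),
                                   n_chip_samples = ncol(chip$counts$counts))
  }

  fx <- function(f) file.path(fixtures, f)

  if ("de" %in% stages) {
    cm <- count_matrix(read_counts(need(fx("rna_counts.tsv"), "simulate")),
                       read_design(fx("rna_design.tsv")))
    sf <- size_factors(cm)
    disp <- estimate_dispersions(cm, sf = sf,
                                 method = config$dispersion_method)
    nde <- list()
    for (nm in names(mutant_contrasts())) {
      res <- nb_wald_test(cm, mutant_contrasts()[[nm]], sf = sf,
                          dispersions = disp)
      write_de_result(res, p(paste0("de_", nm, ".tsv")))
      outputs <- c(outputs, p(paste0("de_", nm, ".tsv")))
      nde[[nm]] <- sum(!is.na(res$padj) & res$padj < config$deg_strict_padj)
    }
    for (m in c("A", "B")) {
      res <- read_de_result(p(paste0("de_", m, "_vs_WT.tsv")),
                            mutant_contrasts()[[paste0(m, "_vs_WT")]])
      mode <- if (paste0(m, "_HET") %in% config$deg_relaxed_for ||
                  (m == "B" && "B_KO" %in% config$deg_relaxed_for))
        "relaxed" else "strict"
      degs <- call_degs(res, mode = mode,
                        padj_cutoff = config$deg_strict_padj,
                        p_cutoff = config$deg_relaxed_p)
      write_tsv(degs, p(paste0("deg_", m, ".tsv")))
      outputs <- c(outputs, p(paste0("deg_", m, ".tsv")))
      nde[[paste0("deg_", m)]] <- nrow(degs)
    }
    counts_report$de <- nde
  }

  if ("chip" %in% stages) {
    cm <- count_matrix(read_counts(need(fx("chip_counts.tsv"), "simulate")),
                       read_design(fx("chip_design.tsv")))
    spike <- read_spike_table(fx("spike_counts.tsv"))
    qc <- spike_specificity(spike, target = config$target_modification,
                            threshold = config$qc_threshold)
    design <- cm$design
    ips <- design$sample[design$role != "input"]
    totals <- if ("total_reads" %in% names(design))
      setNames(design$total_reads, design$sample)
    else setNames(colSums(cm$counts), design$sample)
    snorm <- spike_norm_coefficients(
      spike, ip_totals = totals[ips],
      input_totals = totals[setdiff(design$sample, ips)])
    jsonlite::write_json(
      list(qc = list(pass = qc$pass, reasons = qc$reasons,
                     target_fraction = as.list(qc$target_fraction)),
           enrichment = as.list(snorm$enrichment),
           coefficient = as.list(snorm$coefficient),
           size_factors = as.list(snorm$size_factors)),
      p("spike_norm.json"), digits = NA, auto_unbox = TRUE, pretty = TRUE)
    outputs <- c(outputs, p("spike_norm.json"))
    regions <- read_regions_bed(fx("regions.bed"))
    ndm <- list(qc_pass = qc$pass)
    for (nm in names(mutant_contrasts())) {
      res <- call_dmrs(cm, mutant_contrasts()[[nm]], spike_norm = snorm,
                       mode = NULL,
                       dispersion_method = config$dispersion_method)
      write_de_result(res, p(paste0("dmr_", nm, ".tsv")), extra = regions)
      outputs <- c(outputs, p(paste0("dmr_", nm, ".tsv")))
      ndm[[nm]] <- sum(!is.na(res$padj) & res$padj < config$dmr_strict_padj)
    }
    for (m in c("A", "B")) {
      res <- read_de_result(p(paste0("dmr_", m, "_vs_WT.tsv")),
                            mutant_contrasts()[[paste0(m, "_vs_WT")]])
      res$direction <- ifelse(res$log2FC > 0, "hyper", "hypo")
      keep <- if (paste0(m, "_HET") %in% config$deg_relaxed_for) {
        !is.na(res$pvalue) & res$pvalue < config$dmr_relaxed_p
      } else {
        !is.na(res$padj) & res$padj < config$dmr_strict_padj
      }
      dmrs <- res[keep, , drop = FALSE]
      write_tsv(dmrs, p(paste0("dmrs_", m, ".tsv")))
      outputs <- c(outputs, p(paste0("dmrs_", m, ".tsv")))
      ndm[[paste0("dmrs_", m)]] <- nrow(dmrs)
    }
    counts_report$chip <- ndm
  }

  if ("rescue" %in% stages) {
    report <- list()
    for (assay in c("rna", "chip")) {
      prefix <- if (assay == "rna") "de_" else "dmr_"
      de_list <- list()
      for (nm in names(mutant_contrasts()))
        de_list[[nm]] <- read_de_result(
          need(p(paste0(prefix, nm, ".tsv")),
               if (assay == "rna") "de" else "chip"),
          mutant_contrasts()[[nm]])
      fc <- build_fold_change_table(de_list)
      write_tsv(as.data.frame(fc), p(paste0("fc_table_", assay, ".tsv")))
      outputs <- c(outputs, p(paste0("fc_table_", assay, ".tsv")))
      arep <- list()
      for (m in c("A", "B")) {
        call_file <- p(paste0(if (assay == "rna") "deg_" else "dmrs_",
                              m, ".tsv"))
        calls <- read.delim(need(call_file,
                                 if (assay == "rna") "de" else "chip"),
                            stringsAsFactors = FALSE)
        mrep <- list(n_calls = nrow(calls))
        if (nrow(calls) >= 3) {
          feats <- calls$feature
          cls <- classify_direction(feats, fc, m,
                                    nominal_p = config$nominal_p)
          mrep$direction_classes <- as.list(table(cls$class))
          i <- match(feats, fc$feature)
          x <- fc[[paste0("log2FC_", m, "_vs_WT")]][i]
          y <- fc[["log2FC_DM_vs_WT"]][i]
          ok <- !is.na(x) & !is.na(y)
          for (dir in c("up", "down")) {
            sel <- ok & (if (dir == "up") x > 0 else x < 0)
            if (sum(sel) >= 3) {
              g <- group_rescue_test(x[sel], y[sel],
                                     set_id = paste(assay, m, dir,
                                                    sep = "_"))
              mrep[[paste0("shift_", dir)]] <-
                list(n = g$n, median_single = g$median_single,
                     median_dm = g$median_dm, W = g$statistic,
                     p = g$p.value, direction = g$direction)
            }
          }
          st <- slope_test(x[ok], y[ok], method = config$slope_method)
          mrep$slope <- list(method = st$method, slope = st$slope,
                             conf_int = st$conf_int, p = st$p.value,
                             n = st$n)
          drv <- call_rescue_drivers(
            fc, m, domain = if (assay == "rna") "rna"
                            else "chip_integration",
            t_single_dm = if (assay == "rna") config$driver_rna[1]
                          else config$driver_chip[1],
            t_dm_wt = if (assay == "rna") config$driver_rna[2]
                      else config$driver_chip[2])
          drv <- drv[drv$feature %in% feats & drv$driver, , drop = FALSE]
          write_tsv(drv, p(paste0("drivers_", assay, "_", m, ".tsv")))
          outputs <- c(outputs, p(paste0("drivers_", assay, "_", m,
                                         ".tsv")))
          mrep$n_drivers <- nrow(drv)
          if (assay == "chip") {
            summ <- dmr_rescue_summary(feats, fc, m,
                                       nominal_p = config$nominal_p)
            mrep$dmr_summary <- list(
              focus = summ$focus, n = as.list(summ$n),
              tests = lapply(summ$tests, function(g)
                list(n = g$n, p = g$p.value, direction = g$direction)))
          }
        }
        arep[[m]] <- mrep
      }
      report[[assay]] <- arep
    }
    jsonlite::write_json(report, p("rescue_report.json"), digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
    outputs <- c(outputs, p("rescue_report.json"))
    counts_report$rescue <- list(
      rna_drivers_A = report$rna$A$n_drivers,
      rna_drivers_B = report$rna$B$n_drivers)
  }

  if ("integrate" %in% stages) {
    regions <- read_regions_bed(need(fx("regions.bed"), "simulate"))
    genes <- read_gene_annotation(need(fx("gene_annotation.tsv"),
                                       "simulate"))
    anno <- annotate_peaks(regions, genes)
    write_tsv(anno, p("peak_annotation.tsv"))
    outputs <- c(outputs, p("peak_annotation.tsv"))
    fc_rna <- read.delim(need(p("fc_table_rna.tsv"), "rescue"),
                         stringsAsFactors = FALSE)
    fc_chip <- read.delim(need(p("fc_table_chip.tsv"), "rescue"),
                          stringsAsFactors = FALSE)
    irep <- list(feature_classes = as.list(table(anno$class)))
    for (m in c("A", "B")) {
      drv_file <- p(paste0("drivers_rna_", m, ".tsv"))
      if (!file.exists(drv_file)) next
      drv <- read.delim(drv_file, stringsAsFactors = FALSE)
      if (nrow(drv) < 4) {
        irep[[paste0("quadrants_", m)]] <- list(n = nrow(drv),
                                                note = "too few drivers")
        next
      }
      # pair each rescued gene with its promoter-assigned region
      reg_of_gene <- anno$region[match(drv$feature, anno$gene)]
      contr <- paste0("log2FC_DM_vs_", m)
      x <- fc_rna[[contr]][match(drv$feature, fc_rna$feature)]
      y <- fc_chip[[contr]][match(reg_of_gene, fc_chip$feature)]
      q <- quadrant_analysis(x, y)
      irep[[paste0("quadrants_", m)]] <- list(
        counts = as.list(q$counts), n_zero = q$n_zero, n = q$n,
        tests = q$tests, pearson_r = q$pearson_r,
        pearson_p = q$pearson_p)
      if (file.exists(fx("gene_sets.gmt"))) {
        sets <- read_gmt(fx("gene_sets.gmt"))
        enr <- fisher_enrichment(drv$feature, sets,
                                 universe = fc_rna$feature)
        write_tsv(enr, p(paste0("enrichment_", m, ".tsv")))
        outputs <- c(outputs, p(paste0("enrichment_", m, ".tsv")))
        irep[[paste0("enrichment_", m)]] <- list(
          n_significant = sum(enr$significant),
          top_set = enr$set[which.min(enr$p.value)],
          top_padj = min(enr$padj),
          top_odds_ratio = enr$odds_ratio[which.min(enr$p.value)])
      }
    }
    jsonlite::write_json(irep, p("integrate_report.json"), digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
    outputs <- c(outputs, p("integrate_report.json"))
    counts_report$integrate <- list(n_regions_annotated = nrow(anno))
  }

  outputs <- unique(outputs)
  pref <- paste0(out_dir, "/")
  rel <- ifelse(startsWith(outputs, pref),
                substring(outputs, nchar(pref) + 1L), outputs)
  manifest <- data.frame(file = rel,
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  report <- list(package_version = as.character(
                   utils::packageVersion("epirescue")),
                 config = unclass(config)[!vapply(unclass(config), is.null,
                                                  logical(1))],
                 stages = stages, record_counts = counts_report,
                 manifest = manifest)
  report$config$sim <- if (!is.null(config$sim)) unclass(config$sim)
  jsonlite::write_json(report, p("run_report.json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}
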