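#' Configuration for the synthetic four-genotype experiment
#'
#' Builds and validates the configuration object consumed by
#' [simulate_rnaseq()] and [simulate_chipseq()]. The generator emulates the
#' study design of a writer/eraser mutual-suppression experiment: negative
#' binomial counts for four genotypes (`WT`, writer heterozygote `A_HET`,
#' eraser knockout `B_KO`, double mutant `DM`), planted per-feature effects
#' in each single mutant, configurable opposite/same-direction overlap
#' between the two mutants, multiplicative rescue attenuation in the double
#' mutant, per-sample depth factors, and a barcoded spike-in nucleosome
#' panel whose counts encode per-IP antibody efficiency.
#'
#' Effect composition: the double-mutant effect of a feature is the sum of
#' its two single-mutant effects in log2 space; for rescued features the sum
#' is multiplied by `attenuation_a` in `[0, 1]`. A slope below one of
#' double-mutant versus single-mutant fold changes is therefore the planted,
#' identifiable target of the rescue statistics.
#'
#' Default effect directions mirror the biology being emulated: eraser-KO
#' effects are predominantly up-regulation (loss of an H3K4me3 eraser
#' derepresses genes) and writer-HET effects predominantly down.
#'
#' @param n_genes,n_regions Number of RNA features / ChIP regions.
#' @param reps_rna,reps_chip Replicates per genotype (RNA default 4,
#'   ChIP default 3).
#' @param baseline_logmean,baseline_logsd Log-scale parameters of the
#'   lognormal baseline abundance per feature.
#' @param dispersion Negative binomial dispersion `alpha >= 0`
#'   (`Var = mu + alpha * mu^2`); 0 gives Poisson counts.
#' @param frac_A_up,frac_A_down,frac_B_up,frac_B_down Fractions of features
#'   affected (up/down) in each single mutant; per mutant they must sum to
#'   at most 1, and a feature gets at most one effect class per mutant.
#' @param frac_opposite_overlap,frac_same_overlap Fractions of A-affected
#'   features that also carry a B effect with opposite (resp. same) sign.
#' @param effect_logmean,effect_logsd Lognormal parameters of the absolute
#'   log2 effect size (`meanlog`/`sdlog`); the default gives magnitudes
#'   centred on one log2 unit (two-fold).
#' @param frac_rescued Fraction of affected features whose double-mutant
#'   effect is attenuated.
#' @param attenuation_a Attenuation factor `a` in `[0, 1]` applied to the
#'   summed single-mutant effects of rescued features.
#' @param libsize_low,libsize_high Range of per-sample relative depth
#'   factors, drawn uniformly.
#' @param spike List configuring the spike-in panel: `n_barcodes`,
#'   `target_fraction` (fraction of barcodes carrying the target mark),
#'   `offtarget_rate` (capture rate of off-target barcodes relative to
#'   target), `ip_efficiencies` (per-IP positive reals, or `NULL` to draw
#'   uniformly on `[0.5, 2]`), `spike_depth` (expected spike reads per
#'   sample at depth factor 1).
#' @param seed Integer seed; output is byte-identical for a fixed seed and
#'   configuration.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_regions = 1500L,
                       reps_rna = 4L,
                       reps_chip = 3L,
                       baseline_logmean = log(150),
                       baseline_logsd = 1.2,
                       dispersion = 0.05,
                       frac_A_up = 0.01,
                       frac_A_down = 0.04,
                       frac_B_up = 0.08,
                       frac_B_down = 0.03,
                       frac_opposite_overlap = 0.25,
                       frac_same_overlap = 0.15,
                       effect_logmean = 0,
                       effect_logsd = 0.5,
                       frac_rescued = 0.5,
                       attenuation_a = 0.7,
                       libsize_low = 0.7,
                       libsize_high = 1.3,
                       spike = list(),
                       seed = 1L) {
  spike_defaults <- list(n_barcodes = 15L, target_fraction = 2 / 15,
                         offtarget_rate = 0.02, ip_efficiencies = NULL,
                         spike_depth = 5e4)
  spike <- utils::modifyList(spike_defaults, spike)
  cfg <- structure(list(
    n_genes = as.integer(n_genes), n_regions = as.integer(n_regions),
    reps_rna = as.integer(reps_rna), reps_chip = as.integer(reps_chip),
    baseline_logmean = baseline_logmean, baseline_logsd = baseline_logsd,
    dispersion = dispersion,
    frac_A_up = frac_A_up, frac_A_down = frac_A_down,
    frac_B_up = frac_B_up, frac_B_down = frac_B_down,
    frac_opposite_overlap = frac_opposite_overlap,
    frac_same_overlap = frac_same_overlap,
    effect_logmean = effect_logmean, effect_logsd = effect_logsd,
    frac_rescued = frac_rescued, attenuation_a = attenuation_a,
    libsize_low = libsize_low, libsize_high = libsize_high,
    spike = spike, seed = as.integer(seed)), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fr <- c("frac_A_up", "frac_A_down", "frac_B_up", "frac_B_down",
          "frac_opposite_overlap", "frac_same_overlap", "frac_rescued")
  for (f in fr) if (!is_fraction(cfg[[f]]))
    abort("`", f, "` must be a fraction in [0, 1]")
  if (!is_fraction(cfg$attenuation_a))
    abort("`attenuation_a` must be in [0, 1]")
  if (cfg$frac_A_up + cfg$frac_A_down > 1)
    abort("A-mutant effect fractions sum to more than 1")
  if (cfg$frac_B_up + cfg$frac_B_down > 1)
    abort("B-mutant effect fractions sum to more than 1")
  if (cfg$frac_opposite_overlap + cfg$frac_same_overlap > 1)
    abort("overlap fractions sum to more than 1")
  if (cfg$dispersion < 0) abort("`dispersion` must be >= 0")
  if (cfg$reps_rna < 1 || cfg$reps_chip < 1)
    abort("at least one replicate per genotype is required")
  if (cfg$libsize_low <= 0 || cfg$libsize_high < cfg$libsize_low)
    abort("library size range must be positive with low <= high")
  if (!is_fraction(cfg$spike$target_fraction))
    abort("`spike$target_fraction` must be in [0, 1]")
  invisible(cfg)
}

# Plant per-feature genotype effects. Returns the truth table:
# true_log2FC_A/_B/_DM, rescued flag, direction class.
plant_effects <- function(cfg, n) {
  fcA <- fcB <- numeric(n)
  nA_up <- round(cfg$frac_A_up * n); nA_down <- round(cfg$frac_A_down * n)
  nA <- nA_up + nA_down
  idxA <- if (nA > 0) sample.int(n, nA) else integer(0)
  signA <- rep(c(1, -1), c(nA_up, nA_down))
  if (nA > 0)
    fcA[idxA] <- signA * rlnorm(nA, cfg$effect_logmean, cfg$effect_logsd)

  # overlap: some A-affected features also carry a B effect; drawn uniformly
  # over the A-affected set so overlap is independent of the A sign class
  n_opp <- round(cfg$frac_opposite_overlap * nA)
  n_same <- round(cfg$frac_same_overlap * nA)
  ov <- if (n_opp + n_same > 0) sample(seq_len(nA), n_opp + n_same)
        else integer(0)
  idx_opp <- idxA[ov[seq_len(n_opp)]]
  idx_same <- idxA[ov[n_opp + seq_len(n_same)]]
  if (n_opp > 0)
    fcB[idx_opp] <- -sign(fcA[idx_opp]) *
      rlnorm(n_opp, cfg$effect_logmean, cfg$effect_logsd)
  if (n_same > 0)
    fcB[idx_same] <- sign(fcA[idx_same]) *
      rlnorm(n_same, cfg$effect_logmean, cfg$effect_logsd)

  # fill remaining B-affected features from A-unaffected ones
  nB_up <- round(cfg$frac_B_up * n); nB_down <- round(cfg$frac_B_down * n)
  have_up <- sum(fcB > 0); have_down <- sum(fcB < 0)
  need_up <- nB_up - have_up; need_down <- nB_down - have_down
  if (need_up < 0 || need_down < 0)
    abort("overlap fractions imply more B-mutant effects than frac_B_* allow")
  free <- setdiff(seq_len(n), idxA)
  if (need_up + need_down > length(free))
    abort("effect fractions leave too few unaffected features to fill ",
          "the B-mutant classes")
  pick <- if (need_up + need_down > 0) sample(free, need_up + need_down)
          else integer(0)
  iu <- pick[seq_len(need_up)]; id <- pick[need_up + seq_len(need_down)]
  if (need_up > 0)
    fcB[iu] <- rlnorm(need_up, cfg$effect_logmean, cfg$effect_logsd)
  if (need_down > 0)
    fcB[id] <- -rlnorm(need_down, cfg$effect_logmean, cfg$effect_logsd)

  affected <- fcA != 0 | fcB != 0
  rescued <- rep(FALSE, n)
  n_res <- round(cfg$frac_rescued * sum(affected))
  if (n_res > 0)
    rescued[sample(which(affected), n_res)] <- TRUE
  fcDM <- (fcA + fcB) * ifelse(rescued, cfg$attenuation_a, 1)

  cls <- rep("null", n)
  cls[fcA != 0 & fcB == 0] <- "A_only"
  cls[fcB != 0 & fcA == 0] <- "B_only"
  both <- fcA != 0 & fcB != 0
  cls[both & sign(fcA) != sign(fcB)] <- "opposite"
  cls[both & sign(fcA) == sign(fcB)] <- "same"

  data.frame(true_log2FC_A = fcA, true_log2FC_B = fcB, true_log2FC_DM = fcDM,
             rescued = rescued, direction_class = cls,
             stringsAsFactors = FALSE)
}

sample_design <- function(prefix, reps, assay, role = "none") {
  geno <- rep(genotype_levels(), each = reps)
  data.frame(sample = paste0(geno, "_", rep(seq_len(reps), 4)),
             genotype = geno, assay = assay, role = role,
             stringsAsFactors = FALSE)
}

nb_draw <- function(mu, dispersion) {
  n <- length(mu)
  if (dispersion <= 0) rpois(n, mu) else rnbinom(n, size = 1 / dispersion,
                                                 mu = mu)
}

#' Simulate a four-genotype RNA-seq experiment with planted rescue
#'
#' Draws negative binomial counts with mean
#' `libsize_s * q_g * 2^(beta_g(genotype_s))`, where `q_g` is a lognormal
#' baseline, `libsize_s` a uniform per-sample depth factor, and `beta_g` the
#' planted log2 effect of the sample's genotype (see [sim_config()] for the
#' effect/rescue construction).
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_rnaseq` with elements:
#'   \describe{
#'     \item{counts}{[count_matrix()] of genes x samples.}
#'     \item{truth}{list with `features` (the planted truth table, one row
#'       per gene) and `library_sizes` (named per-sample depth factors).}
#'   }
#' @examples
#' sim <- simulate_rnaseq(sim_config(n_genes = 50, seed = 7))
#' dim(sim$counts)
#' @export
simulate_rnaseq <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  design <- sample_design("g", config$reps_rna, "rna")
  truth <- plant_effects(config, n)
  q <- rlnorm(n, config$baseline_logmean, config$baseline_logsd)
  libsize <- runif(nrow(design), config$libsize_low, config$libsize_high)
  names(libsize) <- design$sample

  beta <- cbind(WT = 0, A_HET = truth$true_log2FC_A,
                B_KO = truth$true_log2FC_B, DM = truth$true_log2FC_DM)
  mu <- (q * 2^beta[, design$genotype]) %*% diag(libsize)
  counts <- matrix(nb_draw(mu, config$dispersion), nrow = n,
                   dimnames = list(sprintf("gene%04d", seq_len(n)),
                                   design$sample))
  truth$feature <- rownames(counts)
  truth <- truth[, c("feature", setdiff(names(truth), "feature"))]
  structure(list(counts = count_matrix(counts, design),
                 truth = list(features = truth, library_sizes = libsize)),
            class = "sim_rnaseq")
}

# deterministic synthetic genome layout: genes spaced along chromosomes,
# alternating strand, a 5 kb body with two exons
gene_layout <- function(n_genes) {
  chrom <- paste0("chr", (seq_len(n_genes) - 1L) %% 19L + 1L)
  idx <- stats::ave(seq_len(n_genes), chrom, FUN = seq_along)
  strand <- rep(c("+", "-"), length.out = n_genes)
  anchor <- 50000L * idx + 10000L
  tx_start <- ifelse(strand == "+", anchor, anchor - 5000L)
  tx_end <- tx_start + 5000L
  tss <- ifelse(strand == "+", tx_start, tx_end)
  exon1_s <- ifelse(strand == "+", tx_start, tx_end - 300L)
  exon2_s <- ifelse(strand == "+", tx_start + 2000L, tx_end - 2400L)
  data.frame(gene = sprintf("gene%04d", seq_len(n_genes)), chrom = chrom,
             strand = strand, tss = as.integer(tss),
             tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
             exon_starts = paste(exon1_s, exon2_s, sep = ","),
             exon_ends = paste(exon1_s + 300L, exon2_s + 400L, sep = ","),
             stringsAsFactors = FALSE)
}

#' Simulate a spike-in calibrated H3K4me3 ChIP-seq experiment
#'
#' Region counts follow the same negative binomial model as
#' [simulate_rnaseq()], additionally scaled by a per-IP antibody efficiency
#' `e_i`, which confounds true signal with IP strength. The spike-in table
#' encodes `e_i`: target-mark barcodes are captured proportionally to `e_i`
#' in each IP, off-target barcodes at `offtarget_rate * e_i`, and all
#' barcodes are represented uniformly in the input sample, so the IP/input
#' spike enrichment recovers `e_i`. One input sample is always included.
#'
#' The first `min(n_regions, n_genes)` regions are placed on the promoters
#' of a deterministic synthetic gene layout so RNA and ChIP results can be
#' integrated feature-by-feature; any remaining regions are intergenic.
#' When `rna_truth` is supplied (the `truth$features` table of a
#' [simulate_rnaseq()] run with matching `n_genes`), promoter regions
#' inherit the corresponding gene's planted effects, coupling chromatin to
#' expression; otherwise region effects are planted independently.
#'
#' @param config A [sim_config()] object.
#' @param rna_truth Optional truth table from [simulate_rnaseq()] used to
#'   couple region effects to gene effects.
#' @return A list of class `sim_chipseq` with elements `counts`
#'   ([count_matrix()] including the input sample), `regions` (BED-style
#'   data frame, 0-based half-open), `spike` (long-format barcode count
#'   table), `genes` (synthetic gene annotation), and `truth` (planted
#'   region effects, per-sample depth factors, per-IP efficiencies).
#' @export
simulate_chipseq <- function(config, rna_truth = NULL) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_regions
  genes <- gene_layout(max(config$n_genes, 1L))

  n_prom <- min(n, nrow(genes))
  prom_mid <- genes$tss[seq_len(n_prom)]
  n_extra <- n - n_prom
  extra_chrom <- if (n_extra > 0)
    paste0("chr", (seq_len(n_extra) - 1L) %% 19L + 1L) else character(0)
  extra_start <- if (n_extra > 0)
    25000L + 50000L * seq_len(n_extra) else integer(0)
  regions <- data.frame(
    region = sprintf("region%04d", seq_len(n)),
    chrom = c(genes$chrom[seq_len(n_prom)], extra_chrom),
    start = c(prom_mid - 500L, extra_start),
    end = 0L, stringsAsFactors = FALSE)
  regions$end <- regions$start + 1000L

  if (!is.null(rna_truth)) {
    if (nrow(rna_truth) < n_prom)
      abort("`rna_truth` has fewer features than promoter regions")
    truth <- plant_effects(config, n)
    cols <- c("true_log2FC_A", "true_log2FC_B", "true_log2FC_DM",
              "rescued", "direction_class")
    truth[seq_len(n_prom), cols] <- rna_truth[seq_len(n_prom), cols]
  } else {
    truth <- plant_effects(config, n)
  }
  truth$feature <- regions$region
  truth <- truth[, c("feature", setdiff(names(truth), "feature"))]
  truth$gene <- c(genes$gene[seq_len(n_prom)], rep(NA, n - n_prom))

  ipd <- sample_design("r", config$reps_chip, "chip", role = "IP")
  design <- rbind(ipd, data.frame(sample = "input_1", genotype = "WT",
                                  assay = "chip", role = "input",
                                  stringsAsFactors = FALSE))
  n_ip <- nrow(ipd)
  eff <- config$spike$ip_efficiencies
  if (is.null(eff)) eff <- runif(n_ip, 0.5, 2)
  if (length(eff) == 1L) eff <- rep(eff, n_ip)
  if (length(eff) != n_ip)
    abort("`spike$ip_efficiencies` must have one value per IP sample (",
          n_ip, ")")
  if (any(eff <= 0)) abort("IP efficiencies must be positive")
  names(eff) <- ipd$sample

  libsize <- runif(nrow(design), config$libsize_low, config$libsize_high)
  names(libsize) <- design$sample
  q <- rlnorm(n, config$baseline_logmean, config$baseline_logsd)

  beta <- cbind(WT = 0, A_HET = truth$true_log2FC_A,
                B_KO = truth$true_log2FC_B, DM = truth$true_log2FC_DM)
  mu_ip <- (q * 2^beta[, ipd$genotype]) %*% diag(libsize[ipd$sample] * eff)
  mu_in <- q * libsize[["input_1"]]
  counts <- cbind(matrix(nb_draw(mu_ip, config$dispersion), nrow = n),
                  nb_draw(mu_in, config$dispersion))
  dimnames(counts) <- list(regions$region, design$sample)

  spike <- simulate_spike_table(config$spike, ipd$sample, eff, libsize)

  structure(list(counts = count_matrix(counts, design), regions = regions,
                 spike = spike, genes = genes,
                 truth = list(features = truth, library_sizes = libsize,
                              ip_efficiencies = eff)),
            class = "sim_chipseq")
}

# Spike barcode counts are Poisson given expected abundance: spike depth is
# small relative to genomic reads. Target barcodes captured ~ e_i, off-target
# ~ offtarget_rate * e_i; input carries every barcode uniformly.
simulate_spike_table <- function(sp, ip_names, eff, libsize) {
  nb <- sp$n_barcodes
  n_target <- max(1L, round(sp$target_fraction * nb))
  mods <- c(rep("H3K4me3", n_target),
            rep_len(c("H3K4me1", "H3K4me2", "H3K9me3", "H3K27me3",
                      "H3K36me3", "H3K4me0", "H3K9me1", "H3K27me1"),
                    nb - n_target))
  barcodes <- sprintf("BC%02d", seq_len(nb))
  per_bc <- sp$spike_depth / nb
  rows <- lapply(c(ip_names, "input_1"), function(s) {
    if (s == "input_1") {
      lambda <- rep(per_bc, nb) * libsize[["input_1"]]
    } else {
      capt <- ifelse(mods == "H3K4me3", eff[[s]], sp$offtarget_rate * eff[[s]])
      lambda <- per_bc * capt * libsize[[s]]
    }
    data.frame(barcode = barcodes, modification = mods, sample = s,
               count = rpois(nb, lambda), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate synthetic gene sets (GMT-style)
#'
#' Random gene sets drawn from a universe, plus one planted set enriched for
#' a given gene list — handy for exercising [fisher_enrichment()] against a
#' known positive.
#'
#' @param universe Character vector of all gene ids.
#' @param enriched_genes Genes the planted set should over-represent.
#' @param n_sets Number of random background sets.
#' @param set_size Size of every set.
#' @param enriched_fraction Fraction of the planted set drawn from
#'   `enriched_genes`.
#' @param seed Integer seed.
#' @return Named list of character vectors; the planted set is named
#'   `"planted_rescue_pathway"`.
#' @export
simulate_gene_sets <- function(universe, enriched_genes, n_sets = 20L,
                               set_size = 50L, enriched_fraction = 0.6,
                               seed = 1L) {
  set.seed(derive_seed(seed, 2L))
  set_size <- min(set_size, length(universe))
  sets <- lapply(seq_len(n_sets), function(i) sample(universe, set_size))
  names(sets) <- sprintf("random_set_%02d", seq_len(n_sets))
  k <- min(round(enriched_fraction * set_size), length(enriched_genes))
  planted <- c(sample(enriched_genes, k),
               sample(setdiff(universe, enriched_genes), set_size - k))
  sets$planted_rescue_pathway <- planted
  sets
}

#' Write a simulation bundle to plain-text fixture files
#'
#' Writes counts TSVs, design TSVs, a regions BED (0-based half-open), the
#' spike-in TSV, the synthetic gene annotation, the truth JSON, and the
#' configuration YAML. A round-trip through [read_fixtures()] reproduces
#' the values exactly.
#'
#' @param bundle List with elements `rna` ([simulate_rnaseq()] output),
#'   `chip` ([simulate_chipseq()] output), `config` (the [sim_config()]),
#'   and optionally `gene_sets` (named list, written as GMT).
#' @param out_dir Output directory, created if needed.
#' @return Named character vector of the files written, invisibly.
#' @export
write_fixtures <- function(bundle, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    abort("cannot create output directory: ", out_dir)
  p <- function(f) file.path(out_dir, f)
  files <- c()
  if (!is.null(bundle$rna)) {
    write_counts(bundle$rna$counts$counts, p("rna_counts.tsv"))
    write_tsv(bundle$rna$counts$design, p("rna_design.tsv"))
    files <- c(files, rna_counts = p("rna_counts.tsv"),
               rna_design = p("rna_design.tsv"))
  }
  if (!is.null(bundle$chip)) {
    write_counts(bundle$chip$counts$counts, p("chip_counts.tsv"),
                 id_col = "region")
    d <- bundle$chip$counts$design
    d$total_reads <- round(bundle$chip$truth$library_sizes[d$sample] * 1e7)
    write_tsv(d, p("chip_design.tsv"))
    write_regions_bed(bundle$chip$regions, p("regions.bed"))
    write_tsv(bundle$chip$spike, p("spike_counts.tsv"))
    write_tsv(bundle$chip$genes, p("gene_annotation.tsv"))
    files <- c(files, chip_counts = p("chip_counts.tsv"),
               chip_design = p("chip_design.tsv"), regions = p("regions.bed"),
               spike = p("spike_counts.tsv"),
               gene_annotation = p("gene_annotation.tsv"))
  }
  if (!is.null(bundle$gene_sets)) {
    write_gmt(bundle$gene_sets, p("gene_sets.gmt"))
    files <- c(files, gene_sets = p("gene_sets.gmt"))
  }
  truth <- list(rna = bundle$rna$truth, chip = bundle$chip$truth)
  jsonlite::write_json(truth, p("truth.json"), digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  files <- c(files, truth = p("truth.json"))
  if (!is.null(bundle$config)) {
    yaml::write_yaml(unclass(bundle$config), p("config.yaml"))
    files <- c(files, config = p("config.yaml"))
  }
  invisible(files)
}

#' Read a fixture directory written by [write_fixtures()]
#'
#' @param dir Directory containing the fixture files.
#' @return List with elements `rna`, `chip`, `gene_sets` (if present),
#'   `truth`, and `config` (if present).
#' @export
read_fixtures <- function(dir) {
  p <- function(f) file.path(dir, f)
  out <- list()
  if (file.exists(p("rna_counts.tsv"))) {
    out$rna <- list(counts = count_matrix(read_counts(p("rna_counts.tsv")),
                                          read_design(p("rna_design.tsv"))))
  }
  if (file.exists(p("chip_counts.tsv"))) {
    out$chip <- list(
      counts = count_matrix(read_counts(p("chip_counts.tsv")),
                            read_design(p("chip_design.tsv"))),
      regions = read_regions_bed(p("regions.bed")),
      spike = read_spike_table(p("spike_counts.tsv")),
      genes = read_gene_annotation(p("gene_annotation.tsv")))
  }
  if (file.exists(p("gene_sets.gmt"))) out$gene_sets <- read_gmt(p("gene_sets.gmt"))
  if (file.exists(p("truth.json")))
    out$truth <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  if (file.exists(p("config.yaml")))
    out$config <- yaml::read_yaml(p("config.yaml"))
  out
}
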