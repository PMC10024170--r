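#' Default pipeline configuration
#'
#' Desk-scale end-to-end configuration: simulate an AIL, build the marker
#' panel from the founder VCF, genotype the sequenced cohort, and scan for
#' QTL. Any element can be overridden via `...` (nested lists are merged
#' shallowly per stage).
#'
#' @param seed Master seed.
#' @param ... Stage overrides: `sim` (arguments to [ail_config()] minus
#'   seed), `markers` (`min_freq_gap`), `genotype` (`window_sizes`, `rho`,
#'   `density_threshold`, `min_individuals`, `strict`), `scan` (`n_perm`,
#'   `alpha`, `fdr_q`, `merge_mb`, `line_difference`).
#' @return Nested configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    sim = list(
      chromosomes = data.frame(chrom = c("1", "2", "3"),
                               length = c(20e6, 10e6, 5e6), cm_per_mb = 1),
      markers_per_mb = 100,
      generation_sizes = c(F1 = 30, F2 = 120),
      qtl = data.frame(chrom = "1", pos = 8e6, a = 90, d = 0),
      coverage = 0.4,
      seq_error = 0.002
    ),
    markers = list(min_freq_gap = 1),
    genotype = list(window_sizes = c(50, 200), rho = 1e-3,
                    density_threshold = 20, min_individuals = 10,
                    strict = FALSE),
    scan = list(n_perm = 200, alpha = 0.05, fdr_q = 0.10, merge_mb = 15,
                line_difference = 1341)
  )
  over <- list(...)
  for (k in names(over)) {
    if (is.list(over[[k]]) && !is.data.frame(over[[k]]) && is.list(cfg[[k]])) {
      for (kk in names(over[[k]])) cfg[[k]][[kk]] <- over[[k]][[kk]]
    } else {
      cfg[[k]] <- over[[k]]
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim$chromosomes))
    y$sim$chromosomes <- as.data.frame(y$sim$chromosomes,
                                       stringsAsFactors = FALSE)
  if (!is.null(y$sim$qtl))
    y$sim$qtl <- as.data.frame(y$sim$qtl, stringsAsFactors = FALSE)
  if (!is.null(y$sim$generation_sizes))
    y$sim$generation_sizes <- unlist(y$sim$generation_sizes)
  do.call(pipeline_config, c(list(seed = if (is.null(y$seed)) 1L else y$seed),
                             y[setdiff(names(y), "seed")]))
}

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[ailmap] ", fmt), ...))
}

run_stage <- function(name, outputs, force, verbose, fun) {
  if (!force && length(outputs) && all(file.exists(outputs))) {
    stage_log(verbose, "stage %s: outputs exist, skipping", name)
    return(NULL)
  }
  stage_log(verbose, "stage %s: running", name)
  tryCatch(fun(), error = function(e) {
    stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full simulate-markers-genotype-scan pipeline
#'
#' Executes the four stages in order, writing all artifacts and a manifest
#' to `out_dir`. Stages whose outputs already exist are skipped unless
#' `force = TRUE`. Any stage failure aborts with a diagnostic naming the
#' stage.
#'
#' @param config A `pipeline_config` (or YAML path).
#' @param out_dir Run directory (created if needed).
#' @param force Re-run stages whose outputs exist.
#' @param verbose Log stage progress to stderr.
#' @param stages Subset of `c("simulate", "markers", "genotype", "scan")` to
#'   execute (in pipeline order); earlier stages' outputs must already be
#'   present in `out_dir` when skipped.
#' @return The run directory, invisibly. Artifacts: `founders.vcf`,
#'   `panel.tsv`, `counts.tsv`, `phenotypes.csv`, `truth_bins.tsv`,
#'   `panel_called.tsv`, `genotypes.tsv`, `bin_qc.tsv`, `scan.tsv`,
#'   `qtl.tsv`, `manifest.yaml`.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE, verbose = TRUE,
                         stages = c("simulate", "markers", "genotype",
                                    "scan")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"),
            all(stages %in% c("simulate", "markers", "genotype", "scan")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  meta <- list(seed = config$seed)
  manifest <- list(seed = config$seed,
                   version = as.character(utils::packageVersion("ailmap")),
                   stages = list())

  # -- stage 1: simulate ----------------------------------------------------
  sim_out <- p(c("founders.vcf", "panel.tsv", "counts.tsv", "phenotypes.csv",
                 "truth_bins.tsv"))
  if ("simulate" %in% stages)
  run_stage("simulate", sim_out, force, verbose, function() {
    cfg <- do.call(ail_config, c(config$sim, list(seed = config$seed)))
    sim <- simulate_ail(cfg)
    write_founder_vcf(sim$founders, p("founders.vcf"))
    write_panel(sim$founders$panel_truth, p("panel.tsv"), meta)
    write_counts(sim$counts, p("counts.tsv"), meta)
    write_phenotypes(sim$phenotypes$phenotypes, p("phenotypes.csv"), meta)
    write_geno_matrix(sim$truth_bins, p("truth_bins.tsv"), meta)
  })
  if (file.exists(p("counts.tsv")))
    manifest$stages$simulate <- list(
      outputs = basename(sim_out),
      rows = nrow(read_counts(p("counts.tsv")))
    )

  # -- stage 2: markers -----------------------------------------------------
  if ("markers" %in% stages)
  run_stage("markers", p("panel_called.tsv"), force, verbose, function() {
    fv <- read_founder_vcf(p("founders.vcf"))
    panel <- select_informative_markers(fv$genotypes, fv$line, fv$sites,
                                        min_freq_gap = config$markers$min_freq_gap)
    write_panel(panel, p("panel_called.tsv"), meta)
  })
  if (file.exists(p("panel_called.tsv")))
    manifest$stages$markers <- list(outputs = "panel_called.tsv",
                                    rows = nrow(read_panel(p("panel_called.tsv"))))

  # -- stage 3: genotype ----------------------------------------------------
  if ("genotype" %in% stages)
  run_stage("genotype", p(c("genotypes.tsv", "bin_qc.tsv")), force, verbose,
            function() {
    counts <- read_counts(p("counts.tsv"))
    panel <- read_panel(p("panel_called.tsv"))
    sim_chrom <- config$sim$chromosomes
    g <- config$genotype
    geno <- call_genotypes(counts, panel, sim_chrom,
                           window_sizes = g$window_sizes, rho = g$rho,
                           density_threshold = g$density_threshold,
                           min_individuals = g$min_individuals,
                           strict = g$strict)
    write_geno_matrix(geno, p("genotypes.tsv"), meta)
    qc <- attr(geno, "bins")
    qc$fallback_rate <- attr(geno, "fallback_rate")
    write_commented(qc, p("bin_qc.tsv"), meta)
  })
  if (file.exists(p("genotypes.tsv")))
    manifest$stages$genotype <- list(outputs = c("genotypes.tsv", "bin_qc.tsv"),
                                     rows = nrow(read_geno_matrix(p("genotypes.tsv"))))

  # -- stage 4: scan --------------------------------------------------------
  if ("scan" %in% stages)
  run_stage("scan", p(c("scan.tsv", "qtl.tsv", "ic.tsv")), force, verbose,
            function() {
    if (!file.exists(p("phenotypes.csv")))
      stop("phenotype file missing: ", p("phenotypes.csv"))
    phen <- standardize(read_phenotypes(p("phenotypes.csv")))
    geno <- read_geno_matrix(p("genotypes.tsv"))
    s <- config$scan
    scan <- hk_scan(geno, phen)
    thr <- permutation_threshold(geno, phen, n_perm = s$n_perm,
                                 alpha = s$alpha, seed = config$seed + 10L)
    sel <- union(fdr_select(scan$p, q = s$fdr_q), which(scan$lod >= thr))
    qtls <- collapse_peaks(scan, sel, thr, merge_mb = s$merge_mb)
    if (nrow(qtls)) {
      bin_names <- paste0(qtls$chrom, ":",
                          format(qtls$start, scientific = FALSE, trim = TRUE))
      eff <- qtl_effects(geno, phen, bin_names)
      jt <- fit_multi_qtl(geno, phen, bin_names)
      qtls$a_g <- eff$a_g
      qtls$se_g <- eff$se_g
      qtls$pct_var <- jt$pct_var[match(bin_names, jt$bin)]
    } else {
      qtls$a_g <- qtls$se_g <- qtls$pct_var <- numeric(0)
    }
    write_commented(scan, p("scan.tsv"),
                    c(meta, list(threshold = sprintf("%.6f", thr))))
    write_commented(qtls, p("qtl.tsv"),
                    c(meta, list(threshold = sprintf("%.6f", thr))))
    ic <- information_content(geno)
    write_commented(data.frame(bin = names(ic), ic = as.numeric(ic),
                               stringsAsFactors = FALSE),
                    p("ic.tsv"), meta)
  })
  if (file.exists(p("scan.tsv"))) {
    scan_tab <- read_commented(p("scan.tsv"))
    thr_line <- grep("^# threshold:", readLines(p("scan.tsv"), n = 5L),
                     value = TRUE)
    manifest$stages$scan <- list(
      outputs = c("scan.tsv", "qtl.tsv", "ic.tsv"),
      rows = nrow(scan_tab),
      threshold = as.numeric(sub("^# threshold: ", "", thr_line)),
      n_perm = config$scan$n_perm, alpha = config$scan$alpha
    )
  }
  manifest$parameters <- list(
    markers = config$markers, genotype = config$genotype, scan = config$scan
  )
  yaml::write_yaml(manifest, p("manifest.yaml"))
  stage_log(verbose, "pipeline complete: %s", out_dir)
  invisible(out_dir)
}

#' Summarize a pipeline run
#'
#' Writes `report.txt` in the run directory: the genome-wide threshold used
#' (as recorded in the manifest), the QTL table, and the line-difference
#' accounting aggregates (`sum_a`, `2*sum_a`, percent of the line
#' difference).
#'
#' @param run_dir Directory produced by [run_pipeline()].
#' @return The report lines, invisibly.
#' @export
write_report <- function(run_dir) {
  qtl_path <- file.path(run_dir, "qtl.tsv")
  man_path <- file.path(run_dir, "manifest.yaml")
  stopifnot(file.exists(qtl_path), file.exists(man_path))
  qtls <- read_commented(qtl_path)
  man <- yaml::read_yaml(man_path)
  ld <- man$parameters$scan$line_difference
  lines <- c(
    "AIL genotyping and QTL scan report",
    sprintf("seed: %d; package version: %s", man$seed, man$version),
    sprintf("genome-wide LOD threshold: %.3f (%d permutations, alpha %.2f)",
            man$stages$scan$threshold, man$stages$scan$n_perm,
            man$stages$scan$alpha),
    ""
  )
  if (nrow(qtls) == 0L) {
    lines <- c(lines, "No QTL peaks detected.")
  } else {
    acc <- line_difference_accounting(qtls$a_g, line_difference = ld)
    lines <- c(
      lines,
      sprintf("QTL peaks: %d", nrow(qtls)),
      utils::capture.output(print(format(qtls, digits = 4),
                                  row.names = FALSE)),
      "",
      sprintf("sum of additive effects: %.1f g", acc$sum_a),
      sprintf("doubled sum (2a): %.1f g", acc$two_sum_a),
      sprintf("fraction of line difference (%.0f g): %.1f%%",
              ld, acc$fraction_pct)
    )
  }
  writeLines(lines, file.path(run_dir, "report.txt"))
  invisible(lines)
}
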