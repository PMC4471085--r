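#' Parse a flat key:value configuration file
#'
#' One `key: value` pair per line; blank lines and `#` comments are
#' ignored. Values that parse as numbers become numeric; comma-separated
#' values become vectors.
#'
#' @param path Configuration file.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  bad <- !grepl(":", lines, fixed = TRUE)
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1]])
  keys <- trimws(sub(":.*$", "", lines))
  vals <- trimws(sub("^[^:]*:", "", lines))
  parse1 <- function(v) {
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else parts
  }
  stats::setNames(lapply(vals, parse1), keys)
}

artifact_paths <- function(outdir) {
  list(
    sim_prefix = file.path(outdir, "simulated"),
    truth = file.path(outdir, "sweep_truth.tsv"),
    qc_prefix = file.path(outdir, "qc_filtered"),
    qc_report = file.path(outdir, "qc_report.tsv"),
    prune_prefix = file.path(outdir, "pruned"),
    kept = file.path(outdir, "pruned_kept_ids.txt"),
    fst_loci = file.path(outdir, "fst_per_locus.tsv"),
    fst_summary = file.path(outdir, "fst_pairwise.tsv"),
    tree = file.path(outdir, "fst_tree.nwk"),
    pca_scores = file.path(outdir, "pca_scores.tsv"),
    windows = file.path(outdir, "windows.tsv"),
    candidates = file.path(outdir, "candidate_windows.tsv"),
    correlation = file.path(outdir, "lsbl_d_correlation.tsv"),
    genes_specific = file.path(outdir, "genes_in_windows.tsv"),
    genes_peak = file.path(outdir, "peak_snp_genes.tsv"),
    summary = file.path(outdir, "report_summary.tsv"),
    manifest = file.path(outdir, "manifest.json")
  )
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

need_artifact <- function(path, stage) {
  if (!all(file.exists(path))) {
    stop("missing upstream artifact ", paste(path, collapse = ", "),
         "; run stage '", stage, "' first")
  }
}

load_stage_genotypes <- function(paths) {
  # prefer QC output, fall back to raw simulated/provided genotypes
  if (file.exists(paste0(paths$qc_prefix, ".ped"))) {
    read_plink(paths$qc_prefix)
  } else {
    need_artifact(paste0(paths$sim_prefix, ".ped"), "simulate")
    read_plink(paths$sim_prefix)
  }
}

#' Run pipeline stages end-to-end
#'
#' Orchestrates the scan as resumable file-backed stages: `simulate`
#' (or user-supplied genotypes), `qc`, `prune`, `fst`, `scan`,
#' `annotate`, `report`, or `all`. Each stage reads its inputs from
#' `outdir` (or the configured external files), writes TSV artifacts
#' there, and updates a JSON manifest with configuration, seed and
#' artifact checksums; re-running a stage with unchanged inputs
#' reproduces identical artifacts.
#'
#' Config keys (flat list or [read_pipeline_config()] file): `outdir`,
#' `seed`; simulate-mode keys mirroring [sim_config()] arguments
#' (`n_per_pop`, `drift_F`, `n_chrom`, `chrom_length_bp`,
#' `snp_spacing_bp`, `n_sweep_regions`, `sweep_shift`,
#' `sweep_width_bp`, `missing_rate`, `pop_labels`); `genotypes_prefix`
#' (PLINK prefix) or `vcf` + `popmap` for real data; `genes` +
#' `genes_format` for annotation; QC/prune/scan threshold keys
#' (`maf_min`, `hwe_p_min`, `window_snps`, `step_snps`, `r2_max`,
#' `window_bp`, `min_snps`, `percentile`, `bin_size`, `near_bp`).
#'
#' @param stage One of `"simulate"`, `"qc"`, `"prune"`, `"fst"`,
#'   `"scan"`, `"annotate"`, `"report"`, `"all"`.
#' @param config Named list or path to a key:value config file.
#' @return Invisibly, a list of the artifacts the stage produced.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "qc", "prune", "fst",
                                   "scan", "annotate", "report"),
                         config) {
  stage <- match.arg(stage)
  if (is.character(config) && length(config) == 1) {
    config <- read_pipeline_config(config)
  }
  cfg <- config
  if (is.null(cfg$outdir)) stop("config needs an 'outdir'")
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- artifact_paths(outdir)
  grab <- function(key, default) if (is.null(cfg[[key]])) default else cfg[[key]]

  stages <- if (stage == "all") {
    c(if (is.null(cfg$genotypes_prefix) && is.null(cfg$vcf)) "simulate",
      "qc", "prune", "fst", "scan",
      if (!is.null(cfg$genes)) "annotate", "report")
  } else stage
  produced <- list()

  for (st in stages) {
    produced[[st]] <- switch(st,
      simulate = {
        sc <- sim_config(
          pop_labels = grab("pop_labels", c("GMM", "AWD", "CMF")),
          n_per_pop = grab("n_per_pop", c(161, 100, 61)),
          n_chrom = grab("n_chrom", 26),
          chrom_length_bp = grab("chrom_length_bp", 9e7),
          snp_spacing_bp = grab("snp_spacing_bp", 5e4),
          drift_F = grab("drift_F", c(0.18, 0.20, 0.08)),
          n_sweep_regions = grab("n_sweep_regions", 0),
          sweep_width_bp = grab("sweep_width_bp", 3e5),
          sweep_shift = grab("sweep_shift", 0.45),
          missing_rate = grab("missing_rate", 0.01),
          seed = grab("seed", 1L)
        )
        sim <- simulate_genotypes(sc)
        write_plink(sim$genotypes, paths$sim_prefix)
        write_truth(sim$truth, paths$truth)
        c(paste0(paths$sim_prefix, c(".ped", ".map")), paths$truth)
      },
      qc = {
        gm <- if (!is.null(cfg$genotypes_prefix)) {
          read_plink(cfg$genotypes_prefix)
        } else if (!is.null(cfg$vcf)) {
          read_vcf(cfg$vcf, cfg$popmap)
        } else {
          need_artifact(paste0(paths$sim_prefix, ".ped"), "simulate")
          read_plink(paths$sim_prefix)
        }
        qc <- apply_qc(gm, qc_config(
          maf_min = grab("maf_min", 0.01),
          hwe_p_min = grab("hwe_p_min", 1e-6),
          hwe_scope = grab("hwe_scope", "pooled")
        ))
        write_plink(qc$genotypes, paths$qc_prefix)
        write_tsv(qc$report, paths$qc_report)
        c(paste0(paths$qc_prefix, c(".ped", ".map")), paths$qc_report)
      },
      prune = {
        need_artifact(paste0(paths$qc_prefix, ".ped"), "qc")
        gm <- read_plink(paths$qc_prefix)
        pr <- prune_ld(gm, prune_config(
          window_snps = grab("window_snps", 25),
          step_snps = grab("step_snps", 5),
          r2_max = grab("r2_max", 0.1)
        ))
        write_plink(pr$genotypes, paths$prune_prefix)
        writeLines(pr$kept_ids, paths$kept)
        pca <- pca_genotypes(pr$genotypes,
                             n_components = min(10, nrow(gm$dosages) - 1))
        write_tsv(
          data.frame(sample_id = rownames(pca$scores),
                     population = pca$populations,
                     round(pca$scores, 6)),
          paths$pca_scores
        )
        c(paste0(paths$prune_prefix, c(".ped", ".map")), paths$kept,
          paths$pca_scores)
      },
      fst = {
        need_artifact(paste0(paths$qc_prefix, ".ped"), "qc")
        gm <- read_plink(paths$qc_prefix)
        scores <- breed_scores(gm)
        per_locus <- cbind(scores$loci,
                           round(scores$theta, 6),
                           round(scores$lsbl, 6), round(scores$d, 6))
        write_tsv(per_locus, paths$fst_loci)
        sm <- pairwise_fst(gm)
        write_tsv(within(sm, theta <- round(theta, 6)), paths$fst_summary)
        writeLines(fst_tree(sm), paths$tree)
        c(paths$fst_loci, paths$fst_summary, paths$tree)
      },
      scan = {
        need_artifact(c(paste0(paths$qc_prefix, ".ped")), "qc")
        gm <- read_plink(paths$qc_prefix)
        scan_cfg <- scan_config(
          window_bp = grab("window_bp", 3e5),
          min_snps = grab("min_snps", 3),
          percentile = grab("percentile", 0.99),
          bin_size = grab("bin_size", 5000)
        )
        scores <- breed_scores(gm)
        wt <- build_windows(scores, scan_cfg)
        write_tsv(as.data.frame(wt), paths$windows)
        sets <- candidate_sets(wt, scan_cfg)
        cand <- do.call(rbind, lapply(names(sets$merged), function(b) {
          data.frame(
            breed = b,
            window = sort(unique(c(sets$lsbl[[b]], sets$d[[b]]))),
            lsbl_selected = sort(unique(c(sets$lsbl[[b]], sets$d[[b]]))) %in%
              sets$lsbl[[b]],
            d_selected = sort(unique(c(sets$lsbl[[b]], sets$d[[b]]))) %in%
              sets$d[[b]],
            merged = sort(unique(c(sets$lsbl[[b]], sets$d[[b]]))) %in%
              sets$merged[[b]]
          )
        }))
        write_tsv(cand, paths$candidates)
        corr <- do.call(rbind, lapply(attr(wt, "breeds"), function(b) {
          sc <- stat_correlation(scores, b, scan_cfg)
          cbind(breed = b, sc$bins,
                overall_r = round(sc$overall_r, 4))
        }))
        write_tsv(corr, paths$correlation)
        c(paths$windows, paths$candidates, paths$correlation)
      },
      annotate = {
        need_artifact(c(paths$windows, paths$candidates), "scan")
        if (is.null(cfg$genes)) stop("config needs 'genes' for annotate")
        gm <- load_stage_genotypes(paths)
        scan_cfg <- scan_config(
          window_bp = grab("window_bp", 3e5),
          min_snps = grab("min_snps", 3),
          percentile = grab("percentile", 0.99)
        )
        scores <- breed_scores(gm)
        wt <- build_windows(scores, scan_cfg)
        sets <- candidate_sets(wt, scan_cfg)
        genes <- read_gene_intervals(cfg$genes,
                                     format = grab("genes_format", "auto"))
        giw <- genes_in_windows(wt, genes, sets$merged)
        write_tsv(giw$specific, paths$genes_specific)
        pk <- peak_snp_genes(wt, genes, sets$merged, scores,
                             near_bp = grab("near_bp", 5e4))
        write_tsv(pk, paths$genes_peak)
        c(paths$genes_specific, paths$genes_peak)
      },
      report = {
        need_artifact(c(paths$fst_summary, paths$windows,
                        paths$candidates), "fst/scan")
        sm <- utils::read.table(paths$fst_summary, header = TRUE, sep = "\t")
        wt <- utils::read.table(paths$windows, header = TRUE, sep = "\t")
        cand <- utils::read.table(paths$candidates, header = TRUE, sep = "\t")
        breeds <- sub("^lsbl_", "", grep("^lsbl_", names(wt), value = TRUE))
        merged <- lapply(breeds, function(b) {
          cand$window[cand$breed == b & cand$merged]
        })
        names(merged) <- breeds
        shared <- if (length(merged) >= 2) {
          nrow(cross_breed_overlap(merged)$windows)
        } else 0
        lines <- c(
          sprintf("pairwise_fst\t%s-%s\t%.4f", sm$pop_i, sm$pop_j, sm$theta),
          sprintf("n_windows\tall\t%d", nrow(wt)),
          sprintf("mean_snps_per_window\tall\t%.2f", mean(wt$n_snps)),
          sprintf("n_selected_per_statistic\tall\t%d",
                  ceiling(0.01 * nrow(wt))),
          sprintf("n_merged_windows\t%s\t%d", names(merged),
                  vapply(merged, length, integer(1))),
          sprintf("n_shared_windows\tall\t%d", shared)
        )
        writeLines(c("metric\tscope\tvalue", lines), paths$summary)
        paths$summary
      }
    )
  }
  files <- unlist(produced, use.names = FALSE)
  manifest <- list(
    stage = stage, config = cfg,
    artifacts = as.list(tools::md5sum(files[file.exists(files)])),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("lsblscan"))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(produced)
}

#' Per-breed candidate window sets from a window table
#'
#' Convenience wrapper: for every breed, the LSBL outlier set, the d
#' outlier set and their intersection (merged set).
#'
#' @param wt A [build_windows()] table.
#' @param cfg A [scan_config()].
#' @return List with named lists `lsbl`, `d`, `merged` (window indices
#'   per breed).
#' @export
candidate_sets <- function(wt, cfg = scan_config()) {
  breeds <- attr(wt, "breeds")
  if (is.null(breeds)) {
    breeds <- sub("^lsbl_", "", grep("^lsbl_", names(wt), value = TRUE))
  }
  l <- lapply(breeds, function(b) select_outlier_windows(wt, "lsbl", b, cfg))
  d <- lapply(breeds, function(b) select_outlier_windows(wt, "d", b, cfg))
  m <- Map(merge_candidates, l, d)
  names(l) <- names(d) <- names(m) <- breeds
  list(lsbl = l, d = d, merged = m)
}
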