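# End-to-end orchestration: config, run, report files.

#' Pipeline run configuration
#'
#' Bundles paths and parameters for a full scan: filter thresholds, window
#' tiling, outlier rules and the populations to compare.
#'
#' @param vcf,popmap,out_dir input VCF, sample-map TSV and output
#'   directory.
#' @param gtf optional GTF annotation; when `NULL` no candidate genes are
#'   reported.
#' @param fst_pops exactly two population labels for the differentiation
#'   scan.
#' @param hp_pops populations for the heterozygosity scan (default: both
#'   `fst_pops`).
#' @param filter a [filter_config()].
#' @param window_size,step,min_snps window tiling parameters (bp, bp,
#'   SNPs).
#' @param fst_fraction top fraction of windows flagged by
#'   \eqn{ZF_{ST}} (default 0.01).
#' @param zhp_threshold,zhp_inclusive \eqn{ZH_P} cutoff (default -4,
#'   inclusive).
#' @param sigma standard-deviation convention for the Z-transforms
#'   (`"sample"` or `"population"`).
#' @param flank bp of flank around gene bodies for the overlap rule.
#' @return object of class `run_config`.
#' @export
run_config <- function(vcf, popmap, out_dir, gtf = NULL, fst_pops,
                       hp_pops = fst_pops, filter = filter_config(),
                       window_size = 100000, step = 50000, min_snps = 10,
                       fst_fraction = 0.01, zhp_threshold = -4,
                       zhp_inclusive = TRUE, sigma = "sample", flank = 0) {
  if (length(fst_pops) != 2) {
    stop("config error: exactly 2 populations must be selected for F_ST")
  }
  stopifnot(inherits(filter, "filter_config"), fst_fraction > 0,
            fst_fraction <= 1)
  structure(list(vcf = vcf, popmap = popmap, gtf = gtf, out_dir = out_dir,
                 fst_pops = fst_pops, hp_pops = hp_pops, filter = filter,
                 window_size = window_size, step = step, min_snps = min_snps,
                 fst_fraction = fst_fraction, zhp_threshold = zhp_threshold,
                 zhp_inclusive = zhp_inclusive, sigma = sigma, flank = flank),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_outlier_bed <- function(os, path) {
  if (nrow(os$windows)) {
    bed <- data.frame(chrom = os$windows$chrom,
                      start = as.integer(os$windows$start),
                      end = as.integer(os$windows$end),
                      name = paste0(os$statistic, "_", os$label),
                      score = os$windows$z, stringsAsFactors = FALSE)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    file.create(path)
  }
  path
}

#' Run the full selection scan
#'
#' Reads and filters the VCF, computes the window statistic table, calls
#' \eqn{ZF_{ST}} and \eqn{ZH_P} outliers, annotates candidate genes when a
#' GTF is given, and writes all artifacts to the output directory:
#' `filter_report.tsv`, `windows.tsv`, `fst_outliers.bed`,
#' `hp_outliers_<pop>.bed`, `candidates_<pop>.tsv` and `run.log`. The run
#' is deterministic: identical inputs and configuration produce
#' byte-identical outputs.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) list with the in-memory results (`windows`,
#'   `fst_outliers`, `hp_outliers`, `candidates`, `filter_report`) and the
#'   written `paths`. Errors in any stage are reported with the stage
#'   name.
#' @export
run_scan <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  note("sweepscan run")
  note("vcf=", cfg$vcf)
  note("popmap=", cfg$popmap)
  note("gtf=", if (is.null(cfg$gtf)) "(none)" else cfg$gtf)
  note("fst_pops=", paste(cfg$fst_pops, collapse = ","),
       " hp_pops=", paste(cfg$hp_pops, collapse = ","))
  note("window_size=", format(cfg$window_size, scientific = FALSE),
       " step=", format(cfg$step, scientific = FALSE),
       " min_snps=", cfg$min_snps)
  note("filter: ", cfg$filter$depth_min, "<depth<", cfg$filter$depth_max,
       " maf>", cfg$filter$maf_min, " missing<", cfg$filter$max_missing)
  note("fst_fraction=", cfg$fst_fraction,
       " zhp_threshold=", cfg$zhp_threshold,
       " zhp_boundary=", if (cfg$zhp_inclusive) "inclusive(<=)" else "strict(<)",
       " sigma=", cfg$sigma)

  sm <- stage("sample_map", read_sample_map(cfg$popmap))
  vt <- stage("read_vcf", read_vcf(cfg$vcf, sm))
  note("sites_read=", n_sites(vt))

  fr <- stage("filter", filter_variants(vt, cfg$filter))
  vtf <- fr$table
  note("sites_retained=", n_sites(vtf), " removed=",
       paste(fr$report$criterion, fr$report$removed, sep = ":", collapse = " "))
  paths <- list(filter_report = write_tsv(fr$report,
                                          file.path(cfg$out_dir, "filter_report.tsv")))

  ws <- stage("window_stats",
              window_stats(vtf, cfg$fst_pops, cfg$hp_pops,
                           window_size = cfg$window_size, step = cfg$step,
                           min_snps = cfg$min_snps, sigma = cfg$sigma))
  note("windows=", nrow(ws), " fst_evaluable=", sum(!is.na(ws$zfst)))
  paths$windows <- write_tsv(ws, file.path(cfg$out_dir, "windows.tsv"))

  fst_out <- stage("fst_outliers", call_fst_outliers(ws, cfg$fst_fraction))
  note("fst_outliers=", nrow(fst_out$windows))
  paths$fst_outliers <- write_outlier_bed(fst_out,
                                          file.path(cfg$out_dir, "fst_outliers.bed"))

  hp_out <- list()
  for (p in cfg$hp_pops) {
    hp_out[[p]] <- stage("hp_outliers",
                         call_hp_outliers(ws, p, cfg$zhp_threshold,
                                          cfg$zhp_inclusive))
    note("hp_outliers_", p, "=", nrow(hp_out[[p]]$windows))
    paths[[paste0("hp_outliers_", p)]] <-
      write_outlier_bed(hp_out[[p]],
                        file.path(cfg$out_dir, paste0("hp_outliers_", p, ".bed")))
  }

  candidates <- list()
  if (!is.null(cfg$gtf)) {
    genes <- stage("read_gtf", read_gtf(cfg$gtf))
    note("genes=", nrow(genes))
    for (p in cfg$hp_pops) {
      cand <- stage("candidates",
                    candidate_genes(genes, fst_out, hp_out[[p]],
                                    flank = cfg$flank))
      candidates[[p]] <- cand
      note("candidates_", p, "=", nrow(cand))
      tab <- data.frame(gene = cand$gene_name, chrom = cand$chrom,
                        start_Mb = cand$start / 1e6, end_Mb = cand$end / 1e6,
                        fst = cand$fst_mean, zfst = cand$zfst,
                        hp = cand$hp, zhp = cand$zhp,
                        split_support = cand$split_support,
                        stringsAsFactors = FALSE)
      paths[[paste0("candidates_", p)]] <-
        write_tsv(tab, file.path(cfg$out_dir, paste0("candidates_", p, ".tsv")))
    }
  }

  log_path <- file.path(cfg$out_dir, "run.log")
  writeLines(log_lines, log_path)
  message(paste(log_lines, collapse = "\n"))
  paths$log <- log_path

  invisible(list(windows = ws, fst_outliers = fst_out, hp_outliers = hp_out,
                 candidates = candidates, filter_report = fr$report,
                 paths = paths))
}
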