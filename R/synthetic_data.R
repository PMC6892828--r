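# Two-population diploid genotype simulator with planted selective
# sweeps, used to validate the scan end to end without external data.

#' Default planted sweep intervals
#'
#' Five 150-kb sweeps spread over the two default chromosomes, all driving
#' the locally major allele of the `BG` population towards fixation
#' (target frequency 0.98). The 150-kb width guarantees that at least one
#' 100-kb scan window lies entirely inside each sweep regardless of how
#' the window grid aligns with the sweep.
#'
#' @return data frame: chrom, start, end (0-based half-open bp),
#'   population, target_freq.
#' @export
default_sweeps <- function() {
  data.frame(
    chrom = c("1", "1", "1", "2", "2"),
    start = c(1000000, 2400000, 3800000, 1200000, 3300000),
    end = c(1150000, 2550000, 3950000, 1350000, 3450000),
    population = "BG",
    target_freq = 0.98,
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Describes a two-population diploid resequencing experiment: ancestral
#' allele frequencies drawn from a Beta distribution, independent drift of
#' each population away from the ancestral frequency (Balding-Nichols
#' model: Beta with mean q and variance `F q(1-q)`), and optional planted
#' sweeps that replace the swept population's frequency by `target_freq`
#' for the locally major allele, producing both reduced heterozygosity in
#' that population and elevated differentiation between populations.
#'
#' @param n_chrom number of chromosomes (named "1", "2", ...).
#' @param chrom_length chromosome length in bp.
#' @param snp_per_chrom SNPs per chromosome (uniform positions without
#'   replacement, sorted).
#' @param n_per_pop named integer vector of diploid sample sizes; the
#'   default (12 and 11) matches the two analysis populations of the
#'   motivating study design.
#' @param background_beta shape parameters (a, b) of the ancestral
#'   allele-frequency distribution.
#' @param divergence drift parameter F in `[0, 1)` applied independently
#'   per population; F = 0 means both populations keep the ancestral
#'   frequency.
#' @param sweeps data frame as [default_sweeps()] (may have zero rows for
#'   a neutral simulation).
#' @param missing_rate per-call probability of a missing genotype.
#' @param depth_mean mean per-sample sequencing depth (Poisson), written
#'   to the `DP` FORMAT field.
#' @param seed mandatory integer seed; identical configuration and seed
#'   give byte-identical output files.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 2, chrom_length = 5e6, snp_per_chrom = 5000,
                       n_per_pop = c(AB = 12, BG = 11),
                       background_beta = c(1, 1), divergence = 0.05,
                       sweeps = default_sweeps(), missing_rate = 0.02,
                       depth_mean = 16, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_chrom >= 1, chrom_length > 0,
            snp_per_chrom >= 1, snp_per_chrom <= chrom_length,
            !is.null(names(n_per_pop)), all(n_per_pop >= 2),
            length(background_beta) == 2, all(background_beta > 0),
            divergence >= 0, divergence < 1,
            missing_rate >= 0, missing_rate < 1, depth_mean > 0)
  chroms <- as.character(seq_len(n_chrom))
  if (nrow(sweeps)) {
    stopifnot(all(c("chrom", "start", "end", "population", "target_freq")
                  %in% names(sweeps)))
    if (!all(sweeps$chrom %in% chroms)) stop("sweep on unknown chromosome")
    if (!all(sweeps$population %in% names(n_per_pop))) {
      stop("sweep population not among simulated populations")
    }
    if (any(sweeps$start < 0 | sweeps$end > chrom_length | sweeps$start >= sweeps$end)) {
      stop("sweep interval outside chromosome bounds")
    }
    if (any(sweeps$target_freq <= 0.5 | sweeps$target_freq > 1)) {
      stop("target_freq must lie in (0.5, 1]")
    }
  }
  structure(list(n_chrom = n_chrom, chroms = chroms,
                 chrom_length = chrom_length, snp_per_chrom = snp_per_chrom,
                 n_per_pop = n_per_pop, background_beta = background_beta,
                 divergence = divergence, sweeps = sweeps,
                 missing_rate = missing_rate, depth_mean = depth_mean,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# one population's drifted frequency given ancestral q
drift_freq <- function(q, f) {
  if (f == 0) return(q)
  stats::rbeta(length(q), q * (1 - f) / f, (1 - q) * (1 - f) / f)
}

#' Simulate a two-population resequencing dataset with planted sweeps
#'
#' Draws per-SNP ancestral frequencies, drifts them independently per
#' population, plants the configured sweeps, samples diploid genotypes,
#' missing calls and per-sample depths, and writes four plain-text files:
#' a VCF 4.2 (GT and DP), a sample map TSV, the sweep truth intervals as
#' BED, and a toy GTF placing one gene inside each sweep plus background
#' genes outside.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return (invisibly) list with paths `vcf`, `sample_map`, `truth_bed`,
#'   `gtf`, the `truth` sweep data frame, and `freqs` (per-SNP generating
#'   frequencies per population, in memory only).
#' @export
simulate_sweep_data <- function(cfg, dir = tempfile("sweepsim")) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)

  pops <- names(cfg$n_per_pop)
  n_tot <- sum(cfg$n_per_pop)
  sample_ids <- unlist(lapply(pops, function(p) {
    sprintf("%s%02d", p, seq_len(cfg$n_per_pop[[p]]))
  }))
  sample_pop <- rep(pops, cfg$n_per_pop)

  bases <- c("A", "C", "G", "T")
  records <- character(0)
  freq_tabs <- list()

  for (ch in cfg$chroms) {
    m <- cfg$snp_per_chrom
    pos <- sort(sample.int(cfg$chrom_length, m))
    q <- stats::rbeta(m, cfg$background_beta[1], cfg$background_beta[2])
    ref <- sample(bases, m, replace = TRUE)
    alt <- bases[(match(ref, bases) + sample.int(3, m, replace = TRUE) - 1) %% 4 + 1]

    pmat <- matrix(NA_real_, m, length(pops), dimnames = list(NULL, pops))
    for (p in pops) {
      pf <- drift_freq(q, cfg$divergence)
      sw <- cfg$sweeps[cfg$sweeps$population == p & cfg$sweeps$chrom == ch, ,
                       drop = FALSE]
      if (nrow(sw)) {
        for (i in seq_len(nrow(sw))) {
          # site pos (1-based) lies in the 0-based half-open sweep interval
          idx <- which(pos > sw$start[i] & pos <= sw$end[i])
          # drive the locally major allele to target_freq
          pf[idx] <- ifelse(pf[idx] >= 0.5, sw$target_freq[i],
                            1 - sw$target_freq[i])
        }
      }
      pmat[, p] <- pf
    }

    geno <- matrix(NA_integer_, m, n_tot)
    col <- 0L
    for (p in pops) {
      np <- cfg$n_per_pop[[p]]
      geno[, col + seq_len(np)] <- matrix(stats::rbinom(m * np, 2, pmat[, p]),
                                          m, np)
      col <- col + np
    }
    miss <- matrix(stats::runif(m * n_tot) < cfg$missing_rate, m, n_tot)
    dp <- matrix(stats::rpois(m * n_tot, cfg$depth_mean), m, n_tot)

    gt_str <- matrix(c("0/0", "0/1", "1/1")[geno + 1L], m, n_tot)
    field <- matrix(paste0(gt_str, ":", dp), m, n_tot)
    field[miss] <- "./.:."
    cols <- lapply(seq_len(n_tot), function(j) field[, j])
    records <- c(records, do.call(paste, c(
      list(ch, pos, ".", ref, alt, ".", "PASS", ".", "GT:DP"), cols,
      list(sep = "\t"))))

    ft <- data.frame(chrom = ch, pos = pos, q = q, stringsAsFactors = FALSE)
    for (p in pops) ft[[paste0("p_", p)]] <- pmat[, p]
    freq_tabs[[ch]] <- ft
  }

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan_simulator",
    sprintf("##contig=<ID=%s,length=%d>", cfg$chroms, as.integer(cfg$chrom_length)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  vcf_path <- file.path(dir, "sim.vcf")
  writeLines(c(header, records), vcf_path)

  map_path <- file.path(dir, "sample_map.tsv")
  writeLines(paste(sample_ids, sample_pop, sep = "\t"), map_path)

  bed_path <- file.path(dir, "sweeps_truth.bed")
  if (nrow(cfg$sweeps)) {
    writeLines(paste(cfg$sweeps$chrom, as.integer(cfg$sweeps$start),
                     as.integer(cfg$sweeps$end),
                     paste0(cfg$sweeps$population, ":", cfg$sweeps$target_freq),
                     sep = "\t"), bed_path)
  } else {
    file.create(bed_path)
  }

  gtf_path <- file.path(dir, "genes.gtf")
  writeLines(make_toy_gtf(cfg), gtf_path)

  invisible(list(vcf = vcf_path, sample_map = map_path, truth_bed = bed_path,
                 gtf = gtf_path, truth = cfg$sweeps,
                 freqs = do.call(rbind, freq_tabs)))
}

# toy annotation: one 30-kb gene centred in each sweep, plus up to three
# 40-kb background genes per chromosome placed away from the sweeps
make_toy_gtf <- function(cfg) {
  gtf_row <- function(chrom, feature, start, end, gid, tid = NULL) {
    attrs <- sprintf('gene_id "%s"; gene_name "%s";', gid, gid)
    if (!is.null(tid)) attrs <- paste0(attrs, sprintf(' transcript_id "%s";', tid))
    paste(chrom, "sweepscan_sim", feature, as.integer(start), as.integer(end),
          ".", "+", ".", attrs, sep = "\t")
  }
  lines <- character(0)
  if (nrow(cfg$sweeps)) {
    for (i in seq_len(nrow(cfg$sweeps))) {
      mid <- floor((cfg$sweeps$start[i] + cfg$sweeps$end[i]) / 2)
      s <- max(1, mid - 15000 + 1)
      e <- min(cfg$chrom_length, mid + 15000)
      gid <- sprintf("GSW%02d", i)
      lines <- c(lines,
                 gtf_row(cfg$sweeps$chrom[i], "gene", s, e, gid),
                 gtf_row(cfg$sweeps$chrom[i], "exon", s, e, gid,
                         paste0(gid, ".t1")))
    }
  }
  for (ch in cfg$chroms) {
    sw <- cfg$sweeps[cfg$sweeps$chrom == ch, , drop = FALSE]
    for (frac in c(0.08, 0.3, 0.7, 0.92)) {
      s <- max(1, floor(frac * cfg$chrom_length))
      e <- min(cfg$chrom_length, s + 40000 - 1)
      # skip background genes that would touch a sweep
      if (nrow(sw) && any(s - 1 < sw$end & e > sw$start)) next
      gid <- sprintf("GBG_%s_%02d", ch, round(frac * 100))
      lines <- c(lines,
                 gtf_row(ch, "gene", s, e, gid),
                 gtf_row(ch, "exon", s, e, gid, paste0(gid, ".t1")))
    }
  }
  lines
}

#' Read sweep truth intervals from a BED file
#'
#' @param path BED file as written by [simulate_sweep_data()] (chrom,
#'   start, end, name; 0-based half-open).
#' @return data frame: chrom, start, end, name (zero rows for an empty
#'   file).
#' @export
read_truth_bed <- function(path) {
  if (!file.exists(path)) stop("truth BED not found: ", path)
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), name = character(0),
                      stringsAsFactors = FALSE))
  }
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "numeric", "numeric",
                                          "character"))
  names(bed) <- c("chrom", "start", "end", "name")
  bed
}

#' Sensitivity and false-discovery fraction against planted sweeps
#'
#' Compares jointly-flagged windows (flagged by both \eqn{ZF_{ST}} and
#' \eqn{ZH_P}; see [joint_outlier_windows()]) with the simulator's planted
#' sweep intervals. Sensitivity is the fraction of truth intervals
#' overlapped by at least one jointly-flagged window; the false-discovery
#' fraction (FDR) is the fraction of jointly-flagged windows overlapping
#' no truth interval.
#'
#' @param joint data frame of jointly-flagged windows (chrom, start, end;
#'   0-based half-open), e.g. from [joint_outlier_windows()].
#' @param truth data frame of sweep intervals (chrom, start, end; 0-based
#'   half-open), e.g. the `truth` element of [simulate_sweep_data()] or
#'   [read_truth_bed()].
#' @return list with `sensitivity`, `fdr` (`NA` when no window is
#'   flagged), `n_joint` and `n_truth`.
#' @export
truth_recovery_report <- function(joint, truth) {
  stopifnot(is.data.frame(joint), is.data.frame(truth))
  n_truth <- nrow(truth)
  if (n_truth == 0) stop("no truth intervals supplied")
  tg <- win_gr(truth)
  if (!nrow(joint)) {
    return(list(sensitivity = 0, fdr = NA_real_, n_joint = 0L,
                n_truth = n_truth))
  }
  jg <- win_gr(joint)
  list(sensitivity = mean(IRanges::overlapsAny(tg, jg)),
       fdr = mean(!IRanges::overlapsAny(jg, tg)),
       n_joint = nrow(joint), n_truth = n_truth)
}
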