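# VCF input, SNP filtering and per-population allele counts.

.GT_DOSE <- c(
  "0/0" = 0L, "0|0" = 0L,
  "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
  "1/1" = 2L, "1|1" = 2L
)

#' Read a sample-to-population map
#'
#' @param path two-column tab-separated file (sample_id, population), no
#'   header.
#' @return data frame with columns `sample_id` and `population`.
#' @details Duplicated sample ids are an error; every population must have
#'   at least two samples, since single-sample "populations" carry no
#'   within-population frequency information.
#' @export
read_sample_map <- function(path) {
  if (!file.exists(path)) stop("sample map file not found: ", path)
  sm <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character",
                          col.names = c("sample_id", "population"))
  validate_sample_map(sm)
}

validate_sample_map <- function(sm) {
  stopifnot(is.data.frame(sm), all(c("sample_id", "population") %in% names(sm)))
  sm$sample_id <- as.character(sm$sample_id)
  sm$population <- as.character(sm$population)
  dup <- sm$sample_id[duplicated(sm$sample_id)]
  if (length(dup)) {
    stop("duplicated sample id(s) in sample map: ", paste(unique(dup), collapse = ", "))
  }
  n <- table(sm$population)
  small <- names(n)[n < 2]
  if (length(small)) {
    stop("population(s) with fewer than 2 samples: ", paste(small, collapse = ", "))
  }
  sm[, c("sample_id", "population")]
}

# contig lengths from ##contig meta lines; empty named vector if none
parse_contig_lengths <- function(meta) {
  cl <- grep("^##contig=", meta, value = TRUE)
  if (!length(cl)) return(stats::setNames(numeric(0), character(0)))
  id <- sub('.*[<,]ID=([^,>]+).*', "\\1", cl)
  len <- suppressWarnings(as.numeric(sub(".*[<,]length=([0-9]+).*", "\\1", cl)))
  keep <- grepl("length=", cl) & !is.na(len)
  stats::setNames(len[keep], id[keep])
}

#' Read a VCF into a variant table
#'
#' Parses a VCF 4.x file (plain or bgzipped) and returns all records,
#' flagging those that are not biallelic SNPs; no record is dropped at
#' read time so that [filter_variants()] can report removals per
#' criterion. Genotypes are stored as ALT-allele dosages (0/1/2, `NA` for
#' missing or non-diploid-biallelic calls) for the samples listed in the
#' sample map only; VCF samples absent from the map are ignored.
#'
#' @param path VCF file.
#' @param sample_map data frame from [read_sample_map()].
#' @return an object of class `variant_table`: a list with `sites` (data
#'   frame: chrom, pos (1-based), ref, alt, is_biallelic_snp, mean_depth),
#'   `geno` (sites x samples integer dosage matrix), `sample_map`,
#'   `chrom_lengths` (from `##contig` header lines, possibly empty) and
#'   `dp_present`.
#' @details `mean_depth` is the mean of the per-sample `DP` FORMAT values
#'   over samples with a non-missing genotype call at the site. If the VCF
#'   carries no `DP` field, `mean_depth` is `NA` and `dp_present` is
#'   `FALSE`; such sites pass the depth filter (see [filter_variants()]).
#' @export
read_vcf <- function(path, sample_map) {
  sample_map <- validate_sample_map(sample_map)
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)

  fix <- vcf@fix
  chrom_lengths <- parse_contig_lengths(vcf@meta)
  vcf_samples <- colnames(vcf@gt)[-1]
  absent <- setdiff(sample_map$sample_id, vcf_samples)
  if (length(absent)) {
    stop("sample(s) in map absent from VCF header: ", paste(absent, collapse = ", "))
  }

  n <- nrow(fix)
  if (is.null(n) || n == 0L) {
    sites <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        is_biallelic_snp = logical(0), mean_depth = numeric(0),
                        stringsAsFactors = FALSE)
    geno <- matrix(NA_integer_, nrow = 0, ncol = nrow(sample_map),
                   dimnames = list(NULL, sample_map$sample_id))
    return(new_variant_table(sites, geno, sample_map, chrom_lengths, FALSE))
  }

  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1]
    stop("malformed VCF record (non-numeric POS) at data line ", bad)
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = n, dimnames = list(NULL, vcf_samples))
  gt <- gt[, sample_map$sample_id, drop = FALSE]
  geno <- matrix(.GT_DOSE[gt], nrow = n,
                 dimnames = list(NULL, sample_map$sample_id))

  dp <- tryCatch(
    vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE),
    error = function(e) NULL
  )
  dp_present <- !is.null(dp) && !all(is.na(dp))
  if (dp_present) {
    if (is.null(dim(dp))) dp <- matrix(dp, nrow = n, dimnames = list(NULL, vcf_samples))
    dp <- dp[, sample_map$sample_id, drop = FALSE]
    dp[is.na(geno)] <- NA  # depth averaged over called individuals only
    mean_depth <- rowMeans(dp, na.rm = TRUE)
    mean_depth[!is.finite(mean_depth)] <- NA_real_
  } else {
    mean_depth <- rep(NA_real_, n)
  }

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_bsnp <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")

  sites <- data.frame(chrom = as.character(fix[, "CHROM"]), pos = pos,
                      ref = ref, alt = alt, is_biallelic_snp = is_bsnp,
                      mean_depth = mean_depth, stringsAsFactors = FALSE)
  o <- order(chrom_rank(sites$chrom), sites$pos)
  new_variant_table(sites[o, , drop = FALSE], geno[o, , drop = FALSE],
                    sample_map, chrom_lengths, dp_present)
}

new_variant_table <- function(sites, geno, sample_map, chrom_lengths, dp_present) {
  rownames(sites) <- NULL
  structure(
    list(sites = sites, geno = geno, sample_map = sample_map,
         chrom_lengths = chrom_lengths, dp_present = dp_present),
    class = "variant_table"
  )
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$sites), "sites,",
      nrow(x$sample_map), "samples in",
      length(unique(x$sample_map$population)), "population(s)\n")
  invisible(x)
}

#' Number of sites in a variant table
#' @param vt a `variant_table`.
#' @return integer site count.
#' @export
n_sites <- function(vt) nrow(vt$sites)

#' SNP filter configuration
#'
#' Holds the site-retention thresholds used by [filter_variants()]:
#' biallelic autosomal SNPs with `depth_min < mean depth < depth_max`
#' (strict on both sides), pooled minor allele frequency strictly above
#' `maf_min`, and missing-call fraction strictly below `max_missing`.
#'
#' @param depth_min,depth_max mean sequencing depth bounds (reads);
#'   defaults 3 and 30.
#' @param maf_min minimum minor allele frequency (exclusive); default 0.05.
#'   Computed on the sample pooled across all mapped individuals.
#' @param max_missing maximum fraction of mapped samples with a missing
#'   genotype (exclusive); default 0.1.
#' @param autosomes character vector of chromosome names regarded as
#'   autosomal; the default covers goat autosomes 1-29 in both bare and
#'   `chr`-prefixed spelling.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(depth_min = 3, depth_max = 30, maf_min = 0.05,
                          max_missing = 0.1,
                          autosomes = c(as.character(1:29), paste0("chr", 1:29))) {
  stopifnot(maf_min >= 0, maf_min < 0.5,
            max_missing >= 0, max_missing <= 1,
            depth_min < depth_max)
  structure(list(depth_min = depth_min, depth_max = depth_max,
                 maf_min = maf_min, max_missing = max_missing,
                 autosomes = as.character(autosomes)),
            class = "filter_config")
}

#' Filter a variant table
#'
#' Applies the SNP retention criteria in a fixed order — (1) biallelic
#' SNP, (2) autosomal, (3) mean depth within bounds, (4) pooled minor
#' allele frequency, (5) missingness — and attributes each removed site to
#' the first criterion it fails, so the report counts sum to the number of
#' sites removed.
#'
#' @param vt a `variant_table` from [read_vcf()].
#' @param cfg a [filter_config()].
#' @return list with `table` (the filtered `variant_table`) and `report`
#'   (data frame: criterion, removed). If the VCF has no `DP` field the
#'   depth criterion is skipped and the report carries a `note` attribute
#'   saying so.
#' @details A site with no called genotype at all has an undefined allele
#'   frequency; it is not attributed to the MAF criterion and falls
#'   through to missingness. Filtering is idempotent.
#' @export
filter_variants <- function(vt, cfg = filter_config()) {
  stopifnot(inherits(vt, "variant_table"), inherits(cfg, "filter_config"))
  s <- vt$sites
  g <- vt$geno
  n <- nrow(s)
  n_map <- nrow(vt$sample_map)

  called <- !is.na(g)
  n_called <- rowSums(called)
  alt <- rowSums(g, na.rm = TRUE)
  p <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  maf <- pmin(p, 1 - p)

  pass_snp <- s$is_biallelic_snp
  pass_auto <- s$chrom %in% cfg$autosomes
  if (vt$dp_present) {
    pass_depth <- is.na(s$mean_depth) |
      (s$mean_depth > cfg$depth_min & s$mean_depth < cfg$depth_max)
  } else {
    pass_depth <- rep(TRUE, n)
  }
  pass_maf <- is.na(maf) | maf > cfg$maf_min
  pass_miss <- (1 - n_called / n_map) < cfg$max_missing

  crit <- list(not_biallelic_snp = pass_snp, non_autosomal = pass_auto,
               mean_depth = pass_depth, maf = pass_maf, missingness = pass_miss)
  fail_at <- rep(0L, n)
  for (i in seq_along(crit)) {
    fail_at[fail_at == 0L & !crit[[i]]] <- i
  }
  keep <- fail_at == 0L

  report <- data.frame(criterion = names(crit),
                       removed = tabulate(fail_at, nbins = length(crit)),
                       stringsAsFactors = FALSE)
  if (!vt$dp_present) {
    attr(report, "note") <- "no DP field in VCF; depth criterion not applied"
  }

  out <- new_variant_table(s[keep, , drop = FALSE], g[keep, , drop = FALSE],
                           vt$sample_map, vt$chrom_lengths, vt$dp_present)
  list(table = out, report = report)
}

#' Per-site allele counts and frequency for one population
#'
#' Counts major and minor alleles among the non-missing diploid calls of
#' one population at every site of a variant table. The major allele is
#' the more frequent allele *within that population*; at a 50/50 tie
#' `nMaj == nMin` (the assignment does not affect \eqn{H_P}).
#'
#' @param vt a `variant_table`.
#' @param population population label present in the sample map.
#' @return data frame with one row per site: chrom, pos, n_called, nMaj,
#'   nMin, p (ALT-allele frequency, `NA` if untyped) and typed (`FALSE`
#'   when the population has zero non-missing calls at the site; such
#'   sites are excluded from downstream windows for that population).
#' @export
allele_counts <- function(vt, population) {
  stopifnot(inherits(vt, "variant_table"))
  ids <- vt$sample_map$sample_id[vt$sample_map$population == population]
  if (!length(ids)) stop("unknown population: ", population)
  g <- vt$geno[, ids, drop = FALSE]
  n_called <- rowSums(!is.na(g))
  alt <- rowSums(g, na.rm = TRUE)
  total <- 2 * n_called
  p <- ifelse(n_called > 0, alt / total, NA_real_)
  data.frame(chrom = vt$sites$chrom, pos = vt$sites$pos,
             n_called = n_called,
             nMaj = pmax(alt, total - alt), nMin = pmin(alt, total - alt),
             p = p, typed = n_called > 0,
             stringsAsFactors = FALSE)
}
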