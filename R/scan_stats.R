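# Sliding-window tiling, per-SNP F_ST, window H_P, Z-transforms and
# outlier calling: the core of the scan.

#' Tile chromosomes into overlapping windows
#'
#' Produces 0-based half-open windows starting at 0 and advancing by
#' `step`; a trailing window is emitted whenever its start lies before the
#' chromosome end, with its end truncated to the chromosome length.
#' Defaults give the 100-kb windows with 50-kb increments used for the
#' scan.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param window_size window width in bp (default 100000).
#' @param step increment in bp (default 50000); must not exceed
#'   `window_size`.
#' @return data frame: chrom, start (0-based inclusive), end (exclusive),
#'   index (rank along the chromosome).
#' @examples
#' make_windows(c(`1` = 250000))
#' @export
make_windows <- function(chrom_lengths, window_size = 100000, step = 50000) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("chrom_lengths must be a named vector")
  }
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (step <= 0 || window_size <= 0) stop("window_size and step must be positive")
  if (step > window_size) stop("step must not exceed window_size")
  chroms <- chrom_order(names(chrom_lengths))
  out <- lapply(chroms, function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, by = step, length.out = ceiling(len / step))
    data.frame(chrom = ch, start = as.integer(starts),
               end = as.integer(pmin(starts + window_size, len)),
               index = seq_along(starts), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-SNP weighted F_ST between two populations
#'
#' Computes, for each site, the variance-based differentiation estimator
#' \deqn{F_{ST} = s^2 / (\bar p (1-\bar p) + s^2/r)} where \eqn{\bar p}
#' is the mean allele frequency across the \eqn{r = 2} populations and
#' \eqn{s^2} is the between-population sampling variance of allele
#' frequency, \eqn{s^2 = \sum_i (p_i - \bar p)^2 / (r - 1) =
#' (p_1-p_2)^2/2}. With the \eqn{r-1} divisor a fixed difference
#' (\eqn{p_1 = 1, p_2 = 0}) yields \eqn{F_{ST} = 1}.
#'
#' @param p1,p2 allele frequencies in `[0, 1]` (vectors of equal length);
#'   `NA` is propagated (untyped site).
#' @param r number of populations (fixed at 2 for a pairwise scan).
#' @param ss_divisor divisor of the sum of squared deviations; default
#'   `r - 1` (sample convention). Set to `r` for the maximum-likelihood
#'   convention.
#' @return data frame with columns `fst`, `s2` and `pbar`. Sites
#'   monomorphic in both populations have a zero denominator and are
#'   returned as `NA` (unevaluable); they are excluded from window means.
#' @examples
#' per_snp_fst(0.8, 0.2)$fst  # 0.18 / (0.25 + 0.09)
#' @export
per_snp_fst <- function(p1, p2, r = 2, ss_divisor = r - 1) {
  if (length(p1) != length(p2)) stop("p1 and p2 must have the same length")
  ok <- !(is.na(p1) | is.na(p2))
  if (any(p1[ok] < 0 | p1[ok] > 1 | p2[ok] < 0 | p2[ok] > 1)) {
    stop("allele frequencies must lie in [0, 1]")
  }
  pbar <- (p1 + p2) / 2
  s2 <- ((p1 - pbar)^2 + (p2 - pbar)^2) / ss_divisor
  denom <- pbar * (1 - pbar) + s2 / r
  fst <- ifelse(denom > 0, s2 / denom, NA_real_)
  data.frame(fst = fst, s2 = s2, pbar = pbar)
}

# site -> window assignment for overlapping windows; returns a data frame
# of (site_idx, window_idx) pairs
assign_to_windows <- function(chrom, pos, windows) {
  sg <- GenomicRanges::GRanges(as.character(chrom),
                               IRanges::IRanges(start = pos, end = pos))
  wg <- win_gr(windows)
  ov <- GenomicRanges::findOverlaps(sg, wg)
  data.frame(site = S4Vectors::queryHits(ov), window = S4Vectors::subjectHits(ov))
}

#' Window-averaged F_ST
#'
#' Assigns sites to (possibly overlapping) windows by position and takes
#' the unweighted arithmetic mean of the evaluable per-SNP \eqn{F_{ST}}
#' values in each window. Windows with fewer evaluable SNPs than
#' `min_snps` are unevaluable (`fst_mean = NA`) and excluded from the
#' Z-transform.
#'
#' @param sites data frame with chrom, pos (1-based) and fst columns (as
#'   from [per_snp_fst()]).
#' @param windows data frame from [make_windows()].
#' @param min_snps minimum evaluable SNPs per window (default 10).
#' @return `windows` with added columns `n_snps` (sites in window),
#'   `fst_n` (evaluable sites) and `fst_mean`.
#' @export
window_fst <- function(sites, windows, min_snps = 10) {
  stopifnot(all(c("chrom", "pos", "fst") %in% names(sites)))
  asg <- assign_to_windows(sites$chrom, sites$pos, windows)
  n_snps <- tabulate(asg$window, nbins = nrow(windows))
  ev <- asg[!is.na(sites$fst[asg$site]), , drop = FALSE]
  fst_n <- tabulate(ev$window, nbins = nrow(windows))
  sums <- rep(0, nrow(windows))
  if (nrow(ev)) {
    agg <- rowsum(sites$fst[ev$site], group = ev$window)
    sums[as.integer(rownames(agg))] <- agg[, 1]
  }
  windows$n_snps <- n_snps
  windows$fst_n <- fst_n
  windows$fst_mean <- ifelse(fst_n >= max(min_snps, 1), sums / fst_n, NA_real_)
  windows
}

#' Window pooled heterozygosity H_P
#'
#' For each window, sums the major- and minor-allele counts of the typed
#' sites of one population and computes
#' \deqn{H_P = 2 \Sigma n_{Maj} \Sigma n_{Min} /
#'   (\Sigma n_{Maj} + \Sigma n_{Min})^2,}
#' which lies in `[0, 0.5]` and reaches 0 at fixation. Windows with fewer
#' typed sites than `min_snps` are unevaluable (`hp = NA`).
#'
#' @param counts data frame from [allele_counts()] (chrom, pos, nMaj,
#'   nMin, typed).
#' @param windows data frame from [make_windows()].
#' @param min_snps minimum typed sites per window (default 10).
#' @return `windows` with added columns `hp_n` (typed sites) and `hp`.
#' @export
window_hp <- function(counts, windows, min_snps = 10) {
  stopifnot(all(c("chrom", "pos", "nMaj", "nMin", "typed") %in% names(counts)))
  counts <- counts[counts$typed, , drop = FALSE]
  asg <- assign_to_windows(counts$chrom, counts$pos, windows)
  hp_n <- tabulate(asg$window, nbins = nrow(windows))
  smaj <- smin <- rep(0, nrow(windows))
  if (nrow(asg)) {
    am <- rowsum(cbind(counts$nMaj[asg$site], counts$nMin[asg$site]),
                 group = asg$window)
    idx <- as.integer(rownames(am))
    smaj[idx] <- am[, 1]
    smin[idx] <- am[, 2]
  }
  tot <- smaj + smin
  hp <- ifelse(hp_n >= max(min_snps, 1) & tot > 0,
               2 * smaj * smin / tot^2, NA_real_)
  windows$hp_n <- hp_n
  windows$hp <- hp
  windows
}

#' Z-transform a genome-wide window statistic
#'
#' Centers and scales to \eqn{z = (x - \mu)/\sigma}, with \eqn{\mu} and
#' \eqn{\sigma} taken over all evaluable (non-`NA`) windows genome-wide.
#' `NA` values are preserved in place.
#'
#' @param x numeric vector of per-window values.
#' @param sigma `"sample"` (default, `n - 1` divisor, as [stats::sd()]) or
#'   `"population"` (`n` divisor).
#' @return numeric vector of z-scores, same length as `x`.
#' @export
z_transform <- function(x, sigma = c("sample", "population")) {
  sigma <- match.arg(sigma)
  ev <- x[!is.na(x)]
  if (length(ev) < 2) stop("need at least 2 evaluable windows to Z-transform")
  s <- stats::sd(ev)
  if (sigma == "population") s <- s * sqrt((length(ev) - 1) / length(ev))
  if (!is.finite(s) || s == 0) stop("degenerate statistic distribution (sigma = 0)")
  (x - mean(ev)) / s
}

#' Compute the full per-window statistic table
#'
#' Convenience wrapper running the whole scan on a filtered variant
#' table: per-population allele counts, per-SNP \eqn{F_{ST}} between the
#' two `fst_pops`, window means, per-population window \eqn{H_P}, and the
#' genome-wide Z-transforms \eqn{ZF_{ST}} and \eqn{ZH_P}.
#'
#' @param vt filtered `variant_table`.
#' @param fst_pops character vector of exactly two population labels.
#' @param hp_pops populations for which to compute \eqn{H_P} (default:
#'   the two `fst_pops`).
#' @param windows optional data frame from [make_windows()]; by default
#'   windows are tiled over the chromosomes present in `vt`, using the
#'   `##contig` header lengths when available and the maximum observed
#'   position otherwise.
#' @param window_size,step,min_snps tiling and evaluability parameters.
#' @param sigma standard-deviation convention for [z_transform()].
#' @return data frame with one row per window: chrom, start, end, index,
#'   n_snps, fst_n, fst_mean, zfst, and per population `<pop>`:
#'   `hp_n_<pop>`, `hp_<pop>`, `zhp_<pop>`. Populations and parameters are
#'   attached as attributes.
#' @export
window_stats <- function(vt, fst_pops, hp_pops = fst_pops, windows = NULL,
                         window_size = 100000, step = 50000, min_snps = 10,
                         sigma = "sample") {
  stopifnot(inherits(vt, "variant_table"))
  if (length(fst_pops) != 2) stop("exactly 2 populations are required for F_ST")
  pops <- unique(vt$sample_map$population)
  unknown <- setdiff(union(fst_pops, hp_pops), pops)
  if (length(unknown)) stop("unknown population(s): ", paste(unknown, collapse = ", "))
  if (n_sites(vt) == 0) stop("variant table has no sites")

  if (is.null(windows)) {
    chroms <- chrom_order(vt$sites$chrom)
    lens <- vapply(chroms, function(ch) {
      if (ch %in% names(vt$chrom_lengths)) vt$chrom_lengths[[ch]]
      else max(vt$sites$pos[vt$sites$chrom == ch])
    }, numeric(1))
    windows <- make_windows(stats::setNames(lens, chroms), window_size, step)
  }

  ac <- lapply(stats::setNames(nm = union(fst_pops, hp_pops)),
               function(p) allele_counts(vt, p))
  a1 <- ac[[fst_pops[1]]]
  a2 <- ac[[fst_pops[2]]]
  p1 <- ifelse(a1$typed, a1$p, NA_real_)
  p2 <- ifelse(a2$typed, a2$p, NA_real_)
  fst <- per_snp_fst(p1, p2)$fst

  ws <- window_fst(data.frame(chrom = vt$sites$chrom, pos = vt$sites$pos,
                              fst = fst, stringsAsFactors = FALSE),
                   windows, min_snps = min_snps)
  ws$zfst <- z_transform(ws$fst_mean, sigma = sigma)

  for (p in hp_pops) {
    wh <- window_hp(ac[[p]], windows, min_snps = min_snps)
    ws[[paste0("hp_n_", p)]] <- wh$hp_n
    ws[[paste0("hp_", p)]] <- wh$hp
    ws[[paste0("zhp_", p)]] <- z_transform(wh$hp, sigma = sigma)
  }
  attr(ws, "fst_pops") <- fst_pops
  attr(ws, "hp_pops") <- hp_pops
  attr(ws, "params") <- list(window_size = window_size, step = step,
                             min_snps = min_snps, sigma = sigma)
  ws
}

new_outlier_set <- function(statistic, rule, parameter, windows, label) {
  structure(list(statistic = statistic, rule = rule, parameter = parameter,
                 windows = windows, label = label),
            class = "outlier_set")
}

#' @export
print.outlier_set <- function(x, ...) {
  cat("outlier_set:", x$statistic, "(", x$label, ") rule =", x$rule,
      "parameter =", x$parameter, "->", nrow(x$windows), "window(s)\n")
  invisible(x)
}

#' Call ZF_ST outlier windows (top fraction)
#'
#' Flags the `k = ceiling(fraction * N)` evaluable windows with the
#' highest \eqn{ZF_{ST}}, `N` being the number of evaluable windows. Ties
#' at the cutoff are broken deterministically by (chrom, start) ascending
#' so exactly `k` windows are flagged.
#'
#' @param ws window statistic table from [window_stats()].
#' @param fraction top fraction to flag (default 0.01, the top 1 percent).
#' @return an `outlier_set` whose `windows` data frame has columns chrom,
#'   start, end, index, n, value (window mean \eqn{F_{ST}}) and z.
#' @export
call_fst_outliers <- function(ws, fraction = 0.01) {
  if (!"zfst" %in% names(ws)) stop("ws must carry a zfst column")
  ev <- which(!is.na(ws$zfst))
  if (!length(ev)) stop("no evaluable windows")
  k <- min(ceiling(fraction * length(ev)), length(ev))
  o <- ev[order(-ws$zfst[ev], chrom_rank(ws$chrom)[ev], ws$start[ev])]
  sel <- sort(o[seq_len(k)])
  w <- data.frame(chrom = ws$chrom[sel], start = ws$start[sel],
                  end = ws$end[sel], index = ws$index[sel],
                  n = ws$fst_n[sel], value = ws$fst_mean[sel],
                  z = ws$zfst[sel], stringsAsFactors = FALSE)
  label <- paste(attr(ws, "fst_pops"), collapse = "-")
  new_outlier_set("ZFST", "top_fraction", fraction, w,
                  if (nzchar(label)) label else "fst")
}

#' Call ZH_P outlier windows (fixed threshold)
#'
#' Flags windows whose Z-transformed pooled heterozygosity for one
#' population falls at or below the threshold (default \eqn{ZH_P \le
#' -4}); extreme deficits of heterozygosity are the sweep signal.
#'
#' @param ws window statistic table from [window_stats()].
#' @param population population whose \eqn{ZH_P} track to threshold.
#' @param threshold Z cutoff (default -4).
#' @param inclusive flag windows equal to the threshold (default `TRUE`,
#'   i.e. `<=`); set `FALSE` for a strict `<`.
#' @return an `outlier_set` (possibly with zero windows) whose `windows`
#'   data frame has columns chrom, start, end, index, n, value
#'   (\eqn{H_P}) and z.
#' @export
call_hp_outliers <- function(ws, population, threshold = -4, inclusive = TRUE) {
  zc <- paste0("zhp_", population)
  if (!zc %in% names(ws)) stop("unknown population (no ZH_P track): ", population)
  z <- ws[[zc]]
  sel <- which(!is.na(z) & (if (inclusive) z <= threshold else z < threshold))
  w <- data.frame(chrom = ws$chrom[sel], start = ws$start[sel],
                  end = ws$end[sel], index = ws$index[sel],
                  n = ws[[paste0("hp_n_", population)]][sel],
                  value = ws[[paste0("hp_", population)]][sel],
                  z = z[sel], stringsAsFactors = FALSE)
  new_outlier_set("ZHP", if (inclusive) "threshold_le" else "threshold_lt",
                  threshold, w, population)
}
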