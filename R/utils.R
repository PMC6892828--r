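# shared internal helpers

# natural chromosome order: numeric names (with or without "chr" prefix)
# first in numeric order, everything else lexicographic after them
chrom_order <- function(x) {
  ux <- unique(as.character(x))
  num <- suppressWarnings(as.numeric(sub("^chr", "", ux)))
  ux[order(is.na(num), num, ux)]
}

# rank of each chromosome under chrom_order(); used for deterministic sorting
chrom_rank <- function(x) match(as.character(x), chrom_order(x))

# GRanges from a data frame of 0-based half-open intervals (chrom/start/end)
win_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end)
  )
}

#' Wald-Wolfowitz runs test for a binary sequence
#'
#' Tests whether the TRUE values of a logical sequence are positioned
#' randomly (no clustering or over-dispersion), using the normal
#' approximation to the distribution of the number of runs. Used to check
#' that outlier windows called on neutral (no-sweep) simulations show no
#' positional clustering beyond chance.
#'
#' @param x logical (or 0/1) vector; `NA`s are dropped.
#' @return list with `runs` (observed run count), `expected`, `statistic`
#'   (approximate standard normal deviate) and `p.value` (two-sided).
#'   Degenerate sequences (all one value, or too short for a variance)
#'   return `p.value = 1`.
#' @examples
#' runs_test(c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
#' @export
runs_test <- function(x) {
  x <- as.logical(x)
  x <- x[!is.na(x)]
  n1 <- sum(x)
  n2 <- sum(!x)
  n <- n1 + n2
  if (n1 == 0L || n2 == 0L || n < 3L) {
    return(list(runs = NA_integer_, expected = NA_real_,
                statistic = NA_real_, p.value = 1))
  }
  r <- 1L + sum(x[-1] != x[-n])
  mu <- 1 + 2 * n1 * n2 / n
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (v <= 0) {
    return(list(runs = r, expected = mu, statistic = NA_real_, p.value = 1))
  }
  z <- (r - mu) / sqrt(v)
  list(runs = r, expected = mu, statistic = z,
       p.value = 2 * stats::pnorm(-abs(z)))
}
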