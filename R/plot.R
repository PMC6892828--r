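# Manhattan-style plots of the Z-transformed window tracks.

#' Plot Z-transformed window tracks along the genome
#'
#' Draws one panel per statistic (\eqn{ZF_{ST}} and one \eqn{ZH_P} per
#' population) with windows placed at their genomic midpoint on a
#' cumulative axis, chromosomes in alternating colours, and dashed lines
#' at the active cutoffs: the top-fraction empirical \eqn{ZF_{ST}}
#' quantile and \eqn{\pm}`zhp_threshold` for \eqn{ZH_P}.
#'
#' @param ws window statistic table from [window_stats()], or the path of
#'   a `windows.tsv` written by [run_scan()].
#' @param out_file image file to write (extension selects the device, as
#'   in [ggplot2::ggsave()]).
#' @param zhp_threshold dashed cutoff for the \eqn{ZH_P} panels
#'   (default -4).
#' @param fst_fraction top fraction defining the dashed \eqn{ZF_{ST}}
#'   cutoff (default 0.01).
#' @return (invisibly) the output path.
#' @export
plot_tracks <- function(ws, out_file, zhp_threshold = -4, fst_fraction = 0.01) {
  if (is.character(ws)) {
    ws <- utils::read.table(ws, sep = "\t", header = TRUE,
                            colClasses = NA, stringsAsFactors = FALSE)
    ws$chrom <- as.character(ws$chrom)
  }
  if (!nrow(ws)) stop("empty window table; nothing to plot")
  zcols <- c("zfst", grep("^zhp_", names(ws), value = TRUE))
  zcols <- zcols[zcols %in% names(ws)]
  if (!length(zcols)) stop("no Z columns found in window table")

  chroms <- chrom_order(ws$chrom)
  lens <- vapply(chroms, function(ch) max(ws$end[ws$chrom == ch]), numeric(1))
  offset <- stats::setNames(c(0, cumsum(lens))[seq_along(chroms)], chroms)
  mid <- (ws$start + ws$end) / 2 + offset[ws$chrom]

  panel_name <- function(zc) {
    if (zc == "zfst") "ZFst" else paste0("ZHp (", sub("^zhp_", "", zc), ")")
  }
  long <- do.call(rbind, lapply(zcols, function(zc) {
    data.frame(x = mid, z = ws[[zc]], chrom = ws$chrom,
               statistic = panel_name(zc), stringsAsFactors = FALSE)
  }))
  long <- long[!is.na(long$z), , drop = FALSE]
  if (!nrow(long)) stop("all windows unevaluable; nothing to plot")
  long$statistic <- factor(long$statistic,
                           levels = vapply(zcols, panel_name, character(1)))
  long$shade <- factor(match(long$chrom, chroms) %% 2)

  cuts <- do.call(rbind, lapply(zcols, function(zc) {
    if (zc == "zfst") {
      data.frame(statistic = panel_name(zc),
                 y = stats::quantile(ws$zfst, probs = 1 - fst_fraction,
                                     na.rm = TRUE, names = FALSE))
    } else {
      data.frame(statistic = panel_name(zc),
                 y = c(zhp_threshold, -zhp_threshold))
    }
  }))
  cuts$statistic <- factor(cuts$statistic, levels = levels(long$statistic))

  gp <- ggplot2::ggplot(long, ggplot2::aes(x = x, y = z, colour = shade)) +
    ggplot2::geom_point(size = 0.5, show.legend = FALSE) +
    ggplot2::geom_hline(data = cuts, ggplot2::aes(yintercept = y),
                        linetype = "dashed", colour = "grey30") +
    ggplot2::scale_colour_manual(values = c("0" = "#1b6ca8", "1" = "#e08214")) +
    ggplot2::facet_wrap(~statistic, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "genomic position (cumulative bp)", y = "Z") +
    ggplot2::theme_bw()

  ggplot2::ggsave(out_file, gp, width = 9,
                  height = 2.2 * length(zcols), dpi = 120)
  invisible(out_file)
}
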