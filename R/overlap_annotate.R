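# Gene annotation: GTF reading, outlier-window intersection, candidate
# gene calling by joint evidence of the two statistics.

#' Read gene models from a GTF annotation
#'
#' Imports a GTF/GFF2 file and collapses all features sharing a `gene_id`
#' to one gene model spanning the minimum start to the maximum end, so
#' annotations carrying only transcript or exon features still yield one
#' record per gene.
#'
#' @param path GTF file.
#' @return data frame with one row per gene: gene_id, gene_name (falls
#'   back to gene_id), chrom, start, end (1-based inclusive, as in GTF)
#'   and strand, sorted by (chrom, start).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("failed to parse GTF ", path, ": ",
                                          conditionMessage(e)))
  md <- S4Vectors::mcols(gr)
  if (!"gene_id" %in% names(md)) {
    stop("GTF has no gene_id attribute: ", path)
  }
  df <- data.frame(
    gene_id = as.character(md$gene_id),
    gene_name = if ("gene_name" %in% names(md)) as.character(md$gene_name) else NA_character_,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$gene_id)) stop("GTF record(s) without gene_id: ", path)
  sp <- split(df, df$gene_id)
  genes <- do.call(rbind, lapply(sp, function(d) {
    nm <- d$gene_name[!is.na(d$gene_name)]
    data.frame(gene_id = d$gene_id[1],
               gene_name = if (length(nm)) nm[1] else d$gene_id[1],
               chrom = d$chrom[1], start = min(d$start), end = max(d$end),
               strand = d$strand[1], stringsAsFactors = FALSE)
  }))
  genes <- genes[order(chrom_rank(genes$chrom), genes$start, genes$gene_id), ,
                 drop = FALSE]
  rownames(genes) <- NULL
  genes
}

#' Overlapping pairs between two outlier window sets
#'
#' Returns every pair of windows, one from each set, sharing at least one
#' base pair. Windows are 0-based half-open, so abutting windows (e.g.
#' `[0, 100kb)` and `[100kb, 200kb)`) do not overlap. Symmetric in its
#' arguments up to column naming.
#'
#' @param a,b `outlier_set` objects on the same genome coordinates.
#' @return data frame with the coordinates and z-scores of each
#'   overlapping pair (columns suffixed `_a` and `_b`); zero rows when
#'   either set is empty or nothing overlaps.
#' @export
intersect_outlier_sets <- function(a, b) {
  stopifnot(inherits(a, "outlier_set"), inherits(b, "outlier_set"))
  empty <- data.frame(chrom = character(0), start_a = numeric(0), end_a = numeric(0),
                      z_a = numeric(0), start_b = numeric(0), end_b = numeric(0),
                      z_b = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(a$windows) || !nrow(b$windows)) return(empty)
  ov <- GenomicRanges::findOverlaps(win_gr(a$windows), win_gr(b$windows))
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  if (!length(qi)) return(empty)
  data.frame(chrom = a$windows$chrom[qi],
             start_a = a$windows$start[qi], end_a = a$windows$end[qi],
             z_a = a$windows$z[qi],
             start_b = b$windows$start[si], end_b = b$windows$end[si],
             z_b = b$windows$z[si], stringsAsFactors = FALSE)
}

#' Windows flagged by both statistics
#'
#' The identical windows (same chrom, start, end) present in both a
#' \eqn{ZF_{ST}} and a \eqn{ZH_P} outlier set — the joint-evidence window
#' set used for truth recovery on simulated data.
#'
#' @param fst_out,hp_out `outlier_set` objects from [call_fst_outliers()]
#'   and [call_hp_outliers()].
#' @return data frame: chrom, start, end, zfst, zhp (zero rows if the
#'   intersection is empty).
#' @export
joint_outlier_windows <- function(fst_out, hp_out) {
  stopifnot(inherits(fst_out, "outlier_set"), inherits(hp_out, "outlier_set"))
  m <- merge(fst_out$windows[, c("chrom", "start", "end", "z")],
             hp_out$windows[, c("chrom", "start", "end", "z")],
             by = c("chrom", "start", "end"), suffixes = c("fst", "hp"))
  m <- m[order(chrom_rank(m$chrom), m$start), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Candidate genes under joint selection evidence
#'
#' A gene is a candidate when it overlaps (by at least one base pair) at
#' least one window flagged by \eqn{ZF_{ST}} *and* at least one window
#' flagged by \eqn{ZH_P}. The two supporting windows need not be the same
#' window; when no single jointly-flagged window overlaps the gene the
#' candidate is marked `split_support`. The reported per-gene statistics
#' come from the supporting window with the most extreme Z of each
#' statistic.
#'
#' @param genes data frame from [read_gtf()] (1-based inclusive
#'   coordinates; converted internally to 0-based half-open).
#' @param fst_out `outlier_set` from [call_fst_outliers()].
#' @param hp_out `outlier_set` from [call_hp_outliers()].
#' @param flank bp added on both sides of the gene body before testing
#'   overlap (default 0).
#' @return data frame sorted by (chrom, start): gene_id, gene_name, chrom,
#'   start, end, strand, fst_mean, zfst, hp, zhp, split_support,
#'   n_fst_windows, n_hp_windows, population.
#' @export
candidate_genes <- function(genes, fst_out, hp_out, flank = 0) {
  stopifnot(inherits(fst_out, "outlier_set"), inherits(hp_out, "outlier_set"))
  if (fst_out$statistic != "ZFST" || hp_out$statistic != "ZHP") {
    stop("expected a ZFST outlier set and a ZHP outlier set, in that order")
  }
  empty <- data.frame(gene_id = character(0), gene_name = character(0),
                      chrom = character(0), start = numeric(0), end = numeric(0),
                      strand = character(0), fst_mean = numeric(0),
                      zfst = numeric(0), hp = numeric(0), zhp = numeric(0),
                      split_support = logical(0), n_fst_windows = integer(0),
                      n_hp_windows = integer(0), population = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(genes) || !nrow(fst_out$windows) || !nrow(hp_out$windows)) return(empty)

  # gene body, 1-based inclusive, with optional flank
  ggr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1, genes$start - flank), genes$end + flank)
  )
  of <- GenomicRanges::findOverlaps(ggr, win_gr(fst_out$windows))
  oh <- GenomicRanges::findOverlaps(ggr, win_gr(hp_out$windows))
  fhit <- split(S4Vectors::subjectHits(of), S4Vectors::queryHits(of))
  hhit <- split(S4Vectors::subjectHits(oh), S4Vectors::queryHits(oh))
  cand <- intersect(as.integer(names(fhit)), as.integer(names(hhit)))
  if (!length(cand)) return(empty)

  key <- function(w, i) paste(w$chrom[i], w$start[i], w$end[i])
  joint_keys <- intersect(key(fst_out$windows, seq_len(nrow(fst_out$windows))),
                          key(hp_out$windows, seq_len(nrow(hp_out$windows))))

  rows <- lapply(cand, function(gi) {
    fw <- fhit[[as.character(gi)]]
    hw <- hhit[[as.character(gi)]]
    fbest <- fw[order(-abs(fst_out$windows$z[fw]), fst_out$windows$start[fw])][1]
    hbest <- hw[order(-abs(hp_out$windows$z[hw]), hp_out$windows$start[hw])][1]
    split <- !any(intersect(key(fst_out$windows, fw), key(hp_out$windows, hw))
                  %in% joint_keys)
    data.frame(gene_id = genes$gene_id[gi], gene_name = genes$gene_name[gi],
               chrom = genes$chrom[gi], start = genes$start[gi],
               end = genes$end[gi], strand = genes$strand[gi],
               fst_mean = fst_out$windows$value[fbest],
               zfst = fst_out$windows$z[fbest],
               hp = hp_out$windows$value[hbest],
               zhp = hp_out$windows$z[hbest],
               split_support = split,
               n_fst_windows = length(fw), n_hp_windows = length(hw),
               population = hp_out$label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(chrom_rank(out$chrom), out$start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
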