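#' Read gene intervals from BED or GFF3
#'
#' BED input (0-based half-open) is used as-is; GFF3 input (1-based
#' inclusive) is restricted to `type == "gene"` features and converted to the
#' internal 0-based half-open convention. Gene identifiers come from the BED
#' name column, or from the first available of `ID`, `Name`, `gene_id` in
#' GFF3 attributes.
#'
#' @param path annotation file path.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return Data frame with `gene_id`, `chrom`, `start` (0-based), `end`
#'   (exclusive), `strand`.
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gtf)(\\.gz)?$", path, ignore.case = TRUE)) {
      "gff3"
    } else "bed"
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else
    "GFF3")
  if (format == "gff3") {
    if ("type" %in% names(S4Vectors::mcols(gr))) {
      gr <- gr[as.character(gr$type) == "gene"]
    }
    ids <- NULL
    for (col in c("ID", "Name", "gene_id")) {
      if (col %in% names(S4Vectors::mcols(gr))) {
        ids <- as.character(S4Vectors::mcols(gr)[[col]])
        if (!all(is.na(ids))) break
      }
    }
    if (is.null(ids)) ids <- paste0("gene", seq_along(gr))
  } else {
    ids <- if ("name" %in% names(S4Vectors::mcols(gr))) {
      as.character(gr$name)
    } else paste0("gene", seq_along(gr))
  }
  data.frame(gene_id = ids,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Genes overlapping significant windows
#'
#' Maps sweep-candidate windows (empirical p below `alpha`) to genes.
#' "Located within" is implemented as any overlap of at least 1 bp under
#' half-open semantics, not full containment: genes are frequently longer
#' than a scan window and could never be fully contained. Each gene is
#' reported once, with the number of overlapping significant windows and the
#' best (smallest) empirical p among them.
#'
#' @param windows a `window_stats` table from [scan_windows()].
#' @param genes gene table from [read_gene_annotation()] (columns `gene_id`,
#'   `chrom`, `start`, `end`; 0-based half-open).
#' @param alpha significance threshold on the empirical p-value
#'   (default 0.01, strict `<`).
#' @return Data frame sorted by `gene_id` with columns `gene_id`, `chrom`,
#'   `n_overlapping_significant_windows`, `best_empirical_p`; zero rows when
#'   nothing is significant.
#' @export
candidate_genes <- function(windows, genes, alpha = 0.01) {
  stopifnot(all(c("chrom", "start", "end", "empirical_p") %in%
                  names(windows)),
            all(c("gene_id", "chrom", "start", "end") %in% names(genes)),
            alpha > 0, alpha < 1)
  sig <- windows[!is.na(windows$empirical_p) &
                   windows$empirical_p < alpha, , drop = FALSE]
  empty <- data.frame(gene_id = character(0), chrom = character(0),
                      n_overlapping_significant_windows = integer(0),
                      best_empirical_p = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(sig) || !nrow(genes)) return(empty)
  wch <- unique(sig$chrom)
  gch <- unique(genes$chrom)
  if (!length(intersect(wch, gch))) {
    stop("chromosome name mismatch between windows and annotation: ",
         "windows use {", paste(wch, collapse = ", "), "}, annotation uses {",
         paste(gch, collapse = ", "), "}")
  }
  gr_w <- GenomicRanges::GRanges(sig$chrom,
                                 IRanges::IRanges(sig$start + 1L, sig$end))
  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1L,
                                                  genes$end))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(gr_g, gr_w))
  if (!length(ov)) return(empty)
  gi <- S4Vectors::queryHits(ov)
  wi <- S4Vectors::subjectHits(ov)
  agg_n <- tapply(wi, gi, length)
  agg_p <- tapply(sig$empirical_p[wi], gi, min)
  idx <- as.integer(names(agg_n))
  out <- data.frame(gene_id = genes$gene_id[idx],
                    chrom = genes$chrom[idx],
                    n_overlapping_significant_windows = as.integer(agg_n),
                    best_empirical_p = as.numeric(agg_p),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Divergent-site count in a flanking region
#'
#' For a candidate gene's flank, counts callable sites (positions passing the
#' filter stack for the given sample) and divergent sites among them.
#' Divergent sites are integer homozygous-alternate differences; heterozygous
#' sites are *not* counted, matching the convention of reporting an integer
#' count of divergent sites rather than the 0.5-weighted divergence sum.
#'
#' @param ss a [site_set()].
#' @param sample the genome contrasted against the reference.
#' @param chrom,start,end the flanking interval (0-based half-open).
#' @param config a [filter_config()].
#' @return List with `divergent_sites` and `callable_sites`; `(0, 0)` with a
#'   warning when the region has no callable site.
#' @export
flanking_divergence <- function(ss, sample, chrom, start, end,
                                config = filter_config()) {
  stopifnot(inherits(ss, "site_set"), sample %in% ss$samples,
            start < end, start >= 0)
  status <- site_passes_filters(ss, config, samples = sample)
  in_region <- ss$sites$chrom == chrom & ss$sites$pos > start &
    ss$sites$pos <= end
  pass <- which(in_region & status$pass)
  callable <- length(pass)
  if (!is.null(ss$callable)) {
    cal <- ss$callable[ss$callable$chrom == chrom, , drop = FALSE]
    if (nrow(cal)) {
      ir_c <- IRanges::reduce(IRanges::IRanges(cal$start + 1L, cal$end))
      ir_r <- IRanges::IRanges(start + 1L, end)
      ov <- IRanges::findOverlaps(ir_r, ir_c)
      span <- sum(IRanges::width(IRanges::pintersect(
        ir_r[S4Vectors::queryHits(ov)], ir_c[S4Vectors::subjectHits(ov)])))
      n_expl_cal <- sum(in_region & sites_in_callable(ss))
      callable <- callable + max(span - n_expl_cal, 0)
    }
  }
  if (callable == 0) {
    warning("no callable sites in ", chrom, ":", start, "-", end)
    return(list(divergent_sites = 0L, callable_sites = 0L))
  }
  divergent <- sum(ss$gt[pass, sample] == 2L)
  list(divergent_sites = as.integer(divergent),
       callable_sites = as.integer(callable))
}
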