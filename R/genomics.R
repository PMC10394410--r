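#' Gene annotation record
#'
#' Coordinates are 0-based, half-open. For plus-strand genes the TSS is
#' the lower coordinate; for minus-strand genes it is the higher one, so
#' the transcription direction always runs from `tss` towards `tes`.
#'
#' @param chrom chromosome name.
#' @param tss,tes transcription start and end site coordinates.
#' @param strand `"+"` or `"-"`.
#' @param symbol gene label.
#' @return An object of class `gene_annotation`.
#' @export
gene_annotation <- function(chrom, tss, tes, strand = "+", symbol = "gene") {
  strand <- match.arg(strand, c("+", "-"))
  if (tss == tes) stop("tss and tes must differ", call. = FALSE)
  if (strand == "+" && tss >= tes) {
    stop("plus-strand gene must have tss < tes", call. = FALSE)
  }
  if (strand == "-" && tss <= tes) {
    stop("minus-strand gene must have tss > tes", call. = FALSE)
  }
  structure(list(chrom = chrom, tss = tss, tes = tes, strand = strand,
                 symbol = symbol),
            class = "gene_annotation")
}

#' Read gene annotations from a BED6 file
#'
#' @param path BED file (0-based half-open, strand in column 6).
#' @return A list of [gene_annotation()] objects, named by the BED name
#'   column.
#' @export
read_annotations <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- lapply(seq_along(gr), function(i) {
    st <- as.character(S4Vectors::decode(GenomicRanges::strand(gr)))[i]
    if (!st %in% c("+", "-")) st <- "+"
    s0 <- GenomicRanges::start(gr)[i] - 1L   # GRanges is 1-based closed
    e0 <- GenomicRanges::end(gr)[i]
    if (st == "+") {
      gene_annotation(as.character(GenomicRanges::seqnames(gr))[i],
                      tss = s0, tes = e0, strand = "+",
                      symbol = gr$name[i])
    } else {
      gene_annotation(as.character(GenomicRanges::seqnames(gr))[i],
                      tss = e0, tes = s0, strand = "-",
                      symbol = gr$name[i])
    }
  })
  names(out) <- vapply(out, function(g) g$symbol, character(1))
  out
}

# genomic interval [start, end) covered by the flanked gene
flanked_interval <- function(gene, flank_upstream) {
  if (gene$strand == "+") {
    c(gene$tss - flank_upstream, gene$tes)
  } else {
    c(gene$tes, gene$tss + flank_upstream)
  }
}

#' Read and bin a coverage profile over a flanked gene
#'
#' Sums per-base signal into uniform bins along the transcription
#' direction of the gene, including an upstream flank (to capture poised
#' polymerase ahead of the TSS). Minus-strand genes are reversed so that
#' index 1 is the most upstream bin. A bin's value is the coverage-
#' weighted mean per-base signal over the bin (a bin fully covered by a
#' bedGraph record of score `s` receives `s`); overlapping bedGraph
#' records are resolved by summation.
#'
#' @param path a bedGraph file (4 columns, 0-based half-open) or a
#'   tab-separated profile table written by [write_profile()].
#' @param gene a [gene_annotation()].
#' @param format `"bedgraph"` or `"tsv"` (`"auto"` guesses from the
#'   extension).
#' @param bin_width bin size in nucleotides.
#' @param flank_upstream nucleotides of upstream flank ahead of the TSS.
#' @param time_label run-on time label attached to the profile.
#' @return A tibble of class `binned_profile` with columns `bin`,
#'   `start`, `end` (genomic), `pos` (bin-centre offset from the TSS
#'   along the transcription direction; negative = upstream flank) and
#'   `value`; gene, bin width and time label are attributes.
#' @export
read_profile <- function(path, gene, format = c("auto", "bedgraph", "tsv"),
                         bin_width = 20, flank_upstream = 500,
                         time_label = "untreated") {
  stopifnot(inherits(gene, "gene_annotation"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE)) {
      "bedgraph"
    } else "tsv"
  }
  iv <- flanked_interval(gene, flank_upstream)
  width <- iv[2] - iv[1]
  n_bins <- ceiling(width / bin_width)
  starts <- iv[1] + (seq_len(n_bins) - 1) * bin_width
  ends <- pmin(starts + bin_width, iv[2])

  if (format == "bedgraph") {
    gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                   error = function(e) {
                     stop("malformed bedGraph file: ", conditionMessage(e),
                          call. = FALSE)
                   })
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) == gene$chrom]
    bins <- GenomicRanges::GRanges(
      gene$chrom, IRanges::IRanges(start = starts + 1L, end = ends))
    value <- numeric(n_bins)
    if (length(gr) > 0) {
      hits <- GenomicRanges::findOverlaps(bins, gr)
      if (length(hits) > 0) {
        ov <- GenomicRanges::pintersect(bins[S4Vectors::queryHits(hits)],
                                        gr[S4Vectors::subjectHits(hits)])
        contrib <- GenomicRanges::width(ov) *
          gr$score[S4Vectors::subjectHits(hits)]
        agg <- tapply(contrib, S4Vectors::queryHits(hits), sum)
        value[as.integer(names(agg))] <- as.numeric(agg) / bin_width
      }
    }
    if (all(value == 0)) {
      warning("no coverage overlaps gene ", gene$symbol,
              "; returning all-zero profile", call. = FALSE)
    }
  } else {
    tb <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("gene", "bin_start", "bin_end", "time_label", "value")
    if (!all(need %in% names(tb))) {
      stop("profile table must have columns ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    tb <- tb[tb$gene == gene$symbol & tb$time_label == time_label, ]
    value <- numeric(n_bins)
    idx <- match(tb$bin_start, starts)
    bad <- is.na(idx)
    if (any(bad)) {
      warning(sum(bad), " table bins do not align with the requested grid",
              call. = FALSE)
    }
    value[idx[!bad]] <- tb$value[!bad]
    if (nrow(tb) == 0) {
      warning("no rows for gene ", gene$symbol, " at time ", time_label,
              call. = FALSE)
    }
  }

  mid <- (starts + ends) / 2
  pos <- if (gene$strand == "+") mid - gene$tss else gene$tss - mid
  ord <- order(pos)
  out <- tibble::tibble(bin = seq_len(n_bins),
                        start = starts[ord], end = ends[ord],
                        pos = pos[ord], value = value[ord])
  attr(out, "gene") <- gene
  attr(out, "bin_width") <- bin_width
  attr(out, "time_label") <- time_label
  class(out) <- c("binned_profile", class(out))
  out
}

#' Write a binned profile to the tab-separated table format
#'
#' Columns `gene`, `bin_start`, `bin_end`, `time_label`, `value`; the
#' writer is bit-stable given fixed inputs and round-trips exactly with
#' [read_profile()].
#'
#' @param profile a `binned_profile`.
#' @param path output path.
#' @param append append to an existing table.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, append = FALSE) {
  gene <- attr(profile, "gene")
  tb <- data.frame(gene = gene$symbol,
                   bin_start = profile$start,
                   bin_end = profile$end,
                   time_label = attr(profile, "time_label"),
                   value = profile$value)
  utils::write.table(tb, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !append,
                     append = append)
  invisible(path)
}

#' Linear interpolation of a binned profile
#'
#' Piecewise-linear interpolation between bin centres, constant
#' (clamped) beyond the observed range.
#'
#' @param x increasing positions (e.g. bin centres).
#' @param values profile values at `x`.
#' @param x_targets positions to evaluate at.
#' @return Values at `x_targets`.
#' @export
interpolate_profile <- function(x, values, x_targets) {
  if (length(x) < 2) stop("need at least 2 positions", call. = FALSE)
  if (is.unsorted(x, strictly = TRUE)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  stats::approx(x, values, xout = x_targets, rule = 2)$y
}

#' Metagene average of inferred rate profiles
#'
#' Aggregates per-gene rate profiles of different lengths into one
#' summary curve: the segments around the TSS (upstream flank up to
#' `TSS + end_window`) and around the TES (`TES - end_window` to the end)
#' are averaged on their native length scale, while each gene's interior
#' is stretched to a common support by resampling it at
#' `n_interior_points` evenly spaced positions before averaging. The
#' native length scale is therefore conserved only near the TSS and TES.
#'
#' @param rate_profiles list of data frames, one per gene, each with
#'   columns `pos` (nt offset from the TSS along the transcription
#'   direction; negative = upstream flank) and `rate`.
#' @param gene_lengths TSS-to-TES length of each gene in nt; defaults to
#'   the largest `pos` of each profile.
#' @param n_interior_points number of resampling points for the interior.
#' @param end_window native-scale window (nt) preserved at each end.
#' @return A tibble with columns `segment` (`"tss"`, `"body"`, `"tes"`),
#'   `pos` (native nt offset from the TSS or TES for the end segments;
#'   relative position in `[0, 1]` for the body), `rate` (across-gene
#'   mean), `rate_q25`, `rate_q75` (across-gene interquartile range) and
#'   `n_genes`.
#' @export
metagene_average <- function(rate_profiles, gene_lengths = NULL,
                             n_interior_points = 100, end_window = 1000) {
  if (length(rate_profiles) < 1) stop("need at least one gene", call. = FALSE)
  if (is.null(gene_lengths)) {
    gene_lengths <- vapply(rate_profiles, function(p) max(p$pos), numeric(1))
  }
  keep <- gene_lengths > 2 * end_window
  if (any(!keep)) {
    warning(sum(!keep), " gene(s) shorter than twice the end window excluded",
            call. = FALSE)
  }
  rate_profiles <- rate_profiles[keep]
  gene_lengths <- gene_lengths[keep]
  if (length(rate_profiles) == 0) {
    stop("no gene is longer than twice the end window", call. = FALSE)
  }
  interp <- function(p, at) interpolate_profile(p$pos, p$rate, at)

  # common native grids covered by every gene
  step <- min(vapply(rate_profiles,
                     function(p) stats::median(diff(sort(p$pos))),
                     numeric(1)))
  lo_tss <- max(vapply(rate_profiles, function(p) min(p$pos), numeric(1)))
  tss_grid <- seq(lo_tss, end_window, by = step)
  hi_tes <- min(mapply(function(p, len) max(p$pos) - len,
                       rate_profiles, gene_lengths))
  tes_grid <- seq(-end_window, hi_tes, by = step)
  u <- seq(0, 1, length.out = n_interior_points)

  stack <- function(segment_at) {
    do.call(rbind, mapply(function(p, len) segment_at(p, len),
                          rate_profiles, gene_lengths, SIMPLIFY = FALSE))
  }
  m_tss <- stack(function(p, len) interp(p, tss_grid))
  m_body <- stack(function(p, len) {
    interp(p, end_window + u * (len - 2 * end_window))
  })
  m_tes <- stack(function(p, len) interp(p, len + tes_grid))

  seg_tbl <- function(m, seg, pos) {
    tibble::tibble(
      segment = seg, pos = pos,
      rate = colMeans(m),
      rate_q25 = apply(m, 2, stats::quantile, probs = 0.25),
      rate_q75 = apply(m, 2, stats::quantile, probs = 0.75),
      n_genes = nrow(m)
    )
  }
  dplyr::bind_rows(
    seg_tbl(m_tss, "tss", tss_grid),
    seg_tbl(m_body, "body", u),
    seg_tbl(m_tes, "tes", tes_grid)
  )
}

#' Write a density field to a tab-separated table
#'
#' @param field a `density_field` tibble (columns `time`, `x`, `rho`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_density_field <- function(field, path) {
  utils::write.table(as.data.frame(field[, c("x", "time", "rho")]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a density field written by [write_density_field()]
#'
#' @param path input path.
#' @return A `density_field` tibble.
#' @export
read_density_field <- function(path) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t")
  x <- sort(unique(tb$x))
  times <- sort(unique(tb$time))
  a <- if (length(x) > 1) x[2] - x[1] else 1
  grid <- spatial_grid(length(x), a)
  m <- matrix(NA_real_, length(times), length(x))
  for (j in seq_along(times)) {
    sl <- tb[tb$time == times[j], ]
    m[j, ] <- sl$rho[order(sl$x)]
  }
  density_field(grid, times, m)
}
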