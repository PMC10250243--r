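#' Spike-in scaling values from fly-aligned read counts
#'
#' For each sample the raw scaling is `constant / fly_reads` (the arbitrary
#' constant is 100000 for a 10% spike-in, 200000 for 20%); scalings are then
#' normalized so that the asynchronous reference sample is exactly 1. The
#' normalized scalings are invariant to the choice of constant.
#'
#' @param counts A data.frame with columns `sample`, `condition`
#'   (`"asynchronous"` or `"mitotic"`), `fly_reads` — e.g. from
#'   [simulate_spikein_counts()] or [read_spikein_counts()].
#' @param constant The arbitrary scaling constant (default: the table's
#'   `constant` attribute, else 100000).
#' @param reference Name of the asynchronous reference sample (default: the
#'   table's `reference` attribute).
#' @return A data.frame of class `spikein_table` with added columns
#'   `raw_scaling` and `scaling`, plus `constant` and `reference` attributes.
#' @examples
#' counts <- data.frame(sample = c("async", "mitotic"),
#'                      condition = c("asynchronous", "mitotic"),
#'                      fly_reads = c(50000, 25000))
#' compute_scaling(counts, constant = 1e5, reference = "async")
#' @export
compute_scaling <- function(counts,
                            constant = attr(counts, "constant"),
                            reference = attr(counts, "reference")) {
  stopifnot(is.data.frame(counts),
            all(c("sample", "condition", "fly_reads") %in% names(counts)))
  if (is.null(constant)) constant <- 1e5
  if (is.null(reference) || !reference %in% counts$sample)
    stop("missing reference: no asynchronous reference sample named",
         call. = FALSE)
  bad <- counts$sample[counts$fly_reads <= 0]
  if (length(bad))
    stop(sprintf("zero fly reads for sample(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  out <- counts
  out$raw_scaling <- constant / out$fly_reads
  out$scaling <- out$raw_scaling / out$raw_scaling[out$sample == reference][1]
  attr(out, "constant") <- constant
  attr(out, "reference") <- reference
  class(out) <- c("spikein_table", "data.frame")
  out
}

#' @export
print.spikein_table <- function(x, ...) {
  cat(sprintf("spike-in scaling table (constant %g, reference '%s')\n",
              attr(x, "constant"), attr(x, "reference")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Apply spike-in scalings to a per-site read-count matrix
#'
#' Each sample column is multiplied by its scaling value; counts stay real
#' numbers (no re-rounding). The reference sample's normalized counts equal
#' its raw counts, and within-sample rank order of sites is preserved.
#'
#' @param mat Numeric matrix of read counts, sites x samples, with sample
#'   names as column names; or a data.frame whose non-coordinate columns are
#'   samples (coordinate columns `chrom`, `start`, `end` are carried
#'   through).
#' @param table A `spikein_table` from [compute_scaling()].
#' @return Same shape as `mat` with scaled counts.
#' @export
normalize_counts <- function(mat, table) {
  stopifnot(inherits(table, "spikein_table"))
  coords <- NULL
  if (is.data.frame(mat)) {
    coord_cols <- intersect(c("chrom", "start", "end"), names(mat))
    coords <- mat[coord_cols]
    mat <- as.matrix(mat[setdiff(names(mat), coord_cols)])
  }
  missing <- setdiff(colnames(mat), table$sample)
  if (length(missing))
    stop(sprintf("sample mismatch: no scaling for %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  sc <- table$scaling[match(colnames(mat), table$sample)]
  out <- sweep(mat, 2, sc, `*`)
  if (!is.null(coords)) out <- cbind(coords, as.data.frame(out))
  out
}

#' Paired asynchronous-vs-mitotic values for scatter plotting
#'
#' @param normalized Normalized count matrix/data.frame from
#'   [normalize_counts()].
#' @param asynchronous,mitotic Sample (column) names to pair.
#' @return A data.frame with per-site `asynchronous` and `mitotic` normalized
#'   counts (plus coordinates if present), ready for a log-log scatter plot.
#' @export
scatter_pairs <- function(normalized, asynchronous, mitotic) {
  df <- as.data.frame(normalized)
  stopifnot(all(c(asynchronous, mitotic) %in% names(df)))
  out <- df[intersect(c("chrom", "start", "end"), names(df))]
  out$asynchronous <- df[[asynchronous]]
  out$mitotic <- df[[mitotic]]
  out
}

#' Read / write binding sites as BED
#'
#' BED is 0-based half-open; the returned data.frame keeps that convention
#' (`start` 0-based, `end` exclusive).
#'
#' @param path BED file path.
#' @return `read_sites_bed`: data.frame with `chrom`, `start`, `end`.
#' @export
read_sites_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' @rdname read_sites_bed
#' @param sites Data.frame with `chrom`, `start` (0-based), `end`.
#' @export
write_sites_bed <- function(sites, path) {
  gr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$start + 1L, sites$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a spike-in read-count CSV
#'
#' Expected columns: `sample`, `condition`, `fly_reads`.
#'
#' @param path CSV path.
#' @param constant,reference Optional scaling constant and reference-sample
#'   name to attach as attributes.
#' @export
read_spikein_counts <- function(path, constant = NULL, reference = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "condition", "fly_reads") %in% names(df)))
  if (!is.null(constant)) attr(df, "constant") <- constant
  if (!is.null(reference)) attr(df, "reference") <- reference
  df
}
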