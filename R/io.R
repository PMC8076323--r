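#' Read a delimited expression table
#'
#' Reads a features-by-samples table of expression values with a header
#' row and a leading identifier column. The delimiter is sniffed from
#' the header (tab if present, else comma, else whitespace) unless set
#' explicitly. Structural problems are reported with the offending line:
#' missing header, ragged rows, duplicated feature identifiers and
#' non-numeric cells are all format errors.
#'
#' @param path File path.
#' @param rows_are_features If `FALSE` the table is transposed after
#'   reading (samples in rows on disk). Default `TRUE`.
#' @param delim Field delimiter; `NULL` (default) to sniff.
#' @param log2_transform Apply `log2(x + 1)` to the values after reading.
#'   Default `FALSE`: values are used as stored.
#' @param covariate Optional numeric per-sample covariate attached to the
#'   result (e.g. hours).
#' @return An [omics_matrix()].
#' @export
read_expression_table <- function(path, rows_are_features = TRUE,
                                  delim = NULL, log2_transform = FALSE,
                                  covariate = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(lines))) {
    abort(sprintf("format error in '%s': empty file", path))
  }
  if (length(lines) < 2) {
    abort(sprintf("format error in '%s': header but no data rows", path))
  }
  delim <- delim %||% sniff_delim(lines[[1]])
  nf <- count.fields(textConnection(lines), sep = delim, quote = "\"")
  if (length(unique(nf)) != 1) {
    bad <- which(nf != nf[1])[1]
    abort(sprintf("format error in '%s': ragged row at line %d (%d fields, expected %d)",
                  path, bad, nf[bad], nf[1]))
  }
  df <- read.delim(textConnection(lines), sep = delim, header = TRUE,
                   check.names = FALSE, colClasses = "character")
  ids <- df[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    abort(sprintf("format error in '%s': duplicated feature ID(s): %s",
                  path, paste(dup, collapse = ", ")))
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !(toupper(trimws(vals)) %in% c("NA", "")))
  if (length(bad)) {
    row <- (bad[1] - 1) %% nrow(vals) + 1
    abort(sprintf("format error in '%s': non-numeric value '%s' at data line %d",
                  path, vals[bad[1]], row + 1))
  }
  colnames(num) <- colnames(df)[-1]
  rownames(num) <- ids
  if (!rows_are_features) num <- t(num)
  if (log2_transform) num <- log2(num + 1)
  omics_matrix(num, covariate = covariate)
}

sniff_delim <- function(header) {
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
}

#' Read BED-like genomic intervals
#'
#' Reads a whitespace- or tab-delimited interval file with columns
#' chrom, start, end and (optionally) a numeric value. Coordinates are
#' kept 0-based half-open as in BED. Comment and track lines (starting
#' with `#`, `track` or `browser`) are skipped; rows lacking the value
#' column default to 1. Intervals with `start >= end` are format errors
#' reported with their file line number.
#'
#' @param path File path.
#' @param value_col 1-based column index of the value (default 4).
#' @return A tibble with columns `chrom`, `start`, `end`, `value`, in
#'   file order.
#' @export
read_intervals <- function(path, value_col = 4) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(#|track\\b|browser\\b)", trimws(lines))
  if (!any(keep)) {
    abort(sprintf("format error in '%s': no interval records", path))
  }
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  n <- lengths(fields)
  if (any(n < 3)) {
    abort(sprintf("format error in '%s': fewer than 3 columns at line %d",
                  path, lineno[which(n < 3)[1]]))
  }
  chrom <- vapply(fields, `[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    abort(sprintf("format error in '%s': non-numeric coordinate at line %d",
                  path, lineno[bad]))
  }
  value <- vapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) >= value_col) {
      v <- suppressWarnings(as.numeric(f[value_col]))
      if (is.na(v)) {
        abort(sprintf("format error in '%s': non-numeric value at line %d",
                      path, lineno[i]))
      }
      v
    } else 1
  }, numeric(1))
  bad <- which(start >= end)
  if (length(bad)) {
    abort(sprintf("format error in '%s': start >= end at line %d",
                  path, lineno[bad[1]]))
  }
  if (any(value < 0)) {
    abort(sprintf("format error in '%s': negative value at line %d",
                  path, lineno[which(value < 0)[1]]))
  }
  tibble(chrom = chrom, start = start, end = end, value = value)
}

#' Sum interval values into fixed genomic bins
#'
#' Apportions each interval's value into consecutive fixed-width bins
#' (`[b*size, (b+1)*size)` per chromosome, counted from position 0).
#' The default proportional mode splits a value across the bins an
#' interval overlaps in proportion to the overlap length, so total mass
#' is conserved; the alternative midpoint mode assigns the whole value
#' to the bin containing the interval midpoint. Only bins overlapped by
#' at least one interval are reported.
#'
#' @param intervals Tibble from [read_intervals()] (columns `chrom`,
#'   `start`, `end`, `value`; 0-based half-open).
#' @param bin_size Bin width in bases (default 25000).
#' @param method `"proportional"` (default) or `"midpoint"`.
#' @return A tibble of class `binned_coverage` with columns `chrom`,
#'   `bin` (0-based index), `start`, `end`, `total`, sorted by
#'   chromosome and bin, with attribute `bin_size`.
#' @export
bin_coverage <- function(intervals, bin_size = 25000,
                         method = c("proportional", "midpoint")) {
  method <- match.arg(method)
  if (bin_size <= 0) abort("`bin_size` must be positive")
  if (nrow(intervals) == 0) {
    out <- tibble(chrom = character(), bin = integer(),
                  start = numeric(), end = numeric(), total = numeric())
    attr(out, "bin_size") <- bin_size
    class(out) <- c("binned_coverage", class(out))
    return(out)
  }
  if (method == "midpoint") {
    bin <- floor((intervals$start + intervals$end) / 2 / bin_size)
    key_chrom <- intervals$chrom
    weights <- intervals$value
  } else {
    gr <- GenomicRanges::GRanges(
      intervals$chrom,
      IRanges::IRanges(start = intervals$start + 1, end = intervals$end)
    )
    maxend <- tapply(intervals$end, intervals$chrom, max)
    nb <- ceiling(unlist(maxend) / bin_size)
    tiles <- GenomicRanges::GRanges(
      rep(names(nb), nb),
      IRanges::IRanges(
        start = unlist(lapply(nb, function(n) (seq_len(n) - 1) * bin_size + 1),
                       use.names = FALSE),
        width = bin_size
      )
    )
    hits <- GenomicRanges::findOverlaps(gr, tiles)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    ov <- GenomicRanges::width(GenomicRanges::pintersect(gr[qi], tiles[si]))
    weights <- intervals$value[qi] * ov /
      (intervals$end[qi] - intervals$start[qi])
    key_chrom <- as.character(GenomicRanges::seqnames(tiles))[si]
    bin <- (GenomicRanges::start(tiles)[si] - 1) / bin_size
  }
  key <- paste(key_chrom, bin, sep = "\r")
  tot <- rowsum(weights, key)
  parts <- strsplit(rownames(tot), "\r", fixed = TRUE)
  out <- tibble(
    chrom = vapply(parts, `[`, "", 1),
    bin = as.integer(vapply(parts, `[`, "", 2)),
    total = as.vector(tot)
  )
  out <- out[order(out$chrom, out$bin), ]
  out$start <- out$bin * bin_size
  out$end <- out$start + bin_size
  out <- out[, c("chrom", "bin", "start", "end", "total")]
  attr(out, "bin_size") <- bin_size
  class(out) <- c("binned_coverage", class(out))
  out
}

#' Assemble binned samples into a region x time x condition tensor
#'
#' Stacks per-sample binned coverages into a 3-way tensor whose region
#' mode is the union of all non-empty bins across samples (bins absent
#' from a sample are 0 there). Samples must be supplied time-fastest
#' within condition: all time points of condition 1, then all time
#' points of condition 2, and so on.
#'
#' @param binned_samples List of [bin_coverage()] results, one per
#'   sample, all with the same bin size.
#' @param time_labels,condition_labels Labels of the two sample modes;
#'   `length(binned_samples)` must equal their product.
#' @return An [omics_tensor()] with modes `(region, time, condition)`;
#'   region labels are `"chrom:bin"`.
#' @export
assemble_tensor <- function(binned_samples, time_labels, condition_labels) {
  nt <- length(time_labels)
  nc <- length(condition_labels)
  if (length(binned_samples) != nt * nc) {
    abort(sprintf("layout error: %d samples for a %d x %d (time x condition) layout",
                  length(binned_samples), nt, nc))
  }
  sizes <- vapply(binned_samples, function(b) attr(b, "bin_size"), numeric(1))
  if (length(unique(sizes)) != 1) {
    abort("all samples must share the same bin size")
  }
  keys <- lapply(binned_samples, function(b) paste(b$chrom, b$bin, sep = ":"))
  universe <- sort(unique(unlist(keys)))
  m <- matrix(0, length(universe), nt * nc)
  for (s in seq_along(binned_samples)) {
    m[match(keys[[s]], universe), s] <- binned_samples[[s]]$total
  }
  omics_tensor(
    array(m, c(length(universe), nt, nc)),
    mode_names = c("region", "time", "condition"),
    mode_labels = list(universe, time_labels, condition_labels)
  )
}

#' Serialize / restore a tensor as plain text
#'
#' Writes an [omics_tensor()] (or plain array) as a directory holding a
#' JSON sidecar (dimensions, mode names and labels, free-form metadata)
#' plus a flat text dump of the values at 17 significant digits, which
#' round-trips IEEE doubles bit-exactly.
#'
#' @param x Tensor to write.
#' @param dir Target directory (created if needed).
#' @param meta Optional named list merged into the sidecar.
#' @return `dir` (write) / the restored [omics_tensor()] (read).
#' @export
write_tensor <- function(x, dir, meta = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  side <- c(list(
    dim = dim(x),
    mode_names = mode_names(x),
    mode_labels = attr(x, "mode_labels") %||% lapply(dim(x), seq_len)
  ), meta)
  jsonlite::write_json(side, file.path(dir, "tensor.json"),
                       auto_unbox = FALSE, digits = NA)
  writeLines(sprintf("%.17g", as.vector(x)), file.path(dir, "values.txt"))
  invisible(dir)
}

#' @rdname write_tensor
#' @export
read_tensor <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "tensor.json"),
                              simplifyVector = TRUE, simplifyMatrix = FALSE)
  vals <- as.numeric(readLines(file.path(dir, "values.txt")))
  d <- as.integer(side$dim)
  if (length(vals) != prod(d)) abort("value dump does not match dimensions")
  omics_tensor(array(vals, d), side$mode_names,
               mode_labels = as.list(side$mode_labels))
}
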