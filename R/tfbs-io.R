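#' Read transcription factor binding site annotations
#'
#' Reads TFBS locations from BED, GFF3 or a simple tabular dialect into the
#' package's internal representation: a data frame with one row per site and
#' columns `tf`, `chrom`, `start`, `end`, `strand`, `score`. Coordinates are
#' stored 0-based half-open (BED native); GFF3 input (1-based closed) has its
#' start decremented on read. Records keep file order and are not
#' deduplicated.
#'
#' @param path Path to the annotation file.
#' @param format One of `"bed"`, `"gff3"`, `"tsv"`. For BED the name column
#'   (column 4) holds the TF label. The TSV dialect has a header line with
#'   columns `tf_label`, `chrom`, `start`, `end`, `strand` and optionally
#'   `score`, with coordinates already 0-based half-open.
#' @param gff_attr Attribute key holding the TF label in GFF3 input
#'   (default `"Name"`).
#' @return A data frame of binding sites (`tf`, `chrom`, `start`, `end`,
#'   `strand`, `score`), strand one of `+`, `-`, `.`; `score` is `NA` where
#'   absent.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t110\tABF1\t0\t+", bed)
#' read_tfbs(bed, "bed")
#' @export
read_tfbs <- function(path, format = c("bed", "gff3", "tsv"),
                      gff_attr = "Name") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
    bed  = .read_bed(path),
    gff3 = .read_gff3(path, gff_attr),
    tsv  = .read_site_tsv(path)
  )
}

.fail_line <- function(path, lineno, field, msg) {
  stop(sprintf("%s: line %d: field '%s': %s", path, lineno, field, msg),
       call. = FALSE)
}

.parse_pos <- function(x, path, lineno, field) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v) || v != trunc(v) || v < 0)
    .fail_line(path, lineno, field, paste0("not a non-negative integer: '", x, "'"))
  as.integer(v)
}

.check_strand <- function(s, path, lineno) {
  if (!s %in% c("+", "-", "."))
    .fail_line(path, lineno, "strand", paste0("expected +, - or . but got '", s, "'"))
  s
}

.site_df <- function(tf, chrom, start, end, strand, score) {
  data.frame(tf = tf, chrom = chrom, start = start, end = end,
             strand = strand, score = score, stringsAsFactors = FALSE)
}

.empty_sites <- function() {
  .site_df(character(0), character(0), integer(0), integer(0),
           character(0), numeric(0))
}

.read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(.empty_sites())
  rows <- lapply(idx, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4)
      .fail_line(path, i, "columns", sprintf("BED needs >= 4 columns, got %d", length(f)))
    start <- .parse_pos(f[2], path, i, "start")
    end <- .parse_pos(f[3], path, i, "end")
    if (start >= end)
      .fail_line(path, i, "end", sprintf("start (%d) >= end (%d)", start, end))
    if (!nzchar(f[4])) .fail_line(path, i, "name", "empty TF label")
    score <- if (length(f) >= 5 && f[5] != ".")
      suppressWarnings(as.numeric(f[5])) else NA_real_
    strand <- if (length(f) >= 6) .check_strand(f[6], path, i) else "."
    .site_df(f[4], f[1], start, end, strand, score)
  })
  do.call(rbind, rows)
}

.read_gff3 <- function(path, gff_attr) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(.empty_sites())
  attr_re <- paste0("(^|;)\\s*", gff_attr, "=([^;]*)")
  rows <- lapply(idx, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9)
      .fail_line(path, i, "columns", sprintf("GFF3 needs 9 columns, got %d", length(f)))
    start1 <- .parse_pos(f[4], path, i, "start")
    end1 <- .parse_pos(f[5], path, i, "end")
    start <- start1 - 1L   # 1-based closed -> 0-based half-open
    end <- end1
    if (start < 0L) .fail_line(path, i, "start", "GFF3 start must be >= 1")
    if (start >= end)
      .fail_line(path, i, "end", sprintf("empty interval after conversion (%d >= %d)", start, end))
    m <- regmatches(f[9], regexec(attr_re, f[9]))[[1]]
    if (length(m) < 3 || !nzchar(m[3]))
      .fail_line(path, i, "attributes", paste0("missing attribute '", gff_attr, "'"))
    score <- if (f[6] != ".") suppressWarnings(as.numeric(f[6])) else NA_real_
    strand <- .check_strand(f[7], path, i)
    .site_df(m[3], f[1], start, end, strand, score)
  })
  do.call(rbind, rows)
}

.read_site_tsv <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) return(.empty_sites())
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("tf_label", "chrom", "start", "end", "strand")
  if (length(header) < 5 || any(header[1:5] != need))
    stop(path, ": line 1: expected header 'tf_label\tchrom\tstart\tend\tstrand[\tscore]'",
         call. = FALSE)
  has_score <- length(header) >= 6 && header[6] == "score"
  idx <- which(nzchar(trimws(lines)))
  idx <- idx[idx > 1]
  if (!length(idx)) return(.empty_sites())
  rows <- lapply(idx, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5)
      .fail_line(path, i, "columns", sprintf("need >= 5 columns, got %d", length(f)))
    if (!nzchar(f[1])) .fail_line(path, i, "tf_label", "empty TF label")
    start <- .parse_pos(f[3], path, i, "start")
    end <- .parse_pos(f[4], path, i, "end")
    if (start >= end)
      .fail_line(path, i, "end", sprintf("start (%d) >= end (%d)", start, end))
    strand <- .check_strand(f[5], path, i)
    score <- if (has_score && length(f) >= 6 && nzchar(f[6]) && f[6] != ".")
      suppressWarnings(as.numeric(f[6])) else NA_real_
    .site_df(f[1], f[2], start, end, strand, score)
  })
  do.call(rbind, rows)
}

#' Validate a binding-site data frame
#'
#' Checks the invariants of the internal site representation: required
#' columns, non-empty TF labels, `0 <= start < end`, strand in `+`/`-`/`.`.
#' Adds missing `strand`/`score` columns with defaults.
#'
#' @param sites Data frame with at least `tf`, `chrom`, `start`, `end`.
#' @return The validated (possibly completed) data frame.
#' @export
validate_sites <- function(sites) {
  if (!is.data.frame(sites))
    stop("sites must be a data frame")
  need <- c("tf", "chrom", "start", "end")
  miss <- setdiff(need, names(sites))
  if (length(miss)) stop("sites lacks columns: ", paste(miss, collapse = ", "))
  if (!"strand" %in% names(sites)) sites$strand <- rep(".", nrow(sites))
  if (!"score" %in% names(sites)) sites$score <- rep(NA_real_, nrow(sites))
  if (nrow(sites) == 0) return(sites)
  if (any(!nzchar(sites$tf) | is.na(sites$tf)))
    stop("empty TF label at row ", which(!nzchar(sites$tf) | is.na(sites$tf))[1])
  if (any(sites$start < 0))
    stop("negative start at row ", which(sites$start < 0)[1])
  if (any(sites$start >= sites$end))
    stop("start >= end at row ", which(sites$start >= sites$end)[1])
  bad <- !sites$strand %in% c("+", "-", ".")
  if (any(bad)) stop("invalid strand at row ", which(bad)[1])
  sites
}
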