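#' Write a transactional database to a text file
#'
#' One transaction per line:
#' `<id>\t<chrom>:<span_start>-<span_end>\t<TF>:<degree>;<TF>:<degree>;...`
#' with degrees at exactly 4 decimal places and TFs in lexicographic order.
#' A leading `#` header line records the membership parameters so a file is
#' self-describing. Round-trips with [read_transactions()] up to the 4-decimal
#' degree quantisation.
#'
#' @param db A `crm_db` object.
#' @param path Output file path.
#' @export
write_transactions <- function(db, path) {
  stopifnot(inherits(db, "crm_db"))
  p <- db$params
  header <- sprintf(
    "# fuzzycrm transactions mode=%s cluster_threshold=%s core_halfwidth=%s ramp_width=%s site_anchor=%s N=%d",
    db$mode,
    if (is.null(p)) "NA" else p$cluster_threshold,
    if (is.null(p)) "NA" else p$core_halfwidth,
    if (is.null(p)) "NA" else p$ramp_width,
    if (is.null(p)) "NA" else p$site_anchor,
    db$N)
  body <- vapply(db$transactions, function(t) {
    it <- t$items[order(names(t$items))]
    paste0(t$id, "\t", t$chrom, ":", t$span_start, "-", t$span_end, "\t",
           paste(sprintf("%s:%.4f", names(it), unname(it)), collapse = ";"))
  }, character(1))
  writeLines(c(header, body), path)
}

#' Read a transactional database written by [write_transactions()]
#'
#' Transactions are restored in file order with degrees parsed as reals in
#' `[0, 1]`. The file carries TF-to-degree pairs only, not the underlying
#' sites, so a database read this way supports mining and significance
#' scoring but not the site-level overlap refit.
#'
#' @param path Path to a transaction file.
#' @return A `crm_db` object (transactions have `site_pool = NULL`).
#' @export
read_transactions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  mode <- "fuzzy"
  hdr <- grep("^#", lines, value = TRUE)
  if (length(hdr) && grepl("mode=crisp", hdr[1])) mode <- "crisp"
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  trans <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 3)
      stop(path, ": transaction line ", i, ": expected 3 tab-separated fields")
    loc <- regmatches(f[2], regexec("^(.+):([0-9]+)-([0-9]+)$", f[2]))[[1]]
    if (length(loc) != 4)
      stop(path, ": transaction line ", i, ": bad locus '", f[2], "'")
    pairs <- strsplit(f[3], ";", fixed = TRUE)[[1]]
    kv <- strsplit(pairs, ":", fixed = TRUE)
    if (any(lengths(kv) != 2))
      stop(path, ": transaction line ", i, ": bad item field '", f[3], "'")
    tf <- vapply(kv, `[`, character(1), 1)
    deg <- suppressWarnings(as.numeric(vapply(kv, `[`, character(1), 2)))
    if (anyNA(deg) || any(deg < 0 | deg > 1))
      stop(path, ": transaction line ", i,
           ": membership degree outside [0,1]")
    if (anyDuplicated(tf))
      stop(path, ": transaction line ", i, ": duplicate TF '",
           tf[duplicated(tf)][1], "'")
    items <- stats::setNames(deg, tf)
    items <- items[order(names(items))]
    trans[[i]] <- list(id = f[1], chrom = loc[2],
                       span_start = as.integer(loc[3]),
                       span_end = as.integer(loc[4]),
                       items = items, site_pool = NULL)
  }
  .new_db(trans, mode = mode)
}

#' Write itemset and CRM-instance result files
#'
#' The itemset table is TSV with columns `id`, `tf_list` (comma-joined,
#' lexicographic), `size`, `fuzzy_support` (6 decimals), `p_value`
#' (scientific, 4 significant digits) and `postfit_support`. Instances are
#' written as BED: chrom, min fitted site start, max fitted site end, the TF
#' list as name, `round(1000 * fit_degree)` as score, strand `.`.
#'
#' @param itemsets Itemset data frame as returned by [crm_mine()] /
#'   [filter_report()] (optionally with `postfit_support`).
#' @param instances Instance data frame from [refit_all()], or `NULL`.
#' @param itemset_path,instance_path Output paths.
#' @export
write_results <- function(itemsets, instances, itemset_path, instance_path) {
  hdr <- "id\ttf_list\tsize\tfuzzy_support\tp_value\tpostfit_support"
  lines <- hdr
  if (!is.null(itemsets) && nrow(itemsets)) {
    pf <- if ("postfit_support" %in% names(itemsets))
      sprintf("%.6f", itemsets$postfit_support) else rep("NA", nrow(itemsets))
    pv <- if ("p_value" %in% names(itemsets))
      sprintf("%.3e", itemsets$p_value) else rep("NA", nrow(itemsets))
    lines <- c(lines, sprintf("%d\t%s\t%d\t%.6f\t%s\t%s",
                              seq_len(nrow(itemsets)), itemsets$tf_list,
                              itemsets$size, itemsets$support, pv, pf))
  }
  writeLines(lines, itemset_path)

  bed <- character(0)
  if (!is.null(instances) && nrow(instances)) {
    bed <- sprintf("%s\t%d\t%d\t%s\t%d\t.", instances$chrom,
                   instances$start, instances$end, instances$tf_list,
                   as.integer(round(1000 * instances$fit_degree)))
  }
  writeLines(bed, instance_path)
}
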