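#' Run the full pipeline and write all artifacts to a directory
#'
#' Thin orchestration over [crm_mine()]: reads the input, runs the selected
#' mode, and writes the transaction file, the itemset TSV, the CRM-instance
#' BED and a JSON run manifest (every parameter, the input file's MD5 and the
#' package version) into `outdir`. Per-stage counts are reported via
#' `message()`. Re-running with the same input and manifest parameters
#' reproduces the outputs byte for byte.
#'
#' @param input Path to the input sites (or transaction file).
#' @param outdir Output directory, created if needed.
#' @param ... Passed to [crm_mine()].
#' @param quiet Suppress stage messages.
#' @return The `crm_fit`, invisibly.
#' @export
crm_run <- function(input, outdir, ..., quiet = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  fit <- crm_mine(input, ...)
  cn <- fit$counts
  say("sites read:         %s", cn$sites)
  say("transactions:       %d (empty clusters dropped: %d)",
      cn$transactions, cn$empty_clusters %||% 0L)
  say("frequent TFs:       %s", cn$frequent_items %||% 0L)
  say("itemsets mined:     %s", cn$itemsets_mined %||% 0L)
  say("itemsets reported:  %s", cn$itemsets_reported %||% 0L)
  say("CRM instances:      %s", cn$instances %||% 0L)

  write_transactions(fit$db, file.path(outdir, "transactions.tsv"))
  write_results(fit$itemsets, fit$instances,
                file.path(outdir, "itemsets.tsv"),
                file.path(outdir, "instances.bed"))
  manifest <- c(
    list(tool = "fuzzycrm",
         version = as.character(utils::packageVersion("fuzzycrm")),
         input = normalizePath(input),
         input_md5 = unname(tools::md5sum(input)),
         mode = fit$mode),
    fit$params[c("cluster_threshold", "core_halfwidth", "ramp_width",
                 "site_anchor")],
    fit$thresholds %||% list())
  writeLines(.to_json(manifest), file.path(outdir, "manifest.json"))
  invisible(fit)
}

# minimal JSON writer for the flat manifest (scalars only)
.to_json <- function(x) {
  esc <- function(s) gsub("\"", "\\\\\"", s)
  fields <- vapply(names(x), function(k) {
    v <- x[[k]]
    val <- if (is.character(v)) paste0("\"", esc(v), "\"")
    else if (is.logical(v)) tolower(as.character(v))
    else format(v, scientific = FALSE)
    sprintf("  \"%s\": %s", k, val)
  }, character(1))
  paste0("{\n", paste(fields, collapse = ",\n"), "\n}")
}

#' Compare fuzzy and crisp runs on the same input
#'
#' Runs both modes with identical thresholds and joins the union of reported
#' itemsets: each row carries the fuzzy and crisp support and p-value (NA
#' where an itemset is reported by one mode only) and membership flags. The
#' attached `"means"` attribute gives the per-mode mean support and p-value
#' over reported itemsets — the summary on which fuzzy/crisp differences are
#' judged.
#'
#' @param x Input sites (path or data frame).
#' @param ... Passed to [crm_mine()] (mode is set internally).
#' @return A data frame (`tf_list`, `size`, `support_fuzzy`,
#'   `p_value_fuzzy`, `support_crisp`, `p_value_crisp`, `in_fuzzy`,
#'   `in_crisp`) with a `"means"` attribute and the two fits in `"fits"`.
#' @export
compare_modes <- function(x, ...) {
  ff <- crm_mine(x, mode = "fuzzy", ...)
  fc <- crm_mine(x, mode = "crisp", ...)
  fz <- ff$itemsets; cr <- fc$itemsets
  keys <- sort(union(fz$tf_list, cr$tf_list))
  iz <- match(keys, fz$tf_list); ic <- match(keys, cr$tf_list)
  out <- data.frame(
    tf_list = keys,
    size = ifelse(is.na(iz), cr$size[ic], fz$size[iz]),
    support_fuzzy = fz$support[iz],
    p_value_fuzzy = fz$p_value[iz],
    support_crisp = cr$support[ic],
    p_value_crisp = cr$p_value[ic],
    in_fuzzy = !is.na(iz),
    in_crisp = !is.na(ic),
    stringsAsFactors = FALSE)
  attr(out, "means") <- data.frame(
    mode = c("fuzzy", "crisp"),
    n_itemsets = c(nrow(fz), nrow(cr)),
    mean_support = c(mean(fz$support), mean(cr$support)),
    mean_p_value = c(mean(fz$p_value), mean(cr$p_value)),
    stringsAsFactors = FALSE)
  attr(out, "fits") <- list(fuzzy = ff, crisp = fc)
  out
}
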