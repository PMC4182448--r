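#' Mine putative cis-regulatory modules from binding sites
#'
#' The package's main entry point. Runs the full procedure on a set of TFBS
#' annotations: cluster sites per chromosome (average linkage, stop distance
#' `cluster_threshold`), render each cluster as a fuzzy transaction through
#' the trapezoidal membership function (or hard borders in crisp mode), mine
#' frequent TF combinations with the fuzzy FP-tree, score each against the
#' independence null, and resolve overlapping sites by the optimal
#' non-overlapping refit.
#'
#' @param x Input sites: a file path (see `format`), a binding-site data
#'   frame, or a prebuilt `crm_db` (in which case clustering parameters are
#'   ignored).
#' @param format Input format when `x` is a path: `"auto"` (by extension),
#'   `"bed"`, `"gff3"`, `"tsv"` or `"transactions"` (a file written by
#'   [write_transactions()]).
#' @param mode `"fuzzy"` (default) or `"crisp"` baseline.
#' @param cluster_threshold,core_halfwidth,ramp_width,site_anchor Membership
#'   parameters; see [membership_params()].
#' @param crisp_halfwidth Border half-width for crisp mode (default
#'   `core_halfwidth + ramp_width`).
#' @param min_support Minimum fuzzy support (default 0.01).
#' @param max_pvalue p-value threshold (default 0.01).
#' @param min_size Minimum itemset size (default 2).
#' @param count_rounding Discretisation of the fuzzy count for the binomial
#'   tail; see [itemset_pvalue()].
#' @param bh Apply Benjamini-Hochberg adjustment before thresholding.
#' @param refit Run the overlap-aware refit (default `TRUE`; automatically
#'   skipped, with a note in the diagnostics, for databases that carry no
#'   site-level pools).
#' @param gff_attr GFF3 attribute key holding the TF label.
#' @return An object of class `crm_fit` with components `itemsets` (scored,
#'   filtered, refitted), `instances` (one row per fitted CRM occurrence),
#'   `db`, `header`, `null`, `params` and per-stage `counts`. Methods:
#'   `print`, `summary`, `coef` (item marginal supports), `plot`,
#'   `simulate` (crisp draws from the fitted null), `as.data.frame`.
#' @examples
#' sites <- data.frame(
#'   tf = c("A", "B", "C", "A", "B", "C"),
#'   chrom = "chr1",
#'   start = c(100, 160, 220, 5100, 5160, 5230),
#'   end = c(110, 170, 230, 5110, 5170, 5240))
#' fit <- crm_mine(sites, min_support = 0.5, max_pvalue = 1, min_size = 3)
#' fit$itemsets[, c("tf_list", "support", "p_value", "postfit_support")]
#' @export
crm_mine <- function(x,
                     format = c("auto", "bed", "gff3", "tsv", "transactions"),
                     mode = c("fuzzy", "crisp"),
                     cluster_threshold = 300, core_halfwidth = 150,
                     ramp_width = 100, site_anchor = "midpoint",
                     crisp_halfwidth = core_halfwidth + ramp_width,
                     min_support = 0.01, max_pvalue = 0.01, min_size = 2,
                     count_rounding = "ceil", bh = FALSE, refit = TRUE,
                     gff_attr = "Name") {
  mode <- match.arg(mode)
  format <- match.arg(format)
  cl <- match.call()
  params <- membership_params(cluster_threshold, core_halfwidth, ramp_width,
                              site_anchor)
  counts <- list()

  db <- NULL
  sites <- NULL
  if (inherits(x, "crm_db")) {
    db <- x
    counts$sites <- NA_integer_
  } else if (is.character(x) && length(x) == 1) {
    if (format == "auto") format <- .guess_format(x)
    if (format == "transactions") {
      db <- read_transactions(x)
      counts$sites <- NA_integer_
    } else {
      sites <- read_tfbs(x, format, gff_attr)
    }
  } else {
    sites <- validate_sites(x)
  }
  if (is.null(db)) {
    counts$sites <- nrow(sites)
    db <- if (mode == "fuzzy") build_database(sites, params)
          else build_crisp_database(sites, params, crisp_halfwidth)
  }
  counts$transactions <- db$N
  counts$empty_clusters <- db$n_empty

  if (db$N == 0) {
    fit <- .empty_fit(cl, mode, params, db, counts)
    return(fit)
  }
  header <- find_frequent_items(db, min_support)
  counts$frequent_items <- nrow(header)
  tree <- build_fptree(db, header)
  itemsets <- mine_topdown(tree, min_support, min_size)
  counts$itemsets_mined <- nrow(itemsets)
  null <- null_model(db)
  itemsets <- filter_report(itemsets, null, max_pvalue, min_support,
                            count_rounding, bh)
  counts$itemsets_reported <- nrow(itemsets)

  has_pool <- db$N > 0 && !is.null(db$transactions[[1]]$site_pool)
  if (refit && has_pool) {
    rf <- refit_all(db, itemsets, min_support)
    itemsets <- rf$itemsets
    instances <- rf$instances
  } else {
    instances <- NULL
    if (refit && !has_pool) counts$refit_skipped <- TRUE
  }
  counts$instances <- if (is.null(instances)) 0L else nrow(instances)

  structure(list(call = cl, mode = mode, params = params,
                 thresholds = list(min_support = min_support,
                                   max_pvalue = max_pvalue,
                                   min_size = min_size,
                                   count_rounding = count_rounding,
                                   bh = bh,
                                   crisp_halfwidth = crisp_halfwidth),
                 db = db, header = header, null = null,
                 itemsets = itemsets, instances = instances,
                 counts = counts),
            class = "crm_fit")
}

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         bed = "bed", gff = "gff3", gff3 = "gff3",
         tsv = "tsv", txt = "tsv",
         stop("cannot guess format from extension '", ext,
              "'; pass format= explicitly"))
}

.empty_fit <- function(cl, mode, params, db, counts) {
  empty <- data.frame(tf_list = character(0), size = integer(0),
                      support = numeric(0), stringsAsFactors = FALSE)
  empty$items <- list()
  empty$p_value <- numeric(0)
  counts$frequent_items <- 0L
  counts$itemsets_mined <- 0L
  counts$itemsets_reported <- 0L
  counts$instances <- 0L
  structure(list(call = cl, mode = mode, params = params,
                 thresholds = NULL, db = db, header = NULL, null = NULL,
                 itemsets = empty, instances = NULL, counts = counts),
            class = "crm_fit")
}

#' @export
print.crm_fit <- function(x, n = 10, ...) {
  cat(sprintf("Putative CRM mining (%s mode)\n", x$mode))
  cn <- x$counts
  cat(sprintf("  %s sites -> %d transactions -> %s frequent TFs -> %s itemsets reported\n",
              if (is.na(cn$sites %||% NA)) "?" else cn$sites,
              cn$transactions, cn$frequent_items %||% 0,
              cn$itemsets_reported %||% 0))
  if (nrow(x$itemsets)) {
    cat("Top itemsets:\n")
    cols <- intersect(c("tf_list", "size", "support", "p_value",
                        "postfit_support"), names(x$itemsets))
    print(utils::head(x$itemsets[, cols, drop = FALSE], n), digits = 4)
  } else cat("No itemsets passed the thresholds.\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.crm_fit <- function(object, ...) {
  s <- list(mode = object$mode, counts = object$counts,
            thresholds = object$thresholds,
            params = object$params,
            alphabet_size = length(object$db$alphabet),
            itemsets = object$itemsets,
            size_table = if (nrow(object$itemsets))
              table(object$itemsets$size) else table(integer(0)))
  class(s) <- "summary.crm_fit"
  s
}

#' @export
print.summary.crm_fit <- function(x, ...) {
  cat(sprintf("CRM mining summary (%s mode)\n", x$mode))
  cat(sprintf("  TF alphabet: %d   transactions: %d (+%d empty clusters)\n",
              x$alphabet_size, x$counts$transactions,
              x$counts$empty_clusters %||% 0L))
  if (!is.null(x$thresholds))
    cat(sprintf("  thresholds: support >= %g, p <= %g, size >= %d (%s count)\n",
                x$thresholds$min_support, x$thresholds$max_pvalue,
                x$thresholds$min_size, x$thresholds$count_rounding))
  cat(sprintf("  itemsets reported: %d", nrow(x$itemsets)))
  if (nrow(x$itemsets))
    cat("  by size: ",
        paste(sprintf("%s TFs: %d", names(x$size_table), x$size_table),
              collapse = ", "))
  cat("\n")
  if (nrow(x$itemsets)) {
    cols <- intersect(c("tf_list", "size", "support", "p_value",
                        "postfit_support", "postfit_dropped"),
                      names(x$itemsets))
    print(x$itemsets[, cols, drop = FALSE], digits = 4)
  }
  invisible(x)
}

#' @export
coef.crm_fit <- function(object, ...) {
  if (is.null(object$null)) return(stats::setNames(numeric(0), character(0)))
  object$null$marginals
}

#' @export
as.data.frame.crm_fit <- function(x, ...) {
  out <- x$itemsets
  out$items <- NULL
  out
}

#' @export
plot.crm_fit <- function(x, ...) {
  it <- x$itemsets
  if (!nrow(it)) {
    graphics::plot.new()
    graphics::title(main = "No reported itemsets")
    return(invisible(x))
  }
  graphics::plot(it$support, -log10(pmax(it$p_value, 1e-300)),
                 pch = 19, cex = 0.4 + 0.3 * it$size,
                 xlab = "fuzzy support",
                 ylab = expression(-log[10] ~ p),
                 main = sprintf("Reported TF combinations (%s mode)", x$mode),
                 ...)
  invisible(x)
}

#' Simulate databases from the fitted independence null
#'
#' Draws crisp transactional databases in which each TF occurs independently
#' across transactions with probability equal to its fitted marginal support
#' — the null model the p-values are computed under. Useful for Monte-Carlo
#' checks of the significance calculation.
#'
#' @param object A `crm_fit`.
#' @param nsim Number of databases to draw.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `nsim` `crm_db` objects with all degrees in \{0, 1\}.
#' @export
simulate.crm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(object$null)) stop("fit has no null model (empty database)")
  marg <- object$null$marginals
  N <- object$null$N
  lapply(seq_len(nsim), function(s) {
    trans <- lapply(seq_len(N), function(t) {
      present <- names(marg)[stats::runif(length(marg)) < marg]
      list(id = paste0("T", t), chrom = "sim", span_start = 0L, span_end = 1L,
           items = stats::setNames(rep(1, length(present)), present),
           site_pool = NULL)
    })
    .new_db(trans, alphabet = names(marg), mode = "crisp")
  })
}
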