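#' Optimally fit an itemset into one transaction
#'
#' Chooses exactly one binding site per itemset TF from the transaction's
#' site pool such that the chosen intervals are pairwise non-overlapping
#' (half-open semantics: abutting sites do not overlap) and the minimum
#' membership degree of the chosen sites — the itemset's degree in the
#' transaction — is maximal. Overlapping predicted sites are thus resolved
#' rather than discarded. The optimum is exact: depth-first enumeration over
#' one-site-per-TF assignments with a branch-and-bound on the running
#' minimum; ties broken by higher total degree, then leftmost locus.
#'
#' @param transaction One transaction of a `crm_db` built from sites (its
#'   `site_pool` must be present).
#' @param items Character vector of TF labels.
#' @return A list (`items`, `transaction_id`, `chosen` site data frame,
#'   `fit_degree`, `chrom`, `start`, `end`) or `NULL` when some TF has no
#'   sites in the transaction or no disjoint assignment exists.
#' @export
fit_itemset <- function(transaction, items) {
  if (is.null(transaction$site_pool))
    stop("transaction carries no site-level pool; ",
         "databases read from a transaction file cannot be refitted")
  pools <- transaction$site_pool[items]
  if (any(vapply(pools, is.null, logical(1)))) return(NULL)
  # fewest candidates first: fail fast, prune hard
  ord <- order(vapply(pools, nrow, integer(1)))
  pools <- pools[ord]
  # within a TF, try high degrees first so good bounds are found early
  pools <- lapply(pools, function(p) p[order(-p$degree, p$start), , drop = FALSE])

  best <- new.env(parent = emptyenv())
  best$min <- -1; best$sum <- -Inf; best$start <- Inf; best$end <- Inf
  best$rows <- NULL

  k <- length(pools)
  chosen <- vector("list", k)

  overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

  recurse <- function(depth, run_min, run_sum) {
    if (run_min < best$min) return(invisible())
    if (depth > k) {
      st <- min(vapply(chosen, function(r) r$start, numeric(1)))
      en <- max(vapply(chosen, function(r) r$end, numeric(1)))
      better <- run_min > best$min ||
        (run_min == best$min && (run_sum > best$sum ||
          (run_sum == best$sum && (st < best$start ||
            (st == best$start && en < best$end)))))
      if (better) {
        best$min <- run_min; best$sum <- run_sum
        best$start <- st; best$end <- en
        best$rows <- chosen
      }
      return(invisible())
    }
    p <- pools[[depth]]
    for (r in seq_len(nrow(p))) {
      cand <- p[r, , drop = FALSE]
      if (cand$degree < best$min) break   # degrees sorted descending
      ok <- TRUE
      if (depth > 1) for (j in seq_len(depth - 1)) {
        if (overlaps(cand$start, cand$end,
                     chosen[[j]]$start, chosen[[j]]$end)) { ok <- FALSE; break }
      }
      if (!ok) next
      chosen[[depth]] <<- cand
      recurse(depth + 1, min(run_min, cand$degree), run_sum + cand$degree)
    }
    invisible()
  }
  recurse(1, Inf, 0)
  if (is.null(best$rows)) return(NULL)
  sel <- do.call(rbind, best$rows)
  sel <- sel[order(match(sel$tf, sort(items))), , drop = FALSE]
  rownames(sel) <- NULL
  list(items = sort(items), transaction_id = transaction$id,
       chosen = sel, fit_degree = best$min,
       chrom = transaction$chrom,
       start = min(sel$start), end = max(sel$end))
}

#' Refit all reported itemsets into every transaction
#'
#' Runs [fit_itemset()] for every (itemset, transaction) pair, emits one CRM
#' instance per successful fit with positive degree, and recomputes each
#' itemset's support from the constrained fits:
#' `postfit_support = sum_t fit_degree_t / N` (failed fits contribute 0).
#' Because the constrained optimum can never exceed the unconstrained
#' transaction degree, `postfit_support <= fuzzy support` always. Itemsets
#' that drop below `min_support` after refitting are flagged
#' (`postfit_dropped`) but kept in the table, so both numbers stay visible.
#'
#' @param db A `crm_db` built from sites (with site pools).
#' @param itemsets Scored itemset data frame (from [filter_report()]).
#' @param min_support Threshold used for the `postfit_dropped` flag.
#' @return A list: `itemsets` (input plus `postfit_support`,
#'   `postfit_dropped`) and `instances`, a BED-like data frame (`chrom`,
#'   `start`, `end`, `tf_list`, `fit_degree`, `transaction_id`).
#' @export
refit_all <- function(db, itemsets, min_support = 0.01) {
  stopifnot(inherits(db, "crm_db"))
  inst <- list()
  postfit <- numeric(nrow(itemsets))
  for (r in seq_len(nrow(itemsets))) {
    items <- itemsets$items[[r]]
    total <- 0
    for (t in db$transactions) {
      if (!all(items %in% names(t$items))) next
      fit <- fit_itemset(t, items)
      if (is.null(fit) || fit$fit_degree <= 0) next
      total <- total + fit$fit_degree
      inst[[length(inst) + 1L]] <- data.frame(
        chrom = fit$chrom, start = fit$start, end = fit$end,
        tf_list = paste(fit$items, collapse = ","),
        fit_degree = fit$fit_degree,
        transaction_id = fit$transaction_id,
        stringsAsFactors = FALSE)
    }
    postfit[r] <- total / db$N
  }
  itemsets$postfit_support <- postfit
  itemsets$postfit_dropped <- postfit < min_support
  instances <- if (length(inst)) do.call(rbind, inst) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               tf_list = character(0), fit_degree = numeric(0),
               transaction_id = character(0), stringsAsFactors = FALSE)
  list(itemsets = itemsets, instances = instances)
}
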