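#' Independence null model for itemset significance
#'
#' Under the null, TFs occur independently across transactions with
#' probabilities equal to their single-item fuzzy supports in the same
#' database (a self-calibrated null). An itemset's expected co-occurrence
#' probability is then the product of its members' marginals.
#'
#' @param db A `crm_db` object.
#' @return A list of class `crm_null` with `N` and `marginals` (named vector
#'   over the full TF alphabet, including infrequent items).
#' @export
null_model <- function(db) {
  stopifnot(inherits(db, "crm_db"))
  if (db$N == 0) stop("empty database")
  trans <- lapply(db$transactions, `[[`, "items")
  tf <- unlist(lapply(trans, names), use.names = FALSE)
  deg <- unlist(trans, use.names = FALSE)
  marg <- stats::setNames(numeric(length(db$alphabet)), db$alphabet)
  s <- vapply(split(deg, tf), sum, numeric(1)) / db$N
  marg[names(s)] <- s
  structure(list(N = db$N, marginals = marg), class = "crm_null")
}

.observed_count <- function(N, support, count_rounding) {
  x <- round(N * support, 9)   # shave summation fuzz before discretising
  switch(count_rounding,
         ceil = ceiling(x),
         floor = floor(x),
         round = round(x))
}

#' Binomial tail p-value of an itemset under the independence null
#'
#' With null co-occurrence probability `p0` (the product of the member TFs'
#' marginal supports) and an observed count `k` obtained by discretising the
#' fuzzy sigma-count (`k = ceiling(N * support)` by default), returns the
#' upper binomial tail `P(X >= k)`, `X ~ Binomial(N, p0)` — the probability
#' of seeing co-occurrence this frequent by chance. `k = 0` gives 1. The
#' ceiling is the conservative discretisation: it never starts the tail
#' earlier than the fuzzy count warrants.
#'
#' @param support Observed fuzzy support of the itemset in `[0, 1]`.
#' @param items Character vector of member TFs.
#' @param null A `crm_null` from [null_model()].
#' @param count_rounding How the fuzzy count is discretised: `"ceil"`
#'   (default), `"floor"` or `"round"`.
#' @return p-value in `(0, 1]` (exactly 0 only in the degenerate case
#'   `p0 = 0` with `k > 0`, which warns).
#' @examples
#' nm <- structure(list(N = 10, marginals = c(A = 0.4, B = 0.5)),
#'                 class = "crm_null")
#' itemset_pvalue(0.5, c("A", "B"), nm)   # P(X >= 5), X ~ Bin(10, 0.2)
#' @export
itemset_pvalue <- function(support, items, null,
                           count_rounding = c("ceil", "floor", "round")) {
  count_rounding <- match.arg(count_rounding)
  stopifnot(inherits(null, "crm_null"))
  if (support < 0 || support > 1) stop("support must be in [0, 1]")
  miss <- setdiff(items, names(null$marginals))
  if (length(miss))
    stop("items missing from null marginals: ", paste(miss, collapse = ", "))
  p0 <- prod(null$marginals[items])
  k <- .observed_count(null$N, support, count_rounding)
  if (k <= 0) return(1)
  if (p0 == 0) {
    warning("degenerate null: itemset has a zero marginal but positive support")
    return(0)
  }
  stats::pbinom(k - 1, null$N, p0, lower.tail = FALSE)
}

#' Score and filter mined itemsets
#'
#' Attaches the independence-null p-value to every itemset, keeps those with
#' `support >= min_support` and `p_value <= max_pvalue`, and sorts by
#' ascending p-value, then descending support, then TF list — most
#' significant first. Optionally applies Benjamini-Hochberg adjustment
#' across all scored itemsets before thresholding.
#'
#' @param itemsets Itemset data frame from [mine_topdown()] or
#'   [mine_bruteforce()].
#' @param null A `crm_null` from [null_model()].
#' @param max_pvalue Significance threshold (default 0.01).
#' @param min_support Support threshold (default 0.01).
#' @param count_rounding Passed to [itemset_pvalue()].
#' @param bh If `TRUE`, threshold the BH-adjusted p-values instead of the raw
#'   ones (raw p-values are still reported in `p_value`; adjusted ones in
#'   `p_adjusted`).
#' @return The filtered, ordered itemset data frame with a `p_value` column.
#' @export
filter_report <- function(itemsets, null, max_pvalue = 0.01,
                          min_support = 0.01,
                          count_rounding = c("ceil", "floor", "round"),
                          bh = FALSE) {
  count_rounding <- match.arg(count_rounding)
  if (nrow(itemsets) == 0) {
    itemsets$p_value <- numeric(0)
    return(itemsets)
  }
  itemsets$p_value <- vapply(seq_len(nrow(itemsets)), function(r)
    itemset_pvalue(itemsets$support[r], itemsets$items[[r]], null,
                   count_rounding), numeric(1))
  if (bh) itemsets$p_adjusted <- stats::p.adjust(itemsets$p_value, "BH")
  crit <- if (bh) itemsets$p_adjusted else itemsets$p_value
  keep <- itemsets$support >= min_support & crit <= max_pvalue
  out <- itemsets[keep, , drop = FALSE]
  out <- out[order(out$p_value, -out$support, out$tf_list), , drop = FALSE]
  rownames(out) <- NULL
  out
}
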