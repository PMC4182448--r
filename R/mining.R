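#' Frequent single items and their fuzzy supports
#'
#' Scans the database once and computes, for every TF, the sigma-count
#' support: the sum over transactions of its membership degree, divided by
#' the number of transactions `N`. Items at or above `min_support` form the
#' header table, sorted by descending support with lexicographic tie-break —
#' the insertion order of the FP-tree.
#'
#' @param db A `crm_db` object.
#' @param min_support Minimum fuzzy support in `(0, 1]`.
#' @return A data frame of class `crm_header` with columns `item` and
#'   `support`, plus a `degrees` attribute: per item, the named vector of
#'   positive degrees by transaction index.
#' @export
find_frequent_items <- function(db, min_support) {
  stopifnot(inherits(db, "crm_db"))
  if (min_support <= 0 || min_support > 1)
    stop("min_support must be in (0, 1]")
  if (db$N == 0) stop("empty database")
  trans <- lapply(db$transactions, `[[`, "items")
  tf <- unlist(lapply(trans, names), use.names = FALSE)
  deg <- unlist(trans, use.names = FALSE)
  tid <- rep.int(seq_along(trans), lengths(trans))
  sup <- vapply(split(deg, tf), sum, numeric(1)) / db$N
  keep <- names(sup)[sup >= min_support]
  sup <- sup[keep]
  ord <- order(-sup, names(sup))
  header <- data.frame(item = names(sup)[ord], support = unname(sup)[ord],
                       stringsAsFactors = FALSE)
  sel <- tf %in% keep
  degrees <- split(stats::setNames(deg[sel], tid[sel]), tf[sel])[header$item]
  attr(header, "degrees") <- degrees
  attr(header, "N") <- db$N
  class(header) <- c("crm_header", "data.frame")
  header
}

# --- FP-tree node plumbing -------------------------------------------------
# Nodes are environments so that children/parent references form a real tree.
# Each node stores, sparsely, the (transaction index, degree) pairs of the
# transactions routed through it for its own item.

.fp_node <- function(item, parent) {
  n <- new.env(parent = emptyenv())
  n$item <- item
  n$parent <- parent
  n$children <- list()
  n$tids <- integer(0)
  n$degs <- numeric(0)
  n
}

.fp_insert <- function(root, items, degs, tid, links) {
  node <- root
  for (j in seq_along(items)) {
    it <- items[j]
    child <- node$children[[it]]
    if (is.null(child)) {
      child <- .fp_node(it, node)
      node$children[[it]] <- child
      cur <- get0(it, envir = links, ifnotfound = list())
      cur[[length(cur) + 1L]] <- child
      assign(it, cur, envir = links)
    }
    child$tids <- c(child$tids, tid)
    child$degs <- c(child$degs, degs[j])
    node <- child
  }
}

.fp_build <- function(trans, rank) {
  root <- .fp_node(".ROOT", NULL)
  links <- new.env(parent = emptyenv())
  for (tid in seq_along(trans)) {
    items <- trans[[tid]]
    keep <- names(items)[names(items) %in% names(rank)]
    if (!length(keep)) next
    keep <- keep[order(rank[keep])]
    .fp_insert(root, keep, unname(items[keep]), tid, links)
  }
  list(root = root, links = links)
}

#' Build the fuzzy FP-tree
#'
#' Each transaction's frequent items, ordered by header rank, are inserted as
#' a path from the root; transactions sharing their leading frequent items
#' share the upper part of their path. Every traversed node records the
#' transaction's membership degree for that node's item, and per-item node
#' links (in insertion order) are attached to the header table.
#'
#' @param db A `crm_db` object.
#' @param header Header table from [find_frequent_items()].
#' @return A list of class `crm_fptree` with the root node, the node-link
#'   environment and the header.
#' @export
build_fptree <- function(db, header) {
  stopifnot(inherits(db, "crm_db"), inherits(header, "crm_header"))
  rank <- stats::setNames(seq_len(nrow(header)), header$item)
  built <- .fp_build(lapply(db$transactions, `[[`, "items"), rank)
  structure(list(root = built$root, links = built$links, header = header,
                 N = db$N),
            class = "crm_fptree")
}

# Conditional pattern base of one item: for each node carrying the item and
# each transaction routed through it, the ancestor items on the path to the
# root with degrees min-combined against the transaction's degree at this
# node. Vectors are copied out of the tree — upper levels are never mutated,
# so mining can be repeated from the same tree.
.fp_conditional <- function(nodes) {
  out <- list()
  for (node in nodes) {
    path <- list()
    anc <- node$parent
    while (!is.null(anc$parent)) {
      path[[length(path) + 1L]] <- anc
      anc <- anc$parent
    }
    if (!length(path)) next
    items <- vapply(path, function(a) a$item, character(1))
    for (k in seq_along(node$tids)) {
      tid <- node$tids[k]
      d <- node$degs[k]
      adeg <- vapply(path, function(a) a$degs[match(tid, a$tids)], numeric(1))
      cond <- stats::setNames(pmin(d, adeg), items)
      out[[length(out) + 1L]] <- list(tid = tid, items = cond)
    }
  }
  out
}

# Recursive fuzzy FP-growth over (transaction-index, degree) lists. `N` stays
# the global transaction count throughout, so conditional supports are true
# itemset supports of prefix + item.
.fp_mine_rec <- function(trans, N, min_support, prefix, acc) {
  if (!length(trans)) return(acc)
  tf <- unlist(lapply(trans, function(t) names(t$items)), use.names = FALSE)
  deg <- unlist(lapply(trans, function(t) unname(t$items)), use.names = FALSE)
  sup <- vapply(split(deg, tf), sum, numeric(1)) / N
  sup <- sup[sup >= min_support]
  if (!length(sup)) return(acc)
  ord <- order(-sup, names(sup))
  items <- names(sup)[ord]
  rank <- stats::setNames(seq_along(items), items)
  built <- .fp_build(lapply(trans, `[[`, "items"), rank)
  for (it in items) {                      # top-down over the header
    itemset <- sort(c(prefix, it))
    acc[[length(acc) + 1L]] <- list(items = itemset, support = sup[[it]])
    cond <- .fp_conditional(get0(it, envir = built$links, ifnotfound = list()))
    acc <- .fp_mine_rec(cond, N, min_support, itemset, acc)
  }
  acc
}

.itemset_frame <- function(found, min_size) {
  if (length(found)) {
    keep <- vapply(found, function(f) length(f$items), integer(1)) >= min_size
    found <- found[keep]
  }
  if (!length(found)) {
    out <- data.frame(tf_list = character(0), size = integer(0),
                      support = numeric(0), stringsAsFactors = FALSE)
    out$items <- list()
    return(out)
  }
  tf_list <- vapply(found, function(f) paste(f$items, collapse = ","),
                    character(1))
  out <- data.frame(tf_list = tf_list,
                    size = vapply(found, function(f) length(f$items),
                                  integer(1)),
                    support = vapply(found, `[[`, numeric(1), "support"),
                    stringsAsFactors = FALSE)
  out$items <- lapply(found, `[[`, "items")
  out <- out[order(-out$support, out$tf_list), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mine frequent fuzzy itemsets from an FP-tree
#'
#' Extracts every itemset whose fuzzy support — the sigma-count of the
#' minimum t-norm, `sum_t min_i degree_t(i) / N`, with missing items
#' contributing 0 — reaches `min_support`. Header items are processed top
#' down; for each, the tree is walked from its linked nodes towards the root
#' and the per-transaction degree vectors are min-combined into copies, so
#' upper levels are never modified and the traversal can be repeated on the
#' same tree. The minimum t-norm makes support anti-monotone, which prunes
#' the recursion.
#'
#' @param tree A `crm_fptree` from [build_fptree()].
#' @param min_support Minimum fuzzy support in `(0, 1]`.
#' @param min_size Minimum itemset size to report (default 2: single TFs are
#'   not modules).
#' @return A data frame with `tf_list` (comma-joined, lexicographic), `size`,
#'   `support` and a list column `items`, sorted by descending support then
#'   `tf_list`.
#' @export
mine_topdown <- function(tree, min_support, min_size = 2) {
  stopifnot(inherits(tree, "crm_fptree"))
  header <- tree$header
  found <- list()
  for (r in seq_len(nrow(header))) {
    it <- header$item[r]
    found[[length(found) + 1L]] <- list(items = it,
                                        support = header$support[r])
    cond <- .fp_conditional(get0(it, envir = tree$links,
                                 ifnotfound = list()))
    found <- .fp_mine_rec(cond, tree$N, min_support, it, found)
  }
  .itemset_frame(found, min_size)
}

#' Brute-force fuzzy itemset enumeration (reference oracle)
#'
#' Enumerates every subset of the frequent items and computes its support by
#' direct summation of minimum degrees over all transactions. Exponential in
#' the alphabet; refused beyond 20 items. Output matches [mine_topdown()]
#' exactly (same itemsets, same ordering).
#'
#' @inheritParams find_frequent_items
#' @param min_size Minimum itemset size to report.
#' @return Same layout as [mine_topdown()].
#' @export
mine_bruteforce <- function(db, min_support, min_size = 2) {
  stopifnot(inherits(db, "crm_db"))
  if (length(db$alphabet) > 20)
    stop("alphabet larger than 20 items: use build_fptree() + mine_topdown()")
  header <- find_frequent_items(db, max(min_support, 1e-300))
  k <- nrow(header)
  if (k == 0) return(.itemset_frame(list(), min_size))
  items <- sort(header$item)
  M <- matrix(0, nrow = db$N, ncol = k, dimnames = list(NULL, items))
  for (t in seq_len(db$N)) {
    it <- db$transactions[[t]]$items
    it <- it[names(it) %in% items]
    if (length(it)) M[t, names(it)] <- unname(it)
  }
  found <- list()
  for (size in seq_len(k)) {
    for (combo in utils::combn(items, size, simplify = FALSE)) {
      sup <- sum(do.call(pmin, lapply(combo, function(i) M[, i]))) / db$N
      if (sup >= min_support)
        found[[length(found) + 1L]] <- list(items = combo, support = sup)
    }
  }
  .itemset_frame(found, min_size)
}
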