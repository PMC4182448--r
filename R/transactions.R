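#' Membership parameters for cluster-to-transaction conversion
#'
#' Bundles the parameters that control how binding-site clusters become fuzzy
#' transactions: the clustering stop distance and the trapezoidal membership
#' function around each cluster centroid. The trapezoid has a flat core of
#' degree 1 on `[c - a, c + a]` and linear ramps of width `b` on both sides,
#' so membership reaches 0 at distance `a + b` from the centroid `c`.
#'
#' @param cluster_threshold Average-linkage stop distance in bp; merging
#'   continues while the closest pair of clusters is at most this far apart
#'   (inclusive). Default 300 bp, the scale of a typical cis-regulatory
#'   module.
#' @param core_halfwidth Half-width `a` (bp) of the constant-1 core.
#' @param ramp_width Width `b` (bp) of each linear border; must be positive.
#' @param site_anchor Which point of a site is clustered and evaluated by the
#'   membership function: the interval `"midpoint"` (default) or `"start"`.
#' @return An object of class `membership_params`.
#' @export
membership_params <- function(cluster_threshold = 300, core_halfwidth = 150,
                              ramp_width = 100,
                              site_anchor = c("midpoint", "start")) {
  site_anchor <- match.arg(site_anchor)
  if (cluster_threshold <= 0) stop("cluster_threshold must be > 0")
  if (core_halfwidth < 0) stop("core_halfwidth must be >= 0")
  if (ramp_width <= 0) stop("ramp_width must be > 0")
  structure(list(cluster_threshold = cluster_threshold,
                 core_halfwidth = core_halfwidth,
                 ramp_width = ramp_width,
                 site_anchor = site_anchor),
            class = "membership_params")
}

.anchors <- function(sites, params) {
  if (params$site_anchor == "midpoint") (sites$start + sites$end) / 2
  else as.numeric(sites$start)
}

#' Trapezoidal membership function
#'
#' Degree of membership of a position `x` to a cluster centred at `c`:
#' 1 when `|x - c| <= a`, linearly decreasing to 0 over `a < |x - c| <= a + b`,
#' and 0 beyond. Vectorised over `x`.
#'
#' @param x Position(s), bp.
#' @param c Cluster centroid, bp.
#' @param a Core half-width, bp (`>= 0`).
#' @param b Ramp width, bp (`> 0`).
#' @return Membership degree(s) in `[0, 1]`.
#' @examples
#' trapezoid_membership(c(0, 200, 251), c = 0, a = 150, b = 100)
#' @export
trapezoid_membership <- function(x, c, a, b) {
  if (b <= 0) stop("ramp width b must be > 0")
  d <- abs(x - c)
  ifelse(d <= a, 1, ifelse(d <= a + b, (a + b - d) / b, 0))
}

#' Cluster binding sites along each chromosome
#'
#' Agglomerative average-linkage clustering of site anchor positions, run
#' independently per chromosome. In one dimension the average pairwise
#' distance between two contiguous clusters equals the difference of their
#' means, so agglomeration reduces to repeatedly merging the adjacent pair of
#' clusters with the smallest mean difference. Merging continues while that
#' distance is `<= cluster_threshold` (inclusive); among equal-distance
#' candidates the leftmost pair is merged first. Every site ends up in
#' exactly one cluster; singletons are kept.
#'
#' @param sites Binding-site data frame (see [read_tfbs()]).
#' @param params A [membership_params()] object.
#' @return A list of clusters ordered by (chromosome, leftmost anchor); each
#'   has `cluster_id`, `chrom`, `members` (site rows), `anchors` and
#'   `centroid` (median anchor).
#' @export
cluster_sites <- function(sites, params = membership_params()) {
  sites <- validate_sites(sites)
  if (nrow(sites) == 0) return(list())
  anchors <- .anchors(sites, params)
  out <- list()
  for (chrom in sort(unique(sites$chrom))) {
    rows <- which(sites$chrom == chrom)
    ord <- rows[order(anchors[rows])]      # stable: ties keep file order
    a <- anchors[ord]
    groups <- .agglomerate_1d(a, params$cluster_threshold)
    for (g in groups) {
      idx <- ord[g]
      out[[length(out) + 1L]] <- list(
        chrom = chrom,
        members = sites[idx, , drop = FALSE],
        anchors = anchors[idx],
        centroid = stats::median(anchors[idx])
      )
    }
  }
  for (i in seq_along(out)) out[[i]]$cluster_id <- sprintf("C%05d", i)
  out
}

# Average-linkage agglomeration of sorted 1-D positions. Clusters stay
# contiguous, so the candidate merges are always adjacent pairs and the
# linkage distance is the difference of cluster means; which.min() selects
# the leftmost pair among ties.
.agglomerate_1d <- function(a, threshold) {
  k <- length(a)
  groups <- as.list(seq_len(k))
  means <- a
  sizes <- rep(1L, k)
  while (length(groups) > 1L) {
    gaps <- diff(means)
    i <- which.min(gaps)
    if (gaps[i] > threshold) break
    groups[[i]] <- c(groups[[i]], groups[[i + 1L]])
    means[i] <- (means[i] * sizes[i] + means[i + 1L] * sizes[i + 1L]) /
      (sizes[i] + sizes[i + 1L])
    sizes[i] <- sizes[i] + sizes[i + 1L]
    groups[[i + 1L]] <- NULL
    means <- means[-(i + 1L)]
    sizes <- sizes[-(i + 1L)]
  }
  groups
}

.new_db <- function(transactions, alphabet = NULL, params = NULL,
                    mode = "fuzzy", n_empty = 0L) {
  if (is.null(alphabet))
    alphabet <- as.character(sort(unique(unlist(
      lapply(transactions, function(t) names(t$items))))))
  structure(list(transactions = transactions,
                 alphabet = alphabet,
                 N = length(transactions),
                 params = params,
                 mode = mode,
                 n_empty = n_empty),
            class = "crm_db")
}

#' @export
print.crm_db <- function(x, ...) {
  cat(sprintf("Fuzzy transactional database (%s mode)\n", x$mode))
  cat(sprintf("  transactions: %d   TF alphabet: %d", x$N, length(x$alphabet)))
  if (x$n_empty > 0) cat(sprintf("   (plus %d empty clusters dropped)", x$n_empty))
  cat("\n")
  if (x$N > 0) {
    sizes <- vapply(x$transactions, function(t) length(t$items), integer(1))
    cat(sprintf("  items per transaction: mean %.2f, max %d\n",
                mean(sizes), max(sizes)))
  }
  invisible(x)
}

.cluster_to_transaction <- function(cl, degrees) {
  keep <- degrees > 0
  if (!any(keep)) return(NULL)
  mem <- cl$members[keep, , drop = FALSE]
  deg <- degrees[keep]
  items <- vapply(split(deg, mem$tf), max, numeric(1))
  items <- items[order(names(items))]
  pool <- split(seq_len(nrow(mem)), mem$tf)
  site_pool <- lapply(pool, function(i) {
    d <- mem[i, , drop = FALSE]
    d$degree <- deg[i]
    d
  })
  list(chrom = cl$chrom,
       span_start = min(mem$start),
       span_end = max(mem$end),
       items = items,
       site_pool = site_pool)
}

#' Build the fuzzy transactional database
#'
#' Clusters the sites, computes the trapezoidal membership degree of every
#' member site to its cluster (centroid = median anchor; even member counts
#' use the mean of the two middle anchors), and renders each cluster as a
#' fuzzy transaction. A TF appearing through several sites takes the maximum
#' degree; all sites with positive degree are retained in the transaction's
#' site pool for the overlap-aware refit. Clusters whose every site has
#' degree 0 are dropped but counted in the `n_empty` diagnostic.
#'
#' @inheritParams cluster_sites
#' @return A `crm_db` object: ordered transactions, TF alphabet, transaction
#'   count `N`, and the membership parameters used.
#' @export
build_database <- function(sites, params = membership_params()) {
  clusters <- cluster_sites(sites, params)
  a <- params$core_halfwidth; b <- params$ramp_width
  trans <- list(); n_empty <- 0L
  for (cl in clusters) {
    deg <- trapezoid_membership(cl$anchors, cl$centroid, a, b)
    t <- .cluster_to_transaction(cl, deg)
    if (is.null(t)) n_empty <- n_empty + 1L else trans[[length(trans) + 1L]] <- t
  }
  for (i in seq_along(trans)) trans[[i]]$id <- paste0("T", i)
  .new_db(trans, params = params, mode = "fuzzy", n_empty = n_empty)
}

#' Build the crisp baseline database
#'
#' Same clustering as [build_database()], but with hard cluster borders: a
#' site belongs to its cluster (degree exactly 1) if its whole interval lies
#' within `[c - W, c + W]` around the centroid, and is excluded (degree 0)
#' otherwise — a site merely straddling a border does not count. This is the
#' classic crisp counterpart used to quantify what the fuzzy borders add.
#'
#' @inheritParams cluster_sites
#' @param crisp_halfwidth Border half-width `W` in bp. The default,
#'   `core_halfwidth + ramp_width`, makes the crisp window coincide with the
#'   trapezoid's support.
#' @return A `crm_db` object with all membership degrees equal to 1.
#' @export
build_crisp_database <- function(sites, params = membership_params(),
                                 crisp_halfwidth =
                                   params$core_halfwidth + params$ramp_width) {
  clusters <- cluster_sites(sites, params)
  W <- crisp_halfwidth
  trans <- list(); n_empty <- 0L
  for (cl in clusters) {
    inside <- cl$members$start >= cl$centroid - W &
      cl$members$end <= cl$centroid + W
    t <- .cluster_to_transaction(cl, as.numeric(inside))
    if (is.null(t)) n_empty <- n_empty + 1L else trans[[length(trans) + 1L]] <- t
  }
  for (i in seq_along(trans)) trans[[i]]$id <- paste0("T", i)
  db <- .new_db(trans, params = params, mode = "crisp", n_empty = n_empty)
  db$crisp_halfwidth <- W
  db
}
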