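#' Configuration for the synthetic TFBS landscape generator
#'
#' Describes a genome-wide binding-site landscape with known ground truth:
#' a uniform background of sites over a TF alphabet, plus optional planted
#' modules — chosen TF subsets co-occurring within a small window at many
#' loci. The defaults describe the regime used throughout the package's
#' validation: ten 200 kb chromosomes, a 12-TF alphabet and 2000 background
#' sites, which clusters into roughly 1200-1400 transactions at the default
#' 300 bp aggregation threshold.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param tf_alphabet Character vector of TF labels.
#' @param n_background_sites Number of uniformly placed background sites.
#' @param site_length Site length in bp (default 10).
#' @param planted_modules List of modules, each a list with `tfs` (subset of
#'   the alphabet), `n_loci` and `window` (bp within which the module's sites
#'   co-occur around a locus anchor).
#' @param tf_freqs Optional background sampling weights over the alphabet
#'   (default uniform); lets skewed, spurious-itemset-prone frequency
#'   profiles be emulated.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(chrom_lengths =
                               stats::setNames(rep(200000, 10),
                                               paste0("chr", 1:10)),
                             tf_alphabet = paste0("TF", LETTERS[1:12]),
                             n_background_sites = 2000,
                             site_length = 10,
                             planted_modules = list(),
                             tf_freqs = NULL,
                             seed = 1) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be named")
  if (any(chrom_lengths <= site_length))
    stop("chromosomes must be longer than site_length")
  if (anyDuplicated(tf_alphabet)) stop("duplicate TF labels in alphabet")
  for (m in planted_modules) {
    if (!all(c("tfs", "n_loci", "window") %in% names(m)))
      stop("each planted module needs tfs, n_loci and window")
    if (!all(m$tfs %in% tf_alphabet))
      stop("planted TFs must belong to the alphabet")
    if (m$n_loci < 0) stop("n_loci must be >= 0")
    if (m$window < length(m$tfs) * site_length)
      stop("window too small to hold ", length(m$tfs), " disjoint sites")
  }
  if (!is.null(tf_freqs)) {
    if (length(tf_freqs) != length(tf_alphabet) || any(tf_freqs < 0))
      stop("tf_freqs must be non-negative, one per alphabet TF")
  }
  structure(list(chrom_lengths = chrom_lengths, tf_alphabet = tf_alphabet,
                 n_background_sites = n_background_sites,
                 site_length = site_length,
                 planted_modules = planted_modules,
                 tf_freqs = tf_freqs, seed = seed),
            class = "synthetic_config")
}

#' Generate a synthetic TFBS landscape with known ground truth
#'
#' Background sites get TF labels drawn from the alphabet (uniformly, or per
#' `tf_freqs`) and start positions uniform within each chromosome, with
#' chromosomes chosen proportionally to length. For each planted module,
#' locus anchors are drawn uniformly and one site per module TF is placed
#' uniformly within `window/2` of the anchor, re-drawn on overlap with a
#' site of the same locus (up to 1000 attempts, then an error naming the
#' locus). Deterministic given the config seed.
#'
#' @param config A [synthetic_config()] object.
#' @return A list with `sites` (binding-site data frame, background first
#'   then planted loci in order) and `truth`, a data frame with one row per
#'   planted locus (`module`, `locus`, `chrom`, `anchor`, `tfs`).
#' @export
simulate_tfbs <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  L <- config$chrom_lengths
  slen <- config$site_length
  n <- config$n_background_sites
  chrom <- sample(names(L), n, replace = TRUE, prob = L / sum(L))
  start <- floor(stats::runif(n, 0, L[chrom] - slen))
  bg <- .site_df(sample(config$tf_alphabet, n, replace = TRUE,
                        prob = config$tf_freqs),
                 chrom, as.integer(start), as.integer(start + slen),
                 rep(".", n), rep(NA_real_, n))

  planted <- list(); truth <- list()
  half <- function(w) w / 2
  for (mi in seq_along(config$planted_modules)) {
    m <- config$planted_modules[[mi]]
    for (li in seq_len(m$n_loci)) {
      chr <- sample(names(L), 1, prob = L / sum(L))
      anchor <- floor(stats::runif(1, half(m$window),
                                   L[[chr]] - half(m$window)))
      lo <- anchor - half(m$window); hi <- anchor + half(m$window) - slen
      placed <- matrix(numeric(0), ncol = 2)
      for (tf in m$tfs) {
        ok <- FALSE
        for (att in seq_len(1000)) {
          s <- floor(stats::runif(1, lo, hi))
          if (!any(placed[, 1] < s + slen & s < placed[, 2])) {
            placed <- rbind(placed, c(s, s + slen)); ok <- TRUE; break
          }
        }
        if (!ok)
          stop(sprintf("module %d locus %d: could not place %s without overlap after 1000 attempts",
                       mi, li, tf))
      }
      planted[[length(planted) + 1L]] <-
        .site_df(m$tfs, rep(chr, length(m$tfs)),
                 as.integer(placed[, 1]), as.integer(placed[, 2]),
                 rep(".", length(m$tfs)), rep(NA_real_, length(m$tfs)))
      truth[[length(truth) + 1L]] <- data.frame(
        module = mi, locus = li, chrom = chr, anchor = anchor,
        tfs = paste(sort(m$tfs), collapse = ","), stringsAsFactors = FALSE)
    }
  }
  sites <- rbind(bg, if (length(planted)) do.call(rbind, planted))
  rownames(sites) <- NULL
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(module = integer(0), locus = integer(0), chrom = character(0),
               anchor = numeric(0), tfs = character(0),
               stringsAsFactors = FALSE)
  list(sites = sites, truth = truth)
}
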