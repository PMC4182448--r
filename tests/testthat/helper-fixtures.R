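# In-code fixtures: transactional databases and site tables built fresh for
# every test run.

make_transaction <- function(items, id = "T1", chrom = "chr1",
                             span = c(0L, 1000L), site_pool = NULL) {
  items <- items[order(names(items))]
  list(id = id, chrom = chrom, span_start = span[1], span_end = span[2],
       items = items, site_pool = site_pool)
}

make_db <- function(...) {
  trans <- list(...)
  if (length(trans) == 1 && is.list(trans[[1]]) &&
      is.null(trans[[1]]$items)) trans <- trans[[1]]
  for (i in seq_along(trans)) trans[[i]]$id <- paste0("T", i)
  fuzzycrm:::.new_db(trans)
}

# The three-transaction database used throughout the mining unit tests.
toy_db <- function() {
  make_db(make_transaction(c(A = 1.0, B = 0.5)),
          make_transaction(c(A = 0.8, C = 1.0)),
          make_transaction(c(A = 1.0, B = 1.0)))
}

# Random fuzzy database: up to `max_items` TFs, up to `max_n` transactions,
# uniform degrees. Crisp = degrees in {0, 1}.
random_db <- function(seed, max_items = 12, max_n = 200, crisp = FALSE) {
  set.seed(seed)
  k <- sample(2:max_items, 1)
  n <- sample(5:max_n, 1)
  alphabet <- LETTERS[seq_len(k)]
  trans <- lapply(seq_len(n), function(t) {
    m <- sample(1:min(k, 6), 1)
    tfs <- sample(alphabet, m)
    deg <- if (crisp) rep(1, m) else round(stats::runif(m, 0.05, 1), 3)
    make_transaction(stats::setNames(deg, tfs))
  })
  make_db(trans)
}

# Dense degree matrix (transactions x items) of a database; absent items are 0.
db_matrix <- function(db) {
  M <- matrix(0, nrow = db$N, ncol = length(db$alphabet),
              dimnames = list(NULL, db$alphabet))
  for (t in seq_len(db$N)) {
    it <- db$transactions[[t]]$items
    M[t, names(it)] <- unname(it)
  }
  M
}

# Independent support computation straight from the definition.
support_of <- function(db, items) {
  M <- db_matrix(db)
  sum(do.call(pmin, lapply(items, function(i) M[, i]))) / db$N
}

site_row <- function(tf, start, end, degree = NULL, chrom = "chr1") {
  d <- data.frame(tf = tf, chrom = chrom, start = as.integer(start),
                  end = as.integer(end), strand = ".", score = NA_real_,
                  stringsAsFactors = FALSE)
  if (!is.null(degree)) d$degree <- degree
  d
}

# The worked overlap-resolution transaction: A at 0.9 overlapping one B at
# 0.8, an alternative B at 0.6, and a disjoint C at 0.7.
fig_transaction <- function() {
  pool <- list(
    A = site_row("A", 0, 10, 0.9),
    B = rbind(site_row("B", 5, 15, 0.8), site_row("B", 20, 30, 0.6)),
    C = site_row("C", 35, 45, 0.7))
  make_transaction(c(A = 0.9, B = 0.8, C = 0.7), span = c(0L, 45L),
                   site_pool = pool)
}

# Brute-force optimum fit: scan every one-site-per-TF assignment and return
# the best achievable minimum degree (NULL when no disjoint assignment).
fit_oracle <- function(pool, items) {
  grids <- lapply(items, function(tf) seq_len(nrow(pool[[tf]])))
  combos <- expand.grid(grids)
  best <- NULL
  for (r in seq_len(nrow(combos))) {
    rows <- lapply(seq_along(items), function(j)
      pool[[items[j]]][combos[r, j], , drop = FALSE])
    iv <- do.call(rbind, rows)
    ok <- TRUE
    for (i in seq_len(nrow(iv) - 1)) for (j in (i + 1):nrow(iv)) {
      if (iv$start[i] < iv$end[j] && iv$start[j] < iv$end[i]) ok <- FALSE
    }
    if (!ok) next
    m <- min(iv$degree)
    if (is.null(best) || m > best) best <- m
  }
  best
}

# Binomial upper tail by explicit term-by-term summation (oracle for the
# p-value route, independent of pbinom).
tail_sum <- function(k, N, p0) {
  if (k <= 0) return(1)
  j <- k:N
  sum(choose(N, j) * p0^j * (1 - p0)^(N - j))
}

# Random sites on a handful of chromosomes, some deliberately overlapping.
random_sites <- function(seed, n = 120, tfs = LETTERS[1:6]) {
  set.seed(seed)
  chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
  start <- sample.int(50000, n)
  len <- sample(8:30, n, replace = TRUE)
  data.frame(tf = sample(tfs, n, replace = TRUE), chrom = chrom,
             start = start, end = start + len, strand = ".",
             score = NA_real_, stringsAsFactors = FALSE)
}

# Synthetic configuration used by the recovery experiments: the package's
# documented study conditions.
recovery_config <- function(seed, planted = TRUE) {
  synthetic_config(
    planted_modules = if (planted)
      list(list(tfs = c("TFA", "TFB", "TFC"), n_loci = 50, window = 150))
    else list(),
    seed = seed)
}
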