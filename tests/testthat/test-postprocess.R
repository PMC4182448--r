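test_that("the worked overlap example fits at degree 0.6", {
  tr <- fig_transaction()
  fit <- fit_itemset(tr, c("A", "B", "C"))
  expect_equal(fit$fit_degree, 0.6)
  expect_equal(fit$chosen$start[fit$chosen$tf == "B"], 20L)  # alternative B
  expect_equal(fit$fit_degree,
               fit_oracle(tr$site_pool, c("A", "B", "C")))
  expect_equal(fit$start, 0L)
  expect_equal(fit$end, 45L)
})

test_that("infeasible and unconstrained fits behave as specified", {
  tr <- fig_transaction()
  expect_null(fit_itemset(tr, c("A", "B", "Z")))   # Z absent
  # all candidates mutually disjoint: degree is the unconstrained minimum
  pool <- list(A = site_row("A", 0, 10, 0.9),
               B = site_row("B", 20, 30, 0.8),
               C = site_row("C", 40, 50, 0.7))
  tr2 <- make_transaction(c(A = 0.9, B = 0.8, C = 0.7), site_pool = pool)
  expect_equal(fit_itemset(tr2, c("A", "B", "C"))$fit_degree, 0.7)
  # abutting half-open intervals do not overlap
  pool3 <- list(A = site_row("A", 0, 10, 1), B = site_row("B", 10, 20, 1))
  tr3 <- make_transaction(c(A = 1, B = 1), site_pool = pool3)
  expect_equal(fit_itemset(tr3, c("A", "B"))$fit_degree, 1)
  # fully blocked: every B overlaps the only A
  pool4 <- list(A = site_row("A", 0, 30, 1),
                B = rbind(site_row("B", 5, 15, 1), site_row("B", 20, 29, 1)))
  tr4 <- make_transaction(c(A = 1, B = 1), site_pool = pool4)
  expect_null(fit_itemset(tr4, c("A", "B")))
})

test_that("branch-and-bound finds the exact optimum on random transactions", {
  for (seed in 1:25) {
    set.seed(seed)
    tfs <- c("A", "B", "C")[seq_len(sample(2:3, 1))]
    pool <- lapply(tfs, function(tf) {
      n <- sample(1:4, 1)
      start <- sample.int(60, n)
      site_row(rep(tf, n), start, start + sample(5:20, n, replace = TRUE),
               round(stats::runif(n, 0.1, 1), 3))
    })
    names(pool) <- tfs
    items <- stats::setNames(vapply(pool, function(p) max(p$degree),
                                    numeric(1)), tfs)
    tr <- make_transaction(items, site_pool = pool)
    fit <- fit_itemset(tr, tfs)
    want <- fit_oracle(pool, tfs)
    if (is.null(want)) {
      expect_null(fit)
    } else {
      expect_equal(fit$fit_degree, want)
      # chosen sites are pairwise disjoint
      iv <- fit$chosen[order(fit$chosen$start), ]
      if (nrow(iv) > 1)
        expect_true(all(iv$end[-nrow(iv)] <= iv$start[-1]))
    }
  }
})

test_that("refitting never raises support and flags drops instead of hiding them", {
  # single-transaction database: postfit equals the worked fit
  db <- make_db(list(fig_transaction()))
  it <- mine_bruteforce(db, 0.1, min_size = 3)
  rf <- refit_all(db, it, min_support = 0.1)
  expect_equal(rf$itemsets$postfit_support, 0.6)
  expect_false(rf$itemsets$postfit_dropped)
  expect_equal(nrow(rf$instances), 1L)

  # random site databases: postfit <= fuzzy support for every itemset,
  # and all emitted instances are internally disjoint
  for (seed in c(4, 11)) {
    sites <- random_sites(seed, n = 150)
    sdb <- build_database(sites, membership_params())
    its <- mine_bruteforce(sdb, 2 / sdb$N, min_size = 2)
    out <- refit_all(sdb, its, min_support = 2 / sdb$N)
    expect_true(all(out$itemsets$postfit_support <=
                      out$itemsets$support + 1e-12))
    expect_true(all(out$instances$fit_degree > 0))
  }

  # itemset infeasible everywhere: zero postfit, zero instances
  pool <- list(A = site_row("A", 0, 30, 1), B = site_row("B", 5, 15, 1))
  db2 <- make_db(list(make_transaction(c(A = 1, B = 1), site_pool = pool)))
  it2 <- mine_bruteforce(db2, 0.5, min_size = 2)
  rf2 <- refit_all(db2, it2, 0.5)
  expect_equal(rf2$itemsets$postfit_support, 0)
  expect_true(rf2$itemsets$postfit_dropped)
  expect_equal(nrow(rf2$instances), 0L)
})

test_that("databases without site provenance refuse to refit", {
  db <- toy_db()
  it <- mine_bruteforce(db, 0.4, min_size = 2)
  expect_error(refit_all(db, it), "site-level")
})

test_that("non-overlapping databases keep their support after refit", {
  # sites spaced so no two overlap anywhere
  set.seed(8)
  start <- seq(0, by = 40, length.out = 60)
  sites <- site_row(sample(c("A", "B", "C"), 60, replace = TRUE),
                    start, start + 10)
  db <- build_database(sites, membership_params())
  its <- mine_bruteforce(db, 1 / db$N, min_size = 2)
  out <- refit_all(db, its, 1 / db$N)
  expect_equal(out$itemsets$postfit_support, out$itemsets$support,
               tolerance = 1e-12)
})
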