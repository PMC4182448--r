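test_that("trapezoid membership has a flat core, linear ramps and bounded support", {
  expect_equal(trapezoid_membership(500, c = 500, a = 150, b = 100), 1)
  expect_equal(trapezoid_membership(700, c = 500, a = 150, b = 100), 0.5)
  expect_equal(trapezoid_membership(751, c = 500, a = 150, b = 100), 0)
  x <- seq(-400, 400, by = 7)
  expect_equal(trapezoid_membership(x, 0, 150, 100),
               trapezoid_membership(-x, 0, 150, 100))   # symmetry
  d <- trapezoid_membership(x, 0, 150, 100)
  expect_true(all(d >= 0 & d <= 1))
  expect_true(all((abs(x) <= 150) == (d == 1)))
})

test_that("average-linkage agglomeration matches hand-executed merges", {
  p <- membership_params(cluster_threshold = 300, site_anchor = "start")
  s1 <- site_row(c("A", "B", "C"), c(100, 150, 500), c(110, 160, 510))
  cl <- cluster_sites(s1, p)
  expect_length(cl, 2)
  expect_equal(sort(cl[[1]]$anchors), c(100, 150))
  expect_equal(cl[[2]]$anchors, 500)

  # ties resolve leftmost-first; the inclusive threshold then merges all
  s2 <- site_row(c("A", "B", "C"), c(0, 200, 400), c(10, 210, 410))
  cl2 <- cluster_sites(s2, p)
  expect_length(cl2, 1)

  s3 <- site_row("A", 1234, 1244)
  cl3 <- cluster_sites(s3, p)
  expect_length(cl3, 1)
  expect_equal(cl3[[1]]$centroid, 1234)
})

test_that("clustering partitions sites and orders clusters by locus", {
  for (seed in c(3, 17, 42)) {
    sites <- random_sites(seed)
    cl <- cluster_sites(sites, membership_params())
    expect_equal(sum(vapply(cl, function(x) nrow(x$members), integer(1))),
                 nrow(sites))
    # cluster anchor ranges never interleave within a chromosome
    for (chr in unique(sites$chrom)) {
      cc <- Filter(function(x) x$chrom == chr, cl)
      lo <- vapply(cc, function(x) min(x$anchors), numeric(1))
      hi <- vapply(cc, function(x) max(x$anchors), numeric(1))
      expect_true(all(diff(lo) > 0))
      expect_true(all(hi[-length(hi)] < lo[-1]))
    }
  }
})

test_that("fuzzy transactions take the median centroid and max per-TF degree", {
  p <- membership_params(site_anchor = "start")
  # even member count: centroid is the mean of the two middle anchors
  s <- site_row(c("A", "A", "B", "C"), c(100, 150, 160, 220),
                c(110, 160, 170, 230))
  db <- build_database(s, p)
  expect_equal(db$N, 1L)
  t1 <- db$transactions[[1]]
  ctr <- stats::median(c(100, 150, 160, 220))   # 155
  expect_equal(unname(t1$items["A"]),
               max(trapezoid_membership(c(100, 150), ctr, 150, 100)))
  expect_equal(nrow(t1$site_pool$A), 2L)   # both A sites kept in the pool
  expect_true(all(unlist(lapply(t1$site_pool, function(x) x$degree)) > 0))
  # items degree equals max over the pool
  for (tf in names(t1$items))
    expect_equal(unname(t1$items[tf]), max(t1$site_pool[[tf]]$degree))
})

test_that("sites with zero membership are excluded and empty clusters counted", {
  p <- membership_params(cluster_threshold = 300, core_halfwidth = 0,
                         ramp_width = 50, site_anchor = "start")
  # two anchors 200 apart merge (<= 300) but both sit 100 bp from the
  # centroid, outside the 50 bp support: the cluster yields no transaction
  s <- site_row(c("A", "B"), c(1000, 1200), c(1010, 1210))
  db <- build_database(s, p)
  expect_equal(db$N, 0L)
  expect_equal(db$n_empty, 1L)
})

test_that("crisp membership requires full containment within the borders", {
  p <- membership_params(site_anchor = "midpoint")
  # three sites, median anchor 500 -> centroid 500, borders [350, 650]
  s <- rbind(site_row("A", 490, 510),          # fully inside
             site_row("X", 495, 505),          # fully inside
             site_row("B", 630, 670))          # straddles c + W = 650
  db <- build_crisp_database(s, p, crisp_halfwidth = 150)
  expect_equal(db$N, 1L)
  expect_equal(db$transactions[[1]]$items, c(A = 1, X = 1))
})

test_that("wide crisp borders dominate fuzzy memberships", {
  for (seed in c(5, 9)) {
    sites <- random_sites(seed)
    p <- membership_params()
    W <- p$core_halfwidth + p$ramp_width + max(sites$end - sites$start)
    fz <- build_database(sites, p)
    cr <- build_crisp_database(sites, p, crisp_halfwidth = W)
    # same clustering: transaction lists align; crisp item sets are supersets
    expect_gte(cr$N, fz$N)
    cr_by_span <- vapply(cr$transactions,
                         function(t) paste0(t$chrom, ":", t$span_start),
                         character(1))
    for (t in fz$transactions) {
      j <- match(paste0(t$chrom, ":", t$span_start), cr_by_span)
      if (is.na(j)) j <- which(vapply(cr$transactions, function(u)
        u$chrom == t$chrom && u$span_start <= t$span_start &&
          u$span_end >= t$span_end, logical(1)))[1]
      expect_false(is.na(j))
      expect_true(all(names(t$items) %in%
                        names(cr$transactions[[j]]$items)))
      expect_true(all(cr$transactions[[j]]$items == 1))
    }
  }
})

test_that("database construction is deterministic", {
  sites <- random_sites(21)
  d1 <- build_database(sites, membership_params())
  d2 <- build_database(sites, membership_params())
  expect_identical(d1, d2)
})
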