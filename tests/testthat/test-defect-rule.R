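# build a category vector placing given codes at chosen (x, y) locations
cat_at <- function(lay, coords, codes) {
  a <- lay$locations[lay$active, ]
  pd_cat <- rep(0L, 52)
  for (i in seq_len(nrow(coords))) {
    j <- which(a$x == coords[i, 1] & a$y == coords[i, 2])
    stopifnot(length(j) == 1)
    pd_cat[j] <- codes[i]
  }
  pd_cat
}

test_that("the cluster criterion requires three contiguous non-edge points with one at <1%", {
  lay <- fx_layout()
  # three mutually contiguous interior points, one at <1%
  tri <- rbind(c(3, 3), c(9, 3), c(3, 9))
  expect_true(glaucomatous_defect(cat_at(lay, tri, c(1, 1, 3)), lay)$is_defect)
  # <0.5% satisfies the <1% requirement (probability nesting)
  expect_true(glaucomatous_defect(cat_at(lay, tri, c(1, 1, 4)), lay)$is_defect)
  # all three merely <5%: no qualifying point
  expect_false(glaucomatous_defect(cat_at(lay, tri, c(1, 1, 1)), lay)$is_defect)
  # two abnormal interior points only
  expect_false(glaucomatous_defect(cat_at(lay, tri[1:2, ], c(3, 3)), lay)$is_defect)
  # a triple in which one point sits on the pattern edge does not qualify
  a <- lay$locations[lay$active, ]
  edge_xy <- a[a$edge & a$y == 15 & a$x == 15, c("x", "y")]
  tri_edge <- rbind(c(9, 9), c(9, 15), as.numeric(edge_xy))
  expect_false(glaucomatous_defect(cat_at(lay, tri_edge, c(3, 1, 1)),
                                   lay)$is_defect)
  # same geometry with the third point interior qualifies
  tri_in <- rbind(c(9, 9), c(9, 15), c(3, 9))
  expect_true(glaucomatous_defect(cat_at(lay, tri_in, c(3, 1, 1)),
                                  lay)$is_defect)
  # the whole field at <0.5% trivially contains a qualifying cluster
  expect_true(glaucomatous_defect(rep(4L, 52), lay)$is_defect)
  expect_error(glaucomatous_defect(rep(NA_integer_, 52), lay))
})

test_that("cluster enumeration matches an independent union-find oracle on random maps", {
  lay <- fx_layout()
  adj <- vf_adjacency(lay)
  a <- lay$locations[lay$active, ]
  set.seed(71)
  for (k in 1:60) {
    pd_cat <- random_pd_cat()
    comps <- enumerate_clusters(pd_cat, lay)
    oracle <- uf_clusters(pd_cat >= 1 & !a$edge, adj)
    expect_identical(length(comps), length(oracle))
    key <- function(sets) sort(vapply(sets, function(s) {
      paste(sort(s), collapse = ",")
    }, character(1)))
    expect_identical(key(comps), key(oracle))
  }
  expect_identical(enumerate_clusters(rep(0L, 52), lay), list())
  # two disjoint pairs come back as two size-2 components
  pairs <- cat_at(lay, rbind(c(3, 3), c(9, 3), c(-9, -9), c(-15, -9)),
                  rep(1L, 4))
  expect_identical(lengths(enumerate_clusters(pairs, lay)), c(2L, 2L))
})

test_that("the defect call equals a brute-force search over connected non-edge triples", {
  lay <- fx_layout()
  adj <- vf_adjacency(lay)
  a <- lay$locations[lay$active, ]
  trip <- combn(52, 3)
  t_adj <- cbind(adj[t(trip[c(1, 2), ])], adj[t(trip[c(1, 3), ])],
                 adj[t(trip[c(2, 3), ])])
  connected3 <- rowSums(t_adj) >= 2  # any two edges connect three nodes
  set.seed(72)
  for (k in 1:200) {
    pd_cat <- random_pd_cat()
    eligible <- pd_cat >= 1 & !a$edge
    ok <- eligible[trip[1, ]] & eligible[trip[2, ]] & eligible[trip[3, ]] &
      connected3 &
      (pd_cat[trip[1, ]] >= 3 | pd_cat[trip[2, ]] >= 3 |
         pd_cat[trip[3, ]] >= 3)
    expect_identical(glaucomatous_defect(pd_cat, lay)$is_defect, any(ok))
  }
})

test_that("worsening any location never flips a defect call to negative", {
  lay <- fx_layout()
  set.seed(73)
  for (k in 1:40) {
    pd_cat <- random_pd_cat()
    before <- glaucomatous_defect(pd_cat, lay)$is_defect
    i <- sample.int(52, 1)
    pd_cat2 <- pd_cat
    pd_cat2[i] <- min(pd_cat2[i] + sample(1:3, 1), 4L)
    after <- glaucomatous_defect(pd_cat2, lay)$is_defect
    if (before) expect_true(after)
  }
})

test_that("the qualifying cluster is connected and reported deterministically", {
  lay <- fx_layout()
  set.seed(74)
  adj <- vf_adjacency(lay)
  for (k in 1:20) {
    pd_cat <- random_pd_cat()
    call <- glaucomatous_defect(pd_cat, lay)
    expect_identical(call$is_defect, length(call$qualifying_cluster) > 0)
    for (cl in call$clusters) {
      if (length(cl) > 1) {
        sub <- adj[cl, cl, drop = FALSE]
        reach <- (diag(length(cl)) + sub) > 0
        for (s in seq_len(length(cl))) reach <- (reach %*% reach) > 0
        expect_true(all(reach))
      }
    }
    # determinism
    call2 <- glaucomatous_defect(pd_cat, lay)
    expect_identical(call, call2)
  }
})

test_that("4-connectivity and hemifield restriction tighten the criterion", {
  lay <- fx_layout()
  # a diagonal-only chain of interior points qualifies under 8- but not
  # 4-connectivity
  diag3 <- cat_at(lay, rbind(c(-3, 3), c(3, 9), c(9, 15)), c(3, 1, 1))
  expect_true(glaucomatous_defect(diag3, lay, connectivity = 8)$is_defect)
  expect_false(glaucomatous_defect(diag3, lay, connectivity = 4)$is_defect)
  # a cluster straddling the horizontal midline splits under the
  # hemifield restriction
  straddle <- cat_at(lay, rbind(c(3, 3), c(3, -3), c(9, 3), c(9, -3)),
                     c(1, 1, 3, 1))
  expect_true(glaucomatous_defect(straddle, lay)$is_defect)
  h <- glaucomatous_defect(straddle, lay, hemifield = TRUE)
  expect_false(h$is_defect)
})
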