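test_that("tree preparation resolves polytomies, sets unit lengths, prunes", {
  bin <- ape::read.tree(text = "((A:2,B:3):1,(C:1,D:1):4);")
  prep <- prepare_tree(bin, seed = 1)
  expect_identical(ape::write.tree(ape::compute.brlen(prep, 1)),
                   ape::write.tree(ape::compute.brlen(bin, 1)))  # topology kept
  expect_true(all(prep$edge.length == 1))

  star <- ape::read.tree(text = "(A,B,C,D);")
  r1 <- prepare_tree(star, seed = 3)
  expect_true(ape::is.binary(r1))
  expect_equal(r1$Nnode, 3L)
  expect_identical(ape::write.tree(prepare_tree(star, seed = 3)),
                   ape::write.tree(r1))                          # seeded

  # a single trichotomy has exactly 3 rooted resolutions; all are reachable
  tri <- ape::read.tree(text = "(A,B,C);")
  valid <- c("((A,B),C)", "((A,C),B)", "((B,C),A)")
  canon <- function(tr) {
    tr$edge.length <- NULL
    lab <- function(n) {
      if (n <= length(tr$tip.label)) return(tr$tip.label[n])
      kids <- sort(vapply(tr$edge[tr$edge[, 1] == n, 2], lab, character(1)))
      paste0("(", paste(kids, collapse = ","), ")")
    }
    lab(length(tr$tip.label) + 1L)
  }
  seen <- unique(vapply(1:30, function(s) canon(prepare_tree(tri, seed = s)),
                        character(1)))
  expect_true(all(seen %in% valid))
  expect_equal(sort(seen), sort(valid))

  expect_error(prepare_tree(bin, species = c("A", "B", "Z")), "Z")
  expect_warning(pr <- prepare_tree(bin, species = c("A", "B", "C")),
                 "pruning")
  expect_identical(sort(pr$tip.label), c("A", "B", "C"))
})

test_that("contrasts match the closed forms of the pruning recursion", {
  cherry <- ape::read.tree(text = "(A:1,B:1);")
  pc <- pic_contrasts(cherry, c(A = 3, B = 1))
  expect_equal(pc$contrast, 2 / sqrt(2), tolerance = 1e-12)   # 1.41421

  tr <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
  pc <- pic_contrasts(tr, c(A = 4, B = 2, C = 0))
  # hand-run pruning: cherry contrast 2/sqrt(2); ancestor value 3 on a branch
  # lengthened to 1 + 1/2, so the root contrast is 3/sqrt(2.5)
  expect_equal(sort(pc$contrast), sort(c(2 / sqrt(2), 3 / sqrt(2.5))),
               tolerance = 1e-12)
  expect_equal(sort(pc$variance), c(2, 2.5), tolerance = 1e-12)

  # constant data: all contrasts zero; S tips give S - 1 contrasts
  tree <- simulate_tree(12, seed = 2)
  pc <- pic_contrasts(tree, setNames(rep(5, 12), tree$tip.label))
  expect_equal(nrow(pc), 11L)
  expect_true(all(abs(pc$contrast) < 1e-12))

  poly <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_error(pic_contrasts(poly, c(A = 1, B = 2, C = 3)), "polytomies")
})

test_that("contrasts are invariant to tip-order permutation of the data", {
  tree <- prepare_tree(simulate_tree(15, seed = 3), seed = 1)
  x <- setNames(rnorm(15), tree$tip.label)
  a <- pic_contrasts(tree, x)
  b <- pic_contrasts(tree, x[sample(names(x))])
  expect_equal(a$contrast, b$contrast, tolerance = 1e-12)
})

test_that("the contrast matrix aligns traits and handles missing species by pruning", {
  tree <- prepare_tree(simulate_tree(10, seed = 4), seed = 1)
  x <- setNames(rnorm(10), tree$tip.label)
  m <- pic_matrix(tree, cbind(t1 = x, t2 = x))
  expect_equal(ncol(m), 2L)
  expect_equal(m[, "t1"], m[, "t2"])   # identical columns, PIC correlation 1
  expect_equal(pic_correlations(m)$r, 1)

  # pruning a missing-data tip == computing on the pre-pruned tree
  x2 <- cbind(t1 = x, t2 = x + rnorm(10))
  x2[3, "t1"] <- NA
  keep <- rownames(x2)[-3]
  m_auto <- pic_matrix(tree, x2)
  m_hand <- pic_matrix(ape::drop.tip(tree, rownames(x2)[3]),
                       x2[keep, ])
  expect_equal(unclass(m_auto), unclass(m_hand), tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_error(pic_matrix(tree, cbind(t1 = c(x[1:3], rep(NA, 7)))),
               "fewer than 4")
})

test_that("tip correlations on an imbalanced tree are inflated relative to contrasts", {
  # caterpillar tree: strong shared ancestry, so independent Brownian traits
  # show spuriously dispersed tip correlations that contrasts remove
  nwk <- Reduce(function(acc, i) sprintf("(%s:1,t%d:1)", acc, i),
                3:24, init = "(t1:1,t2:1)")
  cat_tree <- ape::read.tree(text = paste0(nwk, ";"))
  set.seed(99)
  r_tip <- numeric(80); r_pic <- numeric(80)
  for (i in 1:80) {
    x <- ape::rTraitCont(cat_tree, model = "BM", sigma = 1)
    y <- ape::rTraitCont(cat_tree, model = "BM", sigma = 1)
    r_tip[i] <- cor(x, y)
    m <- pic_matrix(cat_tree, cbind(a = x, b = y))
    r_pic[i] <- pic_correlations(m)$r
  }
  expect_gt(mean(abs(r_tip)), mean(abs(r_pic)))
  expect_lt(abs(mean(r_pic)), 0.1)   # contrasts centred on zero
})
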