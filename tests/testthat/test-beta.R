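test_that("bray-curtis matches hand values and vegan", {
  tb <- make_table(matrix(c(2, 0, 1, 1,
                            0, 2, 1, 3), 4, 2,
                          dimnames = list(paste0("S", 1:4), NULL)))
  d <- bray_curtis(tb)
  expect_equal(d["S1", "S2"], 1)
  expect_equal(d["S3", "S4"], 1 / 3)
  expect_equal(diag(d), setNames(rep(0, 4), paste0("S", 1:4)))

  set.seed(21)
  v <- matrix(rpois(60, 8), 6, 10, dimnames = list(paste0("S", 1:6), NULL))
  tb2 <- make_table(v)
  expect_equal(unname(bray_curtis(tb2)),
               unname(as.matrix(vegan::vegdist(v, "bray"))),
               tolerance = 1e-12)
})

test_that("unweighted unifrac: identity, disjoint star, worked 4-leaf tree", {
  tree4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  v <- matrix(c(1, 1, 0,
                1, 0, 0,
                0, 1, 0,
                0, 0, 1), 3, 4,
              dimnames = list(c("P1", "P2", "P3"), NULL))
  tb <- make_table(v, genera = c("A", "B", "C", "D"))
  d <- unweighted_unifrac(tb, tree4)
  # sample P1 = {A,B}, P2 = {A,C}: unique = B + C + CD-stem = 3,
  # union = A + B + C + AB-stem + CD-stem = 5
  expect_equal(d["P1", "P2"], 3 / 5)
  expect_equal(d["P1", "P1"], 0)

  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  vd <- matrix(c(1, 0, 1, 0, 0, 1, 0, 1), 2, 4,
               dimnames = list(c("Q1", "Q2"), NULL))
  td <- make_table(vd, genera = c("A", "B", "C", "D"))
  expect_equal(unweighted_unifrac(td, star)["Q1", "Q2"], 1)

  # identical presence sets at different depths are at distance zero
  vi <- matrix(c(5, 50, 3, 30, 0, 0, 0, 0), 2, 4,
               dimnames = list(c("R1", "R2"), NULL))
  ti <- make_table(vi, genera = c("A", "B", "C", "D"))
  expect_equal(unweighted_unifrac(ti, tree4)["R1", "R2"], 0)

  # missing taxa are reported by name
  tbad <- make_table(matrix(c(1, 1, 1, 1), 2, 2,
                            dimnames = list(c("S1", "S2"), NULL)),
                     genera = c("A", "Zzz"))
  expect_error(unweighted_unifrac(tbad, tree4), "Zzz")
})

test_that("unifrac stays in [0,1], symmetric, zero diagonal on random data", {
  set.seed(33)
  for (rep in 1:3) {
    labels <- paste0("g", 1:12)
    tree <- generate_tree(labels, seed = rep)
    v <- matrix(rbinom(8 * 12, 1, 0.5) * rpois(8 * 12, 5), 8, 12,
                dimnames = list(paste0("S", 1:8), NULL))
    v[rowSums(v) == 0, 1] <- 1
    tb <- make_table(v, genera = labels)
    d <- unweighted_unifrac(tb, tree)
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, 8))
  }
})

test_that("pcoa: collinear points, centering, distance reconstruction", {
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(paste0("S", 1:3), paste0("S", 1:3)))
  p <- pcoa(d, 3)
  expect_equal(length(p$explained), 1)  # one positive axis
  expect_equal(p$explained[1], 1)
  expect_lt(max(abs(colMeans(p$coordinates))), 1e-10)

  # Euclidean-embeddable input is reconstructed at full rank
  set.seed(4)
  x <- matrix(rnorm(5 * 3), 5, 3, dimnames = list(paste0("S", 1:5), NULL))
  de <- as.matrix(dist(x))
  pe <- pcoa(de, 5)
  rec <- as.matrix(dist(pe$coordinates))
  expect_lt(max(abs(rec - de)), 1e-8)
  expect_error(pcoa(de, 0), "n_axes")
})

test_that("permanova agrees with a brute-force enumeration oracle", {
  set.seed(9)
  x <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("S", 1:4), NULL))
  d <- as.matrix(dist(x))
  md <- two_group_metadata(paste0("S", 1:4), 2)
  res <- permanova(d, md)
  expect_equal(res$mode, "exact")

  # independent brute force: F over all label assignments from first
  # principles
  brute_f <- function(d, g) {
    n <- nrow(d); a <- 2
    sst <- sum(d[upper.tri(d)]^2) / n
    ssw <- 0
    for (lev in unique(g)) {
      i <- which(g == lev)
      ssw <- ssw + sum(d[i, i]^2) / (2 * length(i))
    }
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  gs <- list(c(1, 1, 2, 2), c(1, 2, 1, 2), c(1, 2, 2, 1))
  fobs <- brute_f(d, c(1, 1, 2, 2))
  fall <- vapply(gs, function(g) brute_f(d, g), 0)
  expect_equal(res$pseudo_f, fobs)
  expect_equal(res$p_value, mean(fall >= fobs - 1e-12))
})

test_that("permanova matches vegan::adonis2 F and R2", {
  set.seed(14)
  x <- matrix(rnorm(20 * 4), 20, 4, dimnames = list(paste0("S", 1:20), NULL))
  d <- as.matrix(dist(x))
  md <- two_group_metadata(paste0("S", 1:20), 10)
  res <- permanova(d, md, n_permutations = 99, seed = 5)
  grp <- md$group
  ref <- vegan::adonis2(as.dist(d) ~ grp, permutations = 99)
  expect_equal(res$pseudo_f, ref$F[1], tolerance = 1e-10)
  expect_equal(res$r_squared, ref$R2[1], tolerance = 1e-10)
})

test_that("permanova R2 is invariant to duplicating every sample", {
  set.seed(2)
  x <- matrix(rnorm(8 * 3), 8, 3, dimnames = list(paste0("S", 1:8), NULL))
  d <- as.matrix(dist(x))
  md <- two_group_metadata(paste0("S", 1:8), 4)
  r1 <- permanova(d, md, 99, seed = 1)$r_squared

  d2 <- d[rep(1:8, 2), rep(1:8, 2)]
  ids2 <- paste0("S", 1:16)
  dimnames(d2) <- list(ids2, ids2)
  md2 <- sample_metadata(ids2, rep(md$group, 2))
  r2 <- permanova(d2, md2, 99, seed = 1)$r_squared
  expect_equal(r2, r1, tolerance = 1e-10)
})

test_that("permanova is reproducible under a fixed seed and guards input", {
  set.seed(6)
  x <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(paste0("S", 1:30), NULL))
  d <- as.matrix(dist(x))
  md <- two_group_metadata(paste0("S", 1:30), 15)
  a <- permanova(d, md, 199, seed = 42)
  b <- permanova(d, md, 199, seed = 42)
  expect_identical(a, b)
  expect_gte(a$p_value, 1 / 200)

  mdc <- sample_metadata(paste0("S", 1:30), rep("CT", 30))
  expect_error(permanova(d, mdc, 99, 1), "constant")
})
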