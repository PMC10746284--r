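test_that("perfectly rank-concordant genera form a rho = 1 positive edge", {
  set.seed(51)
  n <- 12
  ids <- paste0("S", seq_len(n))
  base <- sort(runif(n, 0.1, 0.5))
  vb <- cbind(base, runif(n, 0.1, 0.3))
  vb <- cbind(vb, 1 - rowSums(vb))
  rownames(vb) <- ids
  bt <- make_table(vb, genera = c("Bup", "Bnoise", "Brest"),
                   state = "relative")
  vf <- cbind(base + 0.01, 0.99 - base)  # same rank order as Bup
  rownames(vf) <- ids
  ft <- make_table(vf, genera = c("Fup", "Fdown"), kingdom = "fungi",
                   state = "relative")
  net <- build_transkingdom_network(bt, ft, network_params(adjust = "none"))
  e <- net$edges[net$edges$from == "bacteria:Bup" &
                   net$edges$to == "fungi:Fup", ]
  expect_equal(nrow(e), 1)
  expect_equal(e$rho, 1)
  expect_equal(e$sign, "positive")
  expect_error(build_transkingdom_network(
    make_table(vb[1:3, ], genera = c("a", "b", "c"), state = "relative"),
    ft, network_params()), "4 shared samples")
})

test_that("network summary counts and connectedness are as defined", {
  tri <- fake_network(data.frame(from = c("a", "b", "c"),
                                 to = c("b", "c", "a"),
                                 stringsAsFactors = FALSE),
                      kingdoms = c("bacteria", "bacteria", "fungi"))
  s <- summarize_network(tri)
  expect_equal(s$n_nodes, 3)
  expect_equal(s$n_edges, 3)
  expect_equal(s$n_clusters, 1)
  expect_equal(s$relative_connectedness, 1)
  expect_equal(s$fungi_bacteria_ratio, 1 / 2)
  expect_equal(s$n_positive_edges, 3)

  two <- fake_network(data.frame(from = c("a", "c"), to = c("b", "d"),
                                 rho = c(0.9, -0.8),
                                 stringsAsFactors = FALSE))
  s2 <- summarize_network(two)
  expect_equal(s2$n_clusters, 2)
  expect_equal(s2$n_negative_edges, 1)

  empty <- fake_network(data.frame(from = character(0), to = character(0),
                                   stringsAsFactors = FALSE))
  expect_error(summarize_network(empty), "empty network")
})

test_that("null data produce edge counts consistent with the false-positive
           expectation", {
  cfg <- cohort_config(n_per_group = 25, n_bact_genera = 30,
                       n_fung_genera = 15, n_latent = 3,
                       coupling_strength = c(control = 0, affected = 0),
                       fungal_richness_deficit = 0,
                       group_location_shift = 0, seed = 77)
  co <- generate_cohort(cfg)
  net <- build_transkingdom_network(to_relative(co$bacterial_table),
                                    to_relative(co$fungal_table))
  # under independence at n = 50, P(|rho| >= 0.6) is ~1e-6; with ~1000
  # tested pairs and BH on top, more than a couple of edges would signal a
  # construction defect
  expect_lte(nrow(net$edges), 2)
})

test_that("module detection orders components deterministically", {
  g <- fake_network(data.frame(
    from = c("a", "b", "c", "x", "y", "z", "p"),
    to = c("b", "c", "a", "y", "z", "x", "q"),
    stringsAsFactors = FALSE))
  mods <- detect_modules(g, min_size = 3)
  expect_equal(length(mods), 2)  # the dyad p-q is discarded
  expect_equal(mods[[1]], c("a", "b", "c"))
  expect_equal(mods[[2]], c("x", "y", "z"))

  # invariance under node relabeling
  g2 <- fake_network(data.frame(
    from = c("zz_a", "zz_b", "zz_c", "x", "y", "z", "p"),
    to = c("zz_b", "zz_c", "zz_a", "y", "z", "x", "q"),
    stringsAsFactors = FALSE))
  mods2 <- detect_modules(g2, min_size = 3)
  expect_equal(vapply(mods2, length, 0L), vapply(mods, length, 0L))
  expect_true(all(c("zz_a", "zz_b", "zz_c") %in% unlist(mods2)))
})

test_that("module profiles are standardized means of member z-scores", {
  set.seed(61)
  v <- matrix(rpois(8 * 4, 30) + 1, 8, 4,
              dimnames = list(paste0("S", 1:8), NULL))
  v[, 2] <- v[, 1] * 3  # perfectly correlated pair
  tb <- make_table(v, genera = c("m1", "m2", "m3", "m4"))
  pr <- module_profile(c("m1", "m2"), tb)
  expect_lt(abs(mean(pr)), 1e-12)
  expect_equal(cor(pr, v[, 1]), 1)
  expect_equal(cor(pr, v[, 2]), 1)

  single <- module_profile("m3", tb)
  expect_equal(unname(single), as.numeric(scale(v[, 3])))
})

test_that("partial spearman adjusts for the covariate correctly", {
  set.seed(71)
  n <- 40
  a <- rnorm(n)
  b <- 0.8 * a + rnorm(n, 0, 0.4)
  covar <- rnorm(n)
  # constant covariate reduces to plain spearman
  mc <- module_correlation(a, b, rep(1, n))
  expect_equal(mc$partial_rho, cor(a, b, method = "spearman"),
               tolerance = 1e-10)
  # symmetry in the two profiles
  expect_equal(module_correlation(b, a, covar)$partial_rho,
               module_correlation(a, b, covar)$partial_rho)
  expect_error(module_correlation(rep(1, n), b, covar), "constant profile")
  expect_error(module_correlation(a[1:4], b[1:4], covar[1:4]), "at least 5")

  # profile equal to the covariate loses its correlation after adjustment
  rhos <- vapply(1:30, function(i) {
    set.seed(i)
    cv <- rnorm(n)
    noise <- rnorm(n)
    abs(module_correlation(cv, noise, cv)$partial_rho)
  }, 0)
  expect_lt(mean(rhos), 2 / sqrt(n))
})

test_that("network construction is invariant to sample order and writes
           edge lists", {
  co <- generate_cohort(cohort_config(n_per_group = 10, n_bact_genera = 12,
                                      n_fung_genera = 8, n_latent = 3,
                                      seed = 13))
  bt <- to_relative(co$bacterial_table)
  ft <- to_relative(co$fungal_table)
  net <- build_transkingdom_network(bt, ft)
  pm <- sample(nrow(bt$values))
  btp <- bt
  btp$values <- bt$values[pm, ]
  netp <- build_transkingdom_network(btp, ft)
  expect_equal(netp$edges, net$edges)
  expect_equal(netp$nodes, net$nodes)

  path <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, path, graphml = gml)
  el <- read.delim(path)
  expect_equal(nrow(el), nrow(net$edges))
  expect_true(file.exists(gml))
})
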