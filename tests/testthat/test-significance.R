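test_that("positional models partition levels by the base at each index", {
  m <- toy_model(k = 3)
  pos <- build_positional_models(m)
  expect_length(pos, 3L)
  for (p in pos) {
    # complete 3-mer model: each base list holds 4^2 = 16 levels
    expect_true(all(lengths(p$levels) == 16L))
    # partition property: union of the four lists is the full level multiset
    expect_equal(sort(unlist(p$levels, use.names = FALSE)),
                 sort(unname(m$levels)))
  }
  # constructed model where the level encodes the base at index 1
  code <- c(A = 1, C = 2, G = 3, T = 4)
  km <- all_kmers(3)
  m1 <- kmer_model(stats::setNames(code[substring(km, 2, 2)], km))
  p1 <- build_positional_models(m1)[[2]]
  for (b in names(code)) {
    expect_true(all(p1$levels[[b]] == code[[b]]))
  }
})

test_that("histogram similarity behaves like Pearson on shared-bin counts", {
  set.seed(51)
  x <- rnorm(200)
  expect_equal(histogram_similarity(x, x), 1)

  # disjoint supports: strongly negative, equal to brute-force Pearson
  x <- runif(100, 0, 1); y <- runif(100, 9, 10)
  edges <- seq(min(c(x, y)), max(c(x, y)), length.out = 10)
  cx <- tabulate(findInterval(x, edges, rightmost.closed = TRUE,
                              all.inside = TRUE), 9)
  cy <- tabulate(findInterval(y, edges, rightmost.closed = TRUE,
                              all.inside = TRUE), 9)
  expect_equal(histogram_similarity(x, y), cor(cx, cy))
  # two single-bin masses give exactly -1/(n_bins - 1)
  expect_lt(histogram_similarity(x, y), 0)

  # symmetry over random list pairs
  for (i in 1:10) {
    a <- rnorm(50, sample(0:3, 1)); b <- rnorm(50, sample(0:3, 1))
    expect_equal(histogram_similarity(a, b), histogram_similarity(b, a))
  }

  # degenerate shapes define similarity 1 with a warning
  expect_warning(s <- histogram_similarity(rep(1, 5), rep(1, 5)), "degenerate")
  expect_equal(s, 1)
})

test_that("bin-count reading uses one more edge than the default", {
  set.seed(52)
  x <- rnorm(500); y <- rnorm(500, 0.5)
  s_edges <- histogram_similarity(x, y, num_bins = 10)
  s_bins <- histogram_similarity(x, y, num_bins = 9, bins_as_count = TRUE)
  expect_equal(s_edges, s_bins)
})

test_that("significant indices are those whose base identity shifts levels", {
  # level depends only on index 2's base, well separated: the other
  # positions partition the levels into identical multisets (similarity 1)
  km <- all_kmers(4)
  code <- c(A = 0, C = 10, G = 20, T = 30)
  m <- kmer_model(stats::setNames(code[substring(km, 3, 3)], km))
  rep <- significant_indices(m)
  expect_equal(rep$significant_indices, 2L)
  expect_true(all(rep$per_index$mean_similarity[c(1, 2, 4)] >= 1 - 1e-12))
  expect_lt(rep$per_index$mean_similarity[3], 0.5)

  # identical level for every k-mer: no significant index
  mc <- kmer_model(stats::setNames(rep(1, 64), all_kmers(3)))
  rep0 <- suppressWarnings(significant_indices(mc))
  expect_equal(length(rep0$significant_indices), 0L)
  expect_true(all(rep0$per_index$mean_similarity == 1))
})

test_that("weighted positions are detected and unweighted ones are not", {
  # level = sum weights[i] * effect(base_i): zero-weight positions give
  # identical per-base multisets, weighted ones shifted distributions
  for (w in list(c(0, 1.2, 1.5, 1.2, 0), c(1.5, 1.2, 0, 0, 1.2))) {
    m <- positional_kmer_model(5, weights = w)
    rep <- significant_indices(m)
    expect_equal(rep$significant_indices, which(w > 0) - 1L)
    expect_true(all(rep$per_index$mean_similarity[w == 0] >= 1 - 1e-12))
  }
})

test_that("mean similarity is invariant under affine level transforms", {
  m <- positional_kmer_model(4, weights = c(0, 1, 1, 0),
                             level_noise_sd = 0.3, seed = 9)
  r1 <- significant_indices(m)
  m2 <- kmer_model(m$levels * 7.3 - 41, space = m$space)
  r2 <- significant_indices(m2)
  expect_equal(r2$per_index$mean_similarity, r1$per_index$mean_similarity)
})

test_that("model collapsing group-averages parents onto kept positions", {
  # all parents of one child share a level: child inherits it
  km <- all_kmers(3)
  central <- substring(km, 2, 2)
  code <- c(A = 1, C = 2, G = 3, T = 4)
  m <- kmer_model(stats::setNames(code[central], km))
  col <- collapse_model(m, keep_indices = 1L)
  expect_equal(col$k, 1L)
  expect_equal(unname(col$levels[c("A", "C", "G", "T")]), c(1, 2, 3, 4))

  # random model: equals brute-force group means, 4^(k-k') parents each
  m2 <- toy_model(k = 3)
  col2 <- collapse_model(m2, keep_indices = 1L)
  for (b in c("A", "C", "G", "T")) {
    parents <- m2$levels[substring(names(m2$levels), 2, 2) == b]
    expect_length(parents, 16L)
    expect_equal(unname(col2$levels[b]), mean(parents))
  }

  # identity collapse
  expect_equal(collapse_model(m2, 0:2)$levels, m2$levels)

  # non-contiguous indices are ambiguous
  expect_error(collapse_model(m2, c(0L, 2L)), "contiguous")
  expect_error(collapse_model(m2, 5L), "range")
})

test_that("collapsing a model onto its significant span keeps all child indices significant", {
  m <- positional_kmer_model(6, weights = c(0, 0, 1.3, 1.3, 0, 0),
                             level_noise_sd = 0.15, seed = 10)
  parent_rep <- significant_indices(m)
  expect_equal(parent_rep$significant_indices, c(2L, 3L))
  child <- collapse_model(m, keep_indices = 2:3)
  child_rep <- significant_indices(child)
  expect_equal(child_rep$significant_indices, c(0L, 1L))
})

test_that("density profile is the long-format positional partition", {
  m <- toy_model(k = 2)
  d <- density_profile(m)
  expect_equal(nrow(d), 2 * 16)
  expect_equal(sort(unique(d$index)), c(0L, 1L))
  sub <- d[d$index == 0 & d$base == "A", "level"]
  expect_equal(sort(sub),
               sort(unname(m$levels[substring(names(m$levels), 1, 1) == "A"])))
})
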