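test_that("tanimoto follows the set-overlap definition", {
  expect_equal(tanimoto(c(1, 3, 5), c(3, 5, 7)), 0.5)
  expect_equal(tanimoto(c(4, 9), c(4, 9)), 1)
  expect_equal(tanimoto(c(1, 2), c(3, 4)), 0)
  expect_equal(tanimoto(integer(0), integer(0)), 1)
  expect_equal(tanimoto(integer(0), c(1)), 0)
  set.seed(12)
  for (k in 1:25) {
    a <- random_fp(sample(0:40, 1))
    b <- random_fp(sample(1:40, 1))
    got <- tanimoto(a, b)
    expect_equal(got, oracle_tanimoto(a, b))
    expect_equal(got, tanimoto(b, a))
    expect_true(got >= 0 && got <= 1)
  }
})

test_that("snn and intdiv match brute-force oracles on random sets", {
  set.seed(13)
  G <- replicate(12, random_fp(sample(5:40, 1)), simplify = FALSE)
  R <- replicate(17, random_fp(sample(5:40, 1)), simplify = FALSE)
  expect_equal(snn(G, R), oracle_snn(G, R), tolerance = 1e-12)
  expect_equal(intdiv(G, 1), oracle_intdiv(G, 1), tolerance = 1e-12)
  expect_equal(intdiv(G, 2), oracle_intdiv(G, 2), tolerance = 1e-12)
  # G subset of R: every generated molecule has an exact match
  expect_equal(snn(G[1:5], c(G, R)), 1)
  # single generated molecule with known best match
  a <- c(1L, 3L, 5L)
  expect_equal(snn(list(a), list(c(3L, 5L, 7L), c(100L, 200L))), 0.5)
  # diversity closed forms
  expect_equal(intdiv(list(a, a, a), 1), 0)
  expect_equal(intdiv(list(c(1L, 2L), c(3L, 4L)), 1), 0.5)
  expect_equal(intdiv(list(c(1L, 2L), c(3L, 4L)), 2), 1 - sqrt(0.5),
               tolerance = 1e-12)
  expect_error(snn(list(), R), "non-empty")
})

test_that("fragment and scaffold vectors count as stated", {
  toy <- toy_mols()
  benz_tol <- toy[toy$canonical %in% c("c1ccccc1", "Cc1ccccc1"), ]
  sv <- scaffold_vector(benz_tol)
  # both Murcko frameworks are the bare benzene ring
  expect_length(sv, 1)
  expect_equal(unname(sv), 2)
  expect_equal(length(scaffold_vector(toy[0, ])), 0)

  some <- toy[toy$valid, ][25:32, ]
  fv1 <- fragment_vector(some)
  fv2 <- fragment_vector(rbind(some, some))
  expect_equal(fv2[names(fv1)], fv1 * 2)
})

test_that("frequency-vector cosine similarities behave like Frag/Scaff", {
  fg <- c(a = 1, b = 1)
  fr <- c(a = 1, c = 1)
  expect_equal(frag_similarity(fg, fr), 0.5)
  expect_equal(frag_similarity(fg, fg), 1)
  expect_equal(frag_similarity(c(a = 2), c(b = 3)), 0)
  expect_equal(frag_similarity(fg, fr, as_distance = TRUE), 0.5)
  # symmetry against the oracle on random count vectors
  set.seed(14)
  for (k in 1:10) {
    v1 <- setNames(rpois(6, 3) + 1, letters[1:6])
    v2 <- setNames(rpois(6, 3) + 1, letters[4:9])
    expect_equal(frag_similarity(v1, v2), oracle_cosine(v1, v2),
                 tolerance = 1e-12)
    expect_equal(frag_similarity(v1, v2), frag_similarity(v2, v1))
  }
  expect_warning(out <- frag_similarity(c(a = 0), c(a = 1)), "undefined")
  expect_true(is.na(out))
})

test_that("Frechet activation distance matches closed forms", {
  # identical stats
  s1 <- make_stats(c(0, 1), diag(c(1, 2)))
  expect_equal(fcd(s1, s1), 0)
  # 1-D: mean gap with equal variance
  expect_equal(fcd(make_stats(0, 1), make_stats(1, 1)), 1,
               tolerance = 1e-10)
  # 1-D: equal means, variances 1 vs 4 -> 1 + 4 - 2*2 = 1
  expect_equal(fcd(make_stats(0, 1), make_stats(0, 4)), 1,
               tolerance = 1e-10)
  # diagonal case reduces to sums of 1-D closed forms
  a <- make_stats(c(0, 2), diag(c(1, 3)))
  b <- make_stats(c(1, 0), diag(c(4, 3)))
  expect_equal(fcd(a, b),
               oracle_fcd_1d(0, 1, 1, 4) + oracle_fcd_1d(2, 3, 0, 3),
               tolerance = 1e-10)
  # symmetry on random PSD pairs
  set.seed(15)
  for (k in 1:5) {
    m1 <- matrix(rnorm(25), 5); m2 <- matrix(rnorm(25), 5)
    sa <- make_stats(rnorm(5), m1 %*% t(m1))
    sb <- make_stats(rnorm(5), m2 %*% t(m2))
    expect_equal(fcd(sa, sb), fcd(sb, sa), tolerance = 1e-8)
    expect_gte(fcd(sa, sb), 0)
  }
  expect_error(fcd(make_stats(0, -1), make_stats(0, 1)), "semidefinite")
})

test_that("activation statistics match a textbook mean/covariance oracle", {
  toy <- toy_mols()
  mols20 <- toy[toy$valid, ][1:20, ]
  set.seed(16)
  m <- matrix(rnorm(20 * 5), 20, 5)
  provider <- function(mols) m[seq_len(nrow(mols)), , drop = FALSE]
  st <- activation_stats(mols20, provider)
  want <- oracle_mean_cov(m)
  expect_equal(st$mu, want$mu, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unclass(st$sigma), unclass(want$sigma), tolerance = 1e-10,
               ignore_attr = TRUE)
  # duplicated single molecule: zero covariance, and fcd to itself is 0
  dup <- parse_molecules(rep("CCO", 10))
  std <- activation_stats(dup)
  expect_equal(max(abs(std$sigma)), 0)
  both <- activation_stats(mols20)
  expect_equal(fcd(both, both), 0)
  expect_error(activation_stats(mols20[1, ]), "at least 2")
})

test_that("conversion metrics count exactly as specified", {
  src <- parse_molecules(c("C1CCCCC1", "CC1CCCCC1", "OC1CCCCC1",
                           "NC1CCCCC1"))
  spec <- domain_spec("aliphatic_rings")
  # 3 of 4 decode; of the valid ones, 2 are non-identical and land in the
  # target counts {2, 3}
  gen <- c("C1CCC2CCCCC2C1",          # 2 rings, changed -> success
           NA,                        # failure
           "C1CCC(CC1)C1CCCCC1",      # 2 rings, changed -> success
           "NC1CCCCC1")               # identical to its source
  m <- conversion_metrics(src, gen, train_set = character(), spec,
                          "x_to_y")
  expect_equal(m$valid, 0.75)
  expect_equal(m$success_rate, 0.5)
  expect_equal(m$non_identity, 2 / 3)
  expect_equal(m$novelty, 1)
  expect_equal(m$filters, 1)

  # generator that returns every source unchanged
  ident <- conversion_metrics(src, src$canonical, character(), spec,
                              "x_to_y")
  expect_equal(ident$valid, 1)
  expect_equal(ident$non_identity, 0)
  expect_equal(ident$success_rate, 0)

  # mode collapse: all outputs one molecule
  coll <- conversion_metrics(src, rep("C1CCC2CCCCC2C1", 4), character(),
                             spec, "x_to_y")
  expect_equal(coll$uniqueness, 0.25)

  # novelty counts membership of the training set
  nov <- conversion_metrics(src, gen,
                            train_set = "C1CCC2CCCCC2C1", spec, "x_to_y")
  expect_equal(nov$novelty, 2 / 3)

  # ratios are invariant to input order permutation
  perm <- c(3, 1, 4, 2)
  mp <- conversion_metrics(src[perm, ], gen[perm], character(), spec,
                           "x_to_y")
  expect_equal(mp[c("valid", "success_rate", "uniqueness", "novelty")],
               m[c("valid", "success_rate", "uniqueness", "novelty")])

  expect_error(conversion_metrics(src, gen[1:2], character(), spec,
                                  "x_to_y"), "align")
})

test_that("property profile reports MW/logP/SA with sane ranges", {
  eth <- parse_molecule("CCO")
  prof <- property_profile(eth)
  expect_equal(prof$per_molecule$mw, 46.07, tolerance = 0.01)
  toy <- toy_mols()
  pt <- property_profile(toy[toy$valid, ])
  expect_true(all(pt$per_molecule$sa >= 1 & pt$per_molecule$sa <= 10))
  # duplicating the set leaves the mean untouched
  dup <- property_profile(rbind(eth, eth))
  expect_equal(dup$summary$mw[["mean"]], prof$summary$mw[["mean"]])
})

test_that("tanimoto_profile aligns pairs and propagates failures", {
  src <- parse_molecules(c("CCO", "c1ccccc1"))
  tp <- tanimoto_profile(src, c("CCO", NA))
  expect_equal(tp[1], 1)
  expect_true(is.na(tp[2]))
})
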