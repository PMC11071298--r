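test_that("containment handles identity, disjoint and empty cases", {
  a <- modimizer_sketch(c(1, 5, 9, 13), s = 1)
  expect_equal(containment(a, a)$value, 1)
  b <- modimizer_sketch(c(2, 6, 10), s = 1)
  expect_equal(containment(a, b)$value, 0)
  empty <- modimizer_sketch(rep(NA_real_, 5), s = 1)
  expect_warning(est <- containment(empty, a), "empty sketch")
  expect_equal(est$value, 0)
  expect_error(containment(a, modimizer_sketch(c(2, 4), s = 2)),
               "different sparsities")
})

test_that("the bias correction matches the closed form", {
  # A: 8 distinct hashes of which 2 are modimizers at s = 4; all found in B
  av <- c(4, 8, 1, 2, 3, 5, 6, 7)
  bv <- c(av, 12, 16)
  est <- containment(modimizer_sketch(av, 4), modimizer_sketch(bv, 4))
  expect_equal(est$correction, 1 - (1 - 1 / 4)^8)
  expect_equal(est$raw, 2 / (2 * (1 - 0.75^8)))
  expect_equal(est$value, 1)  # clamped
  # huge set: correction indistinguishable from 1, estimate exactly |A∩B|/|A|
  set.seed(3)
  h <- random_hashes(16000)
  ska <- modimizer_sketch(h, 4)
  skb <- modimizer_sketch(h[1:8000], 4)
  est2 <- containment(ska, skb)
  expect_equal(est2$correction, 1 - (1 - 1 / 4)^ska$distinct_count)
  expect_equal(est2$value,
               min(1, est2$intersection_size /
                        (est2$denominator_size * est2$correction)))
})

test_that("ANI inverts containment through the k-mer survival model", {
  expect_equal(ani_from_containment(1, 21), 100)
  expect_equal(ani_from_containment(0, 21), 0)
  expect_equal(ani_from_containment(0.9, 21), 100 * exp(log(0.9) / 21))
  expect_equal(ani_from_containment(c(0, 1, 0.5), 21),
               c(0, 100, 100 * 0.5^(1 / 21)))
})

test_that("interval expansion grows by half-windows and clamps at the ends", {
  expect_equal(expand_interval(100, 200, w = 100, factor = 1, bound = 1000),
               c(50, 250))
  expect_equal(expand_interval(0, 100, w = 100, factor = 1, bound = 1000),
               c(0, 150))
  expect_equal(expand_interval(100, 200, w = 100, factor = 0, bound = 1000),
               c(100, 200))
  expect_equal(expand_interval(900, 1000, w = 100, factor = 2, bound = 1000),
               c(800, 1000))
})

test_that("sketch containment at s = 1 equals brute-force set containment", {
  seq <- random_dna(60000, seed = 21)
  hs <- canonical_hashes(seq, k = 21)
  set.seed(22)
  for (rep in 1:10) {
    a0 <- sample(0:(length(hs$hashes) - 2000), 1)
    b0 <- sample(0:(length(hs$hashes) - 2000), 1)
    ska <- modimizer_sketch(hs$hashes[(a0 + 1):(a0 + 2000)], 1)
    skb <- modimizer_sketch(hs$hashes[(b0 + 1):(b0 + 2000)], 1)
    exact <- brute_containment(substr(seq, a0 + 1, a0 + 2000 + 20),
                               substr(seq, b0 + 1, b0 + 2000 + 20), 21)
    expect_equal(containment(ska, skb)$value, exact)
  }
})

test_that("self cells score 100 and in-register tandem copies score 100", {
  unit <- random_dna(4000, seed = 31)
  rec <- tibble::tibble(name = "tandem", seq = strrep(unit, 3),
                        length = 12000)
  ix <- build_index(rec, w_hat = 4000, m_hat = 500, max_layers = 1)
  expect_equal(cell_identity(ix, 1, 1), 100)
  expect_equal(cell_identity(ix, 1, 2, expansion = 0), 100)
})

test_that("window expansion rescues out-of-register repeats", {
  op <- make_offset_pair(unit_length = 6000, seed = 41)
  ix <- build_index(op$record, w_hat = 6000, m_hat = 1000, max_layers = 1)
  ly <- ix$layers[[1]]
  i <- which(ly$windows$start == op$unit_starts[1])
  j <- which(ly$windows$start <= op$unit_starts[2] &
               ly$windows$end > op$unit_starts[2])
  ani_plain <- cell_identity(ix, i, j, expansion = 0)
  ani_exp <- cell_identity(ix, i, j, expansion = 1)
  expect_lt(ani_plain, 98)
  expect_gt(ani_exp, 99.8)
  # monotone in the expansion factor
  anis <- vapply(c(0, 0.5, 1, 2), function(f) cell_identity(ix, i, j,
                                                            expansion = f),
                 numeric(1))
  expect_true(all(diff(anis) >= 0))
})

test_that("estimator variance grows as the sketch shrinks", {
  ani_for <- function(m_target, rep) {
    a <- random_dna(100000, seed = 500 + rep)
    b <- mutate_substitutions(a, 0.01, seed = 600 + rep)
    s <- 2^floor(log2((100000 - 20) / m_target))
    ska <- modimizer_sketch(canonical_hashes(a, 21)$hashes, s)
    skb <- modimizer_sketch(canonical_hashes(b, 21)$hashes, s)
    ani_from_containment(containment(ska, skb), 21)
  }
  big <- vapply(1:8, function(r) ani_for(1000, r), numeric(1))
  small <- vapply(1:8, function(r) ani_for(100, r), numeric(1))
  expect_gt(sd(small), sd(big))
})
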