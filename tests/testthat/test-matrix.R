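test_that("self matrices are symmetric with a 100% diagonal", {
  hor <- make_hor_array(4, per_copy_substitution_rate = 0.01,
                        flank_length = 2000, seed = 51)
  ix <- build_index(hor$record, w_hat = 1026, m_hat = 500, max_layers = 1)
  m <- self_identity(ix, t = 86)
  expect_s3_class(m, "identity_matrix")
  expect_true(m$self_plot)
  expect_equal(m$values, t(m$values))
  expect_true(all(diag(m$values) == 100))
  nz <- m$values[m$values > 0]
  expect_true(all(nz >= m$t & nz <= 100))
})

test_that("random sequence shows no off-diagonal similarity at t = 80", {
  ix <- build_index(random_dna(200000, seed = 52), w_hat = 4000, m_hat = 1000,
                    max_layers = 1)
  m <- self_identity(ix, t = 80)
  # the first off-diagonal reflects genuine overlap between a window and its
  # expanded neighbor (~50% containment); all farther cells must be empty
  idx <- which(abs(row(m$values) - col(m$values)) > 1)
  expect_true(all(m$values[idx] == 0))
  m0 <- self_identity(ix, t = 80, expansion = 0)
  off <- m0$values
  diag(off) <- 0
  expect_true(all(off == 0))
})

test_that("HOR block identities match the divergence truth table", {
  # windows aligned to copies (no flank), expansion off so each cell compares
  # exactly one copy pair
  hor <- make_hor_array(6, per_copy_substitution_rate = 0.005, seed = 53)
  w <- hor$copies$end[1] - hor$copies$start[1]
  ix <- build_index(hor$record, w_hat = w, m_hat = 1000, max_layers = 1)
  m <- self_identity(ix, t = 90, expansion = 0)
  for (r in seq_len(nrow(hor$truth))) {
    i <- hor$truth$copy_a[r]; j <- hor$truth$copy_b[r]
    expect_lt(abs(m$values[i, j] - hor$truth$expected_ani[r]), 0.3)
  }
})

test_that("comparative matrices recover diagonals for copies and revcomps", {
  x <- random_dna(60000, seed = 54)
  ix <- build_index(x, k = 21, w_hat = 3000, m_hat = 500, max_layers = 1,
                    name = "x")
  iy <- build_index(x, k = 21, w_hat = 3000, m_hat = 500, max_layers = 1,
                    name = "x_copy")
  m <- comparative_identity(ix, iy, t = 86)
  expect_false(m$self_plot)
  expect_true(all(diag(m$values) == 100))
  irc <- build_index(revcomp(x), k = 21, w_hat = 3000, m_hat = 500,
                     max_layers = 1, name = "x_rc")
  mrc <- comparative_identity(ix, irc, t = 86)
  r <- nrow(mrc$values)
  expect_true(all(mrc$values[cbind(1:r, r:1)] > 99.9))
  # unrelated sequences share nothing
  iz <- build_index(random_dna(60000, seed = 55), w_hat = 3000, m_hat = 500,
                    max_layers = 1, name = "z")
  expect_true(all(comparative_identity(ix, iz, t = 80)$values == 0))
})

test_that("indices built under different k or seed are rejected", {
  a <- build_index(random_dna(5000, seed = 1), k = 21, w_hat = 500, m_hat = 100)
  b <- build_index(random_dna(5000, seed = 2), k = 19, w_hat = 500, m_hat = 100)
  expect_error(comparative_identity(a, b), "k differs")
  c2 <- build_index(random_dna(5000, seed = 2), k = 21, w_hat = 500,
                    m_hat = 100, seed = 7)
  expect_error(comparative_identity(a, c2), "seed differs")
})

test_that("viewport queries select layers and agree with full matrices", {
  seq <- random_dna(260000, seed = 56)
  ix <- build_index(seq, w_hat = 1000, m_hat = 200, r_min = 60)
  top <- length(ix$layers) - 1
  full <- self_identity(ix, level = top, t = 86)
  q <- query_identity(ix, region = NULL, display_cells = 60, t = 86)
  expect_equal(q$params$level, top)
  expect_equal(q$values, full$values)
  # half viewport: one level finer
  qh <- query_identity(ix, region = c(0, 130000), display_cells = 60, t = 86)
  expect_equal(qh$params$level, top - 1)
  expect_error(query_identity(ix, region = c(0, 1e7)), "outside")
})

test_that("tidy and glance expose cells and summaries", {
  hor <- make_hor_array(3, seed = 57)
  w <- hor$copies$end[1] - hor$copies$start[1]
  ix <- build_index(hor$record, w_hat = w, m_hat = 500, max_layers = 1)
  m <- self_identity(ix, t = 86)
  td <- tidy(m)
  expect_true(all(c("x_start", "y_start", "identity") %in% names(td)))
  expect_true(all(td$identity >= m$t))
  td_all <- tidy(m, keep_zero = TRUE)
  expect_equal(nrow(td_all), length(m$values))
  gl <- glance(m)
  expect_equal(gl$n_x, nrow(m$values))
  expect_equal(gl$threshold, 86)
})

test_that("region strings parse per the 1-based inclusive convention", {
  r <- parse_region("chrX:1,001-2,000", available = c("chrX", "chrY"))
  expect_equal(r, list(name = "chrX", start = 1000, end = 2000))
  expect_equal(parse_region("chrY")$start, NULL)
  expect_error(parse_region("chrZ:1-10", available = "chrX"), "available")
  expect_error(parse_region("chrX:5-2"), "invalid")
})
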