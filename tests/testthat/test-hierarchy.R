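test_that("layer count follows the doubling rule against minimum resolution", {
  expect_equal(layer_count(250e6, w_hat = 10000, r_min = 1000), 5)
  # exact boundary: 2^(l-1) * w == n / r_min still qualifies
  expect_equal(layer_count(160000 * 1000, w_hat = 10000, r_min = 1000), 5)
  expect_equal(layer_count(160000 * 1000 - 1000, w_hat = 10000, r_min = 1000), 4)
  # coarsening impossible: single layer
  expect_equal(layer_count(5e5, w_hat = 1000, r_min = 1000), 1)
})

test_that("merged layers equal direct sketches where sparsity is nominal", {
  seq <- random_dna(300000, seed = 9)
  ix <- build_index(seq, w_hat = 2000, m_hat = 500, r_min = 10)
  expect_gte(length(ix$layers), 3)
  for (lev in 1:2) {
    ly <- ix$layers[[lev + 1]]
    expect_equal(ly$window_size, 2000 * 2^lev)
    expect_equal(ly$sparsity, ix$s_hat * 2^lev)
    nominal <- which(ly$eff_s == ly$sparsity)
    expect_gt(length(nominal), 0)
    for (j in nominal) {
      direct <- modimizer_sketch(
        ix$stream$hashes[(ly$windows$start[j] + 1):ly$windows$end[j]],
        ly$sparsity)
      expect_identical(ly$sketches[[j]]$hashes, direct$hashes)
      expect_identical(ly$sketches[[j]]$distinct_count, direct$distinct_count)
    }
  }
})

test_that("every parent sketch is contained in the union of its children", {
  seq <- random_dna(150000, seed = 12)
  ix <- build_index(seq, w_hat = 1500, m_hat = 300, r_min = 10)
  for (lev in seq_along(ix$layers)[-1]) {
    child <- ix$layers[[lev - 1]]
    parent <- ix$layers[[lev]]
    for (j in seq_len(parent$r)) {
      kids <- unlist(lapply(
        child$sketches[c(2 * j - 1, min(2 * j, child$r))], `[[`, "hashes"))
      if (parent$eff_s[j] >= parent$sparsity) {
        expect_true(all(parent$sketches[[j]]$hashes %in% kids))
      }
    }
  }
})

test_that("total stored hashes stay within the geometric-series bound", {
  ix <- build_index(random_dna(400000, seed = 5), w_hat = 2000, m_hat = 500,
                    r_min = 10)
  per_layer <- vapply(ix$layers, function(l) {
    sum(vapply(l$sketches, function(s) length(s$hashes), numeric(1)))
  }, numeric(1))
  expect_lte(sum(per_layer), 2 * per_layer[1] + 1000)
})

test_that("short sequences yield a single-layer index with a warning", {
  expect_warning(
    ix <- build_index(random_dna(1500, seed = 2), w_hat = 745, m_hat = 100,
                      r_min = 1),
    "single-layer")
  expect_length(ix$layers, 1)
})

test_that("index save/load round-trips and rejects corrupt files", {
  ix <- build_index(random_dna(5000, seed = 3), w_hat = 500, m_hat = 100)
  path <- tempfile(fileext = ".rds")
  save_index(ix, path)
  expect_equal(load_index(path), ix)
  bad <- tempfile()
  writeLines("not an index", bad)
  expect_error(load_index(bad), "corrupt|not an anidot")
})

test_that("layer selection picks the coarsest layer that fills the display", {
  ix <- build_index(random_dna(260000, seed = 6), w_hat = 1000, m_hat = 200,
                    r_min = 60)
  top <- length(ix$layers) - 1
  expect_gte(top, 2)
  # full sequence at the minimum resolution: coarsest layer qualifies
  expect_equal(select_layer(ix, 260000, 60), top)
  # halving the viewport forces one level finer
  expect_equal(select_layer(ix, 130000, 60), top - 1)
  # tiny viewport: fall back to the finest level
  expect_equal(select_layer(ix, 3000, 60), 0)
})
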