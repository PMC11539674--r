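make_tiny <- function(scores) {
  # scores: matrix over the six bands of tiny_panel()
  p <- tiny_panel()
  colnames(scores) <- p$band
  rownames(scores) <- paste0("A", seq_len(nrow(scores)))
  as_band_tbl(scores)
}

test_that("band frequencies are presence proportions", {
  p <- tiny_panel()
  m <- matrix(0L, 4, 6)
  m[, 1] <- 1L          # fixed present
  m[1:3, 3] <- 1L       # 3 of 4
  x <- make_tiny(m)
  f <- band_frequencies(x, p)
  expect_equal(f$freq, c(1, 0, 0.75, 0, 0, 0))
  expect_equal(band_frequencies(x, p, marker = "M2")$freq, 0.75)
  expect_error(band_frequencies(x, p, marker = "M9"), "unknown marker")
})

test_that("banding patterns are tabulated per marker with frequencies summing to 1", {
  p <- tiny_panel()
  # M1 patterns over 4 accessions: 10, 10, 01, 11
  m <- matrix(0L, 4, 6)
  m[, 1] <- c(1L, 1L, 0L, 1L)
  m[, 2] <- c(0L, 0L, 1L, 1L)
  x <- make_tiny(m)
  ph <- phenotype_frequencies(x, p, marker = "M1")
  expect_equal(ph$pattern, c("01", "10", "11"))
  expect_equal(ph$freq, c(0.25, 0.5, 0.25))

  all_ph <- phenotype_frequencies(x, p)
  sums <- tapply(all_ph$freq, all_ph$marker, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # monomorphic marker: one pattern at frequency 1
  expect_equal(phenotype_frequencies(x, p, marker = "M3")$freq, 1)
})

test_that("allele-class counting honours the frequency threshold", {
  expect_equal(allele_count(1), 1)
  expect_equal(allele_count(c(0.5, 0.25, 0.25)), 3)
  expect_equal(allele_count(c(0.96, 0.02, 0.02), min_freq = 0.05), 1)
  expect_error(allele_count(c(0.5, 0.5), min_freq = 1), "min_freq")
})

test_that("diversity statistics reproduce the published worked examples", {
  # marker with two pattern classes at 0.972/0.028 prints I = 0.13, H = 0.06
  expect_equal(round(shannon_index(c(0.972, 0.028)), 2), 0.13)
  expect_equal(round(diversity_h(c(0.972, 0.028), n = 56), 2), 0.06)
  # two-class PIC at 0.909/0.091 prints 0.15; at 0.891/0.109 prints 0.18
  expect_equal(round(pic_botstein(c(0.909, 0.091)), 2), 0.15)
  expect_equal(round(pic_botstein(c(0.891, 0.109)), 2), 0.18)

  expect_equal(shannon_index(c(0.5, 0.5)), log(2))
  expect_equal(shannon_index(1), 0)
  expect_equal(diversity_h(1, n = 56), 0)
  expect_equal(pic_botstein(1), 0)
  # large-n limit of H for four equal classes is 1 - 4/16 = 0.75
  expect_equal(diversity_h(rep(0.25, 4), n = 1e9), 0.75, tolerance = 1e-8)

  expect_error(diversity_h(c(0.5, 0.5), n = 1), "at least 2")
  expect_error(shannon_index(c(-0.1, 1.1)), "non-negative")
  expect_error(pic_botstein(c(0.5, 0.4)), "sum to 1")
})

test_that("PIC matches the explicit double sum and respects its bounds", {
  set.seed(71)
  for (c_classes in 2:6) {
    for (rep in 1:10) {
      p <- as.vector(stats::rgamma(c_classes, 1))
      p <- p / sum(p)
      expect_equal(pic_botstein(p), bf_pic(p), tolerance = 1e-12)
      expect_gte(pic_botstein(p), 0)
      expect_lte(pic_botstein(p), 1 - sum(p^2))
      expect_lte(1 - sum(p^2), 1 - 1 / c_classes)
      # order invariance
      expect_equal(pic_botstein(sample(p)), pic_botstein(p), tolerance = 1e-12)
      expect_equal(shannon_index(sample(p)), shannon_index(p), tolerance = 1e-12)
    }
  }
})

test_that("Shannon's index is maximized by equal class frequencies", {
  set.seed(72)
  for (c_classes in 2:6) {
    uniform <- shannon_index(rep(1 / c_classes, c_classes))
    expect_equal(uniform, log(c_classes))
    for (rep in 1:10) {
      p <- as.vector(stats::rgamma(c_classes, 1)); p <- p / sum(p)
      expect_lte(shannon_index(p), uniform + 1e-12)
    }
  }
})

test_that("diversity table handles monomorphic and synthetic inputs", {
  p <- tiny_panel()
  ones <- make_tiny(matrix(1L, 5, 6))
  div <- diversity_table(ones, p)
  expect_equal(div$na, rep(1L, 3))
  expect_equal(div$h, rep(0, 3))
  expect_equal(div$i, rep(0, 3))
  expect_equal(div$pic, rep(0, 3))
  expect_equal(glance(div)$polymorphic_bands, 0)

  # recovered band frequencies stay within 3 standard errors of the truth
  panel <- cucumber_panel()
  sim <- simulate_bands(group_sizes = 56, divergence = 0, noise = 0, seed = 9)
  truth <- sim$freqs$freq[sim$freqs$group == 1]
  est <- band_frequencies(sim$matrix, panel)$freq
  se <- sqrt(pmax(truth * (1 - truth), 1e-6) / 56)
  expect_true(all(abs(est - truth) <= pmax(3 * se, 0.05)))

  # monomorphic rows of the packaged survey design: (Na, H, I, PIC) = (1, 0, 0, 0)
  div56 <- diversity_table(sim$matrix, panel)
  mono <- div56[div56$marker %in% cucumber_monomorphic_markers(), ]
  expect_equal(mono$na, rep(1L, 4))
  expect_equal(mono$h + mono$i + mono$pic, rep(0, 4))
})
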