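test_that("triplet and dense readers reproduce their inputs", {
  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 1 3", "1 2 2"), tf)
  m <- read_matrix(tf, "triplet", n = 3)
  expect_equal(m$values, matrix(c(0, 3, 0, 3, 0, 2, 0, 2, 0), 3))

  df <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 5", "5 0"), df)
  expect_equal(read_matrix(df, "dense")$values, matrix(c(0, 5, 5, 0), 2))

  # mirrored duplicates are the same entry: summed once, with a warning
  wf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 1 3", "1 0 2"), wf)
  expect_warning(md <- read_matrix(wf, "triplet", n = 2), "duplicate")
  expect_equal(md$values, matrix(c(0, 5, 5, 0), 2))

  expect_error(read_matrix(tf, "cooler"), "not supported")
  nonsq <- withr::local_tempfile()
  writeLines(c("0 1 2", "3 4 5"), nonsq)
  expect_error(read_matrix(nonsq, "dense"), "square")
  neg <- withr::local_tempfile()
  writeLines("0 1 -3", neg)
  expect_error(read_matrix(neg, "triplet"), "negative")
})

test_that("matrix writers round-trip integer counts bit-exactly", {
  set.seed(11)
  for (fmt in c("dense", "triplet")) {
    m <- contact_matrix(rand_sym_counts(9))
    tf <- withr::local_tempfile(fileext = ".txt")
    write_matrix(m, tf, fmt)
    m2 <- read_matrix(tf, fmt, n = 9)
    expect_identical(m2$values, m$values)
  }
})

test_that("pseudo_bulk sums cells and conserves counts", {
  set.seed(3)
  m <- contact_matrix(rand_sym_counts(6))
  expect_equal(pseudo_bulk(list(m, m))$values, 2 * m$values)
  expect_equal(pseudo_bulk(list(m))$values, m$values)

  cells <- lapply(1:4, function(i) contact_matrix(rand_sym_counts(6)))
  pb <- pseudo_bulk(cells)
  expect_equal(sum(pb$values), sum(vapply(cells, function(c) sum(c$values), 1)))
  expect_equal(pb$n_cells, 4L)
  # order independence
  expect_equal(pseudo_bulk(rev(cells))$values, pb$values)

  expect_error(pseudo_bulk(list()), "empty")
  expect_error(pseudo_bulk(list(m, contact_matrix(rand_sym_counts(5)))),
               "share")
})

test_that("expected_profile averages bands, with edge cases", {
  const <- contact_matrix(matrix(4, 5, 5))
  expect_equal(expected_profile(const)$band_means, rep(4, 5))

  m3 <- contact_matrix(matrix(c(0, 4, 2, 4, 0, 6, 2, 6, 0), 3))
  expect_equal(expected_profile(m3)$band_means, c(0, 5, 2))

  # band n-1 has a single contributing entry
  set.seed(5)
  m <- contact_matrix(rand_sym_counts(7))
  expect_equal(expected_profile(m)$band_means[7], m$values[1, 7])
})

test_that("O/E normalization is self-consistent and guarded", {
  set.seed(8)
  m <- contact_matrix(rand_sym_counts(12, lambda = 6, zero_frac = 0.1))
  oe <- oe_normalize(m, expected_profile(m))
  expect_identical(oe$normalized, "oe")
  for (d in 0:11) {
    i <- seq_len(12 - d)
    band <- oe$values[cbind(i, i + d)]
    if (any(m$values[cbind(i, i + d)] > 0)) {
      expect_equal(mean(band), 1, tolerance = 1e-9)
    } else {
      expect_true(all(band == 0))
    }
  }
  # identity expected leaves the matrix unchanged; symmetry preserved
  ones <- structure(list(band_means = rep(1, 12), source_n_cells = 1L),
                    class = "ExpectedProfile")
  expect_equal(oe_normalize(m, ones)$values, m$values)
  expect_true(isSymmetric(oe$values))
  expect_error(oe_normalize(oe, expected_profile(m)), "already normalized")
})

test_that("bedGraph CpG reader bins by coverage-weighted mean", {
  tf <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t100\t7",          # exactly bin 0
               "chr1\t150\t250\t4",        # half of bin 1, half of bin 2
               "chr1\t300\t350\t2",        # two halves of bin 3
               "chr1\t350\t400\t4"), tf)
  tr <- read_cpg_track(tf, "chr1", resolution = 100, n = 5)
  expect_equal(tr$values, c(7, 4, 4, 3, 0))
  expect_error(read_cpg_track(tf, "chr9", 100, 5), "chr9")
})

test_that("mask_bins removes low-marginal bins and is idempotent", {
  v <- rand_sym_counts(5)
  v[3, ] <- 0; v[, 3] <- 0
  m <- contact_matrix(v)
  expect_equal(mask_bins(m, 0)$mask, rep(TRUE, 5))
  mm <- mask_bins(m, 1)
  expect_equal(which(!mm$mask), 3L)
  expect_equal(mask_bins(mm, 1)$mask, mm$mask)
  expect_error(mask_bins(contact_matrix(matrix(0, 3, 3) + diag(0, 3)), 1),
               "all bins masked")
})

test_that("compartment writers emit bedGraph lines and round-trip tsv", {
  prof <- structure(list(labels = c("A", "B"), ncut_values = c(0.3, -0.2),
                         cpg_corr = 0.5, strength = 2, weak_flag = FALSE,
                         K_used = 1L, seed_list = 1L, chrom = "chr1",
                         resolution = 1e5, bin_start = 0),
                    class = "CompartmentProfile")
  pre <- withr::local_tempfile()
  files <- write_compartments(list(prof), pre, "bedgraph")
  expect_equal(readLines(files[1]),
               c("chr1\t0\t100000\t0.3", "chr1\t100000\t200000\t-0.2"))

  prof2 <- prof
  prof2$labels <- c("B", NA)
  prof2$ncut_values <- c(-0.1, NA)
  tfiles <- write_compartments(list(prof, prof2), pre, "tsv")
  lab <- as.matrix(read.table(tfiles[1], sep = "\t"))
  expect_equal(unname(lab), rbind(c(1, 0), c(0, NA)))
  expect_error(write_compartments(list(), pre), "empty")
})
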