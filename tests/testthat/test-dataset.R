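test_that("spectra_set enforces its invariants", {
  expect_s3_class(toy_set(), "spectra_set")
  m <- matrix(1:12, 3, 4)
  expect_error(spectra_set(m, c(1100, 1102, 1104), 1:3), "wavelength axis")
  expect_error(spectra_set(m, c(1100, 1102, 1102, 1104), 1:3),
               "strictly increasing")
  expect_error(spectra_set(m, c(1100, 1102, 1104, 1106), 1:2), "y length")
  m2 <- m; m2[2, 2] <- NA
  expect_error(spectra_set(m2, c(1100, 1102, 1104, 1106), 1:3), "non-finite")
  expect_error(spectra_set(m, c(1100, 1102, 1104, 1106), 1:3,
                           ids = c("a", "a", "b")), "unique")
})

test_that("delimited round-trip reproduces values exactly", {
  s <- toy_set(3, 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_delimited(s, f)
  s2 <- read_delimited(f)
  expect_identical(s2$spectra, s$spectra)
  expect_identical(s2$y, s$y)
  expect_identical(s2$ids, s$ids)
  expect_equal(s2$wavelengths, s$wavelengths)
  # second round trip is byte-stable
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_delimited(s2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("read_delimited rejects malformed headers and rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,y,1104,1102", "a,1,0.1,0.2"), f)
  expect_error(read_delimited(f), "strictly increasing")
  writeLines(c("sample_id,y,1100,xx", "a,1,0.1,0.2"), f)
  expect_error(read_delimited(f), "non-numeric wavelength")
  writeLines(c("sample_id,1100,1102", "a,0.1,0.2"), f)
  expect_error(read_delimited(f), "missing y column")
})

test_that("align_pair reorders, is idempotent, and rejects mismatches", {
  m <- toy_set(5, 6, seed = 1)
  perm <- c(3, 1, 5, 2, 4)
  s_shuffled <- subset_samples(m, perm)
  pair <- align_pair(m, s_shuffled)
  expect_identical(pair$slave$ids, m$ids)
  expect_identical(pair$slave$spectra, m$spectra)
  # idempotence
  pair2 <- align_pair(pair$master, pair$slave)
  expect_identical(pair2$slave$spectra, pair$slave$spectra)
  # missing id
  expect_error(align_pair(m, subset_samples(m, 1:4)), "pairing error")
  # axis mismatch
  bad <- spectra_set(m$spectra, m$wavelengths + 0.5, m$y, m$ids)
  expect_error(paired_sets(m, bad), "axes differ")
})

test_that("MAT v5 container reader recovers arrays and corn slices", {
  set.seed(3)
  arrs <- list(mp5spec = matrix(rnorm(80), 8, 10),
               mp6spec = matrix(rnorm(80), 8, 10),
               propvals = matrix(runif(32), 8, 4))
  f <- withr::local_tempfile(fileext = ".mat")
  write_mat5_stub(f, arrs)
  got <- read_mat5(f)
  expect_setequal(names(got), names(arrs))
  expect_equal(got$mp5spec, arrs$mp5spec)
  expect_equal(got$propvals, arrs$propvals)

  s5 <- read_corn_container(f, "mp5", "oil")
  expect_equal(dim(s5$spectra), c(8, 10))
  expect_equal(s5$wavelengths[1], 1100)
  expect_equal(diff(s5$wavelengths), rep(2, 9))
  expect_equal(s5$y, arrs$propvals[, 2])   # oil is the 2nd property column
  s6 <- read_corn_container(f, "mp6", "starch")
  expect_equal(s6$wavelengths, s5$wavelengths)
  expect_equal(s6$y, arrs$propvals[, 4])
  expect_error(read_corn_container(f, "mp5", "fat"), "arg")
  expect_error(
    read_corn_container(f, "mp5", "oil",
                        key_map = list(mp5 = "nope", properties = "propvals",
                                       property_order = "oil")),
    "lookup error")
})

test_that("subset_pair keeps both members aligned", {
  g <- small_demo_pair(seed = 2, n = 20, p = 30)
  sub <- subset_pair(g$pair, samples = c(5, 1, 9), wavelengths = 3:12)
  expect_identical(sub$master$ids, g$pair$master$ids[c(5, 1, 9)])
  expect_identical(sub$slave$spectra,
                   g$pair$slave$spectra[c(5, 1, 9), 3:12])
})
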