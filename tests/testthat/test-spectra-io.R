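test_that("SpectralSet construction, accessors and validity", {
  inten <- matrix(runif(15), nrow = 5)
  wl <- seq(400, 500, length.out = 5)
  s <- SpectralSet(inten, wl, classes = c("A", "B", "A"),
                   tablets = c("t1", "t2", "t1"))
  expect_s4_class(s, "SpectralSet")
  expect_equal(wavelengths(s), wl)
  expect_equal(unname(intensities(s)), inten)
  expect_equal(as.character(classLabels(s)), c("A", "B", "A"))
  expect_equal(spectrumClasses(s), c("A", "B"))
  expect_equal(tabletIds(s), c("t1", "t2", "t1"))
  expect_length(shotIndices(s), 3L)

  expect_error(SpectralSet(inten, rev(wl), classes = c("A", "B", "A")),
               "increasing")
  expect_error(SpectralSet(inten, wl[1:3], classes = c("A", "B", "A")),
               "wavelengths")
  expect_error(SpectralSet(inten, wl, classes = c("A", "B")), "one class")
  bad <- inten; bad[2, 2] <- NA
  expect_error(SpectralSet(bad, wl, classes = c("A", "B", "A")), "finite")
})

test_that("write/read round trip preserves values, labels and grouping", {
  # 3 spectra x 5 wavelengths
  inten <- matrix(rnorm(15), nrow = 5)
  wl <- c(370.1, 400, 512.25, 700.5, 1100)
  s <- SpectralSet(inten, wl, classes = c("A", "B", "A"),
                   tablets = c("t1", "t2", "t1"))
  path <- file.path(tempdir(), "tiny.csv")
  writeSpectra(s, path)
  s2 <- readSpectra(path)
  expect_equal(ncol(s2), 3L)
  expect_equal(nrow(s2), 5L)
  expect_identical(unname(intensities(s2)), unname(intensities(s)))
  expect_identical(wavelengths(s2), wl)
  expect_identical(as.character(classLabels(s2)),
                   as.character(classLabels(s)))
  expect_identical(tabletIds(s2), tabletIds(s))
  expect_identical(shotIndices(s2), shotIndices(s))
})

test_that("large synthetic dataset round-trips bitwise", {
  ds <- fxSmallSet()
  path <- file.path(tempdir(), "roundtrip.tsv")
  writeSpectra(ds, path)
  ds2 <- readSpectra(path)
  expect_identical(unname(intensities(ds2)), unname(intensities(ds)))
  expect_identical(spectrumClasses(ds2), spectrumClasses(ds))
  expect_identical(tabletIds(ds2), tabletIds(ds))
})

test_that("reader errors are labeled", {
  inten <- matrix(1:6 + 0.5, nrow = 2)
  s <- SpectralSet(inten, c(400, 500), classes = c("A", "A", "B"))
  path <- file.path(tempdir(), "miss.csv")
  writeSpectra(s, path)
  # drop one manifest row -> error naming the missing id
  man <- read.csv(sub("\\.csv$", "_manifest.csv", path))
  dropped <- man$sample_id[2L]
  write.csv(man[-2L, ], sub("\\.csv$", "_manifest.csv", path),
            row.names = FALSE)
  expect_error(readSpectra(path), dropped, fixed = TRUE)

  # non-monotone wavelength header is rejected
  bad <- file.path(tempdir(), "bad.csv")
  writeLines(c("sample_id,500,400", "s1,1,2"), bad)
  writeLines("sample_id,class,tablet,shot_index\ns1,A,t1,0",
             file.path(tempdir(), "bad_manifest.csv"))
  expect_error(readSpectra(bad), "increasing")
})

test_that("empty dataset writes a header-only file that reads back", {
  s <- SpectralSet(matrix(numeric(), nrow = 3, ncol = 0),
                   c(1, 2, 3), classes = character())
  path <- file.path(tempdir(), "empty.csv")
  writeSpectra(s, path)
  expect_length(readLines(path), 1L)
  s2 <- readSpectra(path)
  expect_equal(ncol(s2), 0L)
  expect_equal(wavelengths(s2), c(1, 2, 3))
})

test_that("inconsistent grids across files are rejected naming the file", {
  dir <- file.path(tempdir(), "multigrid")
  dir.create(dir, showWarnings = FALSE)
  a <- SpectralSet(matrix(1:4 + 0.1, 2), c(400, 500), classes = c("A", "B"))
  b <- SpectralSet(matrix(1:4 + 0.1, 2), c(410, 510), classes = c("A", "B"),
                   sampleIds = c("x1", "x2"))
  writeSpectra(a, file.path(dir, "a.csv"))
  writeSpectra(b, file.path(dir, "b.csv"))
  man <- rbind(read.csv(file.path(dir, "a_manifest.csv")),
               read.csv(file.path(dir, "b_manifest.csv")))
  write.csv(man, file.path(dir, "all_manifest.csv"), row.names = FALSE)
  expect_error(readSpectra(dir, file.path(dir, "all_manifest.csv")),
               "b\\.csv")
})
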