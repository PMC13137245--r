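test_that("CSV and MGF peak lists load and normalize", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("mz,intensity", sprintf("%.3f,%.1f", seq(100, 145, by = 5), 10:1)), csv)
  pl <- read_peaklist(csv)
  expect_equal(nrow(pl$peaks), 10)
  expect_true(all(diff(pl$peaks$mz) > 0))

  # headerless and tab-separated also parse
  tsv <- tempfile(fileext = ".csv")
  writeLines(c("150.1\t3", "120.2\t5"), tsv)
  expect_equal(read_peaklist(tsv)$peaks$mz, c(120.2, 150.1))

  mgf <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=test", "PEPMASS=365.106", "CHARGE=1+",
               "245.06 100", "305.08 5", "END IONS"), mgf)
  pm <- read_peaklist(mgf)
  expect_equal(pm$precursor_mz, 365.106)
  expect_equal(nrow(pm$peaks), 2)

  empty <- tempfile(); file.create(empty)
  expect_error(read_peaklist(empty), "empty")
  bad <- tempfile(fileext = ".csv")
  writeLines(c("mz,intensity", "245.06,100", "oops"), bad)
  expect_error(read_peaklist(bad), "line 3")
})

test_that("peak-list writers round-trip through the readers", {
  sim <- gen_spectrum("Manb1-2Manb-18O1", seed = 7)
  csv <- tempfile(fileext = ".csv"); mgf <- tempfile(fileext = ".mgf")
  write_peaklist_csv(sim$peaklist, csv)
  write_mgf(sim$peaklist, mgf)
  expect_equal(read_peaklist(csv)$peaks$mz, sim$peaklist$peaks$mz, tolerance = 1e-6)
  back <- read_peaklist(mgf)
  expect_equal(back$peaks$mz, sim$peaklist$peaks$mz, tolerance = 1e-6)
  expect_equal(back$precursor_mz, sim$peaklist$precursor_mz, tolerance = 1e-6)
})

test_that("noiseless synthetic spectra annotate completely with no false matches", {
  for (s in c("Manb1-2Manb-18O1", "Manb1-4Manb-18O1", "GlcNAcb1-2Man")) {
    sim <- gen_spectrum(s, seed = 2)
    ann <- annotate(sim$peaklist, s, tol = 0.3)
    expect_true(all(ann$matched), label = s)
    expect_true(all(abs(ann$mass_error) <= 0.3), label = s)
    expect_equal(ann$mz_nominal, sim$truth$mz_nominal, label = s)
  }
})

test_that("annotation flags unmatched peaks and ambiguous assignments", {
  pl <- peaklist(c(247.08, 250.0, 337.10), c(100, 5, 2))
  ann <- annotate(pl, "Manb1-2Manb-18O1", tol = 0.3)
  expect_equal(ann$matched, c(TRUE, FALSE, TRUE))
  expect_equal(ann$tier[1], "major")
  # nominal 307 is reached by several distinct routes -> ambiguity flag
  sp <- predict_spectrum("Manb1-2Manb-18O1")
  mz307 <- sp$mz[sp$mz_nominal == 307]
  a2 <- annotate(peaklist(mz307, 10), "Manb1-2Manb-18O1", tol = 0.3)
  expect_true(a2$ambiguous[1])
})

test_that("linkage recovery is exact on noiseless synthetic spectra", {
  for (s in man_candidates) {
    sim <- gen_spectrum(s, seed = 11)
    res <- infer_linkage(sim$peaklist, man_candidates)
    expect_equal(res$candidate[1], s, label = s)
    expect_false(attr(res, "uninformative"))
    expect_false(attr(res, "mixture_required"))
  }
})

test_that("linkage scores are invariant to uniform intensity rescaling", {
  sim <- gen_spectrum("Manb1-3Manb", seed = 5)
  r1 <- infer_linkage(sim$peaklist, man_candidates)
  scaled <- peaklist(sim$peaklist$peaks$mz, sim$peaklist$peaks$intensity * 1234,
                     precursor_mz = sim$peaklist$precursor_mz)
  r2 <- infer_linkage(scaled, man_candidates)
  expect_equal(r1$score, r2$score)
  expect_equal(r1$candidate, r2$candidate)
})

test_that("minor peaks explained by the mechanisms do not force a mixture call", {
  # dominant loss of 120 with small loss-60/90 companions: a single 1->2
  # structure explains everything
  g <- parse_glycan("Manb1-2Manb")
  sp <- predict_spectrum(g)
  mz <- sp$mz[match(c(245, 275, 305), sp$mz_nominal)]
  pl <- peaklist(mz, c(100, 3, 4), precursor_mz = attr(sp, "precursor_mz"))
  res <- infer_linkage(pl, man_candidates)
  expect_equal(res$candidate[1], "Manb1-2Manb")
  expect_false(attr(res, "mixture_required"))

  # comparable 60/90/120 losses rank the 1->6 candidate first
  sp6 <- predict_spectrum("Manb1-6Manb")
  mz6 <- sp6$mz[match(c(245, 275, 305), sp6$mz_nominal)]
  pl6 <- peaklist(mz6, c(95, 100, 95), precursor_mz = attr(sp6, "precursor_mz"))
  res6 <- infer_linkage(pl6, man_candidates)
  expect_equal(res6$candidate[1], "Manb1-6Manb")
})

test_that("a spectrum without cross-ring peaks is reported uninformative", {
  pl <- peaklist(c(101.3, 166.8), c(10, 5))
  res <- infer_linkage(pl, man_candidates)
  expect_true(attr(res, "uninformative"))
  expect_true(all(is.na(res$score)))
})
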