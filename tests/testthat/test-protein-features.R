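test_that("instability index reproduces the dipeptide-weight formula", {
  ## two residues: II = (10/2) * DIWV(x1, x2)
  expect_equal(instabilityIndex("AC"), 5 * 44.94)
  ## homopolymer of length L: II = 10 * DIWV(x,x) * (L-1) / L
  expect_equal(instabilityIndex("LLLL"), 10 * 1 * 3 / 4)
  expect_equal(instabilityIndex(strrep("W", 10)), 10 * 1 * 9 / 10)
  ## frozen values from an independent implementation of the same published
  ## table (biopython ProtParam)
  expect_equal(instabilityIndex("ACDEFGHIKL"), 99.16, tolerance = 1e-9)
  expect_equal(instabilityIndex("MKDEDERHACYW"), 69.24166666666667,
               tolerance = 1e-9)
  expect_error(instabilityIndex("A"), "at least 2")
  expect_warning(ii <- instabilityIndex("ACXDE"), "skipped")
})

test_that("stability classification uses the conventional threshold of 40", {
  r <- proteinFeatureReport(strrep("LEKLESLKELL", 5))
  expect_equal(r@stabilityClass, if (r@instabilityIndex < 40) "stable" else "unstable")
  expect_equal(r@stabilityClass, "stable")   # II ~ 11 for this repeat
})

test_that("isoelectric point is the unique zero of the net-charge curve", {
  set.seed(31)
  aas <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")
  for (i in 1:25) {
    p <- paste(sample(aas, sample(8:30, 1), replace = TRUE), collapse = "")
    pi <- isoelectricPoint(p)
    expect_lt(abs(netCharge(p, pi)), 1e-3)
    ## monotone: net charge strictly decreasing in pH
    expect_true(all(diff(netCharge(p, seq(1, 13, 0.5))) < 0))
    ## adding an acidic residue (interior, so the terminal pKa assignments
    ## are untouched) never raises the pI
    p2 <- paste0(substr(p, 1, 1), "D", substr(p, 2, nchar(p)))
    expect_lte(isoelectricPoint(p2), pi + 1e-6)
  }
})

test_that("pI matches a fine-grid bisection oracle and a frozen reference", {
  p <- "MKDEDERHACYW"
  grid <- seq(0, 14, by = 1e-3)
  q <- netCharge(p, grid)
  oracle <- grid[which.min(abs(q))]
  expect_equal(isoelectricPoint(p), oracle, tolerance = 2e-3)
  ## frozen biopython value for the same Bjellqvist pKa set
  expect_equal(isoelectricPoint(p), 4.7492, tolerance = 0.01)
  expect_equal(round(isoelectricPoint("DDEE")), 4)
})

test_that("composition bias counts acidic residues", {
  expect_equal(compositionBias("DDEE")$acidicFraction, 1.0)
  expect_equal(compositionBias("KKKK")$acidicFraction, 0.0)
  set.seed(4)
  p <- paste(sample(c("D", "E", "K", "G"), 60, replace = TRUE), collapse = "")
  ch <- strsplit(p, "")[[1]]
  expect_equal(compositionBias(p)$acidicFraction, mean(ch %in% c("D", "E")))
})

test_that("coiled-coil scan calls ideal heptads and ignores poly-proline", {
  heptad <- strrep("LEELKEK", 8)   # L at a/d, E/K elsewhere
  cc <- coiledCoilScan(heptad, window = 28)
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  expect_equal(nrow(cc$regions), 1L)
  expect_gt(cc$regions$peak[1], 0.9)

  pp <- strrep("P", 60)
  expect_equal(nrow(coiledCoilScan(pp)$regions), 0L)

  expect_error(coiledCoilScan(heptad, window = 20), "14, 21, 28")
  expect_error(coiledCoilScan("LEK", window = 14), "shorter")
})

test_that("coiled-coil calls are invariant to poly-glycine padding", {
  heptad <- strrep("LEELKEK", 8)
  pad <- strrep("G", 40)
  cc0 <- coiledCoilScan(heptad)
  cc1 <- coiledCoilScan(paste0(pad, heptad, pad))
  expect_equal(nrow(cc1$regions), 1L)
  expect_equal(cc1$regions$peak, cc0$regions$peak, tolerance = 1e-9)
  ## the called region must cover the repeat, shifted by the pad length,
  ## with boundary slack below one window
  expect_lt(abs(cc1$regions$start - (cc0$regions$start + 40L)), 28L)
  expect_lt(abs(cc1$regions$end - (cc0$regions$end + 40L)), 28L)
})

test_that("domain truncation status is intact/partial/lost by position", {
  fx <- cachedXyr1()
  tr <- truncationReport(fx$domains, 920L, 780L)
  st <- setNames(tr$status, tr$name)
  expect_equal(unname(st["DBD"]), "intact")
  expect_equal(unname(st["FSTFD"]), "intact")
  expect_equal(unname(st["coiled-coil-3"]), "lost")
  expect_equal(unname(st["AAD"]), "partial")
  tr2 <- truncationReport(fx$domains, 920L, 920L)
  expect_true(all(tr2$status == "intact"))
  tr3 <- truncationReport(data.frame(name = "X", start = 700L, end = 800L),
                          920L, 780L)
  expect_equal(tr3$status, "partial")
  expect_error(truncationReport(data.frame(name = "X", start = 1L, end = 950L),
                                920L, 780L), "out of bounds")
})
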