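test_that("each worked logic-gate system has exactly one nonzero atom", {
  cases <- list(
    list(sys = make_copy_system(), atom = "un1->un2"),
    list(sys = make_downward_xor(), atom = "syn->un1"),
    list(sys = make_ppr(), atom = "syn->syn"))
  for (backend in c("mmi", "ccs")) {
    for (cs in cases) {
      fit <- phiid_decompose(cs$sys, backend)
      nz <- nonzero_atoms(fit)
      expect_equal(names(which(nz)), cs$atom)
      expect_equal(unname(fit$atoms[cs$atom]), 1)
      expect_equal(fit$measures$phi_wms, 1)
    }
  }
})

test_that("atoms conserve TDMI and aggregate to the classical measures", {
  set.seed(7)
  fits <- c(
    lapply(1:30, function(i) phiid_decompose(random_discrete(), "mmi")),
    lapply(1:30, function(i) phiid_decompose(random_discrete(), "ccs")),
    lapply(1:30, function(i) phiid_decompose(random_gaussian(), "mmi")))
  for (fit in fits) {
    m <- fit$measures
    expect_lt(abs(sum(fit$atoms) - m$tdmi), 1e-9)
    expect_lt(abs(ais_from_atoms(fit, 1) - m$ais_1), 1e-9)
    expect_lt(abs(ais_from_atoms(fit, 2) - m$ais_2), 1e-9)
    expect_lt(abs(te_from_atoms(fit, 1, 2) - m$te_1to2), 1e-9)
    expect_lt(abs(te_from_atoms(fit, 2, 1) - m$te_2to1), 1e-9)
    # whole-minus-sum as a signed atom aggregate
    agg <- -fit$atoms["red->red"] + fit$atoms["un1->un2"] +
      fit$atoms["un2->un1"] +
      sum(fit$atoms[grep("syn", names(fit$atoms))])
    expect_lt(abs(unname(agg) - m$phi_wms), 1e-9)
    # revised Phi adds the double-redundancy back
    expect_lt(abs(m$phi_r - m$phi_wms - unname(fit$redundancies["red->red"])),
              1e-9)
    # down-set sums reproduce the redundancy table
    lat <- product_lattice(2)
    expect_all_near(sum_downsets(lat, fit$atoms), fit$redundancies, 1e-9)
  }
})

test_that("whole-minus-sum responds to each pure atom with its known sign", {
  expected_sign <- function(label) {
    if (label == "red->red") return(-1)
    if (label %in% c("un1->un2", "un2->un1")) return(1)
    if (grepl("syn", label)) return(1)
    0
  }
  for (label in phiid_atom_labels()) {
    sys <- make_pure_atom_system(label)
    expect_equal(phi_wms(sys), expected_sign(label),
                 tolerance = 1e-10, label = paste("phi_wms at", label))
  }
})

test_that("PPR carries structure invisible to TE and AIS", {
  fit <- phiid_decompose(make_ppr())
  expect_equal(fit$measures$ais_1, 0)
  expect_equal(fit$measures$ais_2, 0)
  expect_equal(fit$measures$te_1to2, 0)
  expect_equal(fit$measures$te_2to1, 0)
  expect_equal(fit$measures$phi_wms, 1)
})

test_that("the global shared bit is negatively integrated by WMS but not by revised Phi", {
  gb <- make_pure_atom_system("red->red")
  expect_equal(phi_wms(gb), -1)
  expect_equal(phi_r(gb, "mmi"), 0)
  expect_equal(phi_r(make_copy_system(), "mmi"), 1)
})

test_that("causal density double-counts broadcast synergy and is corrected", {
  bx <- make_pure_atom_system("syn->red")
  cd <- causal_density(bx)
  expect_equal(cd$ucd, 2)
  expect_equal(cd$cd_corrected, 1)

  copy_cd <- causal_density(make_copy_system())
  expect_equal(copy_cd$ucd, 1)
  expect_equal(copy_cd$cd_corrected, 1)

  indep <- discrete_system(cbind(expand.grid(x1 = 0:1, x2 = 0:1,
                                             y1 = 0:1, y2 = 0:1), p = 1 / 16))
  cd0 <- causal_density(indep)
  expect_equal(cd0$ucd, 0)
  expect_equal(cd0$cd_corrected, 0)
})

test_that("the six taxonomy modes partition the sixteen atoms", {
  expect_equal(sort(unname(unlist(phiid:::TAXONOMY_MODES))),
               sort(phiid_atom_labels()))
  set.seed(13)
  fit <- phiid_decompose(random_discrete())
  modes <- taxonomy_modes(fit)
  expect_named(modes, c("storage", "copy", "transfer", "erasure",
                        "downward", "upward"))
  expect_equal(sum(modes), sum(fit$atoms), tolerance = 1e-12)

  expect_equal(unname(taxonomy_modes(phiid_decompose(make_copy_system()))),
               c(0, 0, 1, 0, 0, 0))
  expect_equal(unname(taxonomy_modes(phiid_decompose(make_downward_xor()))),
               c(0, 0, 0, 0, 1, 0))
  expect_equal(unname(taxonomy_modes(phiid_decompose(make_ppr()))),
               c(1, 0, 0, 0, 0, 0))
})

test_that("duplication shows up in both storage and transfer", {
  dup <- make_pure_atom_system("un1->red")
  fit <- phiid_decompose(dup)
  expect_equal(fit$measures$ais_1, 1)
  expect_equal(fit$measures$te_1to2, 1)
  expect_equal(names(which(nonzero_atoms(fit))), "un1->red")
})

test_that("tidy, glance and autoplot expose the fit in standard shapes", {
  fit <- phiid_decompose(make_downward_xor())
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 16)
  expect_named(td, c("past", "future", "label", "value", "mode"))
  expect_equal(td$value[td$label == "syn->un1"], 1)
  expect_equal(td$mode[td$label == "syn->un1"], "downward")

  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("tdmi", "ais_1", "te_2to1", "phi_wms", "phi_r", "ucd",
                    "cd_corrected", "storage", "downward") %in% names(gl)))
  expect_equal(gl$tdmi, 1)

  expect_s3_class(autoplot(fit), "ggplot")
  rep <- measure_report(fit)
  expect_true(all(c("tdmi", "ais_1", "ais_2", "te_1to2", "te_2to1",
                    "phi_wms", "phi_r", "ucd", "cd_corrected", "storage",
                    "copy", "transfer", "erasure", "downward", "upward",
                    "atoms") %in% names(rep)))
  expect_length(rep$atoms, 16)
})

test_that("decomposition from estimated Gaussian data approaches the analytic one", {
  sys <- make_ar_system(0.4, 0.5)
  x <- simulate_ar(matrix(0.4, 2, 2), matrix(c(1, 0.5, 0.5, 1), 2, 2),
                   3e4, seed = 88)
  est_fit <- phiid(x)
  ana_fit <- phiid_decompose(sys)
  expect_all_near(est_fit$atoms, ana_fit$atoms, 0.03)
})
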