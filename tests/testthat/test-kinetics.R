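test_that("toy model loading and the no-reaction degenerate case", {
  m <- load_model(list(species = c(A = 1, B = 0),
                       reactions = list(list(reactants = c(A = 1),
                                             products = c(B = 1),
                                             rate = 0.1))))
  expect_s3_class(m, "kinetic_model")
  expect_length(m$species, 2)
  expect_length(m$reactions, 1)

  frozen <- kinetic_model(c(X = 2.5, Y = 0.1))
  tr <- simulate_model(frozen, 10, n_points = 11)
  expect_true(all(tr$conc[, "X"] == 2.5))
  expect_true(all(tr$conc[, "Y"] == 0.1))
})

test_that("integration matches closed forms to 1e-5", {
  decay <- kinetic_model(c(A = 1, B = 0),
                         list(list(reactants = c(A = 1), products = c(B = 1),
                                   rate = 0.1)))
  tr <- simulate_model(decay, 10)
  expect_equal(concentration_at(tr, "A", 10), exp(-1), tolerance = 1e-5)
  expect_equal(concentration_at(tr, "B", 10), 1 - exp(-1), tolerance = 1e-5)

  eq <- kinetic_model(c(A = 1, B = 0),
                      list(list(reactants = c(A = 1), products = c(B = 1),
                                rate = 1, reverse_rate = 1)))
  tr2 <- simulate_model(eq, 50)
  expect_equal(concentration_at(tr2, "A", 50), 0.5, tolerance = 1e-5)
  expect_equal(concentration_at(tr2, "B", 50), 0.5, tolerance = 1e-5)
})

test_that("trajectory interpolation is exact on grid and linear between", {
  decay <- kinetic_model(c(A = 1),
                         list(list(reactants = c(A = 1), products = NULL,
                                   rate = 0.2)))
  tr <- simulate_model(decay, 5, n_points = 51)
  expect_equal(concentration_at(tr, "A", 0), 1)
  i <- 10
  mid <- (tr$time[i] + tr$time[i + 1]) / 2
  expect_equal(concentration_at(tr, "A", mid),
               unname(tr$conc[i, "A"] + tr$conc[i + 1, "A"]) / 2)
  withr::local_seed(4)
  ts <- stats::runif(20, 0, 5)
  expect_equal(concentration_at(tr, "A", ts), exp(-0.2 * ts), tolerance = 1e-4)
  expect_error(concentration_at(tr, "Z", 1), "unknown species")
  expect_error(concentration_at(tr, "A", 6), "range")
})

test_that("toy cascade conserves its three moieties and freezes without reactions", {
  m <- toy_cascade_model()
  tr <- simulate_model(m, 100)
  for (pair in list(c("A", "A_P"), c("B", "B_P"), c("C", "C_P"))) {
    total <- rowSums(tr$conc[, pair])
    expect_equal(max(abs(total - 1)), 0, tolerance = 1e-6)
  }
  expect_gte(min(tr$conc), -1e-10)
  frozen <- kinetic_model(m$species)
  tr0 <- simulate_model(frozen, 100, n_points = 11)
  expect_true(all(tr0$conc == rep(m$species, each = 11)))
})

test_that("SBML write-then-load round trips model structure and dynamics", {
  m <- toy_cascade_model()
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, f)
  m2 <- read_sbml(f)
  expect_equal(m2$species[names(m$species)], m$species)
  expect_length(m2$reactions, length(m$reactions))
  tr1 <- simulate_model(m, 20, n_points = 21)
  tr2 <- simulate_model(m2, 20, n_points = 21)
  expect_equal(tr2$conc[, colnames(tr1$conc)], tr1$conc, tolerance = 1e-10)
})

test_that("non-mass-action SBML rate laws are rejected with the reaction name", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="bad"><listOfCompartments><compartment id="c" size="1"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="A" compartment="c" initialConcentration="1"/>',
    '<species id="B" compartment="c" initialConcentration="0"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="mm1" reversible="false">',
    '<listOfReactants><speciesReference species="A"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B"/></listOfProducts>',
    '<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">',
    '<apply><divide/><ci>A</ci><cn>2</cn></apply>',
    '</math></kineticLaw></reaction>',
    '</listOfReactions></model></sbml>'), f)
  expect_error(read_sbml(f), "mm1")
})

test_that("the MAPK cascade reproduces its published time course", {
  m <- load_model(system.file("extdata", "BIOMD0000000009_mapk_cascade.xml",
                              package = "netpharm"))
  expect_equal(unname(m$species["MAPK"]), 1.2)
  tr <- simulate_model(m, 150)
  expect_equal(concentration_at(tr, "MAPK", 1.5), 1.19995, tolerance = 1e-4)
  expect_equal(concentration_at(tr, "MAPK", 150), 0.0010782, tolerance = 1e-3)
  expect_equal(concentration_at(tr, "MAPK_PP", 150), 0.981202, tolerance = 1e-3)
})

test_that("kinase moieties are conserved along the cascade trajectory", {
  m <- mapk_cascade_model()
  tr <- simulate_model(m, 150)
  moieties <- list(
    MAPK = c("MAPK", "MAPK_P", "MAPK_PP", "KKPP_K", "KPase_KP", "KKPP_KP",
             "KPase_KPP"),
    MAPKK = c("MKK", "MKK_P", "MKK_PP", "KKKP_KK", "KKPase_KKP", "KKKP_KKP",
              "KKPase_KKPP", "KKPP_K", "KKPP_KP"),
    MAPKKK = c("MKKK", "MKKK_P", "E1_KKK", "E2_KKKP", "KKKP_KK", "KKKP_KKP"))
  totals <- c(MAPK = 1.2, MAPKK = 1.2, MAPKKK = 3e-3)
  for (nm in names(moieties)) {
    s <- rowSums(tr$conc[, moieties[[nm]]])
    expect_equal(max(abs(s - totals[[nm]])), 0, tolerance = 1e-6)
  }
  # intermediates exist: free plus doubly phosphorylated MAPK undershoots
  # the total MAPK moiety at 150 s
  expect_lt(concentration_at(tr, "MAPK", 150) +
              concentration_at(tr, "MAPK_PP", 150), 1.2)
})

test_that("solver tolerances are converged at the reporting precision", {
  m <- mapk_cascade_model()
  tr1 <- simulate_model(m, 150)
  tr2 <- simulate_model(m, 150, rtol = 1e-9, atol = 1e-11)
  for (sp in c("MAPK", "MAPK_P", "MAPK_PP")) {
    expect_lt(abs(concentration_at(tr1, sp, 150) -
                    concentration_at(tr2, sp, 150)), 1e-4)
  }
  expect_gte(min(tr1$conc), -tr1$atol)
})

test_that("inhibitor injection perturbs nothing at zero on-rate", {
  m <- mapk_cascade_model()
  spec <- inhibition_spec(targets = "MAPK", k_on = 0, k_off = 0)
  mi <- add_inhibitor(m, spec)
  tr0 <- simulate_model(m, 50, n_points = 101)
  tr1 <- simulate_model(mi, 50, n_points = 101)
  for (sp in names(m$species)) {
    expect_equal(tr1$conc[, sp], tr0$conc[, sp], tolerance = 1e-8)
  }
  expect_error(add_inhibitor(m, inhibition_spec(targets = "NOPE",
                                                k_on = 1, k_off = 1)),
               "unknown inhibition target")
})

test_that("free inhibitor plus complexes is conserved at 20 uM", {
  m <- mapk_cascade_model()
  spec <- inhibition_spec(concentration = 20,
                          targets = c("MAPK", "MAPK_P", "MAPK_PP"),
                          k_on = 1, k_off = 6.6255e-4)
  mi <- add_inhibitor(m, spec)
  tr <- simulate_model(mi, 150)
  total <- tr$conc[, "curcumin"] +
    tr$conc[, "MAPK_curcumin"] +
    tr$conc[, "MAPK_P_curcumin"] +
    tr$conc[, "MAPK_PP_curcumin"]
  expect_equal(max(abs(total - 20)), 0, tolerance = 1e-6)
  # sequestration depresses activated MAPK relative to the free-running cascade
  tr0 <- simulate_model(m, 150)
  expect_lt(concentration_at(tr, "MAPK_PP", 150),
            concentration_at(tr0, "MAPK_PP", 150))
})

test_that("irreversible excess binding depletes a lone target", {
  m <- kinetic_model(c(A = 1))
  mi <- add_inhibitor(m, inhibition_spec(name = "I", concentration = 20,
                                         targets = "A", k_on = 100, k_off = 0))
  tr <- simulate_model(mi, 150)
  expect_lt(concentration_at(tr, "A", 150), 1e-6)
  expect_equal(concentration_at(tr, "A_I", 150), 1, tolerance = 1e-5)
})
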