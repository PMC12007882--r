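test_that("reaction and network constructors enforce the model invariants", {
  expect_error(reaction("r", c(A = -1), c(B = 1)), "strictly positive")
  expect_error(reaction("r", c(A = 1), c(B = 1), 5, 1), "lower_bound")
  expect_error(metabolic_network(c("A", "A")), "duplicated")
  expect_error(
    metabolic_network("A", list(reaction("r", c(A = 1), c(Z = 1)))),
    "unknown metabolites")
  expect_error(
    metabolic_network("A", list(), objective = "nope"), "not in the network")
  # shared participant is allowed and net-balanced later
  net <- metabolic_network("A", list(reaction("r", c(A = 2), c(A = 1), 0, 1)))
  expect_identical(unname(net$reactions$r$reactants), 2)
})

test_that("base ids strip the trailing compartment token only when it matches", {
  net <- metabolic_network(
    data.frame(id = c("glc_e", "glc_c", "atp", "x_c"),
               compartment = c("e", "c", "c", "e"),
               stringsAsFactors = FALSE))
  expect_identical(net$metabolites$base_id, c("glc", "glc", "atp", "x_c"))
})

test_that("boundary classification matches the pseudo-reaction taxonomy", {
  net <- metabolic_network(
    data.frame(id = c("A_e", "A_c", "B_c"), compartment = c("e", "c", "c"),
               stringsAsFactors = FALSE),
    list(reaction("EX_A", c(A_e = 1), numeric(), -10, 1000),
         reaction("DM_A", c(A_c = 1), numeric(), 0, 1000),
         reaction("SK_A", c(A_c = 1), numeric(), -5, 5),
         reaction("T_A", c(A_e = 1), c(A_c = 1), 0, 1000),
         reaction("IMP", numeric(), c(B_c = 1), 0, 10)))
  cls <- classify_boundaries(net)
  expect_identical(cls[["EX_A"]], "exchange")
  expect_identical(cls[["DM_A"]], "demand")
  expect_identical(cls[["SK_A"]], "sink")
  expect_identical(cls[["T_A"]], "internal")
  expect_identical(cls[["IMP"]], "internal")
  # productless with several participants: no pattern, stays internal
  net2 <- metabolic_network(
    c("A", "B"),
    list(reaction("ww", c(A = 1, B = 1), numeric(), -1, 1)))
  expect_message(cls2 <- classify_boundaries(net2), "kept internal")
  expect_identical(cls2[["ww"]], "internal")
})

test_that("SBML round trips are lossless for the modelled fields", {
  for (name in c("trap", "fig1_like", "accumulation_chain")) {
    path <- withr::local_tempfile(fileext = ".sbml")
    net <- generate_fixture(name, sbml_path = path)
    back <- read_sbml(path)
    expect_true(networks_equal(net, back), label = paste(name, "round trip"))
    # serialize(parse(serialize(x))) fixpoint
    path2 <- withr::local_tempfile(fileext = ".sbml")
    write_sbml(back, path2)
    expect_true(networks_equal(back, read_sbml(path2)))
  }
  rn <- generate_random_network(8, 10, seed = 4)
  path <- withr::local_tempfile(fileext = ".sbml")
  write_sbml(rn, path)
  expect_true(networks_equal(rn, read_sbml(path)))
})

test_that("SBML parsing handles edge cases and reports malformed input", {
  expect_error(read_sbml("does/not/exist.sbml"), "not found")

  one_species <- '<?xml version="1.0"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
 <model id="m"><listOfCompartments><compartment id="c"/></listOfCompartments>
  <listOfSpecies><species id="A" compartment="c"/></listOfSpecies>
 </model></sbml>'
  p <- withr::local_tempfile(fileext = ".xml")
  writeLines(one_species, p)
  expect_message(net <- read_sbml(p), "no objective")
  expect_identical(nrow(net$metabolites), 1L)
  expect_length(net$reactions, 0)

  # level-2 reversibility flag supplies COBRA default bounds
  l2 <- '<?xml version="1.0"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
 <model id="m"><listOfCompartments><compartment id="c"/></listOfCompartments>
  <listOfSpecies><species id="A" compartment="c"/>
   <species id="B" compartment="c"/></listOfSpecies>
  <listOfReactions>
   <reaction id="r1" reversible="true">
    <listOfReactants><speciesReference species="A"/></listOfReactants>
    <listOfProducts><speciesReference species="B" stoichiometry="2"/></listOfProducts>
   </reaction>
   <reaction id="r2" reversible="false">
    <listOfReactants><speciesReference species="B"/></listOfReactants>
   </reaction>
  </listOfReactions>
 </model></sbml>'
  writeLines(l2, p)
  suppressMessages(net <- read_sbml(p))
  expect_identical(net$reactions$r1$lower_bound, -1000)
  expect_identical(net$reactions$r1$upper_bound, 1000)
  expect_identical(unname(net$reactions$r1$products), 2)
  expect_identical(net$reactions$r2$lower_bound, 0)

  # neither bounds nor reversibility flag: format error naming the reaction
  bad <- sub(' reversible="true"', "", l2, fixed = TRUE)
  writeLines(bad, p)
  expect_error(suppressMessages(read_sbml(p)), "r1")
})

test_that("a multi-reaction objective keeps the heaviest reaction, with warning", {
  fbc <- '<?xml version="1.0"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
 <model id="m">
  <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>
  <listOfSpecies><species id="A" compartment="c"/></listOfSpecies>
  <listOfParameters>
   <parameter id="lb" value="0" constant="true"/>
   <parameter id="ub" value="10" constant="true"/>
  </listOfParameters>
  <listOfReactions>
   <reaction id="r1" reversible="false" fbc:lowerFluxBound="lb" fbc:upperFluxBound="ub">
    <listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>
   </reaction>
   <reaction id="r2" reversible="false" fbc:lowerFluxBound="lb" fbc:upperFluxBound="ub">
    <listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>
   </reaction>
  </listOfReactions>
  <fbc:listOfObjectives fbc:activeObjective="obj">
   <fbc:objective fbc:id="obj" fbc:type="maximize">
    <fbc:listOfFluxObjectives>
     <fbc:fluxObjective fbc:reaction="r1" fbc:coefficient="0.5"/>
     <fbc:fluxObjective fbc:reaction="r2" fbc:coefficient="2"/>
    </fbc:listOfFluxObjectives>
   </fbc:objective>
  </fbc:listOfObjectives>
 </model></sbml>'
  p <- withr::local_tempfile(fileext = ".xml")
  writeLines(fbc, p)
  expect_warning(net <- read_sbml(p), "largest")
  expect_identical(net$objective, "r2")
  expect_identical(
    suppressWarnings(read_sbml(p, objective_override = "r1"))$objective, "r1")
})
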