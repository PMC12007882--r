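test_that("scope propagates along chains and stops at the fixed point", {
  lin <- normalize_network(generate_fixture("linear3"))
  sc <- compute_scope(lin, "A")
  expect_setequal(sc$reachable, c("A", "B", "C"))
  expect_setequal(sc$activated_reactions, c("r1", "r2"))
  # seeding everything is already the fixed point
  all_m <- lin$network$metabolites$id
  expect_setequal(compute_scope(lin, all_m)$reachable, all_m)
  expect_error(compute_scope(lin, "nope"), "unknown seed")
})

test_that("kept imports activate from the first iteration", {
  net <- metabolic_network(
    data.frame(id = c("A_e", "B_c"), compartment = c("e", "c"),
               stringsAsFactors = FALSE),
    list(reaction("EX_A", c(A_e = 1), numeric(), -10, 1000),
         reaction("r", c(A_e = 1), c(B_c = 1), 0, 10)))
  nn <- normalize_network(net, keep_import = TRUE)
  sc <- compute_scope(nn, character())
  expect_setequal(sc$reachable, c("A_e", "B_c"))
})

test_that("scope equals a naive restart-from-scratch recomputation on random networks", {
  withr::local_seed(42)
  for (s in 1:100) {
    net <- generate_random_network(8, 12, seed = s)
    nn <- normalize_network(net)
    mets <- nn$network$metabolites$id
    seeds <- sort(sample(mets, sample(0:4, 1)))
    expect_identical(sort(compute_scope(nn, seeds)$reachable),
                     naive_scope(nn, seeds))
  }
})

test_that("scope is monotone, idempotent at the fixed point, and coefficient-blind", {
  withr::local_seed(7)
  for (s in 1:25) {
    nn <- normalize_network(generate_random_network(8, 12, seed = s))
    mets <- nn$network$metabolites$id
    small <- sort(sample(mets, 2))
    big <- sort(union(small, sample(mets, 3)))
    sc_small <- compute_scope(nn, small)
    sc_big <- compute_scope(nn, big)
    expect_true(all(sc_small$reachable %in% sc_big$reachable))
    # one extra sweep from the fixed point changes nothing
    expect_setequal(compute_scope(nn, sc_small$reachable)$reachable,
                    sc_small$reachable)
    # tripling every stoichiometric coefficient leaves the scope unchanged
    scaled <- nn$network
    scaled$reactions <- lapply(scaled$reactions, function(r) {
      r$reactants <- r$reactants * 3
      r$products <- r$products * 3
      r
    })
    expect_setequal(compute_scope(scaled, small)$reachable,
                    sc_small$reachable)
  }
})

test_that("no-accumulation flags scope metabolites no activated reaction consumes", {
  trap <- normalize_network(generate_fixture("trap"))
  sc <- compute_scope(trap, "A")
  chk <- check_no_accumulation(trap, sc)
  expect_false(chk$ok)
  expect_identical(chk$violators, "C")

  lin <- normalize_network(linear3_with_demand())
  expect_true(check_no_accumulation(lin, compute_scope(lin, "A"))$ok)

  # a seed consumed by nothing is itself an accumulation violation
  iso <- normalize_network(metabolic_network(
    c("A", "B"), list(reaction("r", c(A = 1), c(B = 1), 0, 1))))
  chk2 <- check_no_accumulation(iso, compute_scope(iso, "B"))
  expect_false(chk2$ok)
  expect_identical(chk2$violators, "B")
})

test_that("targets derive from the objective reaction, a list, or the whole network", {
  trap <- normalize_network(generate_fixture("trap"))
  ts <- derive_targets(trap, "target", "DM_T")
  expect_identical(ts$metabolite_targets, "T")
  expect_identical(ts$objective_reaction, "DM_T")
  expect_identical(derive_targets(trap, "target", c("T"))$metabolite_targets,
                   "T")
  lin <- normalize_network(generate_fixture("linear3"))
  expect_setequal(derive_targets(lin, "full_network")$metabolite_targets,
                  c("A", "B", "C"))
  # a reversed objective still resolves through provenance
  rev <- normalize_network(metabolic_network(
    c("F", "G"), list(reaction("OBJ", c(G = 1), c(F = 1), -10, 0))))
  expect_identical(derive_targets(rev, "target", "OBJ")$metabolite_targets,
                   "F")
  # an objective that consumes nothing cannot define targets
  imp <- normalize_network(metabolic_network(
    "A", list(reaction("src", numeric(), c(A = 1), 0, 1))))
  expect_error(derive_targets(imp, "target", "src"), "no reactants")
})

test_that("backward candidates close over producers and match graph reachability", {
  lin <- normalize_network(generate_fixture("linear3"))
  expect_setequal(backward_candidates(lin, "C"), c("A", "B", "C"))
  # a target no reaction produces closes immediately on itself
  trap <- normalize_network(generate_fixture("trap"))
  expect_identical(backward_candidates(trap, "A"), "A")
  for (s in 1:30) {
    nn <- normalize_network(generate_random_network(8, 12, seed = s))
    targets <- sort(sample(nn$network$metabolites$id, 2))
    expect_identical(sort(backward_candidates(nn, targets)),
                     naive_backward(nn, targets))
  }
})

test_that("external metabolites are the never-produced or transport-only-produced reactants", {
  net <- metabolic_network(
    data.frame(id = c("X_e", "X_c", "A_c", "B_c", "C_c"),
               compartment = c("e", "c", "c", "c", "c"),
               stringsAsFactors = FALSE),
    list(reaction("t", c(X_e = 1), c(X_c = 1), 0, 10),
         reaction("r1", c(X_c = 1), c(A_c = 1), 0, 10),
         reaction("r2", c(A_c = 1), c(B_c = 1), 0, 10),
         reaction("r3", c(B_c = 1), c(C_c = 1), 0, 10)))
  ext <- detect_external_metabolites(normalize_network(net))
  # X_e: consumed, never produced; X_c: produced only by the transport
  expect_setequal(ext, c("X_e", "X_c"))
  # A_c is produced by a genuine conversion, so it is internal
  expect_false("A_c" %in% ext)
})
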