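test_that("shrinking returns 1-minimal subsets and rejects infeasible supersets", {
  lin <- generate_fixture("linear3")
  p <- seed_problem(lin, objective = "C")
  s <- shrink_to_minimal(p, c("A", "B", "C"))
  expect_length(s, 1)
  expect_true(s %in% c("A", "B", "C"))
  expect_identical(shrink_to_minimal(p, "B"), "B")  # already minimal
  expect_error(shrink_to_minimal(p, character()), "not feasible")
  # 1-minimality on random problems: deleting any element breaks feasibility
  for (seed in 1:10) {
    p <- random_problem(seed, n = 8, r = 12)
    s <- shrink_to_minimal(p, p$candidates)
    for (x in setdiff(s, p$forced_seeds)) {
      expect_false(seedkit:::ne_feasible(p, setdiff(s, x)))
    }
  }
})

test_that("reasoning enumerates exactly the minimal Boolean seed sets", {
  lin <- generate_fixture("linear3")
  p <- seed_problem(lin, objective = "C")
  sols <- enumerate_reasoning(p)
  expect_identical(sols$status, "exhausted")
  expect_true(same_set_family(solution_seed_sets(sols),
                              list("A", "B", "C")))
  expect_true(all(vapply(sols$solutions, `[[`, logical(1), "ne_valid")))
})

test_that("no-accumulation excludes seedings that strand by-products", {
  trap <- generate_fixture("trap")
  plain <- seed_problem(trap, no_accumulation = FALSE)
  expect_true(same_set_family(
    solution_seed_sets(enumerate_reasoning(plain)),
    list("T", "B", "A")))
  strict <- seed_problem(trap, no_accumulation = TRUE)
  sols <- enumerate_reasoning(strict)
  expect_true(same_set_family(solution_seed_sets(sols), list("T", "B")))
  expect_true(all(vapply(sols$solutions, `[[`, logical(1),
                         "no_accumulation_valid")))
})

test_that("full-network mode forces external seeds and can close on them alone", {
  net <- metabolic_network(
    data.frame(id = c("A_e", "B_c", "C_c"), compartment = c("e", "c", "c"),
               stringsAsFactors = FALSE),
    list(reaction("EX_A", c(A_e = 1), numeric(), -10, 1000),
         reaction("r1", c(A_e = 1), c(B_c = 1), 0, 10),
         reaction("r2", c(B_c = 1), c(C_c = 1), 0, 10),
         reaction("DM_C", c(C_c = 1), numeric(), 0, 10)))
  p <- seed_problem(net, mode = "full_network")
  expect_identical(p$forced_seeds, "A_e")
  sols <- enumerate_reasoning(p)
  expect_true(same_set_family(solution_seed_sets(sols), list("A_e")))
})

test_that("an unreachable target is reported unsatisfiable, not as a timeout", {
  net <- metabolic_network(
    c("A", "B", "Z"),
    list(reaction("r1", c(A = 1), c(B = 1), 0, 10),
         reaction("rz", c(Z = 1), c(B = 1), 0, 10)),
    objective = "rz")
  p <- seed_problem(net, objective = "rz", forbidden_seeds = "Z")
  expect_message(sols <- enumerate_reasoning(p), "unsatisfiable")
  expect_length(sols$solutions, 0)
  expect_identical(sols$status, "unsatisfiable")
})

test_that("hybrid-filter keeps exactly the flux-valid reasoning solutions", {
  trap <- generate_fixture("trap")
  hf <- hybrid_filter(seed_problem(trap))
  expect_true(same_set_family(solution_seed_sets(hf), list("T", "B")))
  expect_true(all(vapply(hf$solutions, function(s) s$fba_flux > 1e-6,
                         logical(1))))

  # when every Boolean solution carries flux, filtering is the identity
  lin <- linear3_with_demand()
  p <- seed_problem(lin)
  expect_true(same_set_family(
    solution_seed_sets(hybrid_filter(p)),
    solution_seed_sets(enumerate_reasoning(p))))

  # when none does, the stream is empty but distinguishable from timeout
  dead <- metabolic_network(
    c("A", "B", "C"),
    list(reaction("r1", c(A = 1), c(B = 1, C = 1), 0, 10),
         reaction("obj", c(B = 1), numeric(), 0, 10)),
    objective = "obj")
  p2 <- seed_problem(dead, forbidden_seeds = c("B"))
  # only {A}-derived solutions exist and all strand C
  hf2 <- hybrid_filter(p2)
  expect_length(hf2$solutions, 0)
  expect_identical(hf2$status, "exhausted_without_valid")
})

test_that("guess-and-check exhibits hybrid-minimal, Boolean-non-minimal solutions", {
  trap <- generate_fixture("trap")
  p <- seed_problem(trap)
  gc <- hybrid_gc(p)
  expect_true(same_set_family(solution_seed_sets(gc),
                              list("T", "B", c("A", "C"))))
  ac <- Filter(function(s) setequal(s$seeds, c("A", "C")), gc$solutions)[[1]]
  expect_identical(ac$minimality, "hybrid_subset_minimal")
  # {A, C} is not minimal for the Boolean problem: {A} alone reaches T
  expect_true(seedkit:::ne_feasible(p, "A"))
  # but it is minimal for the joint problem: dropping either member fails
  expect_false(validate_seeds_fba(trap, "A")$verdict)
  expect_false(seedkit:::ne_feasible(p, "C"))
})

test_that("guess-and-check reduces to reasoning when every Boolean solution validates", {
  p <- seed_problem(linear3_with_demand())
  expect_true(same_set_family(
    solution_seed_sets(hybrid_gc(p)),
    solution_seed_sets(enumerate_reasoning(p))))
})

test_that("full hybrid search agrees with exhaustive guess-and-check and refuses big inputs", {
  trap <- generate_fixture("trap")
  p <- seed_problem(trap)
  expect_true(same_set_family(
    solution_seed_sets(full_hybrid_solve(p)),
    list("T", "B", c("A", "C"))))
  pm <- seed_problem(trap, optimization = "minimize")
  mins <- full_hybrid_solve(pm)
  expect_true(same_set_family(solution_seed_sets(mins), list("T", "B")))
  expect_true(all(vapply(mins$solutions, `[[`, character(1),
                         "minimality") == "cardinality_minimal"))
  for (s in 1:4) {
    p <- random_problem(s)
    expect_true(same_set_family(
      solution_seed_sets(full_hybrid_solve(p)),
      solution_seed_sets(hybrid_gc(p))))
  }
  big <- generate_random_network(60, 240, seed = 1)
  expect_error(full_hybrid_solve(seed_problem(big, mode = "target")),
               "refused")
})

test_that("the brute-force oracle matches hand enumeration and handles infeasibility", {
  p <- seed_problem(generate_fixture("linear3"), objective = "C")
  expect_true(same_set_family(brute_force_minimal_seed_sets(p),
                              list("A", "B", "C")))
  ph <- seed_problem(generate_fixture("trap"))
  expect_true(same_set_family(
    brute_force_minimal_seed_sets(ph, with_fba = TRUE),
    list("T", "B", c("A", "C"))))
  net <- metabolic_network(
    c("A", "B"), list(reaction("r", c(A = 1), c(B = 1), 0, 10)),
    objective = "r")
  pu <- seed_problem(net, objective = "B", forbidden_seeds = c("A", "B"))
  expect_length(brute_force_minimal_seed_sets(pu), 0)
})

test_that("cardinality-minimal solutions are a subfamily of the subset-minimal ones", {
  for (s in 1:6) {
    net <- generate_random_network(10, 15, seed = s)
    subs <- solution_seed_sets(
      enumerate_reasoning(seed_problem(net, max_solutions = 1000)))
    mins <- solution_seed_sets(
      enumerate_reasoning(seed_problem(net, optimization = "minimize",
                                       max_solutions = 1000)))
    k <- min(lengths(subs))
    expect_true(all(lengths(mins) == k))
    keys <- vapply(subs, function(x) paste(x, collapse = "|"), "")
    expect_true(all(vapply(mins, function(x) paste(x, collapse = "|"), "")
                    %in% keys))
  }
})

test_that("enumeration emits no duplicates and no supersets of earlier solutions", {
  for (s in 1:6) {
    p <- random_problem(s)
    for (sols in list(enumerate_reasoning(p), hybrid_gc(p))) {
      sets <- solution_seed_sets(sols)
      keys <- vapply(sets, function(x) paste(x, collapse = "|"), "")
      expect_identical(anyDuplicated(keys), 0L)
      if (length(sets) > 1) {
        for (i in 2:length(sets)) for (j in 1:(i - 1)) {
          expect_false(all(sets[[j]] %in% sets[[i]]))
        }
      }
    }
  }
})

test_that("solving is deterministic for a fixed problem", {
  p <- random_problem(5)
  expect_identical(solution_seed_sets(enumerate_reasoning(p)),
                   solution_seed_sets(enumerate_reasoning(p)))
  expect_identical(solution_seed_sets(hybrid_gc(p, diversify = TRUE)),
                   solution_seed_sets(hybrid_gc(p, diversify = TRUE)))
})

test_that("a zero time budget yields a timeout status, not a crash", {
  p <- seed_problem(generate_fixture("trap"), time_budget = 0)
  sols <- enumerate_reasoning(p)
  expect_identical(sols$status, "timeout")
  expect_length(sols$solutions, 0)
})
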