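test_that("founders attach to their smallest-id tree child with weight zero", {
  res <- phase_example_constraints()
  ids <- res$ped$id
  at <- vapply(names(res$gstar$attach), function(fk) {
    ids[res$gstar$attach[[fk]]]
  }, character(1))
  names(at) <- ids[as.integer(names(res$gstar$attach))]
  expect_identical(at[c("A", "B", "C", "D", "E", "J", "M", "P")],
                   c(A = "I", B = "H", C = "F", D = "G", E = "K",
                     J = "N", M = "O", P = "R"))
  # attachment declares a weight-0 relation: W[founder] = W[child]
  gs <- res$gstar
  for (fk in names(gs$attach)) {
    f <- as.integer(fk); ch <- gs$attach[[fk]]
    expect_identical(gs$frame[f], gs$frame[ch])
    expect_true(gf2_eq(gs$W[[f]], gs$W[[ch]]))
  }
})

test_that("a childless isolated individual stays a singleton frame", {
  ped <- as_zrhc_ped(data.frame(
    id = 1:4, father = c(NA, NA, 1, NA), mother = c(NA, NA, 2, NA),
    sex = c(1, 2, 0, 1), g1 = c(0L, 1L, 2L, 2L)))
  fit <- zrhc_phase(ped)
  expect_identical(fit$status, "consistent")
  f4 <- fit$gstar$frame[4]
  expect_identical(sum(fit$gstar$frame == f4), 1L)
  # its heterozygous locus is a free anchor: two configurations overall
  expect_length(enumerate_solutions(fit), 2L)
})

test_that("the linking formula determines a local edge's transmission", {
  # father 1 het, mother 2 homozygous 0, children het: the sibling non-tree
  # edge keeps a path constraint; both side pairs share one frame, so
  # h = b_p + W[n_k] + W[n_i] (the endpoint-4 terms cancel)
  ped <- family_ped(2, g = matrix(c(2L, 0L, 2L, 2L), 4, 1))
  fit <- zrhc_phase(ped)
  e <- fit$tree$xedges[1]
  h <- fit$h[[as.character(e)]]
  expect_false(is.null(h))
  expect_true(gf2_is_const(h))
  # cross-check against the brute-force family
  expect_true(family_equals_oracle(list(ped = ped), fit))
})

test_that("residual components get a star of linker variables", {
  # three-generation fully heterozygous chain at one locus: founder
  # attachments leave three frames, so two linkers (plus one phase anchor)
  ped <- as_zrhc_ped(data.frame(
    id = 1:7,
    father = c(NA, NA, 1, NA, 3, NA, 5),
    mother = c(NA, NA, 2, NA, 4, NA, 6),
    sex = c(1, 2, 1, 2, 1, 2, 0),
    g1 = rep(2L, 7)))
  fit <- zrhc_phase(ped)
  reg <- registry_tbl(fit$registry)
  expect_identical(sum(reg$kind == "linker"), 2L)
  expect_identical(sum(reg$kind == "anchor"), 1L)
  # already-connected constraint graphs get no linker
  sim <- sim_zrhc(n = 16, m = 12, loops = 0, seed = 21)
  fit2 <- zrhc_phase(sim$ped)
  expect_identical(sum(registry_tbl(fit2$registry)$kind == "linker"), 0L)
})

test_that("enumeration size is two to the number of free variables", {
  sim <- sim_zrhc(n = 16, m = 12, loops = 0, seed = 21)
  fit <- zrhc_phase(sim$ped)
  expect_length(fit$free_vars, 0L)
  expect_length(enumerate_solutions(fit), 1L)
  ped <- trio_ped(c(2, 2, 2))
  fit1 <- zrhc_phase(ped)
  expect_length(fit1$free_vars, 1L)
  expect_length(enumerate_solutions(fit1), 2L)
  expect_error(enumerate_solutions(fit1, max_vars = 0L), "too many")
})

test_that("a fully heterozygous trio yields exactly the two valid phasings", {
  ped <- trio_ped(c(2, 2, 2))
  fit <- zrhc_phase(ped)
  expect_true(family_equals_oracle(list(ped = ped), fit))
  sols <- enumerate_solutions(fit)
  expect_length(sols, 2L)
  for (p in sols) expect_true(check_configuration(ped, p))
})

test_that("propagation leaves predetermined alleles intact and homozygotes fixed", {
  sim <- sim_zrhc(n = 20, m = 5, loops = 1, seed = 31)
  fit <- zrhc_phase(sim$ped)
  g <- ped_genotypes(sim$ped)
  for (i in seq_len(nrow(g))) {
    for (l in seq_len(ncol(g))) {
      if (g[i, l] != 2L) {
        expect_true(gf2_eq(fit$p[[i]][[l]], gf2(g[i, l])))
      }
    }
  }
})

test_that("the audit passes error-free data and flags infeasible flips", {
  sim <- sim_zrhc(n = 9, m = 4, loops = 1, seed = 33)
  fit <- zrhc_phase(sim$ped)
  expect_identical(fit$status, "consistent")
  # corrupt until the oracle says no configuration exists, then re-check
  flagged <- NULL
  for (s in 1:20) {
    bad <- inject_errors(sim$ped, 2, seed = 1000 + s)
    if (length(zrhc_bruteforce(bad, max_h_bits = 18)) == 0L) {
      flagged <- zrhc_check(bad)
      break
    }
  }
  expect_false(is.null(flagged))
  expect_false(flagged$consistent)
  expect_gte(nrow(flagged$conflicts), 1L)
})

test_that("a single-locus pedigree still passes the inheritance audit", {
  sim <- sim_zrhc(n = 12, m = 1, loops = 0, seed = 35)
  fit <- zrhc_phase(sim$ped)
  expect_identical(fit$status, "consistent")
  expect_true(truth_in_family(sim, fit))
})
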