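# couple 1,2 and children 3,4; one locus, everyone heterozygous:
# the sibling cycle lies fully in the locus graph with d-sum 0+1+1+0
het_cycle_family <- function() {
  family_ped(2, g = matrix(2L, 4, 1))
}

test_that("a complete length-4 cycle gives the d-sum cycle constraint", {
  ped <- het_cycle_family()
  g <- build_graph(ped)
  tr <- build_spanning_tree(g)
  ld <- build_locus_data(g, ped, 1)
  cons <- gen_edge_constraints(g, tr, ld, tr$xedges[1])
  expect_length(cons, 1L)
  expect_identical(cons[[1]]$type, "cycle")
  expect_identical(cons[[1]]$b, 0L)   # 0 + 1 + 1 + 0
})

test_that("a broken cycle gives the path constraint between first predetermined nodes", {
  # father 1 heterozygous, mother 2 homozygous 0/0, children heterozygous:
  # both children predetermined (p = 1), only father edges in the locus graph
  ped <- family_ped(2, g = matrix(c(2L, 0L, 2L, 2L), 4, 1))
  g <- build_graph(ped)
  tr <- build_spanning_tree(g)
  ld <- build_locus_data(g, ped, 1)
  e <- tr$xedges[1]
  cons <- gen_edge_constraints(g, tr, ld, e)
  expect_length(cons, 1L)
  pc <- cons[[1]]
  expect_identical(pc$type, "path")
  expect_setequal(c(pc$ni, pc$nj), c(3L, 4L))
  # b = p_3 + p_4 + d over the father edges = 1 + 1 + 0 + 0
  expect_identical(pc$b, 0L)
  # side map pairs each path endpoint with the edge endpoint on its side
  expect_true(pc$side$ni %in% c(g$edges$parent[e], g$edges$child[e]))
})

test_that("an edge absent from the locus graph generates nothing", {
  ped <- family_ped(2, g = matrix(c(0L, 0L, 0L, 0L), 4, 1))
  g <- build_graph(ped)
  tr <- build_spanning_tree(g)
  ld <- build_locus_data(g, ped, 1)
  expect_length(gen_edge_constraints(g, tr, ld, tr$xedges[1]), 0L)
})

test_that("tree constraints need two predetermined nodes in a forest component", {
  # everyone heterozygous: no predetermined node, no tree constraint
  ped <- trio_ped(c(2, 2, 2))
  g <- build_graph(ped)
  tr <- build_spanning_tree(g)
  expect_length(gen_tree_constraints(g, tr, build_locus_data(g, ped, 1)), 0L)
  # exactly one predetermined node: still nothing
  ped1 <- trio_ped(c(2, 1, 2))   # child predetermined, parents not
  g1 <- build_graph(ped1)
  tr1 <- build_spanning_tree(g1)
  expect_length(gen_tree_constraints(g1, tr1, build_locus_data(g1, ped1, 1)), 0L)
})

test_that("a two-edge chain through a non-predetermined node sums its d-constants", {
  # mother 1 (het) with two homozygous-0 partners 2 and 4; children 3 and 5
  # heterozygous: both predetermined with p = 0, chain 3 - 1 - 5 in the locus
  # graph, mother edges d = w_child = 1 each, so b_t = 0 + 0 + 1 + 1 = 0
  ped <- as_zrhc_ped(data.frame(
    id = 1:5, father = c(NA, NA, 2, NA, 4), mother = c(NA, NA, 1, NA, 1),
    sex = c(2, 1, 0, 1, 0), g1 = c(2L, 0L, 2L, 0L, 2L)))
  g <- build_graph(ped)
  tr <- build_spanning_tree(g)
  cons <- gen_tree_constraints(g, tr, build_locus_data(g, ped, 1))
  keys <- vapply(cons, function(cn) paste(sort(c(cn$ni, cn$nj)), collapse = "-"),
                 character(1))
  expect_true("3-5" %in% keys)
  expect_identical(cons[[which(keys == "3-5")]]$b, 0L)
})

test_that("keyed insertion deduplicates, respects symmetry, and flags conflicts", {
  sys <- new_constraint_system()
  tc <- list(type = "tree", ni = 2L, nj = 5L, b = 0L)
  expect_identical(add_constraint(sys, tc), "added")
  expect_identical(add_constraint(sys, tc), "duplicate")
  expect_identical(add_constraint(sys, list(type = "tree", ni = 5L, nj = 2L, b = 0L)),
                   "duplicate")
  expect_identical(add_constraint(sys, list(type = "tree", ni = 5L, nj = 2L, b = 1L)),
                   "conflict")
  expect_length(sys$conflicts, 1L)
  expect_identical(add_constraint(sys, list(type = "cycle", e = 3L, b = 0L)), "added")
  expect_identical(add_constraint(sys, list(type = "cycle", e = 3L, b = 1L)), "conflict")
})

test_that("error-free simulations generate no conflicts and respect size bounds", {
  for (s in 1:4) {
    sim <- sim_zrhc(n = 20, m = 6, loops = s %% 2, seed = 300 + s)
    g <- build_graph(sim$ped)
    tr <- build_spanning_tree(g)
    lds <- lapply(1:6, function(l) build_locus_data(g, sim$ped, l))
    sys <- generate_constraints(g, tr, lds)
    expect_length(sys$conflicts, 0L)
    expect_lte(length(sys$cc) + length(sys$cp), length(tr$xedges) * 6L)
  }
})

test_that("constraint values are independent of reading direction", {
  # generated twice with endpoint roles swapped via the symmetric key, the
  # same (cycle-broken) path produces one deduplicated entry, never a conflict
  for (s in 1:4) {
    sim <- sim_zrhc(n = 16, m = 4, loops = 1, seed = 500 + s)
    g <- build_graph(sim$ped)
    tr <- build_spanning_tree(g)
    lds <- lapply(1:4, function(l) build_locus_data(g, sim$ped, l))
    sys <- generate_constraints(g, tr, lds)
    for (key in names(sys$cp)) {
      pc <- sys$cp[[key]]
      flipped <- list(type = "path", ni = pc$nj, nj = pc$ni, b = pc$b, e = pc$e,
                      side = list(ni = pc$side$nj, nj = pc$side$ni))
      expect_identical(add_constraint(sys, flipped), "duplicate")
    }
  }
})
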