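test_that("Type-1 transformation turns path constraints into tree constraints", {
  sys <- new_constraint_system()
  add_constraint(sys, list(type = "cycle", e = 9L, b = 1L))
  add_constraint(sys, list(type = "path", ni = 1L, nj = 4L, b = 1L, e = 9L,
                           side = list(ni = 1L, nj = 4L)))
  add_constraint(sys, list(type = "path", ni = 2L, nj = 5L, b = 0L, e = 9L,
                           side = list(ni = 2L, nj = 5L)))
  add_constraint(sys, list(type = "path", ni = 3L, nj = 6L, b = 0L, e = 8L,
                           side = list(ni = 3L, nj = 6L)))   # other edge, kept
  transform_type1(sys)
  expect_length(sys$cp, 1L)
  expect_identical(sys$ct[["1|4"]]$b, 0L)   # b_c + b_p = 1 + 1
  expect_identical(sys$ct[["2|5"]]$b, 1L)
})

test_that("a transformed constraint clashing with an existing one is a conflict", {
  sys <- new_constraint_system()
  add_constraint(sys, list(type = "tree", ni = 1L, nj = 4L, b = 1L))
  add_constraint(sys, list(type = "cycle", e = 9L, b = 0L))
  add_constraint(sys, list(type = "path", ni = 1L, nj = 4L, b = 0L, e = 9L,
                           side = list(ni = 1L, nj = 4L)))
  transform_type1(sys)
  expect_length(sys$conflicts, 1L)
})

test_that("W-assignment seeds each frame at its smallest node and checks revisits", {
  sys <- new_constraint_system()
  add_constraint(sys, list(type = "tree", ni = 2L, nj = 4L, b = 1L))
  add_constraint(sys, list(type = "tree", ni = 4L, nj = 5L, b = 1L))
  gs <- build_constraint_graph(sys, 6L)
  expect_identical(gs$seed[gs$frame[4]], 2L)
  expect_true(gf2_eq(gs$W[[2]], gf2(0)))
  expect_true(gf2_eq(gs$W[[4]], gf2(1)))
  expect_true(gf2_eq(gs$W[[5]], gf2(0)))
  # isolated nodes are singleton frames with W = 0
  expect_true(gf2_eq(gs$W[[1]], gf2(0)))
  expect_identical(sum(gs$frame == gs$frame[1]), 1L)
  expect_length(gs$conflicts, 0L)
})

test_that("an inconsistent tree-constraint triangle trips checkpoint two", {
  sys <- new_constraint_system()
  add_constraint(sys, list(type = "tree", ni = 1L, nj = 2L, b = 0L))
  add_constraint(sys, list(type = "tree", ni = 1L, nj = 3L, b = 0L))
  add_constraint(sys, list(type = "tree", ni = 2L, nj = 3L, b = 1L))
  gs <- build_constraint_graph(sys, 3L)
  expect_gte(length(gs$conflicts), 1L)
})

test_that("a single path constraint within one frame forms the degenerate synthetic cycle", {
  # frames {1,2} via a tree constraint; one path constraint of a global edge
  # with both endpoints in that frame: t = 0 synthetic cycle, b = W1 + W2 + bp
  ped <- loop_pedigree_example()$ped   # only for a tree with a global edge
  idx <- stats::setNames(seq_len(19), ped$id)
  g <- build_graph(ped)
  tr <- build_spanning_tree(g, nontree = lapply(loop_pedigree_example()$nontree,
                                                function(p) unname(idx[p])))
  e_bf <- tr$global[1]
  sys <- new_constraint_system()
  add_constraint(sys, list(type = "tree", ni = idx[["G"]], nj = idx[["N"]], b = 1L))
  add_constraint(sys, list(type = "path", ni = idx[["G"]], nj = idx[["N"]],
                           b = 1L, e = e_bf,
                           side = list(ni = idx[["F"]], nj = idx[["B"]])))
  gs <- build_constraint_graph(sys, g$n)
  extend_by_synthetic_cycles(sys, gs, tr)
  expect_identical(sys$cc[[as.character(e_bf)]]$b, 0L)   # 0 + 1 + 1
  expect_length(sys$cp, 0L)
})

test_that("two parallel path constraints between two frames synthesise nothing", {
  ex <- loop_pedigree_example()
  idx <- stats::setNames(seq_len(19), ex$ped$id)
  g <- build_graph(ex$ped)
  tr <- build_spanning_tree(g, nontree = lapply(ex$nontree,
                                                function(p) unname(idx[p])))
  e_bf <- tr$global[1]
  sys <- new_constraint_system()
  add_constraint(sys, list(type = "tree", ni = idx[["G"]], nj = idx[["K"]], b = 0L))
  add_constraint(sys, list(type = "tree", ni = idx[["N"]], nj = idx[["I"]], b = 0L))
  add_constraint(sys, list(type = "path", ni = idx[["G"]], nj = idx[["N"]],
                           b = 0L, e = e_bf,
                           side = list(ni = idx[["F"]], nj = idx[["B"]])))
  add_constraint(sys, list(type = "path", ni = idx[["K"]], nj = idx[["I"]],
                           b = 1L, e = e_bf,
                           side = list(ni = idx[["F"]], nj = idx[["B"]])))
  gs <- build_constraint_graph(sys, g$n)
  extend_by_synthetic_cycles(sys, gs, tr)
  expect_null(sys$cc[[as.character(e_bf)]])
  expect_length(sys$cp, 2L)
})

test_that("the worked example reduces exactly as printed", {
  res <- phase_example_constraints()
  ids <- res$ped$id
  lab <- function(key) {
    paste(sort(ids[as.integer(strsplit(key, "|", fixed = TRUE)[[1]])]),
          collapse = "-")
  }
  expect_setequal(vapply(res$type1_added, lab, character(1)), c("Q-R", "H-I"))
  expect_identical(res$seeds_initial, c("G", "H", "Q"))
  expect_length(res$synthetic, 1L)
  expect_identical(res$synthetic[[1]]$b, 0L)
  expect_setequal(vapply(res$synthetic_added, lab, character(1)),
                  c("G-N", "G-Q", "N-Q"))
})

test_that("synthesised cycle constraints equal the truth-derived cycle parity", {
  hits <- 0L
  for (s in 1:12) {
    sim <- tryCatch(sim_zrhc(n = 24, m = 3, loops = 2, seed = 700 + s),
                    error = function(e) NULL)
    if (is.null(sim)) next
    g <- build_graph(sim$ped)
    tr <- build_spanning_tree(g)
    lds <- lapply(1:3, function(l) build_locus_data(g, sim$ped, l))
    sys <- generate_constraints(g, tr, lds)
    before <- names(sys$cc)
    transform_type1(sys)
    gs <- build_constraint_graph(sys, g$n)
    extend_by_synthetic_cycles(sys, gs, tr)
    synth <- setdiff(names(sys$cc), before)
    # true transmission bit of an edge, from the recorded gene-dropping truth
    true_h <- function(k) {
      child <- g$edges$child[k]
      if (g$edges$is_father[k]) sim$truth$h_father[child]
      else sim$truth$h_mother[child]
    }
    for (ek in synth) {
      cyc <- tr$cycles[[match(as.integer(ek), tr$xedges)]]
      b_true <- sum(vapply(cyc$edges, true_h, integer(1))) %% 2L
      expect_identical(sys$cc[[ek]]$b, as.integer(b_true))
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 3L)   # the scenario must actually have been exercised
})
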