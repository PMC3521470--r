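test_that("the generator is deterministic given a seed", {
  p1 <- simulate_pedigree(n = 25, loops = 1, seed = 5)
  p2 <- simulate_pedigree(n = 25, loops = 1, seed = 5)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  s1 <- sim_zrhc(n = 25, m = 6, loops = 1, seed = 5)
  s2 <- sim_zrhc(n = 25, m = 6, loops = 1, seed = 5)
  expect_identical(ped_genotypes(s1$ped), ped_genotypes(s2$ped))
  expect_identical(s1$truth, s2$truth)
  s3 <- sim_zrhc(n = 25, m = 6, loops = 1, seed = 6)
  expect_false(identical(ped_genotypes(s1$ped), ped_genotypes(s3$ped)))
})

test_that("loop-free pedigrees have only sibling cycles", {
  for (s in 1:6) {
    ped <- simulate_pedigree(n = 20 + s, loops = 0, seed = 40 + s)
    g <- build_graph(ped)
    tr <- build_spanning_tree(g)
    cl <- classify_nontree_edges(tr, g)
    expect_identical(attr(ped, "k"), 0L)
    expect_true(all(cl$class == "local"))
    # cycle-space dimension identity
    expect_identical(nrow(cl), nrow(g$edges) - g$n + length(unique(tr$comp)))
  }
})

test_that("requested mating loops are realised (achieved k reported, >= target)", {
  for (s in 1:4) {
    ped <- simulate_pedigree(n = 30, loops = 2, seed = 50 + s)
    g <- build_graph(ped)
    tr <- build_spanning_tree(g)
    expect_identical(attr(ped, "k"), tr$k)
    expect_gte(tr$k, 2L)
    cl <- classify_nontree_edges(tr, g)
    expect_identical(sum(cl$class == "global") + sum(cl$class == "local"),
                     nrow(g$edges) - g$n + length(unique(tr$comp)))
  }
  expect_error(simulate_pedigree(n = 6, loops = 5, seed = 1), "increase n")
})

test_that("gene dropping follows the zero-recombination model exactly", {
  sim <- sim_zrhc(n = 24, m = 8, loops = 1, seed = 60)
  ped <- sim$ped
  for (i in seq_len(nrow(ped))) {
    if (is.na(ped$father[i])) next
    fi <- match(ped$father[i], ped$id)
    mo <- match(ped$mother[i], ped$id)
    # each child haplotype is one complete parental haplotype
    expect_true(all(sim$pat[i, ] == sim$pat[fi, ]) ||
                all(sim$pat[i, ] == sim$mat[fi, ]))
    expect_true(all(sim$mat[i, ] == sim$pat[mo, ]) ||
                all(sim$mat[i, ] == sim$mat[mo, ]))
    # recorded transmission bits match the haplotype actually passed
    src <- if (sim$truth$h_father[i] == 0L) sim$pat[fi, ] else sim$mat[fi, ]
    expect_identical(unname(sim$pat[i, ]), unname(src))
    # where the father is homozygous the child's paternal allele is forced
    hom <- sim$pat[fi, ] == sim$mat[fi, ]
    expect_identical(unname(sim$pat[i, hom]), unname(sim$pat[fi, hom]))
  }
  # the code is 2 exactly where the two haplotypes differ
  expect_identical(unname(ped_genotypes(ped) == 2L),
                   unname(sim$pat != sim$mat))
})

test_that("error injection corrupts the stated number of cells, reproducibly", {
  sim <- sim_zrhc(n = 15, m = 4, loops = 0, seed = 70)
  same <- inject_errors(sim$ped, 0, seed = 1)
  expect_identical(ped_genotypes(same), ped_genotypes(sim$ped))
  bad1 <- inject_errors(sim$ped, 3, seed = 2)
  bad2 <- inject_errors(sim$ped, 3, seed = 2)
  expect_identical(ped_genotypes(bad1), ped_genotypes(bad2))
  rec <- attr(bad1, "errors")
  expect_identical(nrow(rec), 3L)
  g0 <- ped_genotypes(sim$ped); g1 <- ped_genotypes(bad1)
  expect_identical(sum(g0 != g1), 3L)
  expect_true(all(rec$old != rec$new))
})

test_that("simulator output always solves consistently", {
  for (s in 1:6) {
    sim <- sim_zrhc(n = 20, m = 8, loops = s %% 3, seed = 90 + s)
    fit <- zrhc_phase(sim$ped)
    expect_identical(fit$status, "consistent")
  }
})

test_that("with many loci the solution usually needs no free variables", {
  zero <- 0L
  for (s in 1:10) {
    sim <- sim_zrhc(n = 30, m = 30, loops = s %% 3, seed = 110 + s)
    fit <- zrhc_phase(sim$ped)
    if (length(fit$free_vars) == 0L) zero <- zero + 1L
  }
  expect_gte(zero, 6L)
})

test_that("the truth file round-trips through write_truth", {
  sim <- sim_zrhc(n = 10, m = 3, loops = 0, seed = 120)
  f <- tempfile(fileext = ".tsv")
  write_truth(sim, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t",
                            colClasses = c("character", "character",
                                           "character", "integer", "integer"))
  expect_identical(back$paternal_hap, sim$truth$paternal_hap)
  expect_identical(back$h_father, sim$truth$h_father)
})
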