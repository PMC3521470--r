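#' A 19-member looped pedigree and its constraint-level worked example
#'
#' A pedigree of 19 individuals (A-S) with eight founders and one mating
#' loop, together with the spanning tree (non-tree edges A-H, E-L, Q-R, B-F;
#' the first three close sibling "local" cycles, B-F closes the length-10
#' global cycle B-F-C-G-D-L-O-Q-N-I-B) and the constraint sets the four-locus
#' genotype data of the example induce. The genotypes themselves are not
#' carried — the example enters the pipeline at the constraint level and is
#' used to exercise Steps 3 and 4 deterministically.
#'
#' @return A list: `ped` (ungenotyped `zrhc_ped`), `nontree` (list of id
#'   pairs), and the printed constraint sets `cc`, `cp`, `ct` as tibbles over
#'   individual ids.
#' @export
loop_pedigree_example <- function() {
  ids <- LETTERS[1:19]
  father <- stats::setNames(rep(NA_character_, 19), ids)
  mother <- father
  assign_child <- function(child, fa, mo) {
    father[child] <<- fa; mother[child] <<- mo
  }
  assign_child("H", "B", "A"); assign_child("I", "B", "A")
  assign_child("F", "B", "C"); assign_child("G", "D", "C")
  assign_child("K", "D", "E"); assign_child("L", "D", "E")
  assign_child("N", "J", "I"); assign_child("O", "M", "L")
  assign_child("Q", "N", "O")
  assign_child("R", "P", "Q"); assign_child("S", "P", "Q")
  sex <- ifelse(ids %in% c("B", "D", "J", "M", "N", "P", "H", "K", "R"), 1L, 2L)
  ped <- as_zrhc_ped(tibble::tibble(
    fid = "EX", id = ids, father = unname(father), mother = unname(mother),
    sex = sex))
  list(
    ped = ped,
    nontree = list(c("A", "H"), c("E", "L"), c("Q", "R"), c("B", "F")),
    cc = tibble::tibble(edge = c("E-L", "Q-R", "A-H"), b = c(0L, 0L, 0L)),
    cp = tibble::tibble(
      ni = c("I", "N", "G", "R", "N"),
      nj = c("H", "G", "Q", "Q", "Q"),
      b = 0L,
      edge = c("A-H", "B-F", "B-F", "Q-R", "B-F"),
      # which endpoint of the non-tree edge lies on ni's side of the path
      side_ni = c("A", "B", "F", "R", "B"),
      side_nj = c("H", "F", "B", "Q", "F")
    ),
    ct = tibble::tibble(
      ni = c("I", "G", "G", "G", "Q"),
      nj = c("N", "K", "L", "O", "S"),
      b = 0L
    )
  )
}

#' Run constraint reduction and haplotype determination on the worked example
#'
#' Feeds the printed constraint sets of [loop_pedigree_example()] through
#' Type-1 transformation, constraint-graph construction, synthetic-cycle
#' extension, founder attachment, linking, and free-variable connection, and
#' reports what each stage produced.
#'
#' @return A list with the `system`, `gstar`, `registry`, `sol` (h
#'   expressions), the tree-constraint keys added by Type-1
#'   (`type1_added`), the synthesised cycle constraints (`synthetic`), and
#'   the tree-constraint keys added by synthesis (`synthetic_added`).
#' @export
phase_example_constraints <- function() {
  ex <- loop_pedigree_example()
  ped <- ex$ped
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  graph <- build_graph(ped)
  tree <- build_spanning_tree(graph, nontree = lapply(ex$nontree, function(pr) {
    unname(idx[pr])
  }))
  edge_id <- function(lbl) {
    pr <- idx[strsplit(lbl, "-")[[1]]]
    which((graph$edges$parent == pr[1] & graph$edges$child == pr[2]) |
          (graph$edges$parent == pr[2] & graph$edges$child == pr[1]))
  }
  system <- new_constraint_system()
  for (r in seq_len(nrow(ex$cc))) {
    add_constraint(system, list(type = "cycle", e = edge_id(ex$cc$edge[r]),
                                b = ex$cc$b[r]))
  }
  for (r in seq_len(nrow(ex$cp))) {
    add_constraint(system, list(
      type = "path", ni = unname(idx[ex$cp$ni[r]]), nj = unname(idx[ex$cp$nj[r]]),
      b = ex$cp$b[r], e = edge_id(ex$cp$edge[r]),
      side = list(ni = unname(idx[ex$cp$side_ni[r]]),
                  nj = unname(idx[ex$cp$side_nj[r]]))))
  }
  for (r in seq_len(nrow(ex$ct))) {
    add_constraint(system, list(type = "tree", ni = unname(idx[ex$ct$ni[r]]),
                                nj = unname(idx[ex$ct$nj[r]]), b = ex$ct$b[r]))
  }
  before <- names(system$ct)
  transform_type1(system)
  type1_added <- setdiff(names(system$ct), before)
  gstar <- build_constraint_graph(system, graph$n)
  multi <- sort(unique(gstar$frame[duplicated(gstar$frame)]))
  seeds_initial <- ped$id[gstar$seed[multi]]
  before <- names(system$ct)
  cc_before <- names(system$cc)
  extend_by_synthetic_cycles(system, gstar, tree)
  synthetic <- system$cc[setdiff(names(system$cc), cc_before)]
  synthetic_added <- setdiff(names(system$ct), before)
  registry <- new_registry()
  sol <- new_solution(nrow(graph$edges), graph$n, 0L)
  attach_founders(gstar, tree, graph, ped)
  link_by_path_constraints(gstar, system, sol)
  connect_free(gstar, tree, registry, ped$id)
  extract_h(gstar, tree, graph, system, sol)
  list(ped = ped, graph = graph, tree = tree, system = system, gstar = gstar,
       registry = registry, sol = sol, type1_added = type1_added,
       synthetic = synthetic, synthetic_added = synthetic_added,
       seeds_initial = seeds_initial)
}
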