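#' Constraint systems over GF(2)
#'
#' Step 2 of the algorithm turns locus graphs into three keyed sets of parity
#' constraints on the transmission indicators (h): cycle constraints `C^C`
#' (one per non-tree edge at most), path constraints `C^P` (keyed by unordered
#' endpoints plus the non-tree edge), and tree constraints `C^T` (keyed by
#' unordered endpoints). Re-inserting an identical constraint is a no-op;
#' inserting the same key with a different parity is a genotype inconsistency
#' and is logged, not thrown, so checking can continue (consistency
#' checkpoint one).
#'
#' @return An environment of class `zrhc_constraints` with fields `cc`, `cp`,
#'   `ct` (named lists) and `conflicts` (character log).
#' @export
new_constraint_system <- function() {
  sys <- new.env(parent = emptyenv())
  sys$cc <- list(); sys$cp <- list(); sys$ct <- list()
  sys$conflicts <- character()
  class(sys) <- "zrhc_constraints"
  sys
}

#' @export
print.zrhc_constraints <- function(x, ...) {
  cat("<zrhc constraints: |C^C| =", length(x$cc),
      " |C^P| =", length(x$cp), " |C^T| =", length(x$ct),
      " conflicts =", length(x$conflicts), ">\n")
  invisible(x)
}

cp_key <- function(ni, nj, e) paste(min(ni, nj), max(ni, nj), e, sep = "|")
ct_key <- function(ni, nj) paste(min(ni, nj), max(ni, nj), sep = "|")

#' Insert a constraint with deduplication and conflict detection
#'
#' @param system A `zrhc_constraints`.
#' @param con A constraint record: `list(type = "cycle", e, b)`,
#'   `list(type = "path", ni, nj, b, e, side)` where `side` records which
#'   endpoint of `e` lies on `ni`'s side of the path, or
#'   `list(type = "tree", ni, nj, b)`.
#' @return `"added"`, `"duplicate"`, or `"conflict"`.
#' @export
add_constraint <- function(system, con) {
  slot <- switch(con$type, cycle = "cc", path = "cp", tree = "ct",
                 stop("unknown constraint type"))
  key <- switch(con$type,
    cycle = as.character(con$e),
    path = cp_key(con$ni, con$nj, con$e),
    tree = ct_key(con$ni, con$nj)
  )
  cur <- system[[slot]][[key]]
  if (is.null(cur)) {
    system[[slot]][[key]] <- con
    return("added")
  }
  if (cur$b == con$b) return("duplicate")
  system$conflicts <- c(system$conflicts, paste0(
    "conflicting ", con$type, " constraint at key ", key,
    ": ", cur$b, " vs ", con$b))
  "conflict"
}

#' Cycle or path constraint of one non-tree edge at one locus
#'
#' If the edge is absent from the locus graph nothing is generated. If its
#' whole fundamental cycle lies in the locus graph, the cycle constraint is
#' the d-sum around the cycle. Otherwise the cycle is broken by predetermined
#' nodes and missing edges; walking from the edge's endpoints to the first
#' predetermined node on each side yields the path constraint
#' `p_start + p_end + sum(d)`. A single-edge path (both endpoints of the edge
#' predetermined) is kept as a length-1 path constraint.
#'
#' @param graph,tree The pedigree graph and spanning tree.
#' @param ld A `zrhc_locus` for one locus.
#' @param e Non-tree edge id.
#' @return A list of zero or one constraint records.
#' @export
gen_edge_constraints <- function(graph, tree, ld, e) {
  if (!ld$in_el[e]) return(list())
  cy <- tree$cycles[[match(e, tree$xedges)]]
  if (all(ld$in_el[cy$edges])) {
    b <- sum(ld$d[cy$edges]) %% 2L
    return(list(list(type = "cycle", e = e, b = as.integer(b))))
  }
  nodes <- cy$nodes                       # u ... v along the tree path
  pedges <- cy$edges[-1]                  # tree-path edges, u-side first
  len <- length(nodes)
  walk <- function(from_start) {
    ord_n <- if (from_start) seq_len(len) else rev(seq_len(len))
    ord_e <- if (from_start) seq_along(pedges) else rev(seq_along(pedges))
    dsum <- 0L
    for (step in seq_len(len)) {
      v <- nodes[ord_n[step]]
      if (ld$pre[v]) return(list(stop = ord_n[step], dsum = dsum))
      k <- pedges[ord_e[step]]
      if (!ld$in_el[k]) {
        stop("internal: walk crossed a missing locus edge before a ",
             "predetermined node (locus ", ld$l, ", edge ", k, ")")
      }
      dsum <- (dsum + ld$d[k]) %% 2L
    }
    stop("internal: no predetermined node on the broken cycle of edge ", e)
  }
  a <- walk(TRUE); bside <- walk(FALSE)
  ni <- nodes[a$stop]; nj <- nodes[bside$stop]
  b <- (ld$pval[ni] + ld$pval[nj] + a$dsum + bside$dsum + ld$d[e]) %% 2L
  list(list(type = "path", ni = ni, nj = nj, b = as.integer(b), e = e,
            side = list(ni = nodes[1], nj = nodes[len])))
}

#' Tree constraints of one locus forest
#'
#' Per connected component of the locus forest containing at least one
#' predetermined node: the smallest-id predetermined node seeds a traversal
#' accumulating the d-sum, and one tree constraint `(seed, k, b_t)` is emitted
#' for every other predetermined node `k` in the component. Components with no
#' predetermined node (the locus is heterozygous across the whole component)
#' yield nothing.
#'
#' @param graph,tree The pedigree graph and spanning tree.
#' @param ld A `zrhc_locus`.
#' @return A list of tree-constraint records.
#' @export
gen_tree_constraints <- function(graph, tree, ld) {
  n <- graph$n
  active <- which(tree$is_tree & ld$in_el)   # locus-forest edges
  comp <- rep(0L, n); cid <- 0L
  adj <- vector("list", n)
  for (k in active) {
    a <- graph$edges$parent[k]; b <- graph$edges$child[k]
    adj[[a]] <- c(adj[[a]], k); adj[[b]] <- c(adj[[b]], k)
  }
  out <- list()
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cid <- cid + 1L
    members <- integer(); queue <- s; comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      members <- c(members, v)
      for (k in adj[[v]]) {
        u <- edge_other(graph, k, v)
        if (comp[u] == 0L) { comp[u] <- cid; queue <- c(queue, u) }
      }
    }
    pre_m <- members[ld$pre[members]]
    if (length(pre_m) < 2L) next
    seed <- min(pre_m)
    dsum <- rep(NA_integer_, n); dsum[seed] <- 0L
    queue <- seed
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (k in adj[[v]]) {
        u <- edge_other(graph, k, v)
        if (is.na(dsum[u])) {
          dsum[u] <- (dsum[v] + ld$d[k]) %% 2L
          queue <- c(queue, u)
        }
      }
    }
    for (nk in sort(setdiff(pre_m, seed))) {
      b <- (ld$pval[seed] + ld$pval[nk] + dsum[nk]) %% 2L
      out[[length(out) + 1L]] <- list(type = "tree", ni = seed, nj = nk,
                                      b = as.integer(b))
    }
  }
  out
}

#' Generate the full constraint system over all loci
#'
#' Runs [gen_edge_constraints()] for every non-tree edge and
#' [gen_tree_constraints()] for every locus forest, inserting through
#' [add_constraint()] so duplicates collapse and conflicts are logged.
#'
#' @param graph,tree The pedigree graph and spanning tree.
#' @param locusdata List of `zrhc_locus`, one per locus.
#' @return A `zrhc_constraints` environment.
#' @export
generate_constraints <- function(graph, tree, locusdata) {
  sys <- new_constraint_system()
  for (ld in locusdata) {
    for (e in tree$xedges) {
      for (con in gen_edge_constraints(graph, tree, ld, e)) {
        add_constraint(sys, con)
      }
    }
    for (con in gen_tree_constraints(graph, tree, ld)) {
      add_constraint(sys, con)
    }
  }
  sys
}
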