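#' Constraint graph with W-values
#'
#' Step 3 reduces the tree-constraint set to a constraint graph `G*`: nodes
#' are the individuals, one edge per tree constraint, and within each
#' connected component ("frame") every node carries a cumulative parity
#' `W[node]` relative to the frame seed (the smallest node id in the frame;
#' `W[seed] = 0`). Assignment is breadth-first; when a node is reached twice
#' the two derivations must agree — this is consistency checkpoint two, the
#' operational form of the triangle redundancy among tree constraints.
#' Isolated nodes form singleton frames with `W = 0`.
#'
#' Edge weights are stored as GF(2) expressions so that the same machinery
#' later carries the free linker variables introduced in Step 4.
#'
#' @name constraint-graph
NULL

new_gstar <- function(n) {
  gs <- new.env(parent = emptyenv())
  gs$n <- n
  gs$edges <- list()           # list(i, j, b = gf2_expr)
  gs$frame <- integer(n)
  gs$seed <- integer()         # seed node per frame id
  gs$W <- vector("list", n)
  gs$links <- list()           # non-tree connectivity links: list(e, i, j)
  gs$attach <- list()          # founder -> attachment child
  gs$conflicts <- character()
  class(gs) <- "zrhc_gstar"
  gs
}

#' @export
print.zrhc_gstar <- function(x, ...) {
  cat("<zrhc constraint graph: ", x$n, " nodes, ", length(x$edges),
      " edges, ", length(unique(x$frame)), " frame(s), ",
      length(x$links), " link(s)>\n", sep = "")
  invisible(x)
}

gstar_add_edge <- function(gstar, i, j, b) {
  if (!inherits(b, "gf2_expr")) b <- gf2(b)
  gstar$edges[[length(gstar$edges) + 1L]] <- list(i = i, j = j, b = b)
  invisible(gstar)
}

# recompute frames, seeds and W-values from scratch (breadth-first from each
# frame's smallest node); disagreement on revisit is checkpoint 2
recompute_gstar <- function(gstar) {
  n <- gstar$n
  adj <- vector("list", n)
  for (idx in seq_along(gstar$edges)) {
    ed <- gstar$edges[[idx]]
    adj[[ed$i]] <- c(adj[[ed$i]], idx)
    adj[[ed$j]] <- c(adj[[ed$j]], idx)
  }
  frame <- rep(0L, n); seed <- integer()
  W <- vector("list", n)
  fid <- 0L
  for (s in seq_len(n)) {
    if (frame[s] > 0L) next
    fid <- fid + 1L
    seed[fid] <- s
    frame[s] <- fid
    W[[s]] <- gf2_zero()
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (idx in adj[[v]]) {
        ed <- gstar$edges[[idx]]
        u <- if (ed$i == v) ed$j else ed$i
        cand <- gf2_add(W[[v]], ed$b)
        if (frame[u] == 0L) {
          frame[u] <- fid
          W[[u]] <- cand
          queue <- c(queue, u)
        } else if (!gf2_eq(W[[u]], cand)) {
          gstar$conflicts <- c(gstar$conflicts, paste0(
            "W-value disagreement at node ", u, ": ",
            gf2_format(W[[u]]), " vs ", gf2_format(cand)))
        }
      }
    }
  }
  gstar$frame <- frame
  gstar$seed <- seed
  gstar$W <- W
  invisible(gstar)
}

#' Transform path constraints through known cycle constraints (Type 1)
#'
#' For every non-tree edge `e` holding a cycle constraint `(b_c, e)`, each
#' path constraint `(n_i, n_j, b_p, e)` is linearly dependent on it together
#' with the tree path closing the cycle, so it is removed from `C^P` and
#' re-inserted as the tree constraint `(n_i, n_j, b_c + b_p)` (conflict
#' checked).
#'
#' @param system A `zrhc_constraints`.
#' @return The modified system, invisibly.
#' @export
transform_type1 <- function(system) {
  for (ekey in names(system$cc)) {
    bc <- system$cc[[ekey]]$b
    e <- system$cc[[ekey]]$e
    keys <- names(system$cp)
    for (key in keys) {
      pc <- system$cp[[key]]
      if (pc$e != e) next
      system$cp[[key]] <- NULL
      add_constraint(system, list(type = "tree", ni = pc$ni, nj = pc$nj,
                                  b = xor2(bc, pc$b)))
    }
  }
  invisible(system)
}

#' Build the constraint graph from the tree-constraint set
#'
#' @param system A `zrhc_constraints` (after [transform_type1()]).
#' @param n Number of individuals.
#' @return A `zrhc_gstar` with frames and W-values assigned.
#' @export
build_constraint_graph <- function(system, n) {
  gstar <- new_gstar(n)
  for (key in names(system$ct)) {
    ct <- system$ct[[key]]
    gstar_add_edge(gstar, ct$ni, ct$nj, gf2(ct$b))
  }
  recompute_gstar(gstar)
}

#' Extend the constraint graph by synthetic cycles
#'
#' Iterates over the global non-tree edges that lack a cycle constraint. For
#' each such edge `e`, its path constraints are viewed as edges of a
#' multigraph whose vertices are the current frames; an odd cycle in that
#' multigraph (a self-loop first — a single path constraint whose endpoints
#' share a frame — otherwise the first odd cycle found by deterministic
#' two-colouring from the smallest frame) supplies the missing cycle
#' constraint of `e` as `b_c = sum over the chosen constraints of
#' W[n_i] + W[n_j] + b_p`. The synthesised constraint then converts all of
#' `e`'s path constraints to tree constraints (Type 1), the frames touched
#' are merged (seed = smallest old seed, W re-assigned with conflict checks),
#' and `e` leaves the candidate set. The procedure stops when the set is
#' empty or a whole pass changes nothing.
#'
#' @param system A `zrhc_constraints`.
#' @param gstar A `zrhc_gstar`.
#' @param tree The spanning tree (for the global/local classification).
#' @return The updated `gstar`, invisibly.
#' @export
extend_by_synthetic_cycles <- function(system, gstar, tree) {
  es <- sort(setdiff(tree$global, as.integer(names(system$cc))))
  repeat {
    if (length(es) == 0L) break
    changed <- FALSE
    for (e in es) {
      pcs <- Filter(function(pc) pc$e == e, system$cp)
      if (length(pcs) == 0L) next
      pcs <- pcs[order(names(pcs))]
      se <- find_odd_cycle(gstar, pcs)
      if (is.null(se)) next
      bhat <- gf2_zero()
      for (pc in se) {
        bhat <- gf2_add(bhat, gf2_add(gstar$W[[pc$ni]],
                                      gf2_add(gstar$W[[pc$nj]], gf2(pc$b))))
      }
      stopifnot(gf2_is_const(bhat))
      add_constraint(system, list(type = "cycle", e = e, b = bhat$k))
      for (key in names(system$cp)) {
        pc <- system$cp[[key]]
        if (pc$e != e) next
        system$cp[[key]] <- NULL
        st <- add_constraint(system, list(type = "tree", ni = pc$ni,
                                          nj = pc$nj, b = xor2(bhat$k, pc$b)))
        if (st == "added") gstar_add_edge(gstar, pc$ni, pc$nj, gf2(xor2(bhat$k, pc$b)))
      }
      recompute_gstar(gstar)
      es <- setdiff(es, e)
      changed <- TRUE
    }
    if (!changed) break
  }
  invisible(gstar)
}

# odd multigraph cycle among the path constraints of one edge; vertices are
# frames. Self-loops first (the t = 0 special case), then two-colouring from
# the smallest frame id, first offending constraint in scan order.
find_odd_cycle <- function(gstar, pcs) {
  fi <- vapply(pcs, function(pc) gstar$frame[pc$ni], integer(1))
  fj <- vapply(pcs, function(pc) gstar$frame[pc$nj], integer(1))
  loop <- which(fi == fj)
  if (length(loop)) return(pcs[loop[1]])

  verts <- sort(unique(c(fi, fj)))
  color <- stats::setNames(rep(NA_integer_, length(verts)), verts)
  parent_edge <- stats::setNames(rep(NA_integer_, length(verts)), verts)
  parent_vert <- stats::setNames(rep(NA_integer_, length(verts)), verts)
  depth <- stats::setNames(rep(NA_integer_, length(verts)), verts)
  for (root in verts) {
    rk <- as.character(root)
    if (!is.na(color[rk])) next
    color[rk] <- 0L; depth[rk] <- 0L
    queue <- root
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      vk <- as.character(v)
      for (idx in seq_along(pcs)) {
        a <- fi[idx]; b <- fj[idx]
        u <- if (a == v) b else if (b == v) a else next
        uk <- as.character(u)
        if (is.na(color[uk])) {
          color[uk] <- 1L - color[vk]
          depth[uk] <- depth[vk] + 1L
          parent_edge[uk] <- idx
          parent_vert[uk] <- v
          queue <- c(queue, u)
        }
      }
    }
  }
  for (idx in seq_along(pcs)) {
    a <- as.character(fi[idx]); b <- as.character(fj[idx])
    if (color[a] == color[b]) {
      # odd cycle: this constraint plus the forest paths to the meeting point
      path <- integer()
      x <- fi[idx]; y <- fj[idx]
      while (depth[as.character(x)] > depth[as.character(y)]) {
        path <- c(path, parent_edge[as.character(x)])
        x <- parent_vert[as.character(x)]
      }
      while (depth[as.character(y)] > depth[as.character(x)]) {
        path <- c(path, parent_edge[as.character(y)])
        y <- parent_vert[as.character(y)]
      }
      while (x != y) {
        path <- c(path, parent_edge[as.character(x)], parent_edge[as.character(y)])
        x <- parent_vert[as.character(x)]
        y <- parent_vert[as.character(y)]
      }
      return(pcs[c(idx, path)])
    }
  }
  NULL
}
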