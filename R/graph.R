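#' Pedigree graph
#'
#' The undirected graph connecting each parent to each of its children. Nodes
#' are row indices into the (id-sorted) `zrhc_ped`; every edge is annotated
#' with which endpoint is the parent. Transmission (h) and d-constants are
#' symmetric, so one record per undirected edge suffices.
#'
#' @param ped A `zrhc_ped`.
#' @return A `zrhc_graph`: list with `n`, `edges` (tibble `parent`, `child`,
#'   `is_father`), and adjacency list `adj` (edge ids per node, sorted by
#'   neighbour id).
#' @export
build_graph <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  parent <- integer(); child <- integer(); is_father <- logical()
  for (j in seq_len(n)) {
    if (!is.na(ped$father[j])) {
      parent <- c(parent, idx[[ped$father[j]]], idx[[ped$mother[j]]])
      child <- c(child, j, j)
      is_father <- c(is_father, TRUE, FALSE)
    }
  }
  edges <- tibble::tibble(parent = parent, child = child, is_father = is_father)
  adj <- vector("list", n)
  other <- function(k, v) if (edges$parent[k] == v) edges$child[k] else edges$parent[k]
  for (v in seq_len(n)) adj[[v]] <- integer()
  for (k in seq_along(parent)) {
    adj[[parent[k]]] <- c(adj[[parent[k]]], k)
    adj[[child[k]]] <- c(adj[[child[k]]], k)
  }
  for (v in seq_len(n)) {
    nb <- vapply(adj[[v]], other, integer(1), v = v)
    adj[[v]] <- adj[[v]][order(nb)]
  }
  structure(list(n = n, edges = edges, adj = adj, labels = ped$id),
            class = "zrhc_graph")
}

edge_other <- function(graph, k, v) {
  if (graph$edges$parent[k] == v) graph$edges$child[k] else graph$edges$parent[k]
}

#' Spanning tree of the pedigree graph
#'
#' One depth-first spanning tree per connected component, rooted at the
#' smallest node id with neighbours visited in ascending id order, so repeated
#' runs on the same input give the same tree. Alternatively an explicit set of
#' non-tree edges can be imposed (used for worked examples where a particular
#' tree is wanted); it is validated to leave a spanning tree.
#'
#' Non-tree edges are classified by the shape of their fundamental cycle (the
#' edge plus the unique tree path between its endpoints): a length-4 cycle
#' formed by a couple and two of their common children is *local*, anything
#' else is *global*; `k` is the number of global non-tree edges, the pedigree's
#' effective mating-loop count under this tree.
#'
#' @param graph A `zrhc_graph`.
#' @param nontree Optional list of node-index pairs (or two-column matrix)
#'   naming the non-tree edges.
#' @return A `zrhc_tree`: tree membership per edge, rooted parent pointers,
#'   component ids, fundamental cycles and the local/global classification.
#' @export
build_spanning_tree <- function(graph, nontree = NULL) {
  n <- graph$n
  is_tree <- rep(FALSE, nrow(graph$edges))
  comp <- integer(n)

  if (is.null(nontree)) {
    visited <- rep(FALSE, n)
    cid <- 0L
    for (s in seq_len(n)) {
      if (visited[s]) next
      cid <- cid + 1L
      visited[s] <- TRUE
      comp[s] <- cid
      # iterative depth-first traversal with classic recursion semantics:
      # nodes are marked at discovery, neighbours tried in ascending id order
      stack_v <- s
      stack_i <- 1L
      while (length(stack_v)) {
        d <- length(stack_v)
        v <- stack_v[d]
        ks <- graph$adj[[v]]
        if (stack_i[d] > length(ks)) {
          stack_v <- stack_v[-d]; stack_i <- stack_i[-d]
          next
        }
        k <- ks[stack_i[d]]
        stack_i[d] <- stack_i[d] + 1L
        u <- edge_other(graph, k, v)
        if (!visited[u]) {
          visited[u] <- TRUE
          comp[u] <- cid
          is_tree[k] <- TRUE
          stack_v <- c(stack_v, u)
          stack_i <- c(stack_i, 1L)
        }
      }
    }
  } else {
    if (is.matrix(nontree)) nontree <- asplit(nontree, 1)
    xt <- vapply(nontree, function(pr) {
      hit <- which((graph$edges$parent == pr[1] & graph$edges$child == pr[2]) |
                   (graph$edges$parent == pr[2] & graph$edges$child == pr[1]))
      if (length(hit) != 1L) stop("no such edge: ", pr[1], "-", pr[2])
      hit
    }, integer(1))
    is_tree <- !(seq_len(nrow(graph$edges)) %in% xt)
    # components + validation by BFS over tree edges
    comp <- rep(0L, n); cid <- 0L
    for (s in seq_len(n)) {
      if (comp[s] > 0L) next
      cid <- cid + 1L
      queue <- s; comp[s] <- cid
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        for (k in graph$adj[[v]]) {
          if (!is_tree[k]) next
          u <- edge_other(graph, k, v)
          if (comp[u] == 0L) { comp[u] <- cid; queue <- c(queue, u) }
        }
      }
    }
    full <- integer(n); fc <- 0L
    for (s in seq_len(n)) {
      if (full[s] > 0L) next
      fc <- fc + 1L
      queue <- s; full[s] <- fc
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        for (k in graph$adj[[v]]) {
          u <- edge_other(graph, k, v)
          if (full[u] == 0L) { full[u] <- fc; queue <- c(queue, u) }
        }
      }
    }
    if (sum(is_tree) != n - fc || !identical(comp, full)) {
      stop("supplied non-tree edges do not leave a spanning tree")
    }
  }

  # rooted parent pointers per component (BFS from smallest node id)
  par_node <- rep(NA_integer_, n); par_edge <- rep(NA_integer_, n)
  depth <- rep(NA_integer_, n)
  for (cc in sort(unique(comp))) {
    root <- min(which(comp == cc))
    depth[root] <- 0L
    queue <- root
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (k in graph$adj[[v]]) {
        if (!is_tree[k]) next
        u <- edge_other(graph, k, v)
        if (is.na(depth[u])) {
          depth[u] <- depth[v] + 1L
          par_node[u] <- v; par_edge[u] <- k
          queue <- c(queue, u)
        }
      }
    }
  }

  xedges <- which(!is_tree)
  cycles <- lapply(xedges, function(k) {
    u <- graph$edges$parent[k]; v <- graph$edges$child[k]
    path <- tree_path(graph, par_node, par_edge, depth, u, v)
    list(edge = k, nodes = path$nodes, edges = c(k, path$edges))
  })
  is_local <- vapply(cycles, function(cy) local_cycle_p(graph, cy$nodes), logical(1))
  structure(list(
    is_tree = is_tree, comp = comp, par_node = par_node, par_edge = par_edge,
    depth = depth, xedges = xedges, cycles = cycles, is_local = is_local,
    local = xedges[is_local], global = xedges[!is_local],
    k = sum(!is_local)
  ), class = "zrhc_tree")
}

# unique tree path u..v: nodes from u to v, plus the tree edge ids along it
tree_path <- function(graph, par_node, par_edge, depth, u, v) {
  pu <- u; pv <- v
  eu <- integer(); ev <- integer()
  nu <- u; nv <- v
  while (depth[pu[length(pu)]] > depth[pv[length(pv)]]) {
    x <- pu[length(pu)]
    eu <- c(eu, par_edge[x]); pu <- c(pu, par_node[x])
  }
  while (depth[pv[length(pv)]] > depth[pu[length(pu)]]) {
    x <- pv[length(pv)]
    ev <- c(ev, par_edge[x]); pv <- c(pv, par_node[x])
  }
  while (pu[length(pu)] != pv[length(pv)]) {
    x <- pu[length(pu)]
    eu <- c(eu, par_edge[x]); pu <- c(pu, par_node[x])
    y <- pv[length(pv)]
    ev <- c(ev, par_edge[y]); pv <- c(pv, par_node[y])
  }
  list(nodes = c(pu, rev(pv[-length(pv)])), edges = c(eu, rev(ev)))
}

# couple + two common children, cycle of length 4
local_cycle_p <- function(graph, nodes) {
  if (length(nodes) != 4L) return(FALSE)
  ring <- c(nodes, nodes[1])
  parent_of <- matrix(NA_integer_, 4, 2)
  for (i in 1:4) {
    a <- ring[i]; b <- ring[i + 1]
    k <- which((graph$edges$parent == a & graph$edges$child == b) |
               (graph$edges$parent == b & graph$edges$child == a))[1]
    if (is.na(k)) return(FALSE)
    parent_of[i, ] <- c(graph$edges$parent[k], graph$edges$child[k])
  }
  pars <- parent_of[, 1]; kids <- parent_of[, 2]
  couple <- unique(pars); children <- unique(kids)
  length(couple) == 2L && length(children) == 2L &&
    !any(couple %in% children)
}

#' Classify non-tree edges and report fundamental cycles
#'
#' @param tree A `zrhc_tree`.
#' @param graph The `zrhc_graph` the tree was built on.
#' @return A tibble with one row per non-tree edge: endpoints, cycle length,
#'   class (`"local"`/`"global"`), and the cycle node sequence (list column).
#' @export
classify_nontree_edges <- function(tree, graph) {
  if (length(tree$xedges) == 0L) {
    return(tibble::tibble(edge = integer(), parent = integer(),
                          child = integer(), length = integer(),
                          class = character(), cycle = list()))
  }
  tibble::tibble(
    edge = tree$xedges,
    parent = graph$edges$parent[tree$xedges],
    child = graph$edges$child[tree$xedges],
    length = vapply(tree$cycles, function(cy) length(cy$nodes), integer(1)),
    class = ifelse(tree$is_local, "local", "global"),
    cycle = lapply(tree$cycles, function(cy) cy$nodes)
  )
}

#' Per-locus constants, locus graph membership and predetermined nodes
#'
#' For locus `l` this computes the heterozygosity indicator `w` per node, the
#' locus-graph edge membership (an edge is in `G_l` iff its parent endpoint is
#' heterozygous at `l`), the per-edge `d`-constant (0 on father edges, the
#' child's `w` on mother edges), and the predetermined paternal alleles:
#' a homozygous node is its own genotype; a heterozygous child of a homozygous
#' father takes the father's allele; a heterozygous child of a homozygous
#' mother takes the complement of the mother's allele. Single-locus Mendelian
#' feasibility is checked for every child.
#'
#' @param graph A `zrhc_graph`.
#' @param ped The `zrhc_ped` the graph was built from.
#' @param l Locus index.
#' @param strict If `TRUE`, Mendelian infeasibility raises an error naming the
#'   individual and locus; otherwise it is recorded in `$mendel`.
#' @return A `zrhc_locus` list: `w`, `in_el`, `d`, `pre`, `pval`, `mendel`.
#' @export
build_locus_data <- function(graph, ped, l, strict = FALSE) {
  g <- unname(ped_genotypes(ped)[, l])
  n <- graph$n
  w <- as.integer(g == 2L)
  in_el <- w[graph$edges$parent] == 1L
  d <- ifelse(graph$edges$is_father, 0L, w[graph$edges$child])

  pre <- g != 2L
  pval <- ifelse(pre, g, NA_integer_)
  mendel <- character()
  for (j in seq_len(n)) {
    if (is.na(ped$father[j])) next
    f <- g[match(ped$father[j], ped$id)]
    mo <- g[match(ped$mother[j], ped$id)]
    pf <- if (f == 2L) c(0L, 1L) else f       # alleles father can transmit
    pm <- if (mo == 2L) c(0L, 1L) else mo
    ok <- switch(as.character(g[j]),
      "0" = 0L %in% pf && 0L %in% pm,
      "1" = 1L %in% pf && 1L %in% pm,
      "2" = (0L %in% pf && 1L %in% pm) || (1L %in% pf && 0L %in% pm)
    )
    if (!ok) {
      msg <- paste0("Mendelian infeasibility: individual ", ped$id[j],
                    " at locus ", l, " (father g=", f, ", mother g=", mo,
                    ", child g=", g[j], ")")
      if (strict) stop(msg)
      mendel <- c(mendel, msg)
    }
    if (g[j] == 2L && !pre[j]) {
      if (f != 2L) { pre[j] <- TRUE; pval[j] <- f }
      else if (mo != 2L) { pre[j] <- TRUE; pval[j] <- 1L - mo }
    }
  }
  structure(list(l = l, w = w, in_el = in_el, d = as.integer(d),
                 pre = pre, pval = pval, mendel = mendel),
            class = "zrhc_locus")
}
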