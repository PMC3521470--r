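#' Haplotype determination (founder attachment, linking, free variables)
#'
#' Step 4 makes the constraint graph connected so Lemma-2 extraction
#' (`h = W[i] + W[j]` for tree edges within a frame) covers as many
#' transmission indicators as possible, then determines the paternal-allele
#' expressions locus by locus.
#'
#' @name haplotype-determination
NULL

#' Attach founders to the constraint graph
#'
#' Founders can never be endpoints of path or tree constraints, so they sit in
#' singleton frames. Each founder with at least one tree child is attached to
#' its smallest-id tree child by a weight-0 edge, the convention that the
#' founder transmits its paternal haplotype to that child (`h = 0`); the
#' labelling of a founder's two haplotypes is arbitrary, so this is a gauge
#' choice, not a restriction on genotypes.
#'
#' @param gstar A `zrhc_gstar`.
#' @param tree,graph Spanning tree and pedigree graph.
#' @param ped The pedigree (for founder identification).
#' @return The updated `gstar`, invisibly.
#' @export
attach_founders <- function(gstar, tree, graph, ped) {
  for (f in which(is_founder(ped))) {
    if (sum(gstar$frame == gstar$frame[f]) > 1L) {
      warning("founder ", ped$id[f], " is not an isolated constraint-graph ",
              "node; skipping attachment")
      next
    }
    ks <- graph$adj[[f]]
    ks <- ks[tree$is_tree[ks] & graph$edges$parent[ks] == f]
    if (length(ks) == 0L) next
    child <- min(graph$edges$child[ks])
    gstar_add_edge(gstar, f, child, gf2(0L))
    gstar$attach[[as.character(f)]] <- child
    recompute_gstar(gstar)
  }
  invisible(gstar)
}

#' Link frames through remaining path constraints
#'
#' A leftover path constraint `(n_k, n_l, b_p, e = (n_i, n_j))` whose side
#' pairs `(n_k, n_i)` and `(n_l, n_j)` each lie within one W-frame determines
#' the non-tree edge's transmission indicator,
#' `h_e = b_p + W[n_k] + W[n_i] + W[n_j] + W[n_l]`. If the two frames differ,
#' `e` additionally links them in the connectivity sense — but without a
#' W-relation, because the relation between the two frames' origins is the
#' unobserved cycle constraint of `e`. Runs to a fixpoint; disagreeing
#' determinations of the same `h` are logged as conflicts.
#'
#' @param gstar A `zrhc_gstar`.
#' @param system The constraint system (remaining `C^P`).
#' @param sol Solution environment carrying `h` (list per edge id).
#' @return `gstar`, invisibly.
#' @export
link_by_path_constraints <- function(gstar, system, sol) {
  applied <- character()
  repeat {
    progress <- FALSE
    for (key in sort(names(system$cp))) {
      if (key %in% applied) next
      pc <- system$cp[[key]]
      ei <- pc$side$ni; ej <- pc$side$nj   # e endpoints paired with ni / nj
      if (gstar$frame[pc$ni] != gstar$frame[ei]) next
      if (gstar$frame[pc$nj] != gstar$frame[ej]) next
      h <- gf2_add(gf2(pc$b),
                   gf2_add(gf2_add(gstar$W[[pc$ni]], gstar$W[[ei]]),
                           gf2_add(gstar$W[[pc$nj]], gstar$W[[ej]])))
      ek <- as.character(pc$e)
      if (!is.null(sol$h[[ek]])) {
        if (!gf2_eq(sol$h[[ek]], h)) {
          sol$conflicts <- c(sol$conflicts, paste0(
            "conflicting determinations of h on non-tree edge ", ek, ": ",
            gf2_format(sol$h[[ek]]), " vs ", gf2_format(h)))
        }
      } else {
        sol$h[[ek]] <- h
      }
      if (gstar$frame[ei] != gstar$frame[ej]) {
        gstar$links[[length(gstar$links) + 1L]] <-
          list(e = pc$e, i = ei, j = ej)
      }
      applied <- c(applied, key)
      progress <- TRUE
    }
    if (!progress) break
  }
  invisible(gstar)
}

# connectivity components over frames: frames merged by non-tree links
frame_connectivity <- function(gstar) {
  nf <- length(gstar$seed)
  parent <- seq_len(nf)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (lk in gstar$links) {
    a <- find(gstar$frame[lk$i]); b <- find(gstar$frame[lk$j])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  vapply(seq_len(nf), find, integer(1))
}

#' Connect residual components with free variables
#'
#' After founder attachment and linking, `t` connectivity components may
#' remain within each pedigree component. `t - 1` extra constraint-graph
#' edges are introduced in a star from the component containing the smallest
#' node id, joining frame seeds, each weighted by a fresh linker variable:
#' the unknown tree constraint between the two seeds. No edge is added
#' between frames already joined by a non-tree link.
#'
#' @param gstar A `zrhc_gstar`.
#' @param tree Spanning tree (for pedigree components).
#' @param registry Free-variable registry.
#' @param labels Individual ids, for provenance strings.
#' @return `gstar`, invisibly.
#' @export
connect_free <- function(gstar, tree, registry, labels) {
  for (pc_id in sort(unique(tree$comp))) {
    nodes <- which(tree$comp == pc_id)
    repeat {
      conn <- frame_connectivity(gstar)
      comp_of_node <- conn[gstar$frame[nodes]]
      comps <- sort(unique(comp_of_node))
      if (length(comps) <= 1L) break
      hub_comp <- comp_of_node[which.min(nodes)]
      hub_seed <- gstar$seed[gstar$frame[min(nodes)]]
      other <- setdiff(comps, hub_comp)
      mins <- vapply(other, function(cc) min(nodes[comp_of_node == cc]), integer(1))
      for (oc in other[order(mins)]) {
        onode <- min(nodes[comp_of_node == oc])
        oseed <- gstar$seed[gstar$frame[onode]]
        vid <- fresh_var(registry, "linker", paste0(
          "link between components seeded at ", labels[hub_seed],
          " and ", labels[oseed]))
        gstar_add_edge(gstar, hub_seed, oseed, gf2(0L, vid))
      }
      recompute_gstar(gstar)
    }
  }
  invisible(gstar)
}

#' Extract transmission-indicator expressions from the constraint graph
#'
#' Every tree edge whose endpoints share a W-frame gets `h = W[i] + W[j]`
#' (Lemma 2). A non-tree edge carrying a cycle constraint `b_c` whose
#' endpoints share a frame gets `h = b_c + W[i] + W[j]` (immediate from the
#' cycle equation). Non-tree links keep their recorded expressions; anything
#' else stays unknown and is recovered, where the data determine it, during
#' p-propagation.
#'
#' @param gstar A `zrhc_gstar`.
#' @param tree,graph Spanning tree and pedigree graph.
#' @param system Constraint system (for cycle constraints).
#' @param sol Solution environment; `sol$h` is filled in place.
#' @return `sol`, invisibly.
#' @export
extract_h <- function(gstar, tree, graph, system, sol) {
  for (k in seq_len(nrow(graph$edges))) {
    ek <- as.character(k)
    i <- graph$edges$parent[k]; j <- graph$edges$child[k]
    if (tree$is_tree[k]) {
      if (gstar$frame[i] == gstar$frame[j]) {
        sol$h[[ek]] <- gf2_add(gstar$W[[i]], gstar$W[[j]])
      }
    } else if (!is.null(system$cc[[ek]]) &&
               gstar$frame[i] == gstar$frame[j]) {
      h <- gf2_add(gf2(system$cc[[ek]]$b), gf2_add(gstar$W[[i]], gstar$W[[j]]))
      if (!is.null(sol$h[[ek]])) {
        if (!gf2_eq(sol$h[[ek]], h)) {
          sol$conflicts <- c(sol$conflicts, paste0(
            "cycle-constraint h for edge ", ek, " disagrees with linked value"))
        }
      } else {
        sol$h[[ek]] <- h
      }
    }
  }
  invisible(sol)
}

# --- p-determination ------------------------------------------------------

new_solution <- function(n_edges, n, m) {
  sol <- new.env(parent = emptyenv())
  sol$h <- vector("list", n_edges)
  names(sol$h) <- as.character(seq_len(n_edges))
  sol$p <- lapply(seq_len(n), function(i) vector("list", m))
  sol$conflicts <- character()
  sol$conflict_sites <- character()
  sol$eliminated <- list()     # var id (chr) -> gf2_expr in surviving vars
  class(sol) <- "zrhc_solution"
  sol
}

# substitute all eliminated variables into an expression
sol_subst <- function(sol, expr) {
  if (is.null(expr) || length(sol$eliminated) == 0L) return(expr)
  repeat {
    hit <- intersect(as.character(expr$v), names(sol$eliminated))
    if (length(hit) == 0L) return(expr)
    for (vk in hit) {
      expr <- gf2_add(gf2_add(expr, gf2(0L, as.integer(vk))),
                      sol$eliminated[[vk]])
    }
  }
}

# a relation expr == 0 among free variables: constant 0 is vacuous, constant 1
# a genuine conflict, otherwise the highest-id variable is substituted out
sol_bind <- function(sol, relation, where) {
  relation <- sol_subst(sol, relation)
  if (gf2_is_const(relation)) {
    if (relation$k == 1L) {
      sol$conflicts <- c(sol$conflicts, paste0("inconsistency at ", where))
    }
    return(invisible(sol))
  }
  vid <- max(relation$v)
  rest <- gf2_add(relation, gf2(0L, vid))   # vid = rest
  sol$eliminated[[as.character(vid)]] <- rest
  for (vk in names(sol$eliminated)) {
    sol$eliminated[[vk]] <- sol_subst(sol, sol$eliminated[[vk]])
  }
  for (ek in names(sol$h)) {
    if (!is.null(sol$h[[ek]])) sol$h[[ek]] <- sol_subst(sol, sol$h[[ek]])
  }
  for (i in seq_along(sol$p)) {
    for (l in seq_along(sol$p[[i]])) {
      if (!is.null(sol$p[[i]][[l]])) {
        sol$p[[i]][[l]] <- sol_subst(sol, sol$p[[i]][[l]])
      }
    }
  }
  invisible(sol)
}

#' Determine paternal-allele expressions at every locus
#'
#' Seeds every predetermined node with its constant p-value, then propagates
#' `p_child = p_parent + h + d` across locus-graph edges with known
#' transmission expressions, in both directions, to a fixpoint across loci.
#' When two derivations of the same value meet they must agree; a
#' disagreement that still contains free variables binds them (one variable
#' is substituted out), a constant disagreement is a genotype inconsistency.
#' Before any free phase variable is introduced, edges with unknown `h` whose
#' endpoints are both determined at a heterozygous locus have their `h`
#' recovered there (`h = p_i + p_j + d`). Only when neither propagation nor
#' recovery makes progress is the genuinely free phase of a fully
#' heterozygous region realised: a fresh anchor variable becomes the p-value
#' of the smallest undetermined (locus, node) pair, and propagation resumes.
#'
#' @param graph Pedigree graph.
#' @param locusdata List of per-locus data.
#' @param sol Solution environment (after [extract_h()]).
#' @param registry Free-variable registry.
#' @param labels Individual ids for provenance.
#' @return `sol`, invisibly.
#' @export
propagate_p <- function(graph, locusdata, sol, registry, labels) {
  m <- length(locusdata)
  n <- graph$n
  ne <- nrow(graph$edges)
  for (l in seq_len(m)) {
    ld <- locusdata[[l]]
    for (i in which(ld$pre)) sol$p[[i]][[l]] <- gf2(ld$pval[i])
  }
  repeat {
    progress <- FALSE
    # propagation sweeps over every locus graph
    repeat {
      swept <- FALSE
      for (l in seq_len(m)) {
        ld <- locusdata[[l]]
        for (k in which(ld$in_el)) {
          h <- sol$h[[as.character(k)]]
          if (is.null(h)) next
          a <- graph$edges$parent[k]; b <- graph$edges$child[k]
          pa <- sol$p[[a]][[l]]; pb <- sol$p[[b]][[l]]
          if (is.null(pa) && is.null(pb)) next
          step <- gf2_add(h, gf2(ld$d[k]))
          if (is.null(pb)) {
            sol$p[[b]][[l]] <- sol_subst(sol, gf2_add(pa, step))
            swept <- TRUE
          } else if (is.null(pa)) {
            sol$p[[a]][[l]] <- sol_subst(sol, gf2_add(pb, step))
            swept <- TRUE
          } else {
            want <- sol_subst(sol, gf2_add(pa, step))
            have <- sol_subst(sol, pb)
            if (!gf2_eq(want, have)) {
              rel <- gf2_add(want, have)
              where <- paste0("edge ", labels[a], "-", labels[b],
                              " at locus ", l)
              if (gf2_is_const(rel)) {
                # genuine genotype inconsistency; log once, no progress
                if (!(where %in% sol$conflict_sites)) {
                  sol$conflict_sites <- c(sol$conflict_sites, where)
                  sol$conflicts <- c(sol$conflicts,
                                     paste0("inconsistency at ", where))
                }
              } else {
                sol_bind(sol, rel, where)
                swept <- TRUE
              }
            }
          }
        }
      }
      if (!swept) break
      progress <- TRUE
    }
    # recover unknown h where the data now determine it
    for (k in seq_len(ne)) {
      ek <- as.character(k)
      if (!is.null(sol$h[[ek]])) next
      a <- graph$edges$parent[k]; b <- graph$edges$child[k]
      for (l in seq_len(m)) {
        ld <- locusdata[[l]]
        if (!ld$in_el[k]) next
        pa <- sol$p[[a]][[l]]; pb <- sol$p[[b]][[l]]
        if (is.null(pa) || is.null(pb)) next
        sol$h[[ek]] <- sol_subst(sol, gf2_add(gf2_add(pa, pb), gf2(ld$d[k])))
        progress <- TRUE
        break
      }
    }
    if (progress) next
    # free phase of a fully heterozygous region: one anchor, then resume
    anchored <- FALSE
    for (l in seq_len(m)) {
      und <- which(vapply(seq_len(n), function(i) is.null(sol$p[[i]][[l]]),
                          logical(1)))
      if (length(und) == 0L) next
      i <- min(und)
      vid <- fresh_var(registry, "anchor", paste0(
        "phase of individual ", labels[i], " at locus ", l))
      sol$p[[i]][[l]] <- gf2(0L, vid)
      anchored <- TRUE
      break
    }
    if (!anchored) break
  }
  invisible(sol)
}

#' Audit a solved family
#'
#' Re-checks the inheritance identity at every edge and locus with a known
#' transmission expression, derives the transmission of every still-unknown
#' edge at each heterozygous locus and asserts all derivations agree (the
#' zero-recombination condition across loci), and reports edges with no
#' heterozygous locus as unconstrained. Also confirms every homozygous
#' genotype is reproduced. Findings are returned in the status, never thrown.
#'
#' @param sol Solution environment.
#' @param graph Pedigree graph.
#' @param locusdata Per-locus data list.
#' @param labels Individual ids.
#' @return A list with `status` (`"consistent"` or `"inconsistent"`),
#'   `conflicts`, and `unconstrained_edges`.
#' @export
verify_family <- function(sol, graph, locusdata, labels) {
  conflicts <- character()
  unconstrained <- integer()
  m <- length(locusdata)
  for (k in seq_len(nrow(graph$edges))) {
    ek <- as.character(k)
    a <- graph$edges$parent[k]; b <- graph$edges$child[k]
    h <- sol$h[[ek]]
    if (!is.null(h)) {
      for (l in seq_len(m)) {
        ld <- locusdata[[l]]
        pa <- sol$p[[a]][[l]]; pb <- sol$p[[b]][[l]]
        if (is.null(pa) || is.null(pb)) next
        lhs <- gf2_add(pa, gf2_scale(ld$w[a], h))
        rhs <- gf2_add(pb, gf2(ld$d[k]))
        if (!gf2_eq(sol_subst(sol, lhs), sol_subst(sol, rhs))) {
          conflicts <- c(conflicts, paste0(
            "inheritance identity fails on edge ", labels[a], "-", labels[b],
            " at locus ", l))
        }
      }
    } else {
      derived <- NULL
      for (l in seq_len(m)) {
        ld <- locusdata[[l]]
        if (!ld$in_el[k]) next
        pa <- sol$p[[a]][[l]]; pb <- sol$p[[b]][[l]]
        if (is.null(pa) || is.null(pb)) next
        d <- sol_subst(sol, gf2_add(gf2_add(pa, pb), gf2(ld$d[k])))
        if (is.null(derived)) derived <- d
        else if (!gf2_eq(derived, d)) {
          conflicts <- c(conflicts, paste0(
            "recombination required on edge ", labels[a], "-", labels[b],
            " (transmission differs across loci)"))
        }
      }
      if (is.null(derived)) unconstrained <- c(unconstrained, k)
    }
  }
  for (l in seq_len(m)) {
    ld <- locusdata[[l]]
    for (i in which(ld$pre)) {
      pe <- sol$p[[i]][[l]]
      if (is.null(pe)) next
      if (!gf2_eq(sol_subst(sol, pe), gf2(ld$pval[i]))) {
        conflicts <- c(conflicts, paste0(
          "predetermined allele not reproduced for ", labels[i],
          " at locus ", l))
      }
    }
  }
  list(status = if (length(conflicts)) "inconsistent" else "consistent",
       conflicts = conflicts, unconstrained_edges = unconstrained)
}
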