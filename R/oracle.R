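#' Brute-force enumeration of all zero-recombinant configurations
#'
#' Independent of the constraint-graph solver: enumerates every assignment of
#' transmission bits over the edges whose parent endpoint is heterozygous at
#' some locus (other transmissions cannot affect alleles), propagates the
#' inheritance relation per locus over all edges from the homozygous
#' genotypes, and branches on connected components that are heterozygous
#' throughout. Intended for small instances only; used as the oracle in
#' equivalence and error-detection tests.
#'
#' @param ped A genotyped `zrhc_ped`.
#' @param max_h_bits Refuse if more than this many transmission bits would be
#'   enumerated.
#' @return A list of distinct valid paternal-allele matrices (possibly
#'   empty).
#' @export
zrhc_bruteforce <- function(ped, max_h_bits = 16L) {
  g <- ped_genotypes(ped)
  n <- nrow(g); m <- ncol(g)
  graph <- build_graph(ped)
  ne <- nrow(graph$edges)
  w <- g == 2L
  relevant <- which(vapply(seq_len(ne), function(k) {
    any(w[graph$edges$parent[k], ])
  }, logical(1)))
  if (length(relevant) > max_h_bits) {
    stop("too many transmission bits to enumerate (", length(relevant), ")")
  }

  # connected components of the pedigree graph
  comp <- rep(0L, n); cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cid <- cid + 1L
    queue <- s; comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (k in graph$adj[[v]]) {
        u <- edge_other(graph, k, v)
        if (comp[u] == 0L) { comp[u] <- cid; queue <- c(queue, u) }
      }
    }
  }

  propagate <- function(h, l, seeds) {
    # seeds: named p-values to start from; returns full vector or NULL
    p <- rep(NA_integer_, n)
    p[as.integer(names(seeds))] <- as.integer(seeds)
    queue <- as.integer(names(seeds))
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (k in graph$adj[[v]]) {
        a <- graph$edges$parent[k]; b <- graph$edges$child[k]
        d <- if (graph$edges$is_father[k]) 0L else as.integer(w[b, l])
        step <- (as.integer(w[a, l]) * h[k] + d) %% 2L
        u <- if (a == v) b else a
        val <- (p[v] + step) %% 2L
        if (is.na(p[u])) { p[u] <- val; queue <- c(queue, u) }
        else if (p[u] != val) return(NULL)
      }
    }
    p
  }

  results <- list(); seen <- character()
  combos <- as.matrix(expand.grid(rep(list(0:1), length(relevant))))
  if (nrow(combos) == 0L) combos <- matrix(0L, 1, 0)
  for (r in seq_len(nrow(combos))) {
    h <- rep(0L, ne)
    h[relevant] <- as.integer(combos[r, ])
    per_locus <- vector("list", m)
    bad <- FALSE
    for (l in seq_len(m)) {
      per_comp <- vector("list", cid)
      for (cc in seq_len(cid)) {
        nodes <- which(comp == cc)
        fixed <- nodes[g[nodes, l] != 2L]
        if (length(fixed)) {
          seeds <- stats::setNames(g[fixed, l], fixed)
          p <- propagate(h, l, seeds)
          if (is.null(p)) { bad <- TRUE; break }
          per_comp[[cc]] <- list(p[nodes])
        } else {
          root <- min(nodes)
          choices <- list()
          for (bit in 0:1) {
            p <- propagate(h, l, stats::setNames(bit, root))
            if (!is.null(p)) choices[[length(choices) + 1L]] <- p[nodes]
          }
          if (length(choices) == 0L) { bad <- TRUE; break }
          per_comp[[cc]] <- choices
        }
      }
      if (bad) break
      # cartesian product over components at this locus
      grid <- expand.grid(lapply(per_comp, seq_along))
      vecs <- lapply(seq_len(nrow(grid)), function(rr) {
        p <- integer(n)
        for (cc in seq_len(cid)) {
          p[comp == cc] <- per_comp[[cc]][[grid[rr, cc]]]
        }
        p
      })
      per_locus[[l]] <- vecs
    }
    if (bad) next
    grid <- expand.grid(lapply(per_locus, seq_along))
    for (rr in seq_len(nrow(grid))) {
      p <- matrix(NA_integer_, n, m, dimnames = list(ped$id, NULL))
      for (l in seq_len(m)) p[, l] <- per_locus[[l]][[grid[rr, l]]]
      key <- paste(p, collapse = "")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        results[[length(results) + 1L]] <- p
      }
    }
  }
  results
}

#' Set-comparison key for configuration lists
#'
#' @param configs List of paternal-allele matrices.
#' @return Sorted character vector of flattened keys.
#' @export
config_keys <- function(configs) {
  sort(vapply(configs, function(p) paste(p, collapse = ""), character(1)))
}
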