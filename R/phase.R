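#' Phase a pedigree under zero recombination
#'
#' Runs the whole pipeline: pedigree graph and spanning tree, per-locus
#' constants and Mendelian feasibility, constraint generation with
#' deduplication, Type-1 reduction, constraint graph with W-values, synthetic
#' cycles for mating loops, founder attachment, linking, free variables, and
#' finally per-locus determination of every paternal-allele expression. The
#' result is a *general* solution: every haplotype configuration compatible
#' with the genotypes, parameterised by free GF(2) variables, plus a
#' consistency status collecting any Mendelian or cross-locus conflicts.
#'
#' @param ped A `zrhc_ped` (or data frame coercible via [as_zrhc_ped()]).
#' @param nontree Optional explicit non-tree edge set, as a list of pairs of
#'   individual ids; mostly useful to reproduce worked examples with a
#'   particular spanning tree.
#' @return A `zrhc_fit` object; see [tidy.zrhc_fit()], [glance.zrhc_fit()],
#'   [enumerate_solutions()], [write_outputs()].
#' @examples
#' ped <- sim_zrhc(n = 12, m = 6, loops = 0, seed = 1)$ped
#' fit <- zrhc_phase(ped)
#' glance(fit)
#' @export
zrhc_phase <- function(ped, nontree = NULL) {
  ped <- as_zrhc_ped(ped)
  m <- ped_m(ped)
  if (m < 1L) stop("pedigree has no genotype columns (g1, g2, ...)")
  graph <- build_graph(ped)
  nt_idx <- NULL
  if (!is.null(nontree)) {
    idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
    nt_idx <- lapply(nontree, function(pr) unname(idx[as.character(pr)]))
  }
  tree <- build_spanning_tree(graph, nontree = nt_idx)
  locusdata <- lapply(seq_len(m), function(l) build_locus_data(graph, ped, l))
  mendel <- unlist(lapply(locusdata, function(ld) ld$mendel))

  system <- generate_constraints(graph, tree, locusdata)
  stats0 <- c(n_cycle = length(system$cc), n_path = length(system$cp),
              n_tree = length(system$ct))
  transform_type1(system)
  gstar <- build_constraint_graph(system, graph$n)
  n_frames_initial <- length(gstar$seed)
  extend_by_synthetic_cycles(system, gstar, tree)

  registry <- new_registry()
  sol <- new_solution(nrow(graph$edges), graph$n, m)
  attach_founders(gstar, tree, graph, ped)
  link_by_path_constraints(gstar, system, sol)
  connect_free(gstar, tree, registry, ped$id)
  extract_h(gstar, tree, graph, system, sol)
  propagate_p(graph, locusdata, sol, registry, ped$id)
  ver <- verify_family(sol, graph, locusdata, ped$id)

  conflicts <- unique(c(mendel, system$conflicts, gstar$conflicts,
                        sol$conflicts, ver$conflicts))
  free_ids <- setdiff(as.character(seq_len(registry$next_id) - 1L),
                      names(sol$eliminated))
  fit <- structure(list(
    ped = ped, graph = graph, tree = tree, locusdata = locusdata,
    system = system, gstar = gstar, registry = registry, sol = sol,
    h = sol$h, p = sol$p,
    free_vars = as.integer(free_ids),
    unconstrained_edges = ver$unconstrained_edges,
    status = if (length(conflicts)) "inconsistent" else "consistent",
    conflicts = tibble::tibble(message = conflicts),
    stats = c(stats0, n_frames_initial = n_frames_initial,
              k = tree$k, n = graph$n, m = m)
  ), class = "zrhc_fit")
  fit
}

#' Consistency check of a genotyped pedigree
#'
#' Runs the same pipeline as [zrhc_phase()] but is read for its verdict: does
#' a zero-recombinant haplotype configuration exist for these genotypes?
#'
#' @param ped A `zrhc_ped` or coercible data frame.
#' @return A list with `consistent` (logical) and `conflicts` (tibble).
#' @export
zrhc_check <- function(ped) {
  fit <- zrhc_phase(ped)
  list(consistent = fit$status == "consistent", conflicts = fit$conflicts)
}

#' @export
print.zrhc_fit <- function(x, ...) {
  s <- x$stats
  cat("<zrhc fit>  n = ", s[["n"]], ", m = ", s[["m"]],
      ", mating loops (k) = ", s[["k"]], "\n",
      "  constraints: cycle ", s[["n_cycle"]], ", path ", s[["n_path"]],
      ", tree ", s[["n_tree"]], "; initial frames ", s[["n_frames_initial"]],
      "\n  free variables: ", length(x$free_vars),
      "   status: ", x$status, "\n", sep = "")
  invisible(x)
}

#' Tidy the particular solution of a fit
#'
#' One row per individual with the paternal and maternal haplotype strings of
#' the particular solution (all free variables 0) and whether any locus of
#' that individual depends on a free variable.
#'
#' @param x A `zrhc_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.zrhc_fit <- function(x, ...) {
  dep <- vapply(seq_len(nrow(x$ped)), function(i) {
    any(vapply(x$p[[i]], function(e) !is.null(e) && length(e$v) > 0L,
               logical(1)))
  }, logical(1))
  dplyr::mutate(haplotype_tbl(x), depends_on_free = dep)
}

#' One-row summary of a fit
#' @param x A `zrhc_fit`.
#' @param ... Unused.
#' @return A one-row tibble with sizes, constraint counts, free-variable
#'   count and status.
#' @export
glance.zrhc_fit <- function(x, ...) {
  s <- x$stats
  tibble::tibble(
    n = s[["n"]], m = s[["m"]], k = s[["k"]],
    n_cycle_constraints = s[["n_cycle"]],
    n_path_constraints = s[["n_path"]],
    n_tree_constraints = s[["n_tree"]],
    n_frames_initial = s[["n_frames_initial"]],
    n_free_vars = length(x$free_vars),
    status = x$status
  )
}

#' Plot the particular solution as a haplotype map
#'
#' Individuals by loci, tile-filled with the paternal allele of the
#' particular solution; heterozygous genotypes are outlined.
#'
#' @param object A `zrhc_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.zrhc_fit <- function(object, ...) {
  p <- particular_p(object)
  g <- ped_genotypes(object$ped)
  df <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(p, .name_repair = ~paste0("L", seq_along(.x))),
                  id = rownames(p)),
    -"id", names_to = "locus", values_to = "paternal")
  df$locus <- as.integer(sub("^L", "", df$locus))
  df$het <- as.vector(t(g == 2L))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$locus, y = .data$id)) +
    ggplot2::geom_tile(ggplot2::aes(fill = factor(.data$paternal)),
                       colour = "grey80") +
    ggplot2::geom_point(data = df[df$het, ], shape = 1, size = 1.5) +
    ggplot2::scale_fill_manual(values = c(`0` = "#7fc6ff", `1` = "#1f4e8c"),
                               name = "paternal allele") +
    ggplot2::labs(x = "locus", y = "individual",
                  title = "Particular zero-recombinant phasing",
                  subtitle = "circles mark heterozygous genotypes") +
    ggplot2::theme_minimal()
}

#' Enumerate every haplotype configuration of the general solution
#'
#' Instantiates each assignment of the surviving free variables and returns
#' the distinct paternal-allele matrices.
#'
#' @param fit A `zrhc_fit` with status `"consistent"`.
#' @param max_vars Refuse to enumerate beyond this many free variables.
#' @return A list of n x m integer matrices (rownames = individual ids).
#' @export
enumerate_solutions <- function(fit, max_vars = 16L) {
  vars <- fit$free_vars
  if (length(vars) > max_vars) {
    stop("too many free variables (", length(vars), " > ", max_vars, ")")
  }
  combos <- if (length(vars)) {
    as.matrix(expand.grid(rep(list(0:1), length(vars))))
  } else {
    matrix(0L, 1, 0)
  }
  out <- list()
  seen <- character()
  for (r in seq_len(nrow(combos))) {
    assign <- stats::setNames(as.list(as.integer(combos[r, ])),
                              as.character(vars))
    for (vk in names(fit$sol$eliminated)) {
      assign[[vk]] <- gf2_eval(fit$sol$eliminated[[vk]], assign)
    }
    p <- particular_p(fit, assignment = unlist(assign))
    key <- paste(p, collapse = "")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- p
    }
  }
  out
}

#' Validity of one haplotype configuration
#'
#' A paternal-allele matrix is a valid zero-recombinant configuration iff it
#' reproduces every homozygous genotype, satisfies the inheritance relation
#' on every edge at loci where the parent is homozygous, and admits one
#' constant transmission bit per parent-child edge across all loci where the
#' parent is heterozygous.
#'
#' @param ped A `zrhc_ped`.
#' @param p An n x m 0/1 matrix of paternal alleles (rows in `ped` id order).
#' @return `TRUE` or `FALSE`.
#' @export
check_configuration <- function(ped, p) {
  g <- ped_genotypes(ped)
  if (any(p[g != 2L] != g[g != 2L])) return(FALSE)
  graph <- build_graph(ped)
  m <- ncol(g)
  w <- g == 2L
  for (k in seq_len(nrow(graph$edges))) {
    a <- graph$edges$parent[k]; b <- graph$edges$child[k]
    d <- if (graph$edges$is_father[k]) rep(0L, m) else as.integer(w[b, ])
    hom <- !w[a, ]
    if (any(p[b, hom] != (p[a, hom] + d[hom]) %% 2L)) return(FALSE)
    het <- which(w[a, ])
    if (length(het)) {
      hbits <- (p[a, het] + p[b, het] + d[het]) %% 2L
      if (length(unique(hbits)) > 1L) return(FALSE)
    }
  }
  TRUE
}

#' Canonicalise founder phase of a configuration
#'
#' The labelling of a founder's two haplotypes is arbitrary; the solver fixes
#' it by the convention that each founder transmits its *paternal* haplotype
#' to its smallest-id tree child. This helper maps any valid configuration to
#' the representative of its founder-flip orbit under the same convention, so
#' configurations can be compared with the solver's family.
#'
#' @param fit A `zrhc_fit` (supplies the attachment convention).
#' @param p A valid paternal-allele matrix.
#' @return The canonicalised matrix.
#' @export
canonical_phase <- function(fit, p) {
  g <- ped_genotypes(fit$ped)
  w <- g == 2L
  for (fk in names(fit$gstar$attach)) {
    f <- as.integer(fk)
    c_ <- fit$gstar$attach[[fk]]
    het <- which(w[f, ])
    if (length(het) == 0L) next
    k <- which(fit$graph$edges$parent == f & fit$graph$edges$child == c_)[1]
    l <- het[1]
    d <- if (fit$graph$edges$is_father[k]) 0L else as.integer(w[c_, l])
    h <- (p[f, l] + p[c_, l] + d) %% 2L
    if (h == 1L) p[f, het] <- 1L - p[f, het]
  }
  p
}
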