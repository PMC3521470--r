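#' Affine GF(2) expressions in free variables
#'
#' The whole general solution is expressed in a tiny symbolic algebra: an
#' expression is `constant + x_{i1} + x_{i2} + ...` over GF(2), stored as a
#' constant bit plus a sorted, duplicate-free integer vector of free-variable
#' ids. Because the variable set is kept canonical, two expressions denote the
#' same affine function if and only if they are structurally identical, which
#' makes the consistency checks throughout the solver plain equality tests.
#'
#' @param constant Constant bit (0 or 1).
#' @param vars Integer vector of free-variable ids (any order, duplicates
#'   cancel in pairs as befits GF(2)).
#' @return An object of class `gf2_expr`.
#' @examples
#' gf2(1) |> gf2_add(gf2(1))          # 1 + 1 = 0
#' gf2_add(gf2(1, 1), gf2(0, c(1, 2)))  # x1 cancels
#' @export
gf2 <- function(constant = 0L, vars = integer()) {
  v <- as.integer(vars)
  if (length(v)) {
    v <- sort(v)
    # pairs cancel over GF(2)
    if (anyDuplicated(v)) {
      tab <- table(v)
      v <- as.integer(names(tab)[tab %% 2L == 1L])
    }
  }
  structure(list(k = as.integer(constant) %% 2L, v = v), class = "gf2_expr")
}

#' @export
print.gf2_expr <- function(x, ...) {
  cat("<gf2> ", gf2_format(x), "\n", sep = "")
  invisible(x)
}

#' Render a GF(2) expression as a string
#'
#' Used in reports: `"0"`, `"1"`, `"f3"`, `"1+f0+f2"`.
#' @param x A `gf2_expr`.
#' @return A character scalar.
#' @export
gf2_format <- function(x) {
  terms <- character()
  if (x$k == 1L || length(x$v) == 0L) terms <- as.character(x$k)
  if (length(x$v)) terms <- c(terms, paste0("f", x$v))
  paste(terms, collapse = "+")
}

#' Add two GF(2) expressions
#'
#' Constants XOR; variable sets take their symmetric difference.
#' @param a,b `gf2_expr` objects.
#' @return A `gf2_expr`.
#' @export
gf2_add <- function(a, b) {
  va <- a$v; vb <- b$v
  if (length(va) == 0L) v <- vb
  else if (length(vb) == 0L) v <- va
  else v <- sort(c(setdiff(va, vb), setdiff(vb, va)))
  structure(list(k = xor2(a$k, b$k), v = v), class = "gf2_expr")
}

xor2 <- function(a, b) (a + b) %% 2L

#' Multiply a GF(2) expression by a constant bit
#'
#' @param w A bit (0 or 1).
#' @param a A `gf2_expr`.
#' @return `a` if `w == 1`, the zero constant otherwise.
#' @export
gf2_scale <- function(w, a) {
  w <- as.integer(w)
  stopifnot(w %in% c(0L, 1L))
  if (w == 0L) gf2_zero() else a
}

gf2_zero <- function() structure(list(k = 0L, v = integer()), class = "gf2_expr")

#' Evaluate a GF(2) expression under an assignment of its free variables
#'
#' @param a A `gf2_expr`.
#' @param assignment Named integer vector or list, names are variable ids
#'   (as characters), values bits. Must cover every variable in `a`.
#' @return A bit (integer 0 or 1).
#' @export
gf2_eval <- function(a, assignment = integer()) {
  if (length(a$v) == 0L) return(a$k)
  key <- as.character(a$v)
  vals <- unlist(assignment[key], use.names = FALSE)
  if (length(vals) != length(a$v) || anyNA(vals)) {
    missing <- setdiff(key, names(assignment))
    stop("no assignment for free variable(s): ", paste(missing, collapse = ", "))
  }
  (a$k + sum(as.integer(vals))) %% 2L
}

#' Test two GF(2) expressions for equality
#' @param a,b `gf2_expr` objects.
#' @return `TRUE` if they denote the same affine function.
#' @export
gf2_eq <- function(a, b) a$k == b$k && identical(a$v, b$v)

gf2_is_const <- function(a) length(a$v) == 0L

#' Free-variable registry
#'
#' Records every free variable the solver introduces, with its kind
#' (`"linker"` for edges joining constraint-graph components, `"edge_h"` for
#' transmission indicators left free, `"anchor"` for the per-locus phase of a
#' fully heterozygous region) and a human-readable provenance. Ids are
#' consecutive integers issued in creation order, starting at 0.
#'
#' @return An environment of class `zrhc_registry`.
#' @export
new_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$next_id <- 0L
  reg$entries <- list()
  class(reg) <- "zrhc_registry"
  reg
}

#' Issue a fresh free variable
#'
#' @param registry A registry from [new_registry()].
#' @param kind One of `"linker"`, `"edge_h"`, `"anchor"`.
#' @param provenance Character description of what created the variable.
#' @return The new integer id.
#' @export
fresh_var <- function(registry, kind = c("linker", "edge_h", "anchor"),
                      provenance = "") {
  kind <- match.arg(kind)
  id <- registry$next_id
  registry$entries[[as.character(id)]] <- list(kind = kind, provenance = provenance)
  registry$next_id <- id + 1L
  id
}

#' Tabulate a free-variable registry
#' @param registry A registry.
#' @return A tibble with columns `id`, `kind`, `provenance`.
#' @export
registry_tbl <- function(registry) {
  e <- registry$entries
  tibble::tibble(
    id = as.integer(names(e)),
    kind = vapply(e, function(x) x$kind, character(1), USE.NAMES = FALSE),
    provenance = vapply(e, function(x) x$provenance, character(1), USE.NAMES = FALSE)
  )
}

#' @export
print.zrhc_registry <- function(x, ...) {
  cat("<zrhc free-variable registry: ", x$next_id, " variable(s)>\n", sep = "")
  if (x$next_id > 0L) print(registry_tbl(x))
  invisible(x)
}
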