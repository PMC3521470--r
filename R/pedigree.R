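#' Pedigree + genotype tibbles
#'
#' A `zrhc_ped` is an ordinary tibble with one row per individual and columns
#' `fid`, `id`, `father`, `mother`, `sex`, then one integer column per marker
#' locus named `g1 ... gm` holding the genotype code: 0 = homozygous 0/0,
#' 1 = homozygous 1/1, 2 = heterozygous. Founders have `NA` father and mother.
#' Rows are kept sorted by individual id (numerically when all ids are
#' numeric), which fixes the deterministic orderings used throughout the
#' solver.
#'
#' @param x A data frame with the columns above (`fid` and `sex` optional).
#' @return A validated `zrhc_ped` tibble.
#' @export
as_zrhc_ped <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"fid" %in% names(x)) x$fid <- "1"
  if (!"sex" %in% names(x)) x$sex <- 0L
  needed <- c("id", "father", "mother")
  if (!all(needed %in% names(x))) {
    stop("pedigree needs columns id, father, mother")
  }
  gcols <- grep("^g[0-9]+$", names(x), value = TRUE)
  gcols <- gcols[order(as.integer(sub("^g", "", gcols)))]
  x <- x[, c("fid", "id", "father", "mother", "sex", gcols)]
  x$id <- as.character(x$id)
  x$father <- as.character(x$father)
  x$mother <- as.character(x$mother)
  x$father[x$father %in% c("0", "", "NA")] <- NA_character_
  x$mother[x$mother %in% c("0", "", "NA")] <- NA_character_
  if (anyDuplicated(x$id)) stop("duplicate individual ids")

  # deterministic order: numeric when possible, else lexicographic
  num <- suppressWarnings(as.numeric(x$id))
  x <- if (!anyNA(num)) x[order(num), ] else x[order(x$id), ]

  half <- xor(is.na(x$father), is.na(x$mother))
  if (any(half)) {
    stop("individual(s) with exactly one recorded parent: ",
         paste(x$id[half], collapse = ", "),
         " (the model requires both parents or neither)")
  }
  for (col in c("father", "mother")) {
    bad <- !is.na(x[[col]]) & !(x[[col]] %in% x$id)
    if (any(bad)) stop("unknown ", col, " id(s): ",
                       paste(unique(x[[col]][bad]), collapse = ", "))
  }
  self_par <- !is.na(x$father) & (x$father == x$id | x$mother == x$id)
  if (any(self_par)) stop("individual is its own parent: ",
                          paste(x$id[self_par], collapse = ", "))

  # acyclicity of the parent relation (founders peel off layer by layer)
  remaining <- x$id
  parents <- stats::setNames(Map(function(f, m) c(f, m), x$father, x$mother), x$id)
  repeat {
    ready <- remaining[vapply(parents[remaining], function(p) {
      all(is.na(p) | !(p %in% remaining))
    }, logical(1))]
    if (length(ready) == 0L) break
    remaining <- setdiff(remaining, ready)
  }
  if (length(remaining)) {
    stop("parent relation contains a cycle through: ",
         paste(remaining, collapse = ", "))
  }

  for (gc in gcols) {
    v <- x[[gc]]
    if (anyNA(v) || !all(v %in% c(0L, 1L, 2L))) {
      stop("genotype column ", gc, " must be coded 0/1/2 with no missing values")
    }
    x[[gc]] <- as.integer(v)
  }
  class(x) <- c("zrhc_ped", class(tibble::tibble()))
  x
}

ped_gcols <- function(ped) {
  gcols <- grep("^g[0-9]+$", names(ped), value = TRUE)
  gcols[order(as.integer(sub("^g", "", gcols)))]
}

ped_m <- function(ped) length(ped_gcols(ped))

#' Genotype-code matrix of a pedigree
#' @param ped A `zrhc_ped`.
#' @return An n x m integer matrix of codes 0/1/2, rownames = individual ids.
#' @export
ped_genotypes <- function(ped) {
  g <- as.matrix(ped[, ped_gcols(ped), drop = FALSE])
  storage.mode(g) <- "integer"
  rownames(g) <- ped$id
  g
}

is_founder <- function(ped) is.na(ped$father)

#' Encode an ordered allele pair as a genotype code
#'
#' Order-insensitive: (0,0) -> 0, (1,1) -> 1, mixed -> 2. Vectorised.
#' @param paternal_allele,maternal_allele Bits in \{0, 1\}.
#' @return Integer code(s) in \{0, 1, 2\}.
#' @examples
#' encode_genotype(c(0, 1, 0, 0), c(1, 1, 1, 0))  # 2 1 2 0
#' @export
encode_genotype <- function(paternal_allele, maternal_allele) {
  p <- as.integer(paternal_allele); m <- as.integer(maternal_allele)
  stopifnot(all(p %in% c(0L, 1L)), all(m %in% c(0L, 1L)))
  ifelse(p == m, p, 2L)
}

#' Read a LINKAGE-style PED file
#'
#' Whitespace-delimited text, columns `FamID IID PAT MAT SEX` followed by 2m
#' allele columns with alleles coded 1/2 (mapped to 0/1). `PAT`/`MAT` equal to
#' `"0"` marks a founder. Missing alleles (`0`) and non-bi-allelic symbols are
#' rejected: the model assumes complete bi-allelic data.
#'
#' @param path Path to the PED file.
#' @return A `zrhc_ped` tibble.
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) stop("cannot open PED file: ", path)
  nf <- utils::count.fields(path)
  nf <- nf[!is.na(nf)]
  if (length(nf) == 0L) stop("empty PED file: ", path)
  if (length(unique(nf)) != 1L) stop("ragged PED file (rows differ in field count)")
  if (nf[1] < 7L || (nf[1] - 5L) %% 2L != 0L) {
    stop("PED file must have 5 leading columns plus 2 allele columns per locus")
  }
  raw <- utils::read.table(path, header = FALSE, colClasses = "character")
  m <- (ncol(raw) - 5L) %/% 2L
  alle <- as.matrix(raw[, -(1:5), drop = FALSE])
  if (any(alle == "0")) stop("missing alleles (code 0) are not supported")
  if (!all(alle %in% c("1", "2"))) {
    bad <- unique(alle[!(alle %in% c("1", "2"))])
    stop("non-bi-allelic allele symbol(s): ", paste(bad, collapse = ", "))
  }
  bits <- matrix(as.integer(alle) - 1L, nrow = nrow(raw))
  codes <- sapply(seq_len(m), function(l) {
    encode_genotype(bits[, 2L * l - 1L], bits[, 2L * l])
  })
  codes <- matrix(as.integer(codes), nrow = nrow(raw))
  out <- tibble::tibble(
    fid = raw[[1]], id = raw[[2]], father = raw[[3]], mother = raw[[4]],
    sex = suppressWarnings(as.integer(raw[[5]]))
  )
  for (l in seq_len(m)) out[[paste0("g", l)]] <- codes[, l]
  as_zrhc_ped(out)
}

#' Write a pedigree back to PED format
#'
#' Genotype codes are expanded to allele pairs 1/2 (heterozygous written
#' `1 2`), so `read_ped(write_ped(x))` is the identity on the codes.
#' @param ped A `zrhc_ped`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  g <- ped_genotypes(ped)
  a1 <- ifelse(g == 1L, 2L, 1L)          # code 0 -> 1 1, 1 -> 2 2, 2 -> 1 2
  a2 <- ifelse(g == 0L, 1L, 2L)
  alle <- matrix(0L, nrow(g), 2L * ncol(g))
  if (ncol(g)) {
    alle[, seq(1L, 2L * ncol(g), 2L)] <- a1
    alle[, seq(2L, 2L * ncol(g), 2L)] <- a2
  }
  df <- data.frame(
    ped$fid, ped$id,
    ifelse(is.na(ped$father), "0", ped$father),
    ifelse(is.na(ped$mother), "0", ped$mother),
    ped$sex, alle
  )
  utils::write.table(df, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}

#' Write phased haplotypes and/or a general-solution report
#'
#' In `particular` mode a TSV with one row per individual and the paternal and
#' maternal haplotype strings (all free variables set to 0) is written. In
#' `general` mode a structured JSON report is written containing the
#' free-variable registry, per-edge transmission (h) expressions,
#' per-individual per-locus paternal-allele (p) expressions, and the
#' consistency status.
#'
#' @param fit A solved family from [zrhc_phase()].
#' @param mode `"particular"` or `"general"`.
#' @param hap_path Path for the haplotype TSV (particular mode; optional in
#'   general mode).
#' @param report_path Path for the JSON report (general mode).
#' @return The paths written, invisibly.
#' @export
write_outputs <- function(fit, mode = c("particular", "general"),
                          hap_path = NULL, report_path = NULL) {
  mode <- match.arg(mode)
  if (!inherits(fit, "zrhc_fit")) stop("`fit` must come from zrhc_phase()")
  written <- character()
  if (!is.null(hap_path)) {
    utils::write.table(haplotype_tbl(fit), hap_path, quote = FALSE,
                       row.names = FALSE, col.names = TRUE, sep = "\t")
    written <- c(written, hap_path)
  }
  if (mode == "general") {
    if (is.null(report_path)) stop("general mode needs `report_path`")
    jsonlite::write_json(solution_report(fit), report_path,
                         auto_unbox = TRUE, pretty = TRUE)
    written <- c(written, report_path)
  }
  invisible(written)
}

#' Particular-solution haplotypes as a tibble
#'
#' All free variables are set to 0; the maternal haplotype is the paternal one
#' XOR the heterozygosity mask.
#' @param fit A `zrhc_fit`.
#' @return Tibble with columns `id`, `paternal_hap`, `maternal_hap`.
#' @export
haplotype_tbl <- function(fit) {
  p <- particular_p(fit)
  w <- ped_genotypes(fit$ped) == 2L
  mat <- (p + w) %% 2L
  tibble::tibble(
    id = fit$ped$id,
    paternal_hap = unname(apply(p, 1L, paste, collapse = "")),
    maternal_hap = unname(apply(mat, 1L, paste, collapse = ""))
  )
}

# particular solution: every free variable evaluated at 0
particular_p <- function(fit, assignment = NULL) {
  n <- nrow(fit$ped); m <- ped_m(fit$ped)
  if (is.null(assignment)) {
    ids <- seq_len(fit$registry$next_id) - 1L
    assignment <- stats::setNames(rep(0L, length(ids)), as.character(ids))
  }
  p <- matrix(NA_integer_, n, m, dimnames = list(fit$ped$id, NULL))
  for (i in seq_len(n)) {
    for (l in seq_len(m)) {
      e <- fit$p[[i]][[l]]
      if (!is.null(e)) p[i, l] <- gf2_eval(e, as.list(assignment))
    }
  }
  p
}

solution_report <- function(fit) {
  hmap <- list()
  for (k in seq_along(fit$h)) {
    e <- fit$graph$edges
    nm <- paste0(fit$ped$id[e$parent[k]], "-", fit$ped$id[e$child[k]])
    hmap[[nm]] <- if (is.null(fit$h[[k]])) "unknown" else gf2_format(fit$h[[k]])
  }
  pmap <- list()
  for (i in seq_len(nrow(fit$ped))) {
    pmap[[fit$ped$id[i]]] <- stats::setNames(
      lapply(fit$p[[i]], function(e) if (is.null(e)) "unknown" else gf2_format(e)),
      paste0("locus", seq_len(ped_m(fit$ped)))
    )
  }
  reg <- registry_tbl(fit$registry)
  reg <- reg[reg$id %in% fit$free_vars, , drop = FALSE]
  list(
    free_variables = lapply(seq_len(nrow(reg)), function(i) {
      list(id = reg$id[i], kind = reg$kind[i], provenance = reg$provenance[i])
    }),
    h = hmap,
    p = pmap,
    status = fit$status,
    conflicts = fit$conflicts$message %||% character()
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
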