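#' Zero-recombinant pedigree and genotype simulation
#'
#' The generator grows a pedigree from a founder couple by marrying random
#' members to new founders (each couple has 1-4 children), then creates the
#' requested number of mating loops by mating pairs that already share an
#' ancestor — the canonical first-cousin-style mechanism. Genotypes are
#' produced by gene dropping: founders receive two independent random
#' haplotypes and every child inherits one complete haplotype from each
#' parent, the choice made once per parent-child pair and never per locus;
#' that single draw *is* the zero-recombination model, and it is recorded as
#' the true transmission bit.
#'
#' @name simulation
NULL

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a pedigree with a controllable number of mating loops
#'
#' @param n Target number of individuals (>= 3).
#' @param loops Target number of mating loops (global non-tree edges under
#'   the package's own spanning tree).
#' @param seed Integer seed; the same configuration and seed give an
#'   identical pedigree.
#' @param max_children Upper bound on children per couple (default 4).
#' @return A `zrhc_ped` without genotype columns; the achieved loop count is
#'   in `attr(, "k")`.
#' @export
simulate_pedigree <- function(n = 30, loops = 0, seed = NULL,
                              max_children = 4L) {
  stopifnot(n >= 3, loops >= 0)
  with_seed(seed, {
    id <- c(1L, 2L)
    father <- c(NA_integer_, NA_integer_)
    mother <- c(NA_integer_, NA_integer_)
    sex <- c(1L, 2L)
    spouse_of <- c(2L, 1L)
    couples <- list(c(1L, 2L))
    grow_target <- n - loops
    if (grow_target < 4L && loops > 0L && grow_target < 3L) {
      stop("cannot reach ", loops, " mating loops within ", n,
           " individuals; increase n")
    }

    add_children <- function(fa, mo, count) {
      for (i in seq_len(count)) {
        nid <- length(id) + 1L
        id <<- c(id, nid)
        father <<- c(father, fa); mother <<- c(mother, mo)
        sex <<- c(sex, sample(1:2, 1))
        spouse_of <<- c(spouse_of, NA_integer_)
      }
    }

    add_children(1L, 2L, min(max(2L, sample(seq_len(max_children), 1)),
                             max(1L, grow_target - 2L)))
    while (length(id) <= grow_target - 2L) {
      free <- which(is.na(spouse_of) & !is.na(father))
      if (length(free) == 0L) free <- which(is.na(spouse_of))
      x <- if (length(free) == 1L) free else sample(free, 1)
      nid <- length(id) + 1L
      id <- c(id, nid)
      father <- c(father, NA_integer_); mother <- c(mother, NA_integer_)
      sex <- c(sex, if (sex[x] == 1L) 2L else 1L)
      spouse_of <- c(spouse_of, x); spouse_of[x] <- nid
      pair <- if (sex[x] == 1L) c(x, nid) else c(nid, x)
      couples[[length(couples) + 1L]] <- pair
      budget <- grow_target - length(id)
      add_children(pair[1], pair[2], max(1L, min(sample(seq_len(max_children), 1),
                                                 budget)))
    }
    while (length(id) < grow_target) {   # top up with extra children
      cp <- couples[[sample(length(couples), 1)]]
      add_children(cp[1], cp[2], 1L)
    }

    ancestors <- function() {
      anc <- vector("list", length(id))
      for (i in order(id)) {
        ps <- c(father[i], mother[i])
        ps <- ps[!is.na(ps)]
        anc[[i]] <- unique(c(ps, unlist(anc[ps])))
      }
      anc
    }

    for (lp in seq_len(loops)) {
      anc <- ancestors()
      males <- which(sex == 1L); females <- which(sex == 2L)
      pairs <- expand.grid(f = males, m = females)
      ok <- vapply(seq_len(nrow(pairs)), function(r) {
        u <- pairs$f[r]; v <- pairs$m[r]
        length(intersect(anc[[u]], anc[[v]])) > 0L &&
          !(u %in% anc[[v]]) && !(v %in% anc[[u]]) &&
          !any(vapply(couples, function(cp) all(cp == c(u, v)), logical(1)))
      }, logical(1))
      if (!any(ok)) {
        stop("cannot create mating loop ", lp, " within ", n,
             " individuals; increase n")
      }
      cand <- which(ok)
      r <- if (length(cand) == 1L) cand else sample(cand, 1)
      u <- pairs$f[r]; v <- pairs$m[r]
      couples[[length(couples) + 1L]] <- c(u, v)
      # exactly one child per loop mating: each adds one independent cycle
      add_children(u, v, 1L)
    }

    ped <- as_zrhc_ped(tibble::tibble(
      fid = "1", id = as.character(id),
      father = ifelse(is.na(father), NA_character_, as.character(father)),
      mother = ifelse(is.na(mother), NA_character_, as.character(mother)),
      sex = sex
    ))
    graph <- build_graph(ped)
    tree <- build_spanning_tree(graph)
    attr(ped, "k") <- tree$k
    ped
  })
}

#' Gene-drop genotypes onto a pedigree
#'
#' @param ped A `zrhc_ped` (genotype columns, if any, are replaced).
#' @param m Number of marker loci.
#' @param freq Founder allele-1 frequency per locus, in (0, 1).
#' @param seed Integer seed.
#' @return A list: `ped` (with genotype codes), `truth` (tibble: `id`,
#'   `paternal_hap`, `maternal_hap`, `h_father`, `h_mother`), and the raw
#'   matrices `pat`, `mat`.
#' @export
gene_drop <- function(ped, m, freq = 0.5, seed = NULL) {
  stopifnot(m >= 1, freq > 0, freq < 1)
  with_seed(seed, {
    n <- nrow(ped)
    pat <- matrix(NA_integer_, n, m, dimnames = list(ped$id, NULL))
    mat <- matrix(NA_integer_, n, m, dimnames = list(ped$id, NULL))
    hf <- rep(NA_integer_, n); hm <- rep(NA_integer_, n)
    done <- rep(FALSE, n)
    while (!all(done)) {
      for (i in seq_len(n)) {
        if (done[i]) next
        if (is.na(ped$father[i])) {
          pat[i, ] <- as.integer(stats::runif(m) < freq)
          mat[i, ] <- as.integer(stats::runif(m) < freq)
          done[i] <- TRUE
        } else {
          fi <- match(ped$father[i], ped$id)
          mo <- match(ped$mother[i], ped$id)
          if (!done[fi] || !done[mo]) next
          hf[i] <- sample(0:1, 1)       # one draw per edge, all loci
          hm[i] <- sample(0:1, 1)
          pat[i, ] <- if (hf[i] == 0L) pat[fi, ] else mat[fi, ]
          mat[i, ] <- if (hm[i] == 0L) pat[mo, ] else mat[mo, ]
          done[i] <- TRUE
        }
      }
    }
    out <- ped[, setdiff(names(ped), ped_gcols(ped))]
    for (l in seq_len(m)) {
      out[[paste0("g", l)]] <- encode_genotype(pat[, l], mat[, l])
    }
    truth <- tibble::tibble(
      id = ped$id,
      paternal_hap = unname(apply(pat, 1, paste, collapse = "")),
      maternal_hap = unname(apply(mat, 1, paste, collapse = "")),
      h_father = hf, h_mother = hm
    )
    list(ped = as_zrhc_ped(out), truth = truth, pat = pat, mat = mat)
  })
}

#' Inject genotyping errors
#'
#' Flips `n_errors` randomly chosen genotype codes to a different code
#' (0 <-> 1, or to/from heterozygous). The corrupted cells are recorded in
#' `attr(, "errors")`.
#'
#' @param ped A genotyped `zrhc_ped`.
#' @param n_errors Number of cells to corrupt.
#' @param seed Integer seed.
#' @return The corrupted `zrhc_ped`.
#' @export
inject_errors <- function(ped, n_errors, seed = NULL) {
  if (n_errors == 0L) {
    attr(ped, "errors") <- tibble::tibble(id = character(), locus = integer(),
                                          old = integer(), new = integer())
    return(ped)
  }
  with_seed(seed, {
    m <- ped_m(ped)
    n <- nrow(ped)
    cells <- sample(n * m, n_errors)
    rec <- tibble::tibble(id = character(), locus = integer(),
                          old = integer(), new = integer())
    for (cell in cells) {
      i <- ((cell - 1L) %% n) + 1L
      l <- ((cell - 1L) %/% n) + 1L
      old <- ped[[paste0("g", l)]][i]
      new <- sample(setdiff(0:2, old), 1)
      ped[[paste0("g", l)]][i] <- new
      rec <- dplyr::bind_rows(rec, tibble::tibble(
        id = ped$id[i], locus = l, old = old, new = as.integer(new)))
    }
    attr(ped, "errors") <- rec
    ped
  })
}

#' One-call simulation: pedigree, gene drop, optional errors
#'
#' @param n,loops,max_children Passed to [simulate_pedigree()].
#' @param m,freq Passed to [gene_drop()].
#' @param errors Number of genotype errors to inject.
#' @param seed Integer seed driving all three stages.
#' @return A list: `ped` (genotyped, possibly corrupted), `truth`, `pat`,
#'   `mat`, `k` (achieved loop count), `errors` (tibble of corrupted cells).
#' @export
sim_zrhc <- function(n = 30, m = 10, loops = 0, freq = 0.5, errors = 0,
                     seed = NULL, max_children = 4L) {
  base <- simulate_pedigree(n = n, loops = loops, seed = seed,
                            max_children = max_children)
  dropped <- gene_drop(base, m = m, freq = freq,
                       seed = if (is.null(seed)) NULL else seed + 1L)
  ped <- inject_errors(dropped$ped, errors,
                       seed = if (is.null(seed)) NULL else seed + 2L)
  list(ped = ped, truth = dropped$truth, pat = dropped$pat,
       mat = dropped$mat, k = attr(base, "k"), errors = attr(ped, "errors"))
}

#' Write the simulator truth file
#'
#' TSV with one row per individual: id, the two true haplotypes, and the true
#' transmitted-haplotype bits from father and mother (`NA` for founders).
#'
#' @param sim Output of [gene_drop()] or [sim_zrhc()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(sim, path) {
  utils::write.table(sim$truth, path, quote = FALSE, row.names = FALSE,
                     col.names = TRUE, sep = "\t")
  invisible(path)
}
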