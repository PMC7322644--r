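#' Read a pedigree from a delimited text file
#'
#' Reads a comma- or tab-delimited pedigree file with at least three columns
#' (animal, sire, dam) and an optional fourth generation-label column
#' (e.g. `P0`/`F1`/`F2`). A header row is detected automatically from common
#' column names. Unknown parents may be coded `"0"`, an empty field, or
#' `"NA"`. The result is validated and topologically sorted so that every
#' known parent precedes its offspring; animals that appear only as parents
#' are appended as founders.
#'
#' @param path Path to a delimited text file.
#' @param unknown_codes Character codes interpreted as "parent unknown".
#' @return A `pedigree`: a tibble with columns `animal`, `sire`, `dam`,
#'   `generation` (character; `NA` for unknown parents / missing labels),
#'   topologically sorted.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("animal,sire,dam", "s1,0,0", "d1,0,0", "x,s1,d1"), tf)
#' read_pedigree(tf)
#' @export
read_pedigree <- function(path, unknown_codes = c("0", "", "NA")) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) stop("empty pedigree file: ", path)
  delim <- if (grepl("\t", lines[keep[1]], fixed = TRUE)) "\t" else ","
  parts <- lapply(strsplit(lines[keep], delim, fixed = TRUE), trimws)
  first <- tolower(parts[[1]])
  has_header <- any(first %in% c("animal", "id", "sire", "dam", "father",
                                 "mother", "generation", "gen"))
  rows <- if (has_header) parts[-1] else parts
  lineno <- if (has_header) keep[-1] else keep
  if (!length(rows)) stop("pedigree file has a header but no data rows: ", path)
  nf <- vapply(rows, length, 1L)
  if (any(nf < 3L)) {
    stop("malformed pedigree row (fewer than 3 fields) at line ",
         lineno[which(nf < 3L)[1]])
  }
  animal <- vapply(rows, `[[`, "", 1L)
  if (any(animal == "")) {
    stop("malformed pedigree row (empty animal id) at line ",
         lineno[which(animal == "")[1]])
  }
  df <- tibble::tibble(
    animal = animal,
    sire = vapply(rows, `[[`, "", 2L),
    dam = vapply(rows, `[[`, "", 3L),
    generation = vapply(rows, function(r) if (length(r) >= 4L) r[[4L]] else NA_character_, "")
  )
  as_pedigree(df, unknown_codes = unknown_codes)
}

#' Validate and topologically sort a pedigree table
#'
#' Accepts any data frame whose first three columns (or columns named
#' `animal`, `sire`, `dam`) give animal/sire/dam identifiers, plus an
#' optional `generation` column. Checks for duplicate ids and cycles
#' (including self-parenting), appends animals referenced only as parents
#' as founders, and orders records so parents precede offspring.
#'
#' @param x A data frame of pedigree records, or an existing `pedigree`.
#' @param unknown_codes Character codes interpreted as "parent unknown".
#' @return A `pedigree` tibble (see [read_pedigree()]).
#' @export
as_pedigree <- function(x, unknown_codes = c("0", "", "NA")) {
  if (inherits(x, "pedigree")) return(x)
  stopifnot(is.data.frame(x), ncol(x) >= 3L)
  if (all(c("animal", "sire", "dam") %in% names(x))) {
    animal <- as.character(x$animal)
    sire <- as.character(x$sire)
    dam <- as.character(x$dam)
    generation <- if ("generation" %in% names(x)) as.character(x$generation) else NULL
  } else {
    animal <- as.character(x[[1L]])
    sire <- as.character(x[[2L]])
    dam <- as.character(x[[3L]])
    generation <- if (ncol(x) >= 4L) as.character(x[[4L]]) else NULL
  }
  if (is.null(generation)) generation <- rep(NA_character_, length(animal))
  animal <- trimws(animal)
  sire <- trimws(sire)
  dam <- trimws(dam)
  sire[is.na(sire) | sire %in% unknown_codes] <- NA_character_
  dam[is.na(dam) | dam %in% unknown_codes] <- NA_character_
  if (any(is.na(animal) | animal == "")) stop("empty animal id in pedigree")
  if (anyDuplicated(animal)) {
    stop("duplicate animal id in pedigree: ", animal[duplicated(animal)][1])
  }

  # parents never listed as animals become founders
  extra <- setdiff(stats::na.omit(unique(c(sire, dam))), animal)
  if (length(extra)) {
    animal <- c(animal, extra)
    sire <- c(sire, rep(NA_character_, length(extra)))
    dam <- c(dam, rep(NA_character_, length(extra)))
    generation <- c(generation, rep(NA_character_, length(extra)))
  }

  n <- length(animal)
  si <- match(sire, animal)
  di <- match(dam, animal)
  si[is.na(si)] <- 0L
  di[is.na(di)] <- 0L

  # Kahn-style topological sort, round by round, preserving input order
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ok_s <- si == 0L | placed[pmax(si, 1L)]
    ok_d <- di == 0L | placed[pmax(di, 1L)]
    ready <- which(!placed & ok_s & ok_d)
    if (!length(ready)) break
    ord <- c(ord, ready)
    placed[ready] <- TRUE
  }
  if (!all(placed)) {
    rem <- which(!placed)
    cur <- rem[1]
    path <- integer(0)
    while (!(cur %in% path)) {
      path <- c(path, cur)
      cur <- if (si[cur] %in% rem) si[cur] else di[cur]
    }
    cyc <- c(path[which(path == cur)[1]:length(path)], cur)
    stop("pedigree contains a cycle: ", paste(animal[cyc], collapse = " -> "))
  }

  out <- tibble::tibble(
    animal = animal[ord],
    sire = sire[ord],
    dam = dam[ord],
    generation = generation[ord]
  )
  class(out) <- c("pedigree", class(out))
  out
}

# internal: indices and basic checks shared by all pedigree operations
check_pedigree <- function(ped) {
  if (!is.data.frame(ped)) stop("expected a pedigree data frame")
  if (!inherits(ped, "pedigree")) ped <- as_pedigree(ped)
  ids <- ped$animal
  n <- length(ids)
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  si[is.na(si)] <- 0L
  di[is.na(di)] <- 0L
  pos <- seq_len(n)
  if (any(si >= pos) || any(di >= pos)) {
    stop("pedigree is not topologically sorted; use as_pedigree()")
  }
  list(ids = ids, si = si, di = di, gen = ped$generation, n = n)
}

#' Additive (numerator) relationship matrix
#'
#' Builds the dense numerator relationship matrix A by the tabular method:
#' for animal i with parents s and d (processed in pedigree order),
#' `a_ij = 0.5 * (a_{j,s} + a_{j,d})` for earlier animals j (an unknown
#' parent contributes 0) and `a_ii = 1 + 0.5 * a_{s,d}`, so
#' `diag(A) = 1 + F`.
#'
#' @param ped A `pedigree`.
#' @return A symmetric numeric matrix with animal ids as dimnames.
#' @export
additive_matrix <- function(ped) {
  p <- check_pedigree(ped)
  n <- p$n
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- p$si[i]
    d <- p$di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s > 0L) row <- row + A[j, s]
      if (d > 0L) row <- row + A[j, d]
      row <- 0.5 * row
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  dimnames(A) <- list(p$ids, p$ids)
  A
}

#' Inbreeding coefficients from a pedigree
#'
#' `F_i = 0.5 * a(sire_i, dam_i)`, via the tabular relationship matrix.
#' Founders and animals with any unknown parent have `F = 0`.
#'
#' @param ped A `pedigree`.
#' @return A tibble with columns `animal` and `f` (proportion in `[0, 1)`),
#'   in pedigree order.
#' @export
compute_inbreeding <- function(ped) {
  p <- check_pedigree(ped)
  f <- diag(additive_matrix(ped)) - 1
  tibble::tibble(animal = p$ids, f = unname(f))
}

# internal: accept a tibble from compute_inbreeding(), a (named) numeric
# vector, or NULL (recompute); returns plain numeric in pedigree order
inbreeding_vec <- function(ped, f = NULL) {
  p <- check_pedigree(ped)
  if (is.null(f)) return(compute_inbreeding(ped)$f)
  if (is.data.frame(f)) {
    stopifnot(all(c("animal", "f") %in% names(f)))
    idx <- match(p$ids, f$animal)
    if (anyNA(idx)) stop("inbreeding table does not cover all pedigree animals")
    return(f$f[idx])
  }
  stopifnot(is.numeric(f), length(f) == p$n)
  as.numeric(f)
}

#' Sparse inverse of the additive relationship matrix
#'
#' Henderson's rules with the inbreeding adjustment: animal i contributes
#' `1/d_i` to its own diagonal, where the Mendelian-sampling variance is
#' `d_i = 0.5 - 0.25 (F_s + F_d)` with both parents known,
#' `0.75 - 0.25 F_known` with one known, and 1 for founders; off-diagonal
#' contributions follow the usual animal/sire/dam pattern. The result has
#' nonzeros only among animal-sire-dam triples and satisfies
#' `A %*% A_inv = I`.
#'
#' @param ped A `pedigree`.
#' @param f Inbreeding coefficients (tibble from [compute_inbreeding()] or
#'   numeric vector in pedigree order); recomputed when `NULL`.
#' @return A sparse symmetric `Matrix::dgCMatrix` with animal-id dimnames.
#' @export
additive_inverse <- function(ped, f = NULL) {
  p <- check_pedigree(ped)
  fv <- inbreeding_vec(ped, f)
  n <- p$n
  s <- p$si
  d <- p$di
  fs <- ifelse(s > 0L, fv[pmax(s, 1L)], 0)
  fd <- ifelse(d > 0L, fv[pmax(d, 1L)], 0)
  both <- s > 0L & d > 0L
  one <- xor(s > 0L, d > 0L)
  dvar <- ifelse(both, 0.5 - 0.25 * (fs + fd),
                 ifelse(one, 0.75 - 0.25 * (fs + fd), 1))
  if (any(dvar <= 0)) stop("non-positive Mendelian sampling variance; invalid pedigree")
  alpha <- 1 / dvar

  ii <- seq_len(n)
  I <- ii; J <- ii; Xv <- alpha
  for (pp in list(s, d)) {
    k <- which(pp > 0L)
    I <- c(I, k, pp[k], pp[k])
    J <- c(J, pp[k], k, pp[k])
    Xv <- c(Xv, -alpha[k] / 2, -alpha[k] / 2, alpha[k] / 4)
  }
  k <- which(both)
  I <- c(I, s[k], d[k])
  J <- c(J, d[k], s[k])
  Xv <- c(Xv, alpha[k] / 4, alpha[k] / 4)

  Matrix::sparseMatrix(i = I, j = J, x = Xv, dims = c(n, n),
                       dimnames = list(p$ids, p$ids))
}

#' Dominance relationship matrix
#'
#' Classical parent-pair formula: for animals i and j with parents
#' `(s_i, d_i)` and `(s_j, d_j)`,
#' `d_ij = 0.25 * (a_{s_i,s_j} a_{d_i,d_j} + a_{s_i,d_j} a_{d_i,s_j})`,
#' with any term involving an unknown parent set to 0, and `diag(D) = 1`.
#' The unit diagonal is retained for inbred animals as well; exact dominance
#' relationships under inbreeding would require additional condensed
#' identity coefficients, so D is an approximation there (the convention of
#' standard pedigree software).
#'
#' @param ped A `pedigree`.
#' @param A Optional precomputed additive matrix from [additive_matrix()].
#' @return A symmetric numeric matrix with animal-id dimnames.
#' @export
dominance_matrix <- function(ped, A = NULL) {
  p <- check_pedigree(ped)
  if (is.null(A)) A <- additive_matrix(ped)
  n <- p$n
  # augment with a zero row/col standing in for unknown parents
  Aaug <- matrix(0, n + 1L, n + 1L)
  Aaug[seq_len(n), seq_len(n)] <- A
  z <- n + 1L
  s <- ifelse(p$si > 0L, p$si, z)
  d <- ifelse(p$di > 0L, p$di, z)
  D <- 0.25 * (Aaug[s, s, drop = FALSE] * Aaug[d, d, drop = FALSE] +
               Aaug[s, d, drop = FALSE] * Aaug[d, s, drop = FALSE])
  diag(D) <- 1
  dimnames(D) <- list(p$ids, p$ids)
  D
}

#' All pedigree relationship structures at once
#'
#' Computes the additive matrix A, its sparse inverse, the dominance matrix
#' D (optional), and inbreeding coefficients F, sharing the tabular A
#' computation.
#'
#' @param ped A `pedigree`.
#' @param dominance Compute the dominance matrix too?
#' @return An object of class `relationship_set`: a list with elements
#'   `A`, `A_inv`, `D` (or `NULL`), `f` (named numeric), `ids`.
#' @export
relationship_matrices <- function(ped, dominance = TRUE) {
  p <- check_pedigree(ped)
  A <- additive_matrix(ped)
  f <- diag(A) - 1
  out <- list(
    A = A,
    A_inv = additive_inverse(ped, f),
    D = if (dominance) dominance_matrix(ped, A) else NULL,
    f = setNames(unname(f), p$ids),
    ids = p$ids
  )
  class(out) <- "relationship_set"
  out
}

#' @export
print.relationship_set <- function(x, ...) {
  cat("<relationship_set> ", length(x$ids), " animals; mean F = ",
      signif(mean(x$f), 3),
      if (is.null(x$D)) "; additive only\n" else "; with dominance matrix\n",
      sep = "")
  invisible(x)
}

#' Pedigree-level inbreeding statistics and effective population size
#'
#' Equivalent complete generations are accumulated over known ancestors,
#' `t_i = 0.5 (t_s + 1) + 0.5 (t_d + 1)` (an unknown parent contributes 0).
#' The individual increase in inbreeding is
#' `delta_F_i = 1 - (1 - F_i)^(1 / (t_i - 1))` for `t_i > 1`, else 0, and
#' the realized effective population size is
#' `Ne = 1 / (2 * mean(delta_F))` over the reference animals. The reference
#' group is the cohort carrying the last generation label in pedigree order
#' (all non-parents when labels are absent); `Ne` is `Inf` when the mean
#' increase is zero.
#'
#' @param ped A `pedigree`.
#' @param f Optional inbreeding coefficients (see [additive_inverse()]).
#' @return A `pedigree_stats` list with `per_animal` (tibble: `animal`,
#'   `f`, `eq_gen`, `delta_f`, `reference`) and `summary` (one-row tibble:
#'   `mean_f`, `median_f`, `max_f`, `mean_eq_gen`, `mean_delta_f`, `ne`,
#'   `n_reference`, with F statistics over the reference animals).
#' @export
pedigree_stats <- function(ped, f = NULL) {
  p <- check_pedigree(ped)
  fv <- inbreeding_vec(ped, f)
  n <- p$n
  t <- numeric(n)
  for (i in seq_len(n)) {
    s <- p$si[i]
    d <- p$di[i]
    t[i] <- (if (s > 0L) 0.5 * (t[s] + 1) else 0) +
            (if (d > 0L) 0.5 * (t[d] + 1) else 0)
  }
  delta_f <- ifelse(t > 1, 1 - (1 - fv)^(1 / (t - 1)), 0)

  if (any(!is.na(p$gen))) {
    last_lab <- p$gen[max(which(!is.na(p$gen)))]
    ref <- !is.na(p$gen) & p$gen == last_lab
  } else {
    ref <- !(p$ids %in% c(ped$sire, ped$dam))
  }

  mdf <- mean(delta_f[ref])
  out <- list(
    per_animal = tibble::tibble(animal = p$ids, f = fv, eq_gen = t,
                                delta_f = delta_f, reference = ref),
    summary = tibble::tibble(
      mean_f = mean(fv[ref]),
      median_f = median(fv[ref]),
      max_f = max(fv[ref]),
      mean_eq_gen = mean(t[ref]),
      mean_delta_f = mdf,
      ne = if (mdf > 0) 1 / (2 * mdf) else Inf,
      n_reference = sum(ref)
    )
  )
  class(out) <- "pedigree_stats"
  out
}

#' @export
print.pedigree_stats <- function(x, ...) {
  cat("<pedigree_stats> reference cohort of", x$summary$n_reference, "animals\n")
  print(x$summary)
  invisible(x)
}

#' Export a relationship matrix as id-indexed triplets
#'
#' Writes the nonzero upper-triangle entries (including the diagonal) of a
#' dense or sparse symmetric matrix as tab-separated `i_id, j_id, value`.
#'
#' @param m Matrix with id dimnames (dense or `Matrix` sparse).
#' @param path Output file path.
#' @return The triplet tibble, invisibly.
#' @export
write_relationship_triplets <- function(m, path) {
  ids <- rownames(m)
  if (!inherits(m, "Matrix")) m <- Matrix::Matrix(m, sparse = TRUE)
  tm <- methods::as(methods::as(m, "generalMatrix"), "TsparseMatrix")
  keep <- tm@i <= tm@j & tm@x != 0
  out <- tibble::tibble(
    i_id = ids[tm@i[keep] + 1L],
    j_id = ids[tm@j[keep] + 1L],
    value = tm@x[keep]
  )
  readr::write_tsv(out, path)
  invisible(out)
}

#' Export inbreeding coefficients as two-column text
#'
#' @param f Tibble from [compute_inbreeding()] or named numeric vector.
#' @param path Output file path.
#' @return The tibble written, invisibly.
#' @export
write_inbreeding <- function(f, path) {
  out <- if (is.data.frame(f)) {
    tibble::as_tibble(f[, c("animal", "f")])
  } else {
    tibble::tibble(animal = names(f), f = unname(f))
  }
  readr::write_tsv(out, path)
  invisible(out)
}
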