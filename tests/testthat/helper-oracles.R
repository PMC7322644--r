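# Independent oracles used across the suite.

# Gene dropping: founder alleles are dropped through the pedigree many
# times; relationship coefficients are estimated from realized
# identity-by-descent. An unknown parent contributes a fresh unique allele
# (unrelated founder). Returns Monte-Carlo estimates of A and D.
gene_drop <- function(ped, n_drops = 5e4, seed = 1) {
  set.seed(seed)
  ids <- ped$animal
  n <- length(ids)
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  a1 <- matrix(0L, n, n_drops)
  a2 <- matrix(0L, n, n_drops)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (is.na(si[i])) {
      nxt <- nxt + 1L
      a1[i, ] <- nxt
    } else {
      pick <- stats::runif(n_drops) < 0.5
      a1[i, ] <- ifelse(pick, a1[si[i], ], a2[si[i], ])
    }
    if (is.na(di[i])) {
      nxt <- nxt + 1L
      a2[i, ] <- nxt
    } else {
      pick <- stats::runif(n_drops) < 0.5
      a2[i, ] <- ifelse(pick, a1[di[i], ], a2[di[i], ])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        A[i, i] <- 1 + mean(a1[i, ] == a2[i, ])
        D[i, i] <- 1
      } else {
        s <- (a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
             (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])
        A[i, j] <- A[j, i] <- mean(s) / 2
        both <- (a1[i, ] == a1[j, ] & a2[i, ] == a2[j, ]) |
                (a1[i, ] == a2[j, ] & a2[i, ] == a1[j, ])
        D[i, j] <- D[j, i] <- mean(both)
      }
    }
  }
  list(A = A, D = D, mc_sd = sqrt(0.25 / n_drops))
}

# Direct mixed-model-equations solution for posterior means of the
# location effects at fixed variances (reduced, phenotyped-animal
# parameterization; flat prior on fixed effects).
mme_solution <- function(design, rel, sigma_a2, sigma_d2 = NULL, sigma_e2 = 1) {
  idx <- design$animal_index
  y <- design$y
  X <- design$X
  n <- length(y)
  As <- rel$A[idx, idx, drop = FALSE]
  use_d <- !is.null(sigma_d2)
  if (use_d) Ds <- rel$D[idx, idx, drop = FALSE]
  p <- ncol(X)
  blocks <- if (use_d) 2L else 1L
  C <- matrix(0, p + blocks * n, p + blocks * n)
  rhs <- numeric(p + blocks * n)
  w <- 1 / sigma_e2
  ia <- p + seq_len(n)
  C[seq_len(p), seq_len(p)] <- crossprod(X) * w
  C[seq_len(p), ia] <- t(X) * w
  C[ia, seq_len(p)] <- X * w
  C[ia, ia] <- diag(n) * w + solve(As) / sigma_a2
  rhs[seq_len(p)] <- crossprod(X, y) * w
  rhs[ia] <- y * w
  if (use_d) {
    id <- p + n + seq_len(n)
    C[seq_len(p), id] <- t(X) * w
    C[id, seq_len(p)] <- X * w
    C[ia, id] <- diag(n) * w
    C[id, ia] <- diag(n) * w
    C[id, id] <- diag(n) * w + solve(Ds) / sigma_d2
    rhs[id] <- y * w
  }
  sol <- solve(C, rhs)
  list(b = sol[seq_len(p)],
       a = sol[p + seq_len(n)],
       d = if (use_d) sol[p + n + seq_len(n)] else NULL)
}

# small pedigree builders
ped_founders <- function(n) {
  as_pedigree(data.frame(animal = paste0("f", seq_len(n)), sire = 0, dam = 0))
}

ped_full_sibs <- function() {
  as_pedigree(data.frame(
    animal = c("s", "d", "c1", "c2"),
    sire = c(0, 0, "s", "s"),
    dam = c(0, 0, "d", "d")
  ))
}

# a small but non-trivial F2 cross used by several oracle tests
small_cross <- function(seed = 3, n_f2 = 24) {
  generate_cross_pedigree(cross_design(
    n_p0_per_line = 8, n_f1_sires = 6, n_f1_dams = 8, n_f2 = n_f2,
    half_sib_families = 3, random_families = 3,
    full_sib_mating_rate = 0.3, seed = seed
  ))
}

# scaled recovery-experiment design used by the acceptance checks
desk_cross <- function(seed) {
  cross_design(n_f1_sires = 49, n_f1_dams = 150, n_f2 = 600,
               half_sib_families = 25, random_families = 24, seed = seed)
}
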