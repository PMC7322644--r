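test_that("pedigree files are parsed, validated and topologically sorted", {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("animal,sire,dam", "s1,0,0", "d1,0,0", "x,s1,d1"), tf)
  ped <- read_pedigree(tf)
  expect_s3_class(ped, "pedigree")
  expect_equal(ped$animal, c("s1", "d1", "x"))
  expect_true(is.na(ped$sire[1]))

  # offspring listed before parents sorts to the same pedigree
  writeLines(c("animal,sire,dam", "x,s1,d1", "s1,0,0", "d1,0,0"), tf)
  ped2 <- read_pedigree(tf)
  expect_equal(ped2[order(ped2$animal), ], ped[order(ped$animal), ])

  # tab-delimited with generation column, parents appended as founders
  tf2 <- tempfile(fileext = ".tsv")
  writeLines(c("animal\tsire\tdam\tgeneration", "x\ts9\td9\tF2"), tf2)
  ped3 <- read_pedigree(tf2)
  expect_setequal(ped3$animal, c("s9", "d9", "x"))
  expect_equal(ped3$generation[ped3$animal == "x"], "F2")

  writeLines(c("animal,sire,dam", "a,0,0", "a,0,0"), tf)
  expect_error(read_pedigree(tf), "duplicate animal id.*a")
  writeLines(c("animal,sire,dam", "a,a,0"), tf)
  expect_error(read_pedigree(tf), "cycle")
  writeLines(c("animal,sire,dam", "a,b,0", "b,a,0"), tf)
  expect_error(read_pedigree(tf), "cycle.*a.*b|cycle.*b.*a")
  writeLines(c("animal,sire,dam", "a,0,0", "justone"), tf)
  expect_error(read_pedigree(tf), "line 3")
})

test_that("inbreeding matches hand-derived kinship for classic matings", {
  # child of two unrelated founders
  ped <- as_pedigree(data.frame(animal = c("s", "d", "x"),
                                sire = c(0, 0, "s"), dam = c(0, 0, "d")))
  expect_equal(compute_inbreeding(ped)$f, c(0, 0, 0))

  # offspring of full sibs: F = 0.25; of half sibs: F = 0.125
  fs <- as_pedigree(data.frame(
    animal = c("s", "d", "c1", "c2", "g"),
    sire = c(0, 0, "s", "s", "c1"),
    dam = c(0, 0, "d", "d", "c2")))
  expect_equal(compute_inbreeding(fs)$f, c(0, 0, 0, 0, 0.25))

  hs <- as_pedigree(data.frame(
    animal = c("s", "d1", "d2", "c1", "c2", "g"),
    sire = c(0, 0, 0, "s", "s", "c1"),
    dam = c(0, 0, 0, "d1", "d2", "c2")))
  expect_equal(compute_inbreeding(hs)$f[6], 0.125)
})

test_that("repeated full-sib mating reproduces the classical F recurrence", {
  # F_t = 0.25 (1 + 2 F_{t-1} + F_{t-2}), F_0 = F_{-1} = 0
  gens <- 6
  rows <- data.frame(animal = c("m0", "f0"), sire = "0", dam = "0")
  for (t in seq_len(gens)) {
    rows <- rbind(rows, data.frame(
      animal = paste0(c("m", "f"), t),
      sire = paste0("m", t - 1), dam = paste0("f", t - 1)))
  }
  ped <- as_pedigree(rows)
  f <- compute_inbreeding(ped)
  fm <- f$f[match(paste0("m", 1:gens), f$animal)]
  # first-generation offspring of unrelated founders are non-inbred; the
  # recurrence starts once parents are full sibs
  fr <- numeric(gens)
  fr[1] <- 0
  fprev <- c(0, 0)  # (F_{t-2}, F_{t-1}) for the parents of generation t
  for (t in 2:gens) {
    fr[t] <- 0.25 * (1 + 2 * fprev[2] + fprev[1])
    fprev <- c(fprev[2], fr[t])
  }
  expect_equal(fm, fr, tolerance = 1e-12)
})

test_that("additive matrix has textbook entries and the diagonal identity", {
  fs <- ped_full_sibs()
  A <- additive_matrix(fs)
  expect_equal(A["s", "c1"], 0.5)   # parent-offspring
  expect_equal(A["c1", "c2"], 0.5)  # full sibs
  expect_equal(unname(diag(A)), rep(1, 4))

  hs <- as_pedigree(data.frame(
    animal = c("s", "d1", "d2", "c1", "c2"),
    sire = c(0, 0, 0, "s", "s"), dam = c(0, 0, 0, "d1", "d2")))
  expect_equal(additive_matrix(hs)["c1", "c2"], 0.25)

  ped <- small_cross(seed = 11, n_f2 = 40)
  A2 <- additive_matrix(ped)
  expect_equal(unname(diag(A2) - 1), compute_inbreeding(ped)$f)
  expect_true(isSymmetric(A2))
  expect_true(all(A2[upper.tri(A2)] >= 0 & A2[upper.tri(A2)] <= 2))
})

test_that("A is positive semi-definite and invariant to input row order", {
  for (seed in 1:4) {
    ped <- small_cross(seed = seed, n_f2 = 30)
    A <- additive_matrix(ped)
    expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values), -1e-8)

    set.seed(seed)
    shuffled <- as_pedigree(as.data.frame(ped)[sample(nrow(ped)), ])
    A2 <- additive_matrix(shuffled)
    expect_equal(A2[rownames(A), colnames(A)], A)
    D <- dominance_matrix(ped, A)
    D2 <- dominance_matrix(shuffled)
    expect_equal(D2[rownames(D), colnames(D)], D)
  }
})

test_that("sparse additive inverse matches the dense inverse", {
  expect_equal(as.matrix(additive_inverse(ped_founders(4))), diag(4),
               ignore_attr = TRUE)

  ped <- small_cross(seed = 7, n_f2 = 120)
  A <- additive_matrix(ped)
  Ainv <- additive_inverse(ped)
  n <- nrow(A)
  expect_lt(max(abs(as.matrix(A %*% Ainv) - diag(n))), 1e-8)
  expect_lt(max(abs(as.matrix(Ainv) - solve(A))), 1e-8)

  # nonzeros only within animal-sire-dam triples (incl. mate pairs)
  ids <- ped$animal
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  allowed <- diag(n) > 0
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) allowed[i, p] <- allowed[p, i] <- TRUE
    }
    if (!is.na(si[i]) && !is.na(di[i])) {
      allowed[si[i], di[i]] <- allowed[di[i], si[i]] <- TRUE
    }
  }
  nz <- as.matrix(Ainv != 0)
  expect_true(all(!nz | allowed))
})

test_that("dominance matrix has textbook entries", {
  fs <- ped_full_sibs()
  D <- dominance_matrix(fs)
  expect_equal(D["c1", "c2"], 0.25)
  expect_equal(unname(diag(D)), rep(1, 4))

  hs <- as_pedigree(data.frame(
    animal = c("s", "d1", "d2", "c1", "c2"),
    sire = c(0, 0, 0, "s", "s"), dam = c(0, 0, 0, "d1", "d2")))
  expect_equal(dominance_matrix(hs)["c1", "c2"], 0)
})

test_that("A and D agree with gene dropping on a small cross", {
  # A is exact under inbreeding, so the inbred cross exercises it fully
  ped <- small_cross(seed = 5, n_f2 = 20)
  gd <- gene_drop(ped, n_drops = 5e4, seed = 99)
  A <- additive_matrix(ped)
  # bound for a max over ~500 entries, each a mean of (sums of) indicators
  expect_lt(max(abs(A - gd$A)), 4.5 * 2 * gd$mc_sd + 1e-12)

  # the parent-pair D formula is exact only without inbreeding, so its
  # gene-dropping check uses a non-inbred cross
  ped0 <- generate_cross_pedigree(cross_design(
    n_p0_per_line = 60, n_f1_sires = 6, n_f1_dams = 8, n_f2 = 20,
    half_sib_families = 3, random_families = 3,
    full_sib_mating_rate = 0, seed = 13))
  gd0 <- gene_drop(ped0, n_drops = 5e4, seed = 98)
  D0 <- dominance_matrix(ped0)
  expect_lt(max(abs(D0 - gd0$D)), 4.5 * gd0$mc_sd + 1e-12)
})

test_that("pedigree statistics follow the stated conventions", {
  # all founders: no inbreeding accumulation, Ne undefined (Inf)
  st0 <- pedigree_stats(ped_founders(5))
  expect_equal(st0$summary$ne, Inf)
  expect_equal(st0$summary$mean_delta_f, 0)

  ped <- small_cross(seed = 2, n_f2 = 40)
  st <- pedigree_stats(ped)
  pa <- st$per_animal
  # equivalent generations: complete three-generation pedigree depth
  expect_equal(max(pa$eq_gen), 2)
  # delta F arithmetic identity against the per-animal table
  manual <- ifelse(pa$eq_gen > 1, 1 - (1 - pa$f)^(1 / (pa$eq_gen - 1)), 0)
  expect_equal(pa$delta_f, manual)
  # reference group = F2 cohort; Ne = 1 / (2 mean delta F) over it
  expect_equal(sum(pa$reference), 40)
  expect_equal(st$summary$ne,
               1 / (2 * mean(pa$delta_f[pa$reference])))
})

test_that("matrix and inbreeding exports round-trip through triplet text", {
  ped <- ped_full_sibs()
  A <- additive_matrix(ped)
  tf <- tempfile(fileext = ".tsv")
  trip <- write_relationship_triplets(A, tf)
  back <- utils::read.delim(tf)
  expect_equal(nrow(back), nrow(trip))
  rebuilt <- matrix(0, 4, 4, dimnames = dimnames(A))
  for (k in seq_len(nrow(back))) {
    rebuilt[back$i_id[k], back$j_id[k]] <- back$value[k]
    rebuilt[back$j_id[k], back$i_id[k]] <- back$value[k]
  }
  expect_equal(rebuilt, A)

  tf2 <- tempfile(fileext = ".tsv")
  write_inbreeding(compute_inbreeding(ped), tf2)
  fi <- utils::read.delim(tf2)
  expect_equal(fi$f, compute_inbreeding(ped)$f)
})
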