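#' Build design matrices for one trait
#'
#' Assembles the response and design matrices of the animal model
#' `y = X b + Z_a a + Z_d d + e` for a single trait: `X` holds an intercept
#' and the animal's inbreeding coefficient (the fixed covariate), and
#' `Z_a = Z_d` is the record-to-animal incidence matrix over the pedigree
#' (exactly one 1 per row). Records with a missing trait value are dropped
#' with a message; a phenotyped animal absent from the pedigree, or a
#' duplicated animal row (the model expects one averaged record per
#' animal), is an error.
#'
#' @param ped A `pedigree`.
#' @param phenotypes Data frame with an `animal` column and one numeric
#'   column per trait.
#' @param trait Name of the trait column.
#' @param f Optional inbreeding coefficients (tibble or vector); recomputed
#'   when `NULL`.
#' @param include_dominance Flag carried along for downstream model fitting.
#' @return A `design_set` list: `y`, `X`, `Z_a`, `Z_d` (sparse),
#'   `record_ids`, `animal_index` (pedigree positions per record), `trait`,
#'   `include_dominance`.
#' @export
build_design <- function(ped, phenotypes, trait, f = NULL, include_dominance = TRUE) {
  p <- check_pedigree(ped)
  stopifnot(is.data.frame(phenotypes), "animal" %in% names(phenotypes),
            trait %in% names(phenotypes))
  fv <- inbreeding_vec(ped, f)

  animal <- as.character(phenotypes$animal)
  y <- as.numeric(phenotypes[[trait]])
  drop <- is.na(y)
  if (any(drop)) {
    message("dropped ", sum(drop), " records with missing ", trait, " values")
    animal <- animal[!drop]
    y <- y[!drop]
  }
  if (anyDuplicated(animal)) {
    stop("duplicate phenotype rows for animal ", animal[duplicated(animal)][1],
         "; provide one averaged record per animal")
  }
  idx <- match(animal, p$ids)
  if (anyNA(idx)) {
    stop("phenotyped animal not in pedigree: ", animal[which(is.na(idx))[1]])
  }

  n <- length(y)
  X <- cbind(intercept = rep(1, n), f = fv[idx])
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = idx, x = 1,
                            dims = c(n, p$n), dimnames = list(NULL, p$ids))
  structure(list(
    y = y, X = X, Z_a = Z, Z_d = Z,
    record_ids = animal, animal_index = idx,
    trait = trait, include_dominance = isTRUE(include_dominance)
  ), class = "design_set")
}
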