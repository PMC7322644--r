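#' Remove extreme phenotype records
#'
#' Single-pass screen: records whose trait value deviates from the mean by
#' more than `k_sd` standard deviations are removed, with mean and SD
#' computed on the input table (the screen is not iterated, so moderately
#' extreme values survive).
#'
#' @param phenotypes Data frame with the trait column.
#' @param trait Trait column name.
#' @param k_sd Threshold in SD units (default 3).
#' @return The filtered tibble, with attributes `removed` (count) and
#'   `removed_animals`.
#' @export
clean_outliers <- function(phenotypes, trait, k_sd = 3) {
  stopifnot(is.data.frame(phenotypes), trait %in% names(phenotypes), k_sd > 0)
  y <- phenotypes[[trait]]
  stopifnot(is.numeric(y))
  if (sum(!is.na(y)) < 3L) stop("fewer than 3 records; cannot screen outliers")
  m <- mean(y, na.rm = TRUE)
  s <- sd(y, na.rm = TRUE)
  drop <- !is.na(y) & abs(y - m) > k_sd * s
  out <- tibble::as_tibble(phenotypes[!drop, , drop = FALSE])
  attr(out, "removed") <- sum(drop)
  attr(out, "removed_animals") <- if ("animal" %in% names(phenotypes)) {
    as.character(phenotypes$animal[drop])
  } else {
    which(drop)
  }
  out
}

#' Read a phenotype table from delimited text
#'
#' Comma- or tab-delimited, header required; the animal-id column is the
#' one named `animal`/`id` (or the first column), all other columns are
#' parsed as numeric traits.
#'
#' @param path File path.
#' @return A tibble with `animal` plus numeric trait columns.
#' @export
read_phenotypes <- function(path) {
  line1 <- readLines(path, n = 1L, warn = FALSE)
  delim <- if (grepl("\t", line1, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  id_col <- which(tolower(names(df)) %in% c("animal", "id"))[1]
  if (is.na(id_col)) id_col <- 1L
  out <- tibble::tibble(animal = as.character(df[[id_col]]))
  for (nm in names(df)[-id_col]) out[[nm]] <- as.numeric(df[[nm]])
  out
}

#' Configuration for an end-to-end analysis run
#'
#' @param pedigree_path,phenotype_path Input file paths.
#' @param traits Trait column names to analyze.
#' @param models Models to fit per trait: subset of
#'   `c("additive", "dominance")`.
#' @param trait_pairs List of character pairs for bivariate correlation
#'   analyses.
#' @param outlier_sd Outlier screening threshold in SDs.
#' @param chain A [chain_spec()].
#' @param prior A [prior_spec()].
#' @param fix_residual Named list/vector mapping trait name to a fixed
#'   residual variance (applied in every model for that trait).
#' @param output_dir Directory where report tables, posterior draws and the
#'   run log are written; created if missing. `NULL` disables writing.
#' @return A `run_config` list.
#' @export
run_config <- function(pedigree_path, phenotype_path, traits,
                       models = c("additive", "dominance"),
                       trait_pairs = list(), outlier_sd = 3,
                       chain = chain_spec(), prior = prior_spec(),
                       fix_residual = list(), output_dir = NULL) {
  stopifnot(length(traits) >= 1, outlier_sd > 0,
            all(models %in% c("additive", "dominance")), length(models) >= 1)
  structure(list(
    pedigree_path = pedigree_path, phenotype_path = phenotype_path,
    traits = as.character(traits), models = unique(models),
    trait_pairs = trait_pairs, outlier_sd = outlier_sd,
    chain = chain, prior = prior,
    fix_residual = as.list(fix_residual), output_dir = output_dir
  ), class = "run_config")
}

#' Read a run configuration from a flat key = value file
#'
#' Recognized keys: `pedigree`, `phenotypes`, `traits` (comma-separated),
#' `models` (comma-separated), `trait_pairs` (`L:b,a:b`), `outlier_sd`,
#' `iters`, `burnin`, `thin`, `seed`, `v0`, `nu0`, `fix_residual`
#' (`trait:value,...`), `output_dir`. Lines starting with `#` are ignored.
#'
#' @param path Config file path.
#' @param ... Overrides passed on to [run_config()] (taking precedence over
#'   the file).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  lines <- grep("^\\s*(#|$)", readLines(path, warn = FALSE),
                value = TRUE, invert = TRUE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  get <- function(k, default = NULL) if (k %in% keys) vals[match(k, keys)] else default
  split_csv <- function(x) if (is.null(x)) NULL else trimws(strsplit(x, ",")[[1]])

  pairs <- lapply(split_csv(get("trait_pairs")), function(p) {
    trimws(strsplit(p, ":")[[1]])
  })
  fixr <- list()
  for (p in split_csv(get("fix_residual"))) {
    kvp <- trimws(strsplit(p, ":")[[1]])
    fixr[[kvp[1]]] <- as.numeric(kvp[2])
  }
  seed <- get("seed")
  args <- list(
    pedigree_path = get("pedigree"),
    phenotype_path = get("phenotypes"),
    traits = split_csv(get("traits")),
    models = split_csv(get("models", "additive,dominance")),
    trait_pairs = pairs,
    outlier_sd = as.numeric(get("outlier_sd", "3")),
    chain = chain_spec(
      n_iter = as.numeric(get("iters", "500000")),
      burn_in = as.numeric(get("burnin", "20000")),
      thin = as.numeric(get("thin", "100")),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    prior = prior_spec(v0 = as.numeric(get("v0", "1")),
                       nu0 = as.numeric(get("nu0", "0.002"))),
    fix_residual = fixr,
    output_dir = get("output_dir")
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(run_config, args)
}

#' Run the full analysis pipeline
#'
#' Reads pedigree and phenotypes, builds the relationship matrices once,
#' screens each trait for extreme records, fits every requested model per
#' trait (and the bivariate additive model per trait pair), and assembles
#' posterior-summary, DIC and correlation tables. With an `output_dir` the
#' report tables, full posterior draws and a run log (settings, seeds,
#' retained-draw and cleaning counts) are written as delimited text.
#'
#' Per-fit seeds are derived deterministically from `config$chain$seed`
#' (seed + fit counter), so a rerun with the same config reproduces every
#' chain, and posterior-draw files, byte for byte.
#'
#' @param config A [run_config()].
#' @return A `run_report`: list with `summaries` (named list of tidy
#'   posterior tables), `dic` (long tibble trait x model), `correlations`
#'   (tibble per pair), `corr_matrix` (genetic correlations below the
#'   diagonal, phenotypic above), `cleaning` (records before/after per
#'   trait), `fits`, `config`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- "read inputs"
  report <- tryCatch({
    ped <- read_pedigree(config$pedigree_path)
    phen <- read_phenotypes(config$phenotype_path)
    missing_tr <- setdiff(config$traits, names(phen))
    if (length(missing_tr)) stop("trait not in phenotype file: ", missing_tr[1])

    stage <- "relationship matrices"
    rel <- relationship_matrices(ped, dominance = "dominance" %in% config$models)

    stage <- "outlier screening"
    cleaned <- list()
    cleaning <- NULL
    for (tr in config$traits) {
      cl <- clean_outliers(phen, tr, config$outlier_sd)
      cleaned[[tr]] <- cl
      cleaning <- dplyr::bind_rows(cleaning, tibble::tibble(
        trait = tr, n_before = nrow(phen), n_after = nrow(cl),
        removed = attr(cl, "removed")
      ))
    }

    fits <- list()
    summaries <- list()
    dic_tab <- NULL
    fit_counter <- 0L
    next_chain <- function() {
      fit_counter <<- fit_counter + 1L
      ch <- config$chain
      if (!is.null(ch$seed)) ch$seed <- ch$seed + fit_counter
      ch
    }
    for (tr in config$traits) {
      for (mod in config$models) {
        stage <- paste0("fit ", tr, " / ", mod)
        fit <- fit_animal_model(
          cleaned[[tr]], ped, tr, dominance = mod == "dominance",
          fix_residual = config$fix_residual[[tr]],
          prior = config$prior, chain = next_chain(), rel = rel
        )
        key <- paste(tr, mod, sep = "_")
        fits[[key]] <- fit
        summaries[[key]] <- tidy(fit)
        dic_tab <- dplyr::bind_rows(dic_tab,
          dplyr::mutate(dic(fit)[, c("dic", "p_d")], trait = tr, model = mod,
                        .before = 1))
      }
    }

    correlations <- NULL
    biv_fits <- list()
    for (pair in config$trait_pairs) {
      stage <- paste0("bivariate ", pair[1], " x ", pair[2])
      ph2 <- dplyr::inner_join(
        cleaned[[pair[1]]][, c("animal", pair[1])],
        cleaned[[pair[2]]][, c("animal", pair[2])], by = "animal")
      bfit <- fit_bivariate_model(ph2, ped, pair, prior = config$prior,
                                  chain = next_chain(), rel = rel)
      key <- paste(pair, collapse = "_")
      biv_fits[[key]] <- bfit
      cd <- correlation_draws(bfit)
      correlations <- dplyr::bind_rows(correlations, tibble::tibble(
        trait_1 = pair[1], trait_2 = pair[2],
        rg = mean(cd$rg), rg_sd = sd(cd$rg),
        rp = mean(cd$rp), rp_sd = sd(cd$rp)
      ))
    }

    corr_matrix <- NULL
    if (!is.null(correlations)) {
      trs <- unique(c(correlations$trait_1, correlations$trait_2))
      corr_matrix <- matrix(NA_real_, length(trs), length(trs),
                            dimnames = list(trs, trs))
      for (i in seq_len(nrow(correlations))) {
        r1 <- correlations$trait_1[i]
        r2 <- correlations$trait_2[i]
        corr_matrix[r2, r1] <- correlations$rg[i]  # genetic below diagonal
        corr_matrix[r1, r2] <- correlations$rp[i]  # phenotypic above
      }
    }

    structure(list(
      summaries = summaries, dic = dic_tab, correlations = correlations,
      corr_matrix = corr_matrix, cleaning = cleaning,
      fits = c(fits, biv_fits), config = config
    ), class = "run_report")
  }, error = function(e) {
    stop("pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(config$output_dir)) write_run_report(report)
  report
}

# flush all report tables, posterior draws and a run log to output_dir
write_run_report <- function(report) {
  dir <- report$config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(report$summaries)) {
    readr::write_tsv(report$summaries[[key]], file.path(dir, paste0("summary_", key, ".tsv")))
  }
  for (key in names(report$fits)) {
    readr::write_tsv(report$fits[[key]]$draws, file.path(dir, paste0("draws_", key, ".tsv")))
  }
  if (!is.null(report$dic)) readr::write_tsv(report$dic, file.path(dir, "dic.tsv"))
  if (!is.null(report$correlations)) {
    readr::write_tsv(report$correlations, file.path(dir, "correlations.tsv"))
    cm <- tibble::as_tibble(report$corr_matrix, rownames = "trait")
    readr::write_tsv(cm, file.path(dir, "correlation_matrix.tsv"))
  }
  readr::write_tsv(report$cleaning, file.path(dir, "cleaning.tsv"))
  cfg <- report$config
  log_lines <- c(
    paste0("traits: ", paste(cfg$traits, collapse = ",")),
    paste0("models: ", paste(cfg$models, collapse = ",")),
    paste0("outlier_sd: ", cfg$outlier_sd),
    paste0("chain: n_iter=", cfg$chain$n_iter, " burn_in=", cfg$chain$burn_in,
           " thin=", cfg$chain$thin, " retained=", cfg$chain$retained,
           " seed=", if (is.null(cfg$chain$seed)) "NULL" else cfg$chain$seed),
    paste0("prior: v0=", paste(cfg$prior$v0, collapse = ","), " nu0=", cfg$prior$nu0),
    paste0("cleaning: ", paste(report$cleaning$trait, report$cleaning$removed,
                               sep = ":", collapse = ",")),
    paste0("fits: ", paste(names(report$fits), collapse = ","))
  )
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", length(x$fits), " fits over traits ",
      paste(x$config$traits, collapse = ", "), "\n", sep = "")
  if (!is.null(x$dic)) print(x$dic)
  invisible(x)
}

#' Compare fitted models per trait by DIC
#'
#' Lower DIC wins; models within `margin` of each other are reported as
#' equivalent and the simpler (additive) model is preferred, encoding the
#' usual parsimony argument as a reproducible rule.
#'
#' @param x A `run_report`, or a long data frame with columns `trait`,
#'   `model`, `dic`.
#' @param margin DIC-equivalence margin (default 2).
#' @return A tibble with one row per trait: `dic_additive`,
#'   `dic_dominance`, `delta` (dominance minus additive), `equivalent`,
#'   `preferred`.
#' @export
model_compare <- function(x, margin = 2) {
  tab <- if (inherits(x, "run_report")) x$dic else tibble::as_tibble(x)
  stopifnot(all(c("trait", "model", "dic") %in% names(tab)))
  purrr::map_dfr(unique(tab$trait), function(tr) {
    sub <- tab[tab$trait == tr, ]
    if (nrow(sub) < 2L) {
      stop("model comparison for trait ", tr, " needs at least two fitted models")
    }
    da <- sub$dic[sub$model == "additive"]
    dd <- sub$dic[sub$model == "dominance"]
    stopifnot(length(da) == 1L, length(dd) == 1L)
    delta <- dd - da
    equivalent <- abs(delta) <= margin
    tibble::tibble(
      trait = tr, dic_additive = da, dic_dominance = dd, delta = delta,
      equivalent = equivalent,
      preferred = if (equivalent) "additive" else if (dd < da) "dominance" else "additive"
    )
  })
}
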