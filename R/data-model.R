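#' @keywords internal
FAMET_TRAITS <- c("FRY", "ShY", "DRY", "DMC")

pheno_required_cols <- c("trial_id", "environment", "genotype",
                         "replicate", "trait", "value")
pheno_all_cols <- c("trial_id", "environment", "year", "location",
                    "genotype", "replicate", "set_or_block", "trait", "value")

#' Construct a MET dataset from plot-level records
#'
#' A `met_dataset` holds long-format plot-level phenotype records for one
#' active trait, plus the genotype-by-environment incidence implied by the
#' non-missing records. Environments are year-by-location combinations and
#' coincide with trials in the single-stage layout used here.
#'
#' @param records Data frame of plot records with columns `trial_id`,
#'   `environment`, `genotype`, `replicate`, `trait`, `value` (and
#'   optionally `year`, `location`, `set_or_block`). `value` may be `NA`
#'   for recorded-but-lost plots; missing plots are retained, never dropped.
#' @param trait Active trait, one of `"FRY"`, `"ShY"`, `"DRY"`, `"DMC"`.
#'   Records for other traits are discarded.
#' @return An object of class `met_dataset` with elements `records`
#'   (tibble), `trait`, and `incidence` (logical genotype x environment
#'   matrix, `TRUE` where at least one non-missing plot exists).
#' @export
met_dataset <- function(records, trait) {
  trait <- match.arg(trait, FAMET_TRAITS)
  records <- tibble::as_tibble(records)
  missing_cols <- setdiff(pheno_required_cols, names(records))
  if (length(missing_cols) > 0) {
    stop("phenotype table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- records[records$trait == trait, , drop = FALSE]
  if (nrow(records) == 0) {
    stop("no records for trait '", trait, "'", call. = FALSE)
  }
  if (!is.numeric(records$value)) {
    stop("column 'value' must be numeric", call. = FALSE)
  }
  bad_inf <- which(is.infinite(records$value))
  if (length(bad_inf) > 0) {
    stop("non-finite value in row ", bad_inf[1], call. = FALSE)
  }
  if (any(records$replicate < 1 | records$replicate != round(records$replicate))) {
    stop("replicate must be a positive integer", call. = FALSE)
  }
  if (trait == "DMC") {
    bad <- which(!is.na(records$value) &
                   (records$value <= 0 | records$value >= 100))
    if (length(bad) > 0) {
      stop("DMC value outside (0, 100) in row ", bad[1], ": ",
           records$value[bad[1]], call. = FALSE)
    }
  }
  for (col in setdiff(pheno_all_cols, names(records))) {
    records[[col]] <- NA
  }
  records <- records[, pheno_all_cols]
  structure(
    list(records = records, trait = trait,
         incidence = incidence_matrix(records)),
    class = "met_dataset"
  )
}

incidence_matrix <- function(records) {
  obs <- records[!is.na(records$value), , drop = FALSE]
  g <- sort(unique(records$genotype))
  e <- sort(unique(records$environment))
  inc <- matrix(FALSE, length(g), length(e), dimnames = list(g, e))
  inc[cbind(match(obs$genotype, g), match(obs$environment, e))] <- TRUE
  inc
}

#' @export
print.met_dataset <- function(x, ...) {
  cat("<met_dataset>", x$trait, "\n")
  cat("  ", nrow(x$records), "plot records;",
      nrow(x$incidence), "genotypes x", ncol(x$incidence), "environments\n")
  cat("  filled cells:", sum(x$incidence), "/", length(x$incidence), "\n")
  invisible(x)
}

#' Read a long-format phenotype CSV
#'
#' Expects one row per plot with header columns `trial_id`, `environment`,
#' `genotype`, `replicate`, `trait`, `value` (optional: `year`, `location`,
#' `set_or_block`). Missing plot values (empty field or a declared sentinel)
#' are kept as explicit-missing records.
#'
#' @param path Path to the CSV file.
#' @param trait Trait to retain (see [met_dataset()]).
#' @param na Strings interpreted as missing values.
#' @return A [met_dataset()].
#' @export
read_phenotypes <- function(path, trait, na = c("", "NA")) {
  raw <- readr::read_csv(path, na = na, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(pheno_required_cols, names(raw))
  if (length(missing_cols) > 0) {
    stop("phenotype file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  val <- suppressWarnings(as.numeric(raw$value))
  bad <- which(!is.na(raw$value) & is.na(val))
  if (length(bad) > 0) {
    stop("non-numeric value '", raw$value[bad[1]], "' in data row ", bad[1],
         call. = FALSE)
  }
  raw$value <- val
  raw$replicate <- as.integer(raw$replicate)
  if ("year" %in% names(raw)) raw$year <- as.integer(raw$year)
  met_dataset(raw, trait = trait)
}

#' Write a MET dataset back to CSV
#'
#' Inverse of [read_phenotypes()]: writes the plot records (all columns,
#' explicit-missing values as empty fields) so that a read/write cycle
#' reproduces the records exactly.
#'
#' @param data A [met_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(data, path) {
  stopifnot(inherits(data, "met_dataset"))
  readr::write_csv(data$records, path, na = "")
  invisible(path)
}

#' Read an environment-level covariate table
#'
#' One row per environment, keyed by an `environment` column; all other
#' columns are numeric covariates (e.g. Tmax, Tmin, Tav, Rain, Rh, Wspeed,
#' Solrad, Altitude). Unknown extra columns are preserved as additional
#' covariates.
#'
#' @param path Path to the covariate CSV.
#' @return A tibble with `environment` plus numeric covariate columns.
#' @export
read_covariates <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(environment = readr::col_character(),
                                                 .default = readr::col_character()))
  if (!"environment" %in% names(tab)) {
    stop("covariate file lacks an 'environment' column", call. = FALSE)
  }
  dup <- tab$environment[duplicated(tab$environment)]
  if (length(dup) > 0) {
    stop("duplicate environment key: ", dup[1], call. = FALSE)
  }
  for (col in setdiff(names(tab), "environment")) {
    val <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(!is.na(tab[[col]]) & is.na(val))
    if (length(bad) > 0) {
      stop("non-numeric ", col, " value '", tab[[col]][bad[1]],
           "' for environment ", tab$environment[bad[1]], call. = FALSE)
    }
    tab[[col]] <- val
  }
  tab
}

#' Genotype-environment connectivity report
#'
#' Summarizes how well trials are linked by shared genotypes: pairwise
#' shared-genotype counts, per-genotype environment coverage, and the
#' connected components of the environment-sharing graph (environments are
#' linked when they share at least one genotype). Weakly linked pairs
#' (fewer than two shared genotypes) and low-coverage genotypes are
#' flagged; flags are advisory.
#'
#' @param data A [met_dataset()].
#' @param coverage_threshold Minimum fraction of environments a genotype
#'   should appear in (default 0.5, the usual screening rule for focal
#'   genotypes in stability analysis).
#' @return An object of class `connectivity_report` with elements
#'   `shared` (environment x environment shared-genotype counts),
#'   `coverage` (named per-genotype coverage fractions), `components`
#'   (membership vector of the environment-sharing graph), `weak_pairs`
#'   (tibble of environment pairs sharing < 2 genotypes),
#'   `low_coverage` (genotypes below the threshold), and `n_components`.
#' @export
connectivity_report <- function(data, coverage_threshold = 0.5) {
  stopifnot(inherits(data, "met_dataset"))
  inc <- data$incidence
  if (length(inc) == 0) stop("empty dataset", call. = FALSE)
  shared <- t(inc) %*% inc            # env x env shared genotype counts
  storage.mode(shared) <- "integer"
  coverage <- rowMeans(inc)
  adj <- (shared > 0) * 1L
  diag(adj) <- 0L
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)
  envs <- colnames(inc)
  pairs <- which(upper.tri(shared) & shared < 2, arr.ind = TRUE)
  weak_pairs <- tibble::tibble(
    env_a = envs[pairs[, 1]], env_b = envs[pairs[, 2]],
    shared = shared[pairs]
  )
  structure(
    list(shared = shared, coverage = coverage,
         components = setNames(comp$membership, envs),
         n_components = comp$no,
         weak_pairs = weak_pairs,
         low_coverage = names(coverage)[coverage < coverage_threshold],
         coverage_threshold = coverage_threshold),
    class = "connectivity_report"
  )
}

#' @export
print.connectivity_report <- function(x, ...) {
  cat("<connectivity_report>\n")
  cat("  environments:", ncol(x$shared),
      " components:", x$n_components, "\n")
  cat("  env pairs sharing < 2 genotypes:", nrow(x$weak_pairs), "\n")
  cat("  genotypes below coverage", x$coverage_threshold, ":",
      length(x$low_coverage), "\n")
  invisible(x)
}

#' Dry matter content from the gravimetric hydrostatic balance method
#'
#' Root dry matter content (%) from the weight of a root sample in air and
#' its weight immersed in water: `158.3 * w_air / (w_air - w_water) - 142.0`.
#' The buoyancy term `w_air - w_water` must be positive.
#'
#' @param weight_in_air Sample weight in air (g).
#' @param weight_in_water Sample weight in water (g).
#' @return Dry matter content in percent. Vectorized.
#' @examples
#' derive_dmc(5000, 1000) # 55.875
#' @export
derive_dmc <- function(weight_in_air, weight_in_water) {
  if (any(weight_in_water <= 0) || any(weight_in_air <= 0)) {
    stop("weights must be positive", call. = FALSE)
  }
  if (any(weight_in_air <= weight_in_water)) {
    stop("weight in air must exceed weight in water (non-positive buoyancy)",
         call. = FALSE)
  }
  158.3 * weight_in_air / (weight_in_air - weight_in_water) - 142.0
}

#' Dry root yield from fresh root yield and dry matter content
#'
#' `DRY = FRY * DMC / 100`, with FRY in t/ha and DMC in percent, so the
#' result is in t/ha.
#'
#' @param fry Fresh root yield (t/ha), non-negative.
#' @param dmc Dry matter content (%), in (0, 100).
#' @return Dry root yield (t/ha). Vectorized.
#' @export
derive_dry <- function(fry, dmc) {
  if (any(fry < 0)) stop("fry must be non-negative", call. = FALSE)
  if (any(dmc <= 0 | dmc >= 100)) {
    stop("dmc must lie in (0, 100)", call. = FALSE)
  }
  fry * dmc / 100
}
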