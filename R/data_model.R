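#' speciationRI: reproductive isolation across a speciation continuum
#'
#' Tools to estimate habitat and sexual isolation between pairs of
#' populations from behavioral trial data, derive genome-wide genetic
#' distances by calibrating F_ST against nuclear sequence divergence, and
#' model how each component of reproductive isolation accumulates with
#' genetic distance using a Bayesian pairwise linear mixed model (conjugate
#' Gibbs sampler, DIC model comparison) and single-breakpoint regression.
#'
#' @useDynLib speciationRI, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm coef resid quantile median rnorm rbeta rbinom runif
#'   sd var cor cor.test complete.cases pf dnorm setNames
#' @importFrom utils read.csv write.csv packageVersion combn
#' @keywords internal
"_PACKAGE"

# Distance (meters) beyond which two populations are classified allopatric:
# 50 generations' worth of the 12 m per-generation migration distance.
ALLOPATRY_THRESHOLD_M <- 50 * 12

#' Classify pair geography from inter-population distance
#'
#' Populations separated by more than 50 times the per-generation migration
#' distance of 12 m (i.e. strictly more than 600 m) are classified
#' allopatric; populations at or below that distance are in (potential)
#' geographic contact and classified sympatric/parapatric.
#'
#' @param distance_m Non-negative distance(s) in meters between the two
#'   population patches.
#' @return Character vector, `"allopatric"` or `"sympatric_parapatric"`.
#' @examples
#' classify_geography(c(0, 600, 601))
#' @export
classify_geography <- function(distance_m) {
  if (!is.numeric(distance_m) || any(is.na(distance_m)) || any(distance_m < 0))
    stop("distance_m must be non-negative and non-missing", call. = FALSE)
  ifelse(distance_m > ALLOPATRY_THRESHOLD_M, "allopatric", "sympatric_parapatric")
}

GEOGRAPHY_LEVELS <- c("allopatric", "sympatric_parapatric", "unknown")
STATUS_LEVELS <- c("conspecific", "heterospecific")
CHOICE_LEVELS <- c("reference", "alternative", "none")

#' Read and validate a reproductive-isolation dataset
#'
#' Reads the three CSV tables (taxon pairs, host-preference trials, mating
#' trials) and an optional newick tree, validates them against the data
#' model, and returns a canonical dataset object. Pairs are unordered:
#' taxa within a pair are canonicalized to lexicographic order so that a
#' file with taxa swapped yields an identical dataset.
#'
#' The pairs CSV must have columns `pair_id, taxon1, taxon2, species1,
#' species2` and may have `status, geography, distance_m, fst_observed,
#' nuc_divergence`. `status` is always derived from the species identities
#' (conspecific iff `species1 == species2`); a `status` column, if present,
#' is cross-checked and a mismatch is a validation error. Host-trial CSV:
#' `pair_id, taxon_id, choice` with choice in reference/alternative/none.
#' Mating-trial CSV: `pair_id, male_taxon, female_taxon, mated` (0/1).
#' Empty cells are missing values.
#'
#' @param pairs_path Path to the taxon-pair metadata CSV.
#' @param host_trials_path Path to the host-preference trial CSV.
#' @param mating_trials_path Path to the mating trial CSV, or `NULL` if
#'   sexual isolation was not assayed.
#' @param tree_path Optional path to a newick tree with branch lengths.
#' @return An object of class `ri_dataset`: a list with elements `pairs`,
#'   `host_trials`, `mating_trials` (possibly `NULL`), `tree` (possibly
#'   `NULL`).
#' @export
read_ri_dataset <- function(pairs_path, host_trials_path,
                            mating_trials_path = NULL, tree_path = NULL) {
  pairs <- read.csv(pairs_path, stringsAsFactors = FALSE,
                    na.strings = c("", "NA"))
  host <- read.csv(host_trials_path, stringsAsFactors = FALSE,
                   na.strings = c("", "NA"))
  mating <- if (!is.null(mating_trials_path))
    read.csv(mating_trials_path, stringsAsFactors = FALSE,
             na.strings = c("", "NA")) else NULL
  tree <- if (!is.null(tree_path)) ape::read.tree(tree_path) else NULL
  ri_dataset(pairs, host, mating, tree)
}

#' Construct and validate a dataset from in-memory tables
#'
#' @param pairs Data frame of taxon-pair metadata (see [read_ri_dataset()]).
#' @param host_trials Data frame of host-preference trials.
#' @param mating_trials Data frame of mating trials, or `NULL`.
#' @param tree `ape::phylo` tree, or `NULL`.
#' @return An `ri_dataset` object.
#' @export
ri_dataset <- function(pairs, host_trials, mating_trials = NULL, tree = NULL) {
  pairs <- validate_pairs(pairs)
  host_trials <- validate_host_trials(host_trials, pairs)
  if (!is.null(mating_trials))
    mating_trials <- validate_mating_trials(mating_trials, pairs)
  if (!is.null(tree)) {
    if (!inherits(tree, "phylo")) stop("tree must be a phylo object", call. = FALSE)
    if (anyDuplicated(tree$tip.label))
      stop("tree tip labels must be unique", call. = FALSE)
    if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
      stop("tree branch lengths must be non-negative", call. = FALSE)
  }
  structure(list(pairs = pairs, host_trials = host_trials,
                 mating_trials = mating_trials, tree = tree),
            class = "ri_dataset")
}

validate_pairs <- function(pairs) {
  req <- c("pair_id", "taxon1", "taxon2", "species1", "species2")
  miss <- setdiff(req, names(pairs))
  if (length(miss))
    stop("pairs table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in req) {
    bad <- which(is.na(pairs[[col]]) | pairs[[col]] == "")
    if (length(bad))
      stop(sprintf("pairs row %d: missing %s", bad[1], col), call. = FALSE)
  }
  same <- which(pairs$taxon1 == pairs$taxon2)
  if (length(same))
    stop(sprintf("pairs row %d (pair %s): taxon1 equals taxon2",
                 same[1], pairs$pair_id[same[1]]), call. = FALSE)
  if (anyDuplicated(pairs$pair_id))
    stop("duplicate pair_id in pairs table", call. = FALSE)

  # canonicalize unordered pairs: taxon1 < taxon2 lexicographically
  swap <- pairs$taxon1 > pairs$taxon2
  if (any(swap)) {
    t1 <- pairs$taxon1; s1 <- pairs$species1
    pairs$taxon1[swap] <- pairs$taxon2[swap]
    pairs$species1[swap] <- pairs$species2[swap]
    pairs$taxon2[swap] <- t1[swap]
    pairs$species2[swap] <- s1[swap]
  }

  # a taxon must map to a single species across the whole table
  tax <- data.frame(taxon = c(pairs$taxon1, pairs$taxon2),
                    species = c(pairs$species1, pairs$species2),
                    stringsAsFactors = FALSE)
  tab <- unique(tax)
  if (anyDuplicated(tab$taxon)) {
    dup <- tab$taxon[duplicated(tab$taxon)][1]
    stop("taxon ", dup, " assigned to more than one species", call. = FALSE)
  }

  derived <- ifelse(pairs$species1 == pairs$species2,
                    "conspecific", "heterospecific")
  if ("status" %in% names(pairs)) {
    given <- !is.na(pairs$status)
    bad <- which(given & pairs$status != derived)
    if (length(bad))
      stop(sprintf("pairs row %d (pair %s): status '%s' contradicts species identities",
                   bad[1], pairs$pair_id[bad[1]], pairs$status[bad[1]]),
           call. = FALSE)
  }
  pairs$status <- derived

  if (!"geography" %in% names(pairs)) pairs$geography <- NA_character_
  if ("distance_m" %in% names(pairs)) {
    pairs$distance_m <- as.numeric(pairs$distance_m)
    has_d <- !is.na(pairs$distance_m)
    if (any(pairs$distance_m[has_d] < 0))
      stop("distance_m must be non-negative", call. = FALSE)
    fill <- has_d & is.na(pairs$geography)
    if (any(fill))
      pairs$geography[fill] <- classify_geography(pairs$distance_m[fill])
  } else {
    pairs$distance_m <- NA_real_
  }
  pairs$geography[is.na(pairs$geography)] <- "unknown"
  badg <- which(!pairs$geography %in% GEOGRAPHY_LEVELS)
  if (length(badg))
    stop(sprintf("pairs row %d: unknown geography '%s'", badg[1],
                 pairs$geography[badg[1]]), call. = FALSE)

  for (col in c("fst_observed", "nuc_divergence")) {
    if (!col %in% names(pairs)) pairs[[col]] <- NA_real_
    pairs[[col]] <- as.numeric(pairs[[col]])
  }
  if (any(pairs$fst_observed < 0 | pairs$fst_observed > 1, na.rm = TRUE))
    stop("fst_observed must lie in [0, 1]", call. = FALSE)
  if (any(pairs$nuc_divergence < 0, na.rm = TRUE))
    stop("nuc_divergence must be non-negative", call. = FALSE)

  rownames(pairs) <- NULL
  pairs
}

validate_host_trials <- function(host, pairs) {
  req <- c("pair_id", "taxon_id", "choice")
  miss <- setdiff(req, names(host))
  if (length(miss))
    stop("host trials missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!host$choice %in% CHOICE_LEVELS)
  if (length(bad))
    stop(sprintf("host trial row %d: invalid choice '%s'", bad[1],
                 host$choice[bad[1]]), call. = FALSE)
  check_trial_membership(host$pair_id, host$taxon_id, pairs, "host trial")
  host
}

validate_mating_trials <- function(mating, pairs) {
  req <- c("pair_id", "male_taxon", "female_taxon", "mated")
  miss <- setdiff(req, names(mating))
  if (length(miss))
    stop("mating trials missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(mating$mated %in% c(0L, 1L)))
    stop("mated must be 0 or 1", call. = FALSE)
  check_trial_membership(mating$pair_id, mating$male_taxon, pairs, "mating trial")
  check_trial_membership(mating$pair_id, mating$female_taxon, pairs, "mating trial")
  mating
}

check_trial_membership <- function(pair_id, taxon_id, pairs, what) {
  idx <- match(pair_id, pairs$pair_id)
  orphan <- which(is.na(idx))
  if (length(orphan))
    stop(sprintf("%s row %d: unknown pair_id '%s'", what, orphan[1],
                 pair_id[orphan[1]]), call. = FALSE)
  ok <- taxon_id == pairs$taxon1[idx] | taxon_id == pairs$taxon2[idx]
  bad <- which(!ok)
  if (length(bad))
    stop(sprintf("%s row %d: taxon '%s' does not belong to pair '%s'",
                 what, bad[1], taxon_id[bad[1]], pair_id[bad[1]]),
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.ri_dataset <- function(x, ...) {
  cat("ri_dataset:", nrow(x$pairs), "taxon pairs\n")
  cat("  host trials: ", nrow(x$host_trials), "\n", sep = "")
  cat("  mating trials: ",
      if (is.null(x$mating_trials)) "none" else nrow(x$mating_trials),
      "\n", sep = "")
  cat("  tree: ", if (is.null(x$tree)) "none" else
    paste0(length(x$tree$tip.label), " tips"), "\n", sep = "")
  invisible(x)
}

#' Write per-pair estimates and model results to an output directory
#'
#' Per-pair estimates are written as CSV; each result object (posterior
#' summary, model-suite table, breakpoint fit, association statistics) is
#' serialized to JSON together with a provenance block (seed, settings,
#' package version, timestamp). A manifest of the files written is
#' returned and itself written as `manifest.json`.
#'
#' @param estimates Per-pair estimates data frame (from
#'   [estimate_all_pairs()], possibly augmented with genetic distances).
#' @param results Named list of result objects to serialize as JSON (each
#'   element becomes `<name>.json`). May be empty.
#' @param out_dir Output directory (created if needed).
#' @param provenance Named list recorded inside every JSON file (seeds,
#'   settings); the package version and timestamp are added automatically.
#' @return Invisibly, a data frame manifest with columns `file`, `kind`.
#' @export
write_ri_outputs <- function(estimates, results = list(), out_dir,
                             provenance = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory", call. = FALSE)
  provenance$package <- "speciationRI"
  provenance$version <- as.character(packageVersion("speciationRI"))
  provenance$written <- format(Sys.time(), tz = "UTC", usetz = TRUE)

  files <- character(0); kinds <- character(0)
  est_path <- file.path(out_dir, "pair_estimates.csv")
  write.csv(estimates, est_path, row.names = FALSE, na = "")
  files <- c(files, "pair_estimates.csv"); kinds <- c(kinds, "estimates")

  for (nm in names(results)) {
    path <- file.path(out_dir, paste0(nm, ".json"))
    payload <- list(provenance = provenance,
                    result = unclass_deep(results[[nm]]))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE, force = TRUE)
    files <- c(files, paste0(nm, ".json")); kinds <- c(kinds, "result")
  }
  manifest <- data.frame(file = files, kind = kinds, stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# strip S3 classes recursively so jsonlite serializes plainly
unclass_deep <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(x, unclass_deep)
    attributes(x) <- list(names = names(x))
    return(x)
  }
  if (is.data.frame(x)) return(x)
  if (is.object(x)) return(unclass(x))
  x
}

#' Re-read a per-pair estimates CSV written by [write_ri_outputs()]
#'
#' @param path Path to `pair_estimates.csv`.
#' @return Data frame with the same columns and types as written.
#' @export
read_ri_estimates <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
}
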