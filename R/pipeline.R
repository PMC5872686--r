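# End-to-end orchestration: simulate (or load) -> exposure -> deseasonalize
# -> fit -> report, with JSON manifests recording parameters, seed and input
# checksums so a run is a pure function of (inputs, config, seed).

#' Pipeline run configuration
#'
#' @param out_dir output directory.
#' @param sim a \code{\link{sim_config}} to simulate a cohort, or
#'   \code{NULL} to load one from \code{cohort_dir}.
#' @param cohort_dir directory of cohort CSV tables (used when
#'   \code{sim} is \code{NULL}).
#' @param climatology_file optional climatology CSV; default grid otherwise.
#' @param groups groups to analyse; default all in the cohort.
#' @param deseason_method \code{"residual"} or \code{"polynomial"}.
#' @param poly_degree polynomial degree for the control-based method.
#' @param weighted_exposure weight ambient dose by time outdoors.
#' @param exclude_supplement_users drop vitamin D supplement users (and
#'   their matched sets' dependants) before fitting.
#' @param seed integer seed recorded in every manifest (the simulation uses
#'   the seed in \code{sim}).
#' @return list of class \code{run_config}.
#' @export
run_config <- function(out_dir,
                       sim = sim_config(),
                       cohort_dir = NULL,
                       climatology_file = NULL,
                       groups = NULL,
                       deseason_method = c("residual", "polynomial"),
                       poly_degree = 3L,
                       weighted_exposure = TRUE,
                       exclude_supplement_users = FALSE,
                       seed = if (!is.null(sim)) sim$seed else 1L) {
  structure(list(out_dir = out_dir, sim = sim, cohort_dir = cohort_dir,
                 climatology_file = climatology_file, groups = groups,
                 deseason_method = match.arg(deseason_method),
                 poly_degree = as.integer(poly_degree),
                 weighted_exposure = isTRUE(weighted_exposure),
                 exclude_supplement_users = isTRUE(exclude_supplement_users),
                 seed = as.integer(seed)),
            class = "run_config")
}

.log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

.write_manifest <- function(path, stage, params, inputs = character(0)) {
  checks <- if (length(inputs))
    as.list(tools::md5sum(inputs)) else list()
  jsonlite::write_json(
    list(stage = stage, params = params, input_md5 = checks,
         r_version = as.character(getRversion())),
    paste0(path, ".manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
}

#' Exclude vitamin D supplement users (sensitivity analysis)
#'
#' Removes supplement users; matched sets whose case is removed lose their
#' controls too, so set integrity is preserved for conditional analyses.
#'
#' @param bundle a \code{cohort_bundle}.
#' @return the filtered \code{cohort_bundle}.
#' @export
sensitivity_exclude_supplement_users <- function(bundle) {
  p <- bundle$participants
  if (is.null(p$supplement_user)) stop("supplement_user flag absent")
  drop_ids <- p$id[p$supplement_user]
  dropped_cases <- p$matched_set_id[p$supplement_user & p$role == "case"]
  keep <- !(p$id %in% drop_ids) & !(p$matched_set_id %in% dropped_cases)
  bundle$participants <- p[keep, , drop = FALSE]
  ids <- bundle$participants$id
  bundle$residences <- bundle$residences[
    bundle$residences$participant_id %in% ids, , drop = FALSE]
  bundle$outdoors <- bundle$outdoors[
    bundle$outdoors$participant_id %in% ids, , drop = FALSE]
  bundle$serum <- bundle$serum[
    bundle$serum$participant_id %in% ids, , drop = FALSE]
  bundle
}

#' Run the full analysis pipeline
#'
#' Simulates or loads a cohort, reconstructs exposures, deseasonalizes
#' 25OHD, and emits the descriptive table, the mutually adjusted odds
#' ratios, the matched threshold-category odds ratios and the
#' determinants-of-25OHD coefficients, each as a CSV with a JSON manifest.
#' Identical config and seed give byte-identical outputs.
#'
#' @param config a \code{\link{run_config}}.
#' @return invisibly, a list with all stage results and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(f) file.path(config$out_dir, f)

  # stage: cohort
  if (!is.null(config$sim)) {
    .log_stage("simulate", "generating cohort (seed %d)", config$sim$seed)
    bundle <- generate_cohort(config$sim)
    write_cohort(bundle, outp("cohort"))
  } else {
    if (is.null(config$cohort_dir)) stop("need either sim or cohort_dir")
    .log_stage("load", "reading cohort from %s", config$cohort_dir)
    bundle <- read_cohort(config$cohort_dir)
  }
  if (config$exclude_supplement_users) {
    n0 <- nrow(bundle$participants)
    bundle <- sensitivity_exclude_supplement_users(bundle)
    .log_stage("filter", "excluded supplement users: %d -> %d participants",
               n0, nrow(bundle$participants))
  }
  audit_matching(bundle$participants)
  groups <- config$groups %||% unique(bundle$participants$group)

  clim <- if (!is.null(config$climatology_file))
    read_climatology(config$climatology_file) else default_climatology()

  # stage: exposure reconstruction
  .log_stage("exposure", "reconstructing UVR dose for %d participants",
             nrow(bundle$participants))
  expo <- exposure_summary(bundle$participants, bundle$residences,
                           bundle$outdoors, clim,
                           weighted = config$weighted_exposure)
  write.csv(expo, outp("exposures.csv"), row.names = FALSE)
  .write_manifest(outp("exposures.csv"), "exposure",
                  list(weighted = config$weighted_exposure,
                       seed = config$seed))

  # stage: deseasonalization (within group)
  .log_stage("deseason", "method=%s", config$deseason_method)
  adj <- do.call(rbind, lapply(groups, function(g) {
    p <- bundle$participants[bundle$participants$group == g, ]
    s <- bundle$serum[bundle$serum$participant_id %in% p$id, ]
    if (config$deseason_method == "residual") deseasonalize_residual(s)
    else deseasonalize_polynomial(s, p$id[p$role == "control"],
                                  degree = config$poly_degree)
  }))
  write.csv(adj, outp("adjusted_vitd.csv"), row.names = FALSE)
  .write_manifest(outp("adjusted_vitd.csv"), "deseason",
                  list(method = config$deseason_method,
                       degree = config$poly_degree, seed = config$seed))

  # stage: descriptive table
  t1 <- table_one(bundle$participants, bundle$serum)
  write.csv(t1, outp("table1.csv"), row.names = FALSE)

  # stage: mutually adjusted ORs (per group)
  .log_stage("fit", "mutually adjusted logistic models")
  mutual <- do.call(rbind, lapply(groups, function(g)
    mutual_adjustment_analysis(bundle$participants, expo, adj, g)))
  write.csv(mutual, outp("mutual_or.csv"), row.names = FALSE)

  # stage: matched threshold-category ORs
  .log_stage("fit", "matched threshold-category models")
  cat_nmol <- categorize_thresholds(
    adj$deseasonalized_nmol[match(bundle$participants$id,
                                  adj$participant_id)])
  threshold <- do.call(rbind, lapply(groups, function(g)
    tryCatch(threshold_or_analysis(bundle$participants, cat_nmol, g),
             error = function(e) {
               warning(sprintf("threshold model failed for %s: %s",
                               g, conditionMessage(e)))
               NULL
             })))
  write.csv(threshold, outp("threshold_or.csv"), row.names = FALSE)

  # stage: determinants of 25OHD (per group)
  .log_stage("fit", "determinants-of-25OHD linear models")
  determinants <- do.call(rbind, lapply(groups, function(g) {
    p <- bundle$participants[bundle$participants$group == g, ]
    s <- bundle$serum[match(p$id, bundle$serum$participant_id), ]
    cbind(group = g, determinants_of_vitd(s, expo, p),
          stringsAsFactors = FALSE)
  }))
  write.csv(determinants, outp("determinants.csv"), row.names = FALSE)

  for (f in c("table1.csv", "mutual_or.csv", "threshold_or.csv",
              "determinants.csv"))
    .write_manifest(outp(f), "fit",
                    list(groups = groups, seed = config$seed,
                         deseason = config$deseason_method),
                    inputs = c(outp("exposures.csv"),
                               outp("adjusted_vitd.csv")))
  .log_stage("done", "outputs in %s", config$out_dir)
  invisible(list(bundle = bundle, exposures = expo, adjusted = adj,
                 table1 = t1, mutual = mutual, threshold = threshold,
                 determinants = determinants, out_dir = config$out_dir))
}
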