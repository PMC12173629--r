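#' Configuration for a full multi-observer analysis
#'
#' Collects every knob of the end-to-end analysis: the simulated cohort
#' (or file-based observers), the consensus policy, sDSC tolerances, the
#' prescription, the guideline thresholds, and the seed. The defaults
#' emulate a delineation dummy run: ten observers delineating a
#' left-sided breast patient's targets with 3 mm boundary variability,
#' compared against the cohort consensus, planned at 40.05 Gy in 15
#' fractions.
#'
#' @param mode `"synthetic"` (phantom cohort) or `"files"` (observer
#'   NIfTI masks listed in `observers`).
#' @param n_observers number of simulated observers (synthetic mode).
#' @param sigma_mm observer boundary noise in mm (synthetic mode).
#' @param correlation_mm noise smoothness length in mm.
#' @param seed integer seed governing all randomness.
#' @param target_labels structure labels treated as delineated targets.
#' @param tolerances_mm sDSC tolerances in mm.
#' @param prescription_gy,n_fractions prescription.
#' @param ptv_margin_mm CTV-to-PTV margin (default 5 mm).
#' @param penumbra_mm,bath_fraction dose-model parameters.
#' @param reference_policy `"consensus"` or the id of a named observer.
#' @param plan_observers which target definitions get a plan:
#'   `"consensus"`, `"largest"`/`"smallest"` (by breast-target volume),
#'   or explicit observer ids.
#' @param phantom a [phantom_spec] (synthetic mode).
#' @param observers for `mode = "files"`: named list of observers, each
#'   a named list of structure-label -> NIfTI path.
#' @param criteria coverage criteria data.frame
#'   (default [swedish_breast_criteria()]).
#' @param output_dir directory for CSV/JSON reports, or `NULL` to skip
#'   writing.
#' @return An `analysis_config`.
#' @export
analysis_config <- function(mode = c("synthetic", "files"),
                            n_observers = 10L,
                            sigma_mm = 3,
                            correlation_mm = 10,
                            seed = 1L,
                            target_labels = c("CTV-breast", "CTVN", "CTV-IMN"),
                            tolerances_mm = c(3, 5),
                            prescription_gy = 40.05,
                            n_fractions = 15L,
                            ptv_margin_mm = 5,
                            penumbra_mm = 5,
                            bath_fraction = 0.02,
                            reference_policy = "consensus",
                            plan_observers = c("consensus", "largest",
                                               "smallest"),
                            phantom = phantom_spec(),
                            observers = NULL,
                            criteria = swedish_breast_criteria(),
                            output_dir = NULL) {
  mode <- match.arg(mode)
  if (any(tolerances_mm <= 0)) stop("tolerances must be > 0")
  if (mode == "synthetic" && n_observers < 2L)
    stop("comparison reports need at least 2 observers")
  structure(list(mode = mode, n_observers = as.integer(n_observers),
                 sigma_mm = sigma_mm, correlation_mm = correlation_mm,
                 seed = as.integer(seed), target_labels = target_labels,
                 tolerances_mm = tolerances_mm,
                 prescription_gy = prescription_gy,
                 n_fractions = as.integer(n_fractions),
                 ptv_margin_mm = ptv_margin_mm, penumbra_mm = penumbra_mm,
                 bath_fraction = bath_fraction,
                 reference_policy = reference_policy,
                 plan_observers = plan_observers, phantom = phantom,
                 observers = observers, criteria = criteria,
                 output_dir = output_dir),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Top-level YAML keys mirror the arguments of [analysis_config()];
#' unknown keys are rejected. The phantom geometry itself is not
#' configurable from YAML beyond laterality, spacing and dims.
#'
#' @param path YAML file.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  doc <- yaml::read_yaml(path)
  phantom_keys <- intersect(names(doc), c("spacing_mm", "dims", "laterality"))
  ph <- do.call(phantom_spec, doc[phantom_keys])
  doc[phantom_keys] <- NULL
  allowed <- setdiff(names(formals(analysis_config)), "phantom")
  bad <- setdiff(names(doc), allowed)
  if (length(bad))
    stop(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")))
  if (!is.null(doc$criteria)) doc$criteria <- as.data.frame(doc$criteria)
  do.call(analysis_config, c(doc, list(phantom = ph)))
}

#' Per-observer volumes with range summaries
#'
#' @param sets list of [structure_set] objects.
#' @param labels structure labels to summarize.
#' @return List with `volumes` (observer x structure volume in cc) and
#'   `summary` (per structure min/max/range cc across observers).
#' @export
summarize_volumes <- function(sets, labels) {
  stopifnot(length(sets) >= 1L)
  rows <- list(); srows <- list()
  for (lab in labels) {
    v <- c()
    for (s in sets) {
      if (!lab %in% names(s$masks)) next
      vol <- volume_cc(s$masks[[lab]])
      rows[[length(rows) + 1L]] <- data.frame(
        observer = s$observer_id, structure = lab, volume_cc = vol,
        stringsAsFactors = FALSE)
      v <- c(v, vol)
    }
    srows[[length(srows) + 1L]] <- data.frame(
      structure = lab, min_cc = min(v), max_cc = max(v),
      range_cc = max(v) - min(v), stringsAsFactors = FALSE)
  }
  list(volumes = do.call(rbind, rows), summary = do.call(rbind, srows))
}

#' Run the full multi-observer comparison and dosimetric evaluation
#'
#' Orchestrates the whole dummy-run analysis: build (or load) the
#' observer cohort, form the per-structure consensus, and emit the four
#' report families — volumes and border differences, surface dice
#' against the reference, organ-at-risk dose metrics per plan, and the
#' cross-application coverage matrix in which every plan is evaluated
#' against every observer's target definition (and the consensus).
#' Deterministic given the config and its seed.
#'
#' @param config an [analysis_config].
#' @return A `metrics_report`: list of data.frames `volumes`,
#'   `volume_summary`, `borders`, `sdsc`, `oar_dose`, `coverage`, plus
#'   `meta`. Written as CSV/JSON to `config$output_dir` when set.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  cohort <- assemble_cohort(config)
  observers <- cohort$observers
  reference_set <- cohort$reference
  body <- cohort$body
  labels <- config$target_labels

  # consensus per structure from the observers that delineated it
  consensus <- list()
  for (lab in labels) {
    masks <- lapply(Filter(function(s) lab %in% names(s$masks), observers),
                    function(s) s$masks[[lab]])
    if (!length(masks))
      stop(sprintf("analysis stage 'consensus': no observer delineated '%s'", lab))
    consensus[[lab]] <- mean_structure(masks, label = lab)
  }
  consensus_masks <- lapply(consensus, `[[`, "mask")

  reference_masks <- if (identical(config$reference_policy, "consensus")) {
    consensus_masks
  } else {
    s <- Filter(function(o) o$observer_id == config$reference_policy, observers)
    if (!length(s))
      stop(sprintf("reference observer '%s' not in cohort", config$reference_policy))
    s[[1]]$masks
  }

  vols <- summarize_volumes(observers, labels)
  borders <- do.call(rbind, lapply(labels, function(lab) {
    bd <- border_difference_table(observers, lab,
                                  laterality = cohort$laterality)
    bd$structure <- lab
    bd[, c("structure", "border", "max_difference_cm")]
  }))
  sdsc <- sdsc_table(observers, reference_masks, labels,
                     config$tolerances_mm)

  plans <- build_plans(config, observers, consensus_masks, body)
  oar <- oar_dose_table(plans, reference_set, body)
  coverage <- cross_application_table(config, plans, observers,
                                      consensus_masks, body)

  report <- structure(list(volumes = vols$volumes,
                           volume_summary = vols$summary,
                           borders = borders, sdsc = sdsc,
                           oar_dose = oar, coverage = coverage,
                           meta = list(seed = config$seed,
                                       mode = config$mode,
                                       n_observers = length(observers),
                                       prescription_gy = config$prescription_gy,
                                       n_fractions = config$n_fractions,
                                       tolerances_mm = config$tolerances_mm,
                                       package_version =
                                         as.character(utils::packageVersion("rtcompare")))),
                      class = "metrics_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d observers (%s mode), seed %d\n",
              x$meta$n_observers, x$meta$mode, x$meta$seed))
  cat(sprintf("  tables: volumes (%d rows), borders (%d), sdsc (%d), oar_dose (%d), coverage (%d)\n",
              nrow(x$volumes), nrow(x$borders), nrow(x$sdsc),
              nrow(x$oar_dose), nrow(x$coverage)))
  invisible(x)
}

assemble_cohort <- function(config) {
  if (config$mode == "synthetic") {
    reference <- make_phantom(config$phantom)
    observers <- simulate_cohort(reference, config$n_observers,
                                 config$sigma_mm, config$correlation_mm,
                                 seed = config$seed,
                                 labels = config$target_labels)
    list(observers = observers, reference = reference,
         body = get_mask(reference, "Body"),
         laterality = config$phantom$laterality)
  } else {
    if (is.null(config$observers) || length(config$observers) < 2L)
      stop("mode 'files' needs at least 2 observers with structure paths")
    sets <- list(); grid <- NULL
    for (oid in names(config$observers)) {
      s <- structure_set(oid)
      for (lab in names(config$observers[[oid]])) {
        m <- read_mask_volume(config$observers[[oid]][[lab]], label = lab)
        if (is.null(grid)) grid <- m$grid else m <- resample_mask(m, grid)
        s <- add_mask(s, m)
      }
      sets[[length(sets) + 1L]] <- s
    }
    body_paths <- vapply(config$observers,
                         function(o) "Body" %in% names(o), TRUE)
    if (!any(body_paths))
      stop("mode 'files' requires a 'Body' structure for at least one observer")
    body <- sets[[which(body_paths)[1]]]$masks[["Body"]]
    list(observers = sets, reference = sets[[1]], body = body,
         laterality = "left")
  }
}

# One plan per requested target definition: tangential on breast + IMN
# PTVs combined with AP-PA on the nodal PTV.
build_plans <- function(config, observers, consensus_masks, body) {
  ids <- config$plan_observers
  breast_vols <- vapply(observers, function(s)
    if ("CTV-breast" %in% names(s$masks)) volume_cc(s$masks[["CTV-breast"]])
    else NA_real_, 0)
  resolve <- function(id) {
    if (id == "consensus") return(list(name = "consensus",
                                       masks = consensus_masks))
    if (id == "largest") id <- observers[[which.max(breast_vols)]]$observer_id
    else if (id == "smallest")
      id <- observers[[which.min(breast_vols)]]$observer_id
    s <- Filter(function(o) o$observer_id == id, observers)
    if (!length(s)) stop(sprintf("plan observer '%s' not in cohort", id))
    list(name = id, masks = s[[1]]$masks)
  }
  plans <- list()
  for (id in ids) {
    r <- resolve(id)
    if (r$name %in% names(plans)) next  # largest/smallest may coincide
    ptvs <- plan_ptvs(r$masks, config$ptv_margin_mm, body)
    dose <- composite_plan(ptvs$tangential, ptvs$appa, body,
                           penumbra_mm = config$penumbra_mm,
                           bath_fraction = config$bath_fraction,
                           prescription_gy = config$prescription_gy,
                           n_fractions = config$n_fractions)
    plans[[r$name]] <- list(name = r$name, dose = dose, ptvs = ptvs)
  }
  plans
}

# PTVs for one target definition: per-structure margin expansions
# cropped at the patient outline (dose cannot be delivered outside the
# body, so planning volumes are evaluated within it), plus the
# combinations the reports need.
plan_ptvs <- function(masks, margin_mm, body) {
  need <- c("CTV-breast", "CTVN", "CTV-IMN")
  miss <- setdiff(need, names(masks))
  if (length(miss))
    stop(sprintf("plan target definition lacks: %s", paste(miss, collapse = ", ")))
  ptv <- function(lab, out) intersect_masks(expand_mask(masks[[lab]], margin_mm, out), body, label = out)
  ptv_breast <- ptv("CTV-breast", "PTV-breast")
  ptv_n <- ptv("CTVN", "PTVN")
  ptv_imn <- ptv("CTV-IMN", "PTV-IMN")
  list(breast = ptv_breast, nodal = ptv_n, imn = ptv_imn,
       tangential = union_masks(list(ptv_breast, ptv_imn),
                                label = "PTV-breast+IMN"),
       appa = ptv_n,
       total = union_masks(list(ptv_breast, ptv_n, ptv_imn),
                           label = "PTV-total"))
}

# Organ-at-risk dose catalogue per plan, in the layout of conventional
# breast-radiotherapy constraint tables. Organs absent from the
# reference structure set are skipped (file-based cohorts may carry
# targets only).
oar_metric_catalogue <- function() {
  data.frame(
    structure = c("Heart", "Heart", "Lung-ipsilateral", "Lung-ipsilateral",
                  "Lung-ipsilateral", "Lung-contralateral",
                  "Breast-contralateral", "Esophagus", "Esophagus",
                  "Esophagus", "Thyroid", "Humeral-head"),
    metric = c("Dmean_Gy", "V17Gy_pct", "V16Gy_pct", "Dmean_Gy", "V5Gy_pct",
               "Dmean_Gy", "Dmean_Gy", "V9Gy_cc", "V18Gy_cc", "Dmean_Gy",
               "Dmean_Gy", "Dmean_Gy"),
    stringsAsFactors = FALSE)
}

oar_dose_table <- function(plans, reference_set, body) {
  cat_ <- oar_metric_catalogue()
  rows <- list()
  for (p in plans) {
    d <- p$dose
    for (i in seq_len(nrow(cat_))) {
      lab <- cat_$structure[i]
      if (!lab %in% names(reference_set$masks)) next
      m <- reference_set$masks[[lab]]
      val <- switch(cat_$metric[i],
        Dmean_Gy = d_mean(d, m),
        V17Gy_pct = v_dose(d, m, threshold_gy = 17),
        V16Gy_pct = v_dose(d, m, threshold_gy = 16),
        V5Gy_pct = v_dose(d, m, threshold_gy = 5),
        V9Gy_cc = v_dose(d, m, threshold_gy = 9, output = "cc"),
        V18Gy_cc = v_dose(d, m, threshold_gy = 18, output = "cc"))
      rows[[length(rows) + 1L]] <- data.frame(
        plan = p$name, structure = lab, metric = cat_$metric[i],
        value = val, stringsAsFactors = FALSE)
    }
    icru <- icru_volumes(p$dose, body)
    rows[[length(rows) + 1L]] <- data.frame(
      plan = p$name, structure = "Body",
      metric = c("V105pct_cc", "treated_90pct_cc", "irradiated_50pct_cc"),
      value = c(v_dose(p$dose, body, threshold_pct = 105, output = "cc"),
                icru$treated_cc, icru$irradiated_cc),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Cross-application matrix: every plan evaluated against every target
# definition (each observer and the consensus).
cross_application_table <- function(config, plans, observers,
                                    consensus_masks, body) {
  eval_defs <- c(lapply(observers, function(s)
                   list(name = s$observer_id, masks = s$masks)),
                 list(list(name = "consensus", masks = consensus_masks)))
  rows <- list()
  for (p in plans) {
    for (ev in eval_defs) {
      masks <- coverage_masks(ev$masks, config$ptv_margin_mm, body)
      cov <- coverage_report(p$dose, masks, config$criteria)
      ptv_body_cc <- if (!is.null(masks[["PTV-total"]]))
        irradiated_outside_ptv(p$dose, masks[["PTV-total"]], body)
      else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        plan = p$name, observer = ev$name,
        structure = c(cov$structure, "PTV-Body"),
        metric = c(cov$metric, "V90pct_outside_cc"),
        threshold_pct = c(cov$threshold_pct, NA_real_),
        value = c(cov$achieved_pct, ptv_body_cc),
        pass = c(cov$pass, NA),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Assemble the combined structures the guideline criteria refer to from
# one target definition; planning volumes are cropped at the body.
coverage_masks <- function(masks, margin_mm, body) {
  out <- as.list(masks)
  have <- function(...) all(c(...) %in% names(masks))
  if (have("CTV-breast", "CTVN"))
    out[["CTV-breast+CTVN"]] <- union_masks(list(masks[["CTV-breast"]],
                                                 masks[["CTVN"]]),
                                            label = "CTV-breast+CTVN")
  if (have("CTV-breast", "CTVN", "CTV-IMN")) {
    ptv <- function(lab, nm) intersect_masks(expand_mask(masks[[lab]], margin_mm, nm), body, label = nm)
    pb <- ptv("CTV-breast", "PTV-breast")
    pn <- ptv("CTVN", "PTVN")
    pimn <- ptv("CTV-IMN", "PTV-IMN")
    out[["PTV-breast+PTVN"]] <- union_masks(list(pb, pn),
                                            label = "PTV-breast+PTVN")
    out[["PTV-total"]] <- union_masks(list(pb, pn, pimn), label = "PTV-total")
  }
  out
}

#' Write a metrics report as CSV tables with a JSON mirror
#'
#' One CSV per table with numeric cells rounded to 2 decimals (the
#' precision conventionally printed in delineation-study tables), plus a
#' `report.json` carrying full precision and the metadata. Output is
#' deterministic: rerunning the same config reproduces the files
#' byte-for-byte.
#'
#' @param report a `metrics_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("volumes", "volume_summary", "borders", "sdsc",
               "oar_dose", "coverage")) {
    df <- report[[nm]]
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) sprintf("%.2f", x))
    utils::write.csv(df, file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(unclass(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE, na = "null")
  invisible(dir)
}
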