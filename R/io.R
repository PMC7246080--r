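# Disk formats: cohorts as JSON (coordinates in mm, anterior-positive a,
# superior-positive s, isocenter origin), feature tables as CSV, models and
# evaluation reports as JSON. Every artifact embeds the seed and a config
# hash so a deleted intermediate can be regenerated bit-identically.

anatomy_to_list <- function(anatomy) {
  organs <- lapply(organ_names(), function(nm) unclass(anatomy[[nm]]))
  names(organs) <- organ_names()
  if (!is.null(anatomy$gas)) organs$gas <- unclass(anatomy$gas)
  pts <- locate_feature_points(anatomy$bone)
  list(organs = organs, landmarks = list(S = unname(pts$S), I = unname(pts$I)))
}

anatomy_from_list <- function(lst, where = "anatomy") {
  for (nm in organ_names()) {
    if (is.null(lst$organs[[nm]])) {
      stop("missing organ '", nm, "' in ", where)
    }
  }
  known <- c(organ_names(), "gas")
  extra <- setdiff(names(lst$organs), known)
  if (length(extra)) {
    warning("unknown organ key(s) preserved in ", where, ": ",
            paste(extra, collapse = ", "))
  }
  mk <- function(m) contour(m[, 1L], m[, 2L], check_simple = FALSE)
  anat <- sagittal_anatomy(
    bladder = mk(lst$organs$bladder), rectum = mk(lst$organs$rectum),
    prostate = mk(lst$organs$prostate), ctv = mk(lst$organs$ctv),
    bone = mk(lst$organs$bone),
    gas = if (!is.null(lst$organs$gas)) mk(lst$organs$gas),
    validate = FALSE)
  for (nm in extra) anat[[nm]] <- lst$organs[[nm]]
  anat
}

#' Write a cohort to JSON
#'
#' Full double precision: a write/read round trip reproduces every
#' coordinate and shift to better than 1e-9 mm.
#'
#' @param cohort A `ctv_cohort`.
#' @param path Output file.
#' @export
write_cohort <- function(cohort, path) {
  obj <- list(
    format = "ctvshift_cohort",
    seed = cohort$seed,
    n_patients = cohort$n_patients,
    n_fractions_per_patient = cohort$n_fractions_per_patient,
    config_hash = config_hash(cohort$params),
    patients = lapply(cohort$patients, function(p) {
      list(patient_id = p$patient_id,
           planning = anatomy_to_list(p$planning),
           fractions = lapply(p$fractions, function(f) {
             list(fraction = f$fraction_index,
                  shift = as.list(f$reference_shift),
                  latent = as.list(f$latent),
                  pretreatment = anatomy_to_list(f$pretreatment))
           }))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort from JSON
#'
#' @param path File written by [write_cohort()].
#' @return A `ctv_cohort` (without generator parameters; the config hash
#'   and seed are retained).
#' @export
read_cohort <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = TRUE)
  if (!identical(obj$format, "ctvshift_cohort")) {
    stop("not a ctvshift cohort file: ", path)
  }
  patients <- lapply(obj$patients, function(p) {
    planning <- anatomy_from_list(p$planning,
                                  paste0("planning/", p$patient_id))
    attr(planning, "patient_id") <- p$patient_id
    list(patient_id = p$patient_id, planning = planning,
         fractions = lapply(p$fractions, function(f) {
           structure(list(
             patient_id = p$patient_id,
             fraction_index = as.integer(f$fraction),
             pretreatment = anatomy_from_list(
               f$pretreatment, sprintf("%s/fraction %s", p$patient_id,
                                       f$fraction)),
             reference_shift = unlist(f$shift),
             latent = unlist(f$latent),
             gas = !is.null(f$pretreatment$organs$gas)),
             class = "fraction_record")
         }))
  })
  structure(list(params = NULL, seed = obj$seed,
                 n_patients = obj$n_patients,
                 n_fractions_per_patient = obj$n_fractions_per_patient,
                 config_hash = obj$config_hash,
                 patients = patients),
            class = "ctv_cohort")
}

#' Write a feature table to CSV
#'
#' Columns `patient_id, fraction, f1..f9, lr, si, ap`; full precision.
#' @param features Data frame from [extract_features()].
#' @param path Output file.
#' @export
write_feature_table <- function(features, path) {
  need <- c("patient_id", "fraction", feature_cols(), "lr", "si", "ap")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("feature table lacks column(s): ",
                         paste(miss, collapse = ", "))
  out <- features[, need]
  for (nm in setdiff(need, c("patient_id", "fraction"))) {
    out[[nm]] <- sprintf("%.12g", out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' Validates the header and numeric cells (parse failures report the
#' offending row).
#' @param path File written by [write_feature_table()].
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE)
  need <- c("patient_id", "fraction", feature_cols(), "lr", "si", "ap")
  if (!identical(names(df), need)) {
    stop("feature table header mismatch; expected: ",
         paste(need, collapse = ", "))
  }
  for (nm in setdiff(need, "patient_id")) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- which(is.na(v) & !is.na(df[[nm]]))
    if (length(bad)) {
      stop("non-numeric value in column '", nm, "', row ", bad[1L])
    }
    df[[nm]] <- v
  }
  df$fraction <- as.integer(df$fraction)
  df
}

#' Pipeline configuration
#'
#' @param n_train_patients,n_train_fractions Training cohort size (the
#'   clinical protocol this emulates used 10 patients at about 38
#'   fractions each).
#' @param n_val_patients,n_val_fractions Validation cohort size (10
#'   patients at 10 selected fractions each).
#' @param architectures Architectures to evaluate.
#' @param n_features Feature-subset size for LCV and validation.
#' @param seed Master seed; generator, click-noise, trainer and bootstrap
#'   substreams are all derived from it.
#' @param params Generator parameters.
#' @export
run_config <- function(n_train_patients = 10L, n_train_fractions = 38L,
                       n_val_patients = 10L, n_val_fractions = 10L,
                       architectures = c("br_ann", "lm_ann", "scg_ann",
                                         "svr", "rf"),
                       n_features = 1L, seed = 1L,
                       params = generator_params()) {
  structure(list(n_train_patients = as.integer(n_train_patients),
                 n_train_fractions = as.integer(n_train_fractions),
                 n_val_patients = as.integer(n_val_patients),
                 n_val_fractions = as.integer(n_val_fractions),
                 architectures = architectures,
                 n_features = as.integer(n_features),
                 seed = as.integer(seed), params = params),
            class = "ctv_run_config")
}

config_from_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  pl <- lst$params %||% list()
  lst$params <- do.call(generator_params, pl)
  do.call(run_config, lst)
}

#' Run the full simulate - extract - train - evaluate pipeline
#'
#' Simulates disjoint training and validation cohorts, extracts features,
#' runs LCV on the training cohort and the validation protocol on the
#' held-out cohort for every requested architecture, and assembles a
#' report (residual summaries plus all-pairs Steel-Dwass comparison of the
#' architectures' validation residuals). Fully reproducible from
#' `(config, seed)`.
#'
#' @param config A [run_config()] (or a path to a JSON/YAML config file).
#' @param out_dir Optional directory; when given, the cohorts, feature
#'   tables, residuals and report are written there.
#' @return The report, invisibly a list; see its `lcv` and `validation`
#'   entries.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  if (is.character(config)) config <- config_from_file(config)
  if (config$n_train_patients < 2L) {
    stop("LCV needs at least 2 training patients")
  }
  seed <- config$seed
  train <- simulate_cohort(config$params, config$n_train_patients,
                           config$n_train_fractions, derive_seed(seed, 1L))
  val <- simulate_cohort(config$params, config$n_val_patients,
                         config$n_val_fractions, derive_seed(seed, 2L))
  # distinct ids for the validation patients
  for (i in seq_along(val$patients)) {
    pid <- sprintf("V%02d", i)
    val$patients[[i]]$patient_id <- pid
    attr(val$patients[[i]]$planning, "patient_id") <- pid
    for (j in seq_along(val$patients[[i]]$fractions)) {
      val$patients[[i]]$fractions[[j]]$patient_id <- pid
    }
  }
  ftrain <- extract_features(train, seed = derive_seed(seed, 3L))
  fval <- extract_features(val, seed = derive_seed(seed, 4L))
  lcv <- list(); validation <- list()
  for (arch in config$architectures) {
    lcv[[arch]] <- run_lcv(ftrain, arch, config$n_features,
                           seed = derive_seed(seed, 5L))
    validation[[arch]] <- run_validation(ftrain, fval, arch,
                                         config$n_features,
                                         seed = derive_seed(seed, 6L))
  }
  comparison <- if (length(validation) >= 2L) {
    steel_dwass(lapply(validation, function(r) r$residual))$p
  }
  report <- list(
    config_hash = config_hash(config), seed = seed,
    n_train_fractions = nrow(ftrain) %/% 1L,
    n_val_fractions = nrow(fval) %/% 1L,
    ranking = rank_features(ftrain)$order,
    lcv = lapply(lcv, residual_summary),
    validation = lapply(validation, residual_summary),
    steel_dwass_p = comparison)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(train, file.path(out_dir, "train_cohort.json"))
    write_cohort(val, file.path(out_dir, "val_cohort.json"))
    write_feature_table(ftrain, file.path(out_dir, "train_features.csv"))
    write_feature_table(fval, file.path(out_dir, "val_features.csv"))
    utils::write.csv(do.call(rbind, validation),
                     file.path(out_dir, "validation_residuals.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
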